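# Obligate-carrier inference, carrier relatedness, additional-carrier
# counting with evidence tiers, and the 2x2 association.

test_that("an untyped connector on every transmission path is inferred", {
  fx <- fix_mdh2()
  inferred <- infer_obligate_carriers(
    fx$g, c(fx$assay$individual_id[fx$assay$call == "carrier"], fx$pair))
  expect_equal(inferred, "e")
  # a single typed carrier never triggers inference
  expect_equal(infer_obligate_carriers(fx$g, "q3"), character())
})

test_that("inference never exceeds the true carrier set in gene drops", {
  cfg <- sim_config(seed = 81L, n_founder_couples = 2L, n_generations = 4L,
                    mean_offspring = 3L)
  g <- load_genealogy(generate_genealogy(cfg)$trio)
  src <- founders(g)[1]
  set.seed(81)
  for (rep in 1:8) {
    carriers <- gene_drop(g, src, n_rep = 1L)
    true_car <- rownames(carriers)[carriers[, 1] > 0]
    if (length(true_car) < 3) next
    typed <- sample(true_car, max(2, length(true_car) %/% 2))
    non <- sample(setdiff(g$ind$id, true_car),
                  min(5, length(setdiff(g$ind$id, true_car))))
    inf <- infer_obligate_carriers(g, typed, non)
    expect_true(all(inf %in% true_car))
    expect_length(intersect(inf, non), 0L)
  }
})

test_that("carrier relatedness partitions carriers by kinship", {
  fx <- fix_mdh2()
  rel <- carrier_relatedness(fx$g, c("a", "b", "q1"), fx$pair)
  expect_true(rel$related)
  expect_length(rel$components, 1L)

  g <- load_genealogy(rbind(
    trio_row("fa", sex = "male"), trio_row("fb", sex = "female"),
    trio_row("p1", "fa", "fb", "female", 1900),
    trio_row("p2", "fa", "fb", "female", 1902),
    trio_row("z1", sex = "female"), trio_row("z2", sex = "female"),
    trio_row("z3", sex = "female")))
  rel2 <- carrier_relatedness(g, c("z1", "z2", "z3"), c("p1", "p2"))
  expect_false(rel2$related)
  expect_length(rel2$components, 3L)

  rel3 <- carrier_relatedness(g, character(), c("p1", "p2"))
  expect_true(rel3$related)
  expect_length(rel3$components, 0L)
})

test_that("additional-carrier counts reproduce the deep-pedigree pattern", {
  fx <- fix_mdh2()
  seg <- count_additional_carriers(fx$g, fx$assay, index_ids = fx$pair,
                                   recurrent_ids = fx$recurrent,
                                   breast_ids = fx$breast, full_seg = TRUE)
  expect_equal(seg$n_additional_recurrent_carriers, 2L)
  expect_equal(seg$n_additional_breastcancer_carriers, 7L)
  expect_equal(seg$n_inferred, 1L)
  expect_true("e" %in% seg$carriers)
  expect_equal(seg$calls[seg$carriers == "e"], "inferred")
  expect_equal(seg$tier, "full_cosegregation")
})

test_that("a non-cosegregating pathogenic-variant pattern yields (0, 2)", {
  fx <- fix_pms2()
  seg <- count_additional_carriers(fx$g, fx$assay, index_ids = fx$pair,
                                   recurrent_ids = fx$recurrent,
                                   breast_ids = fx$breast, full_seg = FALSE)
  expect_equal(seg$n_additional_recurrent_carriers, 0L)
  expect_equal(seg$n_additional_breastcancer_carriers, 2L)
  expect_equal(seg$tier, "multi_additional")
})

test_that("failed assays and unknown individuals are handled", {
  fx <- fix_pms2()
  failed <- data.frame(individual_id = c("e", "x1"), call = "failed",
                       stringsAsFactors = FALSE)
  seg <- count_additional_carriers(fx$g, failed, index_ids = fx$pair,
                                   recurrent_ids = fx$recurrent,
                                   breast_ids = fx$breast)
  expect_equal(seg$tier, "assay_failed")
  expect_equal(seg$n_additional_breastcancer_carriers, 0L)
  bad <- data.frame(individual_id = "ghost", call = "carrier",
                    stringsAsFactors = FALSE)
  expect_error(
    count_additional_carriers(fx$g, bad, fx$pair, fx$recurrent, fx$breast),
    "unknown individual")
})

test_that("evidence tiers reproduce the assay-study partition", {
  # 31-variant roster: 7 failed assays, 6 with no additional carrier,
  # 11 with one, 2 with two related, 2 with multiple unrelated carriers,
  # 3 fully co-segregating
  fx <- fix_mdh2()
  g2 <- load_genealogy(rbind(
    fx$g$ind[, c("id", "father", "mother", "sex", "birth_year")],
    data.frame(id = c("z1", "z2", "z3"), father = NA, mother = NA,
               sex = "female", birth_year = 1900)))
  breast2 <- c(fx$breast, "z1", "z2", "z3")
  tier_of <- function(assay, full_seg = FALSE) {
    count_additional_carriers(g2, assay, index_ids = fx$pair,
                              recurrent_ids = fx$recurrent,
                              breast_ids = breast2, full_seg = full_seg,
                              infer_obligate = FALSE)$tier
  }
  av <- function(ids, call = "carrier") {
    data.frame(individual_id = ids, call = call, stringsAsFactors = FALSE)
  }
  tiers <- c(
    replicate(7, tier_of(av(c("a", "b"), call = "failed"))),
    replicate(6, tier_of(av(c("a", "b"), call = "non-carrier"))),
    replicate(11, tier_of(av("q1"))),
    replicate(2, tier_of(av(c("q1", "q2")))),
    replicate(2, tier_of(av(c("z1", "z2", "z3")))),
    replicate(3, tier_of(av(c("a", "q1")), full_seg = TRUE)))
  expect_equal(as.vector(table(factor(tiers, levels = c(
    "assay_failed", "no_additional", "one_additional", "multi_additional",
    "unrelated_carriers", "full_cosegregation")))),
    c(7L, 6L, 11L, 2L, 2L, 3L))
})

test_that("odds ratios and Fisher p-values match their definitions", {
  r <- fisher_or(5, 5, 100, 100)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
  r2 <- fisher_or(4, 0, 7639, 7643)
  expect_equal(r2$odds_ratio, Inf)
  r3 <- fisher_or(10, 5, 7633, 7638)
  expect_equal(r3$odds_ratio, (10 * 7638) / (5 * 7633))
  rh <- fisher_or(4, 0, 10, 10, haldane = TRUE)
  expect_equal(rh$odds_ratio, (4.5 * 10.5) / (0.5 * 10.5))
  expect_error(fisher_or(-1, 0, 1, 1), "non-negative")
})

test_that("Fisher p equals exhaustive table enumeration for small margins", {
  # oracle: enumerate all tables with the observed margins, sum the
  # hypergeometric probabilities not exceeding the observed table's
  enum_p <- function(a, b, c, d) {
    m <- a + b; n <- c + d; k <- a + c
    lo <- max(0, k - n); hi <- min(k, m)
    pr <- function(x) {
      exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k))
    }
    p_obs <- pr(a)
    sum(vapply(lo:hi, pr, 0)[vapply(lo:hi, pr, 0) <= p_obs * (1 + 1e-7)])
  }
  set.seed(91)
  for (i in 1:20) {
    tot <- sample(10:200, 1)
    a <- sample(0:tot, 1); rem <- tot - a
    b <- sample(0:rem, 1); rem <- rem - b
    c <- sample(0:rem, 1); d <- rem - c
    expect_equal(fisher_or(a, b, c, d)$p_value, enum_p(a, b, c, d),
                 tolerance = 1e-8)
  }
  expect_equal(fisher_or(4, 0, 7639, 7643)$p_value, enum_p(4, 0, 7639, 7643),
               tolerance = 1e-8)
})
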