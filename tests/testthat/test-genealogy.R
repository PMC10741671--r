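# Graph construction, traversal, kinship and cluster discovery.

test_that("loading validates ids, cycles and parent sex", {
  expect_equal(nrow(load_genealogy(data.frame())$ind), 0L)

  g <- fix_nuclear()
  expect_equal(sort(founders(g)), c("f", "m"))
  expect_equal(sort(ancestors_of(g, "c1")$id), c("f", "m"))
  expect_equal(ancestors_of(g, "c1")$depth, c(1L, 1L))
  expect_equal(sort(descendants_of(g, "f")), c("c1", "c2"))
  expect_equal(ancestors_of(g, "f")$id, character())
  expect_equal(descendants_of(g, "c1"), character())

  dup <- rbind(trio_row("x", sex = "male"), trio_row("x", sex = "male"))
  expect_error(load_genealogy(dup), "duplicate.*x")

  self_parent <- trio_row("x", father = "x", sex = "male")
  expect_error(load_genealogy(self_parent), "cycle")

  bad_sex <- rbind(trio_row("p", sex = "female"),
                   trio_row("k", father = "p", sex = "male"))
  expect_error(load_genealogy(bad_sex), "father with non-male sex")

  expect_error(ancestors_of(fix_nuclear(), "nobody"), "unknown individual")
})

test_that("ancestor depths on a deep chain match exhaustive path search", {
  g <- fix_chain()
  # oracle: enumerate all upward paths by brute-force recursion
  parent_map <- setNames(Map(c, g$ind$father, g$ind$mother), g$ind$id)
  oracle_depths <- function(id) {
    out <- new.env()
    walk <- function(node, d) {
      for (p in parent_map[[node]]) {
        if (is.na(p)) next
        if (is.null(out[[p]]) || out[[p]] > d) out[[p]] <- d
        walk(p, d + 1L)
      }
    }
    walk(id, 1L)
    unlist(as.list(out))
  }
  got <- ancestors_of(g, "g4")
  exp <- oracle_depths("g4")
  expect_setequal(got$id, names(exp))
  expect_equal(got$depth[match(names(exp), got$id)], unname(exp))
})

test_that("ancestors and descendants are mutual inverses on random pedigrees", {
  for (seed in c(11L, 12L)) {
    cfg <- sim_config(seed = seed, n_founder_couples = 3L,
                      n_generations = 4L, mean_offspring = 3L)
    g <- load_genealogy(generate_genealogy(cfg)$trio)
    ids <- g$ind$id
    set.seed(seed)
    for (a in sample(ids, 15)) {
      for (b in descendants_of(g, a)) {
        expect_true(a %in% ancestors_of(g, b)$id)
      }
    }
    for (b in sample(ids, 15)) {
      for (a in ancestors_of(g, b)$id) {
        expect_true(b %in% descendants_of(g, a))
      }
    }
  }
})

test_that("kinship matches closed forms and a Monte-Carlo gene-drop oracle", {
  g <- fix_nuclear()
  expect_equal(kinship(g, "f", "c1"), 0.25)
  expect_equal(kinship(g, "c1", "c2"), 0.25)
  expect_equal(kinship(g, "f", "m"), 0)
  expect_equal(kinship(g, "c1", "f"), kinship(g, "f", "c1"))

  gc <- fix_cousins()
  expect_equal(kinship(gc, "c1", "c2"), 1 / 16)
  expect_equal(kinship(gc, "s1", "s2"), 0)

  # independent Monte-Carlo oracle: drop labelled founder alleles through
  # a hand-coded parent map and compare allele-identity frequency
  set.seed(101)
  pm <- list(p1 = c("gf", "gm"), p2 = c("gf", "gm"), aunt = c("gf", "gm"),
             c1 = c("p1", "s1"), c2 = c("s2", "p2"))
  fdr <- c("gf", "gm", "s1", "s2")
  n <- 4e4
  alle <- list()
  for (i in seq_along(fdr)) {
    alle[[fdr[i]]] <- cbind(rep(2L * i - 1L, n), rep(2L * i, n))
  }
  for (id in c("p1", "p2", "aunt", "c1", "c2")) {
    pa <- alle[[pm[[id]][1]]]; ma <- alle[[pm[[id]][2]]]
    pick <- function(m) ifelse(runif(n) < 0.5, m[, 1], m[, 2])
    alle[[id]] <- cbind(pick(pa), pick(ma))
  }
  draw <- function(m) ifelse(runif(n) < 0.5, m[, 1], m[, 2])
  phat <- mean(draw(alle[["c1"]]) == draw(alle[["c2"]]))
  se <- sqrt(phat * (1 - phat) / n)
  expect_lt(abs(phat - kinship(gc, "c1", "c2")), 3 * se)
})

test_that("relationship labels follow the closest full connection", {
  g <- fix_cousins()
  expect_equal(classify_relationship(g, "p1", "p2"), "sibling")
  expect_equal(classify_relationship(g, "aunt", "c1"), "avuncular")
  expect_equal(classify_relationship(g, "c1", "c2"), "first-cousin")
  expect_equal(classify_relationship(g, "gf", "p1"), "parent-offspring")
  expect_equal(classify_relationship(g, "gf", "c1"), "other-related")
  expect_equal(classify_relationship(g, "s1", "s2"), "unrelated")

  # half siblings (one shared parent) are not full siblings
  gh <- load_genealogy(rbind(
    trio_row("dad", sex = "male"),
    trio_row("m1", sex = "female"), trio_row("m2", sex = "female"),
    trio_row("h1", "dad", "m1", "female", 1930),
    trio_row("h2", "dad", "m2", "male", 1932)))
  expect_equal(classify_relationship(gh, "h1", "h2"), "other-related")
})

test_that("case clusters root at the closest couple and may overlap", {
  g <- fix_nuclear()
  cl <- find_case_clusters(g, c("c1", "c2"))
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$root_couple, c("f", "m"))
  expect_setequal(cl[[1]]$member_cases, c("c1", "c2"))
  expect_true(all(cl[[1]]$member_cases %in% cl[[1]]$descendant_ids))

  # one case per disjoint tree: nothing reaches min_cases = 2
  g2 <- load_genealogy(rbind(
    trio_row("a1", sex = "male"), trio_row("a2", sex = "female"),
    trio_row("ak", "a1", "a2", "female", 1930),
    trio_row("b1", sex = "male"), trio_row("b2", sex = "female"),
    trio_row("bk", "b1", "b2", "female", 1930)))
  expect_length(find_case_clusters(g2, c("ak", "bk")), 0L)

  # a case descending from two unrelated founder couples appears in the
  # cluster of each (verified against exhaustive ancestor intersection)
  g3 <- load_genealogy(rbind(
    trio_row("u1", sex = "male"), trio_row("u2", sex = "female"),
    trio_row("v1", sex = "male"), trio_row("v2", sex = "female"),
    trio_row("m1", "u1", "u2", "male", 1900),
    trio_row("m2", "u1", "u2", "female", 1902),
    trio_row("n1", "v1", "v2", "female", 1901),
    trio_row("n2", "v1", "v2", "female", 1903),
    trio_row("x", "m1", "n1", "female", 1930),
    trio_row("y", NA, "m2", "female", 1932),
    trio_row("z", NA, "n2", "female", 1931)))
  cases <- c("x", "y", "z")
  cl3 <- find_case_clusters(g3, cases)
  in_cluster <- vapply(cl3, function(c) "x" %in% c$member_cases, logical(1))
  expect_equal(sum(in_cluster), 2L)
  member_sets <- lapply(cl3, function(c) sort(c$member_cases))
  expect_true(any(vapply(member_sets, identical, logical(1), c("x", "y"))))
  expect_true(any(vapply(member_sets, identical, logical(1), c("x", "z"))))
  # oracle: pairwise ancestor-set intersections
  shares_anc <- function(a, b) {
    length(intersect(ancestors_of(g3, a)$id, ancestors_of(g3, b)$id)) > 0
  }
  expect_true(shares_anc("x", "y") && shares_anc("x", "z") &&
                !shares_anc("y", "z"))

  expect_error(find_case_clusters(g3, c("x", "ghost")), "ghost")
})

test_that("min_cases = 1 clusters are a superset of min_cases = 2 clusters", {
  cfg <- sim_config(seed = 21L, n_founder_couples = 2L, n_generations = 4L,
                    mean_offspring = 3L)
  g <- load_genealogy(generate_genealogy(cfg)$trio)
  set.seed(21)
  cases <- sample(g$ind$id, 8)
  key <- function(cl) paste(sort(cl$member_cases), collapse = "|")
  k1 <- vapply(find_case_clusters(g, cases, min_cases = 1L), key, "")
  k2 <- vapply(find_case_clusters(g, cases, min_cases = 2L), key, "")
  expect_true(all(k2 %in% k1))
})
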