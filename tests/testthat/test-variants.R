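# VCF parsing, the rare/functional/quality filter cascade, pair sharing
# and cross-pedigree summaries.

test_that("annotated VCF records round-trip through the reader", {
  p <- write_toy_vcf(tempfile(fileext = ".vcf"), character(), c("s1", "s2"))
  vs0 <- read_annotated_vcf(p)
  expect_equal(nrow(vs0$variants), 0L)
  expect_equal(vs0$samples, c("s1", "s2"))

  recs <- c(
    "1\t101\t.\tA\tT\t.\tPASS\tGENE=AAA;CSQCLASS=nonsynonymous;AF=0.0001\tGT:GQ:DP\t0/1:50:30\t0/0:60:25",
    "2\t202\t.\tG\tC\t.\tPASS\tGENE=BBB;CSQCLASS=synonymous;AF=0.01\tGT:GQ:DP\t1/1:70:40\t0/1:80:22",
    "3\t303\t.\tC\tG\t.\tPASS\tGENE=CCC;CSQCLASS=frameshift\tGT:GQ:DP\t./.:.:.\t0/1:90:33")
  p2 <- write_toy_vcf(tempfile(fileext = ".vcf"), recs, c("s1", "s2"))
  vs <- read_annotated_vcf(p2)
  expect_equal(vs$variants$chrom, c("1", "2", "3"))
  expect_equal(vs$variants$pos, c(101L, 202L, 303L))
  expect_equal(vs$variants$gene, c("AAA", "BBB", "CCC"))
  expect_equal(vs$variants$consequence,
               c("nonsynonymous", "synonymous", "frameshift"))
  expect_equal(vs$variants$pop_af, c(1e-4, 0.01, NA))
  expect_equal(unname(vs$geno[, "s1"]), c(1L, 2L, NA))
  expect_equal(unname(vs$geno[, "s2"]), c(0L, 1L, 1L))
  expect_equal(unname(vs$gq[, "s2"]), c(60, 80, 90))
  expect_equal(unname(vs$dp[, "s1"]), c(30, 40, NA))

  multi <- "1\t101\t.\tA\tT,G\t.\tPASS\tGENE=AAA;CSQCLASS=synonymous;AF=0.1\tGT\t0/1\t0/2"
  p3 <- write_toy_vcf(tempfile(fileext = ".vcf"), multi, c("s1", "s2"))
  expect_error(read_annotated_vcf(p3), "multi-allelic")

  expect_error(read_annotated_vcf(p2, samples = c("s1", "sX")),
               "sample set mismatch")
})

test_that("filter cascade keeps rare, functional, confidently-called variants", {
  # 10 records: 2 common, 3 synonymous (rare), 1 whose only carrier fails
  # GQ, 4 clean survivors
  v <- toy_variants(10,
    csq = c("nonsynonymous", "synonymous", "nonsynonymous", "synonymous",
            "frameshift", "synonymous", "splicing", "stopgain",
            "nonsynonymous", "other_exonic"),
    af = c(0.1, 1e-4, 1e-4, 2e-4, 0.05, 3e-4, 1e-4, 4e-4, 1e-4, NA))
  geno <- matrix(1L, 10, 2, dimnames = list(NULL, c("s1", "s2")))
  gq <- matrix(99, 10, 2)
  geno[7, 2] <- 0L; gq[7, 1] <- 5     # only carrier fails quality
  vs <- make_variant_set(v, geno, gq = gq)
  out <- suppressMessages(apply_variant_filters(vs))
  expect_equal(nrow(out$variants), 4L)
  expect_setequal(out$variants$gene, c("G03", "G08", "G09", "G10"))
})

test_that("the MAF boundary is strict and missing AF is kept", {
  v <- toy_variants(3, af = c(0.005, 0.0049, NA))
  geno <- matrix(1L, 3, 1, dimnames = list(NULL, "s1"))
  out <- suppressMessages(apply_variant_filters(make_variant_set(v, geno)))
  expect_setequal(out$variants$gene, c("G02", "G03"))
})

test_that("filters commute", {
  set.seed(61)
  v <- toy_variants(40,
    csq = sample(c("synonymous", "nonsynonymous", "splicing"), 40, TRUE),
    af = ifelse(runif(40) < 0.3, runif(40, 0.005, 0.2), runif(40, 0, 0.004)))
  geno <- matrix(rbinom(80, 1, 0.6), 40, 2, dimnames = list(NULL, c("a", "b")))
  gq <- matrix(sample(c(5, 99), 80, TRUE, prob = c(0.2, 0.8)), 40, 2)
  dp <- matrix(sample(c(4, 30), 80, TRUE, prob = c(0.2, 0.8)), 40, 2)
  vs <- make_variant_set(v, geno, gq = gq, dp = dp)
  joint <- suppressMessages(apply_variant_filters(vs))
  # quality-only pass first (maf/csq thresholds disabled), then the rest
  q_first <- suppressMessages(
    apply_variant_filters(vs, maf_max = 1.1, min_gq = 20, min_dp = 10))
  rest <- suppressMessages(
    apply_variant_filters(q_first, maf_max = 0.005, min_gq = 0, min_dp = 0))
  expect_equal(vkey(rest), vkey(joint))
})

test_that("pair sharing requires confident carriage in both members", {
  v <- toy_variants(12)
  geno <- matrix(0L, 12, 3, dimnames = list(NULL, c("a", "b", "c")))
  geno[1:5, "a"] <- 1L; geno[1:5, "b"] <- 1L      # shared by the pair
  geno[6:8, "a"] <- 1L                             # a only
  geno[9, "b"] <- 2L                               # b only
  geno[10:12, "c"] <- 1L                           # third sample only
  vs <- make_variant_set(v, geno)
  fvs <- suppressMessages(apply_variant_filters(vs))
  cand <- shared_in_pair(fvs, c("a", "b"), pedigree_id = "P1")
  expect_equal(nrow(cand), 5L)
  expect_true(all(vapply(strsplit(cand$carriers_among_sequenced, ","),
                         function(x) all(c("a", "b") %in% x), logical(1))))
  expect_error(shared_in_pair(fvs, c("a", "zz")), "absent from VCF")
  expect_error(shared_in_pair(fvs, "a"), "exactly two")
  # candidates are a subset of the filtered set
  expect_true(all(paste(cand$chrom, cand$pos) %in%
                    paste(fvs$variants$chrom, fvs$variants$pos)))
})

test_that("cross-pedigree recurrence counts pairs and pedigrees", {
  empty <- cross_pedigree_summary(NULL)
  expect_equal(nrow(empty$by_variant), 0L)
  expect_equal(nrow(empty$by_gene), 0L)

  cand <- data.frame(
    chrom = c("1", "2", "3"), pos = c(101L, 202L, 303L),
    ref = "A", alt = "T",
    gene = c("GENEX", "GENEX", "GENEY"),
    consequence = "nonsynonymous", pop_af = 1e-4,
    pedigree_id = c("P1", "P2", "P1"),
    pair_ids = c("a,b", "c,d", "a,b"),
    carriers_among_sequenced = "a,b", stringsAsFactors = FALSE)
  s <- cross_pedigree_summary(cand)
  expect_equal(max(s$by_variant$n_pairs), 1L)
  expect_equal(s$by_gene$n_pedigrees[s$by_gene$gene == "GENEX"], 2L)
  expect_equal(s$by_gene$n_variants[s$by_gene$gene == "GENEX"], 2L)
})

test_that("full segregation demands carriage in every sequenced case", {
  v <- toy_variants(2)
  geno <- matrix(c(1L, 1L, 1L, 1L,
                   1L, 1L, 0L, 0L), 2, 4, byrow = TRUE,
                 dimnames = list(NULL, c("a", "b", "c", "d")))
  vs <- make_variant_set(v, geno)
  cand <- shared_in_pair(vs, c("a", "b"), "P1")
  expect_true(full_segregation_among_sequenced(vs, cand[1, ],
                                               c("a", "b", "c", "d")))
  expect_false(full_segregation_among_sequenced(vs, cand[2, ],
                                                c("a", "b", "c", "d")))
  expect_true(full_segregation_among_sequenced(vs, cand[2, ], "a"))
  expect_error(full_segregation_among_sequenced(vs, cand[1, ], "zz"),
               "absent from VCF")
})

test_that("a planted founder variant is always recovered when the pair carries it", {
  for (seed in c(71L, 72L, 73L)) {
    cfg <- sim_config(seed = seed)
    sim <- simulate_population(cfg)
    if (is.na(sim$vcf_path)) next
    vs <- read_annotated_vcf(sim$vcf_path)
    fvs <- suppressMessages(apply_variant_filters(vs))
    rv <- cfg$risk_variant
    key <- paste(rv$chrom, rv$pos, rv$ref, rv$alt, sep = ":")
    keys <- paste(fvs$variants$chrom, fvs$variants$pos, fvs$variants$ref,
                  fvs$variants$alt, sep = ":")
    carrier_samples <- intersect(sim$samples, sim$truth$carriers)
    if (length(carrier_samples) >= 2) {
      expect_true(key %in% keys)
      pair <- carrier_samples[1:2]
      cand <- shared_in_pair(fvs, pair, "P")
      expect_true(key %in% paste(cand$chrom, cand$pos, cand$ref, cand$alt,
                                 sep = ":"))
    }
  }
})
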