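# Simulation experiments: type-I calibration of the excess test, power
# against a planted founder allele, and end-to-end recovery of the
# planted variant.  These are the package's standard evaluation runs;
# the problem sizes are chosen so cluster expected counts sit where the
# exact Poisson null is near-continuous (calibration) or where a
# high-risk founder line is realistically detectable (power).

founder_couple_clusters <- function(g, couples) {
  lapply(seq_len(nrow(couples)), function(k) {
    h <- couples[k, 1]
    desc <- union(descendants_of(g, couples[k, 1]),
                  descendants_of(g, couples[k, 2]))
    structure(list(cluster_id = paste0("F", k),
                   root_couple = couples[k, ],
                   member_cases = character(),
                   descendant_ids = sort(desc)),
              class = "case_cluster")
  })
}

#' Type-I calibration of the cluster excess test
#'
#' Simulates one null population (no risk allele), estimates the cohort
#' rate table by pooling a set of burn-in phenotype replicates, then
#' repeatedly redraws phenotypes and applies the excess test to every
#' founder-couple cluster against that table.  Pooling decouples the
#' rate estimate from each test replicate: in a desk-scale population a
#' handful of founder clusters partition the whole denominator, so
#' same-replicate re-estimation would force the cluster deviations to
#' sum to zero and make the test conservative -- an artefact of small
#' scale, not of the test.  Returns the fraction of cluster tests with
#' `p < alpha`.
#'
#' @param seed integer seed.
#' @param n_replicates phenotype redraws (each tests every founder
#'   cluster; default 400 over 5 founder clusters = 2000 cluster tests).
#' @param alpha significance level (default 0.05).
#' @param n_burnin pooled replicates for the rate table (default 40).
#' @param cfg population configuration; the default uses five founder
#'   couples, five generations and mean sibship 7 at baseline rate
#'   0.05 so cluster expected counts land around 20-90, where the
#'   exact Poisson null is near-continuous.
#' @return list with `fraction` (share of cluster tests flagged),
#'   `n_tests`, `expected_range` (range of per-cluster expectations).
#' @export
type1_calibration <- function(seed = 1L, n_replicates = 400L, alpha = 0.05,
                              n_burnin = 40L, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- sim_config(seed = seed, n_founder_couples = 5L,
                      n_generations = 5L, mean_offspring = 7,
                      baseline_rate = 0.05, relative_risk = 1,
                      bg_breast_rate = 0, other_cancer_rate = 0)
  }
  set.seed(seed)
  gg <- generate_genealogy(cfg, seed = NULL)
  g <- load_genealogy(gg$trio)
  clusters <- founder_couple_clusters(g, gg$founder_couples)
  rates <- NULL
  for (b in seq_len(n_burnin)) {
    phen <- simulate_phenotypes(g, NULL, cfg, seed = NULL)
    rt <- estimate_rates(g, phen$truth_cases)
    if (is.null(rates)) {
      rates <- rt
    } else {
      rates$case_count <- rates$case_count + rt$case_count
    }
  }
  rates$rate <- ifelse(rates$denom_count > 0,
                       rates$case_count / (n_burnin * rates$denom_count), 0)
  flagged <- 0L; total <- 0L; exp_last <- NULL
  for (r in seq_len(n_replicates)) {
    phen <- simulate_phenotypes(g, NULL, cfg, seed = NULL)
    res <- test_clusters(clusters, g, rates, case_ids = phen$truth_cases,
                         alpha = alpha)
    flagged <- flagged + sum(res$p_value < alpha)
    total <- total + nrow(res)
    exp_last <- res$expected
  }
  list(fraction = flagged / total, n_tests = total,
       expected_range = range(exp_last))
}

#' Power of the excess test against a planted founder risk allele
#'
#' Each replicate draws a fresh population structure, gene-drops a
#' heterozygous risk allele from the most prolific founder, draws
#' phenotypes with the configured relative risk, re-estimates rates and
#' tests the planted founder cluster.  Regenerating the structure every
#' replicate averages over pedigree shapes as well as over transmission
#' and phenotype noise, so the estimate reflects the design rather than
#' one lucky (or unlucky) family tree.  Returns the fraction of
#' replicates in which the planted cluster is flagged high-risk.
#'
#' @param seed integer seed.
#' @param n_replicates structure/gene-drop/phenotype replicates
#'   (default 150).
#' @param relative_risk carrier relative risk (default 20).
#' @param alpha significance level (default 0.05).
#' @param cfg population configuration; the default uses six founder
#'   couples, four generations, mean sibship 7, baseline rate 0.02.
#' @return list with `power`, `n_replicates`, `mean_observed`,
#'   `mean_expected` for the planted cluster.
#' @export
planted_power <- function(seed = 1L, n_replicates = 150L,
                          relative_risk = 20, alpha = 0.05, cfg = NULL) {
  if (is.null(cfg)) {
    cfg <- sim_config(seed = seed, n_founder_couples = 6L,
                      n_generations = 4L, mean_offspring = 7L,
                      baseline_rate = 0.02, relative_risk = relative_risk,
                      bg_breast_rate = 0, other_cancer_rate = 0)
  }
  set.seed(seed)
  hits <- 0L; obs <- 0; expd <- 0
  for (r in seq_len(n_replicates)) {
    gg <- generate_genealogy(cfg, seed = NULL)
    g <- load_genealogy(gg$trio)
    clusters <- founder_couple_clusters(g, gg$founder_couples)
    sizes <- vapply(clusters, function(cl) length(cl$descendant_ids),
                    integer(1))
    k <- which.max(sizes)
    planted <- clusters[[k]]
    src <- gg$founder_couples[k, 1]
    carriers <- gene_drop(g, src, n_rep = 1L)[, 1]
    phen <- simulate_phenotypes(g, carriers, cfg, seed = NULL)
    cases <- phen$truth_cases
    rates <- estimate_rates(g, cases)
    res <- test_cluster(planted, g, rates, case_ids = cases, alpha = alpha)
    hits <- hits + as.integer(res$high_risk)
    obs <- obs + res$observed; expd <- expd + res$expected
  }
  list(power = hits / n_replicates, n_replicates = n_replicates,
       mean_observed = obs / n_replicates,
       mean_expected = expd / n_replicates)
}

#' End-to-end recovery rate of the planted risk variant
#'
#' Runs the full pipeline on the default demo simulation across seeds
#' and reports how often the planted founder variant survives the
#' filters, is shared by a designated index pair in a high-risk
#' pedigree, and reaches the `full_cosegregation` tier.
#'
#' @param seeds integer vector of simulation seeds.
#' @param sim_overrides named list of [sim_config()] overrides.
#' @return list with `n_seeds`, `shared_fraction` (variant shared by a
#'   designated pair), `cosegregation_fraction` (tiered
#'   full_cosegregation).
#' @export
planted_recovery <- function(seeds = 1:11, sim_overrides = list()) {
  shared <- 0L; coseg <- 0L
  for (s in seeds) {
    res <- suppressMessages(run_pipeline(pipeline_config(
      list(simulate = sim_overrides, seed = as.integer(s)))))
    seg <- res$segregation
    if (is.null(seg)) next
    rv <- res$sim$truth$config$risk_variant
    key <- paste(rv$chrom, rv$pos, rv$ref, rv$alt, sep = ":")
    planted <- seg[seg$variant == key, , drop = FALSE]
    if (nrow(planted)) shared <- shared + 1L
    if (any(planted$tier == "full_cosegregation")) coseg <- coseg + 1L
  }
  list(n_seeds = length(seeds), shared_fraction = shared / length(seeds),
       cosegregation_fraction = coseg / length(seeds))
}
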