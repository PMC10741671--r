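# Observed-vs-expected excess testing for case clusters.
#
# Expected counts come from summing cohort-specific rates over the
# death-certified descendants of the cluster root; the test statistic is
# the exact one-sided Poisson upper tail P(X >= observed | lambda =
# expected).

#' Expected number of cases among a cluster's descendants
#'
#' Sums the cohort-specific case rate over every descendant of the
#' cluster root who holds a linked death certificate.  Spouses who
#' married into the pedigree are not descendants and do not contribute.
#' Descendants whose cohort is absent from the rate table contribute 0
#' with a warning.
#'
#' @param cluster a `case_cluster`.
#' @param g a `genealogy`.
#' @param rates a `rate_table` from [estimate_rates()].
#' @return non-negative expected count.
#' @export
expected_cases <- function(cluster, g, rates) {
  di <- idx_of(g, cluster$descendant_ids)
  di <- di[g$ind$has_death_certificate[di]]
  if (!length(di)) return(0)
  sum(rate_lookup(rates, cohorts_of(g, di)))
}

#' Exact one-sided Poisson upper-tail probability
#'
#' `P(X >= observed)` for `X ~ Poisson(expected)`.  Returns 1 when
#' `observed = 0` (the event is certain) regardless of the expectation.
#'
#' @param observed non-negative integer count (vectorised).
#' @param expected non-negative expectation (vectorised).
#' @return upper-tail probability in `(0, 1]`.
#' @export
poisson_upper_tail <- function(observed, expected) {
  if (any(observed < 0) || any(expected < 0)) {
    stop("observed and expected must be non-negative")
  }
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Test a case cluster for an excess of cases
#'
#' Compares the observed number of qualifying cases among the cluster's
#' descendants with the expectation under the cohort-specific population
#' rates, using the exact one-sided Poisson upper tail.  The observed
#' count includes every qualifying case descendant, not only the sampled
#' member cases that seeded the cluster.
#'
#' @param cluster a `case_cluster`.
#' @param g a `genealogy`.
#' @param rates a `rate_table`.
#' @param case_ids full set of qualifying case ids used for the observed
#'   count; defaults to the cluster's member cases.
#' @param alpha significance level for the high-risk flag (default 0.05).
#' @return a one-row `data.frame` with `cluster_id`, `n_descendants`,
#'   `n_death_certified`, `observed`, `expected`, `p_value`, `high_risk`.
#' @export
test_cluster <- function(cluster, g, rates, case_ids = cluster$member_cases,
                         alpha = 0.05) {
  di <- idx_of(g, cluster$descendant_ids)
  certified <- g$ind$has_death_certificate[di]
  observed <- sum(cluster$descendant_ids %in% case_ids)
  expected <- expected_cases(cluster, g, rates)
  p <- poisson_upper_tail(observed, expected)
  data.frame(cluster_id = cluster$cluster_id,
             n_descendants = length(di),
             n_death_certified = sum(certified),
             observed = observed,
             expected = expected,
             p_value = p,
             high_risk = p < alpha,
             stringsAsFactors = FALSE)
}

#' Excess test over a list of clusters
#'
#' @param clusters list of `case_cluster` objects.
#' @inheritParams test_cluster
#' @return a `data.frame` with one row per cluster (see [test_cluster()]).
#' @export
test_clusters <- function(clusters, g, rates, case_ids = NULL, alpha = 0.05) {
  rows <- lapply(clusters, function(cl) {
    test_cluster(cl, g, rates,
                 case_ids = if (is.null(case_ids)) cl$member_cases else case_ids,
                 alpha = alpha)
  })
  if (!length(rows)) {
    return(data.frame(cluster_id = character(), n_descendants = integer(),
                      n_death_certified = integer(), observed = integer(),
                      expected = double(), p_value = double(),
                      high_risk = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
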