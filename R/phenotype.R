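# Case classification, cohort assignment and cohort-specific rates.
#
# A "recurrent breast cancer case" is operational: a female with a
# primary breast cancer registry diagnosis and a death certificate
# listing breast cancer as a cause, with death at least `min_lag_years`
# after the earliest diagnosis.

#' Classify recurrent breast cancer cases
#'
#' Applies the operational case definition to a cancer-registry table
#' joined against the death information carried on the genealogy: the
#' individual must be female, have a primary breast cancer diagnosis,
#' hold a death certificate listing the breast-cancer cause token, and
#' have died at least `min_lag_years` years after the earliest breast
#' cancer diagnosis.
#'
#' @param g a `genealogy` whose individuals carry `death_year`,
#'   `has_death_certificate` and `cause_codes`.
#' @param registry a `data.frame` (or file path) with columns
#'   `individual_id`, `site`, `diagnosis_year`.
#' @param min_lag_years minimum years from earliest diagnosis to death
#'   (default 10, compared as `death_year - diagnosis_year >= lag`).
#' @param site cancer-site token defining the primary diagnosis
#'   (default `"breast"`).
#' @param cause cause-of-death token that must appear among the death
#'   certificate cause codes (default `"breast"`).
#' @return sorted character vector of case ids.
#' @export
classify_recurrent_cases <- function(g, registry, min_lag_years = 10L,
                                     site = "breast", cause = "breast") {
  if (is.character(registry) && length(registry) == 1L) {
    registry <- read_table_auto(registry)
  }
  registry <- as.data.frame(registry, stringsAsFactors = FALSE)
  if (nrow(registry) == 0L) return(character())
  i <- match(as.character(registry$individual_id), g$ind$id)
  if (anyNA(i)) {
    stop("registry record(s) reference unknown individual(s): ",
         paste(unique(registry$individual_id[is.na(i)]), collapse = ", "))
  }
  keep <- registry$site == site
  if (!any(keep)) return(character())
  dx <- tapply(as.integer(registry$diagnosis_year[keep]), i[keep], min)
  idx <- as.integer(names(dx))
  ind <- g$ind[idx, ]
  causes <- strsplit(ind$cause_codes, ";", fixed = TRUE)
  has_cause <- vapply(causes, function(x) cause %in% x, logical(1))
  ok <- ind$sex == "female" &
    ind$has_death_certificate &
    !is.na(ind$death_year) &
    has_cause &
    (ind$death_year - as.integer(dx)) >= min_lag_years
  sort(ind$id[ok])
}

#' Assign an individual to a population cohort
#'
#' Cohorts are defined by biological sex, five-year birth-year bin
#' (anchored at multiples of five) and whether the individual was born
#' in state.
#'
#' @param sex `"female"` or `"male"` (vectorised).
#' @param birth_year integer birth year (vectorised); an error if missing.
#' @param in_state logical, born in state.
#' @return character cohort keys, e.g. `"female|1900-1904|in_state"`.
#' @export
assign_cohort <- function(sex, birth_year, in_state) {
  if (anyNA(birth_year)) stop("birth_year required for cohort assignment")
  lo <- 5L * (as.integer(birth_year) %/% 5L)
  paste0(sex, "|", lo, "-", lo + 4L, "|",
         ifelse(is.na(in_state) | !in_state, "out_state", "in_state"))
}

cohorts_of <- function(g, idx = seq_len(nrow(g$ind))) {
  assign_cohort(g$ind$sex[idx], g$ind$birth_year[idx],
                g$ind$birthplace_in_state[idx])
}

#' Estimate cohort-specific case rates
#'
#' The denominator population is every individual in the genealogy with
#' a linked death certificate; the rate in each cohort is the number of
#' cases in the cohort divided by the number of death-certified
#' individuals in it.  Cases must themselves be death-certified (they
#' are defined through death certificates); a case outside the
#' denominator population is an error.
#'
#' @param g a `genealogy`.
#' @param case_ids character vector of case ids.
#' @return a `data.frame` of class `rate_table` with columns `cohort`,
#'   `case_count`, `denom_count`, `rate`.
#' @export
estimate_rates <- function(g, case_ids) {
  denom_idx <- which(g$ind$has_death_certificate)
  ci <- idx_of(g, case_ids)
  if (!all(ci %in% denom_idx)) {
    stop("case id(s) without a linked death certificate: ",
         paste(g$ind$id[setdiff(ci, denom_idx)], collapse = ", "))
  }
  keys <- cohorts_of(g, denom_idx)
  denom <- table(keys)
  case_keys <- cohorts_of(g, ci)
  cases <- table(factor(case_keys, levels = names(denom)))
  rt <- data.frame(cohort = names(denom),
                   case_count = as.integer(cases),
                   denom_count = as.integer(denom),
                   stringsAsFactors = FALSE)
  rt$rate <- ifelse(rt$denom_count > 0, rt$case_count / rt$denom_count, 0)
  rownames(rt) <- NULL
  class(rt) <- c("rate_table", "data.frame")
  rt
}

rate_lookup <- function(rates, keys) {
  r <- rates$rate[match(keys, rates$cohort)]
  miss <- is.na(r)
  if (any(miss)) {
    warning(sum(miss), " cohort(s) absent from rate table treated as rate 0")
    r[miss] <- 0
  }
  r
}
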