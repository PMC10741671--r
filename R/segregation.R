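# Downstream evaluation of candidate variants: additional-carrier
# counting from assay genotypes, obligate-carrier inference, carrier
# relatedness, evidence tiers, and the 2x2 case-control association.

#' Infer obligate carriers from typed carriers
#'
#' Given the assay-typed carriers of a variant, infers the untyped
#' individuals who must also carry it under Mendelian transmission from
#' a single ancestral source: the inference assumes the variant entered
#' through the most recent common ancestor(s) of the typed carriers and
#' returns every untyped individual lying on all transmission paths
#' from that source to some typed carrier.  Typed non-carriers are
#' never routed through and never inferred; a single typed carrier
#' yields no inference.
#'
#' @param g a `genealogy`.
#' @param typed_carriers ids typed as carrying the variant.
#' @param typed_noncarriers ids typed as not carrying it (never inferred,
#'   and excluded from transmission paths).
#' @return sorted character vector of inferred (obligate) carrier ids.
#' @export
infer_obligate_carriers <- function(g, typed_carriers,
                                    typed_noncarriers = character()) {
  carriers <- idx_of(g, unique(as.character(typed_carriers)))
  if (length(carriers) < 2L) return(character())
  noncar <- if (length(typed_noncarriers)) {
    idx_of(g, unique(as.character(typed_noncarriers)))
  } else integer()
  # candidate sources: ancestors-or-self of every typed carrier
  anc_sets <- lapply(carriers, function(i) {
    d <- ancestor_depths(g, i)
    which(!is.na(d))   # includes i itself at depth 0
  })
  common <- Reduce(intersect, anc_sets)
  common <- setdiff(common, noncar)
  if (!length(common)) return(character())
  # most recent sources: those with no strict descendant also common
  recent <- common[vapply(common, function(s) {
    !any(descendant_idx(g, s) %in% common)
  }, logical(1))]
  obligate_for <- function(src) {
    must <- integer()
    for (c in carriers) {
      if (c == src) next
      between <- intersect(which(!is.na(ancestor_depths(g, c))),
                           c(descendant_idx(g, src), src))
      between <- setdiff(between, c(src, c, carriers, noncar))
      for (v in between) {
        if (!path_exists(g, src, c, avoid = c(v, noncar))) {
          must <- c(must, v)
        }
      }
    }
    unique(must)
  }
  sets <- lapply(recent, obligate_for)
  inferred <- Reduce(intersect, sets)
  sort(g$ind$id[inferred])
}

# is there a parent->child path from src to dst avoiding `avoid`?
path_exists <- function(g, src, dst, avoid = integer()) {
  if (src == dst) return(TRUE)
  seen <- rep(FALSE, nrow(g$ind))
  seen[avoid] <- TRUE
  frontier <- setdiff(g$children[[src]], which(seen))
  while (length(frontier)) {
    if (dst %in% frontier) return(TRUE)
    seen[frontier] <- TRUE
    frontier <- unique(unlist(g$children[frontier]))
    frontier <- frontier[!seen[frontier]]
  }
  FALSE
}

#' Are additional carriers genealogically related to the index pair?
#'
#' A carrier set is "related" when every carrier has kinship greater
#' than zero with at least one index case.  Also partitions the
#' carriers into connected components under pairwise kinship > 0.
#'
#' @param g a `genealogy`.
#' @param carriers ids of additional carriers.
#' @param index_ids ids of the index (discovery) cases.
#' @return list with `related` (logical; vacuously TRUE for an empty
#'   carrier set) and `components` (list of character vectors).
#' @export
carrier_relatedness <- function(g, carriers, index_ids) {
  carriers <- unique(as.character(carriers))
  if (!length(carriers)) return(list(related = TRUE, components = list()))
  ci <- idx_of(g, carriers)
  ii <- idx_of(g, unique(as.character(index_ids)))
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  rel_to_index <- vapply(ci, function(a) {
    any(vapply(ii, function(b) phi_pair(g, a, b, memo) > 0, logical(1)))
  }, logical(1))
  # union-find over the carrier set under kinship > 0
  comp <- seq_along(ci)
  find <- function(x) { while (comp[x] != x) x <- comp[x]; x }
  if (length(ci) > 1L) {
    for (a in seq_along(ci)[-length(ci)]) {
      for (b in seq((a + 1L), length(ci))) {
        if (phi_pair(g, ci[a], ci[b], memo) > 0) {
          comp[find(b)] <- find(a)
        }
      }
    }
  }
  roots <- vapply(seq_along(ci), find, integer(1))
  components <- lapply(split(carriers, roots), sort)
  names(components) <- NULL
  list(related = all(rel_to_index), components = components)
}

#' Count additional affected carriers of a candidate variant
#'
#' Counts, from assay genotype calls plus obligate-carrier inference,
#' the carriers of a candidate variant among affected pedigree members
#' beyond the index cases, and assigns an evidence tier.
#'
#' Assay calls are `carrier`, `non-carrier` or `failed`; `inferred`
#' calls are produced only by the obligate-carrier logic, never read
#' from input.  Counts exclude the index ids (the discovery pair and
#' any other sequenced index cases).
#'
#' Tiers: `assay_failed` (no successful assay call), `no_additional`,
#' `one_additional`, `multi_additional`, `unrelated_carriers`
#' (two or more additional carriers, not all related to the index
#' cases), `full_cosegregation` (set by the caller when the variant is
#' carried by every sequenced case in the pedigree and all additional
#' carriers are related).
#'
#' @param g a `genealogy`.
#' @param assay `data.frame` with columns `individual_id`, `call` for
#'   this variant (calls in carrier/non-carrier/failed).
#' @param index_ids ids of the index (discovery) pair, excluded from all
#'   counts.
#' @param recurrent_ids ids of recurrent breast cancer cases; additional
#'   carriers among these fill `n_additional_recurrent_carriers`.
#' @param breast_ids ids of all breast cancer cases;
#'   `n_additional_breastcancer_carriers` counts carriers among the
#'   non-recurrent breast cancer cases (the two counts are disjoint,
#'   mirroring the two assay-evidence columns of a segregation report).
#' @param full_seg logical: does the variant fully co-segregate among
#'   the sequenced cases (see
#'   [full_segregation_among_sequenced()])?
#' @param infer_obligate infer obligate carriers among untyped
#'   individuals and include them (flagged) in the counts
#'   (default TRUE).
#' @return list of class `segregation_summary`: carrier ids and calls,
#'   `n_additional_recurrent_carriers`,
#'   `n_additional_breastcancer_carriers`, `n_inferred`,
#'   `carriers_related_to_pair`, `tier`.
#' @export
count_additional_carriers <- function(g, assay, index_ids, recurrent_ids,
                                      breast_ids, full_seg = FALSE,
                                      infer_obligate = TRUE) {
  assay <- as.data.frame(assay, stringsAsFactors = FALSE)
  if (nrow(assay)) idx_of(g, assay$individual_id)  # errors on unknown ids
  index_ids <- unique(as.character(index_ids))
  ok <- assay$call %in% c("carrier", "non-carrier")
  if (nrow(assay) > 0L && !any(ok)) {
    return(structure(list(carriers = character(), calls = character(),
                          n_additional_recurrent_carriers = 0L,
                          n_additional_breastcancer_carriers = 0L,
                          n_inferred = 0L,
                          carriers_related_to_pair = NA,
                          tier = "assay_failed"),
                     class = "segregation_summary"))
  }
  typed_car <- assay$individual_id[assay$call == "carrier"]
  typed_non <- assay$individual_id[assay$call == "non-carrier"]
  inferred <- character()
  if (infer_obligate) {
    inferred <- infer_obligate_carriers(g, c(typed_car, index_ids), typed_non)
    inferred <- setdiff(inferred, c(typed_car, typed_non, index_ids))
  }
  carriers <- setdiff(unique(c(typed_car, inferred)), index_ids)
  calls <- ifelse(carriers %in% inferred, "inferred", "carrier")
  n_rec <- sum(carriers %in% recurrent_ids)
  n_brc <- sum(carriers %in% setdiff(breast_ids, recurrent_ids))
  n_tot <- n_rec + n_brc
  affected_carriers <- carriers[carriers %in% union(breast_ids, recurrent_ids)]
  rel <- carrier_relatedness(g, affected_carriers, index_ids)
  tier <- if (full_seg && rel$related) {
    "full_cosegregation"
  } else if (n_tot >= 2L && !rel$related) {
    "unrelated_carriers"
  } else if (n_tot >= 2L) {
    "multi_additional"
  } else if (n_tot == 1L) {
    "one_additional"
  } else {
    "no_additional"
  }
  structure(list(carriers = carriers, calls = calls,
                 n_additional_recurrent_carriers = n_rec,
                 n_additional_breastcancer_carriers = n_brc,
                 n_inferred = length(inferred),
                 carriers_related_to_pair = rel$related,
                 tier = tier),
            class = "segregation_summary")
}

#' @export
print.segregation_summary <- function(x, ...) {
  cat("segregation:", x$tier, "-",
      x$n_additional_recurrent_carriers, "additional recurrent /",
      x$n_additional_breastcancer_carriers, "additional breast cancer carriers",
      if (x$n_inferred) paste0("(", x$n_inferred, " inferred)") else "", "\n")
  invisible(x)
}

#' 2x2 case-control association: odds ratio and Fisher exact p
#'
#' Cross-sectional association of carrier status with case status:
#' `a` carrier cases, `b` carrier controls, `c` non-carrier cases, `d`
#' non-carrier controls.  The odds ratio is the sample cross-product
#' `ad/bc` (infinite when `b = 0` or `c = 0` with a non-zero numerator;
#' optionally the Haldane-Anscombe +0.5 correction); the p-value is the
#' two-sided Fisher exact test (sum over tables with the fixed margins
#' whose probability does not exceed the observed table's).
#'
#' @param a,b,c,d non-negative integer cell counts.
#' @param haldane apply the +0.5 continuity correction to the odds
#'   ratio (default FALSE).
#' @return a one-row `data.frame` with the four counts, `odds_ratio`
#'   and `p_value`.
#' @export
fisher_or <- function(a, b, c, d, haldane = FALSE) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) stop("cell counts must be non-negative")
  if (any(counts != round(counts))) stop("cell counts must be integers")
  or <- if (haldane) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else {
    (a * d) / (b * c)
  }
  p <- stats::fisher.test(matrix(c(a, b, c, d), nrow = 2, byrow = TRUE))$p.value
  data.frame(a = a, b = b, c = c, d = d,
             odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
}
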