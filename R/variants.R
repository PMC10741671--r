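# Rare shared-variant discovery from annotated multi-sample VCFs.
#
# Variants are held in a `variant_set`: a record table (chrom, pos, ref,
# alt, gene, consequence, pop_af) plus per-sample matrices of alternate
# allele counts, genotype quality and depth.  A carrier is a genotype
# with at least one alternate allele (dominant model); a genotype that
# fails the quality thresholds is set to missing.

#' Read an annotated multi-sample VCF
#'
#' Parses a VCF (v4.x) whose INFO field carries `GENE`, `CSQCLASS`
#' (consequence class: synonymous, nonsynonymous, frameshift, splicing,
#' stopgain, other_exonic) and `AF` (population allele frequency), and
#' whose FORMAT includes `GT` plus, when available, `GQ` and `DP`.
#' Multi-allelic records are refused: split them upstream
#' (e.g. `bcftools norm -m-`).
#'
#' @param path path to an uncompressed or bgzipped VCF.
#' @param samples optional character vector of expected sample ids; an
#'   error if the VCF sample set differs.
#' @return a `variant_set`: list with `variants` (data.frame), `geno`
#'   (alt-allele count matrix, NA = missing call), `gq`, `dp`
#'   (integer matrices, NA where the VCF lacks the field), `samples`.
#' @export
read_annotated_vcf <- function(path, samples = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  smp <- colnames(v@gt)[-1]
  if (is.null(smp)) smp <- character()
  if (!is.null(samples) && !setequal(smp, samples)) {
    stop("VCF sample set mismatch; expected: ",
         paste(samples, collapse = ", "), " got: ",
         paste(smp, collapse = ", "))
  }
  n <- nrow(fix)
  if (is.null(n) || n == 0L) {
    return(empty_variant_set(smp))
  }
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    stop("multi-allelic record(s) at line(s) ", paste(which(multi), collapse = ", "),
         "; split multi-allelic sites upstream (e.g. bcftools norm -m-)")
  }
  info_get <- function(key) {
    m <- regmatches(fix[, "INFO"],
                    regexpr(paste0("(^|;)", key, "=[^;]*"), fix[, "INFO"]))
    out <- rep(NA_character_, n)
    hit <- lengths(regmatches(fix[, "INFO"],
                              gregexpr(paste0("(^|;)", key, "="), fix[, "INFO"]))) > 0
    out[hit] <- sub(paste0(".*", key, "="), "", m)
    out
  }
  variants <- data.frame(
    chrom = fix[, "CHROM"],
    pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = alt,
    gene = info_get("GENE"),
    consequence = info_get("CSQCLASS"),
    pop_af = suppressWarnings(as.numeric(info_get("AF"))),
    stringsAsFactors = FALSE
  )
  bad_pos <- which(is.na(variants$pos))
  if (length(bad_pos)) {
    stop("malformed VCF record (unparseable POS) at data line(s) ",
         paste(bad_pos, collapse = ", "))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  geno <- alt_count_from_gt(gt)
  gq <- num_fmt(v, "GQ", dim(geno))
  dp <- num_fmt(v, "DP", dim(geno))
  dimnames(geno) <- dimnames(gq) <- dimnames(dp) <- list(NULL, smp)
  structure(list(variants = variants, geno = geno, gq = gq, dp = dp,
                 samples = smp),
            class = "variant_set")
}

empty_variant_set <- function(samples) {
  m <- matrix(integer(), nrow = 0, ncol = length(samples),
              dimnames = list(NULL, samples))
  structure(list(
    variants = data.frame(chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          gene = character(), consequence = character(),
                          pop_af = double(), stringsAsFactors = FALSE),
    geno = m, gq = m, dp = m, samples = samples), class = "variant_set")
}

alt_count_from_gt <- function(gt) {
  cnt <- function(x) {
    out <- rep(NA_integer_, length(x))
    ok <- !is.na(x) & !grepl("\\.", x)
    alleles <- strsplit(x[ok], "[/|]")
    out[ok] <- vapply(alleles, function(a) sum(a != "0"), integer(1))
    out
  }
  res <- apply(gt, 2, cnt)
  if (is.null(dim(res))) res <- matrix(res, nrow = nrow(gt))
  res
}

num_fmt <- function(v, key, dims) {
  fmt <- v@gt[, 1][1]
  if (!is.na(fmt) && key %in% strsplit(fmt, ":", fixed = TRUE)[[1]]) {
    m <- suppressWarnings(
      apply(vcfR::extract.gt(v, element = key), 2, as.numeric))
    if (is.null(dim(m))) m <- matrix(m, nrow = dims[1])
    m
  } else {
    matrix(NA_real_, nrow = dims[1], ncol = dims[2])
  }
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$variants), "variants x",
      length(x$samples), "samples\n")
  invisible(x)
}

subset_variant_set <- function(vs, keep) {
  structure(list(variants = vs$variants[keep, , drop = FALSE],
                 geno = vs$geno[keep, , drop = FALSE],
                 gq = vs$gq[keep, , drop = FALSE],
                 dp = vs$dp[keep, , drop = FALSE],
                 samples = vs$samples),
            class = "variant_set")
}

#' Rare/functional/quality filter cascade
#'
#' Keeps variants that are rare in the reference population
#' (`pop_af < maf_max`, strictly; a missing frequency is treated as rare
#' and counted in a message), non-synonymous in the broad sense
#' (consequence other than `synonymous`), and confidently called:
#' carrier genotypes failing `GQ >= min_gq` or `DP >= min_dp` are set to
#' missing, and a record left with no confident carrier is dropped.
#' Where the VCF carries no GQ/DP the quality filter does not apply.
#' The three filters commute; the survivor set does not depend on the
#' order of application.
#'
#' @param vs a `variant_set`.
#' @param maf_max maximum population allele frequency, exclusive
#'   (default 0.005).
#' @param min_gq minimum genotype quality for a confident call
#'   (default 20).
#' @param min_dp minimum read depth for a confident call (default 10).
#' @return the filtered `variant_set` (quality-failed genotypes set NA).
#' @export
apply_variant_filters <- function(vs, maf_max = 0.005, min_gq = 20L,
                                  min_dp = 10L) {
  n_missing_af <- sum(is.na(vs$variants$pop_af))
  if (n_missing_af > 0) {
    message(n_missing_af,
            " variant(s) with missing population AF retained as rare")
  }
  rare <- is.na(vs$variants$pop_af) | vs$variants$pop_af < maf_max
  functional <- is.na(vs$variants$consequence) |
    vs$variants$consequence != "synonymous"
  bad_q <- (!is.na(vs$gq) & vs$gq < min_gq) | (!is.na(vs$dp) & vs$dp < min_dp)
  geno <- vs$geno
  geno[bad_q] <- NA_integer_
  has_carrier <- rowSums(geno >= 1L, na.rm = TRUE) > 0
  keep <- rare & functional & has_carrier
  out <- vs
  out$geno <- geno
  subset_variant_set(out, which(keep))
}

#' Variants shared by an affected relative pair
#'
#' Returns the filtered variants for which both members of the pair
#' carry at least one confidently-called alternate allele.
#'
#' @param vs a (typically already filtered) `variant_set`.
#' @param pair character vector of the two index sample ids.
#' @param pedigree_id token identifying the pedigree of origin.
#' @return a `data.frame` of candidate variants: variant columns plus
#'   `pedigree_id`, `pair_ids` (comma-joined), and
#'   `carriers_among_sequenced` (comma-joined sample ids carrying it).
#' @export
shared_in_pair <- function(vs, pair, pedigree_id = NA_character_) {
  if (length(pair) != 2L) stop("pair must contain exactly two sample ids")
  miss <- setdiff(pair, vs$samples)
  if (length(miss)) {
    stop("sample(s) absent from VCF: ", paste(miss, collapse = ", "))
  }
  carrier <- !is.na(vs$geno) & vs$geno >= 1L
  shared <- carrier[, pair[1]] & carrier[, pair[2]]
  idx <- which(shared)
  out <- vs$variants[idx, , drop = FALSE]
  out$pedigree_id <- rep(pedigree_id, length(idx))
  out$pair_ids <- rep(paste(pair, collapse = ","), length(idx))
  out$carriers_among_sequenced <- vapply(idx, function(i) {
    paste(vs$samples[carrier[i, ]], collapse = ",")
  }, character(1))
  rownames(out) <- NULL
  out
}

variant_key <- function(df) {
  paste(df$chrom, df$pos, df$ref, df$alt, sep = ":")
}

#' Cross-pedigree recurrence summaries of candidate variants
#'
#' Tabulates, over the candidates from all pairs, how many distinct
#' pairs share each variant and how many distinct pedigrees contribute
#' (distinct) variants in each gene.
#'
#' @param candidates row-bound candidate tables from [shared_in_pair()].
#' @return list with `by_variant` (variant key, gene, `n_pairs`) and
#'   `by_gene` (gene, `n_variants`, `n_pedigrees`).
#' @export
cross_pedigree_summary <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0L) {
    return(list(
      by_variant = data.frame(variant = character(), gene = character(),
                              n_pairs = integer(), stringsAsFactors = FALSE),
      by_gene = data.frame(gene = character(), n_variants = integer(),
                           n_pedigrees = integer(), stringsAsFactors = FALSE)))
  }
  key <- variant_key(candidates)
  by_variant <- aggregate(
    list(n_pairs = candidates$pair_ids),
    by = list(variant = key, gene = candidates$gene),
    FUN = function(x) length(unique(x)))
  uv <- !duplicated(paste(key, candidates$pedigree_id))
  by_gene <- aggregate(
    list(n_variants = key[uv], n_pedigrees = candidates$pedigree_id[uv]),
    by = list(gene = candidates$gene[uv]),
    FUN = function(x) length(unique(x)))
  list(by_variant = by_variant[order(-by_variant$n_pairs, by_variant$variant), ],
       by_gene = by_gene[order(-by_gene$n_pedigrees, by_gene$gene), ])
}

#' Does a candidate fully segregate among the sequenced cases?
#'
#' TRUE when every sequenced case of the pedigree carries at least one
#' confidently-called alternate allele of the candidate variant.
#'
#' @param vs the filtered `variant_set`.
#' @param candidate one row of a candidate table (from
#'   [shared_in_pair()]).
#' @param sequenced_ids sample ids of all sequenced cases in the
#'   candidate's pedigree (must be VCF samples).
#' @return logical.
#' @export
full_segregation_among_sequenced <- function(vs, candidate, sequenced_ids) {
  miss <- setdiff(sequenced_ids, vs$samples)
  if (length(miss)) {
    stop("sequenced id(s) absent from VCF: ", paste(miss, collapse = ", "))
  }
  i <- match(variant_key(candidate), variant_key(vs$variants))
  if (is.na(i)) stop("candidate variant not present in variant set")
  gt <- vs$geno[i, sequenced_ids]
  all(!is.na(gt) & gt >= 1L)
}
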