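# End-to-end orchestration: classify -> rates -> clusters -> excess ->
# filter/share -> segregation/association, with per-stage TSV outputs.
# Each stage is also callable on its own from the files the previous
# stage wrote, and staged execution reproduces run_pipeline() exactly.

#' Pipeline configuration
#'
#' Reads (or builds) the configuration for [run_pipeline()].  Either a
#' `simulate` block (passed to [sim_config()]) or explicit input paths
#' (`trio`, `registry`, `deaths`, `vcf`) must be present.
#'
#' @param config a named list, or path to a YAML file holding one.
#' @param overrides named list of parameter overrides (flat keys win
#'   over file values).
#' @return validated configuration list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list(), overrides = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  defaults <- list(min_lag_years = 10L, maf_max = 0.005, alpha = 0.05,
                   min_cases = 2L, min_gq = 20L, min_dp = 10L,
                   seed = 1L, out_dir = NULL)
  cfg <- utils::modifyList(defaults, config)
  cfg <- utils::modifyList(cfg, overrides[!vapply(overrides, is.null, logical(1))])
  has_inputs <- !is.null(cfg$trio) && !is.null(cfg$registry) &&
    !is.null(cfg$deaths)
  if (is.null(cfg$simulate) && !has_inputs) {
    stop("config needs either a `simulate` block or input paths ",
         "(trio, registry, deaths)")
  }
  stopifnot(cfg$maf_max > 0, cfg$maf_max <= 1,
            cfg$alpha > 0, cfg$alpha < 1,
            cfg$min_cases >= 1, cfg$min_lag_years >= 0)
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

#' Select the index relative pair of a cluster
#'
#' Among the sampled member cases of a cluster, picks the related pair
#' with the smallest positive kinship (the most distant documented
#' relationship, cousin-like pairs preferred over sibs), breaking ties
#' by id order.  Distant pairs share the least background genome, so
#' variants they share are the strongest candidates.
#'
#' @param g a `genealogy`.
#' @param cluster a `case_cluster`.
#' @param sampled ids of sampled (sequenced) cases.
#' @return character vector of two ids, or NULL if fewer than two
#'   sampled member cases.
#' @export
select_index_pair <- function(g, cluster, sampled) {
  mem <- sort(intersect(cluster$member_cases, sampled))
  if (length(mem) < 2L) return(NULL)
  best <- NULL; best_phi <- Inf
  for (i in seq_len(length(mem) - 1L)) {
    for (j in seq((i + 1L), length(mem))) {
      phi <- kinship(g, mem[i], mem[j])
      if (phi > 0 && phi < best_phi) {
        best <- c(mem[i], mem[j]); best_phi <- phi
      }
    }
  }
  if (is.null(best)) mem[1:2] else best
}

#' Run the full analysis pipeline
#'
#' Executes, in order: case classification, cohort rate estimation,
#' cluster discovery over the sampled cases, the Poisson excess test,
#' variant filtering and pair sharing in each high-risk cluster,
#' cross-pedigree summaries, and (when assay genotypes are supplied)
#' segregation evaluation.  Per-stage TSVs are written under
#' `cfg$out_dir` when set, along with the resolved configuration and
#' seed; stage counts are logged to stderr.
#'
#' @param cfg a `pipeline_config` (or bare list / YAML path accepted by
#'   [pipeline_config()]).
#' @return list of class `pipeline_result` with elements `cases`,
#'   `sampled`, `rates`, `clusters`, `excess`, `candidates`,
#'   `summary` (cross-pedigree recurrence), `segregation`, `sim`
#'   (when simulated).
#' @export
run_pipeline <- function(cfg) {
  if (!inherits(cfg, "pipeline_config")) cfg <- pipeline_config(cfg)
  t0 <- Sys.time()
  log_stage <- function(...) message(sprintf("[%5.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), ...)
  sim <- NULL
  if (!is.null(cfg$simulate)) {
    scfg <- do.call(sim_config, utils::modifyList(cfg$simulate,
                                                  list(seed = cfg$seed)))
    sim <- simulate_population(scfg)
    g <- sim$genealogy
    registry <- sim$registry
    vcf <- sim$vcf_path
    sampled_hint <- sim$samples
    log_stage("simulate: ", nrow(g$ind), " individuals, ",
              length(sim$truth$cases), " true cases")
  } else {
    g <- load_genealogy(cfg$trio, deaths = cfg$deaths)
    registry <- read_table_auto(cfg$registry)
    vcf <- cfg$vcf
    sampled_hint <- NULL
    log_stage("load: ", nrow(g$ind), " individuals")
  }
  cases <- classify_recurrent_cases(g, registry,
                                    min_lag_years = cfg$min_lag_years)
  sampled <- if (is.null(sampled_hint)) cases else
    intersect(cases, sampled_hint)
  log_stage("classify: ", length(cases), " recurrent cases (",
            length(sampled), " sampled)")
  rates <- estimate_rates(g, cases)
  clusters <- find_case_clusters(g, sampled, min_cases = cfg$min_cases)
  log_stage("clusters: ", length(clusters), " case clusters")
  excess <- test_clusters(clusters, g, rates, case_ids = cases,
                          alpha = cfg$alpha)
  log_stage("excess: ", sum(excess$high_risk), " high-risk clusters")
  candidates <- NULL
  segregation <- NULL
  if (!is.null(vcf) && !is.na(vcf) && sum(excess$high_risk) > 0) {
    vs <- read_annotated_vcf(vcf)
    fvs <- apply_variant_filters(vs, maf_max = cfg$maf_max,
                                 min_gq = cfg$min_gq, min_dp = cfg$min_dp)
    cand_list <- list()
    for (k in which(excess$high_risk)) {
      cl <- clusters[[k]]
      pair <- select_index_pair(g, cl, intersect(sampled, vs$samples))
      if (is.null(pair)) next
      cand_list[[cl$cluster_id]] <- shared_in_pair(fvs, pair,
                                                   pedigree_id = cl$cluster_id)
    }
    candidates <- if (length(cand_list)) do.call(rbind, cand_list) else NULL
    if (!is.null(candidates)) rownames(candidates) <- NULL
    log_stage("share: ", if (is.null(candidates)) 0L else nrow(candidates),
              " candidate variants (", nrow(fvs$variants), " of ",
              nrow(vs$variants), " variants passed filters)")
    if (!is.null(candidates) && nrow(candidates)) {
      assay <- NULL
      if (!is.null(cfg$assay)) {
        assay <- if (is.character(cfg$assay)) read_table_auto(cfg$assay) else
          as.data.frame(cfg$assay, stringsAsFactors = FALSE)
      }
      seg_rows <- lapply(seq_len(nrow(candidates)), function(r) {
        cand <- candidates[r, , drop = FALSE]
        cl <- clusters[[match(cand$pedigree_id,
                              vapply(clusters, `[[`, "", "cluster_id"))]]
        seq_ids <- intersect(cl$member_cases, vs$samples)
        pair <- strsplit(cand$pair_ids, ",", fixed = TRUE)[[1]]
        fs <- full_segregation_among_sequenced(fvs, cand, seq_ids)
        av <- if (is.null(assay)) {
          data.frame(individual_id = character(), call = character(),
                     stringsAsFactors = FALSE)
        } else assay[assay$variant == variant_key(cand),
                     c("individual_id", "call")]
        # sequenced non-pair cases act as typed calls from their genotypes
        seq_car <- strsplit(cand$carriers_among_sequenced, ",")[[1]]
        extra <- setdiff(seq_ids, c(pair, av$individual_id))
        if (length(extra)) {
          av <- rbind(av, data.frame(
            individual_id = extra,
            call = ifelse(extra %in% seq_car, "carrier", "non-carrier"),
            stringsAsFactors = FALSE))
        }
        seg <- count_additional_carriers(
          g, av, index_ids = pair, recurrent_ids = cases,
          breast_ids = cases, full_seg = fs)
        data.frame(variant = variant_key(cand), gene = cand$gene,
                   pedigree_id = cand$pedigree_id,
                   full_segregation = fs,
                   n_additional_recurrent = seg$n_additional_recurrent_carriers,
                   n_additional_breast = seg$n_additional_breastcancer_carriers,
                   tier = seg$tier, stringsAsFactors = FALSE)
      })
      segregation <- do.call(rbind, seg_rows)
    }
  }
  summary <- cross_pedigree_summary(candidates)
  res <- structure(list(cases = cases, sampled = sampled, rates = rates,
                        clusters = clusters, excess = excess,
                        candidates = candidates, summary = summary,
                        segregation = segregation, sim = sim,
                        config = cfg),
                   class = "pipeline_result")
  if (!is.null(cfg$out_dir)) write_pipeline_outputs(res, cfg$out_dir)
  res
}

write_pipeline_outputs <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(yaml::as.yaml(unclass(res$config)[!vapply(res$config, is.null,
                                                       logical(1))]),
             file.path(dir, "config_resolved.yaml"))
  write_tsv(data.frame(case_id = res$cases,
                       sampled = res$cases %in% res$sampled),
            file.path(dir, "cases.tsv"))
  write_tsv(as.data.frame(res$rates), file.path(dir, "rates.tsv"))
  cl_df <- do.call(rbind, lapply(res$clusters, function(cl) {
    data.frame(cluster_id = cl$cluster_id,
               root = paste(cl$root_couple, collapse = ","),
               member_cases = paste(cl$member_cases, collapse = ","),
               n_descendants = length(cl$descendant_ids),
               stringsAsFactors = FALSE)
  }))
  if (is.null(cl_df)) cl_df <- data.frame(cluster_id = character())
  write_tsv(cl_df, file.path(dir, "clusters.tsv"))
  write_tsv(res$excess, file.path(dir, "excess.tsv"))
  if (!is.null(res$candidates)) {
    write_tsv(res$candidates, file.path(dir, "candidates.tsv"))
  }
  if (!is.null(res$segregation)) {
    write_tsv(res$segregation, file.path(dir, "segregation.tsv"))
  }
  write_tsv(res$summary$by_variant, file.path(dir, "recurrence_by_variant.tsv"))
  write_tsv(res$summary$by_gene, file.path(dir, "recurrence_by_gene.tsv"))
  if (!is.null(res$sim)) write_sim_output(res$sim, file.path(dir, "sim"))
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("pipeline result:\n",
      " recurrent cases: ", length(x$cases),
      " (", length(x$sampled), " sampled)\n",
      " clusters: ", length(x$clusters),
      " (", sum(x$excess$high_risk), " high-risk)\n",
      " candidate shared variants: ",
      if (is.null(x$candidates)) 0L else nrow(x$candidates), "\n", sep = "")
  invisible(x)
}
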