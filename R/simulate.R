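# Synthetic population generator emulating a linked
# genealogy / cancer-registry / death-certificate resource, with a
# gene-dropped dominant founder risk allele and rare background
# variants, so the whole pipeline runs without access to protected data.

#' Simulation configuration
#'
#' Builds the configuration for [simulate_population()].  Defaults give
#' a multi-generation founder population at desk scale: founder couples
#' born in the early 1800s, Poisson family sizes, married-in spouses
#' drawn as new founders, partial death-certificate coverage, and a
#' dominant founder risk allele with relative risk 20 on a baseline
#' recurrent-case rate of 3% among death-certified women (carrier
#' penetrance 0.6): three-generation founder families with the large
#' sibships typical of a 19th-century founder population, sized so a
#' typical simulated study contains a sequenced affected relative pair
#' inside a significant pedigree.
#'
#' @param seed integer seed driving every stochastic draw.
#' @param n_founder_couples founder couples in the top generation.
#' @param n_generations total generations including founders (>= 3).
#' @param mean_offspring mean children per couple (Poisson).
#' @param founder_birth_year_range inclusive year interval for founder
#'   births.
#' @param generation_gap_mean,generation_gap_sd parent-to-child birth
#'   gap in years (normal, truncated at 16).
#' @param p_in_state probability an individual is born in state.
#' @param lifespan_mean,lifespan_sd lifespan in years (normal,
#'   truncated at 1).
#' @param observation_year individuals dying after this year are alive
#'   at observation and carry no death certificate.
#' @param death_cert_coverage probability a death in the observation
#'   window has a linked certificate.
#' @param baseline_rate recurrent-case probability for a death-certified
#'   non-carrier woman surviving to at least age 30; either a single
#'   number or a named vector keyed by cohort.
#' @param relative_risk multiplicative risk for risk-allele carriers
#'   (per-individual rate is capped below 1; a configured
#'   `rate * RR > 1` is an error).
#' @param bg_breast_rate probability of a non-recurrent breast cancer
#'   registry record for other women.
#' @param other_cancer_rate probability of an other-site registry
#'   record per individual.
#' @param sampling_fraction fraction of recurrent cases with stored DNA
#'   (sequenced samples).
#' @param n_background_variants rare background variants in the
#'   simulated VCF.
#' @param frac_synonymous,frac_common fractions of background variants
#'   annotated synonymous / with population AF above the rarity
#'   threshold.
#' @param frac_low_quality fraction of genotype calls written with
#'   failing GQ/DP.
#' @param risk_variant list describing the planted variant (gene,
#'   chrom, pos, ref, alt, pop_af).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_founder_couples = 8L,
                       n_generations = 3L,
                       mean_offspring = 12L,
                       founder_birth_year_range = c(1800L, 1850L),
                       generation_gap_mean = 28,
                       generation_gap_sd = 5,
                       p_in_state = 0.8,
                       lifespan_mean = 75,
                       lifespan_sd = 12,
                       observation_year = 2020L,
                       death_cert_coverage = 0.9,
                       baseline_rate = 0.03,
                       relative_risk = 20,
                       bg_breast_rate = 0.03,
                       other_cancer_rate = 0.02,
                       sampling_fraction = 0.8,
                       n_background_variants = 60L,
                       frac_synonymous = 0.25,
                       frac_common = 0.3,
                       frac_low_quality = 0.05,
                       risk_variant = list(gene = "RISKGENE", chrom = "7",
                                           pos = 76058064L, ref = "G",
                                           alt = "A", pop_af = 5e-4)) {
  if (n_generations < 3L) stop("n_generations must be at least 3")
  if (n_founder_couples < 1L) stop("need at least one founder couple")
  if (any(baseline_rate * relative_risk > 1)) {
    stop("baseline_rate * relative_risk exceeds 1")
  }
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a synthetic multi-generation genealogy
#'
#' Founder couples are seeded in the top generation; every couple has a
#' Poisson number of children; children of non-terminal generations
#' marry spouses drawn as new population founders.  Birth years
#' increase down the generations; deaths follow a truncated-normal
#' lifespan, and deaths inside the observation window receive a linked
#' death certificate with the configured coverage.  Deterministic given
#' the seed.
#'
#' @param cfg a `sim_config`.
#' @param seed optional seed; set only when supplied (so that
#'   [simulate_population()] can drive everything from one stream).
#' @return list with `trio` (trio-format data.frame, death fields
#'   included) and `founder_couples` (two-column matrix of ids).
#' @export
generate_genealogy <- function(cfg, seed = cfg$seed) {
  if (!is.null(seed)) set.seed(seed)
  id <- character(); father <- character(); mother <- character()
  sex <- character(); birth <- integer(); gen_no <- integer()
  nid <- 0L
  new_id <- function() { nid <<- nid + 1L; sprintf("I%04d", nid) }
  add <- function(s, by, f = NA_character_, m = NA_character_, gn) {
    i <- new_id()
    id <<- c(id, i); father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s); birth <<- c(birth, as.integer(round(by)))
    gen_no <<- c(gen_no, gn)
    i
  }
  couples <- matrix(character(), ncol = 2)   # husband, wife
  fc <- matrix(character(), ncol = 2)
  for (k in seq_len(cfg$n_founder_couples)) {
    by <- stats::runif(1, cfg$founder_birth_year_range[1],
                       cfg$founder_birth_year_range[2])
    h <- add("male", by + stats::runif(1, -3, 3), gn = 0L)
    w <- add("female", by + stats::runif(1, -3, 3), gn = 0L)
    couples <- rbind(couples, c(h, w))
    fc <- rbind(fc, c(h, w))
  }
  for (gn in seq_len(cfg$n_generations - 1L)) {
    next_couples <- matrix(character(), ncol = 2)
    for (r in seq_len(nrow(couples))) {
      h <- couples[r, 1]; w <- couples[r, 2]
      n_kids <- stats::rpois(1, cfg$mean_offspring)
      if (n_kids == 0L) next
      pby <- max(birth[match(c(h, w), id)])
      for (kk in seq_len(n_kids)) {
        gap <- max(16, stats::rnorm(1, cfg$generation_gap_mean,
                                    cfg$generation_gap_sd))
        s <- if (stats::runif(1) < 0.5) "female" else "male"
        child <- add(s, pby + gap, f = h, m = w, gn = gn)
        if (gn < cfg$n_generations - 1L) {
          sp_sex <- if (s == "female") "male" else "female"
          sp <- add(sp_sex, birth[match(child, id)] + stats::runif(1, -5, 5),
                    gn = gn)
          pair <- if (s == "female") c(sp, child) else c(child, sp)
          next_couples <- rbind(next_couples, pair)
        }
      }
    }
    couples <- next_couples
    if (!nrow(couples)) break
  }
  n <- length(id)
  in_state <- stats::runif(n) < cfg$p_in_state
  lifespan <- pmax(1, stats::rnorm(n, cfg$lifespan_mean, cfg$lifespan_sd))
  death_year <- as.integer(round(birth + lifespan))
  dead <- death_year <= cfg$observation_year
  certified <- dead & (stats::runif(n) < cfg$death_cert_coverage)
  death_year[!dead] <- NA_integer_
  trio <- data.frame(id = id, father = father, mother = mother, sex = sex,
                     birth_year = birth, birthplace = in_state,
                     death_year = death_year, death_cert = certified,
                     cause_codes = "", stringsAsFactors = FALSE)
  list(trio = trio, founder_couples = fc)
}

#' Gene-drop a heterozygous founder allele through a genealogy
#'
#' Mendelian transmission: each meiosis passes the variant with
#' probability one half, independently.  Married-in individuals and
#' founders other than the source are non-carriers.
#'
#' @param g a `genealogy`.
#' @param founder_id id of the source founder (must have no recorded
#'   parents); made heterozygous.
#' @param n_rep number of independent replicate drops.
#' @param seed optional seed.
#' @return integer matrix of alternate-allele counts, individuals x
#'   replicates (rownames = ids).
#' @export
gene_drop <- function(g, founder_id, n_rep = 1L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fi <- idx_of(g, founder_id)
  if (!is.na(g$fidx[fi]) || !is.na(g$midx[fi])) {
    stop("gene drop must start at a founder (no recorded parents): ", founder_id)
  }
  n <- nrow(g$ind)
  cnt <- matrix(0L, nrow = n, ncol = n_rep,
                dimnames = list(g$ind$id, NULL))
  cnt[fi, ] <- 1L
  ord <- order(g$gen)
  for (i in ord) {
    f <- g$fidx[i]; m <- g$midx[i]
    if (is.na(f) && is.na(m)) next
    pat <- if (is.na(f)) 0L else (stats::runif(n_rep) < cnt[f, ] / 2)
    mat <- if (is.na(m)) 0L else (stats::runif(n_rep) < cnt[m, ] / 2)
    cnt[i, ] <- as.integer(pat) + as.integer(mat)
  }
  cnt
}

#' Drop founder-labelled alleles at unlinked loci
#'
#' Every founder allele gets a unique label; labels descend by
#' independent Mendelian transmission at each of `n_loci` unlinked
#' loci.  Used to estimate identity-by-descent sharing and as a
#' Monte-Carlo cross-check of the kinship coefficient.
#'
#' @param g a `genealogy`.
#' @param n_loci number of independent loci.
#' @param seed optional seed.
#' @return list of two integer matrices `a1`, `a2` (individuals x loci)
#'   of founder-allele labels, rownames = ids.
#' @export
drop_allele_labels <- function(g, n_loci, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(g$ind)
  a1 <- matrix(0L, n, n_loci, dimnames = list(g$ind$id, NULL))
  a2 <- a1
  ord <- order(g$gen)
  for (i in ord) {
    f <- g$fidx[i]; m <- g$midx[i]
    if (is.na(f)) a1[i, ] <- 2L * i - 1L else {
      bit <- stats::runif(n_loci) < 0.5
      a1[i, ] <- ifelse(bit, a1[f, ], a2[f, ])
    }
    if (is.na(m)) a2[i, ] <- 2L * i else {
      bit <- stats::runif(n_loci) < 0.5
      a2[i, ] <- ifelse(bit, a1[m, ], a2[m, ])
    }
  }
  list(a1 = a1, a2 = a2)
}

#' Genome fraction shared identical-by-descent between two individuals
#'
#' Estimates, over unlinked gene-dropped loci, the mean fraction of
#' alleles shared identical by descent between `a` and `b`
#' (expectation `2 * kinship` for outbred pairs; 1/8 for first
#' cousins).
#'
#' @param g a `genealogy`.
#' @param a,b individual ids.
#' @param n_loci number of unlinked loci (default 1e5).
#' @param seed optional seed.
#' @return list with `fraction` (mean shared fraction), `se` (standard
#'   error over loci) and `n_loci`.
#' @export
ibd_fraction <- function(g, a, b, n_loci = 1e5, seed = NULL) {
  lab <- drop_allele_labels(g, n_loci, seed = seed)
  ia <- idx_of(g, a); ib <- idx_of(g, b)
  a1 <- lab$a1[ia, ]; a2 <- lab$a2[ia, ]
  b1 <- lab$a1[ib, ]; b2 <- lab$a2[ib, ]
  shared <- ((a1 == b1 | a1 == b2) + (a2 == b1 | a2 == b2)) / 2
  list(fraction = mean(shared),
       se = stats::sd(shared) / sqrt(n_loci),
       n_loci = n_loci)
}

#' Simulate cancer phenotypes over a genealogy
#'
#' Each death-certified woman surviving to at least age 30 becomes a
#' recurrent breast cancer case with probability
#' `baseline_rate * relative_risk^carrier` (capped below 1 by
#' construction); cases get a breast cancer registry diagnosis at least
#' ten years before death and a death certificate listing the breast
#' cause token.  Other women receive non-recurrent breast cancer
#' registry records, and individuals of either sex other-site records,
#' at the configured background rates; all certified deaths emit a
#' death-table row.
#'
#' @param g a `genealogy` (death fields populated, cause codes ignored).
#' @param carrier_map named integer vector (or one-column matrix) of
#'   risk-allele counts per individual id; NULL for no risk allele.
#' @param cfg a `sim_config`.
#' @param seed optional seed.
#' @return list with `registry` and `deaths` data.frames and
#'   `truth_cases` (ids of simulated recurrent cases).
#' @export
simulate_phenotypes <- function(g, carrier_map, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ind <- g$ind
  n <- nrow(ind)
  carrier <- rep(0L, n)
  if (!is.null(carrier_map)) {
    cm <- if (is.matrix(carrier_map)) carrier_map[, 1] else carrier_map
    carrier[match(names(cm), ind$id)] <- as.integer(cm)
  }
  death_age <- ind$death_year - ind$birth_year
  eligible <- ind$sex == "female" & ind$has_death_certificate &
    !is.na(death_age) & death_age >= 30
  base <- if (length(cfg$baseline_rate) > 1L) {
    r <- cfg$baseline_rate[cohorts_of(g)]
    r[is.na(r)] <- 0
    r
  } else rep(cfg$baseline_rate, n)
  p_case <- pmin(base * cfg$relative_risk^(carrier > 0), 1 - 1e-12)
  is_case <- eligible & (stats::runif(n) < p_case)
  ci <- which(is_case)
  lag <- pmin(10L + stats::rpois(length(ci), 5), death_age[ci] - 20L)
  lag <- pmax(lag, 10L)
  dx_case <- ind$death_year[ci] - lag
  registry <- data.frame(individual_id = ind$id[ci],
                         site = rep("breast", length(ci)),
                         diagnosis_year = dx_case, stringsAsFactors = FALSE)
  # non-recurrent breast cancers among other women (alive or dead)
  other_f <- which(ind$sex == "female" & !is_case)
  bg <- other_f[stats::runif(length(other_f)) < cfg$bg_breast_rate]
  if (length(bg)) {
    dx_bg <- ind$birth_year[bg] +
      pmax(25L, as.integer(round(stats::rnorm(length(bg), 55, 12))))
    registry <- rbind(registry, data.frame(
      individual_id = ind$id[bg], site = "breast", diagnosis_year = dx_bg,
      stringsAsFactors = FALSE))
  }
  oth <- which(stats::runif(n) < cfg$other_cancer_rate)
  if (length(oth)) {
    dx_o <- ind$birth_year[oth] +
      pmax(25L, as.integer(round(stats::rnorm(length(oth), 60, 12))))
    registry <- rbind(registry, data.frame(
      individual_id = ind$id[oth], site = "colorectal", diagnosis_year = dx_o,
      stringsAsFactors = FALSE))
  }
  certified <- which(ind$has_death_certificate)
  causes <- rep("other", length(certified))
  causes[certified %in% ci] <- "breast;other"
  deaths <- data.frame(individual_id = ind$id[certified],
                       death_year = ind$death_year[certified],
                       cause_codes = causes, stringsAsFactors = FALSE)
  list(registry = registry, deaths = deaths, truth_cases = sort(ind$id[ci]))
}

#' Simulate an annotated multi-sample VCF
#'
#' Emits rare background variants -- each introduced as a single
#' heterozygous copy in a random founder and gene-dropped, so genotype
#' sharing follows the genealogy -- plus the planted risk variant with
#' the supplied carrier genotypes.  Annotations (gene, consequence
#' class, population AF) and per-genotype GQ/DP are drawn so configured
#' fractions of background variants are synonymous, common, or
#' low-quality; the planted variant is always rare, non-synonymous and
#' confidently called.
#'
#' @param g a `genealogy`.
#' @param samples sample ids to write (must exist in `g`).
#' @param risk_carriers named vector of planted-variant allele counts
#'   (from [gene_drop()]); NULL omits the planted variant.
#' @param cfg a `sim_config`.
#' @param path output VCF path.
#' @param seed optional seed.
#' @return `path`, invisibly; side effect: VCF written.
#' @export
simulate_background_variants <- function(g, samples, risk_carriers, cfg,
                                         path, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  idx_of(g, samples)
  nb <- cfg$n_background_variants
  fdr <- founders(g)
  rows <- list()
  if (nb > 0L) {
    csq_pool <- c("nonsynonymous", "frameshift", "splicing", "stopgain",
                  "other_exonic")
    for (k in seq_len(nb)) {
      src <- sample(fdr, 1L)
      drop <- gene_drop(g, src, n_rep = 1L)[samples, 1]
      common <- stats::runif(1) < cfg$frac_common
      af <- if (common) stats::runif(1, 0.005, 0.3) else stats::runif(1, 1e-5, 0.0049)
      csq <- if (stats::runif(1) < cfg$frac_synonymous) "synonymous" else
        sample(csq_pool, 1L)
      gq <- sample(30:99, length(samples), replace = TRUE)
      dp <- 10L + stats::rpois(length(samples), 25)
      low <- stats::runif(length(samples)) < cfg$frac_low_quality
      gq[low] <- sample(0:19, sum(low), replace = TRUE)
      rows[[k]] <- list(chrom = as.character(1 + (k %% 22)),
                        pos = 1000L + 977L * k,
                        ref = "C", alt = "T",
                        gene = sprintf("BGGENE%03d", k),
                        csq = csq, af = af,
                        geno = drop, gq = gq, dp = dp)
    }
  }
  if (!is.null(risk_carriers)) {
    rv <- cfg$risk_variant
    rows[[length(rows) + 1L]] <- list(
      chrom = rv$chrom, pos = as.integer(rv$pos), ref = rv$ref, alt = rv$alt,
      gene = rv$gene, csq = "nonsynonymous", af = rv$pop_af,
      geno = risk_carriers[samples],
      gq = rep(99L, length(samples)), dp = rep(30L, length(samples)))
  }
  write_sim_vcf(rows, samples, path)
  invisible(path)
}

write_sim_vcf <- function(rows, samples, path) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"Consequence class\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Population allele frequency\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  if (length(rows)) {
    ord <- order(vapply(rows, function(r) r$chrom, character(1)),
                 vapply(rows, function(r) r$pos, integer(1)))
    rows <- rows[ord]
  }
  body <- vapply(rows, function(r) {
    gt <- c("0/0", "0/1", "1/1")[pmin(r$geno, 2L) + 1L]
    paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS",
            sprintf("GENE=%s;CSQCLASS=%s;AF=%.6g", r$gene, r$csq, r$af),
            "GT:GQ:DP", paste(gt, r$gq, r$dp, sep = ":")),
          collapse = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' Simulate a complete linked population
#'
#' Runs the whole generator from one seed: genealogy, planted founder
#' risk allele (gene-dropped from the founder with the most
#' descendants), phenotypes, case sampling, and the annotated VCF over
#' the sampled cases.
#'
#' @param cfg a `sim_config`.
#' @param vcf_path where to write the simulated VCF (default: a
#'   tempfile).
#' @return list of class `sim_output`: `genealogy`, `trio`, `registry`,
#'   `deaths`, `vcf_path`, `samples` (sampled case ids), and `truth`
#'   (risk founder, carrier ids, true case ids, config).
#' @export
simulate_population <- function(cfg, vcf_path = tempfile(fileext = ".vcf")) {
  set.seed(cfg$seed)
  gg <- generate_genealogy(cfg, seed = NULL)
  g <- load_genealogy(gg$trio)
  n_desc <- vapply(seq_len(nrow(g$ind)),
                   function(i) length(descendant_idx(g, i)), integer(1))
  fdr_idx <- which(is.na(g$fidx) & is.na(g$midx) & g$gen == 0L)
  risk_founder <- g$ind$id[fdr_idx[which.max(n_desc[fdr_idx])]]
  carriers <- gene_drop(g, risk_founder, n_rep = 1L)[, 1]
  phen <- simulate_phenotypes(g, carriers, cfg, seed = NULL)
  g <- load_genealogy(gg$trio, deaths = phen$deaths)
  cases <- phen$truth_cases
  sampled <- sort(cases[stats::runif(length(cases)) < cfg$sampling_fraction])
  if (length(sampled) >= 2L) {
    simulate_background_variants(g, sampled, carriers, cfg, vcf_path,
                                 seed = NULL)
  } else {
    vcf_path <- NA_character_
  }
  structure(list(genealogy = g, trio = gg$trio, registry = phen$registry,
                 deaths = phen$deaths, vcf_path = vcf_path, samples = sampled,
                 truth = list(risk_founder = risk_founder,
                              carriers = names(carriers[carriers > 0]),
                              cases = cases,
                              founder_couples = gg$founder_couples,
                              config = cfg)),
            class = "sim_output")
}

#' Write a simulated population to disk
#'
#' Emits the trio, registry, death and truth tables as TSVs next to the
#' already-written VCF.
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_sim_output <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(trio = file.path(dir, "trio.tsv"),
             registry = file.path(dir, "registry.tsv"),
             deaths = file.path(dir, "deaths.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_tsv(sim$trio, paths["trio"])
  write_tsv(sim$registry, paths["registry"])
  write_tsv(sim$deaths, paths["deaths"])
  truth <- data.frame(id = sim$genealogy$ind$id, stringsAsFactors = FALSE)
  truth$carrier <- truth$id %in% sim$truth$carriers
  truth$case <- truth$id %in% sim$truth$cases
  truth$sampled <- truth$id %in% sim$samples
  write_tsv(truth, paths["truth"])
  if (!is.na(sim$vcf_path) && file.exists(sim$vcf_path)) {
    vp <- file.path(dir, "variants.vcf")
    file.copy(sim$vcf_path, vp, overwrite = TRUE)
    paths <- c(paths, vcf = vp)
  }
  invisible(paths)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
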