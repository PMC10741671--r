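# Population genealogy graph: construction, traversal, kinship, clusters.

#' Build a genealogy from trio-format records
#'
#' Constructs a validated genealogy graph from a table of individuals with
#' parental links.  Two layouts are accepted: the native trio layout with
#' columns `id`, `father`, `mother`, `sex`, `birth_year`, `birthplace`
#' (plus optional `death_year`, `death_cert`, `cause_codes`), and a
#' PED-compatible 6-column layout (`fam`, `id`, `father`, `mother`, `sex`,
#' `phenotype`) in which sex is coded 1 = male / 2 = female.  A parent
#' coded as `0`, `""` or `NA` is treated as unknown, i.e. the individual
#' is a population founder on that side.
#'
#' @param trio a `data.frame` in one of the two layouts above, or a path
#'   to a tab- or comma-delimited file holding one.
#' @param deaths optional death-certificate table with columns
#'   `individual_id`, `death_year`, `cause_codes` (semicolon-separated
#'   cause tokens); merged onto the individuals.
#' @return An object of class `genealogy`: the individual table plus
#'   parent/child indices and generation numbers.
#' @details Validation enforces unique ids, existing parent ids, sex
#'   consistency of parents (fathers male, mothers female), acyclicity,
#'   and `death_year >= birth_year` where both are present.
#' @examples
#' trio <- data.frame(id = c("f", "m", "c1", "c2"),
#'                    father = c("0", "0", "f", "f"),
#'                    mother = c("0", "0", "m", "m"),
#'                    sex = c("male", "female", "female", "male"),
#'                    birth_year = c(1900, 1902, 1925, 1927),
#'                    birthplace = c(TRUE, TRUE, TRUE, TRUE))
#' g <- load_genealogy(trio)
#' founders(g)
#' @export
load_genealogy <- function(trio, deaths = NULL) {
  if (is.character(trio) && length(trio) == 1L) {
    trio <- read_table_auto(trio)
  }
  trio <- as.data.frame(trio, stringsAsFactors = FALSE)
  if (nrow(trio) == 0L) {
    return(new_genealogy(empty_individual_table()))
  }
  nms <- tolower(names(trio))
  if (!("id" %in% nms) && ncol(trio) == 6L) {
    # PED layout: fam id father mother sex phenotype
    names(trio) <- c("fam", "id", "father", "mother", "sex", "phenotype")
    trio$sex <- ifelse(trio$sex %in% c(2L, "2"), "female",
                       ifelse(trio$sex %in% c(1L, "1"), "male", NA_character_))
    trio$birth_year <- NA_integer_
    trio$birthplace <- NA
  } else {
    names(trio) <- nms
  }
  if (!is.null(deaths)) {
    if (is.character(deaths)) deaths <- read_table_auto(deaths)
    deaths <- as.data.frame(deaths, stringsAsFactors = FALSE)
    i <- match(trio$id, deaths$individual_id)
    trio$death_year <- deaths$death_year[i]
    trio$death_cert <- !is.na(i)
    trio$cause_codes <- ifelse(is.na(i), "", as.character(deaths$cause_codes[i]))
  }
  ind <- data.frame(
    id = as.character(trio$id),
    father = norm_parent(trio$father),
    mother = norm_parent(trio$mother),
    sex = as.character(trio$sex),
    birth_year = as_year(col_or(trio, "birth_year")),
    birthplace_in_state = as.logical(col_or(trio, "birthplace")),
    death_year = as_year(col_or(trio, "death_year")),
    has_death_certificate = isTRUE_vec(col_or(trio, "death_cert")),
    cause_codes = as.character(col_or(trio, "cause_codes", "")),
    stringsAsFactors = FALSE
  )
  ind$cause_codes[is.na(ind$cause_codes)] <- ""
  new_genealogy(ind)
}

norm_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x %in% c("0", "")] <- NA_character_
  x
}

col_or <- function(df, nm, default = NA) {
  if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
}

as_year <- function(x) {
  y <- suppressWarnings(as.integer(x))
  y
}

isTRUE_vec <- function(x) {
  if (is.logical(x)) return(!is.na(x) & x)
  x <- tolower(as.character(x))
  !is.na(x) & x %in% c("true", "t", "1", "yes")
}

empty_individual_table <- function() {
  data.frame(id = character(), father = character(), mother = character(),
             sex = character(), birth_year = integer(),
             birthplace_in_state = logical(), death_year = integer(),
             has_death_certificate = logical(), cause_codes = character(),
             stringsAsFactors = FALSE)
}

new_genealogy <- function(ind) {
  if (anyDuplicated(ind$id)) {
    dup <- unique(ind$id[duplicated(ind$id)])
    stop("duplicate individual id(s): ", paste(dup, collapse = ", "))
  }
  fidx <- match(ind$father, ind$id)
  midx <- match(ind$mother, ind$id)
  bad_f <- !is.na(ind$father) & is.na(fidx)
  bad_m <- !is.na(ind$mother) & is.na(midx)
  if (any(bad_f | bad_m)) {
    stop("parent id(s) not present in genealogy: ",
         paste(unique(c(ind$father[bad_f], ind$mother[bad_m])), collapse = ", "))
  }
  if (any(!is.na(fidx) & ind$sex[fidx] != "male")) {
    stop("father with non-male sex: ",
         paste(unique(ind$id[fidx[!is.na(fidx) & ind$sex[fidx] != "male"]]),
               collapse = ", "))
  }
  if (any(!is.na(midx) & ind$sex[midx] != "female")) {
    stop("mother with non-female sex: ",
         paste(unique(ind$id[midx[!is.na(midx) & ind$sex[midx] != "female"]]),
               collapse = ", "))
  }
  both <- !is.na(ind$death_year) & !is.na(ind$birth_year)
  if (any(both & ind$death_year < ind$birth_year)) {
    stop("death_year precedes birth_year for: ",
         paste(ind$id[both & ind$death_year < ind$birth_year], collapse = ", "))
  }
  gen <- topo_generation(fidx, midx, ind$id)
  n <- nrow(ind)
  children <- vector("list", n)
  for (p in list(fidx, midx)) {
    ok <- which(!is.na(p))
    for (i in ok) children[[p[i]]] <- c(children[[p[i]]], i)
  }
  children <- lapply(children, function(v) sort(unique(v)))
  structure(list(ind = ind, fidx = fidx, midx = midx,
                 children = children, gen = gen),
            class = "genealogy")
}

# Generation number via Kahn ordering; detects (and reports) a cycle.
topo_generation <- function(fidx, midx, ids) {
  n <- length(ids)
  gen <- rep(NA_integer_, n)
  indeg <- (!is.na(fidx)) + (!is.na(midx))
  queue <- which(indeg == 0L)
  gen[queue] <- 0L
  head <- 1L
  order_seen <- 0L
  children <- vector("list", n)
  for (p in list(fidx, midx)) {
    ok <- which(!is.na(p))
    for (i in ok) children[[p[i]]] <- c(children[[p[i]]], i)
  }
  while (head <= length(queue)) {
    v <- queue[head]; head <- head + 1L; order_seen <- order_seen + 1L
    for (c in children[[v]]) {
      g <- gen[v] + 1L
      if (is.na(gen[c]) || g > gen[c]) gen[c] <- g
      indeg[c] <- indeg[c] - 1L
      if (indeg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (order_seen < n) {
    cyc <- ids[which(indeg > 0L)]
    stop("cycle detected in genealogy involving: ",
         paste(utils::head(cyc, 10L), collapse = ", "))
  }
  gen
}

#' @export
print.genealogy <- function(x, ...) {
  cat("genealogy:", nrow(x$ind), "individuals,",
      sum(is.na(x$fidx) & is.na(x$midx)), "founders,",
      max(c(x$gen, 0L)) + ifelse(nrow(x$ind) > 0, 1L, 0L), "generations\n")
  invisible(x)
}

idx_of <- function(g, id) {
  i <- match(id, g$ind$id)
  if (anyNA(i)) stop("unknown individual id(s): ",
                     paste(id[is.na(i)], collapse = ", "))
  i
}

#' Founders of a genealogy
#'
#' Individuals with neither parent recorded.
#' @param g a `genealogy`.
#' @return character vector of founder ids.
#' @export
founders <- function(g) {
  g$ind$id[is.na(g$fidx) & is.na(g$midx)]
}

#' Strict ancestors of an individual with meiosis depth
#'
#' Returns every strict ancestor reachable through recorded parental
#' links together with the minimal number of meioses connecting the two.
#'
#' @param g a `genealogy`.
#' @param id an individual id.
#' @return a `data.frame` with columns `id` and `depth` (minimal meiosis
#'   count, parent = 1); zero rows for a founder.
#' @export
ancestors_of <- function(g, id) {
  i <- idx_of(g, id)
  depth <- ancestor_depths(g, i)
  found <- which(!is.na(depth))
  found <- found[found != i]
  data.frame(id = g$ind$id[found], depth = depth[found],
             stringsAsFactors = FALSE)
}

# BFS up the parent links; returns vector of minimal depths (NA = not an
# ancestor), with depth 0 at the start index itself.
ancestor_depths <- function(g, i) {
  n <- nrow(g$ind)
  depth <- rep(NA_integer_, n)
  depth[i] <- 0L
  frontier <- i
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    parents <- c(g$fidx[frontier], g$midx[frontier])
    parents <- unique(parents[!is.na(parents)])
    parents <- parents[is.na(depth[parents])]
    depth[parents] <- d
    frontier <- parents
  }
  depth
}

#' Strict descendants of an individual
#'
#' All individuals descended from `id` through recorded parental links.
#' Spouses who married into the family are not descendants.
#'
#' @param g a `genealogy`.
#' @param id an individual id.
#' @return character vector of descendant ids (possibly empty).
#' @export
descendants_of <- function(g, id) {
  i <- idx_of(g, id)
  g$ind$id[descendant_idx(g, i)]
}

descendant_idx <- function(g, i) {
  seen <- rep(FALSE, nrow(g$ind))
  frontier <- unlist(g$children[i])
  while (length(frontier)) {
    frontier <- frontier[!seen[frontier]]
    seen[frontier] <- TRUE
    frontier <- unique(unlist(g$children[frontier]))
  }
  which(seen)
}

#' Kinship coefficient between two individuals
#'
#' The probability that an allele drawn at random from `a` and one drawn
#' at random from `b` are identical by descent, computed by the standard
#' recursion over the pedigree (founders are assumed unrelated and
#' non-inbred at the top).  Parent and offspring have kinship 1/4;
#' outbred first cousins 1/16.
#'
#' @param g a `genealogy`.
#' @param a,b individual ids.
#' @return kinship coefficient in `[0, 0.5]` (0.5 only for self-kinship
#'   of a non-inbred individual... self-kinship is `0.5 (1 + F)` in
#'   general).
#' @export
kinship <- function(g, a, b) {
  i <- idx_of(g, a); j <- idx_of(g, b)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  phi_pair(g, i, j, memo)
}

phi_pair <- function(g, i, j, memo) {
  if (is.na(i) || is.na(j)) return(0)
  key <- if (i <= j) paste0(i, ":", j) else paste0(j, ":", i)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (i == j) {
    0.5 * (1 + phi_pair(g, g$fidx[i], g$midx[i], memo))
  } else {
    # recurse on the individual deeper in the pedigree
    if (g$gen[i] < g$gen[j]) { t <- i; i <- j; j <- t }
    0.5 * (phi_pair(g, g$fidx[i], j, memo) + phi_pair(g, g$midx[i], j, memo))
  }
  memo[[key]] <- val
  val
}

#' Classify the genealogical relationship between two individuals
#'
#' Labels the closest connection between `a` and `b` through their
#' nearest common ancestors.  Full relationships (both members of an
#' ancestral couple shared) map to the usual labels; relationships
#' through a single shared ancestor (half-relationships) and anything
#' more distant than second cousins map to `"other-related"`.
#'
#' @param g a `genealogy`.
#' @param a,b individual ids.
#' @return one of `"parent-offspring"`, `"sibling"`, `"avuncular"`,
#'   `"first-cousin"`, `"first-cousin-once-removed"`, `"second-cousin"`,
#'   `"other-related"`, `"unrelated"`.
#' @export
classify_relationship <- function(g, a, b) {
  i <- idx_of(g, a); j <- idx_of(g, b)
  if (i == j) stop("relationship of an individual with itself is undefined")
  da <- ancestor_depths(g, i)
  db <- ancestor_depths(g, j)
  if (!is.na(da[j])) return(if (da[j] == 1L) "parent-offspring" else "other-related")
  if (!is.na(db[i])) return(if (db[i] == 1L) "parent-offspring" else "other-related")
  common <- which(!is.na(da) & !is.na(db))
  common <- common[common != i & common != j]
  if (!length(common)) return("unrelated")
  tot <- da[common] + db[common]
  nearest <- common[tot == min(tot)]
  # is some couple (a mating pair) fully shared at the minimal depth?
  couple <- FALSE
  if (length(nearest) >= 2L) {
    for (x in nearest) {
      mates <- mates_of(g, x)
      if (any(mates %in% nearest)) { couple <- TRUE; break }
    }
  }
  dd <- sort(c(min(da[nearest]), min(db[nearest])))
  lab <- relationship_label(dd[1], dd[2])
  if (!couple && lab != "other-related") "other-related" else lab
}

relationship_label <- function(d1, d2) {
  if (d1 == 1L && d2 == 1L) return("sibling")
  if (d1 == 1L && d2 == 2L) return("avuncular")
  if (d1 == 2L && d2 == 2L) return("first-cousin")
  if (d1 == 2L && d2 == 3L) return("first-cousin-once-removed")
  if (d1 == 3L && d2 == 3L) return("second-cousin")
  "other-related"
}

# indices of individuals who have a recorded child with x
mates_of <- function(g, x) {
  kids <- g$children[[x]]
  if (!length(kids)) return(integer())
  m <- c(g$fidx[kids], g$midx[kids])
  unique(m[!is.na(m) & m != x])
}

#' Find clusters of related cases sharing a common ancestor
#'
#' Scans every ancestor in the genealogy and emits a case cluster for
#' each one whose strict descendants include at least `min_cases` of the
#' supplied case ids.  Clusters whose member-case sets coincide are
#' deduplicated by retaining the most recent common ancestor (the root
#' with the smallest descendant set); when that root's mate heads the
#' same member set the cluster is rooted at the couple.  Clusters with
#' distinct member sets are all retained, so an individual may belong to
#' several clusters through different ancestors.
#'
#' @param g a `genealogy`.
#' @param case_ids character vector of case ids (must exist in `g`).
#' @param min_cases minimum number of member cases per cluster
#'   (default 2).
#' @return a list of `case_cluster` objects, each with elements
#'   `cluster_id`, `root_couple` (one or two ids), `member_cases` and
#'   `descendant_ids`.
#' @export
find_case_clusters <- function(g, case_ids, min_cases = 2L) {
  case_ids <- unique(as.character(case_ids))
  ci <- match(case_ids, g$ind$id)
  if (anyNA(ci)) {
    stop("case id(s) not present in genealogy: ",
         paste(case_ids[is.na(ci)], collapse = ", "))
  }
  n <- nrow(g$ind)
  is_case <- rep(FALSE, n); is_case[ci] <- TRUE
  best <- new.env(parent = emptyenv(), hash = TRUE)
  for (r in seq_len(n)) {
    if (!length(g$children[[r]])) next
    desc <- descendant_idx(g, r)
    members <- desc[is_case[desc]]
    if (length(members) < min_cases) next
    key <- paste(sort(g$ind$id[members]), collapse = "|")
    prev <- best[[key]]
    if (is.null(prev) || length(desc) < length(prev$ndesc) ||
        (length(desc) == length(prev$ndesc) && g$ind$id[r] < g$ind$id[prev$root])) {
      best[[key]] <- list(root = r, ndesc = desc, members = members)
    }
  }
  keys <- sort(ls(best))
  out <- vector("list", length(keys))
  for (k in seq_along(keys)) {
    b <- best[[keys[k]]]
    root <- b$root
    couple <- g$ind$id[root]
    for (m in mates_of(g, root)) {
      desc_m <- descendant_idx(g, m)
      mem_m <- desc_m[is_case[desc_m]]
      if (identical(sort(mem_m), sort(b$members))) {
        couple <- sort(c(couple, g$ind$id[m]))
        break
      }
    }
    out[[k]] <- structure(list(
      cluster_id = paste0("C", k),
      root_couple = couple,
      member_cases = sort(g$ind$id[b$members]),
      descendant_ids = sort(g$ind$id[b$ndesc])
    ), class = "case_cluster")
  }
  out
}

#' @export
print.case_cluster <- function(x, ...) {
  cat("case cluster", x$cluster_id, "rooted at",
      paste(x$root_couple, collapse = " x "), "-",
      length(x$member_cases), "member cases among",
      length(x$descendant_ids), "descendants\n")
  invisible(x)
}

# Delimited-text reader that sniffs tab vs comma from the header line.
read_table_auto <- function(path) {
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, colClasses = "character",
                    quote = "\"", comment.char = "")
}
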