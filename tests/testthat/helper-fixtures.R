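# Pedigree and variant fixtures, all built in code.

trio_row <- function(id, father = "0", mother = "0", sex, birth = 1900,
                     place = TRUE, death = NA, cert = FALSE, causes = "") {
  data.frame(id = id, father = father, mother = mother, sex = sex,
             birth_year = birth, birthplace = place, death_year = death,
             death_cert = cert, cause_codes = causes,
             stringsAsFactors = FALSE)
}

# two founders, two children
fix_nuclear <- function() {
  load_genealogy(rbind(
    trio_row("f", sex = "male", birth = 1900),
    trio_row("m", sex = "female", birth = 1902),
    trio_row("c1", "f", "m", "female", 1925),
    trio_row("c2", "f", "m", "male", 1927)))
}

# 5-generation single-descent chain with married-in spouses
fix_chain <- function() {
  rows <- rbind(trio_row("g0m", sex = "male", birth = 1800),
                trio_row("g0f", sex = "female", birth = 1802))
  f <- "g0m"; m <- "g0f"
  for (k in 1:4) {
    kid <- paste0("g", k)
    sp <- paste0("s", k)
    rows <- rbind(rows,
                  trio_row(kid, f, m, "male", 1800 + 25 * k),
                  trio_row(sp, sex = "female", birth = 1800 + 25 * k))
    f <- kid; m <- sp
  }
  load_genealogy(rows)
}

# grandparent couple, two child couples, one grandchild each: c1 and c2
# are first cousins; "aunt" (gp's daughter) and c1 are avuncular.
fix_cousins <- function() {
  load_genealogy(rbind(
    trio_row("gf", sex = "male", birth = 1850),
    trio_row("gm", sex = "female", birth = 1852),
    trio_row("p1", "gf", "gm", "male", 1875),
    trio_row("p2", "gf", "gm", "female", 1877),
    trio_row("aunt", "gf", "gm", "female", 1879),
    trio_row("s1", sex = "female", birth = 1876),
    trio_row("s2", sex = "male", birth = 1878),
    trio_row("c1", "p1", "s1", "female", 1900),
    trio_row("c2", "s2", "p2", "female", 1902)))
}

# Extended pedigree mirroring a deep segregating-variant family:
# founder couple fa/fb; five gen-1 children a..e with spouses; index
# cousin pair p1/p2, two further sequenced recurrent carriers r3/r4,
# six assayed breast cancer carriers (a, b, c, q1, q2, q3), one assayed
# unaffected connector carrier (d), and one untyped breast cancer case
# (e) forced by Mendelian transmission to be an obligate carrier.
fix_mdh2 <- function() {
  g <- load_genealogy(rbind(
    trio_row("fa", sex = "male", birth = 1805, death = 1880, cert = TRUE),
    trio_row("fb", sex = "female", birth = 1808, death = 1885, cert = TRUE),
    trio_row("a", "fa", "fb", "female", 1835, death = 1915, cert = TRUE,
             causes = "other"),
    trio_row("b", "fa", "fb", "male", 1837, death = 1917, cert = TRUE),
    trio_row("c", "fa", "fb", "female", 1839, death = 1919, cert = TRUE),
    trio_row("d", "fa", "fb", "male", 1841, death = 1920, cert = TRUE),
    trio_row("e", "fa", "fb", "female", 1843, death = 1921, cert = TRUE),
    trio_row("sa", sex = "male", birth = 1834),
    trio_row("sb", sex = "female", birth = 1836),
    trio_row("sc", sex = "male", birth = 1838),
    trio_row("sd", sex = "female", birth = 1840),
    trio_row("se", sex = "male", birth = 1842),
    trio_row("p1", "sa", "a", "female", 1865, death = 1950, cert = TRUE,
             causes = "breast"),
    trio_row("p2", "b", "sb", "female", 1867, death = 1952, cert = TRUE,
             causes = "breast"),
    trio_row("r3", "sc", "c", "female", 1869, death = 1954, cert = TRUE,
             causes = "breast"),
    trio_row("r4", "d", "sd", "female", 1871, death = 1956, cert = TRUE,
             causes = "breast"),
    trio_row("q1", "sc", "c", "female", 1873, death = 1950, cert = TRUE),
    trio_row("q2", "d", "sd", "female", 1875, death = 1952, cert = TRUE),
    trio_row("q3", "se", "e", "female", 1877, death = 1954, cert = TRUE)))
  list(
    g = g,
    pair = c("p1", "p2"),
    recurrent = c("p1", "p2", "r3", "r4"),
    breast = c("p1", "p2", "r3", "r4", "a", "b", "c", "q1", "q2", "q3", "e"),
    assay = data.frame(
      individual_id = c("a", "b", "c", "d", "q1", "q2", "q3", "r3", "r4"),
      call = "carrier", stringsAsFactors = FALSE))
}

# Pair of cousin carriers plus three sequenced recurrent non-carriers
# and two assayed related breast cancer carriers (e and x1).
fix_pms2 <- function() {
  g <- load_genealogy(rbind(
    trio_row("fa", sex = "male", birth = 1805),
    trio_row("fb", sex = "female", birth = 1808),
    trio_row("a", "fa", "fb", "female", 1835),
    trio_row("b", "fa", "fb", "male", 1837),
    trio_row("c", "fa", "fb", "female", 1839),
    trio_row("d", "fa", "fb", "female", 1841),
    trio_row("e", "fa", "fb", "female", 1843),
    trio_row("sa", sex = "male", birth = 1834),
    trio_row("sb", sex = "female", birth = 1836),
    trio_row("sc", sex = "male", birth = 1838),
    trio_row("sd", sex = "male", birth = 1840),
    trio_row("se", sex = "male", birth = 1842),
    trio_row("p1", "sa", "a", "female", 1865),
    trio_row("p2", "b", "sb", "female", 1867),
    trio_row("r3", "sc", "c", "female", 1869),
    trio_row("r4", "sd", "d", "female", 1871),
    trio_row("r5", "sd", "d", "female", 1873),
    trio_row("x1", "se", "e", "female", 1875)))
  list(
    g = g,
    pair = c("p1", "p2"),
    recurrent = c("p1", "p2", "r3", "r4", "r5"),
    breast = c("p1", "p2", "r3", "r4", "r5", "e", "x1"),
    assay = data.frame(
      individual_id = c("e", "x1", "r3", "r4", "r5"),
      call = c("carrier", "carrier", "non-carrier", "non-carrier",
               "non-carrier"),
      stringsAsFactors = FALSE))
}

# build a variant_set directly (bypassing VCF I/O) for filter tests
make_variant_set <- function(variants, geno, gq = NULL, dp = NULL) {
  samples <- colnames(geno)
  n <- nrow(variants)
  if (is.null(gq)) gq <- matrix(99, n, length(samples))
  if (is.null(dp)) dp <- matrix(30, n, length(samples))
  dimnames(geno) <- dimnames(gq) <- dimnames(dp) <- list(NULL, samples)
  structure(list(variants = variants, geno = geno, gq = gq, dp = dp,
                 samples = samples), class = "variant_set")
}

toy_variants <- function(n, gene = sprintf("G%02d", seq_len(n)),
                         csq = rep("nonsynonymous", n),
                         af = rep(1e-4, n)) {
  data.frame(chrom = "1", pos = 100L + seq_len(n), ref = "A", alt = "T",
             gene = gene, consequence = csq, pop_af = af,
             stringsAsFactors = FALSE)
}

vkey <- function(vs) {
  paste(vs$variants$chrom, vs$variants$pos, vs$variants$ref,
        vs$variants$alt, sep = ":")
}

write_toy_vcf <- function(path, records, samples) {
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
           "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"c\">",
           "##INFO=<ID=AF,Number=1,Type=Float,Description=\"a\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
           "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
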