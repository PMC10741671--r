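Package: kindredscan
Title: High-Risk Pedigree Discovery and Shared Rare-Variant Analysis for
    Recurrent Breast Cancer
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genealogy-based discovery of high-risk cancer
    pedigrees and candidate predisposition variants.  Builds a population
    genealogy graph from trio records, classifies recurrent breast cancer
    cases from linked cancer-registry and death-certificate records,
    estimates cohort-specific case rates, finds clusters of related cases
    and tests each for a significant excess of cases with an exact
    one-sided Poisson test, filters annotated multi-sample VCFs to rare
    functional variants shared by affected relative pairs, and evaluates
    candidates by additional-carrier assay counts, obligate-carrier
    inference, carrier relatedness, and case-control odds ratios.  A
    synthetic-population generator emulating a linked
    genealogy/registry/death-certificate resource with a gene-dropped
    founder risk allele makes the whole pipeline testable without access
    to protected data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
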