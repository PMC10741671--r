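---
title: "Methods: pedigree excess testing and shared rare-variant discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pedigree excess testing and shared rare-variant discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The study design

kindredscan implements the analysis pipeline behind a familiar design
in genetic epidemiology: find extended families with a statistically
significant excess of a rare phenotype, sequence affected relative
pairs inside them, and treat rare variants shared by both members of a
pair as candidate predisposition variants.  The logic rests on two
facts.  First, clusters of related cases arise by chance, so a
cluster only earns the label *high-risk pedigree* when the observed
case count significantly exceeds the expectation under population
rates.  Second, distant affected relatives share little background
genome — first cousins share one eighth in expectation — so a rare
variant carried by both members of an affected cousin pair from a
high-risk pedigree is unlikely to be shared by chance.

The phenotype modelled throughout is *recurrent breast cancer*,
operationalised from linked records: a female with a registry
diagnosis of primary breast cancer and a death certificate listing
breast cancer as a cause, dying at least `min_lag_years` (default 10)
after the earliest diagnosis.  Only years are modelled, so the lag
rule is `death_year - diagnosis_year >= 10`; records carry no
month/day resolution.  Males are excluded by definition even though
male breast cancer occurs among carriers in assayed pedigrees.

# Cohort rates and the excess test

Every death-certified individual is assigned to a cohort by sex,
five-year birth bin (anchored at multiples of five) and in-state
birth.  The cohort rate is the recurrent-case count over the
death-certified count; the denominator is restricted to
death-certified individuals because the case definition itself
requires a death certificate, making numerator and denominator
commensurable.

For a cluster rooted at an ancestral couple, the expected count sums
the cohort rates of the death-certified descendants; married-in
spouses are never descendants.  The test statistic is the exact
one-sided Poisson upper tail `P(X >= observed | lambda = expected)`.
Two properties motivate this choice: the per-descendant case
indicators are independent Bernoulli draws with small probabilities,
whose sum is well approximated by a Poisson with matched mean; and the
exact tail requires no large-sample approximation for the small
expected counts typical of single pedigrees.  Degenerate inputs are
defined explicitly: `observed = 0` gives p = 1 (the event "at least
zero" is certain), and `expected = 0` with positive observed gives
p = 0 from the point mass.  Cohorts missing from the rate table
contribute rate 0 with a warning rather than an error, since a
sub-pedigree can contain cohorts absent from a restricted rate table.

A useful internal identity: applying the test to the cluster that
contains the entire rate-estimation population returns
`expected == observed` to machine precision, because the rates were
estimated from exactly that population.  The test suite asserts this
conservation on simulated populations.

## Calibration and discreteness

The exact Poisson test is conservative for small expected counts: the
achieved level at nominal 0.05 is the largest attainable tail
probability below 0.05, which oscillates between roughly 0.03 and
0.05 for expectations between 10 and 80.  The calibration experiment
(`type1_calibration()`) therefore uses a null population whose founder
clusters carry expected counts of a few tens (five founder couples,
five generations, mean sibship 7, baseline rate 0.05 — about 15,000
individuals), where the null distribution is near-continuous.  A
second small-scale artefact is handled explicitly: with a handful of
founder clusters partitioning the whole population, estimating rates
from the same phenotype draw forces the cluster deviations to sum to
zero and biases the test conservative.  The experiment estimates the
rate table once from 40 pooled burn-in phenotype replicates — the
package's own estimator, applied to data independent of each test
replicate — and then tests 5 clusters × 400 fresh replicates = 2000
cluster tests.  In the statewide resource this artefact is negligible
because any one pedigree is a vanishing fraction of the denominator.

The power experiment (`planted_power()`) regenerates, in each of 150
replicates, a six-founder-couple, four-generation population (mean
sibship 7, baseline rate 0.02), gene-drops a heterozygous risk allele
(relative risk 20) from its most prolific founder, and measures how
often the planted cluster is flagged.  Regenerating the structure
every replicate averages over pedigree shapes as well as transmission
and phenotype noise; with a single fixed tree the estimate is
dominated by that tree's sex and sibship layout.

# Cluster discovery

Clusters are discovered by scanning every ancestor: any individual
whose strict descendants include at least `min_cases` (default 2)
sampled cases defines a candidate cluster.  Clusters with identical
member-case sets are deduplicated by keeping the most recent root —
the one with the smallest descendant set, ties broken by id — and the
root becomes a couple when the root's mate heads the same member set.
Distinct member sets are all retained, so one case can sit in several
clusters through different ancestors; this mirrors how overlapping
high-risk pedigrees are reported in practice.  How overlapping
ancestor clusters should be merged is genuinely under-determined;
one-cluster-per-member-set is this package's documented rule, chosen
because it is finite, deterministic, and stable under adding remote
ancestors.

Relationship labels (`classify_relationship()`) come from the minimal
meiosis paths to the nearest common ancestors; a full label (sibling,
avuncular, first-cousin, ...) requires both members of an ancestral
couple to be shared, while half-relationships and anything beyond
second cousins collapse to `other-related`.  Kinship coefficients use
the standard recursion with founders assumed unrelated and non-inbred;
unknown parents make an individual a founder.  No installed package
provides pedigree kinship on arbitrary genealogy graphs, so the
recursion (with memoisation) is implemented here and cross-checked in
the tests against a Monte-Carlo gene-drop oracle.

# Variant filtering and sharing

The filter cascade keeps variants that are rare
(`pop_af < maf_max = 0.005`, strictly, so a frequency exactly at the
threshold is excluded), non-synonymous in the broad sense (any
consequence class except `synonymous`), and confidently called.
"Poor quality" is not standardised anywhere, so the defaults are the
conventional short-read thresholds GQ ≥ 20 and DP ≥ 10; genotypes
failing them become missing, and a record with no confident carrier
left is dropped.  A missing population frequency is treated as rare —
an allele absent from the reference panel is rare by construction —
and the count of such records is reported for audit.  The three
filters commute; the tests assert order-invariance.  Carrier status is
dominant: at least one alternate allele.  Whether pair sharing should
demand identical genotypes (het/het) rather than any-carrier is
undecidable from the design alone; any-carrier is implemented, which
is the weaker and therefore more inclusive rule.  Multi-allelic
records are refused with instructions to split upstream, keeping
one-alternate-allele semantics throughout.

Within each high-risk cluster the pipeline designates one index pair:
the sampled member pair with the smallest positive kinship, ties
broken by id order.  Most-distant-pair selection maximises the
evidential value of sharing (less background genome in common) and
mirrors the preference for cousin pairs over sib pairs in this study
design.  Cross-pedigree summaries report, per variant, the number of
pairs sharing it and, per gene, the number of distinct pedigrees
contributing distinct variants.

# Segregation evaluation

Assay results feed `count_additional_carriers()`, which counts
carriers beyond the index pair among recurrent cases and among
non-recurrent breast cancer cases separately (the two columns of the
familiar segregation-evidence table are disjoint).  Untyped
individuals are inferred as obligate carriers when they lie on every
transmission path from the presumed source — the most recent common
ancestor(s) of the typed carriers — to some typed carrier; typed
non-carriers are never routed through and never inferred, and a
single typed carrier licenses no inference.  This single-source rule
is the package's definition; the underlying data cannot distinguish
it from more permissive rules, and the tests assert the safe
properties (inferred ⊆ true carriers under gene-drop simulation, no
contradiction of typed non-carriers).

Evidence tiers: `assay_failed` (no successful call), `no_additional`,
`one_additional`, `multi_additional` (two or more additional affected
carriers, all related to the index pair), `unrelated_carriers` (two or
more, not all related — carriers unconnected to the discovery pair
argue against a familial variant even when numerous), and
`full_cosegregation` (every sequenced case of the pedigree carries the
variant and the additional carriers are related).  Relatedness means
kinship > 0 with at least one index member — any documented
genealogical connection.

External case-control counts are summarised by the sample
cross-product odds ratio `ad/bc` (infinite when a zero cell makes the
ratio diverge; optionally Haldane–Anscombe corrected) with a
two-sided Fisher exact p-value under the minimum-likelihood rule (sum
over tables, at the observed margins, no more probable than the
observed one).  The underlying cohort machinery — ancestry matching,
imputation — is out of scope; the association consumes pre-matched
counts.

# The synthetic population generator

`simulate_population()` emulates the linked resource end to end:
founder couples born 1800–1850, Poisson sibships with children
marrying spouses drawn as new founders, parent–child birth gaps
normal around 28 years, truncated-normal lifespans around 75 ± 12,
death certificates for 90% of deaths inside the observation window
(to 2020), cohort-structured baseline case probabilities among
death-certified women surviving to age 30, a dominant founder risk
allele transmitted by gene drop (`relative_risk` multiplies the
baseline, capped below 1; configurations implying probability above 1
are rejected), background variants introduced as single founder
copies and gene-dropped so genotype sharing follows the genealogy,
and an annotated VCF over the sampled cases.  One integer seed drives
every draw in documented order, so all outputs are byte-reproducible.

The default configuration is a desk-scale caricature chosen once, by
design analysis, so that the sequencing study design functions in a
population of ~1300 individuals: eight founder couples, three
generations, mean sibship 12 (large pioneer-era families), baseline
rate 0.03 among eligible women, relative risk 20 (carrier penetrance
0.6, in the range of the strongest known breast cancer predisposition
alleles), and stored DNA for 80% of cases.  The high sampling
fraction and large sibships compensate for the small population: with
realistic statewide numbers (millions of individuals, ~6% of cases
sampled) no desk-scale simulation would contain a sequenced affected
pair at all.  What the generator does **not** emulate: linkage
disequilibrium and recombination (loci are unlinked, which is
adequate for every sharing property tested), realistic demographic
calibration, assortative mating, migration, phenocopies with
structured risk, or sequencing error beyond per-genotype GQ/DP draws.
Passing tests on this generator therefore demonstrate the *logic* of
the pipeline — classification, rates, excess testing, sharing,
segregation — not its behaviour on real demographic structure.

Experiment problem sizes (calibration: 2000 cluster tests on a
~15,000-person null population; power: 150 regenerated ~3,000-person
populations; recovery: 11 pipeline seeds) are the package's standard
evaluation runs, each executing in under a minute on a laptop.

# Limitations

Genealogy records assert social, not necessarily biological,
parentage; the kinship and gene-drop machinery takes the records at
face value.  The case definition through death certificates misses
recurrent cases who survive or whose certificates omit the cause, and
the registry linkage is assumed complete from its start year.  The
excess test ignores multiple testing across clusters, as is
conventional for this screening step.  Identity coefficients beyond
the kinship coefficient (inbred self-kinship aside), X-linked
inheritance, and pedigree drawing are out of scope.
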