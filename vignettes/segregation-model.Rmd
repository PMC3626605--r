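---
title: "Modelling S-haplotype segregation and self-compatibility in tetraploid cherry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling S-haplotype segregation and self-compatibility in tetraploid cherry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polySI)
```

# The model

## Gamete formation

A diploid parent contributes monoploid gametes, each homologue with
probability 1/2. A tetraploid under **tetrasomic** inheritance pairs its
four homologues at random, so its (hetero-diploid) gametes are the
$\binom{4}{2} = 6$ unordered pairs of distinct haplotypes. With
double-reduction rate $\alpha$ — the probability that a gamete receives two
copies descending from the same parental chromosome — the distribution is

$$P(\{a,b\}) = \frac{1-\alpha}{6}\ (a \ne b), \qquad
  P(\{a,a\}) = \frac{\alpha}{4}.$$

$\alpha$ is a dimensionless probability, default 0. The default is the
standard assumption for a locus without strong centromere linkage, and it is
the value under which no single-, ternary- or quaternary-allele progeny
classes arise in an interspecific 2x × 4x cross — exactly the class pattern
the bundled data show. The parameter is exposed rather than hard-wired so
that departures are representable and recoverable (`recover_parameters()`
ranks an $\alpha > 0$ candidate above $\alpha = 0$ when the data were
generated that way).

The alternative **fixed disomic** mode (`pairing_mode = "disomic_fixed"`)
models allotetraploid-like behaviour, as described for sour cherry: the four
haplotypes sit in two fixed subgenome pairs and only the four inter-pair
gametes form, each at 1/4. $\alpha$ does not apply there.

Duplicated haplotypes within a tetrasomic parent are rejected with an error
rather than silently collapsed: the closed form above assumes four distinct
labels, and none of the modelled cultivars violates that.

## The GSI filter

Each haplotype carries two functionality flags: `style_active` (S-RNase) and
`pollen_active` (SFB). The style of the seed parent presents all of its
style-active alleles. For a pollen grain, the *effective* specificities are
its distinct pollen-active alleles; a pollen-part-dead haplotype (e.g. the
defective Pps-S2 SFB) is invisible. The acceptance rule, per grain:

* SI disabled → accepted (models a fully compatible cross);
* two or more effective specificities and competitive interaction on →
  accepted, whatever the style — this is the self-compatibility mechanism;
* exactly one effective specificity → accepted iff it is absent from the
  style (classical GSI);
* no effective specificity → decided by `accept_null_pollen` (default
  accept, following the pollen-part-mutant literature; set `FALSE` to model
  a lethal mutant that aborts such grains).

Matching is on species-qualified keys (`Pps-S1` ≠ `Pa-S1`), so an
interspecific style never rejects the other species' specificities. The
`competitive_interaction = FALSE` mode (every effective specificity
independently lethal) is provided deliberately: on a fully functional self
cross it rejects *all* pollen, which is how the package expresses that this
model cannot explain self-fertile orchards — `recover_parameters()` gives it
an infinite score.

## Progeny classes

Eggs are never filtered (GSI acts on pollen only). Accepted pollen classes
are re-weighted by optional non-negative **transmission weights** — the
representation of pollen-tube performance distortion — and renormalised;
weights attach to pollen gamete classes, not zygotes, because that is where
the biology places the distortion. A progeny individual's phenotype class is
the *set* of distinct alleles over both gametes: presence/absence PCR is
dosage-blind, which is why a 2x × 4x seedling shows two or three alleles and
a 4x self seedling two, three or four. Observed-but-unexpected class zeros
(e.g. the missing S2S5/S2S8 cross classes) are *not* hard-coded anywhere;
they are representable only through weights, keeping mechanism and data
cleanly separated.

# Statistics

`chi2_gof()` is the plain Pearson statistic against expectations
proportional to a ratio vector. Conventions, chosen once and used
everywhere:

* **Zero-ratio cells**: expected 0 and observed 0 contributes 0; expected 0
  with a positive observation makes the model impossible (`chi2 = Inf`,
  flagged). This is the only convention that reproduces the published
  fitted-ratio statistics (e.g. 0.357 for 1:2:2:2:0:0).
* **Degrees of freedom**: $k - 1$ over all $k$ cells, including zero-ratio
  cells.
* **Critical values** are always recomputed from df via the χ² quantile
  function, never read from a printed label. The source tables we reproduce
  label 18.31 as a df = 11 entry, but 18.31 is the df = 10 quantile — which
  is also the correct df for an 11-class table — so recomputation quietly
  fixes the label while matching every usable printed value.
* No continuity correction; the published numbers match the uncorrected
  statistic. Internals keep full precision; printing rounds χ² to 3
  decimals.

`find_candidate_ratios()` makes the customary "approximately 5:1:5:5"
eyeball step reproducible: it exhaustively scores all integer ratio vectors
with terms in 0..`max_term` (deduplicated up to common scaling, all-zero
excluded), ranked by χ² with lexical tie-break. The search is capped at 8
classes and 5 × 10⁶ grid points, which covers every table in scope.

# The synthetic-data generator

`simulate_progeny_counts()` draws each replicate as one multinomial sample
of size `n_progeny` from the closed-form class distribution — the exact
sampling model the χ² analysis assumes. Replicate $r$ of a run seeded $s$
uses seed $s + r - 1$, so any replicate is individually reproducible. An
`event_level` mode instead simulates pollination events with per-grain
rejection sampling; it exists to cross-validate the closed form, and the
test suite checks the two routes agree.

What the generator emulates: multinomial sampling noise around the model
distribution, transmission distortion via weights, double reduction via
$\alpha$. What it does not emulate: genotyping error, embryo abortion or
germination selection, finite pollen pools, or spatial/pollinator structure.
A green simulation-based test therefore certifies the *inference machinery*
(calibration, power, model recovery) under the stated sampling model, not
the field realism of that model.

Problem sizes in the shipped tests mirror the study: progenies of 438/450
(selfs) and 24/49 (crosses); calibration uses 2000 replicates at n = 438
(df = 10), model recovery 500 replicates at n = 438, and the
law-of-large-numbers check a single n = 10⁵ table.

# Numerical choices

Gamete and class probabilities are built from exact reciprocals (1/2, 1/6,
1/4) and aggregated over at most a 10 × 10 table, so floating error stays
far below the 10⁻¹² tolerance asserted for probability conservation.
`expected_ratio()` reconstructs the smallest-integer form of a distribution
(e.g. 1:1:1:1:1:1:6:6:6:6:6 over 36) by rational recovery
(`MASS::fractions`) followed by LCM/GCD reduction — exact for every
distribution with rational weights. Output classes are ordered by class size
then lexically, a stable convention that makes TSV reports diffable.

Degenerate inputs fail fast with explanatory errors: a cross whose accepted,
positively weighted pollen mass is zero is "fully incompatible"; count
tables reject duplicate alleles within a class (classes are sets), duplicate
classes, negative or fractional counts, all with line numbers; the YAML
study config is strict — a schema tag is required and unknown keys are
errors.

# Interface decisions

The package surface is function-first (R users compose
`expected_phenotype_distribution()`, `chi2_gof()`, `simulate_progeny_counts()`
directly); the `polysi` script under `inst/exec/` is a thin shell over
`run_cli()` for TSV-in/TSV-out batch use. All randomness flows through
explicit seeds. The bundled study (three cultivars, four progeny tables,
strict YAML config) doubles as documentation and as the acceptance fixture:
every count in it is a published, printed number, so the whole analysis is
desk-reproducible.

# Limitations

* Progeny ploidy and allele dosage are not modelled — only detectable allele
  sets — so the package cannot distinguish, say, S1S1S5S8 from S1S5S8.
* Transmission weights are descriptive; no maximum-likelihood estimation of
  weights is attempted (the ratio search scores user-proposed small-integer
  hypotheses instead).
* Double reduction uses a single rate per cross, applied to both parents'
  gamete formation, and the fixed-disomic mode admits no partial preference
  between pairing modes.
* No multiple-testing correction across a battery of χ² tests; results are
  reported test by test, as is conventional for segregation analyses.
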