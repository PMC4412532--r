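---
title: "Genotype-based sports injury risk assessment: models and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genotype-based sports injury risk assessment: models and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injuryrisk)
```

# The problem

Recreational and elite endurance athletes sustain injuries at high rates,
and several of the underlying risk factors — low bone mineral density,
collagen-gene variants affecting tendon and ligament integrity,
micronutrient handling, the sickle hemoglobin allele — have well-studied
genetic components. `injuryrisk` turns a curated panel of
injury-associated SNPs plus one direct-to-consumer (DTC) raw genotype
file into a per-athlete, per-category risk assessment on a four-tier
colour scale, calibrated against a reference population.

This vignette documents the models, the tunable parameters, the
synthetic-data generator, and the conventions adopted where the
underlying literature leaves the design open.

# The additive model

For a category with loci $i = 1, \dots, L$, each panel variant carries an
effect allele, and an athlete's genotype contributes a dosage
$x_i \in \{0, 1, 2\}$ (copies of the effect allele; $\{0,1\}$ for
hemizygous calls). The category score is the weighted allele count

$$S = \sum_{i=1}^{L} w_i\, x_i,$$

where $w_i = \ln(\mathrm{OR}_i)$ for binary outcomes (ACL rupture,
Achilles injury, osteoarthritis) and $w_i = \beta_i$ for quantitative
traits (bone mineral density, biomarker levels). A category never mixes
the two weight scales. The bone-mineral-density category additionally
defines a *combined genetic score* over its flagged 63-SNP subset, the
score that the published reference bins (quintiles with top-bin odds
1.56 for osteoporosis and 1.60 for fracture; bottom-bin odds 0.38 and
0.54) refer to.

Sickle cell trait is the one Mendelian category: the call is determined
entirely by the rs334 dosage (0 = negative, 1 = trait carrier,
2 = homozygous variant, unmatchable = no call), not by a score.

## Allele matching and strand

DTC files report unphased genotypes on the forward strand of their
build. Matching proceeds per locus:

- call alleles within {effect, other} → direct dosage;
- call alleles within the base complements of {effect, other} → dosage
  counted on complemented alleles, flagged `strand_flipped`;
- palindromic panel sites (A/T or C/G), whose alleles are their own
  complements, cannot be strand-resolved from genotype data alone and
  are **excluded by default** (`ambiguous_site`); the
  `trust_palindromic` flag asserts same-strand reporting. We do not use
  frequency heuristics to rescue these sites.
- no call (`--`) → `missing_call`; insertion/deletion codes → `non_snp`;
  otherwise `allele_mismatch`.

Note that for a panel pair whose complement pair is disjoint (e.g. G/T,
complements C/A) the two sets jointly cover all four bases, so every
well-formed SNP call at such a site resolves either directly or as a
strand flip; genuine mismatches only arise at sites like G/A, where a
C in the call cannot be reconciled.

rs334 itself is an A/T substitution — a palindromic site. Because the
Mendelian call would otherwise always be `no_call`, `call_sickle_cell_trait()`
pins the orientation: it trusts forward-strand reporting at this single
site, with the sickle (HbS) allele encoded as T in the bundled panel.

## Missing loci in the combined score

The combined score assumes complete data. When loci are missing we
rescale by the weight ratio $\sum_i w_i / \sum_{i \in \text{matched}} w_i$
(flagged `rescaled`), and below a coverage floor of 0.9 (fraction of the
63 loci matched) the report abstains — tier *average* with a coverage
warning — rather than bin an unreliable score. Both the floor and the
rescaling are package conventions; per-athlete handling of no-calls is
not specified in the source literature.

# Calibration: the reference distribution

The reference population is modelled as unrelated individuals in
Hardy–Weinberg equilibrium (HWE): at a locus with effect-allele
frequency $p_i$, dosage $x_i \sim \mathrm{Binomial}(2, p_i)$ with
genotype probabilities $((1-p_i)^2,\; 2p_i(1-p_i),\; p_i^2)$, loci
independent (no linkage disequilibrium — a stated limitation shared with
standard polygenic-score reference constructions).

`exact_score_distribution()` computes the probability mass function of
$S$ by dynamic-programming convolution: per locus, the three
dosage-weight contributions are snapped to a grid of width `grid_step`
(default 0.01 on the weight scale; with ~63 loci and weights up to
$\ln 50$ the support stays below $10^4$ points) and convolved into the
running pmf. `mc_score_distribution()` draws the same model by
simulation and serves as an independent cross-check; both are verified
against the Binomial$(2n, p)$ closed form in the equal-weight case, and
the exact mean against the analytic $\sum_i 2 p_i w_i$.

## Bins and tiers

`derive_bins()` cuts the reference distribution at cumulative
probabilities 0.2/0.4/0.6/0.8 (configurable), yielding five quintile
bins as in the published combined-score categories. Quantile convention
for discrete pmfs: the $q$-quantile is the smallest support value whose
CDF reaches $q$; bins are half-open $[\text{lower}, \text{upper})$ with
the last bin closed above, so edge ties break deterministically upward
and a degenerate point-mass distribution maps every score to the last
bin. Whether the published five categories were exact quintiles is not
stated; quintiles are the default and the cut points are configurable.

The report uses four colour-coded tiers — decreased (green), average
(black), slightly increased (yellow), increased (red). The published
material does not state how five bins map to four tiers; this package's
convention is bin 1 → decreased, bins 2–3 → average, bin 4 → slightly
increased, bin 5 → increased. Categories other than the combined
bone-mineral-density score have no published bins at all, so each is
binned against its **own** exact HWE distribution with the same
quintile cuts and tier map — a deterministic, monotone rule that treats
every additive category symmetrically. Single-SNP findings are
additionally surfaced by a dosage rule (`tier_for_dosage()`): any copy
of a large-effect risk allele → increased; one/two copies at a
medium-effect site → slightly increased/increased; zero copies with
protective evidence → decreased; otherwise average.

# The synthetic cohort generator

`simulate_profiles()` draws unphased genotypes at the panel loci from
HWE at the panel's allele frequencies, independently across loci and
individuals, seeded for byte-identical reproducibility, and writes
DTC-dialect files. Injected profiles override the draws to create the
deterministic cases the analysis highlights: `all_heterozygous`
(dosage 1 at every category locus), `max_risk`/`min_risk` (dosage 2/0),
and `sct_carrier` (one sickle allele at rs334).

`default_cohort_spec()` encodes the 14-athlete study structure: 9 male /
5 female; 10 of 14 injured in season one (71.4%); season-two status
known for 12 (one male and one female unknown), of whom 4 were injured
(33.3%). Injury labels are static fixture attributes — the observed
incidence comparison is descriptive counting, not a genotype–outcome
model, and the generator deliberately simulates no such dependence.
The fixture cohort is forced sickle-cell negative (`sct_negative`),
matching the observed cohort regardless of seed: at the bundled
HbS frequency a 14-person HWE draw would otherwise contain a carrier
about a quarter of the time. One individual is injected heterozygous at
all seven osteoarthritis loci and two carry the extreme combined-score
genotypes, mirroring the individuals the study singles out.

What the generator does **not** emulate: linkage disequilibrium,
genotyping error and batch no-calls, ancestry-specific allele
frequencies, and any genotype–injury association. Passing tests
therefore demonstrate the pipeline's correctness under its stated
population model, not predictive validity on real athletes.

# The fixture panel

The bundled panel (`inst/extdata/injury_panel.tsv`) reproduces the
curated review's composition — ACL rupture 4, Achilles tendon 6, bone
mineral density 67 (63 in the combined score), osteoarthritis 7,
vitamin/mineral 39, sickle cell trait 1; 124 total, 113 (91%) new to
sports genetics — but its rsIDs, positions, weights and frequencies are
**synthetic, seeded placeholders** (see `data-raw/make_panel.R`) except
for rs1800012 (Achilles, OR 11, G risk allele) and rs334. Weights were
drawn with realistic magnitudes: $\ln(\mathrm{OR})$ for published OR
ranges (2.4–12.6 ACL, 1.1–1.2 osteoarthritis), small betas
(0.02–0.12 SD) for the GWAS-derived quantitative categories. The
source table's vitamin/mineral sub-rows sum to 41 against a printed
category total of 39; the fixture resolves this with 39 unique variants,
two of them dual-labelled `b_vitamins;homocysteine` (folate-pathway
genes). Its prose reports 66 bone-mineral-density SNPs against a
printed 67; the fixture carries 67 so the grand total is 124. All
fixture loci are autosomal, so hemizygous dosage handling is exercised
by property tests only.

# Numerical choices and problem sizes

- Grid step 0.01 keeps mean-snapping error below $L \cdot
  \text{step}/2$; tests assert the analytic mean within that bound.
- Monte-Carlo cross-checks use $10^5$ draws at seed 2015 (always logged
  in the distribution object); quantile agreement is asserted within
  three binomial standard errors plus one grid point of slack.
- The simulated-cohort convergence check scores 3,000 individuals
  against the exact quintile masses with a chi-squared test at
  $\alpha = 10^{-3}$ — large enough to detect a mis-specified
  generator, small enough to keep the suite fast.
- Ties, degenerate pmfs and empty inputs: smallest-support quantiles,
  upward-closing bins, point mass at 0 for empty locus sets, and typed
  exclusions (never silent drops) in matching.

# Limitations

The assessment inherits every caveat of the source associations: small
candidate-gene studies behind the large ACL/Achilles odds ratios, effect
sizes estimated in non-athlete cohorts, and no modelling of
gene–environment interaction. The package reports relative position in
a model reference population — it is a research and education tool, not
a diagnostic.

```{r example}
panel <- load_panel(system.file("extdata", "injury_panel.tsv",
                                package = "injuryrisk"))
scheme <- derive_bins(exact_score_distribution(panel, combined_only = TRUE))
profiles <- simulate_profiles(panel, default_cohort_spec(seed = 2015))
report <- assess_athlete(profiles$A01, panel, scheme)
writeLines(render_report(report, "text"))
```
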