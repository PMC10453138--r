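---
title: "Methods: purity screening and adulterant quantification for single-ingredient herbs"
author: "ddPurity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: purity screening and adulterant quantification for single-ingredient herbs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddPurity)
```

## The problem

Dried, milled herbs sold as a single ingredient — oregano is the
canonical case — are attractive targets for bulking with cheaper plant
material (olive, myrtle or cistus leaf, marjoram) and routinely carry
field contaminants (bindweed, goosefoot, thyme). DNA metabarcoding
detects essentially every species that left DNA in a sample, but the
*fraction of sequencing reads* a species receives is a poor proxy for
its mass fraction: extraction yield, per-barcode amplification bias,
marker copy number and attribution errors between close relatives all
distort read shares, sometimes by more than an order of magnitude in
either direction. ddPurity implements the complementary quantitative
workflow: droplet digital PCR (ddPCR) absolute quantification, a
DNA-accounting purity screen, copy-percentage estimation of
non-declared species, rule-based classification of read tables, and
concordance analysis between the two measurement routes — together
with a synthetic-data generator that makes the whole chain testable
without instrument data.

## Poisson quantification

A ddPCR reaction is partitioned into on the order of 20,000
nanolitre-scale droplets. Target molecules distribute across droplets
approximately independently, so a droplet's occupancy is Poisson with
mean $\lambda$ (copies per droplet) and

$$\hat\lambda = -\ln\frac{n_{\mathrm{neg}}}{n_{\mathrm{tot}}},\qquad
  \text{copies/reaction} = \hat\lambda\, n_{\mathrm{tot}}.$$

Confidence intervals come from a Wilson score interval on the negative
fraction, mapped through $-\ln$ (the upper fraction bound becomes the
lower $\lambda$ bound). Wilson was preferred over Wald for its
behaviour at few positives or few negatives; both are available
(`ciMethod`). A well with **no negative droplets** carries no
information about $\lambda$ beyond a lower bound, so it raises an
explicit saturation error rather than returning a number; a well with
**no positives** returns $\hat\lambda = 0$ with a one-sided interval
and a `not_detected` flag. Replicate wells are pooled by summing
droplet counts before re-estimating (`poolWells()`), which is tighter
than averaging per-well estimates.

`copies/reaction` is deliberately the quantity all downstream modules
consume: converting to copies/µL requires the droplet-volume constant
(default 0.85 nL, configurable), which cancels in every ratio the
package reports.

## Droplet calling

Instrument software and published callers classify droplets from their
end-point fluorescence; ddPurity fixes one concrete, few-knob design:

1. Gaussian-kernel density estimation of the 1-D amplitude
   distribution. The default bandwidth is Silverman's rule capped at
   1/8 of the amplitude range — the cap only matters for very small
   inputs, where the rule's variance-based bandwidth can smooth two
   obvious clusters into one.
2. The dominant mode is the highest-density peak. The secondary
   population is the candidate peak with the greatest *prominence*:
   its density divided by the deepest valley density between it and
   the dominant mode. Shoulder ripples of a single population score
   near 1; a genuine second cluster scores well above. The call is
   two-population only if the best score exceeds `minValleyRatio`
   (default 1.5), the peak passes a relative height floor
   (`relModeHeight`, default $10^{-3}$ of the maximum — small enough
   to keep a 0.1% positive cluster, large enough to ignore
   single-droplet bumps), and the minority side of the threshold holds
   at least `minSideCount` droplets (default 3, mirroring the trace
   limit of detection; one or two coincident outliers are not a
   population).
3. The threshold is the density minimum between the two modes.
   Droplets exactly at the threshold are called negative —
   conservative for contamination claims.
4. "Rain" (intermediate amplitudes from partly amplified droplets) is
   handled by robust centres: droplets between
   $\mathrm{median}_{\mathrm{neg}} + k\cdot\mathrm{MAD}_{\mathrm{neg}}$
   and $\mathrm{median}_{\mathrm{pos}} - k\cdot\mathrm{MAD}_{\mathrm{pos}}$
   (default $k = 5$) are reassigned to the nearer robust centre.

Unimodal wells never crash: they are flagged and called all-negative
by default, or classified against a user-supplied `negativeBand` when
the instrument's negative amplitude range is known. Equivalence with
any particular published caller is not claimed; the package validates
the *Poisson layer above the calls* (bias, coverage) and validates the
caller itself against a brute-force oracle (`thresholdOracle()`)
that exhaustively minimizes within-class variance on small instances,
plus ground-truth labels on simulated wells.

## DNA accounting

If a sample labelled "100% species S" truly is, then every picogram of
its DNA belongs to S, and the ddPCR copy measurement must match the
copy number implied by the fluorometrically measured DNA mass:

$$\mathrm{expected} = \frac{m\,[\mathrm{ng}] \times 1000}
  {\text{1C}\,[\mathrm{pg}]} \times c_{\mathrm{hap}},$$

with 1C the haploid genome size (C-value scale) and
$c_{\mathrm{hap}}$ the number of target sequences per haploid genome.
The expected *range* propagates the fluorometric uncertainty through
this linear formula as mass mean $\pm k\cdot$sd (default $k = 2$),
where mean and sd come from the four replicate measurements of the
routine fluorometric workflow (two independent dilutions, each
quantified twice). Measured copies below the range indicate foreign
DNA: on a sample whose DNA is a mass fraction $f$ foreign (similar
genome sizes), the measured/expected ratio converges to $1 - f$.

Fluorometric replicate noise is simulated as lognormal with the stated
coefficient of variation (concentrations are positive and fluorometric
error is multiplicative; the lognormal is parameterised to be
mean-unbiased), with a truncated-normal alternative. Under the default
5% CV and $k = 2$, simulated pure samples are flagged `within` about
95–97% of the time; the screen is a coarse filter by design, and
extraction-efficiency or degradation differences between species —
real confounders of the method — are deliberately not modelled.

## Copy percentage of a non-declared species

ddPCR measures *target* copies; species are compared in genome
equivalents $GE = \text{copies} / c_{\mathrm{hap}}$, and

$$\text{copy\%} = 100 \cdot \frac{GE_{\mathrm{adulterant}}}
  {GE_{\mathrm{adulterant}} + GE_{\mathrm{ingredient}}}.$$

Ploidy is kept separate from the per-haploid target correction: it
enters only when per-cell units are requested (`perCell = TRUE`),
because one cell holds ploidy × haploid genomes. The two conventions
are frequently conflated; keeping them orthogonal lets either be
configured. Converting copy% to a DNA **mass** percentage weights the
genome equivalents by 1C sizes — the exact inverse of the mixture
generator's arithmetic, so the composition recovered from noise-free
copies equals the gravimetric input identically. Results with fewer
than 3 positive droplets for the adulterant are flagged
`trace_not_quantifiable` rather than silently reported as a
percentage.

The packaged assay table
(`inst/extdata/species_assays_synthetic.tsv`) carries *synthetic*,
representative C-value-scale constants for the oregano panel; it
supports simulation and demonstration and is not a transcription of
any laboratory calibration.

## Read-table classification

The raw attribution table is filtered to kingdom Plantae, converted to
read percentages, and classified with a taxon→class map
(ingredient / adulterant / contaminant / noise). Decision rules:

* an **adulterant** with ≥ 1 read is always sent to ddPCR
  confirmation — these are the fraud-relevant species and
  metabarcoding under-reports several of them badly;
* a **contaminant** is confirmed only when its read% strictly exceeds
  5% — below that, attribution noise between close relatives is a
  plausible explanation and confirmation effort is not warranted;
* ingredients and noise are never confirmed.

Percentages default to the *retained* (post-filter) denominator so
they sum to 100 over reported taxa; attribution pipelines that report
against a larger total including unlisted reads are supported via
`denominator = "all"`, and the convention used is recorded on the
output. Taxon matching normalizes case and whitespace, treats
"*Genus* spp." map entries as genus wildcards, and resolves
abbreviated genus names ("O. majorana") by initial plus epithet when
unique — mirroring the mixed granularity of real attribution output.
Unknown taxa default to noise, with a message.

## Concordance between read% and copy%

Per species, across samples, the package reports Pearson's $r$, an
ordinary least-squares fit, and the two-sided p-value for zero
correlation (equal to the slope t-test in simple regression; both are
reported). Regression orientation was a genuinely open choice: the
package regresses **copy% on read%**, treating ddPCR as the reference
measurement, so the slope reads directly as a reporting-bias factor —
a species *over-represented* among reads shows a slope well below 1, a
species *under-represented* a slope well above 1, consistent with the
per-species slope patterns reported for this assay family. The
orientation is configurable (`response`). Statistics are computed on
the linear scale; the log-log axes of `scatterExport()` are
presentation only, with zeros drawn at half the smallest positive
value and annotated. `reportingBias()` gives a scale-free direction
call via the sign test on read% − copy%.

## The synthetic-data generator

The generator defines the conditions every test and validation study
runs under:

* **Droplets** (`simulateDroplets()`): occupancy Poisson($\lambda$);
  amplitudes Gaussian per population (defaults 2000 ± 200 negative,
  8000 ± 300 positive, 20,000 droplets — typical for the instrument
  class); an optional `rainFraction` of droplets drawn uniformly
  between the population means, keeping their occupancy ground truth
  (rain arises from partly amplified positives; a label-preserving
  model suffices for caller testing). Amplitude population parameters
  are free simulation knobs, not calibrated to any instrument.
* **Fluorometry** (`simulateFluorometry()`): four lognormal replicates
  with configurable CV (default 5% in the pipeline), averaged as in
  the routine workflow.
* **Mixtures** (`simulateMixtureCopies()`): deterministic conversion
  of mass fractions to target copies via 1C sizes and per-haploid
  target counts; 18 ng template per reaction by default, the routine
  input for this assay family.
* **Read tables** (`simulateReadTable()`): expected shares ∝ abundance
  × per-species bias, zeroed by per-species dropout (emulating total
  extraction failure, as seen for sumac), multinomial counts, then a
  row-stochastic misattribution matrix redistributing reads between
  neighbours (`neighbourLeakMatrix()` builds identity-plus-leak
  matrices emulating cross-talk within tribes of close relatives).
  Totals are conserved exactly.

What the generator does **not** emulate: sequence-level error,
chimeras, barcode-specific primer bias structure, DNA degradation and
extraction-efficiency differences, droplet volume dispersion. Passing
tests therefore demonstrate that the *statistical machinery* is
correct under its stated assumptions — not that those assumptions
capture every behaviour of real market samples.

## Numerical and design notes

* All generators accept a seed and are bit-reproducible;
  `runPipeline()` derives every simulation from a single config seed,
  and its manifest records seed, thresholds and a config hash.
* Validation studies: $\lambda$ recovery runs the full
  simulate→call→estimate chain at $\lambda \in [0.05, 1.5]$,
  $n = 20{,}000$, 500 replicates per point (tolerances: |relative
  bias| < 1%, nominal-95% coverage within ±1.5 percentage points).
  At 500 replicates the Monte-Carlo standard error of a coverage
  estimate is ≈ 1 percentage point, the same order as the band, so
  the package's own coverage assertion uses 2000 count-level
  replicates per $\lambda$; problem sizes were chosen so the full
  suite runs in well under a minute on one core.
* Mixture recovery follows the 1/2/5% (m/m) olive-in-oregano design
  at 30–50 replicates per level, paired with a 0.25× read-bias
  simulation demonstrating the core contrast: read% stays nearly flat
  and below copy% while the ddPCR route recovers the gravimetric
  truth.
* Cross-sample concordance on the package's own synthetic cohorts
  recovers injected bias factors; the per-sample survey pairs behind
  the published per-species table are not redistributable here, so
  `studyTable5()` accepts that table in a documented CSV layout and
  reports an explicit skipped status when it is absent.
* Degenerate inputs are first-class: saturated wells error with a
  dedicated condition class, zero-read tables and unimodal wells are
  flagged, not fatal, and `account()` flags are guaranteed consistent
  with interval membership by the class validity method.

## Known limitations

Duplex assays are processed channel by channel (no 2-D joint
clustering); regression is plain OLS (no errors-in-variables
treatment, matching the method being emulated); cohort-level market
statistics (fractions of samples failing the screen, per-species
detection frequencies) depend on physical survey samples and are out
of scope; and class maps / assay constants shipped with the package
are starting points a laboratory must replace with its own validated
values.
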