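---
title: "Quantifying UV-induced pyrimidine dimers and RNA:DNA hybrids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying UV-induced pyrimidine dimers and RNA:DNA hybrids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvrdh)
library(dplyr)
```

## The problem

Ultraviolet light induces pyrimidine dimers (PDs) in bacterial DNA. In
*Escherichia coli* mutants lacking both RNase H enzymes (`rnhAB`), a small
class of PDs escapes nucleotide excision repair; these lesions stall
transcription elongation complexes and nucleate stable RNA:DNA hybrids
(RDHs, R-loops) that block replication. None of the underlying
measurements are sequencing-based: the evidence comes from gel and blot
assays — plasmid topoisomer gels, western/Southern densitometry,
immunoprecipitation dot blots, serial-dilution survival spotting, and
radioactive pulse labelling.

`uvrdh` implements those quantification methods as a reusable pipeline,
together with a scenario-driven generator that emulates each assay with
the statistical structure the analysis assumes. Every stage of the
pipeline can therefore be exercised end to end without any external
data, and the estimators can be checked against the constants the
generator was given.

## The estimators

**Plasmid relaxation (Poisson zero class).** A lesion-specific nuclease
(T4 PD-glycosylase for PDs, RNase HII/HI for DNA-ribonucleotides) nicks
plasmids at its target lesions, converting supercoiled (SC) molecules to
relaxed circles (RC). Nicks per plasmid are Poisson, so the surviving SC
band is the zero class:

$$\hat\lambda = -\ln\frac{F_\text{treated}}{F_\text{untreated}},
  \qquad F = \frac{SC}{SC + RC},$$

with the untreated lane absorbing background nicking. Scaling by genome
over plasmid length (both in double-stranded nucleotides) gives lesions
per genome. `supercoiled_fraction()`, `mean_nicks()` and
`lesions_per_genome()` implement the three steps;
`estimate_lesion_density()` runs them over a band table.

**Blot densitometry.** A density is a western signal divided by the
matching Southern (DNA loading) signal, making it gain- and
loading-invariant. Two normalization rules make densities comparable
across experiments: hybrid (S9.6) densities are divided by the same
batch's `rnhAB` log-culture density; PD densities are expressed as a
percentage of the same strain's 5-min post-UV density, after
subtracting the pre-UV background (`normalize_series()`).

**16-fraction co-enrichment.** Lane profiles of HaeII-digested genomic
DNA are split into 16 equal migration windows from the well to the
0.2–0.5 kb lane bottom (default cutoff 0.35 kb, the midpoint). In each
fraction, the normalized RDH density (30 min / log) is multiplied by the
normalized PD density (30 min / 5 min); the product is the
co-enrichment value. A peak in a single size fraction indicates that
hybrids and the slow-to-repair PDs co-reside on the same fragments.
Under the default log-size migration model
($\text{size}(x) = 50\,\text{kb}\,(0.35/50)^{x}$), fraction #6 spans
7.8–10.6 kb, bracketing the 8–10 kb window where the co-enrichment
maximum is expected.

**DRIP enrichment.** S9.6 immunoprecipitation splits a digest into
input, DRIP (bound) and eluate (unbound) fractions. Enrichment is the
DRIP (or eluate) density over the input density, per channel; overall
enrichment is DRIP over eluate. The theoretical ceiling for PD
co-enrichment under the anchored-PD model — each hybrid anchored at one
PD, Poisson background at density $\lambda$ over the captured span
$S = \max(\text{fragment}, \text{hybrid length})$ — is

$$E_{\max} = \frac{1 + \lambda S}{\lambda S},$$

implemented in `expected_max_pd_enrichment()` and validated against a
Monte-Carlo oracle in the tests. It reproduces the observed ordering:
no enrichment uncut, ~2-fold for 4-kb digests, larger for fine cutters.

**Survival and epistasis.** Titers come from pooled countable spots
(3–300 colonies; Poisson maximum likelihood, which is
inverse-variance weighting); survival is the treated/untreated titer
ratio with a Poisson-ratio confidence interval. The null expectation
for two independent defects is multiplicative,
$S_{ab} = S_a \times S_b$; `epistasis_predict()` calls synergy or
suppression when the observed double-mutant survival deviates more than
3-fold (configurable) from the product.

**DNA synthesis rates.** Pulse-labelling counts are divided by recorded
cumulative culture-dilution factors (2-fold at 50, 90, 150 min);
`normalize_synthesis()` undoes the dilutions exactly and anchors the
series at the first measurement (unirradiated) or the pre-UV time-0
measurement (UV-treated).

## What the generator emulates

A `scenario()` bundles one strain × dose condition. The central
constants (see `scenario_preset()`):

| parameter | default | meaning |
|---|---|---|
| `pd_induction_rate` | 41.7 | PDs per J/m² per genome (≈1500 at 36 J/m²) |
| `pd_density_per_nt` | – | direct override; the DRIP scenarios use 1/10 kb at 8 J/m² |
| `genome_length` | 9.2e6 nt | single linear genome, 0-based half-open intervals |
| `slow_pd_fraction` | strain | 0.02 (WT), 0.19 (`rnhAB`) |
| `fast/slow_half_life` | 6 / 60–57 min | chromosomal two-class removal after a 5-min lag |
| `plasmid_*_half_life` | 15 / 60 min | plasmid-assay removal (half gone by 20 min) |
| `rdh_length_mean` | 3500 nt | induced hybrid length (gamma, shape 12) |
| `rdh_fold` | table | total hybrid nt vs baseline per timepoint |
| `background_nicks_per_genome` | 45 | relaxation-assay background |
| `noise_cv` | 0.15 | multiplicative log-normal band/fraction noise |

Two PD-density anchors coexist in the source measurements (41.7/J/m²
from the relaxation assay; 1 PD per 10 kb at 8 J/m² in the DRIP
experiments). They are deliberately not reconciled: each scenario
carries the constant its own assay reports.

Mechanistically, a chromosome state at time *t* holds the surviving PDs
(each slow with the strain's probability, classes decaying
exponentially after a 5-min engagement lag) and the hybrid intervals.
Baseline hybrids are short (300 nt) dispersed stretches. UV-induced
hybrids are either additional dispersed stretches (RNase H-proficient
strains, which resolve anchored structures) or full-length structures
anchored each at one surviving slow PD (RNase H-deficient strains),
with the total hybrid nucleotides following the scenario's fold table.

Digestion draws truncated-exponential fragment lengths (0.1–50 kb;
means 4.0 / 1.2 / 0.6 kb for EcoRI+BamHI / HaeII / HaeIII) plus a minor
partial-digestion component (0.6 % of draws, mean 30 kb) so that every
lane fraction carries detectable DNA, as real genomic digests do. For
restriction enzymes, candidate cuts inside a hybrid — plus a
1.3 kb protection margin around anchored structures in the `rnhAB`
scenario, representing the stalled polymerase/fork footprint — are
suppressed, which is what concentrates hybrid-bearing fragments near
9 kb (fraction #6). The DRIP scenario uses no margin (its hybrids
measure 3–4 kb on gels) and no partial-digestion tail (digestion
completeness was verified in that assay), and models "uncut" genomic
preps as randomly sheared to a 5.5 kb mean.

DRIP capture is per fragment: a hybrid-specific hazard per full-length
hybrid equivalent (`p_spec`), non-specific background (`p_bg`), a minor
"sticky" fragment class carrying S9.6-cross-reactive signal that
survives RNase HI (~1 % of the hybrid signal), and a per-PD capture
boost — S9.6 also recognises UV-damaged DNA, which is why observed PD
enrichment can exceed the proximity ceiling. RNase HI treatment scales
each fragment's hybrid content (and hence its specific capture hazard)
to 1 %. DRIP + eluate equal input exactly, by construction.

Scenario constants are calibrated once so that the pipeline, run on
generated data, recovers the assays' reference values (the 13-fold
hybrid rise, the ~29 co-enrichment peak, the 95× / 15× / 10× / 2× / ≥3×
enrichment panel, the 20-fold kill); the presets freeze that
calibration and `write_scenario()` / `read_scenario()` round-trip it as
YAML.

## What passing tests do not show

The generator reproduces the *statistical* structure of the assays, not
their molecular detail. It does not model real restriction-site
positions (sequence-resolved digestion is out of scope), antibody
chemistry beyond effective capture probabilities, chemiluminescence
saturation, gel-image artefacts, or the mechanism of transcription
stalling. Agreement between pipeline and generator demonstrates that
the estimators are correct and well-calibrated under the assumed noise
model — multiplicative log-normal band noise, Poisson counts — not that
real blots satisfy those assumptions. The WT co-enrichment profile
comes out flat around 0.5 rather than showing the small real-data peak
(~2) in fraction #6, because WT-induced hybrids are modeled as fully
dispersed; the `rnhAB` non-peak level is likewise somewhat below the
real one. Both are documented modeling simplifications.

## Numerical choices and edge cases

* Pre-UV samples are encoded as `time_min = -1` throughout.
* `mean_nicks()` clamps negative estimates (treated fraction above
  untreated — blot noise) to zero with a warning, and reports a
  saturated (`Inf`) density when the treated supercoiled band is empty.
* Fractions with zero Southern signal — or, in the lane pipeline, with
  Southern below 1e-3 of the lane total (the detection limit) — are
  flagged missing, never zero, and missing values propagate through the
  co-enrichment product rather than being imputed: the product would
  fabricate peaks.
* Argmax ties in the co-enrichment peak resolve to the lowest fraction
  index, with a warning.
* The countable-spot window (3–300 per spot) and Poisson-ML pooling are
  conventions, both configurable.
* Replicate relaxation gels are pooled by averaging per-gel estimates
  (default); `pool = "fractions"` averages supercoiled fractions first.
* Band profiles are rendered on a 512-point grid with a Gaussian band
  kernel (sd 0.012 migration units, ~1/5 of a fraction width); lanes
  pool 40 genomes (co-enrichment) or 10 genomes (DRIP) per sample, and
  the relaxation assay uses 2000 plasmid molecules per lane — problem
  sizes chosen to keep fraction statistics stable at tractable cost.
* Seeds: every simulator accepts a `seed` and reproduces its output
  byte-identically under a fixed RNG kind; sub-seeds are derived
  arithmetically and stay within 32-bit range.

## A worked run

```{r example, eval = FALSE}
# lesion burden from plasmid relaxation
recover_pd_burden(n_replicates = 50, seed = 7)

# co-enrichment of hybrids and PDs in the rnhAB scenario
co <- recover_coenrichment("rnhAB", seed = 11)
glance(co)
autoplot(co)

# DRIP enrichment panel and its theoretical ceiling
recover_drip_panel(n_replicates = 3, seed = 13)
expected_max_pd_enrichment(1e-4, 1200, 3500)
```

## Known limitations

The co-enrichment peak height is sensitive to the baseline hybrid pool
and the protected-fragment size distribution; with only three replicate
experiments (the assay's own design) its sampling spread is ~10 %.
Whole-lane blot fold changes carry a similar spread at five replicates
under the 15 % band-noise model. The anchored-PD expectation treats the
captured span as fixed at the mean; a full length-distribution
treatment would lower the ceiling slightly for broad fragment
distributions.
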