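---
title: "Collagen fingerprint identification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collagen fingerprint identification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zoomsid)
```

`zoomsid` turns MALDI-ToF collagen spectra into tiered taxonomic
identifications. This vignette is the package's own account of the
method: the processing model stage by stage, every tunable parameter with
its unit and default, what the synthetic-data generator does and does not
emulate, and the design decisions taken where the problem was genuinely
open.

## The processing model

### From trace to peak list

A sample enters as one or more profile-mode traces (replicate MALDI
spots). The stages of `preprocess_spectrum()`:

1. **Replicate averaging.** Traces are linearly interpolated onto a
   uniform grid (`resample_step`, default 0.02 Da) covering the
   intersection of their ranges and averaged pointwise. Averaging profile
   traces — rather than intersecting peak lists — follows the usual
   practice of reading one averaged spectrum per sample; a
   consensus-peak alternative (`consensus_peaks()`, peak kept if seen in
   ≥ 2 replicates) is available for workflows that pick first.
2. **Smoothing.** Savitzky–Golay, `smoothing_window` 15 points and
   `smoothing_polyorder` 2. Fifteen points equal 0.3 Da at the default
   grid — one peptide peak FWHM, the conventional window sizing. The
   filter reproduces any quadratic exactly (including at the edges), so
   peak apex heights are attenuated by under 2 %, while smoothed-noise
   maxima stay near 1.8 σ, comfortably below the 3 σ pick threshold.
3. **Baseline.** SNIP: iteratively clip each point to the mean of its
   neighbours at half-windows growing to `baseline_iterations` (100
   points = 2 Da), which erodes narrow peaks away and leaves the slowly
   varying background. One correction matters in the presence of noise:
   the clipping estimate tracks the *lower envelope* of the trace, so
   the residual would sit about one noise sigma above zero and ordinary
   noise maxima would masquerade as low-grade peaks. The residual is
   therefore recentred by its running median (window `noise_window`)
   before clipping at zero; the window is wide relative to any peptide
   peak, so true peaks are unaffected.
4. **Noise.** A running median absolute deviation over `noise_window`
   (5 Da) windows, scaled by 1.4826 to Gaussian sigma, computed on the
   **unsmoothed** trace. Estimating noise after smoothing would divide
   peak and noise by the same factor and silently inflate the SNR of
   noise maxima ~2×; measuring smoothed apexes against raw noise is what
   keeps the two SNR grades meaningful.
5. **Picking.** Local maxima of the smoothed, baseline-subtracted trace
   with SNR ≥ `snr_low_threshold` are retained; peaks closer than
   `min_peak_separation` (0.3 Da) are merged keeping the more intense
   (ties towards lower m/z). Merging decisions are made on grid values so
   they are exactly reproducible; the retained apexes are then refined by
   parabolic interpolation (position error ≲ grid step/2).
6. **Recalibration (optional).** A two-parameter linear correction
   (offset + slope) fitted by least squares to peaks matched against
   external calibrant masses. Two parameters only, because the calibrant
   geometry of any given plate is unknown and a linear model is robust
   with as few as two matched references; with fewer matches the peak
   list is passed through unchanged with a warning.

### The two SNR grades

Published marker tables annotate some cells as "present but at low
intensity, or below signal to noise threshold" without quantifying the
threshold. The package operationalises this as two configurable grades:
`snr_pick_threshold` 3.0 (the conventional detection limit — full-grade,
"present") and `snr_low_threshold` 1.5 (low-grade, the "?" state). These
are declared conventions, not reconstructions of any particular lab's
settings.

### Contaminants

Keratin is handled as a mass lookup (`flag_keratin`, tolerance 0.2 Da)
against a shipped, user-replaceable TSV of commonly reported tryptic
keratin masses — the field treats these as well-documented lookups, and
the right list is a curation question, not a modelling one. Plastic
residues are detected as maximal arithmetic progressions among peaks
below `polymer_max_mz` (1500 Da, since such residues concentrate at the
low-mass end): at least `polymer_min_length` = 5 members, median gap
within 14–80 Da, every gap within 0.1 Da of the median. The search is a
complete depth-first enumeration — sound because in any valid series all
gaps agree pairwise within twice the gap tolerance — and is checked in
the test suite against an independently written exhaustive oracle.
Flagged peaks are annotated, never deleted: a peak matching both a
keratin mass and a marker mass keeps both roles, and the classifier
demotes keratin-flagged matches to low-grade evidence, which is the
conservative direction for species claims.

### Matching, scoring, tiers

Each marker observation is graded `PRESENT` / `LOW` / `ABSENT` as
described in the README; paired markers require both masses for full
presence, and one-of-two matches count as `LOW` by default (`strict_pairs`
flips them to `ABSENT`) — partial evidence differs from no evidence. The
per-taxon score is the observed fraction of the taxon's expected marker
weight (uncertain-expected markers weigh `uncertain_weight` = 0.5; `LOW`
observations contribute half weight). Tier rules, in order: a top score
below `probable_score` (0.5) or fewer than `min_markers` (3) observed
markers is "X"; a unique top taxon at or above `species_score` (0.75)
with all diagnostic markers fully present is a species call; a unique top
taxon at or above `probable_score` is "Probable"; ties (within 1e-9,
resolved deterministically by label order for reporting) within one rank
group report the group label. The numeric thresholds are inventions — the
reference workflow is expert judgement — chosen once so that a complete
pattern yields a species call and HMWP-degraded patterns demote through
"Probable" to the family label, and exposed in `classifier_params()` for
recalibration against any other panel.

## The synthetic-data generator

`generate_spectrum()` emulates the statistical structure the analysis
assumes: Gaussian peaks (FWHM 0.3 Da) at every expected marker mass of a
taxon, apex height `peak_snr × noise_sigma` (20 × 1 by default;
uncertain-expected markers at half height), an exponential chemical
baseline (amplitude 5, decay 600 Da), a constant noise floor (5 a.u. — a
pure zero-mean noise trace would be half-clipped by the non-negativity
invariant and bias every scale estimate), i.i.d. Gaussian detector noise,
and a linear miscalibration model (constant offset plus ppm slope). All
randomness is fixed by `seed`; every generated spectrum carries a truth
table of planted peaks so that round-trip tests never re-derive ground
truth.

Degraded (storage-bag / eraser) acquisitions are modelled by a single
exponential attenuation above an onset: intensities beyond `onset_mz`
(2000 Da — the problematic markers in practice sit at ≳ 2800) are scaled
by `exp(-(m/z - onset)/tau)`. The qualitative statement being modelled is
that the more damaged the collagen, the fewer intact long peptides
survive; a single exponential is the simplest monotone family with a
closed-form test point. Two modes ship with finite scales (bag τ = 400,
eraser τ = 800 — bags degrade harder); no fitted τ is claimed, and the
validation relies on qualitative tier demotion, not on any particular
value. One ordering decision matters: when a `degradation_config` is
passed to the generator, the attenuation is applied to the peptide
*signal* before noise is added, because analyte loss does not shrink
detector noise — attenuating a finished noisy trace scales signal and
local noise equally, leaving every SNR unchanged, and no demotion could
ever occur. The standalone `degrade_hmwp()` applies the multiplicative
contract to whatever spectrum it is given and is the right tool for
noiseless traces and closed-form checks.

What the generator does **not** emulate: isotope envelopes, detector
saturation, peak-shape asymmetry, mass-dependent resolution, chemical
noise structure, or real keratin/polymer chemistry. Passing tests
therefore demonstrate that the pipeline's logic is correct under its own
stated assumptions, not that any particular instrument's spectra will
behave identically; on real data the SNR thresholds and the keratin list
are the first things to recalibrate.

## The builtin cervid panel

The packaged panel transcribes a published five-cervid marker table:
twelve marker rows (P1 1105; A 1150+1166 roe / 1180+1196 others; B 1427;
C 1550 / 1580; P2 1648; D 2131; F 2883+2899; G 3017+3033 red/fallow,
3043+3059 roe/white-tailed, 3093 caribou) with species-specific markers
flagged diagnostic. Mass variants of one peptide (the A, C and G rows)
are separate marker records sharing a `group`, each with its own
expectation column — the variant identity, not just the group, is what
carries the taxonomic signal. Two caveats are deliberately preserved
rather than repaired: the typographic rendering of the C rows (which
taxa carry 1550 vs 1580, and which cells are emphasised) is ambiguous in
the available transcription, so it is isolated in
`inst/extdata/cervid_panel/` for easy correction; and Red and Fallow
Deer have identical expectation vectors, so `validate_panel()` reports
them as indistinguishable and the classifier can only ever return the
family label for either — which is the honest answer, not a defect.
Non-cervid taxa (bear, human, the Carnivora patterns) are *not* shipped:
their marker masses live in prior literature rather than in the
transcribed table, and inventing them would be worse than omitting them.
The panel format (TSV pair or JSON) exists so users can add them from
the primary sources. The observed marker patterns of the three
archaeological deer-bone samples are shipped separately as a test
fixture (`dr_sample_patterns.tsv`), not as panel taxa.

## Numerical choices and degenerate inputs

* Text spectra and peak-list TSVs are written with 17 significant digits,
  the minimum that round-trips IEEE doubles bit-exactly.
* Score ties are resolved at 1e-9; taxon ordering in reports is
  alphabetical; re-running `explain_identification()` on the same object
  is byte-identical.
* An empty or flat spectrum yields an empty peak list, all-`ABSENT`
  observations and an "X" identification — a result, not an error.
  Readers enforce the container invariants (sorted m/z, non-negative
  intensities) and refuse malformed input loudly with line/element
  context rather than truncating.
* `estimate_noise()` falls back to a single global estimate when the
  window exceeds the spectrum and floors its output at a tiny positive
  value so SNR is always defined.
* The problem sizes used in validation were chosen to exercise the
  defaults honestly at desk scale: full 800–3600 Da grids (140 001
  points) wherever the cervid panel is involved, 50-seed Monte Carlo
  loops for contaminant round-trips and oracle-equivalence checks, and a
  20-point τ scan (5000 → 30 Da) for the demotion property.

## Known limitations

Beyond the generator's idealisations listed above: markers are treated as
singly charged average-mass peaks (no deisotoping or charge
deconvolution, matching how such marker tables are written); deamidation
(+0.984 Da) exists only as a generator stress-test flag, not as panel
logic; mixtures of taxa in one spectrum are out of scope; and the
assignment is rule-based, not probabilistic — the scores are evidence
fractions, not posterior probabilities.
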