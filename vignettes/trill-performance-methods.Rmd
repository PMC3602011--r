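---
title: "Measuring trill performance and testing its link to male success"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring trill performance and testing its link to male success}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trillgauge)
```

## The scientific problem

Trilled bird song carries two candidate signals of male quality. *Vocal
deviation* measures how far a trill sits from the mechanical performance
frontier on the (trill rate, frequency bandwidth) plane: a bird cannot
simultaneously maximize how fast it repeats syllables and how wide a
frequency band each syllable sweeps, so the population's upper bound on
bandwidth at each rate is a performance limit, and trills close to it
(low deviation) are physically demanding. *Trill consistency* measures
how precisely the same syllable is repeated within a trill, scored as
the mean pairwise spectrogram cross-correlation among a trill's
syllables. The package implements the full analysis chain for asking
whether these traits (i) are repeatable properties of individual males,
(ii) correlate with each other and with male phenotypic quality, and
(iii) predict mating success (simultaneous polygyny, within-pair
paternity retention, extra-pair siring success) and annual reproductive
success — together with a seeded synthetic-data generator that stands in
for field recordings and genotypes, so that every stage can be tested
against known ground truth.

## Acoustic measurement

Measurements mirror selection-based measurement tools. Two Hann-window
spectrogram presets are used deliberately: a 4096-point DFT with a
111-sample hop (11.72 Hz grid at 48 kHz) for *measurement* (bandwidth,
pitch, frequency extrema), and a 1024-point DFT with 80% overlap for
syllable *cross-correlation*.

- **Trill rate** is the syllable count divided by the span from first
  syllable onset to last offset. An alternative convention divides
  inter-onset span by count minus one; the onset-to-offset form is used
  throughout because annotations delimit complete syllables.
- **Frequency bandwidth** is the band holding 99% of energy under
  symmetric trimming (0.5% per tail), computed from the pooled power
  spectrum of the whole trill selection so it is invariant to recording
  gain. Band edges are interpolated within bins, so accuracy is about
  one 11.72 Hz grid bin. Pooling uses 50%-overlapping Welch frames,
  padded half a frame at each end so every sample receives near-uniform
  total window weight; the denser hop of the display spectrogram would
  change only the estimator's redundancy, not its expectation.
- **Pitch** is the mean over syllables of the per-syllable 99%-energy
  high frequency; the trill's frequency extrema are the min/max of the
  per-syllable bounds.
- **Consistency** zeroes spectrogram rows outside the trill's extrema
  widened by 200 Hz (suppressing background noise), zeroes cells below
  50% of each spectrogram's peak magnitude (a broadband-masking
  approximation: field correlation software documents this setting
  without defining it, so the simple thresholding is isolated behind
  the `masking_fraction` argument), zero-pads each syllable to twice its
  length, and takes the peak of the normalized cross-correlation over
  time lags only — sounds are never shifted in frequency, so similarity
  includes pitch. Scores are averaged over all unordered syllable
  pairs. Consistency is modelled on the variance-stabilized scale
  `-log(1 - C)` (natural log; scores at the ceiling are capped at
  `1 - 1e-6`).

## The performance limit and vocal deviation

`upper_bound_regression()` bins trill rate (default 2 syllables/s wide,
chosen to give at least five occupied bins over typical wren rate
ranges), takes the maximum-bandwidth trill per occupied bin, and fits
ordinary least squares through those maxima, keeping each maximum's own
rate coordinate so exactly collinear maxima are recovered to machine
precision. `vocal_deviation()` is the signed orthogonal distance to the
fitted line with bandwidth in Hz and rate in syllables/s; positive
below the limit, and points above the fitted line keep their (negative)
deviation rather than being clipped, preserving information.

Two properties of this estimator matter for interpretation. First, with
a hard frontier and deviations decaying away from it, per-bin maxima
approach the true line as the sample grows; recovery of a limit with
slope −168.5 Hz/(syll/s) and intercept 6019 Hz from 500-trill clouds is
within ±15%/±10% in well over 90% of replicates. Second, *measurement
noise biases the fitted limit outward*: bin maxima select positive
measurement errors, so audio-measured studies show a steeper fitted
slope and higher intercept than the underlying truth. Deviation scores
remain a nearly monotone transform of true deviation, which is what the
downstream correlational analyses use.

## The synthetic study

`population_config()` defaults encode the emulated study design: about
60 males over two seasons (a quarter recorded in both), 20–100 trills
per male-year, eight shared syllable types with per-male repertoires of
4–8 types, trill rates 2.5–16 syllables/s under the limit above, mean
deviation 8.2 distance units, mean consistency 0.82, male-identity
variance fractions 0.176 (deviation) and 0.295 (transformed
consistency), a 7-locus microsatellite panel spanning 7–28 alleles with
expected heterozygosity 0.52–0.90 and null-allele frequencies up to
6%, per-transmission single-step mutation at 0.002, 13.5% extra-pair
offspring, 20% simultaneous polygyny, and 3–7 chicks per nest. All
true song-to-success effects default to zero: the default bundle is a
null world, so the battery's rejections measure type-I control.
`effect_sizes` injects real male-level effects (log-odds per SD of male
ability) for power studies.

Syllables are linear frequency sweeps with raised-cosine onset/offset
ramps and a flat sustain — the simplest signal whose bandwidth and
cross-correlation behave controllably. Because the ramps attenuate
band-edge energy, the generator widens each sweep by an analytically
computed factor (`sweep_band_calibration()`) so the *measured*
99%-energy bandwidth matches the target. Rendition jitter perturbs
sweep endpoints and duration multiplicatively and is the single knob
controlling consistency; the mapping from a target consistency to a
jitter SD is a fitted monotone approximation, so audio-measured
consistency tracks the latent target in rank but not exactly in value.
Background noise is white Gaussian at a configurable SNR (default
30 dB), which exercises the 200 Hz bounding logic without swamping the
metrics.

Two deviation-cloud shapes are provided. The bundle generator draws
deviation from a truncated Gaussian around its mean so that male,
syllable-type, and acoustic-covariate structure can be layered on it;
`simulate_trill_cloud()` instead implements a triangular cloud whose
deviation density decays linearly from the limit, the shape expected
under a hard frontier, and is the input for limit-recovery checks. The
true distribution of trills under the limit is not identified by the
emulated study, so the shape is an explicit modelling choice.

What the generator does *not* emulate: real wren syllable morphology,
reverberation and transmission degradation, annotation error,
within-season trends in song, correlated deviation and consistency
(they are independent in the default bundle), or clustering of
extra-pair offspring by sire within a nest (each offspring draws its
sire independently). Passing tests therefore demonstrate correctness of
the measurement and inference machinery under the stated statistical
structure, not robustness to every property of field data.

## Paternity

Trio-wise mismatches are evaluated by exhaustive enumeration over the
four parental allele combinations. A mismatch is *null-consistent*
when the trio becomes compatible once any apparent homozygote is
allowed to hide an unamplified null allele — the classic
double-homozygote signature generalized to trios. An offspring is
called extra-pair only when more than one non-null trio mismatch
remains (single mismatches with a parent of either sex are tolerated as
mutations); trios missing more than two loci are unresolved.
Extra-pair sires must be compatible with the mother–offspring pair at
every typed locus except at most one null-consistent mismatch; ties
among multiple fully compatible candidates are resolved conservatively
by assigning no one. Likelihood-based parentage (and with it
null-allele frequency estimation and non-exclusion probabilities) is
out of scope. Success roll-ups pool all of a male's social nests within
a year for the within-pair proportion; polygyny requires the second
nest's active period to overlap the primary's; annual reproductive
success counts fledged within-pair offspring retained plus fledged
extra-pair offspring sired elsewhere.

## Statistical battery

Gaussian mixed models are fit by REML with Satterthwaite denominator
degrees of freedom; binomial responses use Laplace approximation. The
main alternative, Kenward–Roger df, gives very similar answers on
designs like these; Satterthwaite is the widely available choice and
the small numeric divergence between the two is a documented
limitation. With zero estimated group variance the fixed
estimates coincide with ordinary least squares, and degenerate designs
(one observation per group) are permitted so that contract is testable.
Pitch enters models in kHz so fixed-effect columns share a scale.

Adjusted repeatability is the among-male variance fraction from the
covariate-controlled model (year, trill type, pitch, trill duration,
time in song); its p-value is a likelihood-ratio test against the
fixed-effects-only model with the chi-square(1) tail halved for the
boundary constraint. The deviation–consistency association uses
within-subject centering: consistency is split into the mean per male ×
trill type × year combination and each trill's deviation from that
mean, and both enter the model. Paired comparisons of extra-pair sires
with the males they cuckolded use a mixed model with crossed random
intercepts for male and pair for trill traits, and paired t-tests for
one-value-per-male traits. Effect sizes are the partial correlation
`t/sqrt(t^2 + df)` for continuous predictors and Cohen's d for binary
ones, with confidence intervals from noncentral-t inversion by
root-finding to 1e-8. False discovery rate control is Benjamini–
Hochberg applied table-wise, with the three mating-success tables
treated as one family. Variance inflation factors from the
fixed-effects-only design verify the acoustic covariates are not
problematically collinear (all below 5).

Where a trait must be transformed for normality, the transform is
applied to the trait *as a response* only (square root of reproductive
success plus one, `-log(1 - C)` for consistency, log for the
heterophile:lymphocyte ratio, power 0.55 for flights, arcsine square
root for proportion of time close); predictors stay untransformed.

Some associations in the default bundle are real by construction:
polygyny, within-pair retention, and extra-pair success mechanically
increase annual reproductive success. Type-I calibration is therefore
assessed over the structurally null tests, where across 100 seeded
runs the raw rejection rate sits at the nominal 5% level and table-wise
FDR flags stay at or below q.

## Problem sizes and numerical choices

The package's standard problem sizes, used in its tests: limit-recovery
on 200 clouds of 500 trills; repeatability recovery at 60 males × 40
trills over 50 seeds; decomposition recovery at 59 males × 60 trills
over 50 seeds; type-I calibration on 100 seeded trait-level runs of a
15-male bundle (the calibration of a rejection *rate* is size-free
under the null, so a compact bundle is used and the full-size null run
is exercised separately); determinism on an 8-male audio run executed
twice; and one full-size default run (about 60 males, ~3,500–4,500
trills, audio measured end to end), which completes in roughly 5–6
minutes on one CPU. Degenerate inputs are errors with named causes
(zero-energy spectra, overlapping annotations, singular designs,
constant responses, all-singleton groups), except where a defined value
exists (monomorphic loci have expected heterozygosity 0; a perfectly
fitting condition regression yields all-zero condition; perfect
collinearity yields infinite VIF rather than an error).

## Known limitations

Audio-chain estimates of repeatability are attenuated relative to the
latent variance ratios because measurement error inflates the
within-male component. Even at trait level the covariate-*adjusted*
repeatability of a bundle sits somewhat below the configured variance
ratio, because per-male syllable-type repertoires partially confound
trill type with male identity and the type fixed effect absorbs part of
the between-male variance; the dedicated clean-design recovery checks
match the configured ratios. The fitted performance limit under measurement noise is
steeper than the generating limit, as discussed above. The broadband
masking and "data length" conventions of field correlation software
have no published semantics and are approximated by simple
thresholding and zero-padding. Satterthwaite df differ slightly from
Kenward–Roger. The EP-sire power example injects a strong male-level
effect; at realistic study sizes an effect of one standard deviation is
detected raw but survives family-wise FDR only in a majority of runs,
which is what a power calculation predicts once the family's multiplicity
is accounted for.
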