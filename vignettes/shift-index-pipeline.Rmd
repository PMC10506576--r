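---
title: "Simulated hearing loss and the Shift Index: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated hearing loss and the Shift Index: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitchshift)
```

## The perceptual question

A harmonic complex tone — a sum of pure tones at integer multiples of a
fundamental frequency F0 — is normally heard at the pitch of its F0 even when
the F0 component itself is physically absent (the *missing fundamental*).
Listeners differ robustly in how strongly this synthetic, F0-based mode of
pitch perception dominates over the analytic, *spectral* mode in which pitch
tracks the frequencies of the audible partials.

This package implements a stimulus design that pits the two modes against
each other under *simulated hearing loss*. Partials below a low cutoff (250,
500, 750 or 1000 Hz — increasingly severe low-tone loss) and above a high
cutoff (1600 Hz for the X series, 1300 Hz for the Y series, standing for
high-tone loss or low-pass filtering by walls and obstacles) are eliminated
from each tone. Two tones with F0s of 230 Hz (tone A) and 276 Hz (tone B) — a
just minor third of about 316 cents — are band-limited so that the tone with
the *lower* F0 always has the *higher* lowest partial. An F0 listener
therefore calls B higher; a spectral listener calls A higher, a *pitch
shift*. The same eight elimination conditions are applied note-by-note to a
thirteen-note rendition of the children's song "Lightly Row", where a
spectral listener should hear the band-limited melody as off-key.

## Stimuli

`experiment1_pairs()` constructs the eight two-tone conditions and checks the
design invariants at build time: the designed crossover (lowest partial of A
above B in every pair), the shared 1380-Hz top frequency in the X series, the
1150-vs-1104-Hz tops in the Y series, and the fact that exactly one pair (Y4)
reduces to two pure tones. Cutoffs eliminate partials *strictly* below/above
the boundary, so a partial exactly at a cutoff would be retained; no partial
in this stimulus set lies on a boundary, so the convention is inert but
documented here.

Synthesis (`synthesize_tone()`) is additive: equal-amplitude, zero-phase sine
partials, a choice the stimulus description leaves open and that we fix as
the simplest convention. Each tone is 500 ms (melody notes 500 or 1000 ms)
with 10-ms rise and fall ramps. The ramps are raised-cosine (Hann
half-window), the psychoacoustics standard that avoids spectral splatter;
first and last samples are exactly zero. Each tone is peak-normalised
separately to `1 - 2^-15`, the largest magnitude representable in 16-bit
PCM; no loudness equalisation across tones is attempted, since playback
level is outside the package's scope. Audio is written as 16-bit/44.1-kHz
RIFF/WAVE PCM, mono by default with an option to duplicate the channel
(diotic presentation).

### The melody scale

The note fundamentals of the original melody recordings are not published.
The package's documented convention (`lightly_row_scale()`) is a
just-intonation C-major scale anchored so that E = 230 Hz and G = 276 Hz,
the two tone-pair F0s (6:5, an exact just minor third): C = 184, D = 207,
E = 230, F = 245⅓, G = 276 Hz. The passage is G E E | F D D | C D E F |
G G G with the phrase-final notes (positions 3, 6, 13) at 1000 ms, the
song's conventional rhythm; total duration 8.0 s with no inter-note silence
(the ramps shape the note boundaries). Both scale and rhythm are
configurable.

One consequence of this anchoring deserves emphasis: in version Y4
(1000–1300 Hz band) several notes reduce to pure tones, but in Y3
(750–1300 Hz) every note of this scale retains at least two partials — at
F0s of 184–276 Hz the 550-Hz-wide Y3 band always admits two harmonics. A
report that pure tones occur in *both* Y3 and Y4 can only hold for a melody
pitched differently; since the deposited stimuli's F0s are unknown, the
package asserts the pure-tone property for Y4 only and treats its presence
in Y3 as unresolved. This does not affect the tone-pair experiment, whose
frequencies are all printed and reproduced exactly.

## The listener model

The paper-level analysis needs per-participant binary responses; the
simulator (`simulate_cohort()`) generates them under an explicit response
model that operationalises the F0-vs-spectral listener continuum:

* each participant carries a latent trait \(t \sim N(\mu, \sigma^2)\) on the
  logit scale (their propensity to respond spectrally);
* the probability of a spectral response in condition \(c\) is
  \(\mathrm{logit}^{-1}\!\big(t + \beta_{\mathrm{low}}(k_c - 1) +
  \beta_{\mathrm{series}}\,[c \in Y]\big)\), where \(k_c \in \{1,\dots,4\}\)
  indexes the low-cut severity;
* the two repetitions of each task are independent Bernoulli draws given the
  trait, so *ambiguous* responses (the two repetitions disagreeing) arise
  naturally from intermediate probabilities rather than being modelled
  separately.

Defaults are `mu_trait = -1.53`, `sd_trait = 1.5`, `beta_lowcut = 0.8`,
`beta_series = 0.8`. They were solved (by numerically inverting the
logistic-normal mean) so that the expected cohort-mean Shift Index rises
from −0.5 under X1 through −0.25 and +0.03 to +0.3 under X4 and sits
uniformly about 0.25 higher for the Y series — the qualitative pattern the
stimulus design is meant to elicit, with graphical results from human
cohorts never treated as ground truth. Age has no effect under the default
configuration, making the two age groups (≤ 39 and ≥ 40 years; 19 + 20
participants for the tone pairs, 18 + 20 for the melody) exchangeable.
Task-order randomisation is not modelled.

The model is identifiable from response tables: `fit_listener_model()`
recovers the four population parameters by marginal maximum likelihood,
integrating the trait out with 21-node Gauss–Hermite quadrature and
maximising with BFGS on an unconstrained parametrisation (`log` SD).
Standard errors come from the inverse observed information. The test suite
checks recovery within three standard errors on a simulated cohort of 400
participants with six repetitions per task.

## Shift Index and summaries

For one participant and condition, with `sp` spectral and `f0` F0 responses,

\[ \mathrm{SI} = \frac{sp - f0}{sp + f0} \in [-1, 1], \]

so with the design's two repetitions SI takes only the values −1 (both
responses F0), 0 (ambiguous) and +1 (both spectral); ambiguity and SI = 0
coincide exactly. `shift_index()` generalises to any repetition count, but
`classify_ambiguous()` deliberately errors for designs other than two
repetitions rather than silently extending the definition. Missing
responses are rejected, not imputed — an unbalanced response table is an
error. `cohort_summary()` reports, per condition (optionally per age
group), the mean SI and the percentage split into ambiguous,
unambiguous-spectral and unambiguous-F0 responders, which sums to 100.

## Statistics

The comparison schedule (`comparison_schedule()`) mirrors the study's
analysis: Wilcoxon signed-rank tests on SI for X1 vs X2/X3/X4, Y1 vs
Y2/Y3/Y4 and the four matched Xk-vs-Yk contrasts (the Y1-vs-Y2 contrast is
included for symmetry even though only the Y3 and Y4 contrasts are
headline results), and McNemar tests on the ambiguity flag of every other
condition against the Y4 baseline, the pure-tone pair expected to elicit
the fewest ambiguous responses. P-values are unadjusted by default, with an
optional Holm column, and the schedule can be re-run within age groups.

Both tests are implemented in the package with exact small-sample
behaviour:

* `wilcoxon_signed_rank()` discards zero differences (the reference R
  convention — consequential here because SI differences are zero-rich) and
  mid-ranks ties. The exact two-sided p-value is computed from the full
  null distribution of the positive-rank sum over all \(2^n\) sign
  assignments, obtained by dynamic programming over the doubled mid-ranks
  (integers even under ties). The automatic mode mirrors the reference
  implementation's switch — exact below 50 effective pairs with no ties and
  no zeros, otherwise a continuity-corrected normal approximation with
  tie-corrected variance — so for real SI data the approximation is the
  operative path, while `mode = "exact"` remains available for tied data.
* `mcnemar_test()` uses the continuity-corrected chi-square statistic
  \((|b-c|-1)^2/(b+c)\) on 1 df by default and an exact binomial variant by
  flag (which McNemar variant the original analysis software applied is not
  stated, so both are provided). Zero discordant pairs give a flagged
  degenerate result with p = 1, as does an all-zero Wilcoxon difference
  vector.

Tests are validated against literal brute-force enumeration oracles (all
sign assignments for n ≤ 12; binomial tails for McNemar) and against
`stats::wilcox.test()` / `stats::mcnemar.test()` as independent
cross-checks.

## Calibration and property checks

Two simulation-based properties anchor the statistics stack, both run in
the test suite at fixed seeds:

* **Type-I error.** Under the null configuration (both condition effects
  zero) the schedule's ten Wilcoxon tests are applied to 1000 simulated
  cohorts of 39 participants; the empirical rejection rate at nominal 5%
  must not exceed 6%. SI differences are heavily tied and zero-rich, which
  is exactly where zero-handling and the continuity correction matter.
* **Pattern recovery.** With the default (non-null) parameters, the
  cohort-mean SI must be nondecreasing in the low-cut index within each
  series and higher for Y than matched X. Because this is a property of
  Monte-Carlo *means*, it is checked on 200 seeded cohorts of 200
  participants each (100 per age group), a size at which the two-repetition
  binomial noise no longer masks the expected ordering; at the study's own
  n = 39 single cohorts can and do show local inversions.

Rendered audio is verified end-to-end: `validate_stimuli()` re-reads every
WAV, checks durations to the sample, and confirms on the stationary
(ramp-free) portion of each tone or note that every retained partial is
present (within −6 dB of the spectral maximum, allowing worst-case
rectangular-window scalloping of ~3.9 dB) and every eliminated harmonic up
to 2 kHz is suppressed by at least 40 dB.

## Reproducibility

`run_full_study()` drives the whole pipeline — 16 tone-pair WAVs, 8 melody
WAVs, manifests, simulated response tables for both experiments, scores,
summaries and the full test schedule — from a single global seed that
deterministically fans out into per-stage child seeds; re-running with the
same seed reproduces every output byte-for-byte, which the run manifest's
MD5 checksums make checkable. A full run at study scale completes in
seconds.

## Limitations

The simulator operates on condition labels, not on the audio: there is no
auditory-periphery model, no masking, no autocorrelation or
template-matching pitch extraction, and no modelling of task order,
response times or confidence. Passing its property checks therefore shows
that the analysis stack behaves correctly for data generated by the stated
logistic model, not that human listeners follow that model. The melody's
absolute pitch level is a convention (above), the off-key judgment is
treated as one holistic binary task per version, and playback calibration
(levels, headphones) is out of scope.
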