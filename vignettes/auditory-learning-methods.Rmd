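---
title: "Models and methods for auditory perceptual-learning analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for auditory perceptual-learning analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(audlearn)
```

`audlearn` analyses go/no-go auditory discrimination experiments in which
rodents learn to separate a target sound (a pure tone, or a pup
vocalization) from progressively closer non-targets, while single neurons
are recorded in primary auditory cortex before and after learning. The
package covers four layers: behavioral signal detection, single-neuron
tuning statistics, a generative population model with information-theoretic
and decoder readouts, and sparseness/decorrelation analysis of natural-sound
responses. Because cell-attached recordings of this kind are rarely
released, a synthetic-data generator reproduces the statistical structure
every analysis stage assumes, so the full chain is testable end to end.

## Stimulus geometry

Tone mapping uses a grid of 18 tones logarithmically spaced from 3 to
40 kHz at four sound levels (42–72 dB SPL). All frequency computations run
on the octave axis `x = log2(f / 1 kHz)`; one grid step is
`r round(octave_step(stimulus_grid()), 4)` octave, and the trained band is
7.1–10 kHz (49% of an octave; the second training stage narrows the
separation to 26%). A trial stimulus is a train of six 100-ms tone pips
with 300-ms gaps, 2.1 s in total.

## Behavioral metrics

Sensitivity is `d' = z(hit) − z(FA)` with rates clipped to
`[1/(2N), 1 − 1/(2N)]` so perfect scores stay finite; the clipping rule is
the standard log-linear correction (the experimental literature rarely
states one). Learning curves bin consecutive trials (default 20/bin), and
per-stage summaries use the last third of each stage, after within-stage
learning has plateaued. Psychometric curves from non-reinforced catch
trials are fitted with a 4-parameter logistic on the octave axis by
weighted least squares (`minpack.lm::nlsLM`); the decision boundary is the
fitted inflection, and flat curves (range of lick proportions < 0.05, or
fitted slope < 0.5/octave) are flagged degenerate rather than reported.

Detection time applies a per-bin (50 ms) two-sample t-test of lick counts
between hit and correct-rejection trials and reports the first bin center
crossing `p < 0.001`. Two choices deserve emphasis: the test uses per-bin
(not cumulative) lick counts — the protocol wording does not distinguish
the two, and per-bin counts localize the divergence — and no multiple-bin
correction is applied, because the stated rule is a first crossing of a
fixed threshold. With ~30 bins and α = 0.001 the expected false-detection
rate under the null is ~3%.

## Single-neuron tuning

PSTHs are built at 1-ms resolution (spike times are millisecond-rounded).
The response window is the 100-ms span, starting at any bin edge after
stimulus onset, that maximizes the summed PSTH — a brute-force scan with
ties broken toward the earliest window. Responsiveness and
frequency-response-area (FRA) significance use the pooled-variance
two-sample t-test of window counts against matched 100-ms pre-stimulus
counts; FRA cells are Bonferroni-corrected at `0.05/(n_freq × n_level)`
(72 combinations on the default grid). Best frequency is the argmax of the
level-averaged tuning curve (ties to the lower frequency), selectivity is
the percentage of significant FRA cells, the training-band rate averages
7–10 kHz across levels, and latency is the peak of a 5-ms-smoothed PSTH
(smoothing avoids single-spike peaks; raw 1-ms peaks are used nowhere
else). Signal correlation is the Pearson correlation of two FRA matrices;
"neighboring" pairs share a recording-site label in the synthetic
metadata, the stand-in for anatomical proximity.

## The generative basis-function model

Tuning curves in layer 2/3 are asymmetric and sometimes bimodal, so
parametric (Gaussian) fits are avoided. Instead the N × 18 matrix of
trial-averaged tuning curves is decomposed by SVD and each curve is
modelled as a weighted sum of the K leading frequency components:

$$r_i(f) = \sum_{l=1}^{K} a_l^i\, g_l(f).$$

Design choices:

* **Smoothing.** The SVD frequency vectors are smoothed with a centered
  3-point moving average (edge replication) to reduce finite-trial
  overfitting. Coefficients are computed against the *unsmoothed*,
  orthonormal basis; generated curves are assembled with the smoothed
  copy. The alternative order (smooth first, then project) is a flag away,
  but projecting on the orthonormal basis keeps the coefficients exactly
  the SVD loadings.
* **Sign convention.** Each basis vector is oriented so its
  largest-magnitude entry is positive; SVD signs are otherwise arbitrary
  and would scramble coefficient histograms across refits.
* **Generative sampling.** New model neurons draw each coefficient
  independently from its per-component empirical distribution — a
  factorized approximation that deliberately ignores cross-component
  correlations (tested as such). The default sampler bootstraps the
  observed coefficient values, the bin-width→0 limit of histogram
  sampling; a binned variant (Freedman–Diaconis bins, uniform within-bin
  jitter) is available. Negative assembled rates are floored at zero and
  counted.
* **Trial noise.** Single-trial counts are independent Poisson draws with
  the curve value as mean. Neurons are recorded sequentially, so noise
  correlations are deliberately absent from the model.
* **Model order.** `select_k()` splits trials 80/20 (25 random splits),
  fits on train-trial means, and scores the reconstruction against
  test-trial means; the selected K minimizes test MSE with numerical ties
  broken toward the smaller K. On protocol-scale synthetic data
  (100 neurons × 18 frequencies × 20 trials) the MSE drops steeply up to
  the planted dimensionality and then forms a broad, shallow minimum, so
  any K in that plateau is defensible; K = 6 is the package default.

## Fisher information and decoding

For Poisson spiking the per-neuron Fisher information about the stimulus
is `I(f) = r'(f)² / r(f)` on the octave axis (units octave⁻²); the
population total is the exact sum over neurons. Derivatives use central
differences (one-sided at grid ends). Rates are floored before division —
`1e-6` by default, but the pipeline uses the spontaneous-count scale
(0.05/window) for model-sampled curves, because flooring negative basis
mixtures at zero otherwise creates near-zero denominators whose artefactual
information dominates the profile.

`decode_pair()` draws fresh Poisson population vectors per iteration,
standardizes per neuron on training-set statistics, and trains a linear
soft-margin SVM (`e1071`, cost 1 by default). The tone-protocol convention
is 16 training and 4 test trials per class, at most 500 iterations with
early stopping once the running mean error moves less than 1e-3 over 50
iterations. Classifier error converts to discriminability as
`d' = 2 z(1 − error)` (equal-prior, symmetric-criterion convention; the
error is clipped by the total test-observation count so perfect
classification stays finite).

The identity `d' ≈ Δf √(FI_total)` holds for fine discrimination in the
asymptotic regime — many neurons *and* enough training data. With 16
training trials and 200 neurons a plug-in linear readout is strongly
inefficient (a Raudys-type estimate gives ~50% efficiency), which says
nothing about the bound itself. The package's consistency check therefore
trains on 800 trials per class (50 test, slack cost 0.1, which reaches the
same plateau as cost 1 at lower compute) on a 200-neuron Gaussian-tuned
ensemble at Δf = 0.05 octave, where the measured efficiency is ~0.85.

The flank-enhancement pattern — more information at the edges of the
trained band than inside it — is probed with planted ensembles:
`flank_enhance()` leaves curves untouched within the band plus one grid
step of margin and multiplies them by a gain ramp beyond it. In-band FI is
then equal *by construction* (the margin keeps every in-band central
difference unchanged), making the in-band/flank contrast interpretable.

## Vocalization analysis

Lifetime sparseness per neuron is
`S = (1 − (Σr_i/n)²/(Σr_i²/n)) / (1 − 1/n)` in percent over the n = 12
syllables of the original call (0% dense, 100% one-syllable); population
sparseness per syllable is 100 minus the percentage of significantly
responsive cells. Response similarity between stimulus variants is the
across-neuron mean of per-neuron Pearson correlations of syllable-rate
vectors ("rates" mode, the default); a "psth" mode correlates the
trial-mean counts laid out on the call's time axis with silent gaps —
with window counts rather than spike times the two modes differ only in
the shared zero bins. Zero-variance neurons are excluded per pair and
counted. The Fano factor (unbiased variance/mean of window counts) is
reported per responsive syllable and averaged.

Vocalization identity is decoded from pseudo-population vectors (one
neuron's counts per syllable, syllables added cumulatively) with the same
linear-SVM conventions, by leave-one-out cross-validation: 15 training and
1 test trial per class, iterated with resampled held-out trials and neuron
subsets, 37 neurons in both groups so group comparisons are unbiased.
Because leave-one-out on a fixed 16-trial set retains dataset-level
variance that does not shrink with iterations, group contrasts are
evaluated on means over replicate generated datasets.

## What the synthetic generator does and does not emulate

`generate_tuning_ensemble()` draws per-neuron tuning curves as skewed
log-domain bumps (two-sided Gaussian with independent left/right widths,
an optional second weaker mode) with BFs from a group-specific mixture:
naive BFs spread broadly across the grid; expert BFs concentrate toward
the training band (70% of mass in a 0.35-octave component at the band
center — the concentration strength is a calibration knob; the literature
gives the direction of the shift, not its magnitude). Monotone level gains
emulate intensity tuning, and all counts are Poisson. Default 20 trials
per frequency–level combination (model decoding needs 16 + 4; recorded
cells had 10–12).

`generate_behavior_log()` plays targets at 70% probability, draws licks as
Bernoulli per stage, inserts optional catch trials (6% when enabled)
whose lick probability follows a logistic between the stage's FA and hit
rates, and stamps outcomes by the go/no-go contingency table.

`generate_vocal_responses()` builds the original call's rate field as a
zero-inflated gamma — a Bernoulli responsiveness mask (naive 0.55, expert
0.40 of neuron–syllable pairs) times gamma magnitudes (shape 3, mean 0.7
counts per 100-ms window ≈ 7 Hz evoked, over a 0.15-count ≈ 1.5 Hz
baseline, the rate scale typical of these recordings). Each variant mixes
the original field with an independent copy, the weight solved so the
latent correlation hits the target exactly
(`rho = w/√(w² + (1−w)²)`); expert targets are lower than naive at every
speeding factor. Finite trials attenuate measured similarity below the
latent target (reliability ≈ var(rate)/(var(rate) + mean/16) per entry),
which is the same attenuation real trial-mean correlations suffer.
`warp_syllable()` re-maps a syllable's time axis with a linear speed ramp
from `s` at onset to `2 − s` at offset (mean 1, so duration is preserved)
and cubic-spline interpolation.

Not emulated: acoustic structure of the calls, mechanistic differences of
PV⁺ interneurons (a metadata label only), inter-neuron noise correlations,
and reaction-time dynamics. Passing tests on this generator therefore
demonstrate correctness of the analysis chain and recoverability of
planted population-level structure — not that real cortical data must
show these effects.

## Problem sizes and numerical choices

Test and pipeline runs use deliberately modest sizes — ensembles of tens
to a couple hundred neurons, 20–30 decoder iterations for pattern
contrasts, 4–8 replicate datasets for group comparisons — chosen so the
full chain re-runs in minutes while keeping each assertion's Monte-Carlo
error well inside its tolerance. Degenerate inputs are flagged, not
silently dropped: all-zero PSTHs, zero-variance FRAs, all-zero sparseness
vectors, zero-mean Fano factors, and non-converged psychometric fits each
carry an explicit flag or `NA`. Model-order ties within a 1e-9 relative
band collapse to the smaller K; SVD component signs and window/BF ties are
fixed by the conventions above so that every run of the pipeline with the
same configuration is byte-identical.
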