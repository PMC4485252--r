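---
title: "Methods: visual-field source asymmetries in BOLD responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual-field source asymmetries in BOLD responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The question and the design

Natural scenes deliver systematically different image statistics to the
upper and lower visual fields: above the centre of gaze the input is
typically sky-like (bright, low contrast), below it ground-like (darker,
variegated, rich in low-spatial-frequency luminance structure). If the
cortical representations of the two hemifields are tuned to this
regularity, the response of V1–V3 to a natural image patch should depend on
the interaction between its *presentation location* (upper or lower visual
field) and its *source location* (above or below fixation in a gaze-centred
recording).

`vfasym` implements the analysis chain for a condition-rich rapid
event-related test of that interaction, and a synthetic-data generator so
that every stage can be exercised and validated without scanner data.

Each run contains two 83-event sequences, one per presentation location: 60
image events (30 images x 2 sources) and 15 nulls in random order, with the
final 8 events replicated and prepended so the censored opening of the run
still contains balanced trials. Events are spaced 4 s apart; one sequence
(chosen at random per run) is advanced by 2 s, so 1 s image presentations
in the two hemifields never overlap in time. A run is therefore
83 x 4 = 332 s = 166 volumes at TR = 2 s; censoring the first 16 volumes of
each of 10 runs leaves 1,500 timepoints per session.

Randomisation is a uniform shuffle of the base event list with no further
constraints, and a single run seed deterministically derives the two
sequence shuffles and the 2 s-advance coin flip, so a run is reproducible
as a unit. Runs serialise to BIDS-style `events.tsv` (onset, duration,
trial_type, image_id, source, presentation, is_prepended; `n/a` for
missing) with a JSON sidecar holding the seed and timing metadata so the
round trip is exact.

# The forward model

Per voxel,

$$y(t) = B\,\Big(1 + \sum_c \tfrac{a_c}{100}\,(h * s_c)(t)\Big)
        + d(t) + \varepsilon(t),$$

where $B$ is the baseline (default 100 signal units, so the amplitudes
$a_c$ are in percent signal change by construction), $s_c$ the onset
impulse train of condition $c$, $h$ the canonical double-gamma HRF
(gamma-density lobe shape 6 minus 1/6 of a shape-16 undershoot, unit rate,
peak-normalised to 1 so betas stay in signal units, 32 s support), $d$ a
per-run random cubic polynomial (Legendre basis, coefficient SD 1.5 units),
and $\varepsilon$ stationary ARMA(1,1) noise
$x_t = a x_{t-1} + e_t + b e_{t-1}$ (defaults $a = 0.3$, $b = 0.1$,
innovation SD 1.5 units, 500-sample burn-in).

Defaults were chosen to be realistic rather than convenient: with these
values a single simulated voxel yields localiser t statistics of about
6–9 over a 10-run session, the plausible range for a responsive visual
voxel. The default generative amplitudes carry the interaction of interest:
lower field 0.80 (below-source) vs 0.72 (above-source) psc, upper field
0.84 vs 0.85 psc.

A synthetic session crosses 7 participants x 3 areas (V1–V3 stand-ins) x 2
presentation masks, each cell a pool of 50 voxels (a conservative size for
a localiser-restricted surface ROI) sharing the condition amplitude map.
Amplitudes receive normal jitter (SD 0.05 psc) drawn independently per
participant, area, presentation and source. Drawing the jitter at the area
level (rather than once per participant) matches the precision implied by
the effect sizes the design targets — a 0.08 psc source difference
detectable at $t_6 \approx 5$ after averaging over areas — and makes the
repeated-measures error strata non-degenerate. Scene images are generated
as standardised $1/f^{\alpha}$ textures ($\alpha = 1.2$, within the range
reported for natural scenes) with a bright low-variance upper half
(mean 0.75, SD 0.05) and a darker variegated lower half (mean 0.40,
SD 0.15), plus small opposing chromatic casts (bluish sky, warm ground).

What the generator does *not* emulate: spatial correlation between voxels,
physiological (cardiac/respiratory) noise, motion, distortions, or the
content statistics of real scenes beyond first-order luminance/contrast
asymmetries and a $1/f$ spectrum. Passing tests therefore certify the
estimation chain — not that real cortex behaves this way.

# Estimation

The design matrix holds one HRF-convolved regressor per modelled condition
(events as onset impulses; a boxcar option exists), convolved on a 0.1 s
grid and sampled at the TR, plus per-run Legendre polynomials of degree
0–3; censored rows are dropped. Conditions can be modelled as a single
localiser regressor, per source (2), or per source x image (60), so
image-level preference rankings are computable from one model.

Fits are ordinary least squares or generalised least squares under a
run-wise stationary ARMA(1,1) covariance
($\rho_1 = (1+ab)(a+b)/(1+2ab+b^2)$, $\rho_k = a\rho_{k-1}$), with exact
Toeplitz Cholesky whitening per run (at most 166 timepoints per run, so
exact inversion is cheap). The noise parameters are estimated by REML —
the likelihood of residual contrasts — maximised over a coarse $(a, b)$
grid with Nelder–Mead refinement and the innovation variance profiled out.
Two numerical choices matter here. First, REML rather than a plain
likelihood of the OLS residuals: projecting out ~42 design columns induces
a small long-range negative autocorrelation in the residuals, and a naive
likelihood dutifully "detects" it with large near-cancelling $(a, b)$
pairs. Second, the ARMA(1,1) deviance is nearly flat along the ridge of
near-cancelling pairs, so the white-noise model is retained unless the
two-parameter model improves the deviance by a BIC-sized margin
($2\log N$). With $a = b = 0$ the GLS path reproduces OLS to numerical
precision.

The localiser thresholds two-sided t maps at $p < 0.01$ (sidedness is a
package choice; the threshold is the protocol's). Surviving voxels are
averaged unweighted, condition GLMs are fit per presentation location on
the averaged timecourse (upper and lower fields in separate models, each
with its own mask), and betas convert to percent signal change by dividing
by the temporal mean of the fitted polynomial (drift) timecourse. A
residual diagnostic bins squared residuals (in psc units) by TR lag after
image-event onsets; a mis-specified response model shows up as structure
over lags where white residuals give a flat curve.

# Inference

The response table (participant x area x presentation x source, averaged
over images) feeds a classical univariate three-way repeated-measures
ANOVA: effect sums of squares by the balanced-design partition
(inclusion–exclusion over marginal means), error terms from each effect's
interaction with subjects. Sphericity corrections use effect-specific
orthonormal (Kronecker) contrasts: Greenhouse–Geisser
$\varepsilon_{GG} = \mathrm{tr}(S)^2 / (q\,\mathrm{tr}(S^2))$ on the
contrast covariance $S$, then Huynh–Feldt
$\varepsilon_{HF} = (n q \varepsilon_{GG} - 2)/(q(n - 1 - q\varepsilon_{GG}))$,
clipped to $[1/q, 1]$. Epsilon is reported for every effect and is exactly
1 for effects with a single degree of freedom, where sphericity is vacuous;
corrected p values use the scaled degrees of freedom. The implementation is
cross-checked in the tests against `aov()` error strata and against the
squared paired-t identity for 1-df contrasts.

Paired comparisons (above vs below source within each presentation
location) collapse to participant-level means over areas. Spearman
correlations use Pearson on mid-ranks with the t approximation for p (the
behaviour of `cor.test(..., method = "spearman", exact = FALSE)`), adequate
at the n = 60 image x source entries; correlations with image
characteristics are computed pooled over both sources by default, with the
per-source split available. Preference ranking orders the per-entry
upper-minus-lower differences, breaking ties by image index. Display
normalisation subtracts each participant's grand mean and adds back the
group grand mean; this preserves condition means and within-participant
differences (a constant added to one participant still shifts all
normalised values by its $1/n$ share of the grand mean — the unavoidable
residue of grand-mean add-back).

# Image characterisation

Patches are converted to cone excitations via the monitor calibration (CIE
chromaticities and luminances of the primaries; the default describes a
linearised sRGB-like display whose mid-grey background sits at the 385
cd/m² mean luminance) using Smith–Pokorny fundamentals, then expressed as
cone-contrast DKL coordinates about the background: achromatic
$(\Delta L + \Delta M)/(L_0 + M_0)$, and isoluminant
$\Delta L/L_0 - \Delta M/M_0$ and
$\Delta S/S_0 - (\Delta L + \Delta M)/(L_0 + M_0)$. The background maps to
(0, 0, 0), equal-gun modulations have zero chromatic coordinates, and the
whole map is linear; the matrices are plain list entries, so alternative
fundamentals are a configuration edit.

The Gabor bank spans 1–16 cpd and four orientations, odd-symmetric
(90-degree phase), with the envelope SD fixed by the one-octave bandwidth
formula $\sigma = \frac{\sqrt{\ln 2 / 2}}{\pi f}\,\frac{2^b + 1}{2^b - 1}$
and support truncated at $\pm 3\sigma$ (envelope peak 1, no further
normalisation — energies are comparative). Energy is the square root of
the summed squared *valid-region* convolution, so no padding contaminates
the statistic; the cost is that the averaging region shrinks with kernel
size, which is why energies are compared across patches, never across
frequencies in absolute terms. Spatial-frequency content is summarised by
averaging over orientations and vice versa; left/right patches of a pair
are averaged after characterisation.

Analysis geometry: the display subtends 24.4 degrees over 1,920 px
(78.7 px/deg), and the displayed patch is a 128 px quadrant patch upsampled
by 2.75. The workflow characterises a half-scale version (factor 1.375,
39.1 px/deg, 176 px patches), which keeps every bank frequency below
Nyquist while making the 120-patch characterisation run in about a minute;
the analysis-region size and px/deg are parameters, and the square region
is analysed unwindowed.

# Validation studies and problem sizes

The test suite validates each operation against independent oracles
(hand-solved normal equations, closed-form ARMA autocorrelations,
eigen-structure sphericity, brute-force mid-ranks, hand-multiplied colour
matrix chains) and runs three study-scale checks, all seeded:

* *Recovery*: over replicate 7 x 10-run sessions, mean recovered psc per
  condition within ±0.02 of the generating 0.80/0.72/0.84/0.85 values
  (1,000 single voxels are used for the voxel-level unbiasedness check,
  giving a Monte-Carlo SE well inside the band).
* *Power*: the presentation x source interaction is rejected at
  $\alpha = 0.05$ in at least 80% of 200 replicate sessions.
* *Null calibration*: with the interaction removed from the truth (source
  effects equalised within presentation), the corrected interaction p
  values pass a Kolmogorov–Smirnov uniformity test.

Replicate studies simulate each 50-voxel pool as its spatial average — a
single series with innovation and drift SDs divided by $\sqrt{50}$ — which
is exactly the same distribution the estimation chain sees after ROI
averaging of independent Gaussian voxels, and fit by OLS with source-level
regressors (the second-level ANOVA consumes the psc table; prewhitening
mainly sharpens first-level t statistics). The planted-effect study
characterises the synthetic image set, plants an upper-field preference
proportional to patch luminance (0.3 psc per SD), and checks that at least
4 of the top-5 entries in each preference list come from the congruent
source and that the luminance-mean correlation is positive.

# Limitations

The package validates an estimation chain on data generated by the model
the chain assumes (up to the drift/noise seeds); it cannot detect
mis-specification that real scanner data would exhibit, and the
characterisation statistics of the synthetic scenes are far cleaner than
those of natural images — correlations near 1 in the planted study say
nothing about effect sizes in real data. The ARMA estimator is a REML
implementation of the same model family as the standard voxelwise
prewhitening tools, not a bit-for-bit reproduction of any of them. The
DKL conversion depends on the chosen cone fundamentals; only the
qualitative structure (background-relative, linear, luminance/chromatic
separation) is asserted.
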