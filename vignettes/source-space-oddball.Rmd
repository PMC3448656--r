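---
title: "Source-space analysis of oddball EEG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Source-space analysis of oddball EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`p3source` implements a complete source-space analysis chain for
two-stimulus (oddball) P3b EEG experiments: statistical preprocessing,
Infomax independent component analysis (ICA), equivalent current
dipole localization in a four-shell spherical head model,
Morlet-wavelet event-related spectral perturbation (ERSP) and
inter-trial coherence (ITC), cross-subject K-means clustering of
components, and permutation group statistics under a two-level
multiple-comparison control.  A synthetic cohort generator with known
dipolar ground truth makes every stage testable without patient
recordings.  This vignette records the models, the parameters that
matter, and the design decisions taken where the method leaves choices
open.

# The forward model

The volume conductor is four concentric spheres (brain, CSF, skull,
scalp).  The scalp potential of a current dipole is expanded in
Legendre series; within each shell the order-$n$ potential is
$\phi_j(r) = A_j (r/r_j)^n + B_j (r_{j-1}/r)^{n+1}$, and the seven
coefficients per order follow from potential and radial-current
continuity at the three interfaces plus the insulating outer boundary.
Radial and tangential moment components share the same per-order
radial transfer factor, so the lead field is assembled from one small
boundary-value solve per order.  All outputs are average-referenced.

Defaults: radii 71/72/79/85 mm and conductivities 0.33/1.0/0.0042/0.33
S/m — the de facto spherical-model conventions of the EEG literature;
both are configurable.  The series is truncated at order 80.  Because
the terms decay like $(b/r_1)^n$ with $b$ the source eccentricity,
order 40 is sufficient below ~0.7 eccentricity but not at the ~0.8
eccentricity typical of cortical sources; order 80 keeps the relative
tail of the last five terms below $10^{-6}$ up to ~0.84, and a
convergence check warns beyond that.  The implementation was verified
against the closed-form solution for a central dipole in a homogeneous
sphere, an order-200 series oracle, and the analytic invariances
(superposition, axial symmetry, inverse conductivity scaling).

Electrode positions are treated as directions and evaluated on the
outer shell; `project_to_scalp()` makes the radial projection
explicit, since digitized montages are never exactly spherical.
Coordinates are head-centered, +x right, +y anterior, +z superior.
`to_talairach()` is a fixed nominal affine for reporting cluster
centroids in a Talairach-like frame; it is plumbing, not a
subject-specific registration.

# The synthetic cohort generator

The generator emulates a two-stimulus oddball recording: 205 stimuli
per run with an exact 20% target fraction (no two targets adjacent,
matching pseudorandom presentation), 2 s inter-stimulus interval.
Desk-scale defaults are 32 scalp channels plus 2 EOG channels at
128 Hz and 15 subjects per group; the 128-channel/512 Hz convention of
high-density recordings is available as `cohort_spec_highdensity()`.
Epochs span -500..1000 ms with a -200..0 ms baseline.

Sources are dipoles with one of four activation kinds:

* **oscillatory-ers / oscillatory-erd** — a sinusoid at `center_freq`
  whose amplitude rises (falls) by `band_power_change` dB inside the
  latency window through a raised-cosine envelope.  A configurable
  fraction of trials is stimulus phase-locked (phase zero at onset),
  the rest draw uniform phases, which gives exactly controllable ERSP
  and ITC targets.
* **evoked** — a stereotyped raised-cosine-squared transient, identical
  across applicable trials, so noiseless simulations are exactly
  rank-one.
* **blink** — a stereotyped 300 ms biphasic waveform at Poisson times
  (default 10/min, the order of spontaneous blink rates) from a
  dipole near the eyes, exercising ocular-artifact detection.

Oscillatory amplitude varies log-normally from trial to trial
(`amp_variability`, default 0.75 log-units).  This emulates the
bursty, heavy-tailed amplitude dynamics of ongoing rhythms — the
property that makes super-Gaussian ICA work on real EEG — and leaves
the ERSP unbiased, because a common per-trial amplitude factor cancels
between the response window and the baseline.  Per-subject dipole
positions are jittered (default SD 5 mm) to emulate anatomical
variability.  Sensor noise is white with SD 1.5 uV.

The default layouts plant four source populations (midline parietal
theta ERS with 0.7 phase locking, frontal-midline theta ERS, occipital
alpha ERD, lateral central beta ERD) for the visual-style preset and a
fifth temporal theta population for the auditory-style preset, plus
the blink source.  Group effects are dB offsets applied to group-2
subjects, e.g. `group_effect = c(parietal_theta = -2)` plants a 2 dB
theta-ERS deficit.  No effect-size magnitudes are prescribed by the
protocol itself; the defaults were chosen once for statistical
detectability at desk scale.

What the generator does *not* emulate: 1/f background spectra (the
background is white), volume-conducted muscle artifact, non-stationary
drift, or realistic corneo-retinal blink physics (the blink dipole
sits inside the brain shell, so its scalp-to-EOG amplitude ratio is
more "brain-like" than real blinks).  Passing tests therefore
demonstrate the correctness of the machinery on data satisfying the
model's assumptions, not robustness to everything real recordings
contain.

# Preprocessing

The pipeline order is fixed: zero-phase filtering (4th-order
Butterworth bandpass, 2nd-order band-stop notches, applied
forward-backward so ERP latencies are preserved), average reference
over the scalp electrodes, epoching with per-trial baseline
subtraction, statistical epoch rejection, and spherical-spline channel
interpolation (order 4, regularization 1e-5).

Epoch rejection follows the statistical-thresholding family: three
per-channel metrics (amplitude range, variance, deviation of the trial
channel mean), z-scored across trials, maximum over channels, trial
rejected when any |z| exceeds 3.  Degenerate metrics (zero spread) map
to z = 0, so identical trials are never rejected.  The z = 3 default
follows the published design of the statistical-rejection approach;
every threshold is in the study configuration.

# ICA and artifact components

Sphering is symmetric (ZCA) whitening at full rank — white data map
near-identically — and PCA whitening with dimension reduction when the
covariance is rank deficient, as it always is after average
referencing (32 scalp channels yield 31 components).  The Infomax
rotation uses the logistic nonlinearity with block natural-gradient
updates, learning-rate annealing on weight-change angle (x0.9 above
60 degrees), stopping when the squared weight change per pass falls
below 1e-6, capped at 512 passes.  The sample order is re-permuted per
pass with a dedicated deterministic generator, so a seed fully fixes
the result.  Scale and sign indeterminacies are fixed by unit-norm
scalp maps with a positive maximum-absolute element; recovery quality
in tests is measured by the Amari index, which is permutation- and
scale-invariant.

Artifact components are flagged by three metrics z-scored across
components: maximum absolute correlation of the activation with the
EOG channels (threshold z = 2, the stricter ocular threshold),
activation kurtosis, and log-log spectral slope (threshold z = 3).
Two refinements were adopted after examining the metrics' behavior on
simulated data.  First, the EOG and kurtosis criteria are one-sided —
artifacts are *more* ocular-correlated and *more* spiky, and a
two-sided rule flags clean components for being unusually unremarkable.
Second, the EOG criterion also requires the raw correlation to be
substantive (default 0.65): EOG electrodes record genuine brain
activity, so on data where no large ocular signal dominates the EOG
trace the z-score alone systematically mislabels strong frontal and
parietal sources as ocular.  Decomposition defaults to all channels
(scalp + EOG) so that removing a flagged ocular component actually
cleans the EOG channels; dipole fitting always uses the scalp portion
of the map only.

The z-scoring approach presumes a population of components in which
artifacts are tail events; on simulations containing no artifact at
all the tails are occupied by whatever is most unusual, and a stray
neural component can be flagged.  This is a property of the method,
not a bug, and mirrors its behavior on unusually clean recordings.

# Dipole fitting and component selection

For a fixed position the optimal moment is a linear least-squares
solve against the lead field, so the fit objective is the residual
variance (RV) of the average-referenced scalp map.  The search is
multi-start: a coarse grid of 3 eccentricity shells x 162 near-uniform
directions is scored in one pass through cached orthonormal lead-field
bases, and the best three seeds are refined by Nelder-Mead with the
position confined to the brain volume (positions that escape are
projected back and flagged).  Maps whose best grid RV exceeds 0.5 get
a single short refinement — no dipole model is going to explain them,
and their RV only needs to be roughly right to be excluded.

Components are retained when RV <= 0.15 *and* the dipole lies strictly
inside the brain shell.  The boundary convention follows the exclusion
wording ("more than 15%" excluded): RV exactly 0.15 is kept.  Fitted
moments are oriented radially outward (flipping map, activation, and
ERP together when needed): component polarity is arbitrary, and
without a convention the same cortical source can appear with opposite
ERP signs in different subjects, which splits clusters.

# Time-frequency measures

ERSP and ITC use Morlet wavelets (Gaussian-enveloped complex
exponentials, amplitude-normalized).  The wavelet window is capped at
185 ms and at 12 cycles, whichever is shorter — the cap reading of the
"maximum 185 ms" sliding-window convention; a fixed-cycles rule is
available through `cycle_rule` for the alternative reading.  At the
bottom of the default grid the 185 ms window holds less than one cycle
of a 3 Hz oscillation, which trades frequency resolution for the
uniform temporal resolution the cap is meant to buy.  The common time
axis keeps only latencies with full wavelet support at every retained
frequency, and frequencies whose window does not fit (or at/above
Nyquist) are dropped with a warning.

ERSP is `10*log10` of trial-mean power against the mean pre-stimulus
baseline power per frequency; doubling an oscillation's amplitude
post-stimulus yields +6.02 dB by construction.  ITC is the resultant
length of unit phase vectors across trials, in [0, 1], invariant to
per-trial amplitude scaling.  The default analysis grid is 100
log-spaced frequencies over 3-256 Hz; pipeline presets truncate to
3-45 Hz with 30 frequencies and decimate the output time axis by 4,
since the band-level claims of oddball studies live below ~30 Hz and
the full grid quadruples the statistics maps for no additional power.

# Clustering

Each accepted component contributes a joint feature vector: dipole
position and sign-fixed orientation (6 native dimensions), and scalp
map, activation spectrum, ERP, ERSP and ITC, each z-standardized,
PCA-compressed to at most 10 dimensions, rescaled to unit mean
per-dimension variance, and weighted 1 against the dipole block's 10.
K-means (best of 20 seeded restarts by within-cluster sum of squares,
Lloyd iterations from canonically ordered starts so the partition is
input-order invariant) clusters the pooled components.

Outliers are components whose distance to their centroid exceeds 2
standard deviations of member distances, applied iteratively (flagged
members leave the mean/SD and the rule is re-applied until stable) so
heavy contamination cannot mask itself.  The joint-distance
operationalization of "2 SD from the centroid properties" is the
behavior of the established clustering tools; a per-property variant
was considered and rejected because joint distance is what K-means
optimizes.

The cluster count is selected by a programmatic analogue of the visual
stopping rule: k grows while each increment still separates source
populations, and stops when a step splits one cluster into two whose
*activity* profiles (all non-dipole features) are indistinguishable —
either correlating above 0.95, or closer than 3 sampling-scale units
of separation (the pooled within-child spread; ~1 when the children
are draws from one population).  The two criteria are complementary:
correlation identifies structured profiles that merely duplicate each
other, the separation statistic identifies noise-level profiles where
correlation is uninformative.  The full diagnostic trace is returned
so the choice can be overridden.

# Group statistics

Subject-level maps are built by averaging a subject's components
within a cluster; the group contrast is an unpaired pooled-variance t
per frequency-latency pixel, with the null built by shuffling subject
group labels (the contrasts of interest are between-subject).
Monte-Carlo p-values use the add-one rule, so they are never exactly
zero, and exceedance is counted with a relative tolerance so exact
ties survive common rescaling of the maps.  Significance requires
both Benjamini-Hochberg FDR at q = 0.05 within the cluster's map and a
permutation p at or below the Bonferroni cutoff alpha/k computed from
the realized cluster count — 0.0125 for a 4-cluster solution, 0.01
for 5.  The t statistic was chosen over the raw mean difference for
variance standardization; the choice is recorded in the mask metadata.

# Behavioral module

PASAT raw scores (0-60 correct responses) are corrected by ordinary
least squares on age, years of education and gender over a
user-designated reference sample; Z = (raw - predicted)/residual SD.
Normative coefficients are not built in — the module guarantees the
behavior, not someone else's constants — but externally supplied
coefficients can be used by constructing the `pasat_norms` structure
directly.  Extreme groups take the top and bottom
`ceiling(n * fraction)` of scored subjects by Z (ties broken by id),
the rule that turns 53 scored patients into two groups of 18.
Subjects with missing covariates are excluded from scoring and
reported.

# Problem sizes and determinism

Desk-scale verification runs use the generator defaults (32 + 2
channels, 128 Hz, 205 trials, 15 + 15 subjects) with 30 analysis
frequencies to 45 Hz and 1000 permutations per cluster; one full study
takes on the order of 1-2 minutes per run.  Every stochastic stage
(generator, ICA sample order, permutation draws, K-means restarts)
consumes an explicit seed recorded in the configuration, and a
configuration hash is stamped into every result, so reruns are
bit-reproducible.

# Known limitations

Spherical geometry only (no BEM/FEM, no subject anatomy); single
dipoles only (no bilateral pairs); plain Infomax (sub-Gaussian sources
such as line noise are outside its model; the generator's bursty
rhythms are super-Gaussian); the artifact flagger's z-scores assume
artifacts are a minority; the cluster-count rule is a proxy for a
judgment call and should be reviewed through its diagnostics; and the
Talairach-like affine is nominal, so centroid coordinates are
comparable within a study but are not anatomical claims.
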