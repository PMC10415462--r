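---
title: "Resting-state EEG-fMRI network contrasts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resting-state EEG-fMRI network contrasts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(restcouple)
```

# The scientific problem

Simultaneous EEG-fMRI promises two complementary views of resting-state
brain networks — millisecond-scale electrophysiological coupling and slow
haemodynamic covariation — but EEG recorded inside an MR scanner is buried
under two artifacts that are orders of magnitude larger than brain signal:
the gradient artifact (GA) locked to each volume acquisition, and the
ballistocardiogram (BCG), the electrode/cable movement induced by each
heartbeat in the static field. The analytical question this package
addresses is whether source-level power and connectivity *group contrasts*
(for example, a patient group with generalized epilepsy versus controls)
survive that cleaning, and whether the EEG and fMRI group-difference maps
agree spatially more than chance.

`restcouple` implements the full chain as testable units: a synthetic
cohort generator with known ground truth, artifact removal, DICS beamformer
source reconstruction, imaginary-coherency connectivity, permutation GLM
inference with TFCE, seed-based fMRI correlation, and a sensor-shuffling
surrogate test of cross-modal spatial concordance. Every stage is a pure
function of its inputs and a seed.

# The synthetic cohort

Because patient recordings of this kind are not publicly distributable, the
package ships a generator whose defaults define the study conditions:

* **Groups:** 15 patient-like + 16 control-like subjects; ages uniform
  19–57; sex Bernoulli with probabilities 9/15 and 7/16 (female).
* **Geometry:** a triangulated sphere-like cortical sheet plus interior
  subcortical clusters (bilateral thalamus, hippocampus, amygdala, caudate,
  putamen, pallidum as vertex counts allow). The fixture default is
  260 + 42 = 302 vertices with 64 sensors; the study-scale 2004 + 334 =
  2338 vertices and 256 sensors remain configurable. Contiguous cortical
  regions are grown from anchor directions; the first six carry canonical
  seed labels (`mpfc`, `dmn_lp_l/r`, `precuneus_pcc`, `intracalcarine_l/r`).
* **Forward model:** an analytic concentric three-shell sphere
  (brain/skull/scalp radii 80/86/92 mm, conductivities 0.33/0.004/0.33 S/m)
  solved per spherical harmonic by matching potential and radial current at
  each interface; radial unit sources, one gain column per vertex. With
  equal conductivities the solution reduces to the classic single-sphere
  series, which the tests verify to machine precision.
* **EEG signal:** each vertex carries 1/f-weighted stochastic signal
  between 1 and 60 Hz, synthesized in the frequency domain;
  `source_amplitude = 3` yields a realistic scalp RMS near 50 µV; white
  sensor noise of 2 µV is added.
* **Planted effect:** designated region pairs (thalamus → precuneus by
  default) share band-limited components in the theta band, restricted to
  the band interior (4.5–7.5 Hz) so the effect cannot straddle a
  neighbouring band's edge bin. The target-region copy is phase-lagged by
  π/4, so the imaginary part of coherency — which nulls zero-lag mixing by
  construction — is sensitive to it. Six independent components per region
  pair are assigned to vertices at random. This matters: a single
  region-wide component makes all effect sources mutually coherent, and an
  adaptive beamformer *cancels* coherent sources, hiding the effect; with
  per-vertex component assignment, within-region coherence stays moderate
  while many cross-region pairs remain strongly lag-coupled. The group
  coupling gains (2.5 for patients, 0.25 for controls, ±20% per-subject
  jitter) were calibrated once so that the planted effect is recoverable by
  the full pipeline with the stated power at fixture scale; they are not a
  claim about patient physiology.
* **Artifacts (inside condition):** a GA waveform of slice-frequency
  harmonics repeated exactly at each 2-s TR trigger (5000 µV scale, 2%
  slow amplitude drift), and BCG transients built from a fixed basis of 3
  waveforms with per-beat amplitude jitter, at beat times with 5% interval
  jitter around 1.1 Hz (100 µV scale). The 3-waveform basis with jitter is
  deliberate: a 4-component optimal basis set *can* remove it, but not
  trivially. Patient-like recordings occasionally carry 1-s generalized
  3-Hz spike-wave bursts (Poisson, 1/3 expected per recording).
* **BOLD:** per-vertex white drive convolved with a canonical double-gamma
  haemodynamic response at TR 2 s, slow drift, motion-correlated
  components from six random-walk motion parameters, occasional spike
  volumes, and global physiological signals shared with dedicated
  white-matter-like and CSF-like nuisance locations (so component
  regression can remove them — the pipeline performs no global-signal
  regression). In the patient-like group the thalamic seed regions share
  drive with the precuneus targets (gain 0.8).

What the generator does **not** emulate: realistic head anatomy and
electrode digitization, ocular/muscle artifacts, scanner-specific gradient
spectra, vascular physiology beyond the canonical HRF, and patient
heterogeneity. Passing tests therefore demonstrate algorithmic correctness
and statistical calibration under known ground truth, not clinical
validity on real recordings.

# Artifact removal

`average_artifact_subtraction()` builds, per channel, a sliding-window
average template (default `k = 30` nearest TR epochs) and subtracts it at
each trigger. A per-channel, per-epoch template amplitude is fitted by
least squares (`fit_scale = TRUE`), which absorbs slow artifact drift that
a plain average cannot follow. `obs_bcg_removal()` collects beat-locked
epochs, takes the principal components of the uncentred epoch matrix,
ranked by explained variance, and subtracts the least-squares fit of the
top `n_components = 4` (a cumulative-variance rule is available via
`n_components < 0`).

Two properties are worth stating plainly. First, template subtraction and
filtering are linear operators; the OBS fit is linear only conditional on
its basis, because the basis itself is estimated from the data. Second,
there is a known interaction: the GA template inevitably absorbs the
TR-window mean of the (non-TR-locked) BCG, attenuated by roughly the
window length. After both steps the *beat*-locked residual is
indistinguishable from the matched outside recording's chance level (the
efficacy criterion), while the TR-locked residual retains a smear of
roughly 1.4–2 times the outside chance level. This mirrors the situation
with real recordings, where artifact interactions prevent complete
removal; the beamformer's suppression of non-brain-like topographies
(verified ≥ 10 dB in the tests) is the second line of defence.

`filter_resample()` applies a zero-phase Butterworth chain (order-2
high-pass at 1 Hz, order-4 low-pass at 70 Hz, ±2 Hz band-stops at 50, 100
and 150 Hz) and decimates to 250 Hz. `epoch_and_reject()` cuts 2-s trials
at TR triggers (inside) or on a virtual grid (outside) and rejects trials
whose channel-mean peak-to-peak amplitude or variance exceeds a robust z
of 4 (median/MAD over trials) — an automated, reproducible stand-in for
visual inspection; trials overlapping a spike-wave discharge are rejected
together with both immediate neighbours. The channel-*mean* summary was
chosen over the channel maximum because the maximum over many channels is
so heavy-tailed that it rejects a large fraction of perfectly clean
trials. `select_trials()` draws a fixed number of accepted trials (200 at
study scale, i.e. 400 s) to equalize data quantity across subjects.

# Source reconstruction and connectivity

`estimate_csd()` Hann-tapers each 2-s trial (0.5 Hz resolution), Fourier
transforms it, and averages coefficient outer products over trials and all
bins inside the band — one band-level cross-spectral density per band
(delta 0–4, theta 4–8, alpha 8–12, beta1 12–20, beta2 21–29, gamma
32–48 Hz). The scaling is one-sided spectral density, so the
band-integrated diagonal matches time-domain band-filtered variance.

`dics_filters()` computes the frequency-domain adaptive beamformer
$w_v = C_r^{-1} l_v / (l_v^\top C_r^{-1} l_v)$ with
$C_r = \mathrm{Re}(C) + \lambda\,\overline{\mathrm{diag}\,\mathrm{Re}(C)}\,I$
and $\lambda = 0.05$ — the common convention of regularizing by 5% of the
mean sensor power; only the real part of the CSD enters the inverse. Source
power is $\mathrm{Re}(w_v C w_v^H)$ and the full source-level CSD is
$W C W^H$ (a dense vertices × vertices matrix, guarded by a configurable
cap).

Connectivity is the absolute imaginary part of coherency,
$|\mathrm{Im}(S_{xy}/\sqrt{S_{xx}S_{yy}})|$, computed from the
band-averaged CSD (one value per pair per band); averaging $|\mathrm{Im}|$
per bin first is available as an alternative. Node strength is the mean
connectivity of a vertex to all others; the global metric is the vertex
mean. Seed-based EEG connectivity averages the links from the seed-region
vertices (not the coherency of a seed-averaged time course), consistent
with the link-based vocabulary of the node-strength metric. The relative
condition difference is `100 * (inside - outside) / outside` on group
means.

# fMRI cleaning and seed correlation

`flag_outlier_volumes()` marks volumes with standardized global-signal
change beyond 3 SD, framewise displacement above 0.5 mm (sum of absolute
translation differences plus rotation differences × a 50 mm radius), or
falling on a spike-wave discharge or any of the nine volumes after it
(18 s at TR 2 s). `regress_confounds()` removes, per location: six motion
parameters, three principal-component regressors each from the
white-matter-like and CSF-like location sets, and one spike regressor per
flagged volume — deliberately no global-signal regression. The fitted
nuisance design is stored and reused on repeated calls, making the
operation an exact projection. `bandpass_bold()` detrends each location
(a linear ramp leaks through a recursive filter's edge transients even
though its spectrum is far below the band) and applies a zero-phase
0.008–0.09 Hz Butterworth band-pass. `seed_fc_fmri()` correlates the mean
seed time course with every location over non-flagged volumes; Fisher-z
values are stored for group statistics while the maps display r.

# Permutation inference

`permutation_test()` tests one design column (the group indicator, coded
patient = 1) one-tailed with age and sex as nuisance covariates, using the
Freedman–Lane scheme: nuisance-only residuals are row-permuted and the
full model refit per permutation. P-values are
$(1 + \#\{T^\ast \ge T\})/(1 + n_{perm})$, so they are never zero. With
`enhance`, the compared statistic is the TFCE-enhanced t map
($\sum_h e(h,v)^{E} h^{H}\,dh$ with $H = 2$, $E = 1$, $dh =
\max(t)/100$ recomputed per map, components over the vertex adjacency
graph; subcortical clusters use within-cluster 6-nearest-neighbour
adjacency since they carry no triangulation), and max-statistic
familywise-error p-values come from the same pass. Designs too small for
the requested permutation count are enumerated exhaustively with a
warning. The paired condition × group analysis sign-flips within-subject
differences for the condition main effect and permutes group labels over
the differences for the interaction, both two-sided, FDR-corrected across
bands. Benjamini–Hochberg adjustment wraps `stats::p.adjust`; Cohen's d
uses (n−1)-weighted pooled SD.

The default `n_perm` is 2000 for desk-scale runs; 20000 is the study-scale
preset. The hot loop (Freedman–Lane refits plus TFCE) is compiled C++, so
a 2000-permutation TFCE test on a 302-vertex map takes about a second.

# Cross-modal surrogate test

Shuffling the channel series against the channel labels destroys the
correspondence between data and leadfield while preserving every
within-channel property. Each subject gets a fixed set of distinct
non-identity permutations (50 at study scale); each surrogate passes
through the identical beamformer + seed-connectivity code path as the real
data, a group comparison is recomputed for each of `n_draws` random
per-subject surrogate assignments (500 at study scale, reduced permutation
count since only the map shape feeds the correlation), and the
unthresholded $-\log_{10}p$ map is correlated with the fMRI target map.
Only seed × band combinations whose real-data tests pass the FWE gate are
processed. Significance requires both exceeding the null's 95th percentile
and a BH-FDR-adjusted empirical p ≤ 0.05 across the tested set. Because a
channel-pair average is invariant under a consistent relabelling, applying
a permutation to the sensor CSD is *exactly* equivalent to re-estimating
the CSD from the shuffled recording; the implementation uses this identity
(asserted by a test) to avoid recomputing Fourier transforms per
surrogate.

# Numerical and design choices

* Vertex indices are 1-based in R; all times in seconds, frequencies in
  Hz, EEG amplitudes in µV.
* Degenerate fits (zero residual variance) yield t = 0 via a relative
  threshold rather than 0/0.
* EDF storage is 16-bit with per-channel physical scaling rounded to the
  stored header precision, so round-trip error is bounded by half the
  stored resolution; events live in a JSON sidecar. Covariates, BOLD
  series and maps are TSV; containers are serialized as RDS at run time.
* The trial-rejection thresholds are configuration, not constants tuned to
  reproduce any particular rejection rate.
* Whether $|\mathrm{Im}|$ is taken before or after bin averaging is
  exposed as configuration; the default (band-averaged CSD first) follows
  the band-level beamformer.

# Problem sizes used by the test suite

The suite exercises the full pipeline at fixture scale, chosen as the
smallest sizes at which the statistical claims are meaningful: 302
vertices, 64 sensors, 8 + 8 subjects, 64 simulated trials per recording
(48 selected), 2000 permutations; recovery checks use 20 effect cohorts
and 10 null cohorts; calibration checks use 200 null simulations of the
covariate-adjusted permutation test and 60 surrogate draws. Recovery
cohorts are synthesized at the 250 Hz analysis rate (the band-limited
sources make the anti-alias chain a scientific no-op there); the
artifact-removal checks synthesize at 500 Hz and run the full cleaning
chain.

# Known limitations

* The spherical forward model and sphere-like cortex make localization
  claims topological ("the correct region neighbourhood"), not anatomical.
* AAS smears a fraction of the BCG into its TR-locked template (see
  above); complete artifact removal is not achievable, matching practical
  experience.
* ImCoh estimated from ~36 two-second trials is noisy; between-subject
  variability of the planted effect is dominated by estimation noise and
  beamformer leakage, which is why the recovery criterion is formulated
  over cohorts rather than subjects.
* The surrogate branch reduces the per-draw permutation count; its null
  distribution is for the map *shape*, not for calibrated per-draw
  thresholds.
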