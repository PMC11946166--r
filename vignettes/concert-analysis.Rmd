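---
title: "Concert fNIRS analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Concert fNIRS analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(opusnirs)
```

# The measurement model

Continuous-wave fNIRS measures, per source–detector pair and wavelength,
the intensity of near-infrared light that has traversed scalp, skull and
superficial cortex. `opusnirs` works with the standard linearization of
that measurement:

1. **Optical density.** `intensity_to_od()` forms
   $\Delta OD(t) = -\ln\!\big(I(t)/\bar I\big)$ per channel, with the
   channel's temporal mean as reference. The mean reference makes
   $\Delta OD$ invariant to the arbitrary per-channel gain of the
   instrument and (to second order in the fluctuation size) centres each
   trace at zero. Intensities must be strictly positive; a nonpositive
   sample is treated as a validation error naming the channel rather
   than silently clipped.

2. **Modified Beer–Lambert law.** For two wavelengths,
   $\Delta OD(\lambda) = \big[\varepsilon_{HbO}(\lambda)\,\Delta HbO +
   \varepsilon_{HbR}(\lambda)\,\Delta HbR\big]\cdot L(\lambda)$,
   inverted per pair by `od_to_conc()` as a $2\times 2$ solve. By
   default $L \equiv 1$, so the recovered quantities carry
   **Molar·mm** units — concentration change times effective path
   length. This is deliberate: the partial path length through cortex is
   unknown for any individual channel, and reporting
   concentration-times-path avoids asserting a depth calibration we do
   not have. Setting `pathlength_scaling = TRUE` in `mbll_params()`
   divides by geometric distance × DPF (default 6.0 at both
   wavelengths, the conventional adult-head value) for Molar units.
   The shipped extinction table (`inst/extdata/extinction_hb.csv`,
   1/(Molar·mm)) holds nominal values interpolated from the commonly
   used compiled hemoglobin spectrum; at 762 nm deoxyhemoglobin absorbs
   more strongly than oxyhemoglobin and the order reverses at 842 nm,
   which is the property the wavelength pair exploits. Substitute a
   calibrated CSV for quantitative work.

3. **Bandpass.** The hemodynamic band is isolated with a zero-phase
   3rd-order Butterworth filter, band edges **0.01–0.5 Hz**. The upper
   edge keeps the response to piece-scale events while attenuating the
   cardiac line (~1.2 Hz) by more than 40 dB; the lower edge removes
   drift slower than ~100 s. Numerically the filter is applied as a
   cascade of a 3rd-order high-pass and a 3rd-order low-pass, each run
   forward–backward (`filtfilt`): at 75 Hz the normalized band corners
   ($2.7\times10^{-4}$ and $1.3\times10^{-2}$) make a single bandpass
   biquad ill-conditioned, while the cascade is stable and measured at
   gain 1.02 at 0.1 Hz in the test suite. Forward–backward application
   squares the magnitude response and cancels the phase exactly, which
   matters because all downstream windows are defined in absolute event
   time.

4. **Bad channels** are screened on raw intensity: coefficient of
   variation above 0.15 (loose coupling, motion dominance) or relative
   variance below $10^{-12}$ (dead channel). Flagged channels are
   **masked, not deleted** — downstream matrices keep all 36 columns so
   channel bookkeeping never shifts; the inverse solver drops a pair
   when either wavelength is flagged.

# Event bookkeeping and the three protocols

Pieces are encoded as `"<id>/start"`/`"<id>/end"` event pairs. All
time-to-sample conversion uses one rule: second $t$ maps to zero-based
cell $\lfloor t \cdot f_s\rfloor$, and intervals are half-open
$[a, b)$, so a 20 s window at 75 Hz is exactly 1500 samples and
adjacent windows never share a sample. Whether a boundary sample
belongs to the window ahead of it or behind it is not observable in any
downstream average; the half-open convention was chosen once and is
applied everywhere.

Three window protocols turn pieces into analyses:

- **Whole piece** — the full $[start, end)$ span, *no baseline of any
  kind*. This is the purely averaging, channel-space protocol; its
  outputs deliberately carry no baseline metadata.
- **Initial** — 5 s baseline immediately before the piece, first 20 s
  of the piece. Pieces starting earlier than 5 s into the recording or
  shorter than 20 s are skipped with an explicit reason.
- **Mid** — for pieces *strictly* longer than 180 s: 20 s baseline,
  a three-minute model span, extraction window 60–120 s into the
  piece. "Longer than three minutes" is read literally (> 180 s), so a
  180.0 s piece is excluded; the boundary behaviour is pinned by a
  test. Because the inverse estimator is linear and per-sample,
  inverting the extraction window directly is identical to modelling
  the full three minutes and then extracting — the implementation does
  the former.

Baseline correction is mean subtraction: the channel mean over the
baseline window is removed from the analysis window before source
estimation. Overlapping pieces (attacca transitions) are allowed and
flagged rather than rejected.

# Short-channel correction

The two 8 mm short-separation channels see scalp hemodynamics but
essentially no cortex. The correction implemented as the primary method
operates on **per-piece summary means of HbT**, not sample-wise: for
each piece, the mean of the two short-channel piece means is subtracted
from every long channel's piece mean, and negative results are set to
**exactly zero**. The zeroing is a trust rule, not just cosmetic: a
channel whose piece mean does not exceed the superficial level is
flagged low-trust in the report. Both short channels are pooled into
one mean (no nearest-short pairing), and HbT is the default quantity
(chromophore-wise correction is available via the `chromophore`
argument of `piece_channel_means()`). A sample-wise subtraction exists
as `ssc_subtract_samplewise()` but is labelled an extension and is off
everywhere by default.

The correction is exact precisely when the superficial signal appears
in long channels with coupling 1.0 — the assumption the synthetic
generator implements and the test suite verifies (≥ 90% of the
superficial contribution to piece means removed). On real data coupling
varies by channel, which is why the dominance diagnostic
(`ssc_dominance()`: short/long ratio and zeroed fraction) matters: a
zeroed fraction near 1 says the recording is superficial-noise
dominated and its cortical interpretation should be abandoned rather
than rescued.

# Forward and inverse source model

The forward model is the continuous-wave diffusion approximation for a
semi-infinite homogeneous medium with the extrapolated-boundary
condition: an isotropic source at depth $z_0 = 1/(\mu_a+\mu_s')$ plus a
negative image above the boundary, effective reflection coefficient
0.493 (tissue refractive index ≈ 1.4). Channel-to-vertex sensitivity is
the adjoint (Rytov) form
$\Phi(s\!\to\!v)\,\Phi(v\!\to\!d)/\Phi(s\!\to\!d)$, evaluated from a
tabulated radial fluence profile (0.5–200 mm, 0.25 mm grid); a vertex
outside the tabulated range takes the fluence of the physically closest
in-range vertex, ties broken by lowest vertex index. Optical properties
are a per-wavelength configuration (`optical_props()`; defaults
$\mu_a$ = 0.017/0.019 mm⁻¹, $\mu_s'$ = 1.10/1.00 mm⁻¹ at 762/842 nm,
nominal adult-head values), so each wavelength gets its own forward
model rather than sharing one reference wavelength's fluence.

The template cortex is a structured spherical-cap mesh of exactly
10,000 vertices at 13 mm below the 85 mm scalp sphere, centred under
the montage. It is explicitly a bookkeeping surface, not anatomy: ROIs
("scouts") on it are geodesic patches sized to the vertex counts of the
atlas regions the concert analysis tracks (PRG 107, POG 97, STG 92,
combined rIFG 144 on a 10,000-vertex head model), seeded at the
cortical projections of the corresponding optode groups. Real atlas
scouts can be supplied as TSV/JSON vertex lists against a user mesh
(ASCII OFF/PLY-style I/O provided).

The inverse is a depth-weighted Tikhonov minimum-norm estimator,
$x = W A^{\top}(A W A^{\top} + \alpha I)^{-1} y$ with
$W = \mathrm{diag}\,\lVert a_v\rVert^{-2\gamma}$, $\gamma = 0.5$, and
$\alpha = \lambda \cdot \mathrm{tr}(A W A^{\top})/n_{ch}$ with
$\lambda = 1/\mathrm{SNR}^2$ at an assumed amplitude SNR of 3
($\lambda = 1/9$). Two numerical guards matter:

- **Depth-amplification cap.** Unlimited $\lVert a_v\rVert^{-2\gamma}$
  weighting explodes at the sensitivity fringe (vertices tens of mm
  from any optode) and can park the solution peak there. Amplification
  is capped at 10× relative to the strongest column — the conventional
  weight limit in minimum-norm practice. With the cap, a noiseless
  single source placed beneath any channel localizes within 15 mm in
  the test suite; without it, fringe vertices can win.
- **Short channels are excluded** from the inverse (they inform the
  scalp, not cortex), and no separate superficial-noise removal stage
  is applied inside the source model.

The two wavelength images are converted per vertex to ΔHbO/ΔHbR by the
same $2\times 2$ extinction solve as the channel-level MBLL, and
HbT = HbO + HbR by construction everywhere.

What the model honestly cannot do: separate sources ~1 cm apart. The
method's resolution class is 2–3 cm, and the test suite contains a
deliberate negative test asserting only that two sources 10 mm apart
produce a blob near their centroid — merging is tolerated, separation
is not claimed. Likewise PRG/POG separability on a real head should not
be over-read from adjacent scouts on this template.

# ROI statistics and trend tables

`scout_average()` is the grand mean over (scout vertices × window
samples) — a time average followed by a vertex average, which is the
same number in either order. The interval rule is
$CI = \bar X \pm T \cdot SEM$ with $SEM = s/\sqrt n$ (sample sd, $n-1$
denominator) and $T$ the two-sided Student-t quantile at $n-1$ degrees
of freedom. The literal one-sided form ($\bar X + T\cdot SEM$ only) is
available via `two_sided = FALSE`; the symmetric two-sided interval is
the default because a 95% confidence *interval* is what the statistic
is used as. Empirical coverage of the rule is verified by simulation
(2000 replicates of n = 30 Gaussians ⇒ 95% ± 1.5 points).

**What is the sample $X$?** Several choices are defensible (time
samples within the window, per-vertex values, per-piece summaries).
The default is **per-piece scout-averaged summaries within one
concert** — so with five qualifying pieces, $n = 5$ and the interval
reflects piece-to-piece variability, which is the variability a
cross-concert comparison should be charged with. The choice is recorded
in the output (`sample_unit` column) so alternatives remain
distinguishable.

`trend_table()` assembles per-concert statistics into series ordered by
concert index, inserting **explicit gap rows** (`gap = TRUE`, NA
statistics, n = 0) for concerts without a usable recording. Gaps are
never interpolated; a seven-concert series with two losses has seven
rows, two of them gaps.

# The synthetic generator

`generate_session()` produces the statistical structure the analysis
chain assumes, with known ground truth:

- **Cortical signal**: per-scout boxcar (piece on/off) convolved with a
  double-gamma HRF (unit peak at 5 s, within the physiological 4–6 s
  window; undershoot at 16 s, ratio 1/6), scaled by scout amplitudes of
  order 1 µM·mm (`1e-6` Molar·mm) — the conventional channel-level
  scale; true amplitudes for concert performance are not established
  anywhere, so these are labelled order-of-magnitude conventions. HbR
  is −0.35 × HbO. The activation is forward-projected through the same
  sensitivity matrix the analysis inverts.
- **Superficial physiology**: Mayer waves (0.1 Hz, 0.5 µM·mm),
  respiration (0.25 Hz, 0.3 µM·mm), cardiac (1.2 Hz, 0.2 µM·mm) with
  random phases, shared across channels; **long channels receive it
  scaled by a coupling coefficient (default 1.0), short channels
  undiluted**. That unit default is exactly the assumption that makes
  pooled-SSC subtraction meaningful, and it is stated here rather than
  hidden.
- **Noise and nuisance**: white ΔOD noise (sd 2×10⁻⁵ per sample —
  small relative to cortical channel ΔOD of ~10⁻⁴, large relative to a
  single filtered sample), linear drift, and Poisson-scheduled motion
  spikes/steps (rate 1/300 s).
- **Performer asymmetry**: a per-performer attenuation factor (0.35 for
  the first performer, 1.0 for the second) scales the cortical
  contribution down and the noise up, emulating poorer optical coupling
  through hair. This makes the first performer's recordings
  superficial-dominated by design — the regression scenario where the
  SSC subtraction zeroes most channels — so tests of trend-sign
  recovery are run on the well-coupled performer only.
- **Across concerts**: the rIFG amplitude declines linearly
  (×(1 − 0.15·(concert − 1))), giving a known negative trend target;
  other scouts are held constant.
- **Data losses**: `default_fixture()` omits concert 4 for the first
  performer and concerts 4 and 6 for the second, so the gap-row
  machinery is exercised under the study's actual missing-data
  pattern. The default programme has nine pieces of which exactly five
  exceed 180 s.
- Events may carry Gaussian labelling jitter (sd 1 s when enabled;
  **off by default**) to emulate manual event placement error.

What the generator does **not** emulate: real anatomy (the cap is not a
cortex), channel-specific superficial coupling, heartbeat/respiration
harmonics and amplitude modulation, slow state changes within a piece,
or any acoustic/behavioural structure. Consequently, passing tests
demonstrate that the chain recovers what it assumes — correct wiring,
units, windows, and statistical behaviour — not that it would recover
physiology from an arbitrary real recording.

# Problem sizes and determinism

The test suite runs the full seven-concert fixture (eleven recordings
of ~1470 s × 36 channels at 75 Hz) once for the trend analysis, and
shorter two-piece sessions elsewhere; the source solver thins analysis
windows to ~3 Hz before inversion (`decimate_hz`), which is lossless
for time-averaged scout summaries given the 0.5 Hz signal band. All
stochastic steps are seeded; the same seed reproduces a session down to
identical SNIRF file checksums, and `run_pipeline()` writes a manifest
with the seed, configuration, per-stage timings and MD5 checksums of
every output file.

# Known limitations

- The homogeneous semi-infinite fluence ignores skull/CSF layering; the
  sensitivity profile is qualitatively right (exponential-ish decay,
  banana-path maximum under the channel) but not quantitatively
  calibrated, so source amplitudes are relative.
- The spherical-cap "cortex" makes vertex counts and distances exact
  but anatomy fictional; scouts are positional stand-ins.
- The 8 mm/30 mm nominal separations and the idealized optode
  coordinates are declared geometry, not measured digitization.
- Piece-summary SSC subtraction corrects means only; within-piece
  superficial dynamics pass through to the source model untouched
  (deliberately, to keep the processing homogeneous with the
  channel-level protocol).
- With five pieces per concert, the t-interval has 4 degrees of
  freedom; its width is honest but its normality assumption is
  unchecked at that n.
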