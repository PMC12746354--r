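---
title: "Flip-angle errors in AFI of PVP/water phantoms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Flip-angle errors in AFI of PVP/water phantoms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(afisim)
```

## The measurement and its failure mode

Actual flip angle imaging (AFI) interleaves two repetition times
$TR_1 < TR_2$ with identical RF pulses and estimates the flip angle from the
steady-state signal ratio $r = |S_2|/|S_1|$ via
$\alpha = \arccos\{(rn-1)/(n-r)\}$ with $n = TR_2/TR_1$. The estimator is
exact only if the transverse magnetization is destroyed at the end of each
repetition. Real sequences approximate this with spoiler gradients (here
quantized to integer multiples of $2\pi$ dephasing across the voxel) and RF
spoiling with the quadratic phase schedule
$\Phi_j = \Phi_{j-1} + j\,\Phi_0$. Residual coherences make $\alpha$ depend
on $\Phi_0$; for a voxel containing a single resonance the resulting
"spoiling curve" is symmetric about $\Phi_0 = 90°$.

PVP/water phantoms add a second failure mode. The PVP proton bands sit a few
hundred hertz from water, so the voxel's signal is a sum of two steady
states with different precession frequencies. Their interference at the echo
time depends on $TE$ and on the relative steady-state phases — which depend
on $\Phi_0$ asymmetrically. The package reproduces the characteristic
signatures: asymmetric spoiling curves with minima at $\Phi_0 = 60°$ or
$120°$, $TE$-periodic signal magnitudes with period $1/\Delta\nu$, and
outright estimation failures where interference pushes $|S_2|$ above
$|S_1|$.

## The EPG engine

Magnetization is represented by complex configuration amplitudes
$F^+(k), F^-(k), Z(k)$ over non-negative integer dephasing orders $k$ (one
order = $2\pi$ across the voxel), with $F^-(0) = \overline{F^+(0)}$. Four
operators act on this state:

* **RF rotation.** Every order is mixed by the same $3\times3$ matrix. On
  resonance this is the standard EPG rotation. Off resonance the pulse is a
  constant-amplitude rectangle of duration $\tau$: with
  $\omega_1 = \alpha/\tau$ and $\Delta\omega = 2\pi\Delta\nu$, the rotation
  is by $\sqrt{\omega_1^2 + \Delta\omega^2}\,\tau$ about the effective axis
  tilted out of the transverse plane by $\arctan(\Delta\omega/\omega_1)$,
  with the tilt sign continuing the free-precession sense. The matrix is
  built in Cartesian magnetization space and conjugated into the
  $(F^+, F^-, Z)$ basis; the unit tests verify it against a stepwise
  Runge-Kutta integration of the rotating-frame equation of motion to
  $10^{-9}$. Relaxation and diffusion are suspended during the 0.5 ms pulse
  (it is far shorter than every $T_2$ in the catalog).
* **Relaxation** scales transverse amplitudes by $e^{-t/T_2}$,
  longitudinal ones by $e^{-t/T_1}$, and recovers $Z(0)$ toward $m_0$.
* **Gradient shift** moves $F^+$ orders up and $F^-$ orders down with the
  conjugate hand-off through order zero. Amplitudes shifted past the storage
  cap `k_max` (default 4096) are dropped and their energy accumulated in a
  truncation-loss counter; a simulation aborts if the loss exceeds
  $10^{-6}\,m_0^2$.
* **Diffusion damping** attenuates transverse order $k$ by
  $\exp\{-ADC\,\kappa^2 (k^2 + k\Delta k + \Delta k^2/3)\,t\}$ and
  longitudinal order $k$ by $\exp(-ADC\,\kappa^2 k^2 t)$, with
  $\kappa = 2\pi/\mathrm{voxel}$ and $\Delta k$ the order change during the
  interval — the constant-gradient form of the b-factor, applied with
  pre-shift order labels.

Phase conventions are fixed once, package-wide: $F^+ = M_x + iM_y$, and free
precession at offset $\Delta\nu$ multiplies $F^+$ by
$e^{-2\pi i \Delta\nu t}$. Every other sign in the package follows from
this choice; see the interference section for the one place it matters.

## Sequence simulation and pseudo-steady state

One TR interval is: pulse (with its scheduled phase) → relaxation and
precession to $TE$, where the demodulated signal
$F^+(0)\,e^{-i\Phi_j}$ is recorded → spoiler over $[TE, TR]$ (diffusion
damping, then the order shift) with relaxation/precession over the
remainder. The spoiler is modeled as occupying the interval from readout to
the end of the TR; since diffusion weighting is computed over that interval,
the echo time weakly modulates diffusion damping (about 0.3% on $\alpha$ for
the water tube between $TE$ = 1.5 and 6.1 ms). This is a property of the
chosen spoiler timing, not of the estimator: at $ADC = 0$ the flip-angle
estimate is $TE$-invariant to machine precision, which is how the invariance
property is tested.

RF-spoiled trains settle slowly, so the simulator runs 200 TR pairs of
settling (configurable; about 30 s of sequence time, far beyond the 2 s of
dummy scans a scanner uses) and then averages the demodulated complex
signals over whole periods of the phase schedule — the smallest multiple of
the schedule's pair-period that is at least 32 pairs. The run extends until
two consecutive windows agree to `settle_tol` ($10^{-6}$ relative) and
errors out with a settle report if `max_pairs` is exceeded. The averaging
window is computed from the exact period of
$\Phi_0\,j(j+1)/2 \bmod 360°$, found in integer arithmetic for integer
$\Phi_0$, so phase drift cannot accumulate over thousands of pulses.

An independent brute-force oracle, `simulate_afi_isochromat()`, propagates
thousands of isochromats spanning one voxel with explicit spoiler phases
$2\pi\,\Delta k\,x$ and identical scheduling and averaging. It cannot
represent diffusion (a discrete ensemble has no intra-voxel random walk), so
quantitative EPG-vs-isochromat comparisons run at $ADC = 0$; 4096 spins keep
the ensemble's aliasing (configuration orders wrap at the spin count) well
below the $10^{-3}$ comparison tolerance even for the water tube's long
$T_2$. The acceptance suite checks agreement across six $\Phi_0$ values.

Failed estimates — the arccos argument outside $[-1, 1]$, which genuinely
happens under strong interference — are first-class values: `NA` plus a
`failed` flag, excluded from statistics but counted, never an exception.

## The two-frequency interference model

One AFI acquisition is simulated twice: a resonant water pool
($\Delta\nu = 0$; $T_1$, $T_2$, $ADC$ from the tube catalog) and one
off-resonant PVP pool sharing the same $ADC$. The combined signal is

$$S_i = S_{i,\mathrm{res}} + w\,S_{i,\mathrm{off}}\;
e^{-i(2\pi\Delta\nu\,TE + \varphi)}, \qquad i = 1, 2 .$$

Two conventions required decisions the literature leaves open:

* **No double counting.** The off-pool signal is recorded *at the pulse*
  (its $T_2$ decay over $TE$ applied, but no pulse-to-readout precession
  phase), and the exponential factor supplies the entire pulse-to-readout
  phase; the off-resonant precession within and across TRs remains in the
  EPG state. Recording at $TE$ with the in-state precession retained would
  cancel the factor exactly and no $TE$-beat could occur — the observed
  $1/\Delta\nu$ periodicity of $|S(TE)|$ forces this reading.
* **Frame chirality.** In this package's frame $F^+$ accumulates
  $-2\pi\Delta\nu\,TE$ during $TE$, so the factor that continues the
  in-state phase carries the same sign: $e^{-i(2\pi\Delta\nu TE+\varphi)}$.
  Reported interference parameters quoted in the conjugate-frame convention
  (where the factor is written with a positive exponent) drop in unchanged —
  with this sign choice the package reproduces all three published anchor
  configurations: the 3 T minimum at $\Phi_0 = 60°$
  ($w/\varphi = 0.136/-0.18\pi$, $\Delta\nu = 320$ Hz, $TE = 1.9$ ms), the
  7 T minimum at $60°$ ($0.052/0.21\pi$, 747 Hz, $TE = 1.9$ ms) and the 7 T
  minimum at $120°$ ($0.078/-0.59\pi$, 747 Hz, $TE = 3.0$ ms). The opposite
  sign reproduces only two of the three, which is what fixed the choice.

The off pool's relaxation times are not published for the simulation
setting; the defaults ($T_1$ = 100 ms and $T_2$ = 5.7 ms up to 25 wt% PVP,
70 ms and 1.6 ms at 50 wt%, interpolated between — `pvp_off_pool()`) come
from the inversion-recovery $T_1$ of the PVP resonances and the $T_2^*$ of
the upfield band measured by benchtop NMR. The fitted $w$ partially absorbs
this choice, which is why $w$ is treated as an empirical weight rather than
a proton-density ratio. Only the two-frequency model is implemented; the
spectra show a third band, but adding components multiplies fitting degrees
of freedom without published values to anchor them.

Because the PVP pool's $T_2$ is much shorter than $TR_1$, its transverse
state dies before the next pulse: its steady state is FID-like and nearly
independent of $\Phi_0$ (a unit test drives $T_2$ to 0.4 ms and checks
$\Phi_0$-insensitivity to $10^{-6}$). The interference asymmetry therefore
comes from the $\Phi_0$-dependent *phase* of the water pool beating against
an essentially fixed off-resonant phasor.

## Fitting w and phi

`fit_interference()` minimizes the RMS flip-angle deviation between the
model curve and a measured curve over the mutually successful grid points,
with $\Delta\nu$ held fixed. Two structural facts make this cheap and
robust:

* The per-pool component signals do not depend on $(w, \varphi)$, so they
  are simulated once per grid (20 EPG runs for a 10-point curve) and every
  candidate is evaluated by scalar combination plus the arccos — the
  objective surface can be swept densely at negligible cost.
* The search is deterministic: a coarse grid (21 weights in $[0,1]$ ×
  24 phases on the circle) followed by Nelder-Mead refinement from the best
  three starts. Same data, same settings, same result — verified by test.

Measured points that failed are excluded from the objective (and reported);
candidate parameters whose *simulated* estimate fails at a measured-valid
point are penalized at 90° per point rather than rejected, which keeps the
objective finite near the failure boundary that strong interference
produces. $w$ is bounded to $[0, 1]$ (a minority-component weight; published
fits are below 0.14) and $\varphi$ is wrapped to $(-\pi, \pi]$ at the end.
Noiseless self-consistency recovery is exact to the optimizer tolerance;
the acceptance suite requires $|\hat w - w| < 0.005$ and
$|\hat\varphi - \varphi| < 0.02\pi$ and checks that the recovery error grows
monotonically over noise levels 0.0005, 0.002, 0.008 (20 seeded replicates
each).

## What the synthetic generator does and does not emulate

`generate_measured_curve()`/`generate_te_series()` produce the statistical
structure the analysis assumes: the noiseless two-component signals per grid
point, independent complex Gaussian noise per voxel added to $S_1$ and
$S_2$ (so magnitudes are Rician), flip-angle estimation per voxel, and ROI
mean/sd over the voxel-wise estimates (an ROI-mean-signal variant is
available). Defaults — channel sd $0.002\,m_0$, 100 voxels — are plausible
for a 4 cm tube at $2\times2$ mm$^2$ in-plane resolution (cross-section
$\approx 314$ voxels, a circular ROI safely inside $\approx 100$) and an SNR
of a few hundred on the equilibrium signal; both are configurable, and the
$1/\sqrt{n_\mathrm{voxels}}$ scaling of the ROI standard error is verified
by a seeded Monte-Carlo test.

What it deliberately does not emulate: spatial $B_1^+$ variation across the
ROI (real ROI standard deviations mix noise with true flip-angle spread),
$k$-space acquisition and reconstruction, scanner drift, and any
concentration dependence of the noise. Passing recovery tests on this
generator therefore demonstrates estimator correctness under the model's
own assumptions, not robustness to everything a scanner does.

All randomness flows from one explicit integer seed through a local RNG
scope that restores the caller's random state.

## Numerical choices and problem sizes

* Dephasing orders: `k_max = 4096`; the active state is trimmed to the
  populated orders (amplitudes above $10^{-16}$), which diffusion keeps to a
  few hundred in realistic runs, so one spoiling-curve point simulates in
  about 0.1 s.
* Settling 200 pairs; averaging windows of at least 32 pairs rounded up to
  whole schedule periods; settle tolerance $10^{-6}$; hard cap 2000 pairs.
* Curve minima are grid-restricted (no interpolation) because the published
  statements about minima are grid statements; ties break toward smaller
  $\Phi_0$, degenerate flat curves thus report $\Phi_0 = 0$.
* The asymmetry statistic is defined only when both $60°$ and $120°$ are on
  the grid and both estimates succeeded; otherwise it is `NA`.
* Gyromagnetic ratio $\gamma/2\pi = 42.577478$ MHz/T everywhere; the
  $2\pi$-moment quantum over a 2.0 mm voxel is 11.743 mT·ms/m, and moments
  must be quantized to it within 0.5%.
* Test problem sizes: 10-point $\Phi_0$ grids, 4096 isochromats, 20
  replicates per noise level — sized so the whole suite runs in about a
  minute while every tolerance above is still meaningfully exercised.

## Known limitations

Non-selective 1D simulation only: no slice profiles, imaging gradients,
or spatial $B_1^+$ structure. Isotropic diffusion with a single ADC shared
by both pools. No magnetization transfer or chemical exchange between the
PVP and water pools, although exchange plausibly contributes to the real
phantom's behavior. The two-frequency model treats the PVP spectrum as one
effective band; its fitted $(w, \varphi)$ are effective parameters tied to
the chosen off-pool relaxation times. Measured spoiling curves published
only as figures cannot be regenerated here, so agreement with measurement
is assessed through the reproducible summary statistics (symmetry bounds
and minimum locations) rather than point-by-point RMSE values.
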