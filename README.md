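# afisim

Extended-phase-graph simulation and signal-interference analysis for actual
flip angle imaging (AFI) of PVP/water phantoms.

## The problem

AFI is the workhorse 3D B1+ mapping method: two interleaved repetition times
TR1 < TR2 with identical RF pulses yield steady-state signals S1 and S2, and
the flip angle follows from their ratio,

    alpha = arccos( (r*n - 1) / (n - r) ),   r = |S2|/|S1|,   n = TR2/TR1.

The method assumes the transverse magnetization is spoiled at the end of
every TR, which in practice is approximated by spoiler gradients plus RF
spoiling with a quadratic phase schedule `Phi_j = Phi_{j-1} + j*Phi_0`.
Imperfect spoiling makes the estimate depend on `Phi_0` ("spoiling curves"),
symmetrically about `Phi_0 = 90°` for a single resonance.

Phantoms mixed from polyvinylpyrrolidone (PVP) and water — popular because
their permittivity matches tissue — violate a second, quieter assumption:
the voxel contains a single resonance. PVP's methylene/methine protons form
broad bands a few hundred Hz from water (about 320 Hz at 3 T, 747 Hz at
7 T). The off-resonant pool's steady-state signal interferes with the water
signal at the echo time, which makes spoiling curves asymmetric, makes the
estimate depend on TE (it should not), and can drive the flip-angle estimate
tens of degrees below the true value or make the arccos fail outright.

`afisim` is for MRI physicists who need to understand, predict, or correct
these errors: it simulates the dual-TR sequence with a 1D extended phase
graph (EPG) engine — RF rotation including off-resonant excitation about the
tilted effective axis, relaxation, integer-order gradient dephasing, and
isotropic diffusion damping of configuration states — and models the
two-frequency interference

    S_i = S_i,res + w * S_i,off * exp(-1i * (2*pi*dnu*TE + phi)),  i = 1, 2,

whose weight `w` and phase offset `phi` are fitted to measured spoiling
curves by RMSE minimization (`fit_interference()`, a classed model object
with `coef`/`predict`/`residuals`/`plot`/`simulate` methods). A brute-force
isochromat Bloch simulator serves as an independent oracle, a seeded
generator produces synthetic noisy ROI-mean curves (complex Gaussian voxel
noise, Rician magnitudes), and small spectroscopy helpers convert line
widths and inversion-recovery zero crossings into the pool parameters the
model needs.

## Worked example

Simulate the spoiling curve of the 23 wt% PVP tube at 3 T with the fitted
interference parameters, then recover those parameters from a synthetic
noisy measurement:

```r
library(afisim)

sys <- two_component_system(
  res = tube_component("PVP5", "3T"),                       # water pool: T1/T2/ADC from the catalog
  off = tissue_component(100, 5.7, 990, delta_nu_hz = 320)) # PVP band: short T1/T2*, 320 Hz off water

pars <- interference_params(w = 0.136, phi_pi = -0.18, delta_nu_hz = 320)
prot <- afi_protocol(te_ms = 1.9)                           # TR 25/125 ms, 60 deg, moment set I

curve <- simulate_spoiling_curve(prot, sys, params = pars)
curve_minimum(curve)      # $phi0_deg 60, $alpha_deg 20.6
asymmetry(curve)          # 42.4 (deg): strongly asymmetric about 90 deg
```

```
<spoiling_curve> 10 points (simulated), 0 failed, reference = 60 deg
 phi0_deg alpha_deg alpha_sd_deg failed
        0  81.32713            0  FALSE
       20  48.85863            0  FALSE
       40  24.18529            0  FALSE
       60  20.57271            0  FALSE
       80  40.05518            0  FALSE
      100  51.99735            0  FALSE
      120  63.02193            0  FALSE
      140  71.32366            0  FALSE
      160  79.34568            0  FALSE
      180  80.98544            0  FALSE
```

Although the true flip angle is 60°, the simulated AFI reads 20.6° at
`Phi_0 = 60°` (a −66% deviation) and the curve's minimum sits at 60° instead
of being symmetric about 90° — the interference signature. A matched
water tube (`simulate_spoiling_curve(prot, tube_component("W1", "3T"))`)
gives a curve symmetric about 90° with |asymmetry| well below 0.5°.

Fitting the interference parameters back from a noisy synthetic measurement:

```r
meas <- generate_measured_curve(prot, sys, pars, truth_alpha = 60,
          noise = noise_model(complex_noise_sd = 0.002, n_voxels = 100, seed = 42))
fit <- fit_interference(meas, prot, sys)
fit
#> Two-frequency interference fit
#>   w = 0.1348, phi = -0.1757*pi (dnu = 320 Hz, fixed)
#>   RMSE = 0.376 deg over 10 points
plot(fit)   # measured points with error bars + fitted model curve
```

The generating values (w = 0.136, phi = −0.18π) are recovered to the third
decimal at this noise level.

A thin command-line wrapper over the same functions ships in
`inst/cli/afisim.R` (subcommands `simulate-curve`, `te-sweep`, `fit`,
`synth`, `catalog`) for driving batch simulations from YAML configs.

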