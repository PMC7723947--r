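---
title: "Personalising a 0D aortic Windkessel model and validating planar velocity fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Personalising a 0D aortic Windkessel model and validating planar velocity fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemowk)
```

## The problem

Patient-specific haemodynamic studies of the aorta — computational (CFD) or
experimental (mock circulatory loops with particle image velocimetry) — stand
or fall on their boundary conditions. The aortic inlet must carry the
patient's pulsatile flow waveform, and each outlet must present the hydraulic
impedance of the downstream vasculature, usually as a three-element
Windkessel (3WK): a proximal resistance \(R_1\) in series with a parallel
distal resistance \(R_2\) and compliance \(C\). `hemowk` implements the
reduced-order layer of such a study end to end:

1. synthesis of an analytical inlet waveform from clinical parameters
   (stroke volume SV, cycle length \(T\), mean flow \(\bar Q\));
2. a 0D pulsatile simulation of a branched aortic network with 3WK outlets;
3. automatic calibration of the 3WK parameters to clinical targets
   (systolic/diastolic pressure, branch flow distribution);
4. velocity-field analytics for experiment-vs-computation comparison
   (phase averaging, outlier detection, profile extraction, the normalised
   profile-difference metric \(\Delta\), axisymmetric flow-rate integration);
5. a seeded synthetic-data generator built on the analytical Womersley
   solution, standing in for CFD/PIV fields so every operation can be tested
   against an exact oracle.

The bundled study case is a chronic Type-B aortic dissection with four
monitored outlets — brachiocephalic trunk (BT), left common carotid (LCC),
left subclavian artery (LSA) and descending aorta (DA) — with clinical
targets \(P_\mathrm{sys}/P_\mathrm{dia} = 150/80\) mmHg and branch mean
flows 22.5 / 8.9 / 9.8 / 93.3 mL/s out of an inlet mean flow of
134.5 mL/s (`patient_scenario()`).

## Inlet waveform model

`synthesise_inlet_waveform()` builds a strictly non-negative periodic
waveform from two raised-cosine-power lobes,

\[
q(t) = A\left(\tfrac{1 + \cos 2\pi (t - t_0)/T}{2}\right)^{m}
     + b\left(\tfrac{1 + \cos 2\pi (t - t_1)/T}{2}\right)^{m_2},
\]

a sharp systolic ejection lobe centred mid-systole and a wide, low diastolic
bump centred mid-diastole. The power \(m\) is set so the systolic lobe decays
to 5% of its peak at the edges of `systolic_fraction * T` (\(m = 10\) for the
default fraction 1/3, \(m_2 = 3\)). Amplitudes are solved in closed form from
the exact lobe means \(\binom{2m}{m}/4^m\), so the net ejected volume equals
SV identically; when a peak flow is prescribed, a 2×2 linear system fixes
both amplitudes and infeasible combinations (e.g. peak below mean) raise an
error.

Two properties motivated this template over a piecewise systole/diastole
construction:

* each lobe is a trigonometric polynomial, so the waveform is **exactly
  band-limited** to \(\max(m, m_2)\) harmonics. The Womersley generator with
  \(K \ge m\) harmonics reproduces it with no truncation error — the
  generated fields are exact oracles rather than approximations;
* SV, mean flow and non-negativity hold by construction rather than by
  numerical adjustment.

The cost is that "systolic fraction" becomes a nominal width (the lobe decays
smoothly rather than vanishing outside systole) and diastolic flow is low
(default 10% of SV) but not zero. No backflow is modelled.

`adjust_period_to_frame_rate()` implements the acquisition-compatibility
step: the period is increased to the smallest multiple of the frame interval
\(1/f\), e.g. 0.80 s at 22 Hz becomes 18 frames and \(T = 0.8\overline{18}\)
(reported as 0.82 s, 73 bpm). Because \(T\) changes while SV is a measured
volume, SV and mean flow cannot both be preserved; the package preserves SV
and recomputes the mean as SV/\(T\), reporting both.

## 0D network model and integrator

The aortic domain is lumped to a single zero-volume junction: at every
instant the junction pressure \(P_{ao}\) solves
\(\sum_i (P_{ao} - P_{c,i})/(R_{1,i} + R_{s,i}) = Q_{in}(t)\) algebraically,
which makes mass conservation an identity of the scheme (verified to 1e-6
relative in the tests, observed at machine precision). Each branch's
capacitor state advances by
\(C_i \,\mathrm{d}P_{c,i}/\mathrm{d}t = Q_i - (P_{c,i} - P_v)/R_{2,i}\),
integrated with a classical fixed-step RK4 in which the junction is
re-solved at every stage. The default step of 1 ms matches the clinical
sampling of the bundled case; halving it changes final-cycle pressures by
less than 0.1%. An optional per-branch series resistance \(R_s\) is the hook
for connector/tubing losses; venous reference pressure defaults to 0 mmHg
and is configurable. There is no proximal compliance, inertance or valve
model — the compliance of this rigid-domain abstraction lives entirely in
the outlets.

Runs proceed cycle by cycle until the inlet-pressure cycle changes by less
than `tol` (default 1e-3, relative to the cycle's pressure range) or
`max_cycles` is reached; non-convergence is flagged on the result, not
raised. From cold (states at \(P_v\)) the bundled network reaches
periodicity in under 20 cycles; warm starts converge in 2–4.

## Calibration

`calibrate()` is a deterministic fixed-point loop with initial estimates
from the classical formulas \(R_{tot,i} = (\mathrm{MAP} - P_v)/\bar Q_i\)
and \(C_{tot} = \mathrm{SV}/\mathrm{PP}\) (MAP is taken as
\(P_\mathrm{dia} + \mathrm{PP}/3\) throughout; the split
\(R_1 = \kappa R_{tot}\) uses \(\kappa = 0.05\), typical of published aortic
3WK sets, and is configurable). Each iteration simulates to periodic steady
state, then rescales:

* each branch's \(R_{tot}\) by its achieved/target mean-flow ratio — the
  mean flow split depends only on the \(R_{tot}\) ratios, so this step is
  essentially exact after one pass;
* all resistances by target/achieved MAP;
* the total compliance by achieved/target pulse pressure, redistributed
  \(C_i \propto \bar Q_i\).

Evaluating MAP with the same \(P_\mathrm{dia} + \mathrm{PP}/3\) convention
on both sides means convergence of (MAP, PP) forces convergence of
\(P_\mathrm{sys}\) and \(P_\mathrm{dia}\) themselves. On the bundled targets
the loop converges in 2–4 iterations to 0.5 mmHg / 0.5%. Because the loop
multiplies resistances by positive ratios, doubling all target flows at
fixed pressures exactly halves the calibrated resistances (tested). The
\(R_1/R_2\) split is structurally unidentifiable from mean flows and
pressure extrema alone: recovery tests assert \(R_{tot}\) (to 2%) and
\(C_{tot}\) (to 5%) and check the split only against the configured
\(\kappa\). The published 3WK table of the study case is shipped as a
simulation fixture, not as a calibration truth: it was tuned with the 3D
domain's internal resistance in the loop, which a 0D junction cannot
represent, so its steady flow split (e.g. BT \(\approx\) 13%) differs from
the clinical targets by design.

## Flow regime

`flow_regime()` evaluates \(Re = 4\rho Q/(\pi \mu D)\) at mean and peak
flow, the Womersley number \(Wo = (D/2)\sqrt{2\pi\rho/(T\mu)}\), and the
transition criterion \(Re_c = 250\,Wo\). For the bundled case
(\(\rho = 1310\) kg/m³, \(\mu = 2.2\) mPa s, the diameter implied by
\(Re_m = 3472\) at 134.5 mL/s) the package computes \(Wo = 31.4\) at
\(T = 0.82\) s; the study case reports the rounded value 32, and the regime
check therefore uses a 3% tolerance.

## Velocity-field analytics

* `phase_average()` groups frames by phase and returns per-point mean and SD
  over cycles, excluding masked points point-wise; a single contributing
  cycle reports SD 0 with \(n = 1\).
* `convergence_curve()` quantifies phase-average convergence as the maximum
  running-mean change per added cycle over a region and all phases,
  normalised by the largest final phase-averaged axial velocity, in percent.
  The published 1.6%-at-10-cycles criterion does not pin down region or
  norm; this running-mean definition is the package's choice and the region
  is an argument.
* `normalized_median_filter()` is the universal outlier test: the residual
  of each vector to its 5×5 neighbourhood median, normalised by the median
  neighbour residual plus a noise floor (`eps = 0.02` m/s, the velocity
  analogue of the customary 0.1 px floor), flagged above threshold 2 in
  either component. Borders shrink the neighbourhood; fully masked
  neighbourhoods leave the vector unflagged but reported.
* `extract_profile()` samples \(N\) points by bilinear interpolation along a
  directed line whose unit normal is the +90° rotation of its direction —
  fixing the sign of the normal velocity \(u_n\).
* `delta_metric()` computes
  \(\Delta = \frac{100}{N}\sum_i |u^e_{n,i} - u^c_{n,i}| / \max_j |u^c_{n,j}|\)
  on \(N = 1000\) resampled points; scale-invariant but (deliberately) not
  shift-invariant, since the normaliser is the computational profile's peak
  magnitude.
* `axisymmetric_flow_rate()` folds a diametral profile about the axis,
  averages the halves on a common radial grid and integrates
  \(Q = 2\pi\int_0^R u\,r\,\mathrm{d}r\) by trapezoid — second-order
  accurate (Richardson-checked on Poiseuille).
* `mass_conservation_error()` reports (max − min)/mean of section flows in
  percent; the study case does not define the formula behind its printed
  inter-section error, so this definition is a package choice with SD/mean
  as an option.

## Synthetic data: what it emulates, and what it does not

The generator produces planar ensembles of fully developed pulsatile flow in
a straight rigid circular tube — the geometry in which the Womersley
solution is exact. Each waveform harmonic \(k\) contributes the annular
profile \(1 - J_0(\Lambda_k r/R)/J_0(\Lambda_k)\),
\(\Lambda_k = i^{3/2} \alpha_k\), rescaled so its cross-section-integrated
flow equals the waveform's \(k\)-th Fourier coefficient exactly; the steady
component is Poiseuille. \(J_0, J_1\) of complex argument are evaluated from
the contour-integral representation
\(J_n(z) = \frac{1}{2\pi}\int_0^{2\pi} e^{iz\sin\theta} e^{-in\theta}
\mathrm{d}\theta\) with the periodic trapezoid rule (spectrally accurate;
cross-checked in the tests against an independent power series and against
base R's real-argument Bessel functions).

Measurement noise is layered on reproducibly from a single integer seed:
i.i.d. Gaussian noise (default \(\sigma = 0.03\) m/s, chosen so the
10-cycle phase-average convergence variation stays below the 1.6%
acquisition criterion), a per-cycle multiplicative gain (SD 1%) emulating
inter-cycle variability, and optional spurious vectors (amplitude 5× the
maximum speed) whose locations are returned as ground truth for the outlier
filter. The default 200×150 grid is a 20× downscale of a 4000×3000 px
camera. Valve ringing on pressure signals is modelled as damped 20 Hz
sinusoid bursts (decay 0.05 s) at the start of systole and of diastole,
attenuating downstream; frequency and decay are package choices with only
their qualitative placement anchored in the physiology of a mechanical
valve.

What passing tests on these data do **not** show: curved-arch secondary
flows, true/false-lumen jet and recirculation structures, near-wall optical
refraction errors, correlated PIV noise, or wall compliance. The generator
validates the *analytics*, not the aortic flow physics.

## Numerical choices and problem sizes

* Integrator RK4, `dt` 1 ms snapped so a whole number of steps tiles the
  period; periodicity tolerance 1e-3; calibration tolerances 0.5 mmHg and
  0.5%.
* Pressure-signal smoothing delegates to Savitzky–Golay local polynomial
  fits (window 31 samples at 200 Hz, order 3 — both configurable; the
  acquisition described by the study does not state its parameters).
* The test suite runs the full default-grid ensemble (200×150, 18 phases,
  10 cycles) once for the phase-statistics checks and filters three frames
  for the outlier checks; chord-integration and spectral checks use reduced
  grids (e.g. 201 points across the lumen, 4001 radial quadrature nodes),
  sizes at which the closed-form comparisons above are already at their
  asymptotic accuracy.
* Ties/degenerate inputs: zero-flow specs return identically zero waveforms;
  `tol = 0` periodicity never converges (by definition); an all-masked
  neighbourhood leaves a vector unflagged; a zero computational profile
  makes \(\Delta\) undefined and raises an error.

## Known limitations

* The 0D junction cannot reproduce pressure-wave propagation or the internal
  pressure drop of a 3D domain; per-branch \(R_s\) is a first-order hook.
* Calibration matches mean flows and pressure extrema only — not waveform
  shapes per branch.
* The Womersley generator assumes fully developed axial flow; its in-plane
  transverse component is identically zero.
* No valve, inertance, compliant-wall or non-Newtonian rheology models.

## Worked example

```{r example, eval = FALSE}
sc <- patient_scenario()
w <- synthesise_inlet_waveform(sc$waveform_spec)
waveform_stats(w)$net_volume          # 107.6 mL
res <- calibrate(sc$targets, w)
res                                    # converged after 4 iterations,
                                       # 149.77/79.98 mmHg, target splits
fr <- flow_regime(w, 2 * sc$tube$radius, sc$fluid)
round(fr$Re_m)                         # 3472
```
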