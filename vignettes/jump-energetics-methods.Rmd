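---
title: "Methods: jump energetics on compliant cantilever platforms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jump energetics on compliant cantilever platforms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(springboard)
```

## The problem

Latch-mediated spring-actuated (LaMSA) jumpers such as grasshoppers load an
elastic element with slow muscle contraction, latch it, and release it in
tens of milliseconds. Because the release is far faster than neural
feedback, a substrate that gives way under the feet changes the jump in
ways the animal cannot correct mid-launch. `springboard` implements the
full analysis chain for experiments that probe this: animals jump from
marked positions along cantilever "diving boards" spanning substrate
stiffnesses from well below to far above the animal's own effective leg
stiffness, filmed at 1000 frames s^-1 and digitized as two-point
trajectories (a body landmark, and a platform point beneath the tarsus).

Because raw videos from such studies are rarely deposited, the package
pairs the analysis chain with a coupled jumper-platform simulator that
produces synthetic digitized recordings with known ground truth, so every
pipeline stage is testable end to end.

## The effective-spring model

The jumper is summarized by the stiffness of the linear spring that, when
released over the leg-extension stroke, would deliver the observed
take-off kinetic energy. Conservation of energy over the acceleration
distance $x$ gives

$$\tfrac12 k_g x^2 = \tfrac12 m_g v^2
  \quad\Longrightarrow\quad k_g = \frac{m_g v^2}{x^2},$$

with $m_g$ the body mass and $v$ the take-off speed. The stroke comes from
leg geometry: with femur and tibia of lengths $L_f$ and $L_t$ treated as
an isosceles pair (grasshopper femora and tibiae are similar lengths) and
the femur-tibia joint opening to angle $\alpha$ at take-off, the law of
cosines gives

$$x = \sqrt{L_f^2 + L_t^2 - 2 L_f L_t \cos\alpha}.$$

At the cohort means used throughout the worked examples ($m_g$ = 1.13 g,
$v$ = 1.44 m s^-1, $L_f = L_t$ = 15.6 mm, $\alpha$ = 113°) this yields
$x$ = 26.0 mm and $k_g \approx 3.46$ N m^-1. A per-animal mean of
individual estimates is slightly lower than the equation evaluated on the
means (ratio estimators are convex in their inputs); both live in the
3.4 N m^-1 range. Gravity is excluded from the energy bookkeeping
throughout: at these masses and stroke lengths it contributes 1-2% of the
budget, below the digitization noise floor.

Take-off speed is measured as the chord of the body-landmark displacement
over the 10 ms following the last frame of tarsi-platform contact,
divided by 0.010 s — the same two-position measurement a digitizer makes.
No gravity correction is applied over the window, for the same reason as
above. The chord slightly under-reads the instantaneous separation speed
because the last digitized contact frame precedes true separation by up
to one frame; on simulated rigid-platform jumps this bias is below 0.1%,
far under the ~1% noise contribution of 0.1 mm digitization error.

Two quantities are expressed per unit of jumping-muscle mass: kinetic
energy density and power density. Muscle mass is not observable from
video, so the default is a fixed fraction of body mass,
$f = \tfrac{v^2/2}{\mathrm{KED}}$ back-solved from the control-jump means
(1.44 m s^-1 and 24.79 J kg^-1), giving $f = 0.0418$ — 47.3 mg of
jumping muscle on a 1.13 g animal, consistent with the anatomical range
for locust metathoracic extensors. The fraction is configurable per
animal when dissection data exist. Body mass in place of muscle mass is
arithmetically inconsistent with energy densities in the tens of
J kg^-1 ($v^2/2 \approx 1$ J kg^-1), which is why the muscle-mass basis
is the default rather than an option.

## Platform calibration

Each marked line on a board is calibrated statically: a known mass hung
at the line, deflection read off, $k = mg/\delta$ with
$g = 9.81$ m s^-2. Multiple weights per line are combined by averaging
the per-weight estimates (the default; robust to one bad reading), with
least squares through the origin available via `method = "ls"` — the
better choice when small-deflection readings are noisy, as the test suite
quantifies. Each line is treated as one linear stiffness; large-deflection
nonlinearity of real wood is deliberately ignored, matching how such
calibrations are used.

Synthetic boards use the Euler-Bernoulli end-loaded cantilever,
$k = 3EI/L^3$ with $I = bh^3/12$, and lump the distributed overhang into
a tip mass by the first-mode Rayleigh coefficient $33/140$. The default
effective modulus (2.6 GPa) is set below handbook basswood so that a
61 cm board's ten lines span roughly 0.3x to 300x a 3.42 N m^-1 jumper —
the stiffness range the experimental design calls for; real boards are
always calibrated empirically, so the modulus only shapes synthetic
studies.

## The coupled jumper-platform simulator

Dynamics are reduced to the leg-thrust axis. With $s_g$ the jumper
position and $s_p$ the platform tip position along that axis, leg
extension $e = s_g - s_p$, and a pre-loaded linear leg spring of stroke
$x_{\mathrm{true}}$:

$$m_g \ddot s_g = F, \qquad
  m_p \ddot s_p = -k_p s_p - c\,\dot s_p - F, \qquad
  F = k_g\,(x_{\mathrm{true}} - e) \;\; \text{while } e < x_{\mathrm{true}}.$$

Contact is unilateral — legs push, never pull. For a linear leg spring the
contact force reaches zero exactly at full extension, so the two take-off
conditions (full extension; force non-positive) coincide and are located
by the integrator's root finder (`deSolve::lsodar`, tolerances 1e-10 /
1e-12). Flight is ballistic at the separation velocity, resolved at the
configured elevation; platform ring-down after separation follows the
damped-oscillator closed form. Setting $k_p = \infty$ (or
$m_p = \infty$) pins the platform: the rigid control case, which the
integrator reproduces against the closed form
$v = x\sqrt{k_g/m_g}$ to better than 1e-6, taking off at the quarter
period $\tfrac{\pi}{2}\sqrt{m_g/k_g}$ — 28.6 ms at the default
parameters, matching observed take-off times of ~28 ms.

The energy ledger tracks leg-spring potential energy, jumper kinetic
energy, platform elastic and kinetic energy, and viscous dissipation at
every sampled frame; with zero damping the total is conserved to ~1e-9
relative. Momentum is checked against the integrated wall impulse. The
platform damping ratio defaults to 0.02 (lightly damped wood); no
measured damping exists for these boards, and results are insensitive to
it (tested over 0-0.1).

### What the model does and does not predict

The simulator reproduces the study's qualitative regime structure: boards
less stiff than the jumper cost most of the take-off speed (the board
falls away faster than the leg can do work on the body), boards much
stiffer cost almost nothing, and a stiff, light board reaches maximum
displacement and recoils upward *before* the jumper separates — the
energy-recovery window. At the stiff-light reference configuration
(24 N m^-1, 0.25 g tip) the simulated board recoils while in contact and
the jumper leaves at 92.5% of rigid-platform speed at 28 ms.

One model property deserves emphasis. The pre-loaded linear leg spring
applies its full force as a step at release. A step load on a spring-mass
platform excites tip oscillation holding energy of order
$F_0^2/2k_p = (k_g/k_p)E_0$, which adiabatic decoupling cannot return to
the jumper: simulated relative speed is therefore ~0.95 at
$k_p = 10\,k_g$ and only exceeds 0.98 from $k_p \gtrsim 30\,k_g$,
regardless of platform mass or damping. Real animals show no measurable
speed loss anywhere above $k_g$; their extensor linkage develops ground
force progressively over several milliseconds (poor mechanical advantage
at full flexion), which suppresses the ring. This is the main known
discrepancy between the lumped model and the animal, and it is documented
rather than patched because the linear-spring force law is the model —
replacing it with a measured force profile is future work.

## Synthetic studies

`synthetic_study()` emulates the experimental design: each animal jumps
3 controls from the rigid surface, 10 lines of platform A (61 cm,
6.34 g) and 2 lines of platform B (12.4 cm, 1.01 g), at 1000 fps with
0.1 mm Gaussian noise per coordinate. Animal-level parameters are drawn
around the cohort means with standard deviations recovered from the
reported cohort dispersion (s.e.m. × √40): body mass 1.13 ± 0.25 g,
tibia 15.6 ± 1.2 mm, take-off angle 113 ± 12.6°, elevation 43.5 ± 5°
(bounded to the observed 19-69° range), leg stiffness 3.42 ± 0.70
N m^-1. Jump-to-jump variation enters through a 2% lognormal stroke
jitter plus the digitization noise.

What this generator does **not** emulate: digitizer subjectivity in
picking frames and landmarks, landmark-to-centre-of-mass offset (the
recorded landmark is used uncorrected, as in the source protocol),
out-of-plane motion, nonlinear and distributed beam dynamics (one lumped
mode only), resonance-frequency effects, behavioural adaptation by the
animal, and the progressive force onset discussed above. Green tests
therefore certify the *pipeline arithmetic* and the *model's* regime
structure, not biological fidelity of every coefficient.

## Normalization and statistics

Every experimental jump is normalized to the same animal's control means:
ratios for all variables except elevation, which uses differences —
elevation is a polar quantity, so proportions are not meaningful.
Platform displacement is excluded from normalization: its control value
is identically zero on the rigid surface, so a ratio is undefined. Jumps
are split into a compliant regime ($k_p$ below the across-animal mean
control $k_g$) and a stiff regime (at or above it; exact ties — a
measure-zero event — go to stiff, since a strict-inequality split leaves
them undefined).

At each platform line, each normalized variable is tested against its
null (1.0, or 0 for elevation differences) with a two-sided one-sample
t-test; a Shapiro-Wilk check at α = 0.05 triggers a supplementary
Wilcoxon signed-rank report. Across lines, linear mixed models with a
per-animal random intercept (animals are sampled repeatedly) test
platform stiffness as a covariate; in the stiff regime, platform type
enters as a fixed factor with an initial stiffness-by-type interaction
that is dropped and the model refitted when non-significant (p ≥ 0.05).
Inference uses Satterthwaite denominator degrees of freedom
(`lmerTest`), the family indicated by fractional reported dfs in this
literature. No multiple-testing correction is applied across variables;
none is standard in this design and the per-variable reports keep the
raw p-values inspectable. Model correctness is verified by
generate-then-refit: data built with a known stiffness slope and
per-animal intercepts are refitted and the slope interval checked for
coverage (≥ 90/100 null datasets in the acceptance suite).

## Numerical choices and problem sizes

Integrator: `lsodar`, rtol 1e-10, atol 1e-12, root function on
$x_{\mathrm{true}} - e$; dense output at the camera frame rate with the
analytic ring-down appended after separation. The 10 ms velocity window
must be an integer frame count — at 1000 fps, exactly 10 frames — and
frame gaps at required frames are hard errors, never interpolated.
Degenerate inputs (zero take-off interval, zero displacement, zero
control means, ties at the regime boundary) are either errors or
explicitly-defined cases as described above.

The shipped test-and-analysis problem sizes — cohorts of 3-8 animals,
50-jump recovery batches, 100-seed coverage loops, 20-40-point sweeps —
were chosen so the whole suite exercises every stage in seconds while
keeping Monte-Carlo standard errors well under the tolerances being
asserted; all are arguments, so larger runs only cost time.

## Known limitations

* The effective stiffness is a summary, not a mechanism: it folds linkage
  geometry, semi-lunar process and apodeme elasticity into one number.
* The simulator's step force onset overstates energy lost to moderately
  stiff boards (discussed above).
* Calibration of the stiffest lines from static deflection is
  ill-conditioned (sub-millimetre deflections); the least-squares
  combiner mitigates but cannot remove this.
* No resonance-frequency analysis is attempted; the single lumped
  platform mode cannot represent it.
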