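# springboard

Jump energetics of latch-mediated spring-actuated (LaMSA) jumpers on
compliant substrates.

Grasshoppers and other LaMSA jumpers release a pre-loaded elastic element
in tens of milliseconds — too fast for neural feedback to compensate when
the substrate gives way underfoot. Experiments probing this film animals
jumping from marked lines along cantilever "diving boards" whose stiffness
spans from well below to hundreds of times the animal's own leg stiffness,
digitize two landmarks per video (a body point and a platform point under
the tarsus), and ask how substrate stiffness and mass reshape the jump.
`springboard` is the full analysis chain for such experiments, plus a
coupled jumper–platform simulator that generates synthetic digitized
recordings with ground truth so every stage is verifiable without raw
videos.

## The model at the core

The jumper is summarized by the stiffness of the linear spring that would
deliver the observed take-off kinetic energy over the leg-extension
stroke. Conservation of energy gives

    k_g = m_g v² / x²,

and the stroke follows from leg geometry by the law of cosines,

    x = √(L_f² + L_t² − 2 L_f L_t cos α),

with femur and tibia lengths L_f, L_t and femur–tibia joint angle α at
take-off. Take-off speed v is the 10 ms two-position chord after the last
frame of tarsi–platform contact. Per-jump records also include elevation
relative to the deformed platform plane, platform displacement, mean
acceleration, kinetic energy and power with their per-muscle-mass
densities, and the jumper-over-platform stiffness and mass ratios
(k_g/k_p, m_g/m_p) that govern whether jump energy is lost to the
substrate or recovered from its recoil. Experimental jumps are normalized
to each animal's own control means (ratios; differences for elevation),
split into compliant/stiff regimes at the cohort mean k_g, and analysed
with one-sample tests per platform line plus random-intercept mixed
models with platform stiffness as covariate.

The simulator integrates jumper and lumped platform tip along the thrust
axis with a unilateral pre-loaded leg spring, locates take-off by root
finding, tracks a full energy ledger, and renders noisy 1000 fps
two-point recordings in the same format the readers parse.

## Worked example

```r
library(springboard)

# Effective stiffness at the cohort means: 1.13 g animal, 1.44 m/s
# take-off, 15.6 mm leg segments opening to 113 degrees
morph <- morphometrics(body_mass = 1.13e-3, tibia_length = 15.6e-3,
                       takeoff_angle_deg = 113)
x <- acceleration_distance(morph)        # 0.02602 m  (26.02 mm stroke)
grasshopper_stiffness(1.13e-3, 1.44, x)  # 3.462 N/m
spring_launch_speed(3.39, 1.13e-3, x)    # 1.425 m/s back from 3.39 N/m

# Simulate a jump from a stiff, light board (24 N/m, 0.25 g tip)
res <- simulate_jump(sim_config(k_p = 24, m_p_eff = 2.5e-4, noise_sd = 0))
res
#> Simulated jump: take-off at 0.0281 s, speed 1.3242 m/s
#>   max platform displacement 0.006059 m at 0.0090 s; recoil before take-off: TRUE
```

The board reaches maximum displacement and springs back while the jumper
is still in contact — the configuration in which substrate energy can be
recovered — and the jumper leaves at 92.5% of its rigid-surface speed
(1.4313 m/s) at the characteristic ~28 ms take-off time.

The numbered scripts under `analysis/` run the whole workflow as a
narrative — `01` calibrates platform stiffness profiles from
load–deflection tables, `02` simulates and extracts a cohort, `03`
estimates effective stiffness, `04` normalizes and fits the regime
statistics, `05` sweeps the stiffness–mass plane — writing their tables
under `results/`. A single-call orchestrator is also available:

```r
run_pipeline(list(output_dir = "results/run1", seed = 11, n_animals = 4))
```

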