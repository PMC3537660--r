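# gobykin

Landmark-based cranial kinematics of feeding and climbing in stream gobies.

Waterfall-climbing gobies of the genus *Sicyopterus* use the mouth for two
cyclic behaviors: scraping benthic diatoms during feeding, and attaching an
oral sucker to rock while "inching" up waterfalls. Comparing the kinematics
of these behaviors — and of scraping against suction feeding in related
species — asks whether they are variants of one motor program. `gobykin`
implements that analysis as a tested R pipeline for anyone working with
digitized landmark trajectories of cyclic cranial motion:

1. **Landmark I/O** — long-format CSV of 2-D landmarks from synchronized
   ventral (points 1–14) and lateral (points 15–23) high-speed video views,
   with validation, per-view calibration, interior-gap interpolation, and
   registration of every frame to the stationary pectoral-fin midpoint
   (which removes whole-body advance during climbing).
2. **Kinematic variables** — eight per-cycle traces: cranial elevation
   angle, premaxillary protrusion angle and length, hyoid retraction angle
   and length, mandibular retraction length, opercular expansion length, and
   a geometric oral-sucker-area model (circular sector at the upper lip +
   two triangles, bilaterally symmetric: `X = θ|AB|²/2`, `Y = |AB×AC|/2`,
   `Z = |(D−B)×(C−B)|/2`). Angles in degrees, lengths in body lengths (BL),
   areas in BL².
3. **Percent-cycle normalization** — a quintic smoothing spline per trace
   (penalty weight by generalized cross-validation), resampled at 101 evenly
   spaced increments of cycle duration, aggregated into group mean ± s.e.m.
   profiles.
4. **Comparison statistics** — Mann–Whitney *U* / Kruskal–Wallis tests on
   per-cycle peak values, and divergence angles
   `θ = arccos(u·v / ‖u‖‖v‖)` between 101-dimensional mean-profile vectors
   (0° = identical shape, 90° = uncorrelated).
5. **Synthetic generator** — parameterized feeding/climbing cycles with
   analytic ground truth for every variable, defaulting to the published
   behavior regimes (0.141 s at 500 Hz vs 0.313 s at 200 Hz; amplitudes at
   the published mean maxima; 96 + 36 cycle study design).

## Worked example

Simulate the default two-behavior study and analyze it:

```r
library(gobykin)
sim <- tempfile(); out <- tempfile()
cmd_simulate(sim, seed = 1)                                  # 132 cycles
res <- cmd_analyze(file.path(sim, "landmarks.csv"), out, seed = 1)

res$report$summary_table
#>   group_a group_b mean_angle_deg sem_angle_deg n_variables <5deg <10deg
#>  climbing feeding            1.8         0.698           8     7      8
```

The mean divergence angle of 1.8° says the two simulated behaviors share
profile *shapes* (they use the same half-sine waveform family), even though
their peak *values* differ significantly:

```r
subset(res$report$peak_table, variable == "premaxillary_protrusion_length")
#>                        variable    group mean_max  sem_max  n           test statistic  p_value
#>  premaxillary_protrusion_length climbing   0.0350 0.000508 36 Mann-Whitney U      2570 1.71e-05
#>  premaxillary_protrusion_length  feeding   0.0317 0.000413 96 Mann-Whitney U      2570 1.71e-05
```

Here the climbing protrusion peak (0.035 BL) exceeds feeding (0.032 BL) with
p ≈ 2×10⁻⁵, yet the profiles diverge by only 0.6° — exactly the
"different amplitude, same shape" signature the divergence angle is built to
detect. Summaries of the published comparison tables shipped with the
package work the same way:

```r
ds <- divergence_summary(reference_feeding_climbing()$divergence_angle_deg)
round(c(mean = ds$mean, sem = ds$sem), 1)
#> mean  sem
#>  9.0  2.4
ds$counts_below
#> <5deg <10deg
#>     4      6
```

A thin command-line wrapper is installed at
`inst/scripts/gobykin.R` (`simulate` / `analyze` / `compare` subcommands).

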