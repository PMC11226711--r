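# uctborn

2-D acoustic inverse scattering for circular-array ultrasound tomography:
simulate scattered-pressure measurements of disk phantoms with a
method-of-moments Helmholtz forward model, then reconstruct the sound-speed
contrast map with the distorted Born iterative (DBI) method under five
iteration schedules — plain DBI, resolution-turning (RT-DBI), frequency
hopping (FH-DBI), and the two combined RT-FH schedules.

The package is aimed at researchers studying Born-type inverse-scattering
algorithms: every stage (phantom, geometry, forward operators, Tikhonov
update, schedule orchestration, error metric) is an exported, individually
tested function, and whole experiments are driven by one flat configuration
object.

## The method in brief

An inclusion with sound speed `c1(z)` in a background `c0` is described by
the frequency-independent contrast

```
chi(z) = 1/c1(z)^2 - 1/c0^2,        G(z) = omega^2 * chi(z)
```

Transmitters on a circle fire zero-order Bessel beams
`J0(k0 |r - r_t|)`; receivers on a second circle record the scattered
pressure `B D(G) Gamma`, where `B`, `C` are discretized Green's operators
built from the 2-D outgoing-wave kernel `-(i/4) H0^(1)(k d)` and the total
field `Gamma` follows the first-order Born recursion
`(I + C D(G)) Gamma_inc` (an exact solver is available via
`field_mode = "full"`). Each DBI iteration refreshes the fields around the
current estimate, forms the residual against the measured data, and solves
the ridge problem

```
min || residual - M dG ||^2 + gamma ||dG||^2 ,
M = B D(Gamma) + B D(G) C D(Gamma_inc),
gamma = 0.3 * sigma0^2 * ||residual|| / ||measured||
```

with `sigma0` the leading singular value of `M`. Resolution turning runs
the first iteration(s) on a half-resolution grid and nearest-neighbor
upsamples the estimate; frequency hopping runs the first iteration(s) at
the lower frequency. Reconstruction quality is the relative residual error
(RRE) `sum|C - Chat| / sum|C|` against the ideal map.

## Worked example

```r
library(uctborn)

cfg <- scenario_config()          # the default single-disk benchmark:
phase_shift(cfg) / pi             # 8.751 -- two-way excess phase, in pi units

phantom <- make_single_disk(build_grid(cfg, cfg$N2), cfg$disk_diameter,
                            cfg$contrast_pct, cfg$c0)
report <- run_scheme(cfg, phantom, schedule("rt_fh_dbi_2"))
round(report$trace, 4)
#> [1] 0.6323 0.2349 0.1503 0.1027 0.0785 0.0689 0.0665 0.0660
```

The trace is the RRE after each of the 8 iterations: one coarse-grid
low-frequency iteration (0.632), one fine-grid low-frequency iteration,
then six high-frequency iterations ending at 0.066 — i.e. the reconstructed
contrast map differs from the ideal 30% disk by about 7% in total absolute
contrast, with 10% measurement noise. Comparing all schedules on shared
data:

```r
tab <- compare_schemes(cfg, phantom,
                       list(schedule("dbi"), schedule("rt_dbi"),
                            schedule("fh_dbi"), schedule("rt_fh_dbi_2")),
                       seeds = 1:10)
aggregate(final_rre ~ scheme, tab, median)
#>        scheme final_rre
#> 1         dbi    0.2441
#> 2      fh_dbi    0.0636
#> 3      rt_dbi    0.0910
#> 4 rt_fh_dbi_2    0.0665
```

Plain DBI stalls around 0.24 at this contrast; every accelerated schedule
reaches the 0.06–0.09 range — a ~73% error reduction for the combined
schedule.

## Command line

A thin CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "uctborn.R", package = "uctborn"))')
Rscript $CLI simulate    --config scenario.yaml --out runs/
Rscript $CLI reconstruct --config scenario.yaml --out runs/ --scheme rt_fh_dbi_2 -v
Rscript $CLI compare     --config scenario.yaml --out runs/ \
                         --scheme dbi,fh_dbi,rt_fh_dbi_2 --seeds 1,2,3
```

Scenario files are flat YAML with the `scenario_config()` field names
(meters, Hz, fractions) plus optional schedule keys; all outputs are plain
CSV/JSON with a config-hash manifest.

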