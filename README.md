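# forkRPA

Force-regulated kinetics of single-stranded DNA binding proteins at a DNA
fork, for single-molecule biophysicists analysing magnetic-tweezers
unzipping experiments.

Replication protein A (RPA) binds ssDNA tightly, yet at a replication-fork
boundary it is extremely dynamic: above a threshold force it opens a DNA
hairpin by trapping thermal duplex fluctuations with a few-bp "toehold"
microdomain, and at low force the rezipping fork displaces it at hundreds
of bp/s. This package implements the full analysis pipeline for such
experiments -- and a stochastic simulator that serves as its test
substrate -- so every stage can be validated against known ground truth.

## The model

The net fork-opening velocity (bp/s, opening positive) is the difference of
two Arrhenius terms in which the applied force `F` tilts the barrier to the
transition state:

    v_net(F) = k_on C exp[ (c(F) F − c_unz F_unz) Δz_on / kBT ]
             − k_off  exp[ −c(F) F Δz_off / kBT ]

* `k_on` (bp/s/nM) — association pre-factor at the unzipping force `F_unz`;
* `k_off` (bp/s) — dissociation pre-factor at zero force;
* `Δz_on`, `Δz_off` (bp) — toehold sizes for binding and displacement;
* `c(F)` (nm/bp) — polymer-elasticity conversion between opened base pairs
  and measured extension: `2·x_ss(F)` for a hairpin (extensible
  freely-jointed chain), `x_ss − x_ds` for a flapped duplex (minus an
  extensible worm-like chain).

From the root `F_equi` of `v_net` the binding free energy per heterotrimer
follows from the force balance
`ΔG_bind = (c_unz F_unz − c_equi F_equi) · footprint/2`. Step detection
(a recursive Kerssemakers-style chi-square fitter) measures the footprint
(~22–24 bp) directly from stepping traces, and the friction law
`F_unz − F = ζ·v` with the Einstein relation `D = kBT/ζ` quantifies
protein sliding ahead of a rezipping fork.

## Worked example

```r
library(forkRPA)

## Reference kinetics: yeast RPA, 20 nM, 3 mM Mg2+
p <- rpa_condition("yRPA", 3)
net_rate(c(4.5, 13.2, 15.7), p)
#> [1] -94.7  -0.6  16.7        # bp/s: rapid rezipping at 4.5 pN,
#>                              # near balance at 13.2, opening at 15.7
binding_energetics(p)
#> F_equi: 13.42 pN
#> dG_bp:  17.71 pN nm per bp (10.66 kJ/mol)
#> dG_bind: 38.4 kJ/mol per heterotrimer (footprint 23 bp)

## Simulate a resolved-step association trace (12 pN, 2 nM, 300 Hz)
pk <- kinetic_parameters(5.45, 0.25, 0, 0, 18.2, concentration = 2,
                         footprint = 21.8)
trace <- simulate_fork_trace(simulation_config(pk, seed = 101,
  force_schedule = data.frame(duration = 70, force = 12)))
find_steps(trace)
#> Step fit: 24 accepted steps (median |size| 19.1 nm / 21.8 bp)

## Footprint from ten such traces
fits <- lapply(1:10, function(i) find_steps(simulate_fork_trace(
  simulation_config(pk, seed = 100 + i,
    force_schedule = data.frame(duration = 70, force = 12)))))
fit_step_histogram(fits)
#> opening steps: mean 22.1 bp, sd 2.6 bp (n = 191 of 212 pooled)

## Recover the kinetic parameters from noisy rate-vs-force data
forces <- c(seq(11.5, 16, length.out = 15), seq(2, 7, length.out = 15))
d <- simulate_rate_dataset(forces, p, noise_cv = 0.1, seed = 5)
fit_eq1(d, F_unz = 18.2, concentration = 20, seed = 5)
#> Two-term Arrhenius fit (F_unz fixed at 18.2 pN)
#>   k_on [bp/s/nM]  7.684  [5.87, 9.46]
#>   k_off [bp/s]    241.1  [224, 255]
#>   dz_on [bp]      3.152  [2.86, 3.4]
#>   dz_off [bp]     1.588  [1.53, 1.64]
#>   F_equi (derived): 13.42 pN; weighted RSS 24.86
```

The fitted mean of 22.1 bp estimates the binding footprint set to 21.8 bp
in the generator; the Arrhenius fit recovers the generating parameters
(9.0, 239, 3.3, 1.6) within its bootstrap intervals. The equilibrium force
of 13.4 pN sits ~1 pN above the originally reported 12.4 pN because the
package's closed-form elasticity stands in for the instrument's measured
conversion curve (see the methods vignette, `vignettes/fork-kinetics.Rmd`).

## Pipeline / CLI

Configuration is a flat JSON document; traces, step tables and rate tables
are plain TSV. From R: `cmd_simulate()`, `cmd_analyze()`,
`cmd_energetics()`. From a shell:

```sh
Rscript -e 'forkRPA::fork_cli()' simulate --config cfg.json
Rscript -e 'forkRPA::fork_cli()' analyze out/trace_001.tsv --config cfg.json --out result.json
```

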