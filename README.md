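# amylokin

Mechanistic analysis of amyloid self-assembly kinetics and its inhibition
by small molecules.

Amyloid formation by peptides such as IAPP (amylin) is a nucleated
polymerization: fibrils nucleate from monomers, elongate at both ends, and
multiply through secondary processes (fragmentation, or secondary
nucleation on fibril surfaces). When a screening campaign finds a compound
that slows aggregation in a ThT plate assay, the next question is
mechanistic: does it suppress primary nucleation, secondary nucleation, or
elongation? `amylokin` answers that question from ordinary plate-reader
dose series, and implements the surrounding biophysical analyses used to
characterize hits. It is aimed at groups running ThT screens and kinetic
assays who want the model-based analysis as reusable, tested code.

## The models at the core

For fibril number `P` and mass `M` with free monomer `m = m0 - M`:

    dP/dt = kn * m^nc + { kf * M  |  k2 * m^n2 * M  |  k2 * m^n2 / (1 + (m/K2)^n2) * M }
    dM/dt = 2 * kplus * m * P

Curve shapes are governed by two macroscopic rates, `lambda =
sqrt(2 nu_+ nu_n / m0)` (primary pathway) and `kappa = sqrt(2 nu_+ nu_2)`
(secondary pathway), where `nu_n = kn m0^nc`, `nu_+ = kplus m0` and
`nu_2` is the secondary rate law at `m0`. Closed forms:

* no secondary process (exact):
  `M/m0 = 1 - sech^(2/nc)( sqrt(nc/2) * lambda * t )`
* with a secondary pathway:
  `M/m0 = 1 - [ 1 + theta (lambda/kappa)^2 (cosh(kappa t) - 1) ]^(-1/theta)`,
  where `theta` encodes how monomer depletion shuts the secondary pathway
  down (~0.32 for fragmentation or saturated secondary nucleation).

Both are validated in the test suite against numerical integration of the
moment equations (`moment_ode_oracle()`). Scenario classification fits a
whole dose series globally, letting exactly one process's rate vary with
inhibitor concentration (scaling `lambda` and/or `kappa` by the square
root of the fitted factor), and compares the three scenarios by AICc.

## Worked example

Simulate a primary-nucleation inhibitor dose series (one process scaled
per dose, ground truth recorded), classify the mechanism, and extract the
per-dose macroscopic rates:

```r
library(amylokin)

series <- gen_dose_series(seed = 42, process = "primary",
                          factors = c(1, 0.7, 0.4, 0.2, 0.1))
cmp <- compare_scenarios(series, seed = 1)
print(cmp)
#> Scenario comparison (best first):
#>         scenario       rss k_params      aicc delta_aicc        r2
#>     primary_only 0.2899568        6 -26647.34     0.0000 0.9994453
#>  elongation_only 0.4085167        6 -25654.93   992.4078 0.9992184
#>   secondary_only 0.4813251        6 -25180.12  1467.2172 0.9990791

extract_macroscopic(series, seed = 1)[, 1:6]
#>      label conc     lambda    lambda_se    kappa   kappa_se
#> 1   dose_0    0 0.03924411 0.0007094711 2.012717 0.01128179
#> 2  dose_25   25 0.03377336 0.0006505125 1.993588 0.01141509
#> 3  dose_50   50 0.02480508 0.0005110281 2.012175 0.01127055
#> 4  dose_75   75 0.01834870 0.0004074143 1.984502 0.01111830
#> 5 dose_100  100 0.01246815 0.0003096670 2.007066 0.01143822
```

The true scenario (`primary_only`) wins by ~1000 AICc units; `lambda`
falls with dose exactly as the square-root scaling law predicts
(0.04 → 0.0126 at a factor 0.1) while `kappa` stays at its unperturbed
2 h⁻¹. Screening works the same way: a compound that slows both pathways
1.5-fold reads back as

```r
plate <- gen_tht_plate(seed = 1, conditions = list(
  ctrl = list(rates = macro_rates(0.04, 2), n_replicates = 12,
              role = "control_no_compound"),
  inh  = list(rates = macro_rates(0.04 / 1.5, 2 / 1.5), n_replicates = 12)))
call_activity(normalize_plate(blank_subtract(plate)), "inh", "ctrl")
#> Activity call 'inh': fold-change = 1.504 +- 0.003, p = 3.66e-05 -> inhibitor
```

a half-time fold-change of 1.5 beyond both the 1.25× threshold and the
rank-test significance bar.

## The analysis workflow

Numbered drivers under `analysis/` run the full study pipeline on
simulated data and write tables under `results/`:

    01_simulate.R        inputs: plate, dose series, monomer series, traces
    02_screen.R          activity calls (fold-change + Mann-Whitney)
    03_mechanism.R       assembly-mechanism ranking by AICc
    04_dose_scenarios.R  inhibitor scenario classification
    05_rate_extraction.R per-dose lambda/kappa with fitting errors
    06_biophysics.R      TDA, SPR, NMR CSP, copelleting, constants
    07_capflex.R         spike counts and free-compound plateaus

Run them in order from the repository root:
`for f in analysis/0*.R; do Rscript "$f"; done`

See `vignettes/amyloid-inhibition-kinetics.Rmd` for the models, the
fitting and screening conventions, and what the synthetic generators do
and do not emulate.

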