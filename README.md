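# micellr

Micellization and cyclodextrin complexation analysis from fluorescence
titrations.

## The problem

Amphiphilic molecules -- free fatty acids such as linoleic (LA) and
docosahexaenoic (DHA) acid, and their resveratrol esters (lipophenols) --
form micelles above a critical micelle concentration (CMC). A hydrophobic
fluorescent probe reports micelle onset: relative fluorescence versus
amphiphile concentration is flat below the CMC and rises steeply above it.
Hydroxypropyl-beta-cyclodextrin (HP-beta-CD) sequesters monomers in its
cavity and shifts the apparent CMC upward; the shape of the *micellar
diagram* (apparent CMC versus CD concentration) encodes the host-guest
equilibrium:

* 1:1 complexation: CMC = CMC0 (1 + Kc [CD]) -- linear diagram;
* sequential 1:2 complexation: CMC = CMC0 (1 + K1 [CD] + K1 K2 [CD]^2) --
  quadratic diagram,

with CMC0 the zero-CD value, Kc / K1 / K2 association constants in 1/M and
[CD] the added cyclodextrin (M). `micellr` is for experimentalists who
have such titrations and want defensible constants out of them: it
implements two-segment breakpoint regression for the CMC, both forward
models, a calibrated stoichiometry-selection test, residual-bootstrap
uncertainty, and the ligand-efficiency metric (binding energy per heavy
atom) used to compare guests of different size. A synthetic-data module
generates titrations and diagrams with known ground truth so the whole
chain is testable end to end.

## Worked example

Simulate titrations of a 1:1 guest (CMC0 = 6 uM, Kc = 720 1/M) at five CD
levels with 1% fluorescence noise, estimate the per-level CMCs, and fit
the diagram:

```r
library(micellr)

truth <- binding_params("1:1", cmc0 = 6, kc = 720)
cds <- c(0, 1, 2.5, 5, 10) / 1000   # mol/L
curves <- lapply(seq_along(cds), function(i)
  simulate_titration(truth, cd_conc = cds[i], post_slope = 8, noise_sd = 1,
                     seed = 100 + i, guest = "Resv-4'-LA"))
diagram <- build_diagram(estimate_cmc_batch(curves))
fit <- select_stoichiometry(diagram, alpha = 0.05)
fit <- bootstrap_binding(fit, diagram, n_boot = 1000, seed = 1)
print(diagram)
print(fit)
#> <micellar_diagram> Resv-4'-LA, 5 CD levels (0-10 mM), CMC0 = 5.911 uM
#> <binding_fit 1:1> CMC0 = 5.911 uM (measured), kc = 733.3 1/M, R^2 = 1.0000
#>   kc 95% CI: [733.113, 734.288] (B = 1000)
#>   selection: one-sided curvature p = 0.7101 (alpha = 0.05)
```

Reading the output: the measured zero-CD anchor came out at 5.91 uM (true
6), the curvature test sees no evidence for a second binding step
(p = 0.71), so the 1:1 model is selected and its constant lands within 2%
of the generating Kc = 720 1/M. The percentile interval reflects only the
four residuals of this small diagram -- treat it as a scale, not an exact
coverage statement at n = 5.

Ligand efficiency from reported MM-GBSA energies:

```r
g <- guest_fixtures()
rank_guests(g, metric = "le")[, c("name", "heavy_atoms", "le_rounded")]
#> # A tibble: 6 × 3
#>   name        heavy_atoms le_rounded
#>   <chr>             <int>      <dbl>
#> 1 resveratrol          17      -2.68
#> 2 DPHT                 18      -2.63
#> 3 LA                   20      -2.36
#> 4 DHA                  24      -2.13
#> 5 Resv-4'-LA           36      -1.79
#> 6 Resv-4'-DHA          40      -1.46
```

(Full three-decimal values live in the `le_rounded` column: -2.362,
-2.127, -1.788, -1.459 for LA, DHA and the two esters; the tibble print
method abbreviates.)

Raw energies rank the big lipophenol esters first; per-heavy-atom
normalisation reverses that, ranking the compact free fatty acids above
them -- the same reversal the measured constants show.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end on synthetic
data and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_titrations.R   # titrations per guest & CD level
Rscript analysis/02_estimate_cmc.R          # breakpoint CMCs + diagrams
Rscript analysis/03_fit_binding.R           # stoichiometry + constants + CIs
Rscript analysis/04_ligand_efficiency.R     # LE table and rankings
Rscript analysis/05_condition_report.R      # condition grid + fold changes
```

Every script accepts `--seed <int>`. Note that stage 3 operates at
realistic noise: at alpha = 0.05 roughly one truly-linear diagram in
twenty is called 1:2, and K2 in the weak sequential regime is
order-of-magnitude only -- the per-guest JSON reports carry both models'
diagnostics for auditing such calls (see the methods vignette,
`vignettes/micellar-complexation.Rmd`).

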