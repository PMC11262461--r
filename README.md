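# spatccc

Cell–cell communication (CCC) inference from spatially resolved
transcriptomics (SRT) with Tweedie generalized additive models.

Cells signal through ligand–receptor (LR) binding, and most of that
signaling is short-range. Given expression with spatial coordinates —
single-cell resolution or multi-cell spots — `spatccc` estimates, for each
LR pair and each ordered pair of cell types, a **signed communication
strength**: is proximity of sender type g1 to receiver type g2 associated
with higher (or lower) LR activity? It is aimed at analysts of seqFISH+/
STARmap-style single-cell SRT and 10X Visium / Slide-seq-style spot data
(with an upstream deconvolution step supplying per-spot cell-type
proportions).

## The model

For every ordered unit pair (i, j) within a communication radius `dmax`,
the communication score of LR pair k is `C_ijk = L_ik * R_jk` (ligand score
at the sender times receptor score at the receiver), modelled as

```
log E(C_ijk) = beta0_k + exp(-rho * D_ij) * sum_{g1,g2} beta_{g1,g2,k} * M_{i,g1} * M_{j,g2}
               + nuL_i + nuR_j
```

with Euclidean distance `D_ij`, cell-type composition `M` (one-hot for
single-cell data), ridge-penalized sender/receiver random effects bucketed
on a spatial grid, and a Tweedie (compound Poisson–Gamma, power `1 < p < 2`)
response that accommodates the many exact zeros among scores.
`beta_{g1,g2,k}` is the directed strength from sender type g1 to receiver
type g2 — distinct from `beta_{g2,g1,k}`. Fitting is penalized IRLS;
smoothing is selected by GCV, the Tweedie power by profile likelihood over a
grid, the decay rate `rho` by AIC over a candidate set; each coefficient
gets a Wald test and Benjamini–Hochberg FDR adjustment across the full
result table. See the vignette (`vignettes/tweedie-ccc-model.Rmd`) for the
full account.

## Worked example

Simulate a single-cell-resolution dataset with one planted signal —
communication strength 2 from type T1 to type T2 for the pair LIG1→REC1,
decay rate 0.5 — then run the pipeline:

```r
library(spatccc)

b <- matrix(0, 3, 3); b[1, 2] <- 2
sim <- simulate_ccc(n_units = 250, n_types = 3, beta = b, rho = 0.5, seed = 7)

res <- infer_ccc(sim$dataset, sim$lr_db, dmax = 1.3,
                 config = ccc_config(rho_candidates = c(0, 0.5, 2)))
dplyr::arrange(res, p_value)
#> # A tibble: 9 × 14
#>   ligand receptor pathway sender_type receiver_type estimate std_error z_value
#> 1 LIG1   REC1     SIM     T1          T2               1.46     0.0374    39.0
#> 2 LIG1   REC1     SIM     T2          T2               0.714    0.0382    18.7
#> 3 LIG1   REC1     SIM     T3          T2               0.731    0.0415    17.6
#> 4 LIG1   REC1     SIM     T1          T1               0.535    0.0357    15.0
#> # ... p_value, p_adjusted, rho_selected, power_p, aic, converged
```

The planted T1→T2 coefficient is by far the strongest (estimate 1.46,
z = 39); the smaller positive rows are spillover from the generator's
rank-one expression construction (a unit's ligand/receptor level is built
from its marginal score profile, so neighbors of hot units warm up too —
see the vignette). Significant cells at FDR 0.1, sender rows × receiver
columns:

```r
round(ccc_matrix(res, "LIG1->REC1", threshold = 0.1), 3)
#>       receiver
#> sender    T1    T2    T3
#>     T1 0.535 1.459 0.566
#>     T2    NA 0.714    NA
#>     T3    NA 0.731    NA
```

`plot_ccc_heatmap(res, "LIG1->REC1")` and
`plot_ccc_network(res, "LIG1->REC1")` draw the masked heatmap and the
directed network (solid = positive, dashed = negative, width ∝ |estimate|);
`infer_ccc_pathway()` pools member pairs of a pathway
(`C_ij = sum_k C_ijk`) and fits the pooled response the same way.

A command-line interface wrapping the same functions ships with the
package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "spatccc", package = "spatccc"))')
$CLI simulate --out sim --seed 3 --n-units 200
$CLI run --expr sim/expression.mtx --coords sim/coordinates.csv \
     --proportions sim/proportions.csv --lr-db sim/lr_database.csv \
     --dmax 1.3 --out results
$CLI plot --results results/results.tsv --target "LIG1->REC1" --out figs
```

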