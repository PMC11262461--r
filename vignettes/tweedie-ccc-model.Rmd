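---
title: "Inferring cell-cell communication from spatial transcriptomics with Tweedie GAMs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring cell-cell communication from spatial transcriptomics with Tweedie GAMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatccc)
```

## The problem

Ligand-receptor (LR) signaling happens over limited physical distances, so
expression data with spatial coordinates — spatially resolved transcriptomics
(SRT), whether single-cell resolution or multi-cell spots — carry information
that dissociated single-cell data lack: which pairs of cells were actually
close enough to talk. `spatccc` asks, for each LR pair and each ordered pair
of cell types (sender type, receiver type), whether physical proximity of
those types is associated with elevated LR activity, and in which direction.

## The model

For every ordered pair of units (spots or cells) $(i, j)$ within a maximum
communication radius $d_{\max}$, the communication score for LR pair $k$ is
the product of ligand availability at the sender and receptor availability at
the receiver, $C_{ij}^k = L_i^k \times R_j^k$. Its expectation is modelled on
the log scale as

$$\log E(C_{ij}^k) \;=\; \beta_0^k \;+\; e^{-\rho D_{ij}}
\sum_{g_1, g_2} \beta_{g_1 g_2}^k \, M_{i g_1} M_{j g_2}
\;+\; \nu^L_i + \nu^R_j,$$

where $D_{ij}$ is the Euclidean distance, $M_{ig}$ the proportion of cell
type $g$ at unit $i$ (a one-hot indicator for single-cell data), and
$\beta_{g_1 g_2}^k$ the directed communication strength from sender type
$g_1$ to receiver type $g_2$ — distinct from $\beta_{g_2 g_1}^k$. The decay
rate $\rho \ge 0$ encodes that communication weakens with distance;
$\nu^L_i$ and $\nu^R_j$ are normal sender and receiver random effects
absorbing the dependence created by each unit appearing in many pairs.

Scores are non-negative, continuous where positive, and carry many exact
zeros, so the response is modelled as Tweedie — compound Poisson-Gamma with
power $p \in (1, 2)$, variance $\phi \mu^p$, and point mass
$P(C = 0) = \exp(-\mu^{2-p}/(\phi(2-p)))$.

### Grid random effects

Unit-level random effects would add $2N$ parameters. Instead the tissue
field is partitioned into an $n_x \times n_y$ grid of equal rectangles and
the random effects are bucketed by rectangle, reducing the count to
$2\,N_{\mathrm{grid}}$. The biological premise is spatial correlation of
expression over short ranges. The default grid targets about 25 units per
rectangle ($n_x = n_y = \max(2, \sqrt{N/25})$, rounded); the acceptance
simulations confirm that fits with grid effects remain accurate even when
the data are generated with unit-level heterogeneity.

### Fitting

The two random-effect blocks carry ridge penalties with identity penalty
matrices. At fixed smoothing parameters $(\lambda_L, \lambda_R)$ and power
$p$, estimation is penalized iteratively reweighted least squares (PIRLS) on
the Tweedie quasi-deviance with log link: the objective minimized is

$$\tfrac{1}{2} \sum_{ij} d(C_{ij}, \mu_{ij}; p) \;+\;
\lambda_L \lVert \nu^L \rVert^2 \;+\; \lambda_R \lVert \nu^R \rVert^2,$$

with $d$ the Tweedie unit deviance and fixed effects unpenalized. Working
weights are $\mu^{2-p}$; each step includes halving against the true
penalized objective, and convergence requires both a relative change in that
objective below `tol` (default `1e-8`, cap 200 iterations) and a largest
coefficient update below $10^{-6}$ — near the optimum the objective is flat
to second order, so an objective-only rule can stop with coefficients still
$\sim 10^{-4}$ away. Starting values are
$\mu^0 = y + \bar{y}/10$, which guards the log link against exact zeros.
The test suite verifies the PIRLS solution against a generic quasi-Newton
optimizer of the same objective to `1e-4` in sup-norm.

Fitting uses only the deviance; the exact series density is reserved for
model selection. This is standard Tweedie GAM practice — the quasi-likelihood
fit does not require the series, and keeps every IRLS step a weighted least
squares solve.

### Smoothing, power, dispersion, decay

* **Smoothing** $(\lambda_L, \lambda_R)$ minimizes GCV,
  $n D / (n - \mathrm{edf})^2$, over a $7 \times 7$ log-spaced grid on
  $10^{-3}..10^{3}$ followed by Nelder-Mead refinement on the log scale.
  `edf` is the trace of the influence matrix of the final weighted penalized
  least-squares step, so penalized coefficients count fractionally.
* **Power** $p$ is chosen by profiling the exact compound Poisson-Gamma
  log-likelihood (evaluated at the fitted means and Pearson dispersion) over
  the grid $1.1, 1.2, \dots, 1.9$, refitting at each value with the selected
  smoothing. Flat profiles — e.g. a degenerate exactly-fitted response —
  return 1.5, and other ties resolve toward 1.5. A continuous optimization
  buys little here: the likelihood is flat near its maximum in $p$ and every
  downstream quantity changes smoothly with it.
* **Dispersion** $\phi$ is the Pearson estimator
  $\sum (y - \hat\mu)^2/\hat\mu^{p} / (n - \mathrm{edf})$ at convergence —
  stable and conventional, rather than a joint MLE.
* **Decay** $\rho$ is *not* estimated inside the model. A small candidate
  set is fitted end to end (smoothing and power selection included) and the
  candidate with the smallest AIC, $-2\hat\ell + 2\,\mathrm{edf}$ with
  $\hat\ell$ the exact series log-likelihood, is kept; ties go to the
  smallest candidate. The default candidates are scale-adaptive,
  $\{0\} \cup \{-\log(q)/d_{\mathrm{med}} : q = 0.75, 0.5, 0.25, 0.1\}$,
  with $d_{\mathrm{med}}$ the median pairwise distance within $d_{\max}$,
  because a fixed numeric default would be meaningless across coordinate
  units.

The exact series density itself is evaluated by index truncation around the
dominant term of the Poisson-Gamma sum, extending the summation window until
the boundary terms fall below a $10^{-12}$ relative tail tolerance (cap
$10^4$ terms); the zero mass uses the closed form. The suite checks the
series against explicit mixture summation to $10^{-8}$ and the density's
unit integral to $10^{-6}$.

### Inference

Each of the $G^2$ interaction coefficients gets a two-sided Wald test. The
default covariance is the penalized ("Bayesian") form
$\hat\phi (X^\top W X + S_\lambda)^{-1}$ restricted to the fixed-effect
block; a sandwich form is available via `cov_type = "sandwich"`. The
intercept is reported in `tidy()` but never tested. Benjamini-Hochberg
adjustment is applied across the entire emitted table — all LR pairs times
all type pairs as one family, matching how the result table is consumed;
per-pair adjustment is available via `bh_scope = "within_pair"`.

Identifiability note: at $\rho = 0$ the interaction columns sum exactly to
the intercept column, so one column is aliased. Aliased columns are detected
once by pivoted QR, dropped, recorded in the fit, and reported as `NA` rows.
Such fits remain usable for AIC comparison, which is all $\rho = 0$ is
typically good for.

### Pathway aggregation

For a pathway with member pairs $k$, responses are pooled as
$C_{ij} = \sum_k C_{ij}^k$ on the identical pair set and sent through the
same fitting path as a single pseudo-pair. The decay rate is re-selected for
the pooled response rather than inherited from the members, keeping the
pathway analysis self-contained.

### Multi-subunit complexes

Databases such as CellChatDB encode receptor complexes as subunits joined by
`_`. The per-unit complex score is the minimum over subunits — a complex is
only as available as its scarcest component (the CellPhoneDB convention);
the geometric mean is offered as an option. A pair with no measured ligand
or no measured receptor gene is skipped with a warning.

## The synthetic-data generator

`simulate_ccc()` generates the model's own data-generating process: units
uniform on a square (or lattice), one-hot or Dirichlet composition, normal
random effects at grid level (or unit level, to stress the grid
approximation), pairwise means from the model equation, and scores drawn by
exact compound Poisson-Gamma sampling. The drawn scores are returned in the
ground truth, so estimation tests can target the generative response
directly.

It also constructs per-unit ligand/receptor *expression*: square-root-scaled
marginal means of the planted score field with mean-one Gamma noise, so that
$L_i R_j$ reproduces the planted structure in expectation. This
factorization is necessarily approximate — a rank-one product cannot encode
arbitrary pairwise interaction detail — so end-to-end pipeline tests assert
sign recovery and ranking of a strongly planted effect rather than unbiased
magnitudes. What passing tests show: correct numerics, calibrated tests,
and recovery under the model's own assumptions. What they do not show:
robustness to real-data features such as segmentation errors, deconvolution
error in the composition matrix, spatially varying capture efficiency, or
mis-specified LR databases.

### Default study conditions

The reference simulation used by the acceptance checks is 300 single-cell
units on a $10 \times 10$ field, $G = 3$ equiprobable types,
$d_{\max} = 1.3$ (about 4500 ordered pairs including self pairs), one
planted coefficient $\beta_{12} = 1.5$, true $\rho = 0.5$ among candidates
$\{0, 0.5, 2\}$, emission $p = 1.5$, $\phi = 0.5$, and random-effect SDs
0.3. These sizes give distances whose decay weights span roughly 0.5-1, so
the AIC comparison among decay candidates is informative; the null
calibration batch uses 220 replicates of 200 units. The power-recovery
check uses 10 replicates of 200 units at emission $p = 1.3$.

### A note on calibration testing

The $G^2$ Wald statistics from one fitted dataset share a common
per-replicate component (the intercept/decay trade-off shifts all
interaction coefficients together), so they are far from independent.
Binomial acceptance bands for the type-I error rate assume independent
tests, so the calibration check draws *one designated type-pair test per
simulated dataset* and pools across replicates. Pooling all nine would
understate the variance of the empirical rate by roughly the design effect
$1 + (G^2 - 1)\,\mathrm{ICC}$.

## Degenerate inputs and tie-breaks

* All-equal positive response: zero deviance, flat power profile, $p = 1.5$
  by the tie rule.
* Degenerate bounding box (all $x$ equal): that grid axis collapses to one
  bin with a warning.
* Units on the maximal edge of the field fall in the last grid rectangle.
* Pairs whose response is identically zero are skipped and logged, as are
  pairs with no measurable ligand or receptor gene.
* Non-converged fits are reported with `converged = FALSE`, never silently
  dropped.
* Self pairs ($D = 0$, decay weight 1) are included by default: autocrine
  signaling is part of the model. Set `include_self = FALSE` to drop them.

## Known limitations

* The decay kernel is isotropic exponential; no anisotropy or diffusion
  physics.
* Expression is assumed normalized upstream; only a `log1p`
  median-library-size helper is provided.
* $\phi$ and $p$ are per-pair: each LR pair is an independent model.
* Differential communication between conditions is out of scope — run
  groups separately and contrast downstream.
* The rank-one score construction in the generator limits how faithfully
  end-to-end expression-level simulations can represent pairwise
  interaction structure (see above).
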