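---
title: "Calibrating stability selection: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibrating stability selection: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stabcal)
```

## The model

Stability selection turns any sparse selector into a resampling procedure.
`stabcal` supports two base selectors: the LASSO for variable selection
against an outcome (through glmnet), and the graphical LASSO for edge
selection in a Gaussian graphical model (the package's own block
coordinate descent solver, which accepts an elementwise penalty matrix).
For a penalty $\lambda$, the selector is fitted on $K$ random subsamples
of 50% of the observations (bootstrap and complementary-pairs resampling
are also available), and the selection count $H_\lambda(j) \in \{0,
\dots, K\}$ of each of the $N$ candidate features (or node pairs) is
recorded. The stability selection model at threshold $\pi$ is
$V_{\lambda,\pi} = \{j : H_\lambda(j)/K \ge \pi\}$.

### The stability score

Both $\lambda$ and $\pi$ are calibrated by maximising a stability score.
Writing $q_\lambda = \lfloor \frac{1}{K}\sum_j H_\lambda(j) + \frac12
\rfloor$ for the rounded average model size and $\gamma_\lambda =
q_\lambda / N$, the null hypothesis of maximally unstable selection says
every feature is selected independently with probability
$\gamma_\lambda$, so $H_\lambda(j) \sim B(K, \gamma_\lambda)$. Each
feature falls into one of three categories — stably selected ($H \ge
K\pi$), stably excluded ($H \le K(1-\pi)$) or unstable — whose null
probabilities follow from the binomial CDF $F_{K,\gamma}$ evaluated at
$\lceil K\pi \rceil - 1$ and $\lfloor K(1-\pi) \rfloor$. The score is the
negative log-likelihood of the observed classification; the calibrated
pair is its argmax over the grid. It is zero — uninformative by
construction — for empty and saturated models, so calibration is only
meaningful when between $1$ and $N-1$ features are stable.

Three numerical points matter here:

* **Log-scale tails.** At sparse models the category probabilities
  underflow double precision ($P(H \ge K\pi)$ can be below $10^{-300}$);
  all category probabilities are therefore computed on the log scale
  (`pbinom(log.p = TRUE)`, with a log-sum-exp fallback for the middle
  category). A linear-space implementation silently zeroes exactly the
  models one wants to find.
* **Integer boundaries.** $K\pi$ is compared against integer counts with
  a $10^{-9}$ guard so that, e.g., $K = 50, \pi = 0.62$ (where $K\pi$ is
  $31$ up to floating error) classifies $H = 31$ as stably selected. The
  CDF arguments use $\lceil K\pi \rceil - 1$ and $\lfloor K(1-\pi)
  \rfloor$, the unique convention under which the three category
  probabilities sum to one for the integer category definitions.
* **Degenerate nulls.** If $\gamma \in \{0, 1\}$ while a nonconforming
  category is observed, the likelihood is zero; the score is defined as 0
  rather than $\infty$ so the argmax stays well defined.

Ties at the maximal score are broken toward the largest $\lambda$
(sparsest base model), then the largest $\pi$ — the conservative choice.
A two-category variant of the score (stably selected vs the rest) is
available behind `two_categories = TRUE` but off by default, since
discarding the information in stable exclusions can hurt selection.

### Error control

The expected number of falsely selected features (PFER) admits closed-form
upper bounds: $q^2/((2\pi-1)N)$ under exchangeability, and a stricter
two-branch bound (split at $\pi = 0.75$, with $1/K$ corrections) under
unimodality of the selection proportions. Constrained calibration
maximises the score over the cells whose chosen bound is at most a budget
$\eta$; infeasible problems report the minimal achievable bound. Both
bounds are computed for every grid cell and exposed in the fitted object.

## Grids and defaults

| parameter | default | meaning |
|---|---|---|
| `K` | 100 | resampling units (complementary *pairs* under CPSS, so the $1/K$ terms of the error bound use the same $K$) |
| `fraction` | 0.5 | subsample size |
| `n_lambda` | 50 | penalties, log-spaced from the empty model down to the dense target |
| `pi_grid` | 31 values in $[0.6, 0.9]$ | thresholds in selection proportion |
| `lambda0` | 0.1 | weak penalty on off-target blocks (multi-block) |
| `tol` | $10^{-3}$ (resampling), $10^{-4}$ (standalone solver) | relative change of the covariance iterate per sweep |

The LASSO grid starts at $\lambda_{\max} = \max_j |X_j^\top y|/n$
(standardised columns, centred outcome) — the smallest penalty with an
empty model — and ends at `lambda_min_ratio` (0.01) times it. The
graphical grid starts at the largest absolute off-diagonal correlation
(empty graph) and ends at the largest penalty whose full-data fit reaches
50% edge density, located by bisection on the log scale with warm starts.
On rank-deficient covariances (high-dimensional data) the solver can break
down before the density target is reached; the grid is then capped at the
last penalty with a stable fit. Data are standardised *within* each
resample: the graphical LASSO is fitted on the subsample correlation
matrix, and glmnet standardises internally.

The resampling-path solver tolerance ($10^{-3}$) is looser than the
standalone default: the selected support — the only thing the counts use —
agrees with a $10^{-5}$ solve on more than 99% of edges along a full
path, at less than half the cost. Coefficients are called nonzero above
$10^{-8}$.

## The graphical LASSO solver

The solver maximises $\log\det\Omega - \mathrm{tr}(S\Omega) - \sum_{i\ne
j}\Lambda_{ij}|\Omega_{ij}|$ by block coordinate descent over columns of
the covariance estimate $W$; each column update is an $\ell_1$-penalised
quadratic programme solved by coordinate descent with per-coordinate
penalties and an active-set strategy (full pass, then iterate on the
nonzero set, then verify with another full pass). Convergence is declared
when the mean absolute change of the off-diagonal of $W$ per sweep falls
below `tol` times the mean absolute off-diagonal of $S$; the duality gap
$\mathrm{tr}(S\hat\Omega) + \|\Lambda \circ \hat\Omega\|_1 - p$ is
reported. By default the diagonal is *not* penalised, matching the
penalised likelihood above (the sum runs over distinct pairs);
`penalize_diagonal = TRUE` switches to the convention of common
implementations, which adds the penalty to the diagonal of $W$ and
regularises rank-deficient inputs. In this package's own experiments the
unpenalised-diagonal convention gave calibrated models much closer to the
intended sparsity, so it is the default despite being the numerically more
delicate choice; breakdowns are detected and reported rather than
propagated as silent nonsense.

A slow proximal-gradient solver written directly from the objective serves
as an independent oracle in the test suite (objective agreement within
$10^{-4}$ on 5-node instances, scalar and matrix penalties).

## Multi-block models

$G$ a-priori feature groups induce $B = G(G+1)/2$ edge blocks. Two
calibration strategies are implemented:

* **Block-wise (recommended).** For each block $b$, graphical LASSO
  models are fitted with the block penalty matrix ($\lambda_b$ on the
  target block, $\lambda_0$ elsewhere, so partial correlations stay
  conditional on all nodes), and $(\lambda_b, \pi_b)$ maximises the score
  computed from the block's own counts with $\gamma_b = q_b/|E_b|$. The
  final graph is the union of block-stable sets. Under a PFER constraint
  the budget is split proportionally to block sizes ($\eta_b = \eta
  |E_b|/N$) — the neutral allocation, since no rule is canonical — and
  the summed bound then respects $\eta$.
* **Joint product grid.** All block penalties move simultaneously over a
  coarse product grid (no weak penalty); one shared $\gamma$ enters all
  block scores, and per-block thresholds separate given the penalty
  vector. The grid grows as $L^B$, so it is capped (3 blocks, 500 cells)
  and exists mainly as the comparison baseline — in the package's paired
  experiments the block-wise decomposition dominates it clearly. Penalty
  vectors whose fits break down numerically (every block weakly penalised
  on a rank-deficient resample covariance) are excluded from the search.

Per-block penalty grids reuse the empty-to-dense construction, with
density measured on the block's own edges while other blocks sit at
$\lambda_0$. The resample correlation matrices are computed once and
shared across blocks, so all blocks see identical resamples.

## The simulator

Ground-truth datasets are generated in three steps. A binary adjacency
$\Theta$ comes from the Erdős–Rényi model (each pair independently an
edge with probability $\nu$) or Barabási–Albert preferential attachment
(one edge per incoming node — a connected tree with $p-1$ edges; with
$p = 100$ and $\nu = 0.02$ the random graph has 99 expected edges, the
same as the tree). Off-diagonal precision entries on the support are
$\alpha_{ij}$ drawn uniformly from $\{-1, +1\}$ — the literal two-point
reading; a continuous variant is not provided because magnitude diversity
comes from the next step — scaled by $v_b \in [0, 1]$ when the two nodes
belong to different groups ($v_b = 1$ single-block, $0.2$ multi-block).
The diagonal is the absolute row sum plus $u > 0$ (strict diagonal
dominance, hence positive definiteness with smallest eigenvalue at least
$u$), and data are drawn from the centred multivariate Normal with
covariance $\Omega^{-1}$.

The dominance constant $u$ controls the overall signal strength and is
tuned automatically: the *contrast* of a correlation matrix is the number
of unique values among its off-diagonal coefficients truncated (toward
zero, not rounded) to three decimals, and $u$ is chosen from a default
grid of 50 log-spaced values in $[10^{-5}, 10^2]$ to maximise the
contrast of the true correlation matrix, ties going to the smaller $u$.
Contrast is computed on signed values. One integer seed threads through
graph, signs, tuning and sampling, so datasets are bit-reproducible.

Regression outcomes are $y_i \sim N(x_i\beta, \sigma^2)$ with a uniformly
chosen support, effects from $\{-1,+1\}$ or $\pm[0.5, 1]$, and $\sigma =
\sqrt{(1-R^2)/R^2 \cdot s^2}$ where $s^2$ is the realised variance of
$X\beta$ — so $R^2 = s^2/(s^2+\sigma^2)$ holds exactly by construction.

What the simulator does *not* emulate: non-Gaussian marginals, heavy
tails, count data, longitudinal structure, batch effects, or measurement
error. Passing tests therefore certify the machinery under the model's
own assumptions, not robustness on real OMICs data. With the tuned $u$
typically small, simulated signals are strong — isolated connected pairs
can have near-unit partial correlations — which makes recall high and
puts the burden on error control.

## Problem sizes used in the checks

The packaged experiments run at a reduced scale chosen to keep the full
suite reproducible on a single core: $K = 50$ subsamples, 25 penalties
and 30 replicates for the graphical benchmarks ($n \in \{50, 200\}$,
$p = 100$, $\nu = 0.02$); the multi-block comparison uses 10 paired
replicates at $p = 50$ (two groups of 25, $K = 25$); the null-regression
error-control check uses 50 replicates at $n = 100$, $p = 50$, budget
$\eta = 2$. Full-scale settings ($K = 100$, 50 penalties) are the
function defaults.

## Known limitations

* At reduced $K$, the score surface often has a flat top extending toward
  denser models: several (λ, π) cells within a few per mille of the
  maximum can differ noticeably in sparsity, and the argmax tends to the
  denser side. The package's own experiments accordingly show calibrated
  graphical models with near-perfect recall but more false edges than the
  sparsest near-optimal cell would give; the PFER-constrained mode is the
  practical remedy when precision matters.
* The joint multi-block search is exponential in the number of blocks and
  is deliberately capped.
* The stability score assumes independent selection counts; correlated
  features violate this, and the score's absolute value should not be
  interpreted across datasets.
* Graphical-model runs scale as $O(p^3)$ per solver sweep; hundreds of
  nodes are comfortable, thousands are not.
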