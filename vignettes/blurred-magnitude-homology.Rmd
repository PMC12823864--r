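---
title: "Blurred magnitude homology features for directed functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Blurred magnitude homology features for directed functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bmhnet)
```

## Overview

`bmhnet` implements a pipeline for classifying directed functional
connectomes through topological features:

1. **Connectome construction** — lagged Pearson correlation between
   regional time series yields an asymmetric (directed) association
   matrix.
2. **Quasimetric transformation** — correlations are mapped to
   dissimilarities and repaired into a quasimetric by shortest-path
   closure.
3. **Blurred magnitude homology** — Betti curves in degrees 0 and 1
   summarize each functional subnetwork's multiscale directed structure.
4. **Classification** — a two-backbone neural network combines the raw
   connectome vector with the Betti-curve features.

This vignette documents the mathematical conventions, the numerical
choices, and the design decisions that are this package's own, so that
results can be interpreted and reproduced precisely.

## 1. Directed connectomes from lagged correlation

For regional series $x_u, x_v$ of length $T$ and lag $\tau$, the lagged
Pearson correlation is

$$\rho_\tau(u, v) = \operatorname{cor}\bigl(x_u[1:(T-\tau)],\;
  x_v[(\tau+1):T]\bigr),$$

computed with divisor $T - \tau - 1$. Because $\rho_\tau(u,v) \neq
\rho_\tau(v,u)$ in general, the matrix is a *directed* connectome: a
large $\rho_\tau(u,v)$ says activity in $u$ anticipates activity in $v$
one lag later. The default is $\tau = 1$.

```{r}
set.seed(1)
X <- matrix(rnorm(300), 100, 3)
X[-1, 2] <- X[-1, 2] + 0.8 * X[-100, 1]   # region 1 drives region 2
conn <- build_connectome(roi_timeseries(X))
round(conn$rho, 2)
```

Degenerate windows (zero variance after trimming to the overlapping
window) are an error naming the offending region, not a silent `NA`.

## 2. The quasimetric transformation

Correlation becomes dissimilarity through

$$\tilde d(u, v) = \sqrt{\tfrac{1 - \rho_\tau(u, v)}{2}},$$

so $\rho = 1 \mapsto 0$, $\rho = 0 \mapsto 1/\sqrt2$, and $\rho = -1
\mapsto 1$. The raw matrix $\tilde d$ is non-negative with zero diagonal
but generally **violates the triangle inequality**: lagged influence
that travels a relay $A \to B \to C$ arrives at $C$ two lags after
leaving $A$, so $\tilde d(A,B)$ and $\tilde d(B,C)$ can be near zero
while the direct lag-1 term $\tilde d(A,C)$ sits near the independence
value $1/\sqrt2$. (For *symmetric* correlation no violations are
possible — $\sqrt{(1-\rho)/2}$ is half the Euclidean distance between
standardized vectors — so the phenomenon is intrinsically directional.)

`shortest_path_closure()` replaces every entry with the all-pairs
shortest-path distance (Dijkstra, via **igraph**), which is the largest
quasimetric dominated by $\tilde d$. `check_quasimetric()` enumerates
axiom violations explicitly and is used throughout the tests.

```{r}
d <- matrix(c(0, 0.05, 0.9,
              0.05, 0, 0.05,
              0.9, 0.05, 0), 3, 3, byrow = TRUE)
closed <- shortest_path_closure(d)
closed$d
is_quasimetric(check_quasimetric(closed))
```

## 3. Blurred magnitude homology

For a quasimetric space $(V, d)$, a $k$-path is a tuple
$(v_0, \dots, v_k)$ with consecutive entries distinct; its length is
$\sum_i d(v_i, v_{i+1})$. At scale $\ell$:

* **strict** magnitude chains $MC_{k,\ell}$ are generated by $k$-paths
  of length *exactly* $\ell$;
* **blurred** chains $BMC_{k,\ell}$ by $k$-paths of length $\le \ell$.

The boundary $\delta(v_0,\dots,v_k) = \sum_i (-1)^i
(v_0,\dots,\widehat{v_i},\dots,v_k)$ keeps only terms that remain basis
elements (for the strict theory, only length-preserving drops survive;
dropping an endpoint never preserves length, and a drop that merges two
equal neighbours is zero). Betti numbers follow from ranks:
$\beta_0 = \dim C_0 - \operatorname{rank}\delta_1$ and
$\beta_1 = \dim C_1 - \operatorname{rank}\delta_1 -
\operatorname{rank}\delta_2$.

Degree-0 blurred homology counts weakly connected components at scale
$\ell$; degree-1 counts classes of undirected cycles modulo triangle
deformations. A *Betti curve* evaluates $\beta_k$ over a threshold
grid.

```{r}
g <- example1_graph()
betti_curve(g, 0, seq(0, 0.5, by = 0.1))$values
betti_curve(g, 1, seq(0, 0.5, by = 0.1))$values
```

### Conventions that matter

Three numerical/combinatorial conventions are this package's own and
are load-bearing; each is exercised directly by the test suite.

**Shortcut admissibility of 2-paths (digraphs with absent edges).** On a
digraph where some ordered pairs have infinite distance, we admit a
2-path $(v_0, v_1, v_2)$ into the blurred degree-2 basis only if the
shortcut distance $d(v_0, v_2)$ is finite or the middle drop is
degenerate ($v_0 = v_2$). Without this restriction the middle face of
$\delta_2$ can land outside the degree-1 basis, $\delta_1 \delta_2 = 0$
fails, and $\beta_1$ can go negative on small fixtures. On closed
(everywhere-finite) spaces the rule is vacuous. With it, the worked
five-node example above is reproduced exactly and
$\delta_1 \delta_2 = 0$ holds on every space the tests generate.

**Exact ranks over the rationals.** Boundary matrices have entries in
$\{-1, 0, 1\}$ and are incidence-like, so `rank_exact()` performs
integer Gaussian elimination preferring $\pm 1$ pivots (no fractions
ever arise on such matrices), with a fraction-free gcd-reduced fallback
and an overflow guard at $2^{48}$. Floating SVD ranks
(tolerance $10^{-8}$) are computed as a cross-check in the tests; exact
and floating ranks agree on every matrix in the acceptance sweeps.

**Length comparison tolerance.** Path lengths are sums of floats
($0.1 + 0.2 \ne 0.3$ in binary), so all comparisons "length $\le$
level" use $\varepsilon = 10^{-9}\max(1, |\ell|)$. Grid and weight
magnitudes here are $O(1)$, so this is far below any meaningful
length gap while absorbing accumulated rounding.

**Enumerate once, filter per level.** A Betti curve enumerates bases and
boundary matrices once at the top threshold and restricts rows/columns
per grid point, which the tests verify against naive per-level
recomputation.

## 4. Subnetwork feature bundles

Regions are grouped into nine functional subnetworks, fixed in canonical
order: `r paste(bmhnet::SUBNETWORKS, collapse = ", ")`. For each
subnetwork the connectome is restricted to its regions, transformed,
closed, and summarized by $\beta_0$ curves on a $T$-point grid over
$[0, 1]$ and $\beta_1$ curves over $[0, 2]$ (default $T = 256$,
i.e. $18 \times 256 = 4608$ Betti features). The companion raw feature
is the row-major off-diagonal vectorization of the full connectome.
The grid ranges cover the attainable dissimilarity range $[0,1]$ per
edge and (for cycles) sums of two such edges.

## 5. The two-backbone classifier

`bmh_net()` trains, in base R with a fully seeded hand-rolled
forward/backward pass:

* a 128-unit ReLU backbone on the connectome vector,
* a 128-unit ReLU backbone on the (training-standardized) Betti
  features,
* concatenation, dropout 0.5, and a single linear layer to **two
  logits** with softmax and cross-entropy,
* AdamW (decoupled weight decay).

Two logits for a binary problem are redundant in principle; the design
keeps the head symmetric in the classes and generalizes without change
to more classes, at the cost of one extra output unit. Betti features
are standardized with *training-set* statistics (stored in the model and
reapplied at prediction time) because their scales vary by orders of
magnitude across grid points; the connectome inputs are already bounded
in $[-1, 1]$.

### Configurations

`bmh_net_config()` carries literature-style defaults (learning rate
$10^{-5}$, weight decay $10^{-5}$, 50 epochs). At the cohort sizes this
package targets (tens of subjects, full-batch updates), that
learning-rate–epoch product moves parameters by roughly $5\times10^{-4}$
in total — too little to train. `desk_config()` is therefore provided
and used throughout the examples: learning rate $10^{-3}$, 300 epochs,
full batch, everything else unchanged. The choice was made from the
step-size arithmetic above, *a priori*, not by tuning against any test
outcome.

### Evaluation, importance, and group comparison

`evaluate()` scans candidate thresholds (0, midpoints of sorted unique
scores, 1) and reports the F-score-maximizing cut (ties to the lower
threshold), plus accuracy, precision and sensitivity, flagging undefined
cases. `subnetwork_importance()` averages $|\partial p_1 / \partial
x_{\text{betti}}|$ over subjects, chained through the standardization,
and sums within subnetwork. `group_curve_test()` runs per-grid-point
Welch $t$-tests with Holm correction applied over the **whole**
18-curve family (one family-wise error rate for the full feature map,
the comparison actually reported), flagging zero-variance grid points
as `NA` rather than fabricating $p$-values.

## 6. The synthetic cohort generator

`make_cohort()` draws subjects from a stationary VAR(1) process
$x_t = C^\top x_{t-1} + \varepsilon_t$ (burn-in 100, spectral radius
checked $< 1$), with coupling matrices whose **within-subnetwork
density** differs between classes (defaults 0.2 vs 0.6, strength 0.35,
$T = 150$). An `inject_subnetwork` option concentrates the class
contrast in a single subnetwork for importance experiments.

What the generator *emulates*: directed lag-1 dependence, community
structure aligned with the subnetwork partition, class differences in
within-community coupling, subject-level noise. What it does *not*
emulate: haemodynamics, measurement noise structure, inter-subject
registration error, site effects, or any empirical atlas — the shipped
partition under `inst/extdata` is labelled synthetic, and no real
region-to-subnetwork table is fabricated. Conclusions about real
cohorts require real data through the same interfaces
(`read_roi_timeseries()`, `read_partition()`).

Generator defaults are study conditions: they were fixed before the
classifier experiments were run and are not tuned toward any particular
outcome.

## 7. Problem sizes and runtime

Path enumeration in degree 2 is $O(n^3)$ tuples per subnetwork, and
rank computation is polynomial in basis size, so per-subnetwork region
counts in the single digits to low tens are the intended regime (the
nine-subnetwork bundles above use 3–4 regions per subnetwork and run in
seconds; a 40-subject cohort featurizes in well under a minute at
$T = 32$). Whole-connectome homology at hundreds of regions is out of
scope by design — the per-subnetwork decomposition is what makes the
method tractable.

## 8. Limitations

* Homology is implemented in degrees 0 and 1 only.
* Binary classification only (the two-logit head generalizes, the
  training loop's label handling does not yet).
* The shortcut-admissibility rule is a convention for spaces with
  infinite distances; alternative conventions exist and would change
  $\beta_1$ on open digraphs (not on closed connectome-derived spaces).
* The neural network is full-batch and CPU-only; it is meant for
  desk-scale cohorts, not large consortium datasets.

## Reproducibility

Every stochastic function takes an explicit seed or respects
`set.seed()`; model training, cohort generation and the command-line
pipeline (`bmh simulate | extract | train | eval`) are bit-reproducible
given a seed. `scripts/acceptance.R` recomputes the package's worked
example targets from scratch against the installed package.
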