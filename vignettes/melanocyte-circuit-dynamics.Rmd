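---
title: "Ensemble dynamics of the melanocyte pigmentation-proliferation circuit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble dynamics of the melanocyte pigmentation-proliferation circuit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(melcircuit)
```

## The scientific question

Cultured melanocytes coexist in functionally distinct cell states --
broadly, a mature pigmenting state and a proliferative state, with
mixed and stem-like states alongside -- even in clonal populations under
constant conditions. A mechanistic explanation is that a small gene
regulatory network (GRN) coupling the pigmentation regulators (MITF,
LEF1) to the Rb--E2F--Myc cell-cycle entry switch is *multistable*: for a
wide range of kinetic parameters the circuit admits several coexisting
stable steady states, and gene-expression noise can move cells between
them. melcircuit implements the in-silico side of that argument: an
ensemble ODE simulator for signed regulatory circuits, state
classification and pigmentation scoring, in-silico overexpression
experiments, and a synthetic single-cell generator that closes the loop
from simulated states to gene-set state-scoring heatmaps.

## The model

Each node $i$ of a circuit carries a concentration $X_i$ obeying

$$\frac{dX_i}{dt} \;=\; g_i \prod_{j \to i}
H_s\!\left(X_j;\; X^0_{ji}, n_{ji}, \lambda_{ji}\right) \;-\; k_i X_i,$$

where $g_i$ is the basal production rate, $k_i$ the degradation rate,
and the product runs over the regulators of $i$. Regulation enters
through the shifted Hill function

$$H_s(X; X^0, n, \lambda) = \lambda + \frac{1 - \lambda}{1 + (X/X^0)^n},$$

which equals 1 at $X = 0$, tends to the fold-change $\lambda$ as
$X \to \infty$, and is half-way at the threshold $X^0$. Activation is
$\lambda > 1$, inhibition $0 < \lambda < 1$, and $\lambda = 1$ switches
an edge off -- an identity the test suite exploits (a $\lambda = 1$ edge
must behave exactly like a deleted edge).

Rather than fitting one parameter set, the engine samples an *ensemble*
of kinetic models (random-circuit-perturbation style) and asks which
phenotypes the topology itself makes available:

* $g \sim U[1, 100]$, $k \sim U[0.1, 1]$ per node;
* Hill coefficient $n \sim U\{1..6\}$ per edge;
* activating fold-change $\lambda \sim U[1, 100]$;
* inhibiting fold-change: the *reciprocal* of $U[1, 100]$, so strong
  repression is as likely as weak. A flat draw on $[0.01, 1]$ -- the
  other dialect one sees -- makes the median repression only two-fold,
  which washes out switching so thoroughly that even a textbook toggle
  switch loses its bimodal expression marginal (dip statistic ~0.005
  vs ~0.07 with the reciprocal convention). Both modes are available
  (`lam_inh_mode`); the reciprocal one is the default because it is the
  established convention of this simulator family and the only one that
  reproduces switch-like behaviour.
* thresholds $X^0 \sim U[0.02\,M_j,\ 1.98\,M_j]$ around the regulator's
  median level $M_j$ (the "half-functional rule").

For $M_j$ the package defaults to a Monte-Carlo estimate that accounts
for the regulator's own inputs (`threshold_medians()`): starting from
the unregulated median $\tilde g/\tilde k = 50.5/0.55 \approx 91.8$, a
few fixed-point iterations re-estimate each node's median level under
random regulation. This matters: in the melanocyte circuit the regulated
medians span 11 (RB) to ~4,700 (E2F), so centring every threshold on the
constant 91.8 leaves many edges permanently saturated or permanently
silent, producing diffuse, weakly structured ensembles. The constant
rule remains available as `x0_mode = "simple"`. The median estimate uses
a fixed internal seed -- thresholds are study conditions, not per-run
randomness.

Initial conditions are log-uniform per node between its minimum and
maximum achievable levels: the unregulated span $[1, 1000]$ widened by
the strongest incoming inhibition (lower bound) and activation (upper
bound) per edge (`ic_mode = "regulated"`). The widening is not cosmetic:
a mutually-activating pair can place its high-high state near
$\lambda\,g/k \sim 10^5$, entirely above the unregulated box, and
sampling only $[1, 1000]$ provably misses such states (the two-node
brute-force oracle in the test suite caught exactly this).

## Finding steady states

For each model the engine integrates from `n_init` random initial
conditions with an adaptive Cash--Karp RK45 stepper (written in C++, as
is usual for this simulator family; the pre-installed `deSolve::lsoda`
serves as an independent cross-check in the tests, never as the
implementation). A trajectory is considered *settled* when the
scale-free residual $\max_i |dX_i/dt| / (1 + |X_i|)$ stays below
$10^{-5}$ at two consecutive checkpoints 5 time units apart (horizon
1,000 units). Settled endpoints are then polished by a damped Newton
iteration to the steady-state tolerance of $10^{-8}$. The polish is what
makes that tolerance honest: at integration tolerance `rtol = 1e-6` an
endpoint hovers at a residual of order $10^{-6}$ indefinitely, because
the local error control keeps re-injecting noise proportional to
`rtol`·$|X|$.

Polished endpoints are deduplicated (two endpoints are one state when
their log2 vectors differ by less than 0.05 in Euclidean norm, about a
3.5% relative difference) and screened by a numerical-Jacobian
eigenvalue check so that saddles a slow trajectory parked near are not
reported as phenotypes. Trajectories that never settle are dropped and
counted; models where no trajectory converges are flagged as possibly
oscillatory. All randomness derives from one master seed through
per-model substreams, so ensembles are bit-reproducible and
perturbation runs can re-materialise the identical parameter sets.

```{r engine, eval = FALSE}
net <- melanocyte_network()
ens <- run_ensemble(net, n_models = 2000, n_init = 20, seed = 1)
glance(ens)
```

## The packaged circuit

`melanocyte_network()` returns the seven-node circuit coupling the
pigmentation module to cell-cycle entry: MITF and LEF1 mutually
activate; MITF and MYC mutually inhibit (the antagonism between the
pigmentation and proliferation programs); MYC activates E2F and CycD;
CycD and CycE inhibit RB; RB inhibits E2F; E2F activates CycE and
itself (the bistable Rb--E2F restriction-point switch). The same circuit
ships as `inst/extdata/melanocyte.topo` in the standard whitespace
`.topo` dialect (`Source Target Type`, 1 = activation, 2 = inhibition),
and any other circuit can be supplied the same way. The precise edge
list of the published figure is not enumerated in text anywhere we
could consult, so this reconstruction is a declared default, not a
verbatim copy; variants we examined (one-way MYC--MITF antagonism
closed indirectly through the cycle machinery, MITF braking CycD, MYC
repressing LEF1) left the headline analyses qualitatively unchanged.

## State analysis

Steady states are log2-transformed and z-scored per node over all
states (`log2_znormalize()`); every analysis downstream works in these
coordinates. The per-state *pigmentation score* is the mean z of MITF
and LEF1 (`pigmentation_score()`; the node set is configurable since
"pigmentation genes" admits readings). On the default ensemble its
distribution is strongly bimodal -- assessed operationally by
`assess_bimodality()`: Hartigan's dip test (implemented in the package,
with Monte-Carlo p-values under the uniform null, and validated against
closed forms: equally spaced samples have dip exactly $1/2n$, two-point
mixtures $\min(p, 1-p)/2$) *and* a two-component Gaussian mixture
preferred over one by BIC (mclust). States with score above 0.22 are
called high-pigment; 0.22 is the antimode-derived cutoff of the control
ensemble, and `rederive_threshold()` re-estimates it from any bimodal
score distribution as the kernel-density minimum between the two
dominant modes.

Clustering (`cluster_states()`) is Ward-linkage agglomerative on
Euclidean distance in z-space, with the cluster number chosen by
maximal mean silhouette over $k = 2..8$ when not fixed, and clusters
canonically relabelled in descending mean pigmentation score.

### What automatic cluster-number selection actually returns

A finding worth stating plainly: on the default ensemble the four
phenotypic states -- high-pigment/low-cycle, both-high, a non-cycling
stem-like state, and low-pigment/proliferative -- appear with balanced
sizes and the expected signatures at the $k = 4$ cut, and the
silhouette profile carries the tell-tale 2×2 signature ($k=4$ scores
above $k=3$ and above $k \ge 5$ in nearly every run). But the *maximal*
mean silhouette lands on $k = 2$: the pigmented-vs-proliferative
super-split. This is robust across seeds, ensemble sizes, initial
condition counts, sampling conventions, plausible topology variants,
and even substituting k-means for Ward. Point-level mean silhouette
systematically favours the coarsest well-separated split when blobs
arrange on a grid with unequal axis separations; with the sampling
ranges above, the between-model parameter scatter (roughly
half a node-sd within a phenotype) keeps the four blobs wide enough
that merging along the weaker axis always wins. So: inspect
`cluster_states(norm, k = 4)` for the four-state structure, and treat
the automatic $k$ as what it is -- a model-selection heuristic with a
known coarseness bias, not a count of the biologically meaningful
states.

## In-silico overexpression

`run_perturbation_experiment()` overexpresses a node by multiplying its
basal production rate (20-fold by default) and re-solving the
seed-matched ensemble: identical sampled parameters and initial
conditions except the one rate. Scoring is *control-anchored*: the
normalisation statistics and the 0.22 cutoff come from the unperturbed
ensemble, and perturbed states are projected into those coordinates
before classification. Per-replicate high-pigment fractions (3
replicate ensembles of 2,000 models by default; the replicate count
behind the published t test is unstated, so 3 is our choice) are
compared with a two-sided two-sample Student's t test, equal variances
(equal-n replicates). At the default settings MITF overexpression
raises the high-pigment fraction by about +0.30 and MYC overexpression
lowers it by about −0.17, each at p well below 0.01, replicating the
published directions.

## Synthetic single-cell stage

The scoring procedure used on real single-cell clusters needs testable
ground truth, which no accession can provide; `simulate_cells()`
generates it. Cells are drawn from a small number of discrete states;
gene $g$ in cell $c$ has expression
$\exp(\beta + e \cdot [g \in \text{markers of } c\text{'s state}] +
\varepsilon)$, $\varepsilon \sim N(0, \sigma)$ -- log-normal
multiplicative noise (baseline $\beta = 2$, effect $e$, dispersion
$\sigma$), with disjoint 20-gene marker sets per state and 100
background genes (defaults: 4 states, 1,000 cells; seconds-scale).
This emulates exactly the structure the scoring stage relies on --
discrete states with elevated own-marker means -- and deliberately
nothing else: no library-size variation, dropout, doublets, or
cell-cycle effects, so passing tests certify the scoring logic, not
robustness to real scRNA-seq artefacts.

`module_score()` is the mean expression of a gene set minus that of a
size-matched random background set drawn (fixed seed) from non-member
genes -- a simplified stand-in for expression-binned control-gene
scoring that keeps the centring role of the background (global additive
shifts cancel exactly) without re-implementing binning; numerical
parity with any particular published utility is not claimed.
`state_score_heatmap()` averages scores per (cluster, state) and
z-scores each cluster row across states; `evaluate_recovery()` checks
the row-argmax against the generating states. At effect 1.0 and
dispersion 0.5 the heatmap is diagonal-dominant and recovery is exact;
at effect 0 it collapses to chance (1/4), and recovery is
non-decreasing in the effect size between those endpoints.

## Numerical choices and degenerate inputs

* Convergence: settle at $10^{-5}$ (scale-free), polish to $10^{-8}$;
  horizon 1,000 time units; checkpoints every 5.
* Deduplication at 0.05 on log2 vectors; stability screen at
  eigenvalue real parts $< 10^{-6}$.
* Zero-variance nodes make z-scores undefined: `log2_znormalize()`
  errors naming the node rather than silently dividing by zero.
* A score distribution that fails the bimodality assessment makes
  `rederive_threshold()` error with advice to use the fixed default --
  an antimode of a unimodal density is noise.
* Single-state heatmap rows have no across-state variance; their
  z-scores are reported as 0 by convention.
* Each steady state contributes one row to the analysis, whether its
  model is monostable or multistable; no weighting is applied (the
  source analyses state none).

## Problem sizes

Analyses in the tests and the reproduction script run at 2,000 models ×
20 initial conditions per ensemble -- the package's fast profile, which
resolves all the statistics above with comfortable margins (an ensemble
takes well under a minute on one core). `run_ensemble()` scales to the
10,000 × 100 headline profile unchanged if finer estimates are wanted.

## Known limitations

* Deterministic steady states only: noise-driven switching between
  coexisting states is inferred, not simulated (no SDE/Langevin mode),
  and oscillatory parameter sets are excluded rather than characterised.
* No bifurcation continuation or parameter fitting.
* The packaged circuit is a literature-guided reconstruction; its edge
  list is configurable precisely because it is not authoritative.
* The synthetic-cell generator's log-normal noise is the minimal model
  carrying the needed structure; a count-level negative-binomial mode
  would be the natural extension for dropout-like behaviour.
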