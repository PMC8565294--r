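---
title: "Graph-theoretic analysis of functional connectivity networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph-theoretic analysis of functional connectivity networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`fcnet` implements the standard graph-theoretic pipeline for two-group
resting-state functional-connectivity studies: regional time series are
correlated into a connectivity matrix per subject, binarized across a band of
network sparsities, summarized by global and nodal topology metrics and their
area under the curve (AUC) across the band, and compared between groups with
parametric and non-parametric inference. Because clinical fMRI datasets are
rarely shareable, the package also ships a synthetic cohort generator with a
known ground truth, so every stage of the pipeline can be validated end to
end and its statistical calibration (type-I error, power, brain-behavior
recovery) measured by simulation.

## From time series to binary networks

For each subject with time series matrix $X \in \mathbb{R}^{T \times N}$
(rows = volumes, columns = nodes), the connectivity matrix is the pairwise
Pearson correlation $r_{ij}$, variance-stabilized by Fisher's transform
$z_{ij} = \operatorname{atanh}(r_{ij})$. Correlations are clipped to
$[-1+10^{-7},\, 1-10^{-7}]$ before the transform so that duplicated or
perfectly anti-correlated signals yield large finite $z$ rather than
$\pm\infty$; a column with zero variance is an input error and is reported by
node name rather than silently dropped. The diagonal is set to zero.

Thresholding is by *network sparsity* rather than by correlation value: at
sparsity $s$ the $E(s) = \mathrm{round}(s\,N(N-1)/2)$ strongest strictly
positive entries become the edges of an undirected, unweighted graph. Fixing
the edge count rather than the cut point equates network density across
subjects, which would otherwise confound group comparisons of topology.
Negative and zero correlations are never edges. Three numerical details are
made explicit because no convention is universal:

* rounding of $E(s)$ is half-away-from-zero (`round_half_away`), not R's
  banker's rounding;
* ties in $z$ are broken by ascending $(i, j)$ order, making the edge set a
  deterministic function of the matrix;
* thresholding on $z$ or on $r$ is equivalent (atanh is monotone); the
  implementation ranks $z$.

The default band is $s = 0.05, 0.10, \dots, 0.40$ (8 points). The lower end
is chosen so that the mean degree $2E/N$ exceeds $\ln N$ — the conventional
floor below which sparse random graphs fragment — and the upper end stays
below 50% density, beyond which "small-world" topology is no longer
meaningful. `check_connectedness_floor()` reports the floor check and the
number of connected components. A finer band with step 0.01 is available
(`threshold_grid(0.05, 0.40, 0.01)`) as a robustness check; conclusions
should not depend on the step.

## Topology metrics

All metrics operate on the binary adjacency matrix. Writing $k_i$ for the
degree of node $i$, $t_i$ for the number of edges among its neighbors, and
$d_{ij}$ for the shortest-path (hop) distance:

* **Clustering** $C_i = 2t_i / (k_i(k_i-1))$, with $C_i = 0$ when
  $k_i < 2$; $C_p$ is the mean over all $N$ nodes.
* **Characteristic path length** $L_p$ is the mean of $d_{ij}$ over pairs
  with finite distance. If any pair is unreachable a `disconnected` flag is
  raised; averaging only finite pairs keeps $L_p$ usable on small or
  synthetic graphs that fragment, without letting infinities poison the mean.
* **Global efficiency** $E_{glob} = \frac{1}{N(N-1)} \sum_{i \ne j}
  d_{ij}^{-1}$ (with $1/\infty = 0$), and nodal efficiency
  $NE_g(i) = \frac{1}{N-1}\sum_{j \ne i} d_{ij}^{-1}$ — robust to
  disconnection by construction.
* **Local efficiency** $NE_{loc}(i)$ is the global efficiency of the
  subgraph induced by the neighbors of $i$ (with $i$ removed), zero when
  $k_i < 2$; $E_{loc}$ is the mean over all nodes. This is the
  induced-subgraph convention used by the common connectome toolboxes; note
  that some libraries (igraph among them) instead allow detour paths through
  the rest of the graph, which yields larger values.
* **Betweenness** $BC(i) = \sum_{s \ne i \ne t} \sigma_{st}(i)/\sigma_{st}$
  over unordered pairs, computed with Brandes' accumulation; it is reported
  as raw pair counts (bound $(N-1)(N-2)/2$) rather than normalized, since
  the group tests downstream are scale-invariant.

Nodes of degree $< 2$ contribute $C_i = 0$ and $NE_{loc} = 0$ to the means
rather than being excluded — the convention of the mainstream connectome
toolboxes; excluding them would make $C_p$ incomparable across subjects with
different numbers of near-isolated nodes.

The kernels are implemented in C++ (word-parallel bitset BFS frontiers),
which keeps the repeated-simulation studies below tractable; each is verified
in the test suite against naive brute-force references (Floyd–Warshall
distances, exhaustive triangle counts, recursive shortest-path counting) on
dozens of random graphs, and cross-checked against igraph.

## Small-world normalization

$C_p$ and $L_p$ are only interpretable relative to random graphs with the
same degree sequence, so the package builds Maslov–Sneppen null ensembles:
repeated double-edge swaps $(a,b),(c,d) \to (a,d),(c,b)$, accepted only when
the four endpoints are distinct and neither new edge exists. Defaults are
100 nulls with $100 \times E$ swap attempts per null — enough attempts that
the ensemble is well mixed at the graph sizes in scope; both are
configurable and the ensemble is fully seed-controlled. Then

$$\gamma = C_p / \langle C_p^{rand}\rangle, \qquad
  \lambda = L_p / \langle L_p^{rand}\rangle, \qquad
  \sigma = \gamma / \lambda,$$

with $\sigma > 1$ the usual small-world signature. Two degenerate cases are
errors rather than silent results: a graph without two independent edges
cannot be rewired, and a null ensemble whose mean $C_p$ or $L_p$ is zero
(possible for very sparse thresholds on small graphs, where rewired nulls can
be triangle-free) makes the normalization undefined. At realistic scale
(hundreds of nodes, $s \ge 0.05$) neither occurs.

## AUC summarization

Each metric's trajectory across the band is reduced to its trapezoidal
integral, $\mathrm{AUC} = \sum_k (s_{k+1}-s_k)(v_k+v_{k+1})/2$ — a
threshold-independent scalar per metric per subject (a metric constant at
$c$ over the default band integrates to $0.35\,c$). All group inference
operates on AUCs, which also keeps the number of tests down: one test per
global metric, and one per node per nodal metric.

## Statistical layer

Group comparisons use the two-sample t-test, accepting either raw samples or
published summary triples (mean, sd, n) so that printed tables can be
re-tested. Welch (unpooled, Satterthwaite df) is the default: re-deriving a
published clinical table from its summary triples showed some rows matching
the Welch statistic and others (age, one language sub-score) only the pooled
Student statistic, so both variants are exposed and the choice is explicit.
Every parametric comparison is backed by a Mann–Whitney U (exact enumeration
up to 12 observations, tie-corrected normal approximation beyond) and a
permutation test (default 5,000 relabelings; exact enumeration is switched on
automatically when $\binom{n_a+n_b}{n_a} \le 10{,}000$). Sampled permutation
p-values use the add-one estimator $(1 + \#\{|t^*| \ge |t|\})/(B+1)$, which
is never zero and bounded below by $1/(B+1)$.

Nodal tests are Bonferroni-corrected at two levels, following common practice
in nodal connectome analyses: the strict family-wise level $\alpha/N$ and a
liberal exploratory level $1/N$. No FDR alternative is offered — the point of
the layer is to reproduce this exact correction scheme.

Brain-behavior analysis correlates each *significant* global AUC with each
clinical score within the patient group only (controls sit at ceiling and
would inflate correlations), as a Pearson correlation and as a partial
correlation controlling for age, sex (0/1), head motion and disease duration
— residualizing both variables on an intercept-plus-covariates design via
least squares, with $df = n - 2 - k$.

## The synthetic cohort generator

The generator emulates the structure of a stroke-aphasia resting-state
study: two groups (24 patients, 19 controls), per-subject regional time
series (default 150 volumes), and a clinical table (four language sub-scores
on 0–100, their composite, and two 0–30 cognition screens, plus age, sex,
duration and head motion).

Each subject's time series is an i.i.d. draw from a zero-mean multivariate
normal whose correlation matrix is block-modular: `rho_within = 0.6` inside
each of 6 equal modules, `rho_between = 0.1` across modules. Patients carry
a scalar *severity* $\in [1 - \mathrm{spread}, 1]$; within the lesioned
modules (defaults: modules 1–2) the within-module correlation drops to
$\rho_w - \mathrm{severity}\cdot L \cdot (\rho_w - \rho_b)$ with lesion
strength $L = 0.7$, i.e. 0.6 down to 0.25 at full severity. The same severity
scalar drives the clinical scores
($\mathrm{score} = \mathrm{baseline} + 30(1-\mathrm{severity}) +
\mathcal{N}(0, 10^2)$, truncated to range), so the brain-behavior
correlation the statistics layer must recover is well-posed by construction.
The default severity spread of 0.8 reflects the wide clinical heterogeneity
of a 1–24-month post-stroke cohort and gives the clinical scores a realistic
dispersion; the ABC baselines (41, 64, 62, 42) anchor the patient group's
expected means to published values for such cohorts. Demographics are drawn
independently of severity, so partial-correlation adjustments have a known
null. Every covariance matrix is checked for positive semi-definiteness
(smallest eigenvalue $\ge -10^{-10}$); incompatible rho/lesion settings are
rejected rather than repaired silently.

What the generator deliberately does **not** emulate: temporal
autocorrelation (band-passed BOLD is upstream of this pipeline's scope, and
graph construction depends only on the inter-node correlation structure),
scanner artifacts and motion spikes, hemodynamics, and lesion geometry in
voxel space. Passing tests therefore demonstrate that the pipeline recovers
known correlation-structure differences at realistic sample sizes and noise
levels — not that it is robust to the full range of fMRI artifacts.

Three preset conditions parameterize the simulation studies:

| preset | lesion | severity | used for |
|---|---|---|---|
| `null_cohort_config()` | none ($L=0$) | — | type-I error |
| `strong_lesion_config()` | $0.6 \to 0.25$ | all patients at 1 | power |
| `coupled_cohort_config()` | graded | uniform on $[0.2, 1]$ | brain-behavior recovery |

## Calibration results the package computes about itself

`estimate_type1_error()` simulates null cohorts (no lesion) and reports the
rejection rate of the Welch test on the patients-vs-controls local-efficiency
AUC; `estimate_power()` does the same under the full-strength lesion;
`estimate_behavior_detection()` reports how often the within-patient
Eloc-AUC–language correlation is positive and significant. The test suite
runs these at 500, 20 and 20 cohorts respectively (60 nodes, 150 timepoints,
24 + 19 subjects — sizes chosen so the full suite stays fast while the
binomial tolerances remain meaningful) and asserts a type-I rate in the 3–8%
band around the nominal 5%, power $\ge 90\%$, and a behavior-detection rate
$\ge 80\%$. The acceptance script recomputes the same rates from scratch at
the same sizes. These simulations use the cheap profile path (local
efficiency only, no null ensembles), which the full-profile path is tested
to agree with exactly.

## Numerical and design choices, collected

* Correlation clipping at $1 - 10^{-7}$ (finite $z$ for duplicated
  signals) rather than dropping pairs.
* $E(s)$ rounding half-away-from-zero; documented because toolboxes differ
  and the convention is rarely stated.
* $L_p$ on disconnected graphs averages finite pairs and raises a flag.
* Degree-$<2$ nodes contribute zeros to $C_p$ and $E_{loc}$ means.
* BC as raw pair counts; normalization is presentation only.
* Null model: Maslov–Sneppen, 100 nulls, $100E$ attempts, seed-controlled.
* Permutation p never zero (add-one estimator); exhaustive when feasible.
* Welch default, Student available; two-sided p throughout.
* The node-table convention is 1-based node ids; edge lists are written
  0-based (`node_i < node_j`) with a JSON sidecar giving $N$, $s$, $E$.

## Known limitations

* Weighted, signed and directed networks are out of scope; negative
  correlations are discarded at thresholding, as is conventional for this
  pipeline but debated in the field.
* The one-scalar-severity lesion model cannot produce spatially
  heterogeneous degradation within a module, so nodal-test spatial precision
  is only coarsely exercised.
* $NE_g$ and $NE_{loc}$ are distinct quantities that the applied literature
  sometimes describes with interchangeable wording; both are implemented
  under their standard definitions (mean inverse distance to all nodes vs
  neighbor-subgraph efficiency) and reported separately.
* Real-data headline statistics from any particular study are not
  reproducible without that study's raw images; the package validates
  against printed summary tables, closed forms, brute-force oracles and
  simulation ground truth instead.
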