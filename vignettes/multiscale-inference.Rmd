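---
title: "Multi-scale inference for functional connectomes: models, accounting, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale inference for functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A paired task-versus-rest functional connectivity study observes, for each
of $n$ subjects, two symmetric $V \times V$ connectomes (z-scored Pearson
correlations between atlas nodes). The scientific question — *where does
connectivity differ between conditions?* — can be answered at four spatial
scales, and the choice of scale changes statistical power by an order of
magnitude when effects are spatially widespread. `connbench` implements
seven inferential procedures spanning those scales and a resampling
benchmark that measures their power and error control against a full-sample
ground truth.

All computation happens on the *edge vector*: the upper triangle of the
connectome in a fixed row-major order over node pairs $(i, j)$, $i < j$,
giving $E = V(V-1)/2$ edges. A node partition into $K$ communities induces
*network pairs* — unordered community pairs, $K(K+1)/2$ of them — which are
the units of network-level inference.

# Edgewise statistics and the permutation engine

For subject $s$, the paired difference $x_s = \text{task}_s - \text{rest}_s$
is computed per edge. The edgewise statistics are the one-sample t statistic
$t = \bar{x} / (s_x/\sqrt{n})$ and paired Cohen's
$d = \bar{x}/s_x$, with the $(n-1)$-denominator standard deviation and
parametric p-values from the $t_{n-1}$ reference. Zero-variance edges are
flagged rather than dropped: $t = 0$ when the mean is also zero, $\pm\infty$
otherwise.

The shared null model is the exact paired scheme: under exchangeability of
the two condition labels within subject, each subject's difference vector
may be multiplied by an independent fair $\pm 1$. One engine draw is a sign
vector; a whole draw set is a $P \times n$ matrix generated in a single
deterministic pass from the engine seed, so any draw is reproducible from
`(seed, draw)`. Because sign flips leave $\sum_s x_s^2$ per edge unchanged,
the permutation t matrix for all $P$ draws reduces to one matrix product —
this is the hot loop of the whole package. Every permutation p-value uses
the add-one convention $p = (1 + \#\{\text{null} \geq \text{obs}\})/(P+1)$,
so $p$ is never zero and ties count conservatively against the observed
value.

# The seven procedures

* **edge (FWER)** — Bonferroni over $E$ edges per directional analysis,
  parametric p-values.
* **edge (FDR)** — Storey q-values per tail: $\hat\pi_0 = \min(1, \#\{p >
  \lambda\}/(m(1-\lambda)))$ with fixed $\lambda = 0.5$ (no smoother; stable
  under dense signal) floored at $1/m$, then the step-up
  $q_i = \min_{p_j \ge p_i} \hat\pi_0\, m\, p_j / \text{rank}(p_j)$. With
  $\hat\pi_0 = 1$ this is Benjamini–Hochberg.
* **cluster (NBS)** — edges with one-sided $t$ beyond a cluster-determining
  threshold (CDT) form components (two edges are contiguous when they share
  a node); observed component edge counts are tested against the
  permutation null of the maximum component size. The CDT defaults to the
  $t$ quantile of a one-sided $p = 0.01$ test at the sample's degrees of
  freedom; the statistic form is also accepted.
* **cluster (TFCE)** — threshold-free cluster enhancement on the graph:
  $\text{tfce}(e) = \sum_k \text{extent}_k(e)^{E_x} h_k^{H_x} \Delta h$
  over $n_{\text{steps}}$ heights spanning $(0, \max t]$, with classical
  defaults $E_x = 0.5$, $H_x = 2$, 100 steps. Edgewise scores are tested
  against the permutation null of the maximum score.
* **network (FWER / FDR)** — the pooled-network statistic: the mean of
  edgewise $t$ within each network pair, compared to its own permutation
  null; the per-pair p-values are corrected per tail by Bonferroni or by
  the Simes/Benjamini–Hochberg step-up.
* **whole brain (mv)** — an omnibus test of the pooled-network vector
  $T$: squared Mahalanobis distance to the permutation null cloud,
  $D^2 = (T-\hat\mu)^\top \hat\Sigma^{-1} (T-\hat\mu)$ with $\hat\mu,
  \hat\Sigma$ from the null draws and ridge
  $\hat\Sigma + \varepsilon I$, $\varepsilon = 10^{-6}
  \operatorname{tr}(\hat\Sigma)/K_{\text{pairs}}$. The null reference
  distances are *exact leave-one-out* distances obtained from the
  full-sample ones by a rank-one identity, so observed and null values are
  computed on the same footing. This construction is our interpretation of
  a multivariate omnibus test built on pooled network statistics; the
  statistic is signless (a test of inequality).

## Directional analyses and the overall level

All procedures except the whole-brain test run two one-sided analyses (task
greater than rest, and the reverse). By default each directional analysis
runs at $\alpha/2$, so the two-sided suite has overall level $\alpha$: with
independent null edges, two full-$\alpha$ directional analyses would
realize a weak-sense familywise error rate near $1-(1-\alpha)^2 \approx
2\alpha$, which no benchmark would certify as valid control at $\alpha$.
The independent-directional convention remains available
(`split_tails = FALSE`) for comparison with toolboxes that analyse one
direction at a time.

A resolution consequence: a Bonferroni-corrected network-pair test at the
overall level needs permutation p-values smaller than
$(\alpha/2)/K_{\text{pairs}}$, and the smallest achievable permutation
p-value is $1/(P+1)$. The benchmark therefore defaults to $P = 1000$ draws
(at $K_{\text{pairs}} = 21$ and $\alpha = 0.05$: $1/1001 < 0.025/21$);
$P = 500$ would make network-FWER detections impossible by construction.

# Ground truth and its variants

The ground truth is estimated once on the full population: edgewise $d$ and
sign, a two-sided significance mask (Storey FDR at $\alpha$), pooled
network-level $d$/sign with significance from two-sided permutation
p-values of the pooled statistic (the same pooling recipe as the inference
procedure, for internal consistency), and a whole-brain non-null flag (at
least one significant edge). Variants: *weak* multiplies $d$ by a factor
(default 0.5; the multiplicative construction is our choice — the exact
construction of weaker published maps is not specified), *sparse* declares
every element with $|d|$ below a cutoff (canonically 0.2) null — its sign
and significance are zeroed and any detection there counts as a false
positive.

Two characterisation tools mirror the ground-truth analyses: cluster
counting at $|d|$ thresholds (components of $d > c$ and $d < -c$
separately), and a between-network heterogeneity F statistic with two
shuffle nulls (node-community shuffling, and edge shuffling within the
within-community and between-community edge sets separately).

# The benchmark and its accounting

Each experiment cell (procedure, contrast, group size) runs $R$
repetitions: resample $n$ subjects without replacement, build the contrast
(for the *fake* contrast the two rest runs are swapped per subject by a
fair coin — the weak-sense FWER condition), compute statistics and one
shared set of permutation draws, run every procedure, classify detections
against the ground truth. Per-repetition seeds derive from the base seed by
XOR with the repetition index, so any repetition can be re-run alone and
results are invariant to cell execution order.

Classification is sign-matched and happens at two granularities, and the
choice of granularity per measure is a deliberate design decision:

* **Power** is counted per element at the procedure's level of inference,
  except cluster-level procedures, whose true positives are defined at the
  edge level (a significant cluster's implicated edges with matching
  ground-truth sign). Mean power averages over non-null elements only.
* **FDR, FWER, and the spatial extent of false positives** are counted at
  the procedure's own *detection units*: edges; supra-threshold clusters
  (for TFCE, components of the significant-edge set), where a cluster is a
  true positive when at least one member edge matches the ground-truth
  sign — the cluster-level inferential claim is exactly "an effect exists
  for at least one edge within the cluster"; network pairs, signed by the
  pooled effect; the signless whole-brain test. Counting these measures per
  implicated edge instead would brand every broad detection a false
  positive whenever a single enclosed edge has the opposite sign, making
  valid FWER control unattainable for cluster and network procedures on any
  dense two-signed effect map — inconsistent with the published finding
  that all seven procedures achieve valid control while network-level
  precision is only ~70%.
* **Spatial precision** is the edge-level overlap measure — the fraction of
  implicated edges overlapping same-sign ground-truth effects — and is
  precisely where broader-scale procedures pay for their power. It is
  undefined (NA) for the whole-brain test.

FWER validity uses the 95% binomial criterion: the observed rate must fall
below $\alpha + 1.96\sqrt{\alpha(1-\alpha)/R}$.

# The synthetic generator

The generator produces paired task/rest populations with analytically known
ground truth. Rest runs are $x_{ser} = \mu_e + u_{se} + v_{ser}$ (baseline
+ Gaussian subject effect + run noise); the task condition adds the effect
and unit-variance task noise on top of rest run 1, so the paired difference
is exactly $\delta_e + \varepsilon_{se}$ with
$\varepsilon = \sqrt{1-\rho^2}\, z + \rho\, g_{s,k(e)}$ — mean $\delta_e$,
standard deviation 1, hence the population Cohen's d *equals* $\delta_e$.
The shared factor $g$ (one per subject per network pair, loading $\rho$)
is the simplest dependence structure that separates cluster/network
procedures from edge procedures; pairwise noise correlation within a pair
is $\rho^2$.

The default effect map emulates the published spatial signature:
within-community edges at $d = -0.5$ (task below rest), one designated
community-pair block at $-0.4$, remaining between-community edges drawn
from $\mathcal{N}(+0.1, 0.1)$ — widespread small effects of mixed sign.
The desk-scale design is $V = 60$ nodes, $K = 6$ equal communities,
$N = 600$ subjects, $\rho = 0.3$; baselines ($\mu$ of 0.4 within, 0.15
between communities, subject sd 0.2, run noise sd 0.3) are typical
magnitudes for z-scored correlation connectomes and cancel from the paired
contrast by construction. Group sizes $n \in \{20, 40, 60\}$ scale the
published $\{40, 80, 120\}$ design by half; $R = 200$ repetitions at
$n = 40$ and $R = 100$ elsewhere keep the full suite within minutes on one
CPU while holding Monte-Carlo standard errors near 1.5–3 percentage
points. An optional extra task-noise knob emulates unequal scan durations
(off by default; when on, the realized $d$ shrinks by
$1/\sqrt{1 + \tau^2}$ and the generator documents it rather than
pretending $\delta$ is still exact).

What the generator does *not* emulate: empirical HCP edge covariance beyond
the one-factor-per-pair block structure, heavy-tailed or motion-related
noise, and spatial autocorrelation of effects beyond the community layout.
Consequently the benchmark certifies the *machinery* — error control,
power ordering across scales, monotonicity — not numeric power values for
real connectomes, which depend on restricted data.

# Numerical choices and degenerate inputs

* Connected components and TFCE run in compiled code; TFCE sweeps heights
  descending with a potential-carrying union-find, so per-edge accumulated
  scores cost near-linear time per draw instead of
  $O(\text{steps} \times E)$. Both are verified against brute-force R
  oracles (flood fill; explicit per-height labelling).
* Permutation ties resolve conservatively (the $\geq$ comparison).
* The Mahalanobis solve is guarded by the trace-scaled ridge; a covariance
  still singular after regularisation raises a diagnostic error, and the
  engine refuses to run the omnibus test with fewer than
  $K_{\text{pairs}} + 2$ draws.
* Storey's $\hat\pi_0$ is floored at $1/m$; a raw zero estimate would zero
  every q-value.
* Asymmetric matrices (beyond $10^{-8}$), incomplete edge-vector files,
  duplicate or missing partition nodes are format errors naming the file.

## A note on whole-brain power at very small groups

With strong dense effects, the sign-flip null of the pooled-statistic
vector is inflated along the effect direction (a draw's edgewise t is
roughly $(\delta Z + \text{noise})/\sqrt{1+\delta^2}$ with one shared $Z$
per draw), so the omnibus separation grows like $\sqrt{n}$ rather than
with the raw effect-to-noise ratio. At the half-scale $n = 20$ — below any
group size in the published design — the whole-brain test consequently
misses in a small percentage of repetitions, while from the scaled
$n = 40$ upward it detects in every repetition. This is a property of
permutation omnibus tests on non-centred data, not an implementation
artifact.

# Known limitations

* Only the paired two-condition contrast is supported; covariates, GLMs
  and unpaired designs are out of scope (the permutation engine is the
  extension point).
* The weak-variant construction and the mv omnibus statistic are stated
  interpretations where published specifications end.
* Network-level inference requires every network pair to contain at least
  one edge; partitions are taken as given (no community detection).
* Benchmark metrics are Monte-Carlo estimates; at $R = 100$–$200$ the
  binomial standard error of a 5% rate is 1.5–2.2 percentage points, which
  is why validity is judged against the binomial upper bound rather than
  the point value.
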