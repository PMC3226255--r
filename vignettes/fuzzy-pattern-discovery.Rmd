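---
title: "Unsupervised fuzzy pattern discovery in mixed-mode expression tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Unsupervised fuzzy pattern discovery in mixed-mode expression tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzpat)
```

## The problem

Association-pattern mining in gene expression tables usually leans on tissue
class labels: the labels drive the discretization of each gene's continuous
expression levels, and patterns are then read off the discrete events. When
labels are unavailable or unreliable, that route is closed. `fuzzpat`
implements a fully unsupervised alternative: the *genes* (attributes, columns)
are clustered by their mutual interdependence, the most representative gene of
each cluster stands in for the missing class variable, and every other gene is
discretized against it. Because a gene can be genuinely correlated with more
than one cluster, the crisp clusters are *fuzzified* before discretization, so
that patterns whose events span cluster boundaries remain discoverable.

The pipeline has five stages, each exposed as an ordinary function:

1. `redundancy_matrix()` — pairwise interdependence between attributes;
2. `select_k()` / `kmodes_cluster()` — attribute clustering with model
   selection over the cluster count;
3. `fuzzy_memberships()` — degrees of membership of every attribute in every
   cluster;
4. `build_cluster_event_tables()` — per-cluster discretization of continuous
   attributes into interval events;
5. `discover_patterns()` / `mine_rules()` — significance-screened event
   associations, and (post hoc, once labels are restored)
   weight-of-evidence classification rules.

## The interdependence measure

For attributes $G_i$, $G_j$ the package uses the normalized interdependence
redundancy

$$R(G_i : G_j) = \frac{I(G_i : G_j)}{H(G_i : G_j)},$$

mutual information over joint entropy. $R$ lies in $[0, 1]$, is symmetric,
equals 1 when either attribute determines the other, and — unlike raw mutual
information — is not inflated by attributes with many states. Probabilities
are plug-in estimates from a contingency table. A continuous attribute is
first quantile-binned into

$$m = \max\!\left(2, \left\lfloor \sqrt{|T| / \alpha} \right\rfloor\right)$$

equal-frequency bins, so that an $m \times m$ table averages at least
$\alpha$ points per cell; $\alpha$ (default 3) is the usual rule-of-thumb
occupancy parameter. Categorical attributes keep their native symbols. Each
attribute is binned once, globally, and the full $N \times N$ matrix is
computed once and reused by every later stage; binning per attribute pair
would be equally defensible but costs $N^2$ binnings and makes results depend
on pair order in caches. Ties always fall into the lower bin, so the coding
is deterministic; constant attributes have zero joint entropy with everything
and are assigned $R = 0$ throughout (they can never represent a cluster).

## Attribute clustering and model selection

`kmodes_cluster()` is a k-means analogue on the attribute side: the cluster
representative is not a centroid but the *mode* — the member with the largest
multiple interdependence redundancy

$$MR(G_i) = \sum_{j \in C_r,\, j \neq i} R(G_i : G_j)$$

within its cluster $C_r$. Assignment sends each attribute to the cluster
whose mode it is most redundant with; the update step re-elects each
cluster's mode; the two alternate until the assignment stabilizes (cap 100
iterations). All ties break deterministically toward the lower index, and a
cluster emptied by reassignment is re-seeded with the attribute worst served
by the current modes. Because the assign/update pair is not guaranteed to
improve the objective monotonically, the run keeps the best iterate it has
seen and returns that.

Model selection maximizes

$$SR(k) = \sum_{r = 1}^{k} MR(G^r),$$

the summed redundancy of the $k$ modes, over a user range of $k$ (default
2..6 in the bundled experiment), with 10 seeded random restarts per $k$ and
SR ties (within $10^{-12}$) resolved toward the smaller $k$. SR sums the
modes' MR only, not all members': summing all members would decrease
monotonically with every split and collapse the selection to $k = 1$.

A caveat worth knowing: SR rewards adding a cluster whenever the new mode's
within-cluster MR exceeds what its members contributed to their old mode.
When between-attribute redundancies are modest — which is exactly what
fine-grained equal-frequency binning produces, since the joint entropy in the
denominator grows like $\log_2 m$ — the optimum can sit at a larger $k$ than
the planted structure, typically by splitting one strong cluster in two. The
acceptance material reports this behaviour rather than masking it; see
"Limitations".

## Fuzzification

A crisp partition hides every cross-cluster correlation. The fuzzifier
converts the partition into a row-stochastic membership matrix

$$\mu_r(G_i) = \frac{R(G_i : G^r)^{1/(f-1)}}
                    {\sum_{c=1}^{k} R(G_i : G^c)^{1/(f-1)}},$$

where $G^c$ are the modes and $f > 1$ is the fuzzification parameter. At
$f = 2$ the exponent is 1 and the redundancies to the modes are simply
normalized to sum to one; as $f \to 1^+$ the nearest mode takes all the
weight; as $f \to \infty$ rows flatten to $1/k$. Membership order always
follows redundancy order. Rows are rescaled by their maximum before powering
(mathematically a no-op, numerically essential near $f = 1$), and an
attribute with zero redundancy to every mode receives the uniform row $1/k$
rather than 0/0. The default $f = 1.5$ matches the bundled benchmark
experiment.

## Discretization within fuzzy clusters

Each cluster table admits the attributes whose membership reaches an
inclusion threshold $\tau$ (default 0.003 — small enough to admit genuine
cross-cluster overlaps, large enough to exclude noise-level memberships; the
open design choice here was threshold gating versus carrying all attributes
weighted by $\mu$, and gating was chosen because the downstream
contingency-table statistics have no natural weighted form). Within a
cluster:

* a **continuous mode** is cut into three equal-frequency states `L`/`N`/`H`
  (the maximum-entropy partition of its empirical distribution, the right
  default when nothing else is known); cut-points sit halfway between
  adjacent boundary observations and ties never straddle a cut;
* every **other continuous member** is discretized by maximizing its
  interdependence redundancy with the mode's discrete codes: candidate
  boundaries are the midpoints between consecutive distinct sorted values,
  and for each interval count $q$ in $2..q_{\max}$ (default 3, matching the
  three-state modes at these sample sizes) the boundary subset maximizing
  $R(\text{intervals} : \text{mode})$ is found exactly, with ties toward
  fewer intervals. Segment contributions to $I$ and $H$ are precomputed from
  cumulative class counts, so each subset is scored in $O(q)$; when an
  attribute has more than `max_candidates` (default 200) candidate midpoints
  the candidate set is thinned to an equal-frequency-spaced subset of that
  size, a resolution of about half a percentile that is far finer than the
  two or three cuts being sought;
* **categorical members** pass through with their native symbols, and a
  categorical mode serves directly as the driving discrete variable.

Because clusters overlap, the same attribute may be discretized several
times, once per cluster it belongs to — that multiplicity is the point, and
duplicate discoveries are collapsed later by `merge_patterns()`, which keeps
the strongest instance of each identical event set and records all source
clusters.

## Pattern significance and rules

A candidate pattern is a conjunction of primary events $(G, \text{interval})$
from distinct attributes. Under independence its expected count is
$e = n \prod_i p_i$ with variance $v = e \prod_i (1 - p_i)$, and the
adjusted residual

$$d = \frac{o - e}{\sqrt{v}}$$

is asymptotically standard normal; for order 2 this is exactly the classical
adjusted residual of a two-way contingency cell, which is the conformance
test the implementation must pass. Patterns with $|d| \ge 1.96$ (95%
two-sided) and $e \ge 3$ are retained, orders 2..4 by default, level-wise
with a sound prune: an extension whose count ceiling (its parent's count)
cannot reach the threshold, and whose maximal under-representation cannot
either, is never evaluated. Significantly under-represented conjunctions are
recorded with negative sign but not grown and not used for rules. No
multiple-testing correction is applied by default, matching the benchmark
protocol; the type-I behaviour of the screen is itself under test (the
acceptance suite checks the null rate of $|d| \ge 1.96$ lands near nominal).

When class labels exist they are restored *after* discretization — the
pipeline-order test asserts that deleting the label column changes no
clustering, membership, discretization or pattern output. The class attribute
is appended as one more event column; significant positive class-conditioned
patterns become rules scored by the Laplace-smoothed weight of evidence

$$\mathrm{WofE} = \log_2
  \frac{P(\text{antecedent} \mid c)}{P(\text{antecedent} \mid \bar c)},$$

and a sample is classified by summing the evidence of its matched rules per
class, higher-order rules first, skipping any rule nested inside one already
counted, with ties going to the larger prior. Base 2 and +1/+K smoothing are
conventions; the base only scales the reported values.

## The synthetic benchmark generator

`generate_synthetic()` regenerates the package's reference dataset: 20
attributes — `A1`, `A2` in {T, F}; `A3`–`A5` in {X, Y, Z}; `A6`–`A20`
continuous on [0, 1] — with three planted attribute groups around `A1`
(driving `A7`–`A12`), `A13` (driving `A2`, `A3`, `A14`–`A20`) and `A6`
(driving `A4`, `A5`, itself conditioned on `A1` and `A13`, which is what
makes the third group genuinely overlap the first). Five sample classes of
sizes 500/300/300/400/300 are imposed through (`A1`, `A13`) combinations:
C1–C3 take `A1 = T` with `A13` in [0, 0.2), [0.2, 0.4), [0.4, 0.7); C4 and
C5 take `A1 = F` with `A13` in [0.7, 1] and [0, 0.5). The class-imposition
ranges are a documented reconstruction (the benchmark's original per-class
ranges are not recoverable), chosen to be mutually distinguishable and
consistent with every conditional attribute rule; they are overridable in
`generator_config()`. Finally 25% of tuples, chosen without replacement, have
all attribute values replaced by uniform draws over each attribute's domain;
class labels are kept, since the noise corrupts measurements, not sample
identity. The same seed reproduces the table bit for bit.

What the generator emulates: mixed continuous/categorical attributes, block
interdependence structure with a planted overlap, and heavy uninformative
noise. What it does not emulate: the heavy-tailed, platform-dependent
intensity distributions of real microarrays, gene-gene correlations that
decay smoothly rather than by block, and sample sizes in the dozens rather
than thousands. Green tests on this generator therefore demonstrate the
machinery — estimator correctness, search optimality, calibration, the
crisp-versus-fuzzy contrast — not performance on any real expression matrix.

## Numerical choices, in one place

* Bin count $m = \max(2, \lfloor\sqrt{|T|/\alpha}\rfloor)$, $\alpha = 3$;
  equal-frequency bins; ties to the lower bin. The bin-count rule is this
  package's reconstruction of an occupancy argument ("as many bins as the
  $\alpha$-per-cell guarantee allows") and is exposed as configuration.
* Logarithms base 2 everywhere; $R$ is base-invariant.
* SR comparisons at $10^{-12}$, ties toward smaller $k$; assignment ties to
  the lowest cluster index; MR ties to the lowest attribute index.
* Membership rows rescaled by their maximum before applying $1/(f-1)$.
* Interval convention half-open $[a, b)$, last interval closed; total over
  the real line so held-out samples always map somewhere.
* Candidate-boundary cap 200 per attribute in the cluster-driven
  discretization; exact search below the cap.
* Residual screen $|d| \ge 1.96$, $e \ge 3$; degenerate conjunctions
  (an always-true event, $v = 0$) return $d = 0$ flagged rather than NaN.
* Missing values are rejected at construction: every statistic here assumes
  complete contingency tables, and silent imputation would corrupt all of
  them.

## Problem sizes used by the test material

The unit suites run on purpose-built fixtures of 40–600 samples where
brute-force oracles (naive entropy sums, exhaustive partition and boundary
enumeration, the classical two-way residual) are affordable. The end-to-end
checks use the full 1800-sample benchmark for clustering, fuzzification and
pattern discovery, and a one-sixth-scale variant (300 samples, same
structure) for the train/test classification check, which is the package's
choice of a size where rule mining stays interactive.

## Limitations

* The redundancy scale depends strongly on the binning resolution: finer
  bins inflate the joint-entropy denominator and deflate every $R$, with two
  visible consequences on the bundled benchmark. First, cross-membership
  magnitudes after fuzzification sit on a different scale than coarser
  binnings would give. Second, SR-based selection of the cluster count can
  prefer splitting one strong cluster (choosing $k = 4$ over the planted
  $k = 3$ on a subset of generator seeds). Both behaviours are reported
  as computed by the acceptance material, not adjusted away; users analyzing
  their own data should treat `alpha` (and through it $m$) as a parameter
  worth a sensitivity check.
* SR model selection has no penalty term; it is a local heuristic with
  restarts, not a global optimum certificate (the exhaustive-equivalence
  test covers only small attribute counts).
* The significance screen is per-pattern; with thousands of candidate
  conjunctions the retained set contains the expected share of false
  positives unless the optional Bonferroni flag is applied to the threshold
  by the caller.
* Rule evaluation is post hoc by design; the package deliberately offers no
  way to feed labels into discretization, so a supervised-discretization
  baseline requires other tooling.
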