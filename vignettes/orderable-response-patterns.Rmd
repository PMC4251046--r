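---
title: "Inferring orderable response patterns from few-replicate multi-treatment experiments"
author: "OrderablePatterns authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring orderable response patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(OrderablePatterns)
```

# The model

An experiment measures the expression of each gene under K treatment
groups (the first group is the control by convention) with R replicates
per group. For one gene, each unordered pair of groups (A, B) is
compared by two one-sided Wilcoxon rank-sum tests, giving one of three
outcomes at a significance level $\alpha$: $A \prec B$ when the p-value
for $H_1: \mu_A < \mu_B$ is at most $\alpha$, $B \prec A$ for the
opposite tail, and a tie $A \sim B$ otherwise. The K(K−1)/2 outcomes
together are the gene's *pattern*, serialized as a ternary string (digit
0 = tie, 1 = first-of-pair less, 2 = second-of-pair less, pairs in
lexicographic label order).

Two working assumptions make patterns interpretable as orders:

1. a tie that would persist at any sample size means the gene responds
   identically to the two treatments, and
2. this "responds identically" relation is transitive.

Under these assumptions the sub-pattern
$\Delta = \{x \prec z,\ x \sim y,\ y \sim z\}$ is self-contradictory:
transitivity of the two ties forces $x$ and $z$ to respond identically,
against the strict outcome. A pattern containing $\Delta$ on any triple
is therefore an artifact of insufficient sampling, never a true order.

## Three orderability predicates

The package exposes three nested predicates, because the formal
definition and the $\Delta$-characterization are *not* equivalent:

* **`delta-free`** — no triple carries $\Delta$.
* **`tie-consistent`** (default) — for every tied pair, the two
  treatments have identical strictly-greater sets
  $G(t) = \{u: t \prec u\}$ and strictly-smaller sets
  $L(t) = \{u: u \prec t\}$. This is the formal definition of an
  orderable pattern.
* **`weak-order`** — the pattern is realizable by an integer ranking
  with ties, i.e. it is an ordered partition (tiers) of the treatments.

Every weak order is tie-consistent and every tie-consistent pattern is
delta-free, but both inclusions are strict. The pattern
$\{A \prec B, B \prec C, A \sim C\}$ is delta-free (only one tie, but
$\Delta$ needs two ties through a shared middle) yet not tie-consistent
($G(A) = \{B\} \ne \emptyset = G(C)$ despite $A \sim C$). A strict
3-cycle has no ties at all, so tie-consistency holds vacuously, yet no
ranking realizes it. Exhaustive enumeration over all K = 3 patterns
gives 13 weak orders (the ordered-set-partition number), 15
tie-consistent patterns and 21 delta-free ones, out of 27; the test
suite verifies the chain for K = 3 and K = 4 against brute-force
oracles.

Tie-consistency is the default because it is the method's stated
criterion; `weak-order` is provided for users who additionally want
strict cycles rejected (observed patterns on real replicate data
essentially never contain strict cycles, because the two one-sided
p-values of a rank-sum test sum to at least 1, making inconsistent
strict triples rare at moderate $\alpha$); `delta-free` is provided
because the forbidden-triple scan is the intuitive reading and users
may want to reproduce counts under either convention.

# The varying-$\alpha$ ladder search

The level $\alpha$ is a lens, not a law: lowering it turns strict
outcomes into ties and vice versa, and since the per-gene tests are
interdependent, a gene-specific level that produces an *orderable*
pattern is preferable to a fixed 0.05 that produces a contradictory
one.

Only levels equal to an observed directional p-value can change the
pattern, so the search scans the gene's *candidate ladder*: the sorted
unique values of $\min(p_{less}, p_{greater})$ over the pairs, capped
at $\alpha_{max}$ (default 0.5). At each rung the p-value table is
re-thresholded (no re-testing) and the first pattern that is orderable
and *non-trivial* — at least one strict outcome; an all-ties pattern is
orderable but says nothing — is returned with the rung used. If no
rung qualifies, failure is returned as a value.

Two details are deliberate design choices:

* **Inclusive thresholds** ($p \le \alpha$, not $p < \alpha$): the
  candidate levels are themselves observed p-values, and a strict
  inequality would make every rung unattainable. On any level grid that
  avoids the observed p-values (e.g. multiples of 0.01 here), the two
  conventions agree.
* **Extension mode** (`extensionMode = TRUE`): the default search scans
  the full ladder from its smallest rung, which can return an orderable
  pattern at a level *below* the base $\alpha$. In extension mode the
  base pattern is tried first and only rungs at or above $\alpha$ are
  scanned, which guarantees the result is an orderable extension of the
  base pattern (all its strict outcomes preserved). The summary curves
  use extension mode, since their distance statistics are defined
  against the base pattern; the plain search default matches the
  ladder-scan pseudocode. Both are exposed because the two readings
  genuinely differ and each is the right tool for one purpose.

Monotonicity of strict outcomes in $\alpha$ (a consequence of
$p_{less} + p_{greater} \ge 1$) implies the orderable fraction is
non-decreasing in $\alpha_{max}$ and extensions never lose strict
outcomes.

# Bootstrap multi-pattern assignment

A gene participating in several biological processes may genuinely
carry more than one plausible order. If the base pattern at
$\alpha = 0.05$ is already orderable it is returned with probability 1
(a conservative short-circuit). Otherwise, for each of M iterations
(default 1000), the replicates of every treatment group involved in at
least one tie of the base pattern are resampled with replacement
(groups with only strict involvements are left alone — their outcomes
are considered settled), a pattern is called on the perturbed data by
either the ladder search (default) or the fixed level, and the distinct
resulting patterns are tallied into frequencies. Iterations where the
ladder search fails count as an explicit "no-pattern" record so the
frequencies always sum to 1 over M; records below a reporting cutoff
`fMin` (default 0.05) are suppressed in pipeline outputs but retained
in the `PatternAssignment` object.

M and `fMin` are not prescribed by the method's description; 1000 gives
a frequency resolution of 0.001 at modest cost, and 0.05 suppresses
noise-level patterns. The per-gene RNG stream is derived
deterministically from the root seed and the gene's position in the
experiment, so results are reproducible and unchanged under gene
subsetting.

# Pipeline, clustering and summary statistics

Genes are first screened with a Kruskal–Wallis test across all K groups
(default level 0.05 on raw p-values; Benjamini–Hochberg adjustment is
available but off by default, since the screen is a pre-filter rather
than an inferential endpoint). Assignment then proceeds per gene; under
the one-pattern scheme, genes whose ladder search fails keep their
fixed-level pattern flagged non-orderable, so every gene lands in
exactly one bin and binning is total. Clusters are simply the bins of
identical pattern codes — a cluster label *is* a response order, which
is what makes these clusters biologically readable.

The summary curves report, per ladder cap $\alpha_{max}$: the fraction
of genes acquiring a non-trivial orderable pattern; $\mu(d_1)$, the
mean Hamming distance between each gene's base pattern and the pattern
the search found (0 for genes orderable at base, averaged over genes
with a successful search); and $\mu(d_2)$, the same mean restricted to
genes *not* orderable at base ($\ge 1$ by construction in extension
mode, and NA when the subset is empty).

The comparator is conventional average-linkage hierarchical clustering
on 1 − Pearson correlation of the K-length per-group mean-expression
vectors, cut to a requested number of clusters. A mean vector with zero
variance has undefined correlations; such a gene is placed at distance
0 from identical profiles and at the maximal distance 2 from everything
else — a deterministic rule that keeps the tree well-defined without
jitter.

# The synthetic-data generator

`simulateExperiment()` emulates the K-groups × R-replicates design with
a planted weak order per gene: a random dense tier assignment (or a
user-fixed one), tier m centred at $m\,\delta\,\sigma$, and i.i.d.
normal noise (lognormal optionally, for raw-scale data; all tests are
rank-based and indifferent to the transform). Defaults K = 4, R = 5
mirror the motivating study design; $\delta = 1.5\sigma$ is a
moderate-signal regime in which fixed-level patterns are frequently
non-orderable and the ladder search has real work to do, and was fixed
as the generator's study condition before any recovery measurement.

What the generator does *not* emulate: probe-level artifacts,
normalization residuals, correlated genes, heteroskedastic or heavy-
tailed noise. Passing recovery tests on this generator therefore show
the algorithmic contracts (monotonicity, extension property, bootstrap
bookkeeping, recovery ordering) — not that the method's error rates
transfer to any particular microarray platform.

Two statistical facts shape what tests may honestly assert:

* Even at huge separation ($\delta = 10\sigma$), a *tied* pair of the
  planted truth is reproduced only with probability
  $\approx 1 - 2\tilde\alpha$, where $\tilde\alpha$ is the attainable
  size of the one-sided exact rank-sum test (12/252 ≈ 0.048 per
  direction at R = 5). Separation protects strict pairs only, so exact
  whole-pattern recovery is guaranteed only for planted chains.
* Under a null effect, each *directional* test fires at rate
  $\tilde\alpha \le \alpha$; the rate of non-tie outcomes per pair
  approaches $2\alpha$ because every pair runs two one-sided tests. The
  calibration checks therefore count strict calls per directional
  hypothesis.

# Numerical and degenerate-input choices

* Exact rank-sum tail when the pooled sample is at most 20 values with
  no ties; tie-corrected normal approximation with continuity
  correction otherwise. Both deterministic; the exact branch is
  verified against full rank-split enumeration for all group sizes up
  to 5.
* An all-identical pooled sample returns p = 1 (no directional
  evidence); an all-constant gene gets Kruskal–Wallis p = 1 and is
  never selected; genes with missing values are excluded from selection
  with a warning.
* At $\alpha > 0.5$ both one-sided tests can pass; the first-of-pair
  direction is checked first. `algoConfig()` warns when
  $\alpha_{max} > 0.5$.
* Ladder candidates are capped inclusively at $\alpha_{max}$.
* Pattern codes fix the pair order (lexicographic by label position)
  and digit meanings (0/1/2 = tie/first-less/second-less); the
  convention is part of the serialization contract and round-trips
  exactly.
* Test problem sizes (500 genes for monotonicity, 300 for recovery,
  M = 200 for bootstrap contracts) keep the full suite under a minute
  while leaving the stochastic assertions well-powered.

# Known limitations

* The varying-$\alpha$ procedure is deliberately heuristic: it controls
  no family-wise error across the dependent pairwise tests, and an
  orderable pattern is *plausible*, not *certified* — at
  $\alpha_{max} = 0.5$ every gene receives some orderable pattern.
* Tie-consistency admits strict cycles (vacuously); users wanting
  ranked tiers in all cases should select the `weak-order` predicate.
* The bootstrap resamples R values with replacement from R; at R = 5
  the resampling distribution is coarse, and reported frequencies
  should be read as rough plausibilities rather than calibrated
  posterior probabilities.
* The Kruskal–Wallis screening level for the motivating study is not
  recorded in its description; 0.05 on raw p-values is assumed, and
  replication counts depend on that choice and on which orderability
  predicate the original analysis used.
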