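# OrderablePatterns

Infer the true *order* of gene response to multiple treatments from
experiments with very few replicates.

## The problem and the method

A typical multi-treatment expression study measures K treatment groups
(one of them a control) with a handful of replicates each — e.g. 4
groups × 5 replicates. For each gene and each of the K(K−1)/2 treatment
pairs (A, B), a directional Wilcoxon rank-sum test yields one of three
outcomes: A ≺ B (the gene responds more to B), B ≺ A, or A ~ B
(statistically indistinguishable). The collection of all pairwise
outcomes is the gene's **response pattern**.

Not every observable pattern can be a true response order. If ties
reflect genuine equivalence of treatments (and equivalence is
transitive), then the sub-pattern

    Δ = { x ≺ z,  x ~ y,  y ~ z }

— two ties through a middle treatment bridging a strict outcome — is
contradictory: it can only arise from insufficient sampling. A pattern
is **orderable** when every tied pair of treatments has identical
strictly-greater sets G(t) = {u : t ≺ u} and strictly-smaller sets
L(t) = {u : u ≺ t}; orderable patterns are the plausible true orders,
and true orders realizable as ranked tiers are exactly the weak orders
(ordered set partitions) of the treatments.

Because the K(K−1)/2 tests per gene are interdependent, the
significance level α need not be fixed at 0.05. The package scans the
gene's **α ladder** — the sorted unique minimal directional p-values —
and returns the pattern at the smallest level that is orderable and has
at least one strict outcome. Any such pattern found at a level above
the base α is an **orderable extension** of the base pattern: it
preserves every strict outcome already observed and only resolves ties.
Where several patterns are nearly equally plausible, a bootstrap over
the replicates of tie-involved treatment groups assigns **multiple
patterns per gene** with frequencies. Genes are then binned by pattern
code (a ternary string such as `011110`, one digit per pair), which
makes clusters directly interpretable as response orders, and the
structural distance d(P, Q) — the Hamming count of differing pairwise
outcomes — summarizes how much the ladder search changed each pattern.

## Worked example

The six directional p-values of the four-treatment illustration (A–D):

```r
library(OrderablePatterns)

pv <- data.frame(
    first  = c("A", "A", "A", "B", "B", "C"),
    second = c("B", "C", "D", "C", "D", "D"),
    p_less = c(0.45, 0.03, 0.055, 0.03, 0.03, 0.45),
    p_greater = c(0.55, 0.97, 0.945, 0.97, 0.97, 0.55))

(base <- patternAtAlpha(pv, LETTERS[1:4], 0.05))
#> Pattern on 4 treatments (A, B, C, D), code 010110
#>   not realizable as a weak order
isOrderable(base)
#> [1] FALSE
```

At the conventional 0.05 level the gene's pattern is
{A~B, A≺C, A~D, B≺C, B≺D, C~D} — it contains Δ (take x = A, y = D,
z = C: A≺C with A~D and D~C) and cannot be a true order. Raising the level
just past the next ladder rung (0.055) rescues it:

```r
alphaLadder(pv)
#> [1] 0.030 0.055 0.450
rescued <- patternAtAlpha(pv, LETTERS[1:4], 0.06)
patternCode(rescued); patternTiers(rescued)
#> [1] "011110"
#> [[1]] "A" "B"
#> [[2]] "C" "D"
```

The rescued pattern orders the treatments as {A,B} ≺ {C,D} at the cost
of a single changed outcome (`patternDistance(base, rescued)` is 1).

The same machinery runs over a whole experiment. On synthetic data with
planted weak orders (4 groups × 5 replicates, tier spacing 1.5 σ):

```r
sim <- simulateExperiment(nGenes = 50, delta = 1.5, seed = 1)
sel <- selectGenes(sim$experiment)          # Kruskal-Wallis screen
asg <- assignPatterns(sim$experiment, algoConfig(seed = 1),
                      scheme = "one_pattern", genes = sel)
summaryCurves(sim$experiment, c(0.05, 0.15, 0.5), genes = sel)
#>   alpha_max fraction_orderable     mu_d1    mu_d2
#> 1      0.05          0.5714286 0.0000000       NA
#> 2      0.15          0.9142857 0.4062500 1.083333
#> 3      0.50          1.0000000 0.4571429 1.066667
```

Read: 57% of the screened genes are orderable at the base level; capping
the ladder at 0.15 rescues 91%, and at 0.5 all of them, changing on
average 0.46 of the 6 pairwise outcomes per gene — and about 1.1
outcomes among the genes that actually needed rescuing (`mu_d2`), i.e.
roughly one added strict outcome turns a non-orderable pattern into an
orderable one.

A command-line front-end wraps the same functions:

```sh
orderpat simulate --genes 200 --K 4 --R 5 --seed 1 --out sim/
orderpat select   --matrix sim/matrix.tsv --design sim/design.tsv --out sel/
orderpat assign   --matrix sim/matrix.tsv --design sim/design.tsv \
                  --scheme multi --M 1000 --seed 1 --out asg/
orderpat curves   --matrix sim/matrix.tsv --design sim/design.tsv \
                  --alpha-grid 0.05,0.075,0.15,0.5 --out curves/
```

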