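# degent — degree-based graph entropy descriptors for QSPR modelling

`degent` computes the *k*-th degree-based graph entropy of
hydrogen-suppressed molecular graphs and puts it to work in quantitative
structure–property relationship (QSPR) modelling. It is aimed at
mathematical chemists and cheminformaticians who want a degree-only
information-theoretic descriptor alongside the classical degree-based
topological indices, with the regression machinery to compare them on
benchmark property data.

## The descriptor

For a connected graph *G* on *n* vertices with vertex degrees
*d*₁, …, *d*ₙ, normalizing the *k*-th powers of the degrees gives a
probability distribution over the vertices, and its Shannon entropy (in
nats) is the *k*-th degree-based entropy

> *I*₍d,k₎(*G*) = −Σᵢ (dᵢᵏ / Σⱼ dⱼᵏ) · ln (dᵢᵏ / Σⱼ dⱼᵏ).

The case *k* = 2 — the **second-degree-based entropy** — is the headline
descriptor: its normalizer Σ dᵢ² is the first Zagreb index *M*₁. The value
always lies in [0, ln *n*], attaining ln *n* exactly for regular graphs or
*k* = 0, and it depends only on the degree multiset, so it is invariant
under isomorphism and identical across molecules sharing a degree
sequence.

For comparison the package also computes *M*₁, *M*₂ (second Zagreb), *F*
(forgotten index, Σ d³), ISI (inverse sum indeg), SDD (symmetric division
degree), SCI (sum connectivity) and RR (reciprocal Randić, Σ √(d_u d_v)),
plus simple-OLS fits reported the QSPR way: slope and intercept with
±2·SE uncertainties, R², residual SE, the regression *F* statistic and its
significance.

## Worked example

```r
library(degent)

## the most branched octane isomer, 2,2,3,3-tetramethylbutane
oct <- loadFixture("octane")
g <- fixtureStructures(oct)[["C8:18"]]
g
#> MolecularGraph 'C8:18': 8 vertices, 7 edges
#>   degree multiset: 1^6 4^2

round(indexSuite(g, k = 2), 4)
#>     Id_k       M1       M2        F      ISI      SDD      SCI       RR
#>   1.3028  38.0000  40.0000 134.0000   6.8000  27.5000   3.0368  16.0000

## regress the acentric factor on Id,2 recomputed from the structures
x <- vapply(fixtureStructures(oct)[oct$name], degreeEntropy, 0, k = 2)
fitSimpleOLS(x, oct$AF)
#> P = 0.2005(+/-0.0265) I + 0.002576(+/-0.0442)
#>   R2 = 0.9347, SE = 0.009343, F = 229.0318, SF = 6.69e-11, n = 18

## a correlation study that needs no external data at all:
## enumerate every decane isomer and correlate Id,2 with M1 and F
decanes <- enumerateAlkanes(10)   # all 75 trees on 10 vertices, max degree 4
idx <- computeIndexTable(decanes)
round(abs(pearsonR(idx$Id_k, idx$M1)), 3)   #> 0.993
round(abs(pearsonR(idx$Id_k, idx$F)), 3)    #> 0.994
```

The entropy 1.3028 nats is the lowest among the 18 octanes (heavy
branching concentrates degree weight on two quaternary carbons), and the
acentric-factor fit shows the strong linear relationship — 93% of the
variance explained with a residual SE under 0.01 — that makes the
descriptor interesting. The near-unit correlations with *M*₁ and *F* over
the complete decane set quantify how closely the entropy tracks the degree
power sums it is built from.

Bundled datasets: `loadFixture("octane")` (18 isomers: entropy S, HVAP,
DHVAP, acentric factor, with edge-list structures), `loadFixture("bhc")`
(21 benzenoid hydrocarbons: boiling point, π-electron energy; structures
for the three identifiable members) and `loadFixture("drug")` (16
drug-related compounds: boiling point, molar refraction).
`reproduceReference(target)` recomputes any bundled reference table or
regression and diffs it cell by cell; `availableTargets()` lists them.

A command line ships in `exec/degent` with subcommands `compute`
(structure file → index CSV), `enumerate`, `fit` (CSV → fit JSON, with
optional train/test split) and `reproduce`.

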