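---
title: "Degree-based graph entropy as a QSPR descriptor: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Degree-based graph entropy as a QSPR descriptor: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degent)
```

## The model

Every descriptor in `degent` is a function of the degree sequence of a
hydrogen-suppressed molecular graph: a simple, connected, undirected graph
whose vertices are heavy atoms and whose edges are bonds. Element
identity, bond order, charge and geometry are parsed (when a SMILES reader
is used) and then discarded; this is a modelling assumption, not a
simplification of convenience — the entropy under study is *defined* on
the skeleton, and keeping chemical annotation around would only suggest a
sensitivity the descriptor does not have.

For degrees $d_1,\dots,d_n$ and a real exponent $k$, normalizing the
$k$-th degree powers gives vertex probabilities
$\alpha_i = d_i^k / \sum_j d_j^k$, and the $k$-th degree-based entropy is
their Shannon entropy in natural-log units:

$$
I_{d,k}(G) \;=\; -\sum_{i=1}^{n} \alpha_i \ln \alpha_i
\;=\; \ln\!\Big(\sum_j d_j^k\Big) \;-\;
\frac{\sum_i d_i^k \ln d_i^k}{\sum_j d_j^k}.
$$

The second form is an exact algebraic identity used as a test oracle (the
two evaluations must agree to $10^{-10}$), not as the implementation.
Properties that follow directly and are enforced as tests: the value lies
in $[0, \ln n]$; it equals $\ln n$ exactly when the graph is regular or
$k = 0$; it depends only on the degree multiset; and it is invariant under
vertex relabelling. Because every vertex of a connected graph on
$n \ge 2$ vertices has degree at least 1, $d^k$ is well-defined for
negative and fractional $k$ too; `k` is an ordinary numeric parameter with
default 2, the case whose normalizer is the first Zagreb index and the one
the bundled datasets exercise.

### Logarithm base

The entropy is computed in nats. The base is a genuine design decision —
entropies are reported in the literature in base 2, e, and 10 — and it was
settled analytically: only the natural log reproduces the tabulated
octane value 1.9784 for the 8-vertex path (base-2 gives 2.8544, base-10
gives 0.8592). The choice is frozen in the code and in the acceptance
tests; no base argument is exposed, because a silently different base
would make every bundled reference value wrong.

### The comparison indices

`indexSuite()` adds the classical degree-based panel: $M_1 = \sum d^2$,
$F = \sum d^3$ (vertex sums, hence degree-sequence-determined like the
entropy), and the edge sums $M_2$, ISI, SDD, SCI, RR. One definition
required a decision: "inverse Randić" (RR) is implemented as the
*reciprocal* Randić index $\sum_{uv} \sqrt{d_u d_v}$, the standard reading
of the symbol. The decane correlation study supports this empirically —
the reciprocal form reproduces the tabulated correlation (0.96) where a
negative-exponent generalized Randić does not — but the definition rests
on the conventional usage, not on that observation.

## Alkane isomer enumeration

Constitutional isomers of the alkane C$_n$H$_{2n+2}$ correspond to
unlabeled trees on $n$ vertices with maximum degree 4. `enumerateAlkanes()`
produces exactly one representative per isomorphism class by leaf
augmentation: every tree on $m$ vertices extends to trees on $m+1$
vertices by attaching a leaf at each vertex of degree below the cap, and
duplicates are removed by canonical code. The method is exact because
deleting a leaf from a degree-capped tree leaves a degree-capped tree, so
level $m$ generates all of level $m+1$.

The canonical code is a centroid-rooted AHU parenthesis string. Trees have
one or two centroids; with two, the lexicographically smaller rooted code
is taken — a label-independent tie-break, since isomorphisms map centroid
sets to centroid sets. Codes decode back to representative trees
(`decodeCanonicalCode()`), and output is sorted by code so downstream
correlation studies are reproducible bit for bit.

Correctness is tested two independent ways: against a brute-force oracle
(decode every Prüfer sequence, deduplicate with igraph's BLISS canonical
labelling) live for $n \le 7$, and against the known class counts for
$n = 8, 9, 10$ — 23 unrestricted trees at $n = 8$, and 18 / 35 / 75
degree-capped classes at $n = 8, 9, 10$ (the $n = 8$ counts were also
verified with the same oracle once; running a quarter-million labelled
trees through it on every test run adds nothing). The enumeration accepts
$n \le 20$; problem sizes in the tests and the acceptance study stop at
decane ($n = 10$, 75 classes), which is the full study the bundled data
support.

## Regression machinery

`fitSimpleOLS()` is ordinary least squares via `stats::lm()`, repackaged
into the report conventional in QSPR work: coefficients with uncertainties
quoted as $\pm 2 \cdot$SE, $R^2$, residual standard error
$\sqrt{\mathrm{RSS}/(n-2)}$, the regression $F$ with $(1, n-2)$ degrees of
freedom, and its exact upper-tail $p$-value (SF). Two identities of simple
regression, $F = (n-2)R^2/(1-R^2)$ and $F = (C_1/\mathrm{SE}_{C_1})^2$,
are asserted on random fits as a guard against report-assembly mistakes.
`trainTestSplit()` draws the train set uniformly without replacement
(ceiling of $n \cdot$ fraction, default 0.8) as a deterministic function
of its seed, and `validateOnTest()` reports the squared Pearson
correlation between predictions and held-out observations.

## Bundled data and the reference reports

Three fixtures ship as plain CSV plus edge-list files, with an MD5
manifest checked at load:

* **octane** — 18 isomers with entropy S (J K⁻¹ mol⁻¹), enthalpy of
  vaporization HVAP and standard enthalpy of vaporization DHVAP
  (kJ mol⁻¹), acentric factor AF (dimensionless), tabulated $I_{d,2}$, and
  full structures. The row-to-structure mapping follows the conventional
  isomer ordering (n-octane; the methylheptanes; 3-ethylhexane; the
  dimethylhexanes; the ethylpentanes; the trimethylpentanes;
  2,2,3,3-tetramethylbutane). Recomputing $I_{d,2}$ from the structures
  validates the mapping class by class; conclusions that depend on the
  mapping are restricted to degree-sequence-determined quantities
  ($I_{d,2}$, $M_1$, $F$), which are invariant to any within-class
  permutation of rows.
* **bhc** — 21 benzenoid hydrocarbons with boiling point (°C) and
  π-electron energy (units of $\beta$). The source table's header order
  contradicts the magnitudes of its columns; recomputation on the three
  structurally identifiable members (naphthalene 2.2338; phenanthrene and
  anthracene both 2.5603, sharing the degree multiset $\{2^{10}, 3^4\}$)
  proves the first numeric column is $I_{d,2}$, the second BP, the third
  $E_\pi$. The fixture stores the corrected roles. The remaining 18
  structures are not recoverable from the data, so their entropies are
  carried as tabulated values.
* **drug** — 16 drug-related compounds with boiling point (°C) and molar
  refraction (cm³ mol⁻¹); no structures, entropies as tabulated.

`reproduceReference()` recomputes each reference block and diffs it cell
by cell at fixed tolerances: $10^{-4}$ for entropies (tabulated to 4
decimals; one octane value is known to be one unit low in its last digit),
one unit in the last tabulated digit for coefficients, correlations and
$R^2$ (the reference tables mix round-half-up with truncation at the final
digit, so demanding strict round-to-printed equality would reject correct
arithmetic), 1% relative for $F$ statistics (the reference $F$ values
derive from differently rounded intermediates), and 5% relative for SF
(tabulated to 2 significant figures). One reference cell is excluded from
comparison: the benzenoid boiling-point fit's intercept uncertainty as
tabulated is inconsistent with its own fit (it appears to duplicate the
slope pattern) and no rounding explains it.

## The synthetic generator

`generateSyntheticRegression()` emulates the structure of the octane
acentric-factor study: $n = 18$ records, descriptor values uniform on
$[1.30, 1.98]$ (the observed octane $I_{d,2}$ range), and
$y = 0.2x + 0.003 + \varepsilon$ with $\varepsilon \sim N(0, 0.0108^2)$.
The noise level was fixed once, analytically, so the population $R^2$ is
about 0.93, matching the real study: with
$\mathrm{Var}(x) = 0.68^2/12$, solving
$R^2 = \beta^2\mathrm{Var}(x) / (\beta^2\mathrm{Var}(x) + \sigma^2)$
for $R^2 = 0.93$ gives $\sigma \approx 0.0108$.

What the generator emulates: the sample size, descriptor range, effect
size and noise-to-signal ratio of a small QSPR calibration. What it does
not: real descriptor values are neither uniform nor tie-free (octane
$I_{d,2}$ takes only 7 distinct values across 18 isomers), property
measurement errors are not homoscedastic Gaussian, and descriptor and
property are jointly determined by structure rather than by a causal
linear map. Passing parameter-recovery tests therefore demonstrates the
regression machinery is calibrated — not that the linear model is the
right model for any particular property.

One statistical subtlety in the recovery test: the acceptance band
$|\hat\beta - \beta| \le 3\,\widehat{\mathrm{SE}}$ uses the *estimated*
standard error, so per-replicate coverage is
$P(|t_{16}| \le 3) = 0.9916$, not the Gaussian 0.9973. Over 1000 seeded
replicates the hit count is therefore asserted above the 0.001 binomial
quantile of that coverage (981), the analytically correct formulation of
"at least 99% recovery" for a finite Monte-Carlo sample.

## Degenerate inputs and numerical choices

* Graphs must be connected and simple; disconnected input (including
  dot-separated SMILES) is rejected, never analyzed per component.
* The entropy requires $n \ge 2$ (all degrees $\ge 1$). The two-vertex
  tree is regular, so $I_{d,k} = \ln 2$ for every $k$. Single-vertex
  graphs exist only as the $n = 1$ enumeration base case.
* `shannonEntropy()` rejects nonpositive weights outright rather than
  adopting the $0 \ln 0 = 0$ convention: a zero degree power cannot arise
  from a valid graph, so a zero weight signals caller error.
* Probability normalization is checked to $10^{-8}$; descriptor values
  are kept at full double precision internally and rounded (half-even, via
  `round()`) only at the reporting boundary — 4 decimals for entropies, 3
  for correlations, 6 significant digits in CSV output.
* Random tree generation rejects Prüfer draws violating the degree cap,
  so classes are sampled with probability proportional to their number of
  labelings — adequate for property tests (every class is reachable; a
  membership test confirms all 18 octane classes appear), but not a
  uniform sampler over isomorphism classes.

## Interfaces and limitations

The R functions are the primary interface; a thin CLI (`exec/degent`,
subcommands `compute`, `enumerate`, `fit`, `reproduce`) wraps them for
shell use with explicit seeds and deterministic output. A config-file
option was considered and dropped: every behaviour is reachable by flag,
and a second configuration channel would only complicate reproducibility.

Known limitations: no stereochemistry, aromaticity perception, valence
checking or 3D information (out of scope by design — the descriptor uses
none of them); enumeration beyond $n = 20$ is refused (class counts grow
exponentially and the pure-R canonicalizer is not built for it);
train/test splitting supports one random split, not cross-validation
schemes; and external-validation numbers for data that ship without
structures or properties cannot be recomputed, only the machinery for
them is provided and tested on synthetic data.
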