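---
title: "Phylogenetic profiling with distance correlation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylogenetic profiling with distance correlation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profcor)
```

## The model

Proteins that act together — in the same metabolic pathway or the same
complex — tend to be jointly retained or jointly lost over evolution.
Phylogenetic profiling turns this into a prediction method: describe each
protein of a query genome by a vector over a reference set of genomes, and
call similar vectors evidence of functional or physical interaction.

`profcor` uses graded rather than binary profiles. For a query protein $p$
and reference genome $g$, let $E_{pg}$ be the best (smallest) E-value of any
alignment of $p$ against the proteins of $g$. The profile entry is

$$P_{pg} = -\frac{1}{\log_{10} E_{pg}},$$

capped at 1 whenever $E_{pg} > 10^{-1}$ and when no hit exists at all.
Small E-values (strong homology) give small $P$; the cap makes $P = 1$ the
single "no significant homolog" state, and the transform is continuous at
the cutoff since $-1/\log_{10}(0.1) = 1$. E-values of exactly zero —
alignment tools emit `0.0` on underflow — are clamped to a configurable
floor (default $10^{-200}$, hence a minimum profile value of $0.005$)
before taking the logarithm.

## Similarity measures

Given two profiles $A_p, A_q \in (0,1]^j$ over $j$ genomes, three measures
of dependence are implemented.

**Distance correlation.** For one profile, form the $j \times j$ matrix of
absolute pairwise differences $d_{kl} = |a_k - a_l|$ and double-center it:

$$da_{kl} = d_{kl} - \bar d_{k\cdot} - \bar d_{\cdot l} + \bar d_{\cdot\cdot},$$

so every row and column of $DA$ sums to zero. The score for a pair of
proteins is the entrywise covariance-to-variance ratio of their centered
matrices,

$$\mathrm{dCor}_{pq} = \frac{\mathrm{Cov}(DA_p, DA_q)}
  {\sqrt{\mathrm{Var}(DA_p)\,\mathrm{Var}(DA_q)}},$$

with $\mathrm{Cov}$ and $\mathrm{Var}$ plain means over all $j^2$ entries
(the population $j^2$ denominators cancel in the ratio, matching the
V-statistic algebra). Because the centered matrices have zero grand mean,
no further mean subtraction is needed. This ratio is algebraically the
**square** of the classical sample distance correlation of Székely's energy
statistics; the test suite verifies the identity against an independent
V-statistic oracle at $10^{-10}$. We compute the ratio as the package's
native score and expose `root = TRUE` for the classical scale. Distance
correlation detects arbitrary — including non-monotone — dependence, which
is the reason to prefer it over linear correlation for profile comparison.

**Pearson correlation** on the raw probability values, used signed (the
ROC sweep covers $[-1, 1]$); an absolute-value treatment can be obtained by
transforming the matrix before benchmarking.

**Mutual information** $MI(A,B) = H(A) + H(B) - H(A,B)$ with plug-in
entropies over binned values, natural logarithm, and $0 \cdot \ln 0 = 0$.
Bins are half-open $[0, 0.1), \ldots$ with the last bin closed at 1, so the
very common value 1 bins deterministically. The self-score reported on the
diagonal is $H(A)$, unnormalized, directly from the defining equation.

### Numerical conventions

* A constant profile has zero-variance centered distances; any pair
  involving one scores 0 and is flagged `degenerate` rather than raising an
  error, so one flat profile cannot abort a genome-scale run. The variance
  threshold is $10^{-24}$.
* Similarity matrices are computed on the upper triangle and mirrored, so
  symmetry is exact, not approximate.
* dCor is clipped implicitly by its algebra to $[0, 1]$ up to rounding;
  property tests assert $[-10^{-9}, 1 + 10^{-9}]$ over random inputs.

## The blocked engine

The all-pairs computation is memory-bound: $i$ centered $j \times j$
matrices need $i j^2$ doubles. The engine therefore splits the profile
matrix into $N$ contiguous row chunks (sizes differing by at most one),
computes each chunk's centered matrices once, and persists them to a
repository — one `.rds` file per chunk (R's native serialized container,
version 2, uncompressed) plus a human-readable TSV manifest with md5
checksums and a format-version header. Manifest updates are atomic (temp
file then rename), so an interrupted store leaves the repository valid.

Assembly streams chunk *pairs* back in a fixed order (upper triangle of
chunk blocks, row-major), so at most two chunks are resident at once; the
covariance block of a chunk pair is a single cross-product of the flattened
centered matrices. Workers parallelize the chunk-pair map, but blocks are
combined in the same fixed order regardless of scheduling, so the result is
independent of both $N$ and the worker count — the test suite checks
equality with the serial computation at $10^{-12}$ across chunkings and
worker counts. $N$ is user-chosen; correctness never depends on it.

## Gold standards

Functional true positives are all pairs of proteins co-occurring in at
least one pathway. Physical true positives come from a curated interaction
pair list (two-column text; extra columns such as confidence scores are
ignored, with no score filtering applied). True negatives use a pathway
graph: pathways are nodes and two pathways are joined when they share at
least one protein — the only inter-pathway signal a membership table
carries; the shared-protein threshold is exposed as `min_shared`. A protein
pair is a true negative when the minimum shortest-path distance over all
pathway pairs containing them is at least 5 (`min_dist`). Three boundary
choices, logged in the output provenance so alternatives can be compared:

* multi-pathway proteins use the *minimum* pathway-pair distance — the most
  conservative rule for declaring non-interaction;
* unreachable pathway pairs (infinite distance) satisfy the criterion;
* unannotated proteins are excluded from TN candidacy: absence of
  annotation is not evidence of non-interaction.

Pairs appearing in both sets stay positive. Shortest paths are computed
with igraph; tests cross-check them against a walk-enumeration oracle.

## Benchmarking

Higher similarity means predicted interaction, for all three metrics. The
ROC curve is traced at thresholds descending in fixed steps of 0.1 score
units over the metric's range ($[0,1]$ for dCor, $[-1,1]$ for PC,
$[0, \lceil \max/0.1 \rceil \cdot 0.1]$ for MI), always anchored at
$(0,0)$ and $(1,1)$. The area is the trapezoid sum

$$AUC = \tfrac12 \sum_i (X_i - X_{i-1})(Y_i + Y_{i-1})$$

over false-positive rate $X$ and true-positive rate $Y$. (A Gini-style
pairing of $(X_i - X_{i-1})$ with $(Y_i + Y_{i+1})$ cannot be evaluated at
the curve boundary; the trapezoid form is the standard reading and is what
we implement.) On the exact, unbinned step curve this area equals the
normalized Mann–Whitney statistic, which the tests verify at $10^{-12}$;
the 0.1-binned area approaches it as samples grow.

Ten-fold cross-validation partitions the labeled pairs uniformly at random
— unstratified, as is usual when classes are plentiful — into ten
near-equal subsets and computes the binned AUC on each. If a draw leaves
some fold single-class it is redrawn up to a retry limit, then a stratified
partition is used and flagged in the report. All randomness flows from one
mandatory seed, and `compare_metrics()` refuses to compare reports whose
fold assignments or pair sets differ.

## The synthetic generator

`simulate_profiles()` emulates the study inputs without any database. Each
interacting module draws one latent genome-occupancy vector
$u \sim U(0,1)^j$; the module's first member carries $u$ itself and every
further member carries $T(u)$, where $T$ is the dependence transform:
identity (linear), $u^2$ (monotone-nonlinear), or the parabola $4u(1-u)$
(non-monotone — essentially uncorrelated with $u$, yet fully dependent,
the regime where distance correlation should win). Members are mixed as
$s \cdot \text{signal} + (1-s) \cdot U(0,1)$ at strength $s$, perturbed
with Gaussian noise, and clipped to $[10^{-6}, 1]$. Background proteins
are i.i.d.: value 1 with probability `absence_rate` (default 0.5, since
real profiles are absence-heavy), else uniform.

Placing the latent vector itself on the first member is deliberate: if all
members carried the same $T(u)$ they would be near-duplicates and *every*
metric would score them perfectly, which tests nothing. With the
latent/transformed split, a sample pair can have high dCor with low |PC|
under the non-monotone transform — note that exactly $\mathrm{dCor} = 1$
with $|PC| < 1$ is impossible for sample vectors, since sample dCor reaches
1 only for affine relations; the tests therefore assert a strong
*separation* (squared dCor far above the $\sim 1/j$ independence
background, |PC| small) rather than an unattainable equality.

`profiles_to_evalue_table()` emits the 12-column tabular hit lines that
invert the transform exactly ($E = 10^{-1/P}$; entries equal to 1 emit no
line), so the full parser-to-profile path is testable as a round trip.
Values below $0.005$ cannot be represented as double-precision E-values
($10^{-1/P}$ underflows); they are clamped to the floor and counted.
`simulate_pathways()` turns each module into one pathway (modules share no
proteins, so module pathways are mutually unreachable and between-module
pairs become true negatives) and adds decoy pathway chains whose
within-chain distances are known by construction.

The generator does **not** emulate phylogenetic realism: no gene gain/loss
process on a tree, no lineage correlation among genomes, no shared
evolutionary covariance between unrelated proteins. Passing benchmarks on
synthetic data therefore demonstrate the machinery's correctness and the
nonlinear-dependence advantage of dCor, not performance on real genomes,
where reference-set composition and tree structure matter.

## Default study conditions and problem sizes

The default `simulation_spec()` — 280 proteins of which 40 modules of size
2, 100 genomes, non-monotone dependence, strength 0.9, noise 0.1, absence
rate 0.5 — defines the package's reference synthetic benchmark: strong but
noisy planted dependence of the kind linear correlation misses, at a scale
(a few hundred proteins) where a full pipeline run takes about a second.
The test suite exercises this benchmark over ten seeds and checks that the
cross-validated median AUC of dCor exceeds Pearson's in at least eight of
the ten; oracle comparisons use 200 random pairs of lengths 5–50, range
checks 1,000 pairs, and the blocked-vs-serial check a 30 × 20 matrix over
four chunkings and two worker counts.

## Known limitations

* The dCor score is the squared classical distance correlation; when
  comparing numbers with energy-statistics software, use `root = TRUE`.
* MI uses fixed-width plug-in binning with no bias correction; its scale
  depends on the bin width and is not comparable across widths.
* The pathway-graph edge rule (share ≥ 1 protein) is the only definition a
  bare membership table supports; richer pathway topologies would justify
  other rules, which is why `min_shared` and `min_dist` are configuration.
* The blocked engine stores full $j \times j$ centered matrices; a
  symmetric-packed layout would halve the repository size and is a noted
  optimization, not implemented since correctness is oracle-checked either
  way.
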