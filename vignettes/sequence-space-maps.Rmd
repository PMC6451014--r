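---
title: "Sequence-space maps: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-space maps: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protspace)
```

`protspace` turns an aligned protein family into a low-dimensional map
in which inter-point distances approximate evolutionary distances, with
a phylogeny drawn over the points. This vignette is the package's own
account of the models it fits, the algorithms it uses, the parameters
that matter, and the choices made where more than one defensible design
existed.

## The substitution model and pairwise distances

Amino-acid replacement is modelled as a reversible continuous-time
Markov process. The package ships the classic Dayhoff empirical model as
a text table (PAML `dayhoff.dat` layout: 190 lower-triangle
exchangeabilities $S_{ab}$ plus 20 stationary frequencies $\pi$).
`dayhoff_model()` assembles the generator

$$Q_{ab} = s\,S_{ab}\,\pi_b \;(a \ne b), \qquad
  Q_{aa} = -\sum_{b \ne a} Q_{ab},$$

with $s$ chosen so that $-\sum_a \pi_a Q_{aa} = 1$. With this unit-mean
normalization, divergences are in expected substitutions per site —
the scale on which tree branch lengths and "changes per residue" scale
bars live, and the scale the PAM series parameterizes (PAM250 is the
same process observed at high divergence). Transition matrices
$P(t) = e^{Qt}$ are computed by eigendecomposition of the
$\pi$-symmetrized generator, which is exact for a reversible model and
stable at any divergence, unlike truncated series.

The pairwise maximum-likelihood distance maximizes
$\ell(t) = \sum_{\text{sites}} \ln(\pi_{a_s} P_{a_s b_s}(t))$ over the
columns where both sequences carry an unambiguous residue. $\ell$ is
smooth and in practice unimodal; the optimizer is a bounded
one-dimensional search on $[0, d_{\max}]$: a 40-point coarse scan
(always including the Poisson estimate $-\ln(1-p)$ as a candidate)
brackets the optimum, and golden-section/parabolic refinement finishes
to an absolute tolerance of $10^{-6}$ on $t$. A brute-force likelihood
grid (step $10^{-3}$) serves as the oracle in the test suite, guarding
against multimodality ever mattering in practice.

Parameters and defaults:

* `gap_policy = "pairwise_deletion"` — each pair uses every column where
  neither member has `-` or `X`; this is the protdist behavior.
  `complete_deletion` removes a column for all pairs if any row has a
  gap there. The choice matters for patchily gapped alignments; for
  curated domain alignments the two rarely differ much.
* `X` is treated as missing data, like a gap. Counting it as a
  20-way-ambiguous residue would bias observed difference fractions
  downward. The other IUPAC ambiguity codes (B/Z/J/U/O) are rejected at
  parse time: they are rare in curated domain alignments, and an
  explicit failure beats a silent bias.
* `d_max = 10` substitutions/site. Pairs whose difference fraction is
  within $10^{-9}$ of 1, or whose likelihood is still rising at
  $d_{\max}$, are capped there and *flagged* rather than dropped, so the
  downstream embedding always receives a total matrix and plots can mark
  the unreliable pairs.

## Sammon mapping

Given original distances $d^*_{ij}$ the map minimizes

$$E(X) = \frac{1}{\sum_{i<j} d^*_{ij}} \sum_{i<j}
        \frac{(d^*_{ij} - \lVert x_i - x_j\rVert)^2}{d^*_{ij}},$$

the Sammon stress. The $1/d^*$ weighting is the point: short distances —
local neighborhoods — are preserved preferentially, which is what makes
the method informative for clusters of related sequences. The optimizer
is Sammon's diagonal-Newton update
$x \leftarrow x - \alpha\, (\partial E/\partial x) /
|\partial^2 E/\partial x^2|$
applied to all coordinates at once, with up to 20 step halvings whenever
a step would increase the stress, so the recorded stress trace is
non-increasing by construction.

Numerical and design choices:

* **Initialization.** The first start is the classical (Torgerson)
  metric MDS solution via `cmdscale`; remaining restarts are seeded
  random Gaussian clouds scaled to the mean original distance. Classical
  MDS is exact for configurations that are Euclidean in $k$ dimensions,
  so perfectly embeddable inputs converge essentially immediately;
  random restarts (`init = "random"` makes them the first start too,
  the historical behavior) protect against local minima on genuinely
  non-Euclidean inputs.
* **Convergence.** `tol = 1e-9` relative stress change, `max_iter = 500`
  per start, `restarts = 10`, `alpha = 0.3` (Sammon's "magic factor").
  These let toy problems converge to machine-level stress and map a
  40-taxon family in seconds.
* **Duplicates.** Zero off-diagonal distances make the $1/d^*$ weight
  undefined, so duplicate taxa are merged onto one representative before
  fitting and re-attached at its coordinates afterwards (with a
  warning). Degenerate all-equal matrices are valid input and relax
  toward a regular simplex.
* **Axes are arbitrary.** Stress depends on distances only, so every
  rotation, reflection and translation of a map is equivalent. All
  comparisons between maps (restart stability, reruns) therefore go
  through `procrustes_align()`, which fits the optimal translation and
  rotation — optionally a reflection, never a scale, because Sammon
  output units approximate substitutions per site and are meaningful.
* **Dimension.** `k = 3` is the default (and what printed figures of
  this kind use); stress at `k = 3` is never worse than at `k = 2` for
  the same input and seed, and the package's tests assert this.

`shepard_data()` / `plot(fit, type = "shepard")` expose the distortion
pair-by-pair; `summary(fit)` reports restart stresses, whose spread is
the practical check that the returned minimum is stable.

## Trees: import, construction, overlay

The package consumes externally inferred trees (typically ML trees) via
Newick; numeric internal labels in $[0,1]$ or $[0,100]$ are carried as
branch supports. It never infers ML trees itself. As a distance-based
stand-in it provides canonical neighbor-joining with two deterministic
refinements: ties in the $Q$ criterion break by the lexicographically
lowest pair of cluster representatives, and a negative estimated branch
is clamped to zero with the deficit moved to its sibling so path lengths
survive. On additive matrices neither rule ever fires and NJ is exact —
the test suite drives this with randomly generated trees.

`overlay_tree()` draws the tree over the map without ever moving the
embedded points. Internal vertices need positions the figure alone does
not define, so two modes are provided: `centroid` (default) places each
internal node at the unweighted mean of its descendant leaves —
deterministic, parameter-free, and faithful to figures whose links
connect existing points; `joint` Sammon-embeds an augmented matrix
(leaf–leaf entries from the original distances, entries involving
internal nodes from patristic distances) with the leaves frozen. The
scene records group labels, display colors (blue for
monofunctional/slow classes, red for bifunctional/fast, by the usual
figure convention), saturation flags and provenance, and exports to
JSON (exact round-trip), a TSV bundle, or a self-contained interactive
HTML view.

## Quantifying "compact" versus "widely spread"

`group_spread()` reports, per annotated group, the RMS of pairwise
embedded distances and its ratio to the global RMS over all pairs. The
relative spread is invariant to rigid motion and global scaling of the
map, which makes it comparable across maps. It quantifies *dispersion*
only; it deliberately does not measure *separation* between groups,
because visual claims that two classes "occupy a different space" admit
many inequivalent statistics and the package does not pick one
implicitly. Singleton groups are reported with `NA` spread and flagged,
never dropped.

## The simulator, and what passing tests do and do not show

`evolve_sequences()` draws a root sequence from $\pi$ and applies one
categorical draw per site per branch from $P(t \cdot m)$, $m$ the
branch's rate multiplier. Each branch consumes its own derived random
stream, so editing one branch never perturbs unrelated subtrees and
regeneration is bit-identical. `two_group_family()` builds a rooted,
balanced two-clade tree and scales every branch of the second clade by
`rate_ratio`, emulating a lineage pair with strongly contrasting
mutational rates. Defaults — 8 taxa per clade, 0.5 substitutions/site
root-to-tip within a clade plus a 0.25 stem, 300 columns — describe a
realistic single-domain family at divergences where distances are
informative but not saturated.

The simulator emulates rate contrast, not everything about real data: no
insertions or deletions (curated domain alignments are largely gapless,
and the gap policies are exercised by hand-built fixtures instead), no
among-site rate variation, no domain fusion. A passing
compact-versus-spread test therefore shows that the pipeline detects a
genuine rate contrast under the model's assumptions; it does not show
that any particular empirical family's spread is caused by rate alone.

With these conditions, the package's acceptance checks find the fast
clade's relative spread exceeding the slow clade's in at least 95% of 50
seeded end-to-end replicates at `rate_ratio = 5`, and no systematic
difference at `rate_ratio = 1` (the replicate mean difference's 95%
confidence interval covers zero).

## Problem sizes used in validation

Test and acceptance runs use deliberately modest sizes chosen so the
checks are sharp: 100-site pairs against the likelihood grid oracle
(25 pairs), 5000-site pairs for recovery bias (4 divergences × 20
replicates, mean relative bias under 5%), random trees up to 12 leaves
for NJ exactness (100 matrices), planted clouds up to 12 points for
embedding recovery, and 16-taxon families (300 sites) for the 100
end-to-end spread replicates. These are the scales at which the
statistical claims were calibrated; all of them rerun from a single seed.

## Known limitations

* One empirical model (Dayhoff); JTT/WAG/LG and gamma/invariant-site
  rate variation are out of scope — distances under those belong to the
  ML software that produced the imported tree.
* Byte-exact agreement with any particular PHYLIP protdist release is
  not promised: protdist's internal Dayhoff table revisions differ
  slightly across versions. Agreement is to the model as defined above.
* Sammon stress is non-convex; restarts mitigate but cannot guarantee
  the global minimum on hard inputs. Inspect `restart_stresses`.
* The embedding consumes point estimates only; distance uncertainty is
  not propagated into the map.
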