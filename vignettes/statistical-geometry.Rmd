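---
title: "Statistical geometry of binary solvent mixtures"
author: "solvtess"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical geometry of binary solvent mixtures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solvtess)
```

## The method

Binary water–cosolvent liquids (water–acetonitrile, water–DMSO, and
similar systems relevant to non-aqueous enzymology) can mix ideally at
the molecular scale or form *microheterogeneous* structure: transient
clusters of nearly pure water next to clusters of nearly pure
cosolvent.  solvtess quantifies this from simulation snapshots with
three geometric statistics.

**1. Periodic Delaunay tessellation.**  Every heavy atom of a frame is
a point; water oxygens carry the label W and cosolvent heavy atoms the
label S (3 per acetonitrile, 4 per DMSO; hydrogens are never
included).  The Delaunay tessellation partitions the periodic box into
tetrahedra such that no atom lies inside any tetrahedron's
circumsphere, so atoms joined by a tetrahedron edge are nearest
neighbours.  The tessellation is therefore a parameter-free definition
of the local neighbourhood structure of the liquid.

**2. Composition classes and the log-odds abundance `f`.**  A
tetrahedron with `k` W-labelled vertices belongs to one of five
classes, W4, W3S, W2S2, WS3, S4 (`k = 4 … 0`).  Pooled over frames,
the observed class probability is `P_obs(i) = n_i / Σ n_i`.  Under
random mixing the reference distribution is binomial in the heavy-atom
water fraction `p_w = n_w / n_T`:

$$P_{exp}(k) = \binom{4}{k} p_w^k (1 - p_w)^{4-k},$$

and the abundance statistic is the ratio `P_obs / P_exp` together with
its logarithm `f = log10(P_obs / P_exp)`.  Positive `f` for W4 and S4
with negative `f` for the mixed classes is the signature of
microheterogeneity; `f ≈ 0` everywhere means the mixture is
statistically ideal at the four-atom scale.

**3. Tetrahedrality.**  The shape of each tetrahedron is summarised by

$$T = \sum_{i<j} \frac{(l_i - l_j)^2}{15\,\bar{l}^2},$$

the normalised sum over the 15 unordered pairs of its 6 edge lengths
(`T = 0` for a regular tetrahedron, invariant under relabelling,
rotation and uniform scaling).  Histograms of `T` per class and pooled
characterise the local packing; `distribution_modes()` reports the
uni-/bi-modality of those histograms.

### Conventions chosen where the statistics are commonly written loosely

* The binomial form of `P_exp` is used because it is the only reading
  under which the five expected probabilities sum to one.
* `f` is reported in base 10, and the raw ratio is kept as a separate
  column, so either convention can be read off the output.
* The divisor 15 in `T` is the number of unordered pairs of 6 edges;
  the sum runs over exactly those pairs.
* Counts are pooled across frames *before* normalisation.  Averaging
  per-frame `f` would be undefined whenever a sparse class misses a
  frame and needlessly noisy otherwise.
* `p_w` is always recomputed from heavy-atom counts, never from the
  molecule-based mole fraction `chi_s`; the two scales differ because
  one cosolvent molecule contributes several heavy atoms.
* Classes with `P_obs = 0` or `P_exp = 0` (unavoidable at the pure
  endpoints `p_w ∈ {0, 1}`) carry `NA` for `f` — an explicit undefined
  marker, never a silent zero.

## Periodic boundaries: ghost replication

The tessellator treats the orthorhombic box periodically by *ghost
replication*: every atom within `buffer_width` of a face is copied to
the opposite side (first-shell images only), the enlarged cloud is
tessellated non-periodically, and a simplex is attributed to the
primary cell exactly when its circumcentre falls inside the half-open
box.  Because a periodic simplex's copies have circumcentres that
differ by exact lattice vectors, each simplex is counted once; summed
simplex volumes then tile the box exactly, which the test suite checks
to 1e-6 relative.

`buffer_width` defaults to a quarter of the smallest box edge, several
times the largest circumradius occurring at liquid densities.  The
choice is validated per frame rather than trusted: any kept simplex
whose circumsphere pokes out of the buffered slab is re-checked
directly against all first-shell periodic images (sound whenever the
circumradius is below the box edge), and an error asking for a larger
buffer is raised if an unreplicated image intrudes.  Dilute or
effectively non-periodic clouds (fixtures in huge boxes) pass through
the same code path.

## Numerical robustness

* **Symbolic perturbation.**  Liquid frames are in general position,
  but lattices and other constructed inputs are massively cospherical,
  where the Delaunay complex is not unique and tie-breaking across
  periodic images can become inconsistent.  Each atom is therefore
  displaced by a deterministic hash-derived offset of relative
  magnitude 1e-9 (identical for all periodic images of that atom, so
  ties break the same way on both sides of the boundary).  The
  perturbation decides only the topology; all reported edge lengths,
  volumes and circumcentres come from the unperturbed coordinates.
* **Degenerate simplices** (volume below 1e-10 nm³) are discarded and
  counted in the diagnostics; near-flat slivers would otherwise
  produce unstable tetrahedrality values.
* **Conflict tolerance.**  The incremental (Bowyer–Watson) insertion
  treats a point as inside a circumsphere only when it is inside by
  more than a guard band scaled to the sphere's size, so round-off
  cannot flip decisions for the perturbed input.
* **Determinism.**  The insertion order is shuffled by a fixed
  xorshift generator independent of R's RNG: identical input yields
  the identical simplex set, and re-running an analysis reproduces
  byte-identical tables.

## The synthetic generators and what they do (not) emulate

`generate_ideal()` places points uniformly with a hard-core exclusion
(default 0.25 nm, one heavy-atom diameter) at a default heavy-atom
density of 30 nm⁻³, and labels them *independently of position* — by
construction the exact null of the binomial expectation.  Bernoulli
labelling (the default) makes the per-tetrahedron label distribution
exactly binomial; the fixed-count variant (`label_mode = "exact"`)
keeps `n_w` constant across frames at the price of a small
hypergeometric correction of order `1/n_T`.

`generate_demixed()` produces the alternative: a slab geometry in
which the label probability follows a logistic composition profile
along z (interface width in nm), or Gaussian cosolvent clusters.  The
slab interface width is the single knob that moves the system from
ideal mixing (width ≫ box) to sharp demixing (width ≪ box).

The generators emulate only the *statistical* structure that the
abundance and tetrahedrality statistics respond to.  They do not model
molecular connectivity (an acetonitrile is not three bonded points
here), hydrogen-bond networks, or realistic radial distribution
functions.  Consequently, passing tests demonstrate that the pipeline
measures composition structure correctly — not that synthetic `T`
distributions resemble those of real water, whose hydrogen-bonded
tetrahedral network (and features such as a bimodal pooled-`T` shape
with a second population near 1.75 in acetonitrile-rich mixtures)
requires genuine molecular-dynamics trajectories.  The mode detector
is accordingly validated on histograms with injected peak positions
rather than on simulated liquids.

## The demixing concentration series

A useful identity: at perfect demixing `P_obs(S4) = χ_S`, so
`f_S4 ≤ 3·log10(1/χ_S)` — the *ceiling* of the S4 abundance falls as
the cosolvent fraction rises.  A series in which the demixed geometry
is held fixed therefore shows a *decreasing* `f_S4`, whereas real
microheterogeneous mixtures (acetonitrile being the canonical case)
mix nearly ideally when dilute and demix increasingly strongly as
`χ_S` grows.  The packaged demonstration series
(`demix_series_params()`) encodes exactly that phenomenology: slabs at
`χ_S = 0.2, 0.3, 0.4, 0.5` whose interface sharpens linearly,
`w(χ_S) = 0.65 − χ_S` nm.  The parameters were fixed from a
composition-profile integral model of the slab (predicting
`f_S4 ≈ 0.27, 0.43, 0.58, 0.65` with `f_W4 > 0` and `f_W2S2 < 0`
throughout) before any pipeline run, and are not tuned thereafter.

## Validation strategy and problem sizes

The test suite validates each stage against an independent oracle:
brute-force enumeration of empty-circumsphere 4-subsets for the
tessellation; exact volume tiling of the periodic box; the explicit
15-pair double loop for `T` (1000 random edge sets, 1e-12 relative);
the closed-form flat-square value `24(3−2√2)/(5(6+4√2))`; and a
binomial-null recovery study — 200 independent ideal frames of 500
points at `p_w ∈ {0.3, 0.5, 0.7}`, requiring every pooled `f` to lie
within 3 Monte-Carlo standard errors of zero, with the error band
estimated from the per-frame spread of `f` itself (tetrahedra sharing
atoms are correlated, so a multinomial error formula would be badly
anticonservative).  The demixing series uses 30 frames of 500 points
per concentration.  These sizes give standard errors on `f` of a few
thousandths, an order of magnitude below the smallest effect the
series is designed to show.

## Worked example

```{r example}
frames <- generate_trajectory(5, "slab", n_points = 400, p_w = 0.6,
                              interface_width = 0.2, seed = 42,
                              chi_s = 0.4)
res <- run_single(frames)
res$abundance
```

```{r plots, fig.width = 6, fig.height = 3.5}
plot_t_distribution(res$t_distribution)
```

## Limitations

* Orthorhombic boxes only; triclinic cells raise an explicit error.
* First-shell ghost replication limits `buffer_width` to the box edge;
  this is never binding at liquid densities.
* The conflict search is quadratic in cloud size — ample for frames of
  10² – 10⁴ heavy atoms, but not tuned for millions of points.
* No confidence intervals on `f` are produced; a bootstrap over frames
  is the natural extension.
* Whether snapshots of a real trajectory are statistically independent
  is the user's responsibility; `frame_stride` exists for thinning.
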