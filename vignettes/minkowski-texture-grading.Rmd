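---
title: "Minkowski-functional texture grading of AFM height maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minkowski-functional texture grading of AFM height maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minkograde)
```

## The problem

Atomic force microscopy (AFM) of unstained histological brain-tumor sections
produces height maps rather than optical images. In low-grade astrocytic
tumors (WHO grade II) the neuropil — the meshwork of neuronal and glial
processes — appears as a dense network of fine raised fibres with regular
nucleus-sized bumps and only small cavities. In glioblastoma (grade IV) that
fine organization is lost: the tissue becomes a pulpy mass riddled with
irregular, large-scale cavities left by necrosis and neuropil reduction. The
grading signal is therefore *topological*: how the bright (raised) structure
connects, and how many dark cavities it encloses, across all height levels.

This package turns that observation into a quantitative pipeline:

1. **Flatten** the height map (remove the instrument's background slope).
2. **Equalize** the height histogram onto 256 gray levels.
3. **Threshold** at every level t = 0..255, giving a stack of level sets.
4. For each level set compute the three 2-D **Minkowski functionals**:
   covered area, boundary length, Euler characteristic.
5. Reduce the Euler and contour curves to **15 geometric descriptors**.
6. Classify grade II vs. grade IV with a **genetic-programming (GP)
   symbolic classifier** under stratified cross-validation.

## The model and its conventions

### Preprocessing

First-order flattening fits a single global plane
$z = a + b\,\mathrm{col} + c\,\mathrm{row}$ by ordinary least squares and
keeps the residuals. Many AFM packages level each scan line separately
instead; that is available as `method = "line"`, but the global plane is the
default because it is the minimal reading of "first-order" background
removal and does not invent per-row degrees of freedom.

Histogram equalization is rank-based: a pixel of height $v$ maps to
$\lfloor 256\,C(v)/N \rfloor$ clipped to 255, where $C(v)$ counts pixels with
height $\le v$. The mapping is monotone, so the family of level sets is
preserved — only the level *labels* change. Tie handling matters for
bit-exact reproducibility: this package fixes the cumulative-count
($\le$) convention, under which a constant image maps to level 255. Heights
are ranked at full numeric precision; no pre-quantization.

### Minkowski functionals

A level set at threshold $t$ is the binary image with foreground
$\{\,\mathrm{gray} \ge t\,\}$: bright raised structure is foreground, dark
cavities are background, so cavity formation drives the hole counts. The
three functionals are:

* **area** $A(t)$ — foreground pixel count;
* **contour length** $P(t)$ — the number of unit pixel edges between
  foreground and background, with the image exterior treated as background
  (border pixels contribute their outward edges). Units are pixel edges; no
  Crofton correction is applied;
* **Euler characteristic** $\chi(t)$ — connected foreground objects minus
  holes, with the standard complementary connectivity pair: foreground
  8-connected, background 4-connected. Background touching the exterior is
  never a hole.

$\chi$ is computed by 2×2 quad-pattern counting on the padded mask,
$\chi = (Q_1 - Q_3 - 2 Q_d)/4$, which is proven equal to the labeling
definition in the test suite by exhaustive enumeration of all 512 binary
3×3 images plus randomized 32×32 masks against an independent
graph-components oracle. Connectivity is deliberately *not* configurable:
fixing it keeps every downstream number bit-exact.

The full curves are produced in one $O(N)$ sweep: each pixel, adjacent
pixel pair, and 2×2 quad changes state at known threshold values, so its
contribution covers a contiguous interval of $t$ accumulated with difference
arrays. Equality with naive per-level recomputation is asserted in the
tests.

By construction $A(0) = N$, $\chi(0) = 1$ and $P(0) = 2(H + W)$, and $A$ is
non-increasing in $t$. Note that $\chi(255)$ is the component count of the
top level set — it exceeds 1 whenever several pixels share the maximum
level, which is the normal case for equalized images.

### The 15 descriptors

Grade II and IV tissues differ in their mean Euler curves (both are
sigmoid-like, with the low-grade curve dipping deeper and later) and their
contour curves (parabola-like, with the low-grade maximum higher). The
curve-to-descriptor reduction keeps exactly the quantities that encode
those differences: from the Euler curve the extremum values and positions,
the first zero crossing after the minimum, the steepest rise between the
extremes (value and position), and the negative/positive/total areas; from
the contour curve the maximum and its position, full width at half maximum,
total area, and centroid. Ties resolve to the lowest gray level; a missing
zero crossing saturates at 255; all-zero curves yield all-zero descriptors.

The slope features are computed after a centered moving average
(`smooth_window`, default 5 levels, configurable) so the slope position is
not dominated by level-to-level noise; the window shrinks at the curve ends.
Smoothing is linear, so the descriptor set remains scale-consistent:
multiplying the Euler curve by $\lambda > 0$ multiplies the value-type
descriptors by $\lambda$ and leaves the position-type descriptors unchanged
(a property test).

### Group statistics and the non-overlap band

Group curves are summarized per gray level by the arithmetic mean and the
sample standard deviation ($n-1$ denominator). The "1σ band" is mean ± one
standard deviation — a deliberate choice of spread, not standard error,
because the band describes where individual samples lie. Gray-level runs
where the two groups' bands are disjoint form the *non-overlap band*; the
mean Euler value over that band is a single scalar with high discriminative
power, and the pipeline cross-validates a classifier on it alongside the
full 15-descriptor model.

The extreme-value comparison divides signed extremes of the mean curves
(like-signed extremes give positive ratios) and reports two decimals; a zero
denominator raises an undefined-ratio flag rather than returning infinity.

### The GP classifier

The classifier is a strongly typed expression tree: arithmetic operators
(+, −, ×, protected ÷ returning 1 on a zero divisor) over feature references
and numeric constants, comparisons (<, ≤, >, ≥) mapping numbers to Booleans,
and logical operators (AND, OR, NOT, XOR) above them. The Boolean root maps
TRUE to grade IV. Trees are built well-typed and never repaired.

Evolution uses tournament selection (size 2), subtree crossover
(probability 0.9) between type-compatible nodes, elitism 1, and a mutation
probability of 10–15 % choosing uniformly among four mutators:
replace-branch, change-node-type (swap within the arity-compatible operator
family), full-tree shaker (re-draws every numeric constant) and one-point
shaker (one constant). Constants are drawn uniformly from per-feature
training ranges. Offspring violating the depth or length cap are rejected
and the parent is kept, so every individual in every generation satisfies
the limits. Fitness is raw training accuracy — the only quantity the
reference experiment reports — and evolution stops early once a tree
reaches accuracy 1, since the fitness cannot improve further and continuing
would only burn cycles reshuffling equivalent trees.

Where the reference parameter table is silent (tournament size, crossover
probability, elitism, fold count), the defaults above follow common GP
practice and are configurable; the tested grid is the Cartesian product
generations {70, 100} × mutation {10, 15} % × depth {8, 10} × length
{25, 50, 80} at population 70, i.e. 24 configurations, available as
`gp_default_grid()`.

Cross-validation is stratified by label, re-randomized every run, with all
seeds derived from a single master seed, and repeated `n_runs` times; the
headline number is the best run's mean fold accuracy. Setting `n_folds`
equal to the sample count degenerates to leave-one-out (stratification is
vacuous for singleton folds). A leakage test perturbs one sample's features
and asserts that the model of the fold holding that sample out is
node-for-node unchanged.

## The synthetic generator

The clinical image set behind the reference study is not public, so the
package ships a generator whose contract is purely *qualitative*: reproduce
the curve geometry (sigmoid Euler curves, parabola-like contour curves) and
the class ordering (grade II: deeper Euler minimum, higher contour maximum),
not any absolute magnitude. On a tilted plane it composes

* fibrous ridges as persistent random walks (direction innovations
  N(0, 0.15) per step) of thickness ~3 px and positive height — dense
  (140 per 512×512 frame) for grade II, sparse (20) for grade IV;
* nucleus bumps as Gaussian blobs (radius 4–10 px);
* cavities as depressions with raised-cosine depth profiles and outlines
  modulated by random 2nd–4th order harmonics — many small ones (28,
  radius 4–12 px) for grade II, few large ones (12, radius 25–70 px) for
  grade IV;
* i.i.d. Gaussian pixel noise (σ = 0.03 in height units where structures
  are 0.4–1.2 high).

Counts scale with frame area, so a 256×256 image emulates a smaller field
of view of the same tissue; radii stay fixed in pixels (cavities capped at a
quarter frame). Dataset generation jitters counts and radii by ±20 % per
image for within-class variance, with per-image seeds derived from the
master seed.

What the generator does *not* emulate: AFM tip convolution, scan-line
artifacts and line noise, stain-related contrast, true biological
within-patient correlation, or the absolute Euler/contour magnitudes of real
tissue. Passing pipeline tests on synthetic data therefore demonstrates that
the *machinery* discriminates the two morphologies; it says nothing about
clinical accuracy on real AFM material.

## Numerical choices and degenerate inputs

* Height maps must be at least 8×8 (the plane fit needs non-collinear
  support); binary masks and gray images have no minimum.
* Equalization of a constant image gives level 255 (the cumulative-count
  convention); its level-set stack is a single step.
* All-zero curves produce all-zero descriptors; an empty gray-level band is
  a contract error for `band_feature`.
* Ratios with a zero-valued denominator extreme set an `undefined` flag.
* Text height maps round-trip at 10 significant digits; raster samples are
  used verbatim (8/16-bit), with no rescaling, since equalization is
  rank-based anyway.
* All stochastic stages (generator, GP, fold assignment) draw every seed
  from one master seed; reruns are byte-identical, which the test suite
  checks with file hashes.

## Problem sizes used in the tests

The test suite and the worked examples run the full experiment at 256×256
with 54 + 59 images (the reference class sizes), 10 cross-validation runs of
10 folds each, and one grid cell (70 generations, population 70, depth 8,
length 50, 10 % mutation); unit and property tests use 8×8 to 64×64 images
and reduced GP settings. These sizes were chosen so the whole suite runs on
a laptop-class single core in minutes while still exercising every code
path at realistic scale.

## Known limitations

* Contour length is an edge count, not a geometric length estimate; curves
  are comparable between images of the same resolution only.
* The GP search is a stochastic heuristic; per-seed results vary, which is
  why accuracies are reported across repeated runs and the grid.
* The generator's parameter space was fixed from the qualitative morphology
  description once; it is not fitted to any data, and absolute feature
  values will not match clinical material.
* Only two-class grading (II vs. IV) is implemented.

## A minimal session

```{r example, eval = FALSE}
library(minkograde)

cfg <- pipeline_config(
  out_dir = "run",
  simulate = list(n_gradeII = 54, n_gradeIV = 59, image_size = 256),
  gp = gp_config(max_generations = 70, max_tree_length = 50,
                 n_runs = 10, n_folds = 10),
  seed = 11)
rep <- run_pipeline(cfg)
print(rep)
print(rep$stats$gradeII)
print(rep$classification$result$best_model)
plot_group_curves(rep$stats$gradeII, rep$stats$gradeIV)
```
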