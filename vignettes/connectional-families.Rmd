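---
title: "Parcellation and connectional families: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parcellation and connectional families: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parcfam)
```

## Overview

`parcfam` analyzes the functional organization of two cortical regions
of interest (called *frontal* and *parietal* throughout, after the
system the method is designed for) in four stages: preprocessing to a
dense connectome, affinity-propagation parcellation of each ROI,
hierarchical grouping of parcel exemplars into connectional families,
and branch-level summaries of large-scale organization. This vignette
explains the models and assumptions behind each stage, the tunable
parameters and their defaults, what the synthetic generator does and
does not emulate, and the numerical choices that matter.

## The generative model behind the synthetic data

The generator plants a known organization so every downstream claim is
checkable. A vertex $v$ in parcel $p$ of family $f$ has signal

$$x_v(t) = \sqrt{a}\, g_f(t) + \sqrt{b}\, h_p(t) + \sqrt{1-a-b}\,\epsilon_v(t),$$

with unit-variance Gaussian i.i.d. latents and noise. Family latents
are mixed across the two ROIs through the eigen-decomposition of a
planted coupling matrix $C$, so their population correlation equals
$C$ exactly. The implied population connectome is closed form: $a+b$
within a parcel, $a$ across parcels of one family, $a\,C_{fg}$ across
families, 0 for non-ROI vertices — `expected_connectome()` is the
oracle used throughout the tests.

Variance shares default to $a = 0.25$, $b = 0.45$: the parcel latent
dominates (parcels must be separable from their family), the family
latent is strong enough for cross-ROI structure to be detectable at
$T \approx 1000$ timepoints, and 30% noise keeps recovery nontrivial.
Because $a$ and $b$ fully determine the structured-to-noise variance
ratio $(a+b)/(1-a-b)$, no separate SNR knob exists — one set of numbers,
one meaning.

Two coupling layouts are provided. `"paired"` gives each frontal family
one strong parietal partner (coupling 0.8, off-partner 0.05) with
families ordered along the dorsal–ventral axis in both ROIs — parallel
pathways. `"gradient"` orders frontal families posterior→anterior and
parietal families anterior→posterior and couples them with a banded
fall-off ($0.5 \times 0.3^{|i-j|}$) — core–shell organization. The
gradient peak is lower than the paired one because the full coupling
matrix must stay positive semi-definite; both values leave a
comfortable margin between partner and non-partner correlations at the
default time-series lengths.

Families are *contiguous coordinate bands* along the relevant axis, and
parcels are grown inside each band by synchronized breadth-first fronts
from seeds placed at the centroids of even band chunks (ties broken by
lowest vertex index, so planting is deterministic given the
configuration). Two consequences are deliberate. First, family bands
occupy disjoint axis ranges, so a planted gradient is *exactly*
recoverable (rank correlation ±1) rather than approximately. Second,
parcels have comparable sizes. Early versions seeded parcels at random
vertices; adjacent seeds then produced sliver parcels of a few
vertices, and under the preference rule below the optimal clustering
genuinely merges a sliver into its family neighbour — not a failure of
the clustering but a degenerate planting. Cortical parcels have
comparable areas, so comparable-size planting is also the realistic
condition.

What the generator does **not** emulate: hemodynamic filtering and
temporal autocorrelation (all series are white — only correlation
structure, not spectra, drives every stage), volumetric space and mesh
curvature (the surface is a flat lattice), inter-subject spatial
misalignment, and realistic artifact spectra (nuisance signals are
white series with Gaussian vertex loadings, standing in for global
confounds such as CSF/white-matter time courses). Passing tests
therefore demonstrate correctness of the *computations* under the
stated statistical structure, not robustness to every property of real
fMRI.

## Preprocessing choices

*Drift removal* is polynomial detrending (default order 2), a
deliberately simple stand-in for scanner drift filtering; the order is
configurable. *Nuisance regression* uses supplied series directly and
is exact OLS, so residuals are orthogonal to the regressors to machine
precision. Vertices with zero residual variance are flagged and zeroed
with a warning rather than erroring — a constant vertex is a data
problem worth surfacing, not a reason to lose a run.

*Surface smoothing* is a Gaussian kernel on geodesic (shortest-path)
distance, truncated at $3\sigma$ (under 1.2% of kernel mass for a
Gaussian) and row-normalized, making every output a convex combination
of inputs. The pipeline default is $\sigma = 0$ (off): planted parcels
have sharp boundaries and vertices are 1 mm apart, so any realistic
kernel width deliberately blurs parcel edges; on real surfaces with
measurement noise a width of a few mm is the field's common choice and
`smooth_on_graph()` supports it.

*Incremental group PCA* folds subjects in one at a time, keeping at
most `internal_dim` variance-weighted left singular components of the
running temporal concatenation. The default dimension is
`min(200, total timepoints)`; with no truncation the result spans the
exact concatenation-PCA subspace (tested to principal angles below
1e-6), and on shared low-rank structure truncation at the true rank is
also exact. Subject order is randomized from a recorded seed because
the fold-in order is otherwise arbitrary. Components are
singular-value scaled so that Pearson correlations on the reduced
matrix approximate full-data correlations.

## Parcellation choices

The similarity matrix is the Pearson correlation between connectivity
profiles (connectome rows over the whole hemisphere). The
self-correlation column (value 1) is retained in profiles; its effect
on similarities is a single shared column among hundreds and is
negligible. The preference is

$$p = \min(S) - (\max(S) - \min(S)),$$

computed over **off-diagonal** entries: the diagonal is where the
preference itself lives, and including a diagonal of 1s would distort
$\max(S)$ whenever profiles are imperfectly correlated.

Affinity propagation is implemented from scratch as damped
responsibility/availability message passing (damping 0.9, up to 1000
iterations, convergence declared after 100 iterations of a stable
exemplar set). Flat preferences on symmetric similarity matrices are
oscillation-prone, hence the high damping; a seeded jitter of relative
magnitude 1e-12 breaks exact ties (disabled when comparing against the
exhaustive oracle, whose ties are broken by documented rules: fewer
exemplars, then lexicographically smallest set).

Message passing heuristically maximizes the net similarity
$\sum_i s(i, e_i) + p\,K$ but stalls in local optima near the
one-cluster boundary: on random 8×8 instances about 4 in 100 runs end
2–31% below the exhaustive optimum, regardless of damping. The
implementation therefore finishes with a greedy ascent on the same
objective — steepest single-exemplar add/drop/swap moves — restarted
from the message-passing solution and from the best one- and
two-exemplar sets (direct scans; the failure regime is exactly
small $K$). With the polish the implementation attains the exhaustive
optimum on 100/100 random instances. `polish = FALSE` restores plain
message passing. Cluster ids are ordered by exemplar vertex index;
assignment ties go to the lowest exemplar index.

Validation metrics use Euclidean geometry on profile rows.
Davies–Bouldin uses mean distance to the centroid as cluster scatter
(0 for singletons); silhouette terms of singleton-cluster points are
defined as 0. The gap statistic compares $\log W$ against reference
draws uniform in the per-dimension bounding box of the profiles,
scored against the nearest observed centroid — a deterministic
reference rule (given the seed; 20 draws by default) chosen so the
statistic is exactly reproducible and independently recomputable.

## Hierarchy and affinity choices

Exemplar fingerprints are clustered with **Ward linkage on city-block
distances** via the Lance–Williams recurrence applied directly to
those distances (`stats::hclust`, `method = "ward.D"`). Ward's
variance derivation assumes squared Euclidean distances; the
city-block combination is kept deliberately, as the method this
package follows specifies it, and a `metric = "euclidean"` switch
exists for comparison. Distances are computed on raw correlations (no
Fisher z, no row standardization). Branch ids follow dendrogram leaf
order; `split_trace` records which branch of the $(k-1)$-solution
divided.

Branch-level affinities average raw correlation coefficients; a
Fisher-z averaging option exists but is off by default, matching the
convention of averaging correlations directly. No automatic choice of
the family level is made: the intended workflow is to inspect where
branches stop splitting into coherent groups and start shedding single
exemplars ("disintegration"), exactly the behaviour the acceptance
checks verify on planted data. On real cortical data that inspection
is additionally informed by anatomical priors and is left to the user;
the pipeline default is the planted family count, since that is what
the default synthetic configuration contains.

The gradient statistic is our operationalization of an organization
that is usually shown visually: the Spearman rank correlation between
seed positions and peak-connectivity-vertex positions along chosen
axes. Axis orientation is documented (axis 1 increases anterior, axis
2 dorsal), so core–shell organization appears as $\rho = -1$ and a
same-direction dorsal–ventral progression as $\rho = +1$. Seeds in the
pipeline are one exemplar per family branch (the member with the
median axis position); identical peak positions are reported as a
degenerate result rather than a correlation.

## Problem sizes and determinism

The shipped tests and the acceptance script run the full pipeline at
100-vertex ROIs (10×10 lattices), 50 extra hemisphere vertices, 6
planted parcels in 3 families per ROI, 2–3 subjects and 1000–2000
timepoints, with 10 replicate seeds per claim; the connectome
convergence check uses a 28-vertex world at 20,000 timepoints. These
sizes keep each claim's evidence recomputable in seconds to a couple
of minutes while leaving all effects far from threshold (recovery is
exact, not marginal, at these settings). Every stochastic stage draws
from an explicit seed recorded in the run manifest, and a fixed
configuration reproduces every artifact byte for byte.

## Known limitations

- Affinity propagation is run without spatial constraints; parcel
  contiguity is a property of the planted data, reported but never
  enforced, so on low-SNR data recovered parcels can be spatially
  fragmented.
- The gap statistic's uniform-box reference is a convention; its
  absolute value is less interpretable than its comparison across
  candidate solutions.
- Ward-on-city-block is not a variance decomposition; heights are
  interpretable only ordinally.
- The synthetic surface is a flat lattice: geodesic distances are
  exact there, but no claim is made about curvature effects on
  smoothing.
- With fewer than three family branches the gradient statistic is
  undefined and skipped (a rank correlation over two points carries no
  information).
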