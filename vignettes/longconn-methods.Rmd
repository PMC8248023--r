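---
title: "Methods: longitudinal structural connectome analysis with longconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: longitudinal structural connectome analysis with longconn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
```

## The problem

Probabilistic tractography turns a diffusion MRI acquisition into, per
subject, a matrix of streamline counts between the 90 regions of the AAL
parcellation. When the same subjects are scanned years apart, the
scientific questions are: which connections change, are the changes
organized into coherent sub-networks, do they track cognition, which
white-matter tracts carry them, and does the network's topology
(efficiency, modularity, hubs) reorganize? `longconn` implements this
whole chain as composable, tested functions, and ships a synthetic cohort
generator so every stage can be exercised and calibrated without access
to imaging data.

## Connectome construction

Raw counts are directed (seeding at region *i* does not give the same
count as seeding at *j*), so construction proceeds in a fixed order:

1. divide each row by the region's *waytotal* (the total number of
   streamlines generated from that seed and not rejected by masks);
2. divide by the subject's maximum value, giving connection
   probabilities in [0, 1];
3. symmetrize by averaging `P_ij` and `P_ji`;
4. zero all entries below 1% of the subject's strongest connection;
5. apply a group consistency mask at 30% density.

The 1% threshold uses the post-symmetrization maximum; taking it before
symmetrization would make the threshold depend on the arbitrary seeding
direction. The consistency mask scores every edge by the inverse
coefficient of variation of its weight across subjects (absent edges
count as zero weight) and keeps the most consistent edges up to the
target density — `round(0.30 * 4005) = 1202` edges at 90 nodes. Ties are
broken by higher mean weight and then lexicographic edge order, so the
mask is a deterministic function of the cohort.

Two masking modes exist. The default, *pooled*, derives one mask for both
timepoints from the cross-subject consistency of the subject-mean
matrices (each subject's two timepoints averaged first). Averaging before
scoring matters in a longitudinal design: scoring the pooled set of
subject-timepoint matrices directly would let a genuine longitudinal
change inflate an edge's apparent variability and push exactly the
interesting edges out of the mask. The *per-timepoint* mode reproduces
the masks used for per-timepoint diagnostics; paired analyses then test
the intersection of the two masks.

## Timepoint consistency

Before comparing timepoints, the pipeline checks that individual
connectivity signatures are stable: each subject's upper-triangle vector
is correlated with the timepoint mean (TC-I, pooled across subjects on
the Fisher-Z scale), and all pairwise subject-subject correlations are
collected per timepoint and pooled across timepoints (TC-II). Perfect
correlations are clipped to `1 - 1e-12` before the Z transform (identical
matrices are legal inputs, infinite z-values are not useful). These
diagnostics run on the thresholded, masked matrices — the same objects
every downstream statistic sees.

## Graph metrics

Degree, density, clustering, and the degree-preserving rewiring operate
on the binary support of the weight matrix; path-based quantities use
weighted shortest paths with edge cost `1 / w`. Global efficiency is the
mean inverse shortest path length over ordered pairs, nodal efficiency
the per-node version, local efficiency the mean of the nodal values, and
the characteristic path length `L` the mean shortest path length. On a
disconnected graph, `1 / Inf = 0` keeps the efficiencies finite and `L`
is computed on the largest component and flagged.

The small-world index is
`sigma = (Cl / Cl_rand) / (L / L_rand)`,
with the normalizing means taken over an ensemble (default 100) of
degree-preserving randomizations. Each randomization attempts `10 * E`
double-edge swaps; each attempted swap picks two edges and a random
orientation, and is applied only if it creates neither self-loops nor
multi-edges. The orientation must be random: always pairing the sorted
endpoints one way biases the stationary distribution and shows up as a
depressed ensemble clustering coefficient. Weights travel with the
rewired edges so that weighted path lengths remain comparable.

## Paired network-based statistics

Each masked edge gets a paired t statistic over the within-subject
differences (timepoint 2 minus timepoint 1), squared into an F value.
Edges exceeding a primary threshold form a graph whose connected
components are the candidate sub-networks; a component's evidence is its
*extent* (edge count). The null distribution of the maximal component
size is obtained by randomly flipping the sign of each subject's whole
difference matrix — the exact permutation group for a paired,
exchangeable design — and the corrected p-value is
`(1 + #(null >= size)) / (1 + n_perm)`. The +1 correction keeps p-values
positive and makes the test slightly conservative; the package's own
calibration (`simulate_null_fwer()`) measures an empirical family-wise
error rate of about 0.02-0.04 at a nominal 0.05 over 200 null cohorts.

The primary threshold trades sensitivity for specificity but does not
affect error control. `threshold_sweep()` exposes the selection rule used
in the analysis scripts: the maximal threshold at which a unique
component with more than two connections is detected. Where no threshold
satisfies the rule, `default_primary_threshold()` falls back to the
squared two-sided t quantile at an edge-level p of 0.001.

Significant components are summarized per subject and timepoint as mean
connectivity over the component's edges, stratified by the sign of the
group-mean difference (all / increases / decreases) crossed with
hemisphere class. Hemisphere classification uses the interleaved AAL
convention: odd 1-based region index = left, even = right. Empty strata
(for instance, no intra-right increases) are omitted and flagged rather
than reported as zero.

## Community structure, hubs, fingerprints

Community detection runs weighted Louvain many times (10,000 in the
analysis scripts) and keeps the modal canonical partition — partitions
are relabeled by first node occurrence before counting, ties broken by
higher modularity then lexicographically. Modularity is the standard
weighted Newman Q. Partition similarity matches every module of one
partition to its best Jaccard counterpart in the other (shared regions
over the union of regions) and averages the best matches; the union
reading is the one under which identical partitions score exactly 1.
Since the direction matters for unequal module counts, a symmetrized
variant is available.

Three hub notions are kept distinct, all computed on group-mean matrices
per timepoint (one hub set and one partition per timepoint is the unit
of interpretation):

* **global hubs** — nodal efficiency normalized by its mean exceeds
  `1 + SD` of the normalized values;
* **provincial hubs** — within-module degree z-score above `mean + SD`
  of all nodes' z-scores, participation coefficient `PC <= 0.3`;
* **connector hubs** — same z-score cutoff with `PC > 0.3`.

The z-score is standardized within each module but the hub cutoff pools
z across modules (a module-local cutoff would force hubs into every
module regardless of contrast); degree quantities in z, PC and the
fingerprints are binary connection counts. Modular-connectivity
fingerprints fix one reference partition across timepoints — the
candidate maximizing the mean modularity over all subject matrices — and
count edges within and between modules; the module-by-module matrix
carries twice the within-module edge count on its diagonal (the degree
convention) and plain edge counts off it. The connector-hub-driven
variant counts, per hub, its edges toward every module, and its overall
value sums the inter-modular part only.

## Tract attribution

Given region-by-tract mean-streamline overlap matrices at both
timepoints, both matrices are thresholded at 5% of their maximum, the
proportion of change `(M2 - M1) / M1` is computed (entries undefined at
`M1 = 0` are masked), and each component edge is attributed to the tracts
whose change matches the edge's sign at *both* endpoint rows. Among
several sign-matching tracts the one with the highest mean intensity
wins, where the mean is taken over the two timepoints and both endpoints
— a symmetric, deterministic reading of "highest at both timepoints".
When no tract matches the sign (an edge whose endpoints only changed the
other way), the fallback picks the highest-mean-intensity tract and
flags the edge. All sign-matching candidates are reported, ranked, with
the winner marked, since a connection may genuinely run through more
than one tract.

## Longitudinal statistics

Paired t-tests report Cohen's d as mean difference over the SD of the
differences; families of tests are corrected with Benjamini-Hochberg.
The repeated-measures correlation is the ANCOVA formulation: subject
enters as a factor, the common slope of x carries the association, and
`r_rm = sign(slope) * sqrt(SS_x / (SS_x + SS_error))` with error degrees
of freedom `N(k - 1) - 1` in the balanced case. It is invariant to
per-subject constant shifts in either variable, which is exactly what a
two-timepoint design needs. Confidence intervals come from a cluster
bootstrap: subjects are resampled with replacement carrying both their
timepoints, and the percentile interval (not BCa) is reported — with
10,000 draws the extra complexity of BCa buys little here. All tests are
two-sided, and the reported interval is sign-consistent with the point
estimate by construction.

## The synthetic cohort generator

The generator is the package's substitute for a real cohort and defines
the regime in which everything is tested:

* **Geometry.** Nodes sit in the unit cube with mirror symmetry: left
  (odd-index) nodes uniform in `[0, 0.45] x [0,1]^2`, right nodes
  mirrored across the mid-sagittal plane. Expected counts decay as
  `count_scale * exp(-d / weight_decay)` (defaults 5000 and 0.25) over a
  deterministic support of the closest `base_density = 0.5` of node
  pairs, closed under mirroring so mirrored pairs always share their
  expectation.
* **Noise.** Counts are Poisson around a log-normally perturbed mean.
  The log-normal CV of edge (i, j) is
  `sqrt(noise_cv^2 + noise_dispersion / mu_ij)` (defaults 0.1 and 50):
  weak connections are reconstructed less consistently across subjects
  than strong ones, which is the empirical phenomenon that motivates
  consistency-based thresholding in the first place, and it makes the
  mask's removals concentrate on weak edges as the diagnostics expect.
  A per-subject log-normal multiplier (CV 0.15) shared by both
  timepoints creates the within-subject correlation that paired tests
  and the repeated-measures correlation rely on. The two directed counts
  of an edge are jittered independently by +-5% so symmetrization is
  non-trivial, and waytotals are row sums times a per-region factor in
  [1, 2] so waytotal normalization is non-trivial.
* **Planted effects.** A configurable edge set has its timepoint-2
  expectation scaled by `1 + delta`. Planted edges receive a baseline at
  least at the support's 90th weight percentile: the emulated regime is
  longitudinal change on strong, reliably reconstructed connections
  (subcortical-frontal connections are among the strongest in the
  connectome), and an effect planted on a vanishing edge would be
  removed by any consistency-thresholded pipeline before testing.
* **Cognition.** Scores follow
  `score = intercept_subject + slope * subnetwork_mean + residual`,
  with Gaussian subject intercepts (SD 1), slope -1 and residual SD 0.1
  by default, giving the repeated-measures correlation a recoverable
  within-subject slope of known sign.
* **Tract fixtures.** Each planted edge is assigned a unique true tract
  whose overlap with both endpoint regions changes with the planted
  sign, while distractor tracts are identical at both timepoints, so
  attribution has an exact right answer.

The bundled demo (`make_demo()`) plants a 16-edge connected component
with 7 increases (2 intra-left, 5 inter-hemispheric) and 9 decreases
(3 intra-left, 5 intra-right, 1 inter-hemispheric) at `|delta| = 0.4`
in a 51-subject cohort.

What the generator does **not** emulate: anatomical geometry beyond
mirror symmetry, distance-dependent false-positive structure of
tractography, head motion, age or sex structure, non-stationary
measurement error between sessions, and any voxel-level process. Passing
tests therefore demonstrate that the statistical machinery is correct
and calibrated under a plausible generative model — not that any
particular biological finding would replicate.

## Problem sizes and numerical choices

The test suite and calibration runs use desk-scale sizes chosen to make
the Monte-Carlo error small relative to the tolerances while keeping a
full run in the order of a minute: 200 null cohorts of 30 subjects with
500 permutations for the family-wise error rate, 20 replicates of the
51-subject demo for component recovery, 50 random graphs of up to 12
nodes against brute-force oracles (Floyd-Warshall, exhaustive triangle
census, explicit ANCOVA sums of squares), and 100-network ensembles for
the small-world checks. Zero-variance inputs are handled explicitly
everywhere (F set to 0 for zero differences and to infinity, with a
warning, for constant nonzero differences; z-scores 0 in singleton
modules; perfect correlations clipped). Seeds propagate from one master
seed through `spawn_seeds()`, so every stage is reproducible in
isolation.

## Known limitations

The pipeline generalizes the 90-node parcellation to any even node
count, but the hemisphere rule assumes the interleaved left/right
convention. Component evidence is extent only (no intensity statistic),
the NBS design is strictly paired (no ANCOVA covariates), and community
detection uses a fixed resolution of 1. The percentile bootstrap can
undercover for strongly skewed statistics at small n; with two
timepoints and n around 50 the coverage simulations in the test suite
stay near nominal.
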