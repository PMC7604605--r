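---
title: "Weighted structural connectome analysis with strucnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted structural connectome analysis with strucnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`strucnet` analyzes weighted structural brain networks: graphs whose 82
nodes are gray-matter regions (68 Desikan-Killiany cortical areas plus 14
subcortical structures, 41 per hemisphere) and whose edges are white-matter
connections estimated from diffusion tractography. This vignette explains
the models and conventions the package commits to, the parameters that
matter, what the synthetic-cohort generator does and does not emulate, and
the numerical choices made where the standard definitions are silent.

## From streamline counts to a weighted network

Tractography yields, for each region pair $(i, j)$, a streamline count
$n_{ij}$ and a mean fiber length $\bar l_{ij}$ (mm); segmentation yields
region volumes $V_i$ (mm³). `build_connectome()` converts these to
connection weights in two steps:

1. **Spurious-connection threshold.** Pairs with fewer than 3 streamlines
   (configurable via `min_streamlines`) are set to zero. The threshold is
   applied to the *raw* count, before any correction, because the count is
   the quantity whose small values indicate unreliable reconstructions.
2. **Corrected streamline density.** Retained pairs get
   $$w_{ij} = \frac{2}{V_i + V_j}\cdot\frac{n_{ij}}{\bar l_{ij}}.$$
   Dividing by length compensates the accumulation advantage of long
   tracts' seed counts; dividing by the mean volume removes the bias toward
   large regions. This is the most widely used realization of a length- and
   volume-corrected count; because the literature varies, the correction is
   swappable (`correction = "raw"`, `"length"`, `"length_volume"`), and
   all downstream metrics accept any nonnegative symmetric weight matrix.
   A useful exact property (tested): scaling all volumes by $a$ scales all
   weights by $1/a$, so the choice of volume units is immaterial to any
   scale-invariant quantity ($\gamma$, $\lambda$, $\sigma$, GLM t
   statistics).

Whether the correction should use per-streamline or pair-mean lengths is
ambiguous in practice; the pair-mean form is implemented because it is what
a per-pair summary table can support.

## The metric suite and its conventions

All metrics operate on the weighted, undirected, zero-diagonal matrix
$W = (w_{ij})$, $N$ nodes. Where a definition leaves freedom, the package
fixes one convention and tests it against an exhaustive brute-force oracle
on small graphs (all simple paths enumerated; triple loops for clustering),
to $10^{-10}$:

* **Edge length.** Shortest paths need a weight-to-length map; the package
  uses $1/w$, the standard choice for streamline densities: stronger
  connections are shorter. $L_{ij}$ is the Dijkstra distance under these
  lengths, $\infty$ for disconnected pairs.
* **Strength** $S_i = \sum_j w_{ij}$; **nodal efficiency**
  $E_{nod,i} = \frac{1}{N-1}\sum_{j\neq i} 1/L_{ij}$ with $1/\infty = 0$,
  so disconnected pairs penalize rather than break the metric.
* **Clustering.** The geometric-mean (Onnela) form
  $C_i = \sum_{j,h}(\hat w_{ij}\hat w_{ih}\hat w_{jh})^{1/3}/(k_i(k_i-1))$
  with $\hat w = w/\max w$. The max-normalization bounds $C_i \le 1$ (the
  unnormalized form is unbounded for $w > 1$) and leaves unit-weight
  graphs unchanged; $k_i$ is the binary degree; $C_i = 0$ when $k_i < 2$.
* **Betweenness.** $B_i = \frac{1}{(N-1)(N-2)}\sum_{j\neq h\neq i}
  \delta_{jh}(i)/\delta_{jh}$ over ordered pairs, i.e. twice the unordered
  Brandes sum with the printed prefactor, so $B_i \in [0,1]$.
* **Global metrics.** $E_{glob} = \mathrm{mean}_i\, E_{nod,i}$;
  $C_p = \mathrm{mean}_i\, C_i$; $E_{loc} = \mathrm{mean}_i$ of the global
  efficiency of each node's neighbor-induced subgraph (nodes with fewer
  than 2 neighbors contribute 0); $L_p = 1/E_{glob}$ — the harmonic-mean
  convention, *never* an arithmetic mean of finite distances, so the
  identity $L_p \cdot E_{glob} = 1$ holds by construction and is asserted
  in tests.
* **Vulnerability.** $V_i = (E_{glob} - E^{(i)}_{glob})/E_{glob}$, where
  $E^{(i)}_{glob}$ is the global efficiency of the $(N-1)$-node network
  after deleting node $i$. $V_i \le 1$; it can be slightly negative when
  removing a weakly connected node raises the average.

## Small-worldness

`small_worldness()` compares the network against `n_random = 100`
degree-matched surrogates: the topology is randomized by Maslov-Sneppen
double-edge swaps (10 attempted swaps per edge; swaps creating self-loops
or multi-edges are rejected, so rewiring-invariant topologies like the
triangle pass through unchanged), which preserves node count, edge count
and the exact degree sequence. The original weight multiset is then
reassigned to the rewired edges as a random permutation — the null matches
topology and the weight distribution, not the weight-topology coupling,
which is exactly what a degree-matched null should destroy. Then
$$\gamma = C_p/\bar C_p^{rand},\qquad \lambda = L_p/\bar L_p^{rand},
\qquad \sigma = \gamma/\lambda,$$
with ensemble *means* as the reference values. $\sigma > 1$ indicates
small-world organization. The whole ensemble is a deterministic function of
the seed.

## Group inference

`permutation_glm()` fits `value ~ group + age + sex` and tests the group
contrast by Freedman-Lane residual permutation: residuals of the
covariates-only model are permuted and added back to its fitted values,
and the full model is refit to each surrogate. This is the accepted scheme
for permutation inference in a GLM with nuisance covariates — permuting
raw observations would break the covariate structure, permuting group
labels alone ignores it. p-values use the add-one estimator
$p = (1+\#\{t^* \ge t\})/(1+n_{perm})$: never exactly zero, valid at any
permutation count. Default `n_perm = 10000`; one-tailed by direction, with
`two.sided` available.

`nodal_comparison()` runs the same test at all 82 nodes with one shared
permutation stream and corrects by the **max-statistic** distribution: the
corrected p of a node is the fraction of permutations whose maximum
statistic across nodes reaches that node's observed statistic. This
controls family-wise error without independence assumptions and is
monotone ($p_{FWE} \ge p_{unc}$, equal for a single node). A node whose
metric is constant across subjects has no residual variance and no valid
t; by default that is an error, and `on_degenerate = "omit"` excludes such
nodes from the family (reported `NA`), which the pipeline uses since
sparse networks routinely have all-zero clustering at some node.

## Network-based statistic

`nbs_compare()` tests all edges present (nonzero) in at least half of the
subjects of either group (the inclusion fraction is configurable; it
exists to keep near-absent edges from producing unstable fits). Edges are
screened at a one-tailed parametric p below `initial_p` — screening is a
component-forming device, not inference, so the cheap parametric cutoff is
appropriate — and connected components of surviving edges are extracted
(union-find, cross-checked against a flood-fill oracle in tests). The
inference is purely permutational: the null distribution of the *maximum
component extent* (edge count) is built from the same Freedman-Lane stream
shared by both directions, and each observed component gets
$p = (1+\#\{\max^* \ge \text{extent}\})/(1+n_{perm})$. Both a strict
(0.005) and a lenient (0.05) initial threshold are run by the pipeline
since the choice is arbitrary; decreases and increases are separate
one-tailed analyses. All components are returned with their p-values and
a `significant` flag at `alpha` so that threshold behavior (e.g.
`initial_p = 1` giving one spanning component) remains observable.

## Hubs and laterality

A node is a **hub** when its group-mean betweenness is at least one SD
above the across-node mean (sample SD over the 82 nodes). The rule is
applied to group-averaged nodal betweenness because a hub table is a
group-level statement; a per-subject voting mode is provided for
sensitivity analyses. When the across-node SD is zero no node can qualify;
the empty result is flagged `degenerate` rather than silently returned.

The **laterality index** of the frontal language area is
$LI = (L-R)/(L+R)$ over activated voxel counts in homologous ROIs;
$LI \ge 0.2$ classifies typical left-lateralization. Upstream fMRI
processing (activation mapping, ROI masking) is out of scope; inputs are
the per-subject voxel counts.

## The synthetic cohort generator

No subject-level imaging data are available to this package, so
`simulate_cohort()` generates cohorts with the statistical structure the
analysis assumes, making every stage testable end to end:

* **Shared backbone.** One Watts-Strogatz topology per cohort (ring
  lattice, `k = 8` neighbors, rewiring probability 0.1) with fixed
  log-normal edge weights; each subject multiplies every weight by
  independent log-normal noise (`sdlog = 0.2`). This mimics the
  within-population topological consistency of real connectomes — which
  the NBS and nodal tests implicitly assume — and gives every subject the
  small-world regime ($\sigma > 1$) observed in human structural networks.
* **Weights.** Log-normal, strictly positive and heavy-tailed like
  streamline densities; `meanlog = log(5.5e-5)` puts the implied
  whole-brain streamline count of a simulated summary near $7\times10^3$,
  the realistic order for deterministic tractography at this resolution.
* **Planted effect.** Patients' weights on a connected 8-edge set are
  multiplied by 0.7 (30% attenuation) by default; `effect_factor = 1`
  gives an exact null. Ground truth (the exact edge list) is returned.
* **Covariates.** Ages $\mathcal N(25, 4^2)$ / $\mathcal N(27.4, 7^2)$
  truncated at 18 for controls/patients; sex Bernoulli with 55.6%/57.1%
  probability; default sizes 27/14 — the power regime the method is
  typically used in. An optional `age_slope` plants a covariate-metric
  trend to exercise the covariate adjustment.
* **Streamline summaries.** `simulate_streamline_summary()` inverts the
  weight correction (volumes log-normal around 8,000 mm³, lengths uniform
  20-100 mm, counts rounded), so construction can be tested as a
  round-trip with a known error bound of $0.5/n_{ij}$ per edge, and
  sub-threshold connections reconstruct to zero by design.

What the generator does **not** emulate: spatial embedding (no
distance-dependent connection probability), hemispheric asymmetries,
lesion-induced focal topology change (effects are multiplicative on an
intact backbone), between-subject topological variability, and any
image-space process. Passing calibration and recovery tests therefore
demonstrates correctness of the statistics under the stated generative
model, not robustness to everything real data can do.

## Numerical choices and degenerate inputs

* Ties between shortest paths are resolved by exact path counting
  (Brandes); the brute-force oracle detects ties with a $10^{-9}$ relative
  tolerance.
* An empty network has $E_{glob} = 0$, $L_p = \infty$; vulnerability and
  small-worldness are errors there (explicitly, not NaN).
* `validate_connectome()` reports violations (asymmetry, negative weights,
  nonzero diagonal, dimension mismatch) instead of raising, so files can
  be screened; constructors raise.
* All randomized procedures (`simulate_cohort`, `matched_random_network`,
  `small_worldness`, permutation tests, NBS) take a `seed` and are
  bit-reproducible; `run_pipeline()` fans one user seed out to fixed
  per-stage offsets and records seed and config hash in its manifest.
* Hub sorting breaks ties by node label; percentages in the laterality
  summary are rounded to one decimal.

## Problem sizes used in the test suite

The suite verifies metric equivalence with the exhaustive oracle on 200
random graphs of 4-8 nodes (enumeration beyond that is combinatorial),
GLM calibration on 500 null datasets at 1,000 permutations, FWE and NBS
calibration on 200 null datasets/cohorts at 500 permutations, recovery on
50 seeded replicates at 200 permutations, and small-worldness on a
10 + 10 cohort with 100 random networks per subject. These sizes give
binomial confidence bands tight enough to detect miscalibration of a few
percentage points while keeping the suite quick to run; production
analyses should use the 10,000-permutation defaults.

## Known limitations

* Binary-network metric variants, directed networks, strength-preserving
  nulls, lattice-referenced small-worldness ($\omega$), intensity-weighted
  NBS extent and FDR-based edge inference are out of scope.
* The GLM assumes exchangeable subjects (no repeated measures or family
  blocks).
* With very sparse networks, parametric edge screening at `initial_p =
  0.005` relies on the t approximation in the screening step only; the
  component p-values remain exact permutation quantities.
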