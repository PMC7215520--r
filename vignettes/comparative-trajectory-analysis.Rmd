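---
title: "Comparing wild-type and variant protein trajectories with trajnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing wild-type and variant protein trajectories with trajnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajnet)
```

## The problem

A missense variant rarely unfolds a protein outright. More often it shifts
how the folded protein *moves*: which regions stay rigid, which loops open,
which residues keep carrying the shortest communication paths through the
structure. trajnet quantifies those shifts by comparing a wild-type (WT)
molecular dynamics trajectory against variant trajectories of the same
protein, residue by residue. The motivating use case is a monomeric
~270-residue carbonic anhydrase domain (author numbering starting at
residue 23) whose missense variants are linked to a cerebellar ataxia
phenotype, but nothing in the package is specific to that system.

The package operates on pre-processed, protein-only trajectories held as
multi-model PDB (one MODEL per frame, fixed atom topology). Water
stripping, imaging and centring are assumed to have been done by the MD
toolchain.

## Metrics

**Superposition.** All deviation measures use the closed-form Kabsch fit:
the proper rotation and translation minimising the sum of squared
distances between paired atoms, from the SVD of the cross-covariance
matrix. Reflections are excluded by sign-correcting the smallest singular
direction. Degenerate (collinear) point sets are rejected.

**RMSD and Rg.** `rmsd_series()` reports the per-frame best-fit RMSD of
the alpha-carbons to a reference frame (frame 1 by default; the choice is
exposed because different MD packages default differently). `rg_series()`
reports the unweighted radius of gyration
$R_g = \sqrt{\tfrac1n\sum_i \lVert r_i - \bar r\rVert^2}$; masses are not
used because the comparison is within one protein across variants, where
mass weighting only rescales all series alike.

**RMSF.** `rmsf_profile()` first superposes every frame onto the *iterated
mean structure*: compute a mean, fit all frames to it, recompute, and
repeat until the mean moves less than $10^{-6}$ Å or ten iterations. Then
$\mathrm{RMSF}_i = \sqrt{\langle \lVert r_i(t) - \langle r_i\rangle
\rVert^2\rangle_t}$. The first pass uses frame 1 as the provisional mean,
so the procedure is well defined even when the naive frame average is
degenerate (e.g. a rigid-body-tumbling trajectory). A consequence worth
knowing: because the fit is global, strongly heterogeneous fluctuation
redistributes a small amount of apparent motion from very mobile onto very
quiet residues. This is a property of fitted RMSF, not of the estimator;
comparisons between WT and variant (computed identically) are unaffected.

**Delta profiles.** All comparative profiles are WT minus variant
(`delta_profile()`), keeping the sign conventions used throughout:
negative ΔRMSF means the variant residue got *more* flexible; positive
ΔL means the variant residue got *more accessible* (its average graph
distance shrank); positive ΔBC means the variant residue's share of
shortest-path traffic — its "communication" — was *reduced*.

**KDE.** `kde_distribution()` summarises conformational sampling by a
Gaussian-kernel density of a per-frame series on a 512-point grid spanning
[min − 3h, max + 3h]. Bandwidth follows Scott's rule, because no single
bandwidth is canonical for RMSD distributions and Scott's rule is the
common default for unimodal-to-mildly-multimodal densities; it is
overridable. Peaks mark the most sampled conformations; a two-state
trajectory shows up as a bimodal RMSD density.

**Summary tables.** `summary_table()` reports per-protein means and
$100\,(\bar m_{WT} - \bar m_{var})/\bar m_{WT}$, printed at 3 and
2 decimals respectively with half-up rounding (matching how such tables
are normally typeset). An optional frame filter supports restricting the
means to an equilibrated tail; the default uses all frames.

## Dynamic cross-correlation

`dcc_matrix()` computes the normalised displacement correlation
$$C_{ij} = \frac{\langle \Delta r_i \cdot \Delta r_j\rangle}
{\sqrt{\langle|\Delta r_i|^2\rangle\,\langle|\Delta r_j|^2\rangle}},
\qquad \Delta r_i(t) = r_i(t) - \langle r_i\rangle,$$
over the alpha-carbons, after fitting frames to the iterated mean
structure (without fitting, rigid-body drift reads as spurious global
correlation; the flag is exposed for callers whose input is already
fitted). Residues with zero fluctuation have an undefined correlation and
are returned as missing with a warning rather than silently dropped.
`classify_motion()` turns the matrix into the fractions of residue pairs
moving anti-correlated / uncorrelated / correlated, using descriptive
cut points at ±0.25 (configurable; the outer bins include their cut
point, so thresholds at ±1 isolate exactly the perfectly correlated
pairs).

## Dynamic residue networks

Each sampled frame yields an undirected, unweighted graph: nodes are
residues, and an edge joins two residues whose beta-carbons (alpha-carbon
for glycine) lie within 6.7 Å. The boundary is inclusive (d ≤ cutoff), the
common contact-map convention, and switchable. No bonded pairs are
excluded: sequence neighbours are genuine contacts.

Two per-residue profiles are computed per frame:

* **L**, the average shortest path: the mean BFS distance from the
  residue's node to every *reachable* other node. A textbook variant of
  this quantity divides the grand total by $n(n-1)$, giving a single
  graph-global number; the per-residue form (divide each node's total by
  its reachable-partner count) is what a residue-resolved ΔL profile
  requires, so that is what `shortest_path_profile()` returns, with the
  global form available as `global_mean_path_length()`.
* **BC**, raw betweenness centrality: over unordered pairs, the sum of the
  fractions of shortest s–t paths passing through the node, endpoints
  excluded. Disconnected pairs contribute zero.

Graph distances and the Brandes accumulation are delegated to igraph; the
test suite verifies both profiles against independent brute-force oracles
(Floyd–Warshall distances; path counting via powers of the adjacency
matrix) on random graphs.

`average_profiles()` min–max normalises each frame's profile to [0, 1]
across residues and then averages over frames. Normalising per frame
(rather than over the pooled series) keeps every frame's profile on a
common scale regardless of how connected that particular snapshot is; the
pooled alternative and the raw averages are also available, and the raw BC
average is always reported. Frames whose profile is constant normalise to
zero with a warning. Residues disconnected in a frame are excluded from
that frame's normalisation and counted in `missing_counts`.

**Outlier selection.** `select_outliers()` flags residues whose Δ value
lies more than k (default 2) *population* standard deviations from the
mean of the Δ distribution, reporting increase and decrease lists
separately under the sign semantics above. Centring on the mean (rather
than zero) makes the rule invariant to a constant offset between the two
averaged profiles; k is configurable. A zero-SD distribution returns an
empty report with a note instead of dividing by zero.

Frame sampling uses a stride; when the analysis interval is given in
picoseconds the stride is `round(interval_ps / timestep_ps)` (100 ps is
the conventional network-analysis interval).

## The synthetic trajectory generator

Real multi-hundred-nanosecond trajectories are too large to ship and too
slow to regenerate, so the package includes a seeded generator whose
statistical structure is known exactly, making every estimator testable
against closed forms. Frame t is

$$r(t) = R_t\Big(\,b_{s(t)} + \textstyle\sum_k a_k\, z_k(t) + \varepsilon(t)\Big) + c_t$$

* **Base geometry** $b$: an ideal alpha-helix trace (rise 1.5 Å, 100°
  turn, radius 2.3 Å) or a compact self-avoiding random walk (3.8 Å
  bonds, 4.0 Å hard-sphere rejection) built from a *separate* geometry
  seed so WT/variant pairs share a topology. Beta-carbons sit 1.53 Å from
  the alpha-carbon along a deterministic local direction (radial for the
  helix, neighbour-bisector for the walk), absent for glycine.
* **Factors** $a_k z_k(t)$: each factor has a signed per-residue loading
  (Å) and an isotropic standard-normal 3-vector latent per frame. Two
  residues sharing a factor with loading a over per-axis jitter σ have
  expected correlation $a^2/(a^2+\sigma^2)$ — the latent being an
  isotropic 3-vector (rather than a scalar along a fixed axis) is what
  makes this simple form exact.
* **Jitter** $\varepsilon$: independent Gaussian, per-residue σ per axis,
  so sample RMSF converges to $\sqrt3\,\sigma_i$.
* **Rigid body** $R_t, c_t$: optional uniform random rotation plus a
  translation per frame; best-fit superposition must remove it exactly.
* **Two-state switching**: a second base geometry with a contiguous
  residue block displaced along the side-chain direction, toggled by a
  symmetric per-frame switching probability. A whole-body displacement
  would vanish under superposition, which is why the second state is a
  *local* deformation; it produces the bimodal RMSD density expected of
  two conformational clusters.

Latents and jitter are i.i.d. across frames: every estimator in the
package is frame-order invariant, so temporal autocorrelation would add
realism without adding test power. Defaults mirror the emulated study:
268 residues numbered 23–290, 2000 frames at 100 ps (a 200 ns run at the
100 ps network interval), σ = 0.5 Å (RMSF ≈ 0.87 Å, typical of a folded
domain), glycines at the positions the real protein has them. What the
generator does **not** emulate: secondary-structure realism beyond the
backbone trace, side chains beyond the beta-carbon, solvent, force-field
energetics, and temporal correlation. Passing tests therefore demonstrate
estimator correctness on trajectories of known structure, not fidelity of
any MD engine; and the compact-walk Rg (~34 Å at 268 residues) is larger
than a natively packed globin-like domain, since a self-avoiding walk is
less compact than a real fold.

`make_variant_pair()` builds matched WT/variant pairs differing only by a
prescribed perturbation (jitter scaling, factor-loading sign flip, or a
permanent base-geometry displacement), with the variant using an
independent noise seed. The packaged analysis scripts (`analysis/01` …
`05`) use exactly this machinery at full study scale: a WT with an
anti-phase motion factor plus a rigidified-N-terminus variant, a
flexible-loop variant, and a displaced-C-terminal-loop variant.

## Binding-site consensus

`consensus()` merges independently predicted binding-site residue sets
(parsed from plain one-label-per-line lists) by strict intersection or by
a majority rule (`majority(1)` = union, `majority(n)` = intersection).
Identity is the residue number — prediction tools disagree on formatting
far more often than on numbering — and name conflicts at a shared number
warn rather than fail. `annotate_consensus()` answers the membership
questions that follow (which variant positions fall inside the site?).
The package ships the three positional groups of the emulated study's
consensus site (14 + 12 + 12 = 38 unique residues) as reference data;
the underlying per-predictor lists were not published, so tests combine
the published groups with synthetic source sets.

## Numerical choices, in one place

* Superposition convergence: mean-shift < $10^{-6}$ Å or 10 iterations.
* Contact cutoff 6.7 Å, inclusive boundary; no bonded exclusion.
* Normalisation: per-frame min–max; constant frames → 0 with warning.
* KDE: Gaussian kernel, Scott's rule bandwidth, 512 grid points,
  ±3 bandwidths of padding.
* Outlier rule: mean ± k·(population SD), k = 2 by default.
* Correlation classification: outer bins closed at ±0.25 cut points.
* Table rounding: half-up, 3 decimals for means, 2 for percents.
* PDB dialect: ATOM/HETATM/MODEL/ENDMDL/TER only; altloc blank/"A";
  insertion codes rejected; non-standard residues rejected unless
  explicitly mapped to their parents (e.g. MSE→MET); single chain
  assumed unless a chain is named.

Problem sizes in the shipped tests were chosen to make each statistical
property sharp at a fixed seed: 2000 frames for RMSF recovery (sampling
error ≈ 1.6%), 5000 for the factor-model correlation check (±0.05), 30
random graphs of up to 12 nodes for the exhaustive graph oracles, and a
120-residue, 300-frame pair for the null-difference control.

## Worked example

```{r example}
cfg <- generator_config(n_residues = 60, n_frames = 400, seed = 1,
                        base_geometry = "compact_walk")
pair <- make_variant_pair(cfg, list(type = "sigma_scale",
                                    residues = 50:60, value = 2.5),
                          labels = c("WT", "S100P-like"))
rep <- run_comparison(list(WT = pair$wt, `S100P-like` = pair$variant))
cat(render_tables(rep), sep = "\n")
```

The flexibilised block 50–60 appears in the ΔRMSF decrease list
(`rep$outliers[["S100P-like"]]$deltaRMSF$decrease`), and the network
quadrants report any contact rewiring it caused.

## Known limitations

* Disconnected contact graphs yield missing L values; heavily fragmented
  frames (tiny cutoffs) make the normalised averages less comparable.
* The outlier rule assumes the Δ distribution is roughly unimodal; a
  variant perturbing half the protein violates the "outlier" premise.
* `read_multimodel_pdb()` targets clean, model-built single-chain input;
  it is not a general PDB archaeology tool.
* Percent differences are undefined for a zero WT mean (not reachable
  for RMSD/Rg of a non-static trajectory).
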