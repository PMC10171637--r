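---
title: "Methods: gridded multi-dimensional marine biodiversity analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gridded multi-dimensional marine biodiversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biodivgrid)
```

## The problem

Conservation planning for the ocean has mostly optimized a single currency
— species richness. Two further dimensions carry independent information:
**genetic diversity** (GD), the within-species variability that determines
evolutionary potential, and **phylogenetic diversity** (PD), the amount of
evolutionary history a set of species spans. `biodivgrid` implements a
complete, testable pipeline that maps all three dimensions onto an
equal-area analysis grid, identifies conservation-priority cells from
their joint distribution, and quantifies how much of each dimension any
protected cell set actually conserves.

The pipeline operates on an **abstract planar grid**, not a geodesic ocean
map. Every downstream computation needs only cell adjacency, centroids and
areas, so removing cartography (projections, coastlines, shapefiles) from
the analysis surface makes each stage exactly checkable. The default cell
side of 385.9 km matches the resolution commonly used for global marine
gridding; cells whose ocean fraction is below 50% are excluded from every
surface (a cell with exactly 50% ocean is retained — the exclusion rule is
strict).

## Genetic diversity from barcode alignments

Per species, nucleotide diversity is estimated as the mean pairwise
**p-distance** over its aligned barcode sequences:

- alignment columns where either sequence carries a gap, `N` or an IUPAC
  ambiguity code are not compared at all (they count neither as match nor
  mismatch — no ambiguity-scoring scheme is invented);
- a pair contributes only when its **overlap** (compared columns /
  alignment length) exceeds 0.60 and its **difference** (mismatches /
  compared columns) is below 0.10. Both bounds are strict: ties are
  excluded. The difference filter guards against misidentified or
  paralogous sequences, the overlap filter against barely-overlapping
  fragments;
- π is the arithmetic mean of the surviving pairwise differences, with no
  multiple-hit (Jukes–Cantor) correction — at barcode-scale divergences
  (<10% by construction) saturation is negligible, and the uncorrected
  distance is the measure the macrogenetic literature aggregates;
- species need at least `min_sequences` sequences (default 2, the minimum
  that yields a pair) for an estimate; the threshold is exposed because
  sensitivity analyses vary it.

π is estimated once per species from **all** of its sequences, wherever
sampled; a cell's GD is then the arithmetic mean of π over the species
present in the cell, `GD = (1/S) Σ π`. Cells where no present species has
an estimate carry a missing value and are excluded from maps and
clustering. The alternative — re-estimating π from within-cell sequences
only — is noted as an open interpretive choice; the global reading is used
because barcode sampling locations are far too sparse to support per-cell
re-estimation.

## Phylogenetic diversity and its standardized effect size

**Faith's PD** of a cell is the summed branch length of the minimal
subtree connecting its species, *including the path to the root*: a
single-species cell scores its tip-to-root distance. This matches the
rooted convention of the standard picante implementation; the root path
can be switched off (`include_root = FALSE`).

Because PD grows mechanically with richness, cells are compared through
the **standardized effect size**: `SES-PD = (PD_obs − mean(PD_null)) /
sd(PD_null)`, where the null shuffles taxa labels — equivalently, draws
communities of the same size uniformly without replacement from the
species pool (default 1000 randomizations). The pool is the full species
list of the presence matrix, not a regional neighborhood; that is the
literal reading of a taxa-label randomization, and the alternative is
noted. Cells equal to the whole pool have a degenerate null (zero spread)
and their SES is flagged undefined rather than fabricated.

Implementation note: PD of any community reduces to one product of an
edge-by-tip incidence matrix with a selection vector, so surfaces and
nulls are computed in batch. Since the label-shuffle null depends only on
community *size*, `pd_surface()` shares one null sample per distinct
richness value across cells; `ses_pd()` on a single community always
draws its own nulls.

Cells are classified into SES-PD deciles (`top10` / `bottom10` /
`middle`) by nearest rank: the `ceiling(0.1 n)` highest and lowest
defined-SES cells, ties broken by cell ID so the classification is
reproducible. An all-equal SES distribution is a classification error,
not a silent all-middle.

## Spatially corrected correlation (modified t-test)

Grid surfaces are spatially autocorrelated, so the nominal n of a Pearson
correlation wildly overstates the information available. The
`modified_t_test()` keeps the correlation estimate untouched and corrects
only the significance, following the Clifford–Richardson moment estimator
in Dutilleul's usage: per-surface autocorrelations are estimated in 10
equal-width classes of inter-centroid distance spanning the observed
range, and the effective sample size is

```
m_eff = n / (1 + (2/n) * sum_k N_k * rho_x(k) * rho_y(k))
```

with `N_k` the pair count of class `k`. `m_eff` is clamped to `[2, n]`
(a non-positive denominator means the estimator diverged and is treated
as "no reduction"); the t statistic then uses `df = m_eff − 2`.
Distances are Euclidean on the planar centroids, consistent with the
abstract-grid design. The class count and estimator are package choices —
they are *not* inferred settings of any particular prior analysis. The
test suite verifies type-I calibration on white noise (rejection rate at
α = 0.05 within [0.03, 0.07] over 1000 simulations on a 15 × 15 grid) and
that the correction both shrinks `m_eff` and repairs the inflated
rejection rate on Gaussian-blurred independent surfaces.

## Prioritization

Cells with all three dimensions defined enter a feature table of min–max
normalized SR, GD and SES-PD (a constant column maps to zeros with a
warning). Cells missing any dimension are excluded and can never be
priority cells; their count is reported. The cells are clustered by
k-means (best of 25 restarts, deterministic under a seed; k = 6 by
default, or chosen by mean silhouette width over k = 2..10 via
`select_k()`). Clusters are scored by the mean over member cells of the
(by default equally) weighted mean of the three normalized dimensions —
the neutral aggregation when no weighting is stated — with ties broken by
larger cluster size, then lower cluster index. The cells of the top 3
clusters form the priority set, reported with the fraction of retained
ocean cells it covers. Both `k`, `n_top` and the dimension weights are
configurable.

## Conservation-efficiency assessment

Any cell set is scored on three percentages, each 100 for the full cell
set and 0 for the empty one:

- **taxonomic**: share of species present in at least one set cell (a
  species counts as conserved from a single covered cell — no minimum
  range-fraction threshold);
- **genetic**: π-weighted species coverage, `Σ π over covered species /
  Σ π over all species` (with estimates). The unweighted mean of π over
  covered species was rejected because it is not monotone under adding
  cells; the weighted form is the simplest monotone measure sensitive to
  which species are covered. This definition is the leading interpretive
  risk of the module and is flagged as such;
- **phylogenetic**: Faith's PD of the covered species as a share of the
  PD of all presence-matrix species on the tree. The denominator uses the
  presence species (not all tree tips) so that covering every cell scores
  exactly 100 even when the tree is larger than the range data — the two
  readings coincide whenever tips and species match.

The null model is an **accumulation curve**: for each sample size, 1000
random cell sets drawn uniformly without replacement from the retained
cells (no area weighting), summarized by the mean and the percentile 95%
band. `compare_to_null()` places an observed set `below` / `within` /
`above` the band and reports a two-sided empirical p. Percentile (not
normal-approximation) intervals are used throughout.

## The synthetic world generator

`generate_world()` builds every pipeline input with known ground truth:

| component | model | default |
|---|---|---|
| grid | planar rows × cols, ocean-fraction exclusion | 20 × 20, side 385.9 km, all ocean |
| ranges | spreading dye: seed cell biased toward the hotspot by `exp(−strength · d/d_max)`, grown through ocean 4-neighbors to a lognormal target size | meanlog log(12), sdlog 0.6, strength 3 |
| tree | pure-birth (Yule) via `ape::rphylo`, tips relabeled | birth rate 1 |
| θ | uniform on [θ_low, θ_high], multiplied for species touching the hotspot | [0.002, 0.02], factor 2 |
| sequences | star-shaped mutation from one random ancestor, per-site substitution probability θ/2 | mean 8 sequences × 500 sites |
| SST | Gaussian bump at the hotspot + white noise | base 8 °C, amplitude 18, noise SD 1 |
| MPA | cells sampled with weight `exp(avoidance · d/d_max)` | 15% of cells, avoidance 3 |

With per-lineage substitution probability `q = θ/2`, the expected
pairwise difference is `2q(1−q) + (2/3)q² ≈ θ(1 − θ/3)` — within 2% of θ
for θ ≤ 0.05, which is why the estimated-π-versus-true-θ regression slope
is required to lie in [0.7, 1.3] only at small θ. A range target larger
than the number of ocean cells is an error naming the species; a range
that stalls on an exhausted connected component simply stays smaller than
its target. Sequence sampling coordinates are cell-centroid jitters and
decimal degrees are reinterpreted as planar km; the spatial density of
sequences per species is exposed (`seq_per_species_mean`) rather than
fixed, since no canonical value exists.

What the generator deliberately does **not** emulate: within-species
coalescent topology (the star model only controls pairwise differences),
realistic climate fields, geodesic geometry, and taxonomic sampling bias.
Passing tests therefore demonstrate the correctness and calibration of
the machinery, not the field accuracy of any real-world map.

`write_world()` / `read_world()` round-trip a world exactly: coordinates
are generated pre-rounded to 4 decimals, branch lengths to 6, SST to 4,
so the plain-text forms (FASTA with `seqID|speciesID|lat|lon` headers,
Newick, CSV, JSON manifest) are lossless; the grid is rebuilt from the
manifest config rather than re-parsed from decimal text.

## Numerical and design choices

- **Strict filter boundaries** (overlap > 0.60, difference < 0.10):
  literal reading of the stated rule; ties excluded.
- **Presence by positive-area intersection** for polygon ranges (not
  centroid-in-polygon): range maps are coarse, and any overlap is treated
  as presence.
- **Grid indexing** is row-major from the NW corner, origin at the NW
  cell centroid; cell area is `side²` (a printed nominal cell area is
  treated as descriptive).
- **k-means** uses the stats implementation (Hartigan–Wong, best of 25
  restarts). The k = n trivial partition is returned directly, as the
  implementation refuses that case.
- **Resolution sensitivity** aggregates the base grid by integer block
  factors (presence = any member cell, ocean fraction = mean, exclusion
  re-applied) and compares the coarse GD surface against the
  block-averaged base surface on the same coarse cells — cross-resolution
  cell matching is otherwise undefined on an abstract grid. Surfaces on
  different grids are never paired directly.
- **Seeds**: every stochastic operation takes an explicit seed and
  restores the caller's RNG stream. The pipeline derives per-stage seeds
  from one global seed by stage-name hashing, so any stage can be
  reproduced in isolation.
- **Problem sizes** used by the test suite (15–20 cells per side, 40–150
  species, 100–1000 randomizations/replicates) were chosen so the
  statistical assertions have the power they need while the whole suite
  stays fast; the acceptance properties (oracle equivalences, null
  calibration, type-I error, end-to-end hotspot recovery) state their
  sizes explicitly.

## Worked example

```{r example, eval = FALSE}
world <- generate_world(world_config(seed = 1))
pi_tab <- species_pi_table(world$alignments)        # per-species pi
gd  <- gd_surface(world$presence, pi_tab)           # per-cell GD
sr  <- richness_surface(world$presence)             # per-cell SR
pd  <- pd_surface(world$tree, world$presence, n_rand = 1000, seed = 2)
ses <- setNames(pd$ses_pd, pd$cell_id)

features <- build_feature_table(sr, gd, ses)
model <- rank_and_select(features, kmeans_cluster(features, 6, seed = 3),
                         n_top = 3, n_total_cells = nrow(world$presence))

report <- coverage_report(model$priority_cells, world$presence, pi_tab,
                          world$tree)
curve <- accumulation_curve(world$presence, pi_tab, world$tree,
                            sample_sizes = report$n_cells,
                            n_replicates = 1000, seed = 4)
compare_to_null(report, curve)
```

Or, end to end from a config:

```{r pipeline, eval = FALSE}
run_pipeline(list(seed = 1, out_dir = "run1",
                  world = list(grid_rows = 20, grid_cols = 20)))
```

## Known limitations

- The genetic-percentage-conserved definition is a package choice (see
  above); no canonical definition exists.
- The SES-PD randomization pool is global; regional pools would give
  different (typically attenuated) effect sizes.
- The modified t-test's class count (10) matters in small grids; the
  estimator is a moment method, not an exact correction.
- Real-data ingestion (shapefiles, GeoTIFF climatologies, sequence
  retrieval, alignment, tree inference) is out of scope: inputs are
  pre-aligned FASTA, Newick, and CSV tables.
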