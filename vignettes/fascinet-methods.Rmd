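---
title: "Modelling fascin-crosslinked actin bundles: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling fascin-crosslinked actin bundles: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fascinet)
```

## The problem

Fascin crosslinks parallel actin filaments (F-actin) into hexagonally
packed bundles, the structural core of filopodia. F-actin is a helical
polymer: successive protomers are related by a twist of about
-166.7 degrees and an axial rise of 2.75 nm, so the filament's surface
pattern repeats only every crossover (~37 nm), while the bundle lattice
imposes a flat 12.15 nm hexagonal geometry. These two symmetries are
incommensurate. The package implements a minimal generative model of
how a plastic crosslinker negotiates that mismatch -- which relative
filament rotations it tolerates, which emergent binding patterns
(linear, slanted and chevron crossbands) appear, and how an excess of
strained crossbridges partitions bundles into internally stable
clusters.

## The model

### Geometry

A filament is a chain of protomers indexed `k = 0, 1, ...` from the
barbed end, placed on a lattice site `(x, y)` with the axis along +z:
protomer `k` has azimuthal phase `theta + k * twist` and height
`k * rise`. Three fiducial sites per protomer (the CA positions of
residues D24, R95 and S350, stored as cylindrical offsets) represent
the fascin-contacting surface. The packaged fiducial table is a
**synthetic stand-in** with plausible actin-surface coordinates
(radii 2.3-2.6 nm); it is not measured from a deposited structure, and
every downstream quantity is self-consistent with whatever table
replaces it (`fiducial_geometry()` accepts any three-row table).

### Crossbridge scoring

A candidate "up"-pose bond engages protomers `i`, `i+2` on filament A
(actin-binding site 1) and `j+1`, `j+3` on filament B (site 2). Five
distances are scored: the four inter-site distances
`|R95_i - R95_(j+1)|`, `|R95_i - S350_(j+3)|`, `|D24_(i+2) - S350_(j+3)|`,
`|D24_(i+2) - R95_(j+1)|`, and the distance from the centroid of the
four sites to the plane containing both filament axes (which penalizes
out-of-plane distortion). Each distance `d_n` contributes a Gaussian
probability

```
P_n(d) = exp(-((d - mu_n) / (m * sigma_n))^2 / 2)
```

and the composite bond probability is the product `P = prod(P_n)`. The
factor `m` (default 4) widens every Gaussian and is the model's single
knob for crossbridge structural plasticity; `tau` (default 0.4) is the
minimum probability for a bond to form. A formed bond has normalized
energy `Ec = -1/P`; an unformed one has `Ec = 0`. Both conventions are
implemented exactly as stated; all ranking and optimization uses `P`
directly, so the sign of `Ec` never enters a decision.

The "down" pose is the same scoring applied to the swapped ordered
pair. Two useful exact symmetries follow from the helix:

* rotating *both* filaments of a pair by the per-subunit twist relabels
  every protomer up by one, so the optimal bond indices shift down by
  one at identical probability (the landscape's teardrop periodicity);
* rotating the pair 180 degrees about its midpoint exchanges the two
  filaments and adds 180 degrees to both spins, giving
  `P(a, b) = P(b + 180, a + 180)` with the pose flipped. Cells with
  `a - b = 180` map onto themselves and hold exactly isoenergetic up
  and down candidates.

### Score parameterization

The experimentally fitted `(mu_n, sigma_n)` table (from multibody
refinement of crossbridge particles) is not redistributed here;
`synth_score_params("experimental")`
fails with transcription instructions rather than substituting
anything. All quantitative work ships with the self-consistent
`"idealized"` set: the five `mu_n` are measured on a reference
crossbridge -- an in-register pair at 12.15 nm spacing, up pose, at the
candidate with the smallest mean inter-site distance -- and
`sigma_n = 0.05 * mu_n` (plane distance: `sigma_5 = 0.25` nm). Two
details matter:

* `mu_5` is *measured*, not fixed at zero: with the synthetic fiducial
  table the site centroid sits ~0.47 nm off the inter-axis plane at
  every in-register optimum, and measuring all five means is the only
  choice that makes the reference bond score exactly `P = 1`.
* the raw optimum lies at the filament end (the crossover phase happens
  to peak there for rotation zero), so the reference is recentred on
  the filament midpoint through the exact screw equivalence: candidate
  `(i - k, j - k)` at common rotation `k * twist` has identical
  geometry. The common reference rotation (79.8 degrees for the
  packaged table) is carried in the `reference` attribute and is what
  the planted-bundle generator means by "registered".

### Assembly

`assemble()` grows a bundle one filament at a time. The first filament
takes a random (or fixed) rotation; each later filament is placed on
the next lattice site having at least two already-placed bridgeable
neighbours (one for the second filament) and swept through rotations
0-359.9 degrees in 0.1-degree steps. At each angle, every candidate
bond with `P >= tau` against every neighbour is nominated; the
one-bond-per-protomer rule is enforced greedily in descending `P`; the
angle is scored by the summed probability of accepted bonds, and the
best angle wins (ties go to the smaller angle; with no candidate at
all, a seeded uniform rotation is drawn). Bonds never change after
acceptance. "Maximum overall score" is implemented as the accepted
probability mass because it reduces exactly to the pairwise
maximum-P rule when only one neighbour exists.

The sweep is evaluated by a small compiled kernel: every scored
distance is a sinusoid in the rotation angle
(`d^2 = C + R cos(theta + delta)`), so candidates reduce to
precomputed constants, impossible candidates are pruned by their
attainable distance range (a bound keeping only components with
`P_n > 1e-9`), and probabilities are tracked as log-quadratic scores
with exponentiation only at threshold hits. A brute-force maximizer
built solely on `candidate_distances()` serves as the independent
oracle in the test suite.

## Emergent-pattern observables

`contact_map()` accumulates bond anchors over seven-filament bundle
elements aligned on the central filament (anchor convention: base
protomer `i` on the site-1 filament, `j+1` on the site-2 filament).
`classify_crossband()` bins consecutive phase shifts at half-way
boundaries (about 0 means `|s| < 12.5`; about +/-25 means within 12.5
of the one-subunit-equivalent rotation 26.7 degrees) and labels planes
linear, slanted, or chevron (one sign reversal, pointing either way --
a reversed chevron is its own mirror image).

`extract_triplets()` measures, for every co-linear three-filament run
with a fascin on each interface within half a crossover, the cumulative
phase shift, the fascins' axial offset, and whether their poses match.
The axial offset is reported in **fascin repeat units**: 1.0 is the
5.5 nm spacing between equivalent same-pose binding positions (one
subunit step along a long-pitch strand, i.e. two protomer rises). The
choice follows from the model's own symmetry: a bond pattern recurs on
the same strand pair only every second protomer, so the natural
quantum of fascin axial displacement is 5.5 nm, and half-steps (one
protomer rise) occur exactly when the pose flips. Under planted
rotations this reproduces the observed rule table --

| cumulative shift | poses | axial offset |
|---|---|---|
| about 0 | same | 0 |
| about -27 | opposite | 0.5 |
| about -53 | same (both down) | 1 |

-- with one caveat: at a chevron's turning point the model may realize
the "wobble" configuration (opposite poses, half-step offset) instead
of the strict about-0 rule, which is precisely the degeneracy that
lets crossbands switch direction.

## Interface graphs and clustering

Per-crossbridge strain is the Mahalanobis distance of multibody
eigenvector amplitudes restricted to the rotational subspace
(`eigen_model()` carries the mask; both diagonal and full covariances
are supported). An interface with `N` crossbridges of mean strain
`Ebar` over a region of length `L` scores
`F.I.S. = (N / L) / (1 + Ebar)`; bundle regions become weighted graphs
with one edge per bridged filament pair.

Ward clustering needs a dissimilarity: adjacent filaments take
`1 / (F.I.S. + 1e-6)` and non-adjacent pairs the shortest-path sum of
adjacent dissimilarities, which makes weak interfaces the preferred
split points. Linkage heights are normalized by the maximum across the
supplied graph set; disconnected components are clustered independently
and merged at normalized distance 1. Metric curves are evaluated at
every partition of the merge sequence (cutting by cluster count, which
is robust to tied heights): average transitivity over clusters of at
least three filaments, weighted Newman modularity (weights = interface
scores, resolution 1), and cluster-size summaries; peaks take the
arg-max, ties to the smaller distance.

One genuine limit is worth knowing: plain Newman modularity cannot
resolve two planted clusters of twelve filaments in a 24-node region
-- the optimum subdivides them regardless of the algorithm used to
find it (an independent Louvain maximization returns the same four
communities), even though the dendrogram's final merge recovers the
planted two-split exactly. Planted-recovery validation therefore runs
at the scale the experimental analysis actually found: three clusters
of eight filaments, matching the observed mean cluster size at the
modularity peak. At that scale recovery is exact (adjusted Rand index
1 across twenty seeds) and every between-cluster edge at the peak is
weaker than every within-cluster edge.

## Synthetic data

The generators replace the study's cryo-EM inputs with draws that have
the statistical structure the analysis assumes:

* `synth_score_params()` -- the idealized score table above;
* `synth_bundle_coords()` -- single actin planes with planted rotation
  patterns (registered / slanted / chevron / random, defaults: 21
  protomers so slanted chains stay clear of filament ends, one fascin
  per interface as observed) decorated by `best_bond()` under the
  occupancy rule, with ground truth attached;
* `synth_eigen_amplitudes()` -- Gaussian amplitude vectors (default six
  eigenvectors, three rotational, unit variances) with a planted
  outlier fraction; the mean squared Mahalanobis distance equals the
  masked dimension, the chi-square expectation;
* `synth_bundle_graph()` -- a three-layer region of 24 filaments with
  near-complete decoration (about one fascin per interface per
  crossover, mean 10 per 400 nm) partitioned into three contiguous
  planted clusters; between-cluster interfaces have their score scaled
  by `weak_factor` via inflated boundary strain.

What passing tests show -- and what they do not: the generators verify
the algorithms (scoring symmetries, planted-pattern recovery,
planted-partition recovery) but not the experimental parameter regime.
In particular, the synthetic fiducial table produces a frustrated
multi-neighbour landscape whose freely assembled bundles settle into
larger inter-filament rotations than the real system, so the triplet
rule table is reproduced on planted configurations rather than on free
assemblies, and the m/tau sweep's quantitative fractions (median
crossbridge fraction 0 below m = 4; no bonds at m = 4 with tau > 0.6)
are properties of the unavailable experimental score table that this
package deliberately does not imitate.

## Numerical choices

* All angles are degrees; reductions to `[0, 360)` and `(-180, 180]`
  funnel through two wrappers so repeated wrapping cannot drift.
* Tie-breaks are deterministic everywhere: candidate order is pose
  "up" first, then smaller `i`, then smaller `j` (plus neighbour id in
  assembly); equal sweep scores go to the smaller angle; equal curve
  peaks to the smaller distance.
* Bridgeable-pair tolerance is 0.5 nm, far below the 9 nm gap to the
  second-neighbour lattice distance.
* Degenerate inputs error early and explicitly: coincident axes (no
  inter-axis plane), fiducial tables without exactly the three
  residues, singular covariances (with a regularization hint),
  single-node graphs, lattices too small for the requested filaments.
* Every stochastic routine takes an explicit seed and records it; the
  pipeline manifest hashes all outputs, and identical configurations
  reproduce identical files.

## Problem sizes

The shipped demonstration configuration (`demo_config()`) runs ten
7-filament bundle elements with central rotations spanning 0-10
degrees, eight 22-filament three-layer bundles, the m = 4 tau sweep
(8 tau values x 50 runs), and twenty planted graph regions; it
completes in about a minute on one CPU. The full 7 x 8 x 50
parameterization grid (2,800 pairwise runs) takes a few minutes. Test
fixtures use the same generators at the same or smaller sizes.

## Known limitations

* Filaments are rigid, straight and z-registered; no twist-bend
  coupling, no axial offsets, no bond breakage or thermodynamics.
* The fiducial table and score set are synthetic stand-ins; absolute
  probabilities and sweep fractions are not comparable to the
  experimental parameterization (see above).
* The double helix is represented as one genetic helix; strand
  identity is index parity.
* Mahalanobis strain is an input (measured or simulated), not derived
  from the assembly model's own geometry.
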