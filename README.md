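# fascinet

Fascin-crosslinked actin bundle assembly and network analysis in R.

Fascin bundles parallel actin filaments (F-actin) into the hexagonal
arrays that fill filopodia. The two geometries involved are
incompatible: F-actin is a helix (twist ≈ −166.7° and rise 2.75 nm per
protomer, crossover repeat ≈ 37 nm), while the bundle lattice spaces
filament axes 12.15 nm apart on flat hexagonal sites. `fascinet`
implements a minimal generative model of how a structurally plastic
crosslinker negotiates that mismatch, plus the network-level analyses
that read out its consequences: emergent crossband morphologies,
three-filament binding rules, and the interface-weighted graph
clustering that exposes stable sub-bundle clusters.

## The model in brief

A candidate fascin crossbridge between protomers *i*, *i*+2 of
filament A and *j*+1, *j*+3 of filament B is scored through five
distances *d₁..d₅* between fiducial surface sites (four inter-site
distances plus the offset of their centroid from the inter-axis
plane). Each contributes a Gaussian probability

> *Pₙ(d) = exp( −((d − μₙ) / (m·σₙ))² / 2 )*

and the bond probability is the product *P = ∏ Pₙ*, with normalized
energy *E_c = −1/P* for formed bonds and 0 otherwise. The factor *m*
(default 4) encodes fascin's structural plasticity; bonds require
*P ≥ τ* (default 0.4). Bundles are assembled filament by filament:
each newcomer sweeps its rotation in 0.1° steps and keeps the angle
maximizing the summed probability of its accepted bonds, under a strict
one-fascin-per-protomer rule. Downstream, bundle regions become
weighted graphs through the filament interface score
*F.I.S. = (N/L) / (1 + Ē)* (crossbridge density discounted by mean
Mahalanobis strain), clustered by Ward linkage with transitivity and
modularity curves.

Everything runs from synthetic inputs: the score table, planted
bundles, multibody-style amplitude vectors and planted bundle graphs
are all generated in-package (see the methods vignette,
`vignettes/fascinet-methods.Rmd`, for what they do and do not emulate).

## Worked example

Score parameters, a seven-filament bundle element, and cluster
recovery on a planted bundle region:

```r
library(fascinet)

params <- synth_score_params()    # self-consistent "idealized" set
params
#> Crossbridge score parameters [idealized]: m = 4, tau = 0.4
#>  distance        mu     sigma
#>        d1  7.524709 0.3762354
#>        d2  8.457213 0.4228606
#>        d3  9.157564 0.4578782
#>        d4 10.753990 0.5376995
#>        d5  0.471042 0.2500000

crossover_length(helical_params())
#> [1] 37.21805

cfg <- assembly_config(hex_lattice(1), n_filaments = 7, n_protomers = 16,
                       params = params, seed = 42, first_site = 1,
                       first_rotation = 5)
bundle <- assemble(cfg)
summary(bundle)
#> Bundle of 7 filaments, 12 fascin crossbridges
#> Phase shifts vs filament 1 (deg):
#> [1]  0.0  0.8 -4.3 -2.2 -0.5 -3.4 -2.6
#> Crossbridge P:    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.9811  0.9863  0.9891  0.9896  0.9924  0.9988
```

The element forms exactly twelve crossbridges -- one per bridgeable
filament pair -- in a mix of "up" and "down" poses, with the small,
heterogeneous inter-filament phase shifts characteristic of these
assemblies. Graph analysis of a planted 24-filament region:

```r
region <- synth_bundle_graph(seed = 1)        # 3 planted clusters of 8
cl  <- hierarchical_cluster(region$graph)
met <- cluster_metrics(cl[[1]], region$graph)
met
#> Cluster metric curves over 24 cut heights
#>   transitivity peak at distance 0.038; modularity peak at 0.117

part <- met$peaks$modularity$partition
table(planted = region$labels, recovered = part[names(region$labels)])
#>        recovered
#> planted 1 2 3
#>       1 8 0 0
#>       2 0 8 0
#>       3 0 0 8
```

The modularity peak recovers the planted clusters exactly, and the
boundaries between recovered clusters run along the weakest (lowest
F.I.S.) interfaces.

The end-to-end demonstration -- bundle elements, 22-filament bundles,
the m = 4 τ-sweep and graph recovery, with a hashed manifest -- is one
call:

```r
run_pipeline(demo_config(seed = 1, out_dir = "demo_run"))
```

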