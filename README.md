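# lensmorph

Anuran (frog and toad) eyes cross an optical boundary during
metamorphosis: aquatic tadpoles need powerful, near-spherical lenses
because the cornea refracts almost nothing under water, while terrestrial
adults pair a refractive cornea with a flatter lens. `lensmorph` is an R
package for quantifying that transition from micro-CT data and testing
its ecological correlates across species. It is aimed at comparative
morphologists working with segmented volumes of museum specimens and a
species phylogeny.

The package has two halves:

**Imaging → shape metrics.** From a segmented voxel volume (multi-page
TIFF or NRRD, with physical voxel spacing) it computes, per lens label,
the covariance eigenvalues `l1 ≥ l2 ≥ l3` of the voxel point cloud and
the four standard 3D shape descriptors

    anisotropy = 1 − l3/l1      flatness  = l3/l2
    elongation = l2/l1          sphericity = π^(1/3) (6V)^(2/3) / A

(a perfect sphere scores 0, 1, 1, 1), plus volume, surface area from a
smoothed closed isosurface mesh (marching tetrahedra + Laplacian
smoothing), and transverse (naso-temporal) diameters.

**Comparative statistics.** Species-level analyses implemented from
first principles and cross-checked against independent implementations:
phylogenetic covariance from the tree, PGLS with maximum-likelihood
Pagel's λ (`y = Xβ + ε`, `ε ~ N(0, σ²V(λ))`, λ profiled on [0, 1]),
multivariate phylogenetic signal K_mult with permutation inference,
Welch t-tests, PCA of species means, a collinearity screen, and pairwise
post-hoc contrasts with compact-letter summaries. A four-stage pipeline
(`run_all()`) strings these into the full analysis: life-stage
comparison, metamorphosis deltas, adult ecology, and relative lens size.

A synthetic-data module generates voxel phantoms with analytic ground
truth (`make_phantom()`), pure-birth trees (`make_tree()`), λ-scaled
Brownian traits (`simulate_bm()`), and complete study datasets with
known effect sizes (`make_study()`), so every stage is testable without
any downloads.

## Worked example

```r
library(lensmorph)

# imaging: an axially flattened spheroid phantom (semi-axes 12, 24, 24 voxels)
ph <- make_phantom(phantom_spec(shape = "ellipsoid",
                                semi_axes = c(12, 24, 24), grid = 56,
                                spacing = 0.01))
compute_shape_metrics(ph$volume, 1)
#> <lens_shape_metrics>
#>   anisotropy 0.7482 | flatness 0.2518 | elongation 1.0000 | sphericity 0.9221
#>   volume 0.029056 mm^3, surface area 0.495683 mm^2 (29056 voxels)
```

Halving one semi-axis moves anisotropy to `1 − (c/a)² = 0.75` and
flatness to `0.25` while elongation stays 1 (the two long axes are
equal); sphericity drops below 1 because the spheroid has more surface
per unit volume than a sphere.

```r
# a full synthetic study: 126 species, 121 adults / 50 tadpoles / 45 paired
bundle <- make_study(study_spec(seed = 2))
run <- run_all(bundle$table, bundle$tree, lens_config(seed = 2, n_perm = 999))

run$reports$lifestage$statistics$t_tests
#>       metric          t        df            p mean_adult mean_tadpole
#> 1 anisotropy 11.8387982 133.17910 1.540341e-22  0.2448117    0.1106307
#> 2 sphericity -4.3792494 119.87299 2.563497e-05  0.9284615    0.9511016
#> 3 elongation  0.1478133  90.19041 8.828200e-01  0.9281688    0.9271219

run$reports$metamorphosis$statistics$slopes
#>       metric environment     estimate   std.error
#> 1 anisotropy     aquatic -0.039514822 0.021653870
#> 2 anisotropy terrestrial  0.147860560 0.004669994
#> ...
```

Adults are decisively more anisotropic and less spherical than tadpoles
(Welch t on species means), and the per-environment metamorphosis deltas
recover the generator's ground truth: species becoming terrestrial gain
about +0.15 anisotropy across metamorphosis while species remaining
aquatic do not (truth: +0.15 vs +0.01). The pooled PCA puts ~50% of
variance on a PC1 loaded oppositely by anisotropy (−0.71) and sphericity
(+0.70), with elongation carried by PC2 — the axis structure expected
when flattening dominates shape variation.

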