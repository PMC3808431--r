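# morphosurf

Theoretical morphology of whole 3D surfaces, in R.

Most morphometrics reduces an organism to landmarks, distances, or outlines.
`morphosurf` instead models the **entire bounded surface** of an organism as a
parametric surface

    S(u, v) = ( x(u,v), y(u,v), z(u,v) ),   (u, v) ∈ [0, 2π]²

derived from a ring torus `x = (R + r cos v) cos u`, `y = (R + r cos v) sin u`,
`z = r sin v`, where `R` is the whorl (major) radius and `r` the aperture
(minor) radius. A registry of torus-derived families covers coiled gastropods
(two generating systems plus turritellids, *Vermicularia*, spiral curves,
limpets), bivalves (clams, oysters, scallops), ammonites, scaphopods,
echinoid tests, and the basic geometric forms (torus, cylinder, cone, dome,
sphere, ellipsoids).

Each surface is summarized by the six first partial derivatives of its
coordinate functions — its **Jacobian**, evaluated at a reference point
(default `u = v = 0`):

    J = [ ∂x/∂u  ∂x/∂v ]
        [ ∂y/∂u  ∂y/∂v ]
        [ ∂z/∂u  ∂z/∂v ]

Because every family is homogeneous of degree 1 in `(R, r)`, rescaling a
model rescales `J` by the same factor, and after reducing measured radii to
their lowest integer proportion the summary is **size-free**: identical
shapes of different sizes get identical summaries. Collections of summaries
are ordinated by correlation-matrix PCA into a common **morphospace** where
mollusks, echinoids and abstract geometric forms can be compared, ontogenetic
trajectories traced, and Jacobian-degenerate model pairs (distinct shapes
with identical first partials, e.g. phase-shifted ammonite pleats) flagged
and separated with second partials (**Hessian elements**). Darboux frames
and principal curvatures are available for the differential-geometric
groundwork, and surfaces export as OBJ/PLY point clouds for external 3D
methods.

Intended users: paleontologists and evolutionary biologists exploring
theoretical morphospaces, and anyone needing differentiable whole-surface
models of shelled invertebrates.

## Worked example

Reduce measured shell radii (cm) to model proportions:

```r
library(morphosurf)
shell_proportions(gastropod_radii())[c(1, 8), ]
#> # A tibble: 2 × 7
#>   taxon                  R_max r_max actual_R actual_r integer_R integer_r
#>   <chr>                  <dbl> <dbl>    <dbl>    <dbl>     <int>     <int>
#> 1 Scaphander lignarius    1      1.5     1         1.5         1         2
#> 2 Architectonica nobilis  1.45   0.4     3.62      1           4         1
```

*Scaphander*'s whorl:aperture ratio reduces to 1:2, *Architectonica*'s to
4:1 (its actual proportion is 3.625:1, printed to three decimals) — these
integer pairs parameterize generalized "blank" models via `R_max`/`r_max`.

Build the mollusk–echinoid collection, summarize, and ordinate:

```r
models <- fixture_collection("mollusk_echinoid")
ms <- morphospace(jacobian_table(models))
ms
#> <morphospace> 19 models, 6 variables retained
#>   eigenvalues: 2.541, 1.209, 1.073, 0.737, 0.360, 0.079
#>   % variance : 42.36, 20.15, 17.88, 12.28, 6.00, 1.32
glance(ms)
#> # A tibble: 1 × 5
#>   n_models n_variables n_dropped percent_pc1 cumulative_pc2
#>      <int>       <int>     <int>       <dbl>          <dbl>
#> 1       19           6         0        42.4           62.5
```

The eigenvalues sum to 6 (the trace of a 6-variable correlation matrix);
PC1 (42.4% of variance) is dominated by the whorl-direction elements
`dy_du` (correlation 0.97) and `dx_du`/`dz_du` (−0.84, −0.79) — tightness
of coiling and spire height — while the aperture-direction elements load
on PC2–PC3. `autoplot(ms)` draws the score plot.

An isometric growth series (turritellids with 5 → 12 whorls) is a straight
line in this space:

```r
series <- fixture_collection("turritellid_series")
ms2 <- morphospace(jacobian_table(c(unclass(models), unclass(series))))
tr <- trajectory(ms2, sprintf("turritellid_%02d", 5:12))
collinearity(tr)
#> [1] 1
```

Export any model for external 3D analysis:

```r
write_point_cloud(surface_grid(canonical_model("volute"), 80, 80),
                  "volute.obj", faces = TRUE)
```

A command-line interface (`exec/morphosurf`) wraps the same functions:
`morphosurf jacobian --collection basic_forms --out jac.csv`, then
`morphosurf ordinate --table jac.csv --out-prefix ms`.

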