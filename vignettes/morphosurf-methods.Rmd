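---
title: "Modeling whole-organism surfaces and ordinating their Jacobians"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling whole-organism surfaces and ordinating their Jacobians}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphosurf)
```

## The model

morphosurf treats the surface of an organism — a coiled gastropod shell, a
bivalve, an ammonite, an echinoid test — as a bounded parametric surface

$$S(u, v) = \big(x(u,v),\; y(u,v),\; z(u,v)\big), \qquad (u, v) \in [0, 2\pi]^2,$$

derived from the ring torus
$x = (R + r\cos v)\cos u$, $y = (R + r\cos v)\sin u$, $z = r\sin v$,
where $R$ is the major (whorl) radius and $r$ the minor (aperture) radius.
Every model family in the registry (`model_kinds()`) is a modification of
this torus built only from sines, cosines, hyperbolic secant/tangent,
polynomials and exponentials of the parameters, so all families are smooth
and symbolically differentiable everywhere.

Rather than describing shell growth by a generating curve swept along a
spiral, the whole surface is the modeled object. For coiled gastropods, $u$
runs along the coil (whorls) and $v$ around the tube cross-section (the
aperture). Whorl counts, tapers, uncoiling, pleating and so on are carried
by named dimensionless coefficients, not by stretching the parameter domain;
the domain stays $[0, 2\pi]^2$ for every family (an explicit
`param_domain()` override exists for partial surfaces).

### The family registry

The parametric families are authored in a single registry file
(`R/registry.R`), one auditable entry per family, and were designed under
four structural constraints:

1. **Torus descent.** Each family is the torus composed with taper,
   envelope, displacement or pleat factors from the restricted function
   vocabulary above.
2. **Homogeneity of degree 1 in the radii.** Every additive term carries
   exactly one factor of $R$ or $r$. Consequently `scale_model(m, c)`
   scales every surface point, and every Jacobian element, by exactly $c$ —
   the mechanism that makes the summary size-free after ratio normalization.
3. **Documented coefficient roles.** For the coiled-gastropod systems,
   $a, c$ act on overall width/height, $b, j$ on height and whorl count in
   the $z$-direction, and $k, l, m$ on how the whorl radius changes along the
   spire; ammonites use $l$ for the degree of coiling (in $x, y$) and $q$
   for pleating (in $z$); bivalve coefficients place the umbo (clam $b$),
   set length/concavity (oyster $c$, clam $j$) and shape auricles, ribs and
   flatness (scallop $a, l, m$).
4. **Named recipes.** `canonical_model()` freezes specific coefficient
   values for particular shells (cone shell $k=0.7$, $l=m=3$, $c=1$,
   $R_{max}=1.5$, $r_{max}=2$; volute $k=1$, $l=m=0$, $R_{max}=1.5$,
   $r_{max}=2$; olive; bubble; *Melampus* $l=1.5$, $m=2.3$, $R_{max}=0.7$,
   $r_{max}=2.4$; sundial $R_{max}=1.3$, $r_{max}=1$, $l=0$, $a=b=2$; and so
   on). Where a recipe pins only a subset of a family's coefficients, the
   registry supplies the remainder as documented defaults (for example
   $k = 1$ for the *Melampus* recipe, $b = 6$ whorls for system-1 shells);
   those supplements are package choices, chosen once so that every recipe
   evaluates finitely and looks like the organism it names.

Two families deserve notes. The **turritellid** uses a per-whorl taper
$e^{-kbu/2\pi}$ with $b$ equal to the whorl count, so that adding whorls is
isometric: each Jacobian element is linear in $b$ and a 5-to-12-whorl growth
series is a straight line in summary space. The **vermicularia** family is
the same equations plus an uncoiling mechanism — a negative $b$ expands the
whorls while a squared $z$-term (weight $a$) drops the freed tube — and
reduces point-wise to the turritellid when $b > 0$ and $a = 0$. Spiral
curves reuse the turritellid equations with an aperture radius that
approaches zero; the default epsilon is $10^{-3}$ because an exact zero is a
degenerate radius and is rejected.

The **echinoid** starts from a horn torus ($R = r = 2$, closing the central
hole) and flattens/elongates it with negative $z$-terms whose last factor is
a polynomial in sines and cosines. The basic geometric forms (torus,
cylinder, cone, dome, sphere, ellipsoid) are parameterized so that $u = 0$
is a regular, informative point — the sphere in latitude–longitude form with
$u = 0$ on the equator, the dome with $u = 0$ at the rim.

## The Jacobian summary

The surface descriptor is the $3 \times 2$ matrix of first partials

$$J = \begin{pmatrix}
\partial x/\partial u & \partial x/\partial v\\
\partial y/\partial u & \partial y/\partial v\\
\partial z/\partial u & \partial z/\partial v
\end{pmatrix}\Bigg|_{(u_0, v_0)},$$

computed by exact symbolic differentiation (`stats::D`) and evaluated at the
reference point. The default reference point is $(0, 0)$: for the shell
families that is the mature aperture end, where whorl and aperture structure
are both expressed; the choice is configurable per analysis and a
grid-averaged variant (`mean_jacobian()`) exists but is never the default.
`numeric_jacobian()` is an independent central-difference oracle (default
step $10^{-6}$) used by the test-suite to cross-check every family at seeded
random points to $10^{-6}$ relative (relative to the summary's largest
element, with a floor of 1 so near-zero elements are compared absolutely).

Flattened rows use the fixed element order
`dx_du, dx_dv, dy_du, dy_dv, dz_du, dz_dv` (rows $x,y,z$; columns $u,v$).
The three $2\times2$ minors of $J$ detect planarity: a model collapsed to a
plane curve has all three equal to zero.

### Degenerate pairs and Hessian post-processing

Distinct surfaces can share a Jacobian. The pleat term of the ammonite
family, $\tfrac{q r}{10}\,(1-\cos 8b(u + u_s))\,\cos 2(v + v_s)$, has
vanishing first partials at the origin for *every* phase $v_s$, so two
ammonites differing only by a $v$-phase shift of their pleats have
bit-identical summaries. `jacobian_table()` flags any pair of rows whose
maximum absolute difference is below $10^{-9}$ (a deliberately strict
threshold: the flag should fire only on analytic coincidences, not on
nearby forms) and recommends second-order post-processing.
`hessian_elements()` then separates such pairs: $\partial^2 z/\partial u^2$
picks up the factor $\cos 2v_s$ and differs across the pair. The default
Hessian subset is the six $u$-dominant elements
$\partial^2\{x,y,z\}/\partial u^2$ and
$\partial^2\{x,y,z\}/\partial u\,\partial v$ — a documented, overridable
choice; any of the nine named elements can be requested. An alternative
fix, the `z_offset` coefficient, adds $z_{\mathrm{off}}\, r\, v$ to the
$z$-equation of one member of the pair, shifting its $\partial z/\partial v$
and splitting the pair at first order.

## Curvature and frames

`principal_curvatures()` computes the eigenvalues of the shape operator from
the first and second fundamental forms, erroring on a degenerate metric
(determinant below $10^{-12}$ relative to $EG$). The unit normal is oriented
as $-(S_u \times S_v)/\lVert\cdot\rVert$; with this convention the classic
torus gives $\kappa_{\text{parallel}} = \cos v/(R + r\cos v)$ and
$\kappa_{\text{meridian}} = 1/r$. Curvature signs (and the sign of the
geodesic torsion in `darboux_frame()`) flip with the normal, so comparisons
are made up to sign where the orientation is not pinned down. Frame
*derivatives* ($\kappa_g$, $\tau_g$) are taken by central differences of the
exactly-evaluated frame along the curve (step $10^{-5}$), which keeps the
code simple at ~$10^{-10}$ accuracy — ample for the property checks
(orthonormality to $10^{-9}$, meridian $\tau_g = 0$ to $10^{-6}$).

## Measurement reduction

`shell_proportions()` reduces measured maximum whorl and aperture radii
(cm) to an **actual proportion** — both members divided by the smaller, each
reported rounded half-away-from-zero to 3 decimals — and a **lowest integer
proportion** — the actual members rounded half-up to integers, then divided
by their gcd. Half-up rounding is the documented tie rule ($1.5 \to 2$).
The bundled reference table (`gastropod_radii()`, fourteen gastropods)
reproduces its published proportion columns exactly under these rules for
twelve of fourteen rows; the remaining two cells (*Oliva sayana* 1.687 where
$1.35/0.8 = 1.6875$; *Calliostoma bairdi* 2.7 where $1.2/0.45 = 2.667$)
carry source-side precision quirks and are asserted at $\pm 0.001$ and
$\pm 0.05$ respectively rather than guessed at. Integer proportions become
the $(R_{max}, r_{max})$ of generalized "blank" models; measured values can
also be used directly when refining a model against a specimen, so both
pathways are exposed.

## Morphospace

`morphospace()` standardizes the Jacobian columns to zero mean and unit
variance and eigen-decomposes the correlation matrix. Consequences used as
invariants: the eigenvalue sum equals the number of retained variables;
scores are centered and mutually uncorrelated with variances equal to the
eigenvalues; variable–PC correlations (eigenvector element times
$\sqrt{\lambda}$) lie in $[-1, 1]$. Constant columns — structural zeros such
as $\partial x/\partial v$ across an all-ammonite collection — are dropped
with a warning and the eigenvalue-sum invariant adjusts to the retained
count. PCA signs are arbitrary, so each PC is oriented to make its
largest-magnitude variable correlation positive; comparisons against
externally reported correlations should be made on $|r|$. The decomposition
is cross-checked against `stats::prcomp` in the tests; the exported path is
the package's own eigen-decomposition so that the standardization
parameters, sign convention and dropped-column bookkeeping are explicit.

`trajectory()` extracts stage scores in growth order and reports step
vectors plus a collinearity statistic — the fraction of the path's variance
on its first principal direction (1 for a straight path; a path whose stages
all coincide is assigned 1 by convention, since a point imposes no
direction). The turritellid series (whorls 5–12) ordinated together with the
mollusk–echinoid collection is monotone along its first principal direction
with collinearity above 0.99 — isometric accretionary growth as a straight
morphospace trajectory — while scaled copies of a ratio-normalized model
receive bit-identical scores and a zero-length trajectory: size-only growth
plots at a single point.

### Fixture collections

The ordinated populations are frozen in `fixture_collection()` so that all
downstream numbers are reproducible within the package: `mollusk_echinoid`
(19 models: every family once, including all named recipes and both
ontogeny exemplars), `basic_forms` (the seven basic geometric forms — two
ellipsoids differing in major-axis length — plus bivalve and gastropod
variants), `turritellid_series` (8 stages), and `ammonite_grid` (a $3\times3$
sweep of coiling $l \in \{0.5, 1, 1.5\}$ against pleating
$q \in \{0.5, 1, 1.5\}$). Eigenvalues and correlations of any particular
published ordination depend on the exact model population ordinated;
populations assembled here are package choices, and the acceptance checks
on ordination are therefore *structural* (eigenvalue sum, centering,
permutation invariance, correlation bounds) rather than numeric
reproductions.

## What the fixtures do and do not show

The fixture models are deterministic analytic surfaces: they emulate the
geometry of shells and tests (coiling, taper, pleating, uncoiling,
spheroidal closure) but none of the noise of real data — no measurement
error in radii, no digitization artifacts, no intraspecific variation, no
deviation of real shells from exact homogeneity. Passing tests therefore
demonstrate the correctness of the machinery (derivatives, reductions,
ordination algebra) and the qualitative phenomena (degeneracy, isometry,
size-freeness), not that any particular living population occupies a
particular region of morphospace.

## Numerical choices, problem sizes, limitations

- Tolerances: symbolic-vs-numeric Jacobian $10^{-6}$ relative; degeneracy
  flag $10^{-9}$; frame orthonormality $10^{-9}$; mixed-partial symmetry
  $10^{-9}$; metric regularity $10^{-12}$.
- Rounding: proportions half-away-from-zero to 3 decimals; integers half-up.
- Angles are radians everywhere; degree-valued bounds are simply out of
  range for the default domain and rejected by the domain check.
- Test problem sizes (package choices, kept small because the quantities are
  analytic and do not benefit from larger grids): $15\times15$ evaluation
  grids for finiteness sweeps, 10–20 seeded random points per property, the
  fixture collections as listed.
- `variance_explained()` renormalizes by the input sum; feeding it values
  that are themselves rounded percentages (summing to 99.999 rather than
  100) reproduces running sums only to about $6\times10^{-4}$.
- Known limitations: the single-point Jacobian summary ignores surface
  features invisible to first derivatives at the reference point (hence the
  Hessian post-processing path); near-planar forms separate weakly; the
  sphere/dome parameterizations have metric-degenerate latitudes where
  curvature queries error by design; OBJ/PLY export is point/quad-lattice
  only, with no binary formats.

## Worked pipeline

```{r pipeline, eval = FALSE}
library(morphosurf)

# measured radii -> integer proportions -> a blank model
props <- shell_proportions(gastropod_radii())
volute <- canonical_model("volute")

# surface -> Jacobian -> morphospace
models <- fixture_collection("mollusk_echinoid")
tbl <- jacobian_table(models)
ms <- morphospace(tbl)
glance(ms)
autoplot(ms)

# ontogeny
series <- fixture_collection("turritellid_series")
ms2 <- morphospace(jacobian_table(c(unclass(models), unclass(series))))
tr <- trajectory(ms2, sprintf("turritellid_%02d", 5:12))
collinearity(tr)

# export for external 3D analysis
write_point_cloud(surface_grid(volute, 80, 80), "volute.obj", faces = TRUE)
```
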