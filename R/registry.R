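# Equation registry: one entry per parametric family.
#
# Every family is derived from the ring torus
#   x = (R + r cos v) cos u,  y = (R + r cos v) sin u,  z = r sin v
# by composing it with sines, cosines, hyperbolic secant/tangent (written as
# 1/cosh and sinh/cosh so stats::D can differentiate them), polynomials and
# exponentials of the parameters. All families are homogeneous of degree 1 in
# the radii (R, r): every additive term carries exactly one factor of R or r,
# so scaling both radii by c scales the surface — and its Jacobian — by c.
#
# Coefficient roles (coiled gastropod systems):
#   a, c  overall width/height;  b, j  height / number of whorls (z-direction);
#   k, l, m  whorl-radius change along the spire (shape of the taper);
#   q  pleating (ammonites);  z_offset  additive v-term in z (see vignette).
#
# `required` coefficients must be supplied; `defaults` fill the rest.

SPIRE_TAPER <- quote(exp(-(k * u + l * u^2 / (2 * pi) + m * u^3 / (4 * pi^2)) / (2 * pi)))

.registry <- list(

  gastropod_system1 = list(
    x = quote(exp(-(k * u + l * u^2 / (2 * pi) + m * u^3 / (4 * pi^2)) / (2 * pi)) *
                (R + r * cos(v)) * cos(b * u)),
    y = quote(exp(-(k * u + l * u^2 / (2 * pi) + m * u^3 / (4 * pi^2)) / (2 * pi)) *
                (R + r * cos(v)) * sin(b * u)),
    z = quote(-c * (j * R * (u / (2 * pi)) + r * sin(v)) *
                exp(-(k * u + l * u^2 / (2 * pi) + m * u^3 / (4 * pi^2)) / (2 * pi)) -
                a * R * (1 - exp(-(k * u + l * u^2 / (2 * pi) + m * u^3 / (4 * pi^2)) / (2 * pi)))),
    required = c("k", "l", "m"),
    defaults = c(a = 1, b = 6, c = 1, j = 1),
    description = "Conispiral gastropod shells; exponential-polynomial whorl taper."
  ),

  # High-spired, tightly coiled shells: b whorls over one pass of u, constant
  # per-whorl taper k so that growth (adding whorls) is isometric.
  turritellid = list(
    x = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * cos(b * u)),
    y = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * sin(b * u)),
    z = quote(-c * R * b * u / (2 * pi) - r * exp(-k * b * u / (2 * pi)) * sin(v)),
    required = c("b"),
    defaults = c(k = 0.1, c = 0.5),
    description = "Normally coiled turritellid; b = whorl count."
  ),

  # Same family as the turritellid: a negative uncoiling coefficient b expands
  # the whorls, and the squared z-term (weight a) drops the freed tube. With
  # b > 0 and a = 0 the model is point-wise identical to a turritellid.
  vermicularia = list(
    x = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * cos(b * u)),
    y = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * sin(b * u)),
    z = quote(-c * R * b * u / (2 * pi) - r * exp(-k * b * u / (2 * pi)) * sin(v) -
                a * R * (b * u / (2 * pi))^2),
    required = c("b"),
    defaults = c(k = 0.1, c = 0.5, a = 0.5),
    description = "Initially coiled, then unwinding gastropod."
  ),

  # Spiral curves use the turritellid equations with an aperture radius that
  # approaches (but never equals) zero, leaving a curve-like tube.
  spiral_curve = list(
    x = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * cos(b * u)),
    y = quote(exp(-k * b * u / (2 * pi)) * (R + r * cos(v)) * sin(b * u)),
    z = quote(-c * R * b * u / (2 * pi) - r * exp(-k * b * u / (2 * pi)) * sin(v)),
    required = c("b"),
    defaults = c(k = 0.1, c = 0.5),
    description = "Conispiral curve with infinitesimal cross-section."
  ),

  gastropod_system2 = list(
    x = quote((R + r * cos(v)) * cos(b * u) / cosh(m * u / (2 * pi))),
    y = quote((R + r * cos(v)) * sin(b * u) / cosh(m * u / (2 * pi))),
    z = quote(-c * r * sin(v) - j * R * sinh(m * u / (2 * pi)) / cosh(m * u / (2 * pi))),
    required = c("b", "m"),
    defaults = c(c = 1, j = 1.5),
    description = "Globose, low-spired gastropod shells; sech envelope."
  ),

  limpet = list(
    x = quote(R * (u / (2 * pi)) * cos(v) + k * r * (u / (2 * pi))^2),
    y = quote(R * (u / (2 * pi)) * sin(v)),
    z = quote(c * r / cosh(b * u / (2 * pi)) - a * R * (u / (2 * pi))),
    required = c("a", "b", "c", "k"),
    defaults = NULL,
    description = "Cap-shaped shell with an offset apex (coefficient k)."
  ),

  # Bivalves: rapidly expanding helicones, <= one whorl. The aperture phase
  # (v + 1/2) tilts the tube cross-section relative to the coiling plane.
  clam = list(
    x = quote(exp(-j * u / (2 * pi)) * (R + r * cos(v + 1 / 2)) * cos(u)),
    y = quote(exp(-j * u / (2 * pi)) * (R + r * cos(v + 1 / 2)) * sin(u)),
    z = quote(-b * r * exp(-j * u / (2 * pi)) * sin(v + 1 / 2) - c * R * u / (2 * pi)),
    required = c("b", "j"),
    defaults = c(c = 1),
    description = "Equivalve bivalve; b places the umbo, j sets length."
  ),

  oyster = list(
    x = quote((R + r * cos(v)) * cos(u)),
    y = quote(c * (R + r * cos(v)) * sin(u)),
    z = quote(-r * sin(v) / cosh(c * (u - pi))),
    required = c("c"),
    defaults = NULL,
    description = "Inequivalve bivalve; c sets length and concavity."
  ),

  scallop = list(
    x = quote((R + r * cos(v)) * cos(u) * (1 + a * sin(u)^2 / 5)),
    y = quote(m * (R + r * cos(v)) * sin(u)),
    z = quote(-r * sin(v) * (1 + l * cos(12 * u) / 10) / 2),
    required = c("a", "l", "m"),
    defaults = NULL,
    description = "Pectinid valve; a shapes auricles, l ribs, m flatness."
  ),

  # Planispiral cephalopod. Coefficient l sets the coiling (whorl expansion)
  # in x and y; q sets the pleating amplitude in z. The pleat term has
  # vanishing first partials at (u, v) = (0, 0) for every phase, which is why
  # a v-phase-shifted pleat leaves the Jacobian summary unchanged while the
  # second partial d2z/du2 records the shift.
  ammonite = list(
    x = quote(exp(-l * u / (2 * pi)) * (R + r * cos(v)) * cos(b * u)),
    y = quote(exp(-l * u / (2 * pi)) * (R + r * cos(v)) * sin(b * u)),
    z = quote(r * sin(v) +
                q * r * (1 - cos(8 * b * (u + u_shift))) * cos(2 * (v + v_shift)) / 10),
    required = c("l", "q"),
    defaults = c(b = 3, u_shift = 0, v_shift = 0),
    description = "Planispiral ammonite; l = coiling, q = pleating."
  ),

  scaphopod = list(
    x = quote(k * r * exp(-u / (2 * pi)) * cos(v) + a * R * (1 - cos(u / 4))),
    y = quote(k * r * exp(-u / (2 * pi)) * sin(v)),
    z = quote(-a * R * sin(u / 4)),
    required = c("a", "k"),
    defaults = NULL,
    description = "Tusk shell: gently curved, tapering tube."
  ),

  # Echinoid test from a horn torus (R = r closes the central hole), with
  # negative z-terms whose last factor is a polynomial in sines and cosines.
  echinoid = list(
    x = quote((R + r * cos(v)) * cos(u)),
    y = quote((R + r * cos(v)) * sin(u)),
    z = quote(-a * r * sin(v) - m * r * sin(v) * cos(v)^2),
    required = c("a", "m"),
    defaults = NULL,
    description = "Spheroidal to ellipsoidal echinoid test."
  ),

  ## ---- basic geometric forms -------------------------------------------

  torus = list(
    x = quote((R + r * cos(v)) * cos(u)),
    y = quote((R + r * cos(v)) * sin(u)),
    z = quote(r * sin(v)),
    required = character(),
    defaults = NULL,
    description = "Ring torus, the generating surface of every family."
  ),

  cylinder = list(
    x = quote(r * cos(v)),
    y = quote(r * sin(v)),
    z = quote(R * (u / pi - 1)),
    required = character(),
    defaults = NULL,
    description = "Right circular cylinder, height 2R."
  ),

  cone = list(
    x = quote(r * (1 - u / (2 * pi)) * cos(v)),
    y = quote(r * (1 - u / (2 * pi)) * sin(v)),
    z = quote(R * u / (2 * pi)),
    required = character(),
    defaults = NULL,
    description = "Right circular cone, base radius r, height R."
  ),

  dome = list(
    x = quote(r * cos(v) * cos(u / 4)),
    y = quote(r * sin(v) * cos(u / 4)),
    z = quote(r * sin(u / 4)),
    required = character(),
    defaults = NULL,
    description = "Hemispherical dome; u = 0 is the rim."
  ),

  sphere = list(
    x = quote(r * cos(v) * cos(u)),
    y = quote(r * sin(v) * cos(u)),
    z = quote(r * sin(u)),
    required = character(),
    defaults = NULL,
    description = "Sphere in latitude-longitude form; u = 0 on the equator."
  ),

  ellipsoid = list(
    x = quote(r * cos(v) * cos(u)),
    y = quote(r * sin(v) * cos(u)),
    z = quote(a * r * sin(u)),
    required = c("a"),
    defaults = NULL,
    description = "Spheroid elongated along z by the axis ratio a."
  )
)

#' List the available model kinds
#'
#' @return A character vector naming every parametric family in the registry.
#' @export
#' @examples
#' model_kinds()
model_kinds <- function() names(.registry)

registry_entry <- function(kind) {
  if (!is.character(kind) || length(kind) != 1 || is.na(kind) || !kind %in% names(.registry)) {
    rlang::abort(
      paste0("Unknown model kind ", deparse(kind), "; see model_kinds()."),
      class = "morphosurf_error_registry"
    )
  }
  .registry[[kind]]
}

# Coefficient recipes behind canonical_model(). Values printed for specific
# shells are kept verbatim; remaining coefficients are registry choices.
.canonical_recipes <- list(
  cone_shell  = list(kind = "gastropod_system1",
                     coefficients = list(k = 0.7, l = 3, m = 3, c = 1, R = 1.5, r = 2)),
  volute      = list(kind = "gastropod_system1",
                     coefficients = list(k = 1, l = 0, m = 0, R = 1.5, r = 2)),
  olive       = list(kind = "gastropod_system1",
                     coefficients = list(k = 2, l = 2, m = 0, R = 1, r = 2)),
  bubble      = list(kind = "gastropod_system1",
                     coefficients = list(k = 1, l = 1, m = 0, R = 1, r = 2)),
  melampus    = list(kind = "gastropod_system1",
                     coefficients = list(k = 1, l = 1.5, m = 2.3, R = 0.7, r = 2.4)),
  sundial     = list(kind = "gastropod_system1",
                     coefficients = list(k = 0.5, l = 0, m = 0, a = 2, b = 2, R = 1.3, r = 1)),
  turritellid = list(kind = "turritellid",
                     coefficients = list(b = 9, R = 1, r = 1)),
  vermicularia = list(kind = "vermicularia",
                      coefficients = list(b = -9, a = 0.5, R = 1, r = 1)),
  spiral      = list(kind = "spiral_curve",
                     coefficients = list(b = 5, R = 1, r = 1e-3)),
  clam        = list(kind = "clam",
                     coefficients = list(b = 1, j = 1.5, R = 1, r = 1)),
  oyster      = list(kind = "oyster",
                     coefficients = list(c = 1.3, R = 1, r = 1)),
  scallop     = list(kind = "scallop",
                     coefficients = list(a = 1, l = 1, m = 0.6, R = 1, r = 1)),
  ammonite    = list(kind = "ammonite",
                     coefficients = list(l = 1, q = 1, R = 2, r = 1)),
  scaphopod   = list(kind = "scaphopod",
                     coefficients = list(a = 1, k = 0.8, R = 1, r = 0.5)),
  echinoid    = list(kind = "echinoid",
                     coefficients = list(a = 0.8, m = 0.3, R = 2, r = 2)),
  torus       = list(kind = "torus", coefficients = list(R = 1, r = 1)),
  cylinder    = list(kind = "cylinder", coefficients = list(R = 1, r = 1)),
  cone        = list(kind = "cone", coefficients = list(R = 1, r = 1)),
  dome        = list(kind = "dome", coefficients = list(R = 1, r = 1)),
  sphere      = list(kind = "sphere", coefficients = list(R = 1, r = 1)),
  ellipsoid   = list(kind = "ellipsoid", coefficients = list(a = 1.5, R = 1, r = 1))
)

#' Construct a named model from the recipe registry
#'
#' Builds a [surface_model()] from a short list of named recipes: specific
#' shells (`"cone_shell"`, `"volute"`, `"olive"`, `"bubble"`, `"melampus"`,
#' `"sundial"`, `"clam"`, `"oyster"`, `"scallop"`, `"scaphopod"`,
#' `"echinoid"`, `"vermicularia"`), parameterized series members
#' (`"turritellid"`, `"spiral"`, `"ammonite"`, `"ellipsoid"`), and the basic
#' geometric forms (`"torus"`, `"cylinder"`, `"cone"`, `"dome"`, `"sphere"`).
#'
#' @param name Recipe name; see Details.
#' @param ... Coefficient overrides merged into the recipe (e.g. `l`, `q`,
#'   `v_shift` for `"ammonite"`).
#' @param n_whorls Whorl count for `"turritellid"` (default 9).
#' @param n_coils Coil count for `"spiral"` (default 5).
#' @param axis_ratio Major-axis ratio for `"ellipsoid"` (default 1.5).
#' @return A `surface_model`.
#' @export
#' @examples
#' canonical_model("volute")
#' canonical_model("turritellid", n_whorls = 7)
#' canonical_model("ammonite", l = 1.2, q = 0.5)
canonical_model <- function(name, ..., n_whorls = NULL, n_coils = NULL, axis_ratio = NULL) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.canonical_recipes)) {
    rlang::abort(
      paste0("Unknown canonical model ", deparse(name), "."),
      class = "morphosurf_error_registry"
    )
  }
  recipe <- .canonical_recipes[[name]]
  coefs <- recipe$coefficients
  if (name == "turritellid" && !is.null(n_whorls)) coefs$b <- n_whorls
  if (name == "spiral" && !is.null(n_coils)) coefs$b <- n_coils
  if (name == "ellipsoid" && !is.null(axis_ratio)) coefs$a <- axis_ratio
  dots <- list(...)
  coefs[names(dots)] <- dots
  surface_model(recipe$kind, coefficients = coefs, label = name)
}
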