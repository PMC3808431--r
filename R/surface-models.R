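#' Parameter domain of a surface model
#'
#' Both parameters are angles in radians; the default domain is
#' \eqn{[0, 2\pi] \times [0, 2\pi]}. Whorl counts and similar extents are
#' controlled through model coefficients, not by widening the domain, but an
#' explicit override is supported for partial surfaces.
#'
#' @param u,v Length-2 numeric vectors `c(lower, upper)` in radians.
#' @return A `param_domain` object.
#' @export
#' @examples
#' param_domain()
#' param_domain(u = c(0, pi))
param_domain <- function(u = c(0, 2 * pi), v = c(0, 2 * pi)) {
  check_range <- function(x, name) {
    if (!is.numeric(x) || length(x) != 2 || anyNA(x) || any(!is.finite(x)) || x[1] >= x[2]) {
      rlang::abort(
        paste0("`", name, "` must be a finite numeric interval c(lower, upper) in radians."),
        class = "morphosurf_error_domain"
      )
    }
    as.numeric(x)
  }
  structure(list(u = check_range(u, "u"), v = check_range(v, "v")),
            class = "param_domain")
}

#' @export
print.param_domain <- function(x, ...) {
  cat(sprintf("<param_domain> u in [%.4g, %.4g], v in [%.4g, %.4g] (radians)\n",
              x$u[1], x$u[2], x$v[1], x$v[2]))
  invisible(x)
}

in_domain <- function(domain, u, v, tol = 1e-9) {
  u >= domain$u[1] - tol & u <= domain$u[2] + tol &
    v >= domain$v[1] - tol & v <= domain$v[2] + tol
}

# Symbols that may appear in expressions without being coefficients.
.reserved_symbols <- c("u", "v", "pi")

#' Construct a parametric surface model
#'
#' Instantiates one of the registry's parametric families (see
#' [model_kinds()]) with named coefficient values. Every family maps the
#' parameters \eqn{(u, v)} to coordinates \eqn{(x, y, z)} through expressions
#' that are symbolically differentiable, so first and second partial
#' derivatives (the model's Jacobian and Hessian summaries) are exact.
#'
#' Radii may be given as `R`/`r` or as `R_max`/`r_max`; both default to 1.
#' `r` must be strictly positive (spiral curves use a small epsilon, not 0).
#' The optional coefficient `z_offset` adds the term `z_offset * r * v` to the
#' z-equation, the augmentation used to split Jacobian-degenerate model pairs.
#'
#' @param family A model kind from [model_kinds()]. (Named `family` rather
#'   than `kind` so that single-letter coefficient arguments like `k = 0.7`
#'   can never partially match it.)
#' @param ... Coefficients given directly as named arguments (e.g. `R = 1`,
#'   `k = 0.7`), merged over `coefficients`.
#' @param coefficients Named list/vector of coefficient values.
#' @param domain A [param_domain()].
#' @param label Optional label used in tables and plots (defaults to `kind`).
#' @return A `surface_model` object.
#' @export
#' @examples
#' torus <- surface_model("torus", R = 1, r = 1)
#' evaluate_surface(torus, u = 0, v = 0)
#' surface_model("gastropod_system1", k = 0.7, l = 3, m = 3, c = 1, R = 1.5, r = 2)
surface_model <- function(family, ..., coefficients = list(),
                          domain = param_domain(), label = family) {
  kind <- family
  entry <- registry_entry(kind)
  coefs <- c(as.list(coefficients), list(...))
  if (length(coefs) && (is.null(names(coefs)) || any(names(coefs) == ""))) {
    rlang::abort("All coefficients must be named.",
                 class = "morphosurf_error_coefficient")
  }
  # radius aliases
  if (!is.null(coefs$R_max)) { coefs$R <- coefs$R_max; coefs$R_max <- NULL }
  if (!is.null(coefs$r_max)) { coefs$r <- coefs$r_max; coefs$r_max <- NULL }
  if (is.null(coefs$R)) coefs$R <- 1
  if (is.null(coefs$r)) coefs$r <- 1

  missing_req <- setdiff(entry$required, names(coefs))
  if (length(missing_req)) {
    rlang::abort(
      paste0("Model kind '", kind, "' requires coefficient(s): ",
             paste(missing_req, collapse = ", "), "."),
      class = "morphosurf_error_coefficient"
    )
  }
  for (nm in names(entry$defaults)) {
    if (is.null(coefs[[nm]])) coefs[[nm]] <- entry$defaults[[nm]]
  }
  if (is.null(coefs$z_offset)) coefs$z_offset <- 0

  bad <- vapply(coefs, function(x) !is.numeric(x) || length(x) != 1 || !is.finite(x), TRUE)
  if (any(bad)) {
    rlang::abort(paste0("Coefficient(s) not finite scalars: ",
                        paste(names(coefs)[bad], collapse = ", "), "."),
                 class = "morphosurf_error_coefficient")
  }
  if (coefs$R <= 0) {
    rlang::abort("Major/whorl radius R must be > 0.", class = "morphosurf_error_radius")
  }
  if (coefs$r <= 0) {
    rlang::abort(
      "Aperture radius r must be > 0 (use a small epsilon for spiral curves, not 0).",
      class = "morphosurf_error_radius"
    )
  }
  if (!inherits(domain, "param_domain")) {
    rlang::abort("`domain` must be created with param_domain().",
                 class = "morphosurf_error_domain")
  }

  z_expr <- call("+", entry$z, quote(z_offset * (r * v)))
  exprs <- list(x = entry$x, y = entry$y, z = z_expr)

  referenced <- unique(unlist(lapply(exprs, all.vars)))
  referenced <- setdiff(referenced, .reserved_symbols)
  unfilled <- setdiff(referenced, names(coefs))
  if (length(unfilled)) {
    rlang::abort(
      paste0("Model kind '", kind, "' references coefficient(s) without values: ",
             paste(unfilled, collapse = ", "), "."),
      class = "morphosurf_error_coefficient"
    )
  }

  structure(
    list(kind = kind, label = label,
         coefficients = vapply(coefs, as.numeric, numeric(1)),
         domain = domain, expressions = exprs),
    class = "surface_model"
  )
}

#' Define a surface directly from coordinate expressions
#'
#' Escape hatch for forms outside the registry: supply the three coordinate
#' expressions of the generalized parametric system yourself, as one-sided
#' formulas in `u`, `v` and named coefficients.
#'
#' @param x,y,z One-sided formulas, e.g. `~ (R + r * cos(v)) * cos(u)`.
#' @param coefficients Named list of coefficient values (`R` and `r` default to 1).
#' @param domain A [param_domain()].
#' @param label Label for tables and plots.
#' @return A `surface_model` with kind `"custom"`.
#' @export
#' @examples
#' flat <- parametric_surface(~ cos(u), ~ sin(u), ~ 0 * u, label = "flat circle")
#' jacobian_minors(jacobian(flat))
parametric_surface <- function(x, y, z, coefficients = list(),
                               domain = param_domain(), label = "custom") {
  grab <- function(f, name) {
    if (inherits(f, "formula")) return(rlang::f_rhs(f))
    if (is.call(f) || is.name(f) || is.numeric(f)) return(f)
    rlang::abort(paste0("`", name, "` must be a one-sided formula or quoted expression."),
                 class = "morphosurf_error_expression")
  }
  exprs <- list(x = grab(x, "x"), y = grab(y, "y"), z = grab(z, "z"))
  coefs <- as.list(coefficients)
  if (is.null(coefs$R)) coefs$R <- 1
  if (is.null(coefs$r)) coefs$r <- 1
  referenced <- setdiff(unique(unlist(lapply(exprs, all.vars))), .reserved_symbols)
  unfilled <- setdiff(referenced, names(coefs))
  if (length(unfilled)) {
    rlang::abort(paste0("Expressions reference coefficient(s) without values: ",
                        paste(unfilled, collapse = ", "), "."),
                 class = "morphosurf_error_coefficient")
  }
  # fail fast if not symbolically differentiable
  for (e in exprs) { stats::D(e, "u"); stats::D(e, "v") }
  structure(
    list(kind = "custom", label = label,
         coefficients = vapply(coefs, as.numeric, numeric(1)),
         domain = domain, expressions = exprs),
    class = "surface_model"
  )
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %s (kind: %s)\n", x$label, x$kind))
  show <- x$coefficients[x$coefficients != 0 | names(x$coefficients) %in% c("R", "r")]
  cat("  coefficients:",
      paste(sprintf("%s = %g", names(show), show), collapse = ", "), "\n")
  cat(sprintf("  domain: u in [%.4g, %.4g], v in [%.4g, %.4g]\n",
              x$domain$u[1], x$domain$u[2], x$domain$v[1], x$domain$v[2]))
  invisible(x)
}

# Evaluate coordinate expressions; no domain check (used by finite differences,
# which step slightly outside closed domains).
eval_coords <- function(model, u, v) {
  env <- c(as.list(model$coefficients), list(u = u, v = v))
  lapply(model$expressions, function(e) {
    val <- eval(e, envir = env)
    rep_len(as.numeric(val), length(u))
  })
}

#' Evaluate a surface model at parameter values
#'
#' @param model A [surface_model()].
#' @param u,v Numeric vectors of angles (radians), recycled to a common length.
#' @param check_domain Error if any point lies outside the model's domain.
#' @return A tibble with columns `u`, `v`, `x`, `y`, `z`.
#' @export
#' @examples
#' evaluate_surface(surface_model("torus"), u = c(0, pi / 2), v = 0)
evaluate_surface <- function(model, u, v, check_domain = TRUE) {
  stopifnot(inherits(model, "surface_model"))
  n <- max(length(u), length(v))
  u <- rep_len(as.numeric(u), n); v <- rep_len(as.numeric(v), n)
  if (check_domain && !all(in_domain(model$domain, u, v))) {
    rlang::abort("Parameter value(s) outside the model domain.",
                 class = "morphosurf_error_domain")
  }
  xyz <- eval_coords(model, u, v)
  for (axis in c("x", "y", "z")) {
    if (any(!is.finite(xyz[[axis]]))) {
      rlang::abort(paste0("Non-finite ", axis, " coordinate for model '",
                          model$label, "'."),
                   class = "morphosurf_error_singularity")
    }
  }
  tibble::tibble(u = u, v = v, x = xyz$x, y = xyz$y, z = xyz$z)
}

#' Sample a surface model on an even parameter grid
#'
#' @param model A [surface_model()].
#' @param nu,nv Sample counts per parameter (>= 2); the grid spans the domain
#'   inclusively, so `nu * nv` points are returned.
#' @return A tibble of class `surface_grid` with columns `u`, `v`, `x`, `y`,
#'   `z` and attributes `nu`, `nv`, `label`.
#' @export
#' @examples
#' g <- surface_grid(surface_model("torus"), nu = 3, nv = 3)
#' nrow(g)
surface_grid <- function(model, nu = 50, nv = 50) {
  stopifnot(inherits(model, "surface_model"))
  ok <- function(n) is.numeric(n) && length(n) == 1 && is.finite(n) && n >= 2 && n == round(n)
  if (!ok(nu) || !ok(nv)) {
    rlang::abort("`nu` and `nv` must be whole numbers >= 2.",
                 class = "morphosurf_error_resolution")
  }
  useq <- seq(model$domain$u[1], model$domain$u[2], length.out = nu)
  vseq <- seq(model$domain$v[1], model$domain$v[2], length.out = nv)
  lattice <- tidyr::expand_grid(u = useq, v = vseq)
  out <- evaluate_surface(model, lattice$u, lattice$v)
  attr(out, "nu") <- as.integer(nu)
  attr(out, "nv") <- as.integer(nv)
  attr(out, "label") <- model$label
  class(out) <- c("surface_grid", class(out))
  out
}

#' Rescale a model's radii
#'
#' Multiplies the whorl and aperture radii (`R`, `r`) by a positive factor
#' while leaving every shape coefficient unchanged. Because all registry
#' families are homogeneous of degree 1 in the radii, the surface — and its
#' Jacobian summary — scales by exactly that factor.
#'
#' @param model A [surface_model()].
#' @param factor Positive scalar.
#' @return The rescaled `surface_model`.
#' @export
#' @examples
#' big <- scale_model(surface_model("torus"), 2)
#' evaluate_surface(big, 0, 0) # (4, 0, 0)
scale_model <- function(model, factor) {
  stopifnot(inherits(model, "surface_model"))
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) || factor <= 0) {
    rlang::abort("`factor` must be a single positive number.",
                 class = "morphosurf_error_scale")
  }
  model$coefficients[["R"]] <- model$coefficients[["R"]] * factor
  model$coefficients[["r"]] <- model$coefficients[["r"]] * factor
  model
}

#' Reflect a model across a coordinate plane
#'
#' Negates one coordinate expression: a change of symmetry, which flips the
#' sign of exactly that row of the Jacobian summary.
#'
#' @param model A [surface_model()].
#' @param axis One of `"x"`, `"y"`, `"z"`.
#' @return The reflected `surface_model` (kind becomes `"custom"`).
#' @export
reflect_model <- function(model, axis = c("z", "x", "y")) {
  stopifnot(inherits(model, "surface_model"))
  axis <- match.arg(axis)
  model$expressions[[axis]] <- call("-", model$expressions[[axis]])
  model$kind <- "custom"
  model$label <- paste0(model$label, " (reflected ", axis, ")")
  model
}
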