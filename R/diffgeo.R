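# Differential-geometry summaries of surface models: Jacobian (first partial
# derivatives), Hessian elements (second partials), fundamental forms,
# principal curvatures, and Darboux/Frenet frames. All derivatives are exact
# symbolic derivatives (stats::D) evaluated at the requested point; the
# central-difference path exists purely as an independent numerical oracle.

first_partials <- function(model) {
  lapply(model$expressions, function(e) list(u = stats::D(e, "u"), v = stats::D(e, "v")))
}

eval_expr <- function(model, expr, u, v) {
  env <- c(as.list(model$coefficients), list(u = u, v = v))
  as.numeric(eval(expr, envir = env))
}

new_jacobian_summary <- function(values, point, label) {
  m <- matrix(values, nrow = 3, ncol = 2, byrow = TRUE,
              dimnames = list(c("x", "y", "z"), c("u", "v")))
  structure(m, point = point, label = label, class = c("jacobian_summary", "matrix"))
}

#' Jacobian summary of a surface model
#'
#' Computes the six first partial derivatives of the coordinate functions
#' \eqn{x, y, z} with respect to the parameters \eqn{u, v}, evaluated at a
#' reference point — by default the origin \eqn{(0, 0)}. The six elements form
#' a 3x2 matrix (rows x, y, z; columns u, v) that is a compact, size-equivariant
#' summary of the whole surface: rescaling the radii by `c` rescales every
#' element by `c` (see [scale_model()]).
#'
#' @param model A [surface_model()].
#' @param u0,v0 Reference point (radians); must lie in the model domain.
#' @return A `jacobian_summary` (3x2 matrix with a `point` attribute).
#' @seealso [numeric_jacobian()] for the finite-difference oracle,
#'   [hessian_elements()] for second-order post-processing.
#' @export
#' @examples
#' jacobian(surface_model("torus")) # elements (0, 0, 2, 0, 0, 1)
jacobian <- function(model, u0 = 0, v0 = 0) {
  stopifnot(inherits(model, "surface_model"))
  if (!in_domain(model$domain, u0, v0)) {
    rlang::abort("Reference point outside the model domain.",
                 class = "morphosurf_error_domain")
  }
  dp <- first_partials(model)
  vals <- numeric(6)
  i <- 0
  for (axis in c("x", "y", "z")) {
    for (par in c("u", "v")) {
      i <- i + 1
      vals[i] <- eval_expr(model, dp[[axis]][[par]], u0, v0)
      if (!is.finite(vals[i])) {
        rlang::abort(
          paste0("Jacobian element d", axis, "/d", par, " is not finite at (",
                 signif(u0, 6), ", ", signif(v0, 6), ") for model '", model$label, "'."),
          class = "morphosurf_error_singularity"
        )
      }
    }
  }
  new_jacobian_summary(vals, point = c(u0 = u0, v0 = v0), label = model$label)
}

#' @export
print.jacobian_summary <- function(x, ...) {
  p <- attr(x, "point")
  cat(sprintf("<jacobian_summary> %s at (u0 = %g, v0 = %g)\n",
              attr(x, "label"), p[1], p[2]))
  print(matrix(as.numeric(x), 3, 2, dimnames = dimnames(x)))
  invisible(x)
}

#' Finite-difference Jacobian (independent oracle)
#'
#' Central-difference estimate of the six first partials. This path never
#' touches the symbolic derivatives and exists to cross-check them.
#'
#' @inheritParams jacobian
#' @param h Step size (> 0).
#' @return A `jacobian_summary`.
#' @export
numeric_jacobian <- function(model, u0 = 0, v0 = 0, h = 1e-6) {
  stopifnot(inherits(model, "surface_model"))
  if (!is.numeric(h) || length(h) != 1 || !is.finite(h) || h <= 0) {
    rlang::abort("`h` must be a single positive step size.",
                 class = "morphosurf_error_step")
  }
  up <- eval_coords(model, u0 + h, v0); um <- eval_coords(model, u0 - h, v0)
  vp <- eval_coords(model, u0, v0 + h); vm <- eval_coords(model, u0, v0 - h)
  vals <- numeric(6)
  i <- 0
  for (axis in c("x", "y", "z")) {
    vals[i + 1] <- (up[[axis]] - um[[axis]]) / (2 * h)
    vals[i + 2] <- (vp[[axis]] - vm[[axis]]) / (2 * h)
    i <- i + 2
  }
  new_jacobian_summary(vals, point = c(u0 = u0, v0 = v0), label = model$label)
}

#' Grid-averaged Jacobian summary
#'
#' Averages the Jacobian over an even parameter grid. Provided as an
#' alternative descriptor; the single-point summary at (0, 0) is the default
#' throughout the package.
#'
#' @inheritParams jacobian
#' @param nu,nv Grid resolution (>= 2).
#' @return A `jacobian_summary` whose `point` attribute is `NA`.
#' @export
mean_jacobian <- function(model, nu = 11, nv = 11) {
  useq <- seq(model$domain$u[1], model$domain$u[2], length.out = nu)
  vseq <- seq(model$domain$v[1], model$domain$v[2], length.out = nv)
  grid <- tidyr::expand_grid(u0 = useq, v0 = vseq)
  js <- purrr::map2(grid$u0, grid$v0, function(a, b) as.numeric(jacobian(model, a, b)))
  col_major_means <- rowMeans(matrix(unlist(js), nrow = 6))
  new_jacobian_summary(col_major_means[c(1, 4, 2, 5, 3, 6)],
                       point = c(u0 = NA_real_, v0 = NA_real_), label = model$label)
}

#' The three 2x2 minors of a Jacobian summary
#'
#' Determinants of the row pairs (x, y), (x, z), (y, z). A surface that has
#' collapsed to a plane curve (no independent change in two directions) has
#' all three minors equal to zero — the planarity criterion.
#'
#' @param J A `jacobian_summary`.
#' @return Named numeric vector `c(xy, xz, yz)`.
#' @export
#' @examples
#' jacobian_minors(jacobian(surface_model("torus"))) # (0, 0, 2)
jacobian_minors <- function(J) {
  stopifnot(inherits(J, "jacobian_summary"))
  det2 <- function(a, b) J[a, "u"] * J[b, "v"] - J[a, "v"] * J[b, "u"]
  c(xy = det2("x", "y"), xz = det2("x", "z"), yz = det2("y", "z"))
}

.hessian_names <- c("d2x_du2", "d2x_dv2", "d2x_dudv",
                    "d2y_du2", "d2y_dv2", "d2y_dudv",
                    "d2z_du2", "d2z_dv2", "d2z_dudv")

# Default six-element subset: the u-dominant second partials.
.default_hessian <- c("d2x_du2", "d2y_du2", "d2z_du2",
                      "d2x_dudv", "d2y_dudv", "d2z_dudv")

#' Hessian elements of a surface model
#'
#' Second partial derivatives of the coordinate functions, evaluated at the
#' reference point. Used as a post-processing descriptor when two distinct
#' models have identical Jacobian summaries (see [jacobian_table()]): second
#' partials record curvature-level differences — such as a phase shift of an
#' ammonite's pleating — that first partials cannot.
#'
#' Element names follow the pattern `d2x_du2`, `d2x_dv2`, `d2x_dudv` (and
#' likewise for y, z). The default subset is the six u-dominant elements
#' `d2{x,y,z}_du2` and `d2{x,y,z}_dudv`.
#'
#' @inheritParams jacobian
#' @param which Character vector of element names.
#' @return A tibble with columns `element` and `value`.
#' @export
#' @examples
#' hessian_elements(surface_model("torus"), which = c("d2x_du2", "d2z_dudv"))
hessian_elements <- function(model, u0 = 0, v0 = 0, which = NULL) {
  stopifnot(inherits(model, "surface_model"))
  if (is.null(which)) which <- .default_hessian
  bad <- setdiff(which, .hessian_names)
  if (length(bad)) {
    rlang::abort(paste0("Unknown Hessian element name(s): ",
                        paste(bad, collapse = ", "), "."),
                 class = "morphosurf_error_name")
  }
  if (!in_domain(model$domain, u0, v0)) {
    rlang::abort("Reference point outside the model domain.",
                 class = "morphosurf_error_domain")
  }
  vals <- vapply(which, function(nm) {
    axis <- substr(nm, 3, 3)
    expr <- model$expressions[[axis]]
    d2 <- switch(sub("^d2._", "", nm),
                 du2 = stats::D(stats::D(expr, "u"), "u"),
                 dv2 = stats::D(stats::D(expr, "v"), "v"),
                 dudv = stats::D(stats::D(expr, "u"), "v"))
    eval_expr(model, d2, u0, v0)
  }, numeric(1))
  tibble::tibble(element = which, value = unname(vals))
}

# First/second fundamental forms and the (sign-convention) unit normal.
# The normal is -(S_u x S_v)/|.|, which makes the classic torus curvatures
# come out as cos(v)/(R + r cos v) and 1/r.
fundamental_forms <- function(model, u0, v0) {
  dp <- first_partials(model)
  Su <- unname(vapply(c("x", "y", "z"), function(a) eval_expr(model, dp[[a]]$u, u0, v0), numeric(1)))
  Sv <- unname(vapply(c("x", "y", "z"), function(a) eval_expr(model, dp[[a]]$v, u0, v0), numeric(1)))
  second <- function(var1, var2) {
    unname(vapply(c("x", "y", "z"), function(a) {
      eval_expr(model, stats::D(stats::D(model$expressions[[a]], var1), var2), u0, v0)
    }, numeric(1)))
  }
  Suu <- second("u", "u"); Suv <- second("u", "v"); Svv <- second("v", "v")
  E <- sum(Su * Su); F <- sum(Su * Sv); G <- sum(Sv * Sv)
  cr <- cross3(Su, Sv)
  ncr <- sqrt(sum(cr^2))
  list(Su = Su, Sv = Sv, Suu = Suu, Suv = Suv, Svv = Svv,
       E = E, F = F, G = G, cross_norm = ncr,
       normal = if (ncr > 0) -cr / ncr else c(NA_real_, NA_real_, NA_real_))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Principal curvatures at a surface point
#'
#' Eigenvalues of the shape operator computed from the first and second
#' fundamental forms. `k1` is the curvature of the principal direction closer
#' to the u-parameter curve, `k2` the one closer to the v-curve; at an umbilic
#' point both are equal and the assignment is arbitrary. Signs follow the
#' package's normal convention (see [darboux_frame()]).
#'
#' @inheritParams jacobian
#' @return A one-row tibble with columns `k1`, `k2`.
#' @export
#' @examples
#' principal_curvatures(surface_model("torus", R = 2, r = 1)) # 1/3 and 1
principal_curvatures <- function(model, u0 = 0, v0 = 0) {
  stopifnot(inherits(model, "surface_model"))
  ff <- fundamental_forms(model, u0, v0)
  detI <- ff$E * ff$G - ff$F^2
  if (!is.finite(detI) || detI <= 1e-12 * max(ff$E * ff$G, 1)) {
    rlang::abort(
      paste0("Degenerate metric at (", signif(u0, 6), ", ", signif(v0, 6),
             "): surface is not regular there."),
      class = "morphosurf_error_regularity"
    )
  }
  L <- sum(ff$Suu * ff$normal)
  M <- sum(ff$Suv * ff$normal)
  N <- sum(ff$Svv * ff$normal)
  W <- solve(matrix(c(ff$E, ff$F, ff$F, ff$G), 2), matrix(c(L, M, M, N), 2))
  ev <- eigen(W)
  vals <- Re(ev$values)
  vecs <- Re(ev$vectors)
  # associate each principal direction with the nearer parameter curve
  tang1 <- vecs[1, 1] * ff$Su + vecs[2, 1] * ff$Sv
  along_u <- abs(sum(tang1 * ff$Su)) / (sqrt(sum(tang1^2)) * sqrt(ff$E))
  if (along_u >= 1 / sqrt(2)) {
    k <- c(vals[1], vals[2])
  } else {
    k <- c(vals[2], vals[1])
  }
  tibble::tibble(k1 = k[1], k2 = k[2])
}

#' Darboux frame along a parameter curve
#'
#' Orthonormal moving frame \{t, u, v\} at a surface point: `t` is the unit
#' tangent of the chosen parameter curve, `normal` the unit surface normal,
#' and `tangent_normal = normal x t`. The geodesic curvature and geodesic
#' torsion of the curve are returned alongside. The normal is oriented as
#' \eqn{-(S_u \times S_v)/\|\cdot\|}; the opposite orientation negates
#' `normal`, `tangent_normal` and `tau_g`, so comparisons should be made up
#' to sign.
#'
#' @inheritParams jacobian
#' @param along `"u"` or `"v"`: which parameter curve the frame follows.
#' @return A list of class `darboux_frame` with elements `t`, `normal`,
#'   `tangent_normal`, `kappa_g`, `tau_g`.
#' @export
#' @examples
#' darboux_frame(surface_model("torus"), along = "u")$t # (0, 1, 0)
darboux_frame <- function(model, u0 = 0, v0 = 0, along = c("u", "v")) {
  stopifnot(inherits(model, "surface_model"))
  along <- match.arg(along)
  frame_at <- function(w) {
    uu <- if (along == "u") w else u0
    vv <- if (along == "v") w else v0
    ff <- fundamental_forms(model, uu, vv)
    speed_vec <- if (along == "u") ff$Su else ff$Sv
    speed <- sqrt(sum(speed_vec^2))
    if (!is.finite(speed) || speed < 1e-12) {
      rlang::abort("Chosen parameter curve has zero speed at this point.",
                   class = "morphosurf_error_degenerate_curve")
    }
    if (ff$cross_norm < 1e-12) {
      rlang::abort("Degenerate metric: surface normal undefined here.",
                   class = "morphosurf_error_regularity")
    }
    t_vec <- speed_vec / speed
    n_vec <- ff$normal
    list(t = t_vec, normal = n_vec, tangent_normal = cross3(n_vec, t_vec),
         speed = speed)
  }
  w0 <- if (along == "u") u0 else v0
  f0 <- frame_at(w0)
  # frame derivatives with respect to arc length, via central differences in
  # the curve parameter (the frame itself is exact at each evaluation)
  h <- 1e-5
  fp <- frame_at(w0 + h); fm <- frame_at(w0 - h)
  dt_ds <- (fp$t - fm$t) / (2 * h) / f0$speed
  dn_ds <- (fp$normal - fm$normal) / (2 * h) / f0$speed
  structure(
    list(t = f0$t, normal = f0$normal, tangent_normal = f0$tangent_normal,
         kappa_g = sum(dt_ds * f0$tangent_normal),
         tau_g = -sum(dn_ds * f0$tangent_normal),
         point = c(u0 = u0, v0 = v0), along = along),
    class = "darboux_frame"
  )
}

#' @export
print.darboux_frame <- function(x, ...) {
  cat(sprintf("<darboux_frame> along %s-curve at (u0 = %g, v0 = %g)\n",
              x$along, x$point[1], x$point[2]))
  m <- rbind(t = x$t, normal = x$normal, tangent_normal = x$tangent_normal)
  colnames(m) <- c("x", "y", "z")
  print(round(m, 6))
  cat(sprintf("  kappa_g = %.6g, tau_g = %.6g\n", x$kappa_g, x$tau_g))
  invisible(x)
}

#' Serret-Frenet frame of a parameter curve
#'
#' Unit tangent, principal normal and binormal of the chosen parameter curve,
#' with its curvature and torsion, from exact symbolic derivatives of the
#' curve.
#'
#' @inheritParams darboux_frame
#' @return A list of class `frenet_frame` with `t`, `n`, `b`, `kappa`, `tau`,
#'   and the velocity vector `w`.
#' @export
frenet_frame <- function(model, u0 = 0, v0 = 0, along = c("u", "v")) {
  stopifnot(inherits(model, "surface_model"))
  along <- match.arg(along)
  d1 <- lapply(model$expressions, stats::D, name = along)
  d2 <- lapply(d1, stats::D, name = along)
  d3 <- lapply(d2, stats::D, name = along)
  ev <- function(dl) unname(vapply(c("x", "y", "z"),
                                   function(a) eval_expr(model, dl[[a]], u0, v0), numeric(1)))
  g1 <- ev(d1); g2 <- ev(d2); g3 <- ev(d3)
  speed <- sqrt(sum(g1^2))
  if (speed < 1e-12) {
    rlang::abort("Chosen parameter curve has zero speed at this point.",
                 class = "morphosurf_error_degenerate_curve")
  }
  cr <- cross3(g1, g2)
  crn <- sqrt(sum(cr^2))
  t_vec <- g1 / speed
  kappa <- crn / speed^3
  if (crn < 1e-12) {
    b_vec <- n_vec <- c(NA_real_, NA_real_, NA_real_)
    tau <- NA_real_
  } else {
    b_vec <- cr / crn
    n_vec <- cross3(b_vec, t_vec)
    tau <- sum(cr * g3) / crn^2
  }
  structure(list(t = t_vec, n = n_vec, b = b_vec, kappa = kappa, tau = tau,
                 w = g1, point = c(u0 = u0, v0 = v0), along = along),
            class = "frenet_frame")
}
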