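# Model-spec documents (JSON), point-cloud export (OBJ / ascii PLY), and
# delimited Jacobian tables.

.spec_keys <- c("kind", "label", "coefficients", "domain", "grid", "eval_point")

#' Read a surface model from a JSON model spec
#'
#' A model spec is a small JSON document with keys `kind`, `coefficients`
#' (named numbers, including the radii), and optionally `label`, `domain`
#' (objects `u`, `v` with `[lower, upper]` bounds in radians), `grid`
#' (`nu`, `nv`), and `eval_point` (`[u0, v0]`). Unknown keys are rejected.
#'
#' @param input Path to a JSON file, or a JSON string.
#' @return A [surface_model()]; `grid` and `eval_point`, when present, are
#'   attached as attributes of the same names.
#' @export
#' @examples
#' m <- read_model_spec('{"kind": "torus", "coefficients": {"R": 1, "r": 1}}')
#' evaluate_surface(m, 0, 0)
read_model_spec <- function(input) {
  spec <- tryCatch(
    jsonlite::fromJSON(input, simplifyVector = TRUE),
    error = function(e) {
      rlang::abort(paste0("Malformed model spec: ", conditionMessage(e)),
                   class = "morphosurf_error_parse")
    }
  )
  unknown <- setdiff(names(spec), .spec_keys)
  if (length(unknown)) {
    rlang::abort(paste0("Unknown model-spec key(s): ", paste(unknown, collapse = ", "), "."),
                 class = "morphosurf_error_parse")
  }
  if (is.null(spec$kind)) {
    rlang::abort("Model spec must name a `kind`.", class = "morphosurf_error_parse")
  }
  domain <- if (!is.null(spec$domain)) {
    param_domain(u = spec$domain$u %||% c(0, 2 * pi),
                 v = spec$domain$v %||% c(0, 2 * pi))
  } else {
    param_domain()
  }
  model <- surface_model(spec$kind,
                         coefficients = as.list(spec$coefficients),
                         domain = domain,
                         label = spec$label %||% spec$kind)
  if (!is.null(spec$grid)) attr(model, "grid") <- spec$grid
  if (!is.null(spec$eval_point)) attr(model, "eval_point") <- as.numeric(spec$eval_point)
  model
}

#' Serialize a surface model to a JSON model spec
#'
#' Round-trips losslessly through [read_model_spec()] for registry kinds.
#'
#' @param model A [surface_model()].
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
write_model_spec <- function(model, path = NULL) {
  stopifnot(inherits(model, "surface_model"))
  if (model$kind == "custom") {
    rlang::abort("Custom expression models cannot be serialized as specs.",
                 class = "morphosurf_error_parse")
  }
  spec <- list(kind = model$kind, label = model$label,
               coefficients = as.list(model$coefficients),
               domain = list(u = model$domain$u, v = model$domain$v))
  json <- jsonlite::toJSON(spec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(as.character(json))
}

#' Export a surface grid as a point cloud
#'
#' Writes Wavefront OBJ (one `v x y z` line per lattice point, optionally
#' with quad faces over the lattice) or ascii PLY. Coordinates are printed
#' with 9 decimal digits.
#'
#' @param grid A [surface_grid()].
#' @param path Output path; when `NULL` the document lines are returned.
#' @param format `"obj"` or `"ply"`.
#' @param faces Also emit quad faces over the lattice (OBJ only).
#' @return Character vector of document lines (invisibly when written).
#' @export
#' @examples
#' g <- surface_grid(surface_model("torus"), nu = 3, nv = 3)
#' head(write_point_cloud(g, format = "obj"), 3)
write_point_cloud <- function(grid, path = NULL, format = c("obj", "ply"), faces = FALSE) {
  format <- match.arg(format)
  if (!is.data.frame(grid) || nrow(grid) == 0 ||
      !all(c("x", "y", "z") %in% names(grid))) {
    rlang::abort("`grid` must be a non-empty surface grid with x, y, z columns.",
                 class = "morphosurf_error_export")
  }
  if (any(!is.finite(grid$x)) || any(!is.finite(grid$y)) || any(!is.finite(grid$z))) {
    rlang::abort("Grid contains non-finite coordinates.",
                 class = "morphosurf_error_export")
  }
  if (format == "obj") {
    lines <- sprintf("v %.9f %.9f %.9f", grid$x, grid$y, grid$z)
    if (faces) {
      nu <- attr(grid, "nu"); nv <- attr(grid, "nv")
      if (is.null(nu) || is.null(nv)) {
        rlang::abort("Faces require a lattice grid from surface_grid().",
                     class = "morphosurf_error_export")
      }
      idx <- function(i, j) (i - 1L) * nv + j
      quads <- character(0)
      for (i in seq_len(nu - 1L)) {
        j <- seq_len(nv - 1L)
        quads <- c(quads, sprintf("f %d %d %d %d",
                                  idx(i, j), idx(i, j + 1L),
                                  idx(i + 1L, j + 1L), idx(i + 1L, j)))
      }
      lines <- c(lines, quads)
    }
  } else {
    header <- c("ply", "format ascii 1.0",
                sprintf("element vertex %d", nrow(grid)),
                "property float x", "property float y", "property float z",
                "end_header")
    lines <- c(header, sprintf("%.9f %.9f %.9f", grid$x, grid$y, grid$z))
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Write a Jacobian table to CSV
#'
#' Header `label, dx_du, dx_dv, dy_du, dy_dv, dz_du, dz_dv`; full double
#' precision, so a read-back reproduces the table exactly.
#'
#' @param table A [jacobian_table()] (an empty table writes header only).
#' @param path Destination CSV path.
#' @return `table`, invisibly.
#' @export
write_jacobian_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(table)
}

#' Read a Jacobian table from CSV
#'
#' Re-derives the degenerate-pair flags from the read values.
#'
#' @param path CSV path written by [write_jacobian_table()].
#' @param tol Degeneracy threshold (max absolute element difference).
#' @return A `jacobian_table` tibble.
#' @export
read_jacobian_table <- function(path, tol = 1e-9) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!"label" %in% names(out)) {
    rlang::abort("Jacobian table must have a `label` column.",
                 class = "morphosurf_error_parse")
  }
  mat <- as.matrix(out[vapply(out, is.numeric, logical(1))])
  attr(out, "degenerate_pairs") <- degenerate_pairs_impl(mat, out$label, tol)
  class(out) <- c("jacobian_table", class(out))
  out
}
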