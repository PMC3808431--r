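# Morphospace construction: flatten Jacobian summaries of a model collection
# into an n x 6 table, ordinate the table with a correlation-matrix PCA, and
# trace ontogenetic trajectories through the resulting score space.

jacobian_columns <- c("dx_du", "dx_dv", "dy_du", "dy_dv", "dz_du", "dz_dv")

flatten_jacobian <- function(J) {
  stats::setNames(as.numeric(t(unclass(J))), jacobian_columns)
}

# Pairs whose summaries coincide to within `tol` (max absolute difference).
degenerate_pairs_impl <- function(mat, labels, tol = 1e-9) {
  out <- list()
  n <- nrow(mat)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (max(abs(mat[i, ] - mat[j, ])) < tol) {
          out[[length(out) + 1]] <- tibble::tibble(label_1 = labels[i], label_2 = labels[j])
        }
      }
    }
  }
  if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(label_1 = character(), label_2 = character())
}

#' Assemble a Jacobian table from a model collection
#'
#' Evaluates the Jacobian summary of each model at a common reference point
#' and flattens the summaries into one row per model, in the documented
#' element order `dx_du, dx_dv, dy_du, dy_dv, dz_du, dz_dv`. Model pairs with
#' numerically identical summaries (max absolute difference < `tol`) are
#' flagged in the `degenerate_pairs` attribute: such pairs are exactly the
#' cases where Hessian post-processing ([hessian_elements()]) is needed to
#' separate the forms.
#'
#' @param models A named list of [surface_model()]s (names become labels), or
#'   a `fixture_collection`.
#' @param u0,v0 Common reference point (radians), default (0, 0).
#' @param tol Degeneracy threshold on the max absolute element difference.
#' @return A tibble of class `jacobian_table` with columns `label` +
#'   the six elements, and attribute `degenerate_pairs`.
#' @export
#' @examples
#' tbl <- jacobian_table(list(torus = canonical_model("torus"),
#'                            volute = canonical_model("volute")))
#' tbl
jacobian_table <- function(models, u0 = 0, v0 = 0, tol = 1e-9) {
  if (inherits(models, "surface_model")) models <- list(models)
  if (!is.list(models) || length(models) < 2) {
    rlang::abort("Need at least two models to assemble an ordination table.",
                 class = "morphosurf_error_precondition"
    )
  }
  labels <- names(models)
  if (is.null(labels) || any(labels == "")) {
    labels <- vapply(models, function(m) m$label, character(1))
  }
  rows <- purrr::map(models, function(m) flatten_jacobian(jacobian(m, u0, v0)))
  mat <- do.call(rbind, rows)
  pairs <- degenerate_pairs_impl(mat, labels, tol)
  if (nrow(pairs)) {
    message("Jacobian-degenerate model pair(s) flagged: ",
            paste(paste(pairs$label_1, pairs$label_2, sep = " ~ "), collapse = "; "),
            ". Consider Hessian post-processing (hessian_elements()).")
  }
  out <- dplyr::bind_cols(tibble::tibble(label = labels), tibble::as_tibble(mat))
  attr(out, "degenerate_pairs") <- pairs
  attr(out, "eval_point") <- c(u0 = u0, v0 = v0)
  class(out) <- c("jacobian_table", class(out))
  out
}

#' Degenerate pairs flagged in a Jacobian table
#'
#' @param table A `jacobian_table`.
#' @return A tibble with columns `label_1`, `label_2`.
#' @export
degenerate_pairs <- function(table) {
  attr(table, "degenerate_pairs") %||%
    tibble::tibble(label_1 = character(), label_2 = character())
}

#' Ordinate a Jacobian table into a morphospace
#'
#' Principal components analysis of the standardized Jacobian elements:
#' columns are centered and scaled to unit variance, the correlation matrix is
#' eigen-decomposed, and scores are the standardized data projected on the
#' eigenvectors. The eigenvalue sum therefore equals the number of retained
#' (non-constant) variables; constant columns are dropped with a warning.
#' Variable-PC correlations are `eigenvector * sqrt(eigenvalue)`. Each PC's
#' sign is fixed so that its largest-magnitude variable correlation is
#' positive (PCA signs are otherwise arbitrary).
#'
#' @param table A `jacobian_table` (or any data frame with a `label` column
#'   and numeric variable columns).
#' @return A `morphospace` object: list with `eigenvalues`, `percent`,
#'   `cumulative`, `scores` (n x k matrix, rownames = labels),
#'   `correlations` (variables x PCs), `center`, `scale`, `dropped`, `labels`.
#' @export
#' @examples
#' ms <- morphospace(jacobian_table(fixture_collection("basic_forms")))
#' glance(ms)
morphospace <- function(table) {
  if (!is.data.frame(table) || !"label" %in% names(table)) {
    rlang::abort("`table` must be a data frame with a `label` column.",
                 class = "morphosurf_error_precondition")
  }
  labels <- as.character(table$label)
  tbl <- tibble::as_tibble(table)
  mat <- as.matrix(tbl[vapply(tbl, is.numeric, logical(1))])
  if (nrow(mat) < 2) {
    rlang::abort("Need at least two rows to ordinate.",
                 class = "morphosurf_error_precondition")
  }
  if (any(!is.finite(mat))) {
    rlang::abort("Ordination table contains non-finite entries.",
                 class = "morphosurf_error_precondition")
  }
  sds <- apply(mat, 2, stats::sd)
  constant <- sds == 0
  if (all(constant)) {
    rlang::abort("All variables are constant; nothing to ordinate.",
                 class = "morphosurf_error_no_variation")
  }
  dropped <- colnames(mat)[constant]
  if (length(dropped)) {
    warning("Dropping constant variable(s): ", paste(dropped, collapse = ", "),
            call. = FALSE)
    mat <- mat[, !constant, drop = FALSE]
    sds <- sds[!constant]
  }
  centers <- colMeans(mat)
  Z <- scale(mat, center = centers, scale = sds)
  C <- stats::cor(mat)
  eig <- eigen(C, symmetric = TRUE)
  lambda <- pmax(eig$values, 0)
  vecs <- eig$vectors
  corr <- vecs %*% diag(sqrt(lambda), nrow = length(lambda))
  # sign convention: largest-|correlation| variable positive on each PC
  for (j in seq_along(lambda)) {
    i_max <- which.max(abs(corr[, j]))
    if (corr[i_max, j] < 0) {
      vecs[, j] <- -vecs[, j]
      corr[, j] <- -corr[, j]
    }
  }
  scores <- Z %*% vecs
  pc_names <- paste0("PC", seq_along(lambda))
  dimnames(scores) <- list(labels, pc_names)
  dimnames(corr) <- list(colnames(mat), pc_names)
  structure(
    list(eigenvalues = lambda,
         percent = 100 * lambda / sum(lambda),
         cumulative = cumsum(100 * lambda / sum(lambda)),
         scores = scores,
         correlations = corr,
         center = centers, scale = sds,
         dropped = dropped, labels = labels),
    class = "morphospace"
  )
}

#' @export
print.morphospace <- function(x, ...) {
  cat(sprintf("<morphospace> %d models, %d variables retained%s\n",
              nrow(x$scores), length(x$eigenvalues),
              if (length(x$dropped)) paste0(" (dropped: ", paste(x$dropped, collapse = ", "), ")")
              else ""))
  cat("  eigenvalues:", paste(sprintf("%.3f", x$eigenvalues), collapse = ", "), "\n")
  cat("  % variance :", paste(sprintf("%.2f", x$percent), collapse = ", "), "\n")
  invisible(x)
}

#' Percent variance explained by a set of eigenvalues
#'
#' @param eigenvalues Non-negative values (eigenvalues, or any per-component
#'   variance shares such as already-computed percentages).
#' @return A tibble with columns `component`, `eigenvalue`, `percent`,
#'   `cumulative`.
#' @export
#' @examples
#' variance_explained(c(2.042, 1.183, 1.037, 0.820, 0.566, 0.352))
variance_explained <- function(eigenvalues) {
  if (!is.numeric(eigenvalues) || length(eigenvalues) == 0 ||
      anyNA(eigenvalues) || any(eigenvalues < 0)) {
    rlang::abort("`eigenvalues` must be non-negative numbers.",
                 class = "morphosurf_error_no_variation")
  }
  total <- sum(eigenvalues)
  if (total == 0) {
    rlang::abort("All eigenvalues are zero; no variation to apportion.",
                 class = "morphosurf_error_no_variation")
  }
  pct <- 100 * eigenvalues / total
  tibble::tibble(component = seq_along(eigenvalues),
                 eigenvalue = as.numeric(eigenvalues),
                 percent = pct,
                 cumulative = cumsum(pct))
}

#' Ontogenetic trajectory through a morphospace
#'
#' Extracts the scores of an ordered sequence of growth stages from an
#' ordination and summarizes the path: step vectors between consecutive
#' stages and a collinearity statistic (fraction of the path's variance on
#' its first principal direction; 1 for a perfectly straight path). A path
#' whose stages all coincide (isometric size-only growth after ratio
#' normalization) has zero-length steps and collinearity 1 by convention.
#'
#' @param space A [morphospace()].
#' @param stages Character vector of stage labels, in growth order (>= 2);
#'   all must be present in the ordination.
#' @return A tibble of class `trajectory`: one row per stage with score
#'   columns, plus attributes `steps` (matrix of consecutive differences) and
#'   `collinearity`.
#' @export
trajectory <- function(space, stages) {
  stopifnot(inherits(space, "morphospace"))
  if (length(stages) < 2) {
    rlang::abort("A trajectory needs at least two stages.",
                 class = "morphosurf_error_precondition")
  }
  missing <- setdiff(stages, space$labels)
  if (length(missing)) {
    rlang::abort(paste0("Stage(s) not present in the ordination: ",
                        paste(missing, collapse = ", "), "."),
                 class = "morphosurf_error_label")
  }
  idx <- match(stages, space$labels)
  pts <- space$scores[idx, , drop = FALSE]
  steps <- diff(pts)
  centered <- sweep(pts, 2, colMeans(pts))
  sv <- svd(centered)$d
  total <- sum(sv^2)
  collinearity <- if (total < 1e-300) 1 else sv[1]^2 / total
  out <- dplyr::bind_cols(tibble::tibble(stage = stages),
                          tibble::as_tibble(pts, .name_repair = "minimal"))
  attr(out, "steps") <- steps
  attr(out, "collinearity") <- collinearity
  class(out) <- c("trajectory", class(out))
  out
}

#' Collinearity of a trajectory
#'
#' @param x A [trajectory()].
#' @return The fraction of path variance on its first principal direction.
#' @export
collinearity <- function(x) {
  stopifnot(inherits(x, "trajectory"))
  attr(x, "collinearity")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
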