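# Radius-measurement reduction: measured maximum whorl and aperture radii
# (R_max, r_max, in cm) -> actual proportion (divided through by the smaller
# member, 3 decimals) -> lowest integer proportion (nearest integers reduced
# by their gcd). The integer pair parameterizes generalized "blank" models;
# the actual pair is used directly when refining a model against a specimen.

round_half_away <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

gcd2 <- function(a, b) {
  while (b != 0) { tmp <- b; b <- a %% b; a <- tmp }
  a
}

#' Actual proportion of a radii measurement
#'
#' Divides the measured whorl and aperture radii through by the smaller of the
#' two, reporting each member rounded half-away-from-zero to 3 decimals, so
#' the smaller member is exactly 1.
#'
#' @param R_max,r_max Measured maximum whorl and aperture radii (cm), both
#'   strictly positive. Vectorized.
#' @return A tibble with columns `actual_R` and `actual_r`.
#' @export
#' @examples
#' actual_proportion(1.8, 0.75)  # (2.4, 1)
#' actual_proportion(0.7, 0.85)  # (1, 1.214)
actual_proportion <- function(R_max, r_max) {
  if (!is.numeric(R_max) || !is.numeric(r_max) ||
      anyNA(R_max) || anyNA(r_max) || any(R_max <= 0) || any(r_max <= 0)) {
    rlang::abort("Radii must be strictly positive numbers.",
                 class = "morphosurf_error_measurement")
  }
  n <- max(length(R_max), length(r_max))
  R_max <- rep_len(R_max, n); r_max <- rep_len(r_max, n)
  smaller <- pmin(R_max, r_max)
  tibble::tibble(actual_R = round_half_away(R_max / smaller),
                 actual_r = round_half_away(r_max / smaller))
}

#' Lowest integer proportion of an actual proportion
#'
#' Rounds each member of an actual proportion half-up to the nearest integer,
#' then reduces the pair by its greatest common divisor.
#'
#' @param actual_R,actual_r Members of the actual proportion (both >= 1 after
#'   normalization, smaller member 1). Vectorized.
#' @return A tibble with integer columns `integer_R` and `integer_r` (gcd 1).
#' @export
#' @examples
#' integer_proportion(3.625, 1)  # (4, 1)
#' integer_proportion(1, 1.5)    # (1, 2)
integer_proportion <- function(actual_R, actual_r) {
  if (!is.numeric(actual_R) || !is.numeric(actual_r) ||
      anyNA(actual_R) || anyNA(actual_r) ||
      any(actual_R < 1) || any(actual_r < 1)) {
    rlang::abort("Actual proportions must be numbers >= 1 (normalized so the smaller member is 1).",
                 class = "morphosurf_error_measurement")
  }
  n <- max(length(actual_R), length(actual_r))
  Ri <- floor(rep_len(actual_R, n) + 0.5)  # round half up
  ri <- floor(rep_len(actual_r, n) + 0.5)
  if (any(Ri < 1) || any(ri < 1)) {
    rlang::abort("A proportion member rounded to zero; measurement degenerate.",
                 class = "morphosurf_error_measurement")
  }
  g <- mapply(gcd2, Ri, ri)
  tibble::tibble(integer_R = as.integer(Ri / g), integer_r = as.integer(ri / g))
}

#' Reduce a table of radii measurements to proportions
#'
#' Data-frame-first wrapper over [actual_proportion()] and
#' [integer_proportion()]: takes one row per specimen and appends the actual
#' and lowest-integer proportion columns.
#'
#' @param data A data frame with columns `R_max` and `r_max` (cm); any other
#'   columns (e.g. `taxon`) are carried through.
#' @return `data` as a tibble with `actual_R`, `actual_r`, `integer_R`,
#'   `integer_r` appended.
#' @export
#' @examples
#' shell_proportions(gastropod_radii())
shell_proportions <- function(data) {
  if (!is.data.frame(data) || !all(c("R_max", "r_max") %in% names(data))) {
    rlang::abort("`data` must be a data frame with columns R_max and r_max.",
                 class = "morphosurf_error_measurement")
  }
  act <- actual_proportion(data$R_max, data$r_max)
  int <- integer_proportion(act$actual_R, act$actual_r)
  dplyr::bind_cols(tibble::as_tibble(data), act, int)
}

#' Measured radii of fourteen gastropod shells
#'
#' Maximum whorl and aperture radii (cm) for the fourteen gastropod taxa used
#' in the worked examples, measured from monograph photographs and verified
#' against museum specimens. These measurements are the standard inputs for
#' the proportion-reduction workflow.
#'
#' @return A tibble with columns `taxon`, `R_max`, `r_max`.
#' @export
#' @examples
#' gastropod_radii()
gastropod_radii <- function() {
  tibble::tribble(
    ~taxon,                    ~R_max, ~r_max,
    "Scaphander lignarius",      1,      1.5,
    "Sinum perspectivum",        1.6,    1.6,
    "Melampus coffeus",          0.7,    0.85,
    "Oliva sayana",              0.8,    1.35,
    "Longchaeus candidus",       0.55,   0.45,
    "Lithopoma phoebium",        1.8,    0.75,
    "Scalenostoma subulatum",    0.55,   0.4,
    "Architectonica nobilis",    1.45,   0.4,
    "Heliacus variegatus",       0.8,    0.3,
    "Calliostoma bairdi",        1.2,    0.45,
    "Janthina globosa",          1.35,   1.25,
    "Vitrinella oldroydi",       0.7,    0.25,
    "Scaphella junonia",         0.9,    1.55,
    "Buccinum glaciale",         1.4,    1.05
  )
}

#' Read radii measurements from a delimited file
#'
#' @param path CSV file with columns `taxon`, `R_max`, `r_max`.
#' @return A tibble.
#' @export
read_radii <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("R_max", "r_max") %in% names(out))) {
    rlang::abort("Radii file must have columns R_max and r_max.",
                 class = "morphosurf_error_measurement")
  }
  out
}

#' Write a proportion report to a delimited file
#'
#' @param data Output of [shell_proportions()].
#' @param path Destination CSV path.
#' @return `data`, invisibly.
#' @export
write_proportions <- function(data, path) {
  readr::write_csv(data, path)
  invisible(data)
}
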