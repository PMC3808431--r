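# Named fixture collections: frozen model populations used for worked
# examples and ordination tests. Compositions are versioned here so that all
# downstream numbers are reproducible within the package.

#' Build a named fixture collection of surface models
#'
#' Four frozen collections are available:
#' \describe{
#'   \item{`mollusk_echinoid`}{One instance of every mollusk and echinoid
#'     family, including all named shell recipes, a globose (system-2) snail,
#'     a limpet, ontogeny exemplars (turritellid, vermicularia, spirals) and
#'     two echinoids.}
#'   \item{`basic_forms`}{The seven basic geometric forms — torus, cylinder,
#'     cone, dome, sphere and two ellipsoids differing in major-axis length —
#'     plus documented bivalve and gastropod variants.}
#'   \item{`turritellid_series`}{The isometric growth series: turritellids
#'     with 5 through 12 whorls (8 stages).}
#'   \item{`ammonite_grid`}{A 3x3 sweep of the ammonite coiling coefficient
#'     `l` in \{0.5, 1, 1.5\} against the pleating coefficient `q` in
#'     \{0.5, 1, 1.5\}.}
#' }
#'
#' @param name Collection name.
#' @return A named list of [surface_model()]s of class `fixture_collection`.
#' @export
#' @examples
#' names(fixture_collection("turritellid_series"))
fixture_collection <- function(name) {
  models <- switch(
    as.character(name)[1],
    mollusk_echinoid = {
      out <- list(
        cone_shell  = canonical_model("cone_shell"),
        volute      = canonical_model("volute"),
        olive       = canonical_model("olive"),
        bubble      = canonical_model("bubble"),
        melampus    = canonical_model("melampus"),
        sundial     = canonical_model("sundial"),
        moon_snail  = surface_model("gastropod_system2", b = 4, m = 1.2,
                                    R = 1, r = 1.5, label = "moon_snail"),
        limpet      = surface_model("limpet", a = 0.3, b = 2, c = 1, k = 0.3,
                                    label = "limpet"),
        turritellid_9 = canonical_model("turritellid", n_whorls = 9),
        vermicularia  = canonical_model("vermicularia"),
        spiral_5    = canonical_model("spiral", n_coils = 5),
        spiral_9    = canonical_model("spiral", n_coils = 9),
        clam        = canonical_model("clam"),
        oyster      = canonical_model("oyster"),
        scallop     = canonical_model("scallop"),
        ammonite    = canonical_model("ammonite"),
        scaphopod   = canonical_model("scaphopod"),
        echinoid    = canonical_model("echinoid"),
        echinoid_elongate = canonical_model("echinoid", a = 1.2)
      )
      out$turritellid_9$label <- "turritellid_9"
      out
    },
    basic_forms = list(
      torus        = surface_model("torus", R = 2, r = 1, label = "torus"),
      cylinder     = canonical_model("cylinder"),
      cone         = canonical_model("cone"),
      dome         = canonical_model("dome"),
      sphere       = canonical_model("sphere"),
      ellipsoid_a  = canonical_model("ellipsoid", axis_ratio = 1.5),
      ellipsoid_b  = canonical_model("ellipsoid", axis_ratio = 2.5),
      clam         = canonical_model("clam"),
      clam_long    = canonical_model("clam", j = 2.5),
      scallop      = canonical_model("scallop"),
      scallop_flat = canonical_model("scallop", m = 0.3),
      volute       = canonical_model("volute"),
      sundial      = canonical_model("sundial"),
      turritellid_6 = canonical_model("turritellid", n_whorls = 6),
      turritellid_8 = canonical_model("turritellid", n_whorls = 8),
      ammonite     = canonical_model("ammonite")
    ),
    turritellid_series = {
      whorls <- 5:12
      out <- purrr::map(whorls, function(n) canonical_model("turritellid", n_whorls = n))
      names(out) <- sprintf("turritellid_%02d", whorls)
      for (nm in names(out)) out[[nm]]$label <- nm
      out
    },
    ammonite_grid = {
      grid <- tidyr::expand_grid(l = c(0.5, 1, 1.5), q = c(0.5, 1, 1.5))
      out <- purrr::map2(grid$l, grid$q, function(l, q) canonical_model("ammonite", l = l, q = q))
      names(out) <- sprintf("ammonite_l%g_q%g", grid$l, grid$q)
      for (nm in names(out)) out[[nm]]$label <- nm
      out
    },
    rlang::abort(paste0("Unknown fixture collection ", deparse(name), "."),
                 class = "morphosurf_error_registry")
  )
  for (nm in names(models)) {
    if (models[[nm]]$label != nm) models[[nm]]$label <- nm
  }
  structure(models, class = "fixture_collection")
}

#' @export
print.fixture_collection <- function(x, ...) {
  cat(sprintf("<fixture_collection> %d models: %s\n", length(x),
              paste(names(x), collapse = ", ")))
  invisible(x)
}
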