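# One representative, finitely-evaluating instance of every registry family.
representative_models <- function() {
  list(
    gastropod_system1 = canonical_model("cone_shell"),
    gastropod_system2 = surface_model("gastropod_system2", b = 4, m = 1.2,
                                      R = 1, r = 1.5, label = "moon_snail"),
    turritellid = canonical_model("turritellid", n_whorls = 9),
    vermicularia = canonical_model("vermicularia"),
    spiral_curve = canonical_model("spiral", n_coils = 5),
    limpet = surface_model("limpet", a = 0.3, b = 2, c = 1, k = 0.3, label = "limpet"),
    clam = canonical_model("clam"),
    oyster = canonical_model("oyster"),
    scallop = canonical_model("scallop"),
    ammonite = canonical_model("ammonite"),
    scaphopod = canonical_model("scaphopod"),
    echinoid = canonical_model("echinoid"),
    torus = canonical_model("torus"),
    cylinder = canonical_model("cylinder"),
    cone = canonical_model("cone"),
    dome = canonical_model("dome"),
    sphere = canonical_model("sphere"),
    ellipsoid = canonical_model("ellipsoid", axis_ratio = 1.5)
  )
}

# Seeded random points inside the default domain, kept away from the exact
# boundary so central differences stay evaluable.
random_domain_points <- function(n, seed = 42) {
  withr::with_seed(seed, {
    tibble::tibble(u = stats::runif(n, 0.05, 2 * pi - 0.05),
                   v = stats::runif(n, 0.05, 2 * pi - 0.05))
  })
}

expect_jacobian_close <- function(a, b, tol) {
  scale <- max(1, max(abs(as.numeric(a))))
  expect_lt(max(abs(as.numeric(a) - as.numeric(b))) / scale, tol)
}
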