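make_random_table <- function(n = 50, seed = 99) {
  withr::with_seed(seed, {
    mat <- matrix(stats::rnorm(n * 6), n, 6,
                  dimnames = list(NULL, c("dx_du", "dx_dv", "dy_du",
                                          "dy_dv", "dz_du", "dz_dv")))
    dplyr::bind_cols(tibble::tibble(label = sprintf("m%02d", seq_len(n))),
                     tibble::as_tibble(mat))
  })
}

test_that("assembled tables have one ordered row per model", {
  torus <- surface_model("torus")
  tbl <- suppressMessages(jacobian_table(list(a = torus, b = torus)))
  expect_equal(tbl$label, c("a", "b"))
  expect_equal(as.numeric(tbl[1, -1]), c(0, 0, 2, 0, 0, 1))
  expect_identical(as.numeric(tbl[1, -1]), as.numeric(tbl[2, -1]))
  expect_error(jacobian_table(list(a = torus)),
               class = "morphosurf_error_precondition")
})

test_that("Jacobian-degenerate pairs are flagged at assembly", {
  pair <- list(base = canonical_model("ammonite"),
               shifted = canonical_model("ammonite", v_shift = pi / 4))
  expect_message(tbl <- jacobian_table(pair), "degenerate")
  flags <- degenerate_pairs(tbl)
  expect_equal(nrow(flags), 1)
  expect_setequal(c(flags$label_1, flags$label_2), c("base", "shifted"))
})

test_that("correlation-PCA eigenvalues sum to the retained variable count", {
  for (name in c("mollusk_echinoid", "basic_forms", "turritellid_series")) {
    tbl <- suppressMessages(jacobian_table(fixture_collection(name)))
    ms <- suppressWarnings(morphospace(tbl))
    expect_equal(sum(ms$eigenvalues), length(ms$eigenvalues), tolerance = 1e-9,
                 info = name)
  }
})

test_that("a rank-1 table has a single non-zero eigenvalue", {
  base <- c(1, 2, 3, 4)
  mat <- outer(base, c(1, 2, 3, 4, 5, 6))
  colnames(mat) <- paste0("v", 1:6)
  tbl <- dplyr::bind_cols(tibble::tibble(label = letters[1:4]), tibble::as_tibble(mat))
  ms <- morphospace(tbl)
  expect_equal(ms$eigenvalues, c(6, 0, 0, 0, 0, 0), tolerance = 1e-9)
  ve <- variance_explained(ms$eigenvalues)
  expect_equal(ve$percent[1], 100)
  expect_equal(ve$cumulative, rep(100, 6))
})

test_that("scores are centered, uncorrelated, with variances equal to the eigenvalues", {
  ms <- morphospace(make_random_table())
  expect_equal(max(abs(colMeans(ms$scores))), 0, tolerance = 1e-9)
  sc_cov <- stats::cov(ms$scores)
  expect_equal(unname(diag(sc_cov)), ms$eigenvalues, tolerance = 1e-9)
  off <- sc_cov - diag(diag(sc_cov))
  expect_lt(max(abs(off)), 1e-9)
  expect_true(all(ms$correlations >= -1 - 1e-12 & ms$correlations <= 1 + 1e-12))
})

test_that("the authored eigen-decomposition agrees with prcomp as an oracle", {
  tbl <- make_random_table(n = 40, seed = 12)
  ms <- morphospace(tbl)
  pr <- stats::prcomp(tbl[, -1], center = TRUE, scale. = TRUE)
  expect_equal(ms$eigenvalues, unname(pr$sdev^2), tolerance = 1e-9)
  expect_equal(abs(unclass(ms$scores)), abs(unname(pr$x)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("ordination is invariant to row order (after the sign convention)", {
  tbl <- make_random_table(n = 30, seed = 4)
  ms1 <- morphospace(tbl)
  perm <- withr::with_seed(8, sample(nrow(tbl)))
  ms2 <- morphospace(tbl[perm, ])
  expect_equal(ms1$eigenvalues, ms2$eigenvalues, tolerance = 1e-9)
  expect_equal(ms1$correlations, ms2$correlations, tolerance = 1e-9)
  expect_equal(ms1$scores[tbl$label, ], ms2$scores[tbl$label, ], tolerance = 1e-9)
})

test_that("duplicated models receive identical score vectors", {
  fc <- fixture_collection("basic_forms")
  fc2 <- c(unclass(fc), list(torus_copy = fc$torus))
  tbl <- suppressMessages(jacobian_table(fc2))
  ms <- suppressWarnings(morphospace(tbl))
  expect_identical(unname(ms$scores["torus", ]), unname(ms$scores["torus_copy", ]))
})

test_that("constant columns are dropped with a warning and the eigenvalue sum adjusts", {
  tbl <- suppressMessages(jacobian_table(fixture_collection("ammonite_grid")))
  expect_warning(ms <- morphospace(tbl), "constant")
  expect_lt(length(ms$eigenvalues), 6)
  expect_equal(sum(ms$eigenvalues), length(ms$eigenvalues), tolerance = 1e-9)
  expect_error(morphospace(tibble::tibble(label = c("a", "b"), v1 = c(1, 1))),
               class = "morphosurf_error_no_variation")
})

test_that("variance_explained reproduces printed-style arithmetic", {
  # the reference percentages are printed at 3 decimals and sum to 99.999,
  # so renormalization shifts the running sums by up to ~6e-4
  printed_percent <- c(34.029, 19.722, 17.275, 13.664, 9.435, 5.874)
  ve <- variance_explained(printed_percent)
  expect_equal(ve$cumulative[2], 53.751, tolerance = 1e-3)
  expect_equal(ve$cumulative[3], 71.027, tolerance = 1e-3)
  expect_equal(ve$cumulative[5], 94.126, tolerance = 1e-3)
  printed_eigen <- c(2.042, 1.183, 1.037, 0.820, 0.566, 0.352)
  expect_equal(variance_explained(printed_eigen)$percent[1], 34.03, tolerance = 0.01)
  expect_error(variance_explained(c(0, 0)), class = "morphosurf_error_no_variation")
})

test_that("size-only copies coincide in morphospace after ratio normalization", {
  # the same specimen measured at two magnifications reduces to one model
  small <- shell_proportions(tibble::tibble(R_max = 1.8, r_max = 0.75))
  large <- shell_proportions(tibble::tibble(R_max = 3.6, r_max = 1.5))
  expect_identical(small$integer_R, large$integer_R)
  m1 <- surface_model("gastropod_system1", k = 1, l = 0, m = 0,
                      R = small$integer_R, r = small$integer_r)
  m2 <- surface_model("gastropod_system1", k = 1, l = 0, m = 0,
                      R = large$integer_R, r = large$integer_r)
  fc <- fixture_collection("basic_forms")
  tbl <- suppressMessages(jacobian_table(c(unclass(fc), list(s1 = m1, s2 = m2))))
  ms <- suppressWarnings(morphospace(tbl))
  expect_identical(unname(ms$scores["s1", ]), unname(ms$scores["s2", ]))
})

test_that("two-stage trajectories are exactly collinear; repeats collapse to a point", {
  fc <- fixture_collection("turritellid_series")
  ms <- suppressWarnings(morphospace(suppressMessages(jacobian_table(fc))))
  tr2 <- trajectory(ms, c("turritellid_05", "turritellid_12"))
  expect_equal(collinearity(tr2), 1, tolerance = 1e-12)
  tr_rep <- trajectory(ms, rep("turritellid_07", 4))
  expect_equal(max(abs(attr(tr_rep, "steps"))), 0)
  expect_error(trajectory(ms, c("turritellid_05", "missing_stage")),
               class = "morphosurf_error_label")
})

test_that("the turritellid whorl series is monotone along its principal direction", {
  stages <- sprintf("turritellid_%02d", 5:12)
  models <- c(unclass(fixture_collection("mollusk_echinoid")),
              unclass(fixture_collection("turritellid_series")))
  ms <- suppressWarnings(morphospace(suppressMessages(jacobian_table(models))))
  tr <- trajectory(ms, stages)
  pts <- ms$scores[stages, ]
  centered <- sweep(pts, 2, colMeans(pts))
  proj <- centered %*% svd(centered)$v[, 1]
  expect_true(all(diff(proj) > 0) || all(diff(proj) < 0))
  expect_gt(collinearity(tr), 0.99)
})

test_that("tidy and glance views expose the ordination components", {
  ms <- suppressWarnings(morphospace(make_random_table(n = 20, seed = 2)))
  sc <- tidy(ms, "scores")
  expect_equal(dim(sc), c(20, 7))
  co <- tidy(ms, "correlations")
  expect_equal(co$variable, c("dx_du", "dx_dv", "dy_du", "dy_dv", "dz_du", "dz_dv"))
  ev <- tidy(ms, "eigenvalues")
  expect_equal(ev$cumulative[length(ev$cumulative)], 100, tolerance = 1e-9)
  g <- glance(ms)
  expect_equal(g$n_models, 20)
  expect_equal(g$n_variables, 6)
})
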