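test_that("the unit-torus Jacobian at the origin matches the symbolic solution", {
  J <- jacobian(surface_model("torus", R = 1, r = 1))
  expect_equal(as.numeric(t(unclass(J))), c(0, 0, 2, 0, 0, 1))
})

test_that("symbolic and finite-difference Jacobians agree on every family", {
  pts <- random_domain_points(10, seed = 11)
  for (m in representative_models()) {
    for (i in seq_len(nrow(pts))) {
      sym <- jacobian(m, pts$u[i], pts$v[i])
      num <- numeric_jacobian(m, pts$u[i], pts$v[i])
      expect_jacobian_close(sym, num, 1e-6)
    }
  }
  expect_error(numeric_jacobian(surface_model("torus"), h = 0),
               class = "morphosurf_error_step")
})

test_that("Jacobians are linear in the radii for every family", {
  for (m in representative_models()) {
    J <- as.numeric(jacobian(m))
    for (c_scale in c(0.5, 2, 10)) {
      Js <- as.numeric(jacobian(scale_model(m, c_scale)))
      expect_equal(Js, c_scale * J, tolerance = 1e-9, info = m$label)
    }
  }
})

test_that("reflection negates exactly the reflected coordinate's derivatives", {
  m <- canonical_model("melampus")
  J <- unclass(jacobian(m))
  Jr <- unclass(jacobian(reflect_model(m, "z")))
  expect_equal(Jr["z", ], -J["z", ])
  expect_equal(Jr[c("x", "y"), ], J[c("x", "y"), ])
})

test_that("rotation (switching sin u and cos u) permutes Jacobian rows", {
  torus <- surface_model("torus")
  rotated <- parametric_surface(~ (R + r * cos(v)) * sin(u),
                                ~ (R + r * cos(v)) * cos(u),
                                ~ r * sin(v),
                                coefficients = list(R = 1, r = 1))
  J <- unclass(jacobian(torus))
  Jr <- unclass(jacobian(rotated))
  expect_equal(Jr["x", ], J["y", ])
  expect_equal(Jr["y", ], J["x", ])
  expect_equal(Jr["z", ], J["z", ])
})

test_that("Jacobian minors follow the 2x2 determinants and flag planarity", {
  J <- jacobian(surface_model("torus"))
  expect_equal(jacobian_minors(J), c(xy = 0, xz = 0, yz = 2))
  flat <- parametric_surface(~ cos(u), ~ sin(u), ~ 0 * u, label = "flat")
  expect_equal(unname(jacobian_minors(jacobian(flat, 0.7, 1.1))), c(0, 0, 0))
})

test_that("mixed second partials are symmetric for every family", {
  pts <- random_domain_points(5, seed = 23)
  for (m in representative_models()) {
    for (i in seq_len(nrow(pts))) {
      for (axis in c("x", "y", "z")) {
        e <- m$expressions[[axis]]
        duv <- eval(stats::D(stats::D(e, "u"), "v"),
                    c(as.list(m$coefficients), list(u = pts$u[i], v = pts$v[i])))
        dvu <- eval(stats::D(stats::D(e, "v"), "u"),
                    c(as.list(m$coefficients), list(u = pts$u[i], v = pts$v[i])))
        expect_equal(duv, dvu, tolerance = 1e-9)
      }
    }
  }
})

test_that("Hessian elements of the torus match hand computations", {
  torus <- surface_model("torus")
  h <- hessian_elements(torus, which = c("d2x_du2", "d2z_dudv", "d2x_dudv"))
  expect_equal(h$value[h$element == "d2x_du2"], -2)  # -(1 + cos v) cos u at origin
  expect_equal(h$value[h$element == "d2z_dudv"], 0)  # z independent of u
  expect_equal(h$value[h$element == "d2x_dudv"], 0)
  expect_error(hessian_elements(torus, which = "d3x_du3"),
               class = "morphosurf_error_name")
})

test_that("v-phase-shifted ammonite pleats leave the Jacobian unchanged but not the Hessian", {
  base <- canonical_model("ammonite")
  shifted <- canonical_model("ammonite", v_shift = pi / 4)
  expect_identical(as.numeric(jacobian(base)), as.numeric(jacobian(shifted)))
  hb <- hessian_elements(base)$value
  hs <- hessian_elements(shifted)$value
  expect_gt(max(abs(hb - hs)), 1e-6)
})

test_that("u-phase-shifted pleats give different but close Jacobians", {
  base <- canonical_model("ammonite")
  shifted <- canonical_model("ammonite", u_shift = 0.005)
  dJ <- max(abs(as.numeric(jacobian(base)) - as.numeric(jacobian(shifted))))
  expect_gt(dJ, 1e-9)
  expect_lt(dJ, 0.5)
})

test_that("the z-direction parameter augmentation separates a degenerate pair", {
  base <- canonical_model("ammonite", v_shift = pi / 4)
  fixed <- canonical_model("ammonite", v_shift = pi / 4, z_offset = -1)
  expect_identical(as.numeric(jacobian(base)),
                   as.numeric(jacobian(canonical_model("ammonite"))))
  dJ <- max(abs(as.numeric(jacobian(base)) - as.numeric(jacobian(fixed))))
  expect_gt(dJ, 1e-6)
})

test_that("torus principal curvatures match the closed form", {
  torus <- surface_model("torus", R = 2, r = 1)
  pc0 <- principal_curvatures(torus, 0, 0)
  expect_equal(pc0$k1, 1 / 3, tolerance = 1e-9)   # cos v / (R + r cos v)
  expect_equal(pc0$k2, 1, tolerance = 1e-9)       # 1 / r
  pc90 <- principal_curvatures(torus, 0, pi / 2)
  expect_equal(pc90$k1, 0, tolerance = 1e-12)
  expect_equal(pc90$k2, 1, tolerance = 1e-9)
  # meridian curvature is constant 1/r everywhere
  for (v0 in c(0.3, 1.1, 2.9, 4.4)) {
    expect_equal(principal_curvatures(torus, 0.5, v0)$k2, 1, tolerance = 1e-9)
  }
})

test_that("the sphere is umbilic at sampled points", {
  sph <- canonical_model("sphere")
  # latitudes away from the parameterization's poles at u = pi/2, 3*pi/2
  us <- seq(0.1, 1.3, length.out = 5)
  vs <- withr::with_seed(5, stats::runif(4, 0, 2 * pi))
  for (u0 in us) for (v0 in vs) {
    pc <- principal_curvatures(sph, u0, v0)
    expect_equal(pc$k1, pc$k2, tolerance = 1e-9)
    expect_equal(abs(pc$k1), 1, tolerance = 1e-9)
  }
})

test_that("degenerate metrics raise a regularity error", {
  sph <- canonical_model("sphere")
  expect_error(principal_curvatures(sph, pi / 2, 0),
               class = "morphosurf_error_regularity")
})

test_that("Darboux frames are orthonormal and correctly oriented", {
  torus <- surface_model("torus")
  f <- darboux_frame(torus, 0, 0, along = "u")
  expect_equal(f$t, c(0, 1, 0), tolerance = 1e-12)
  expect_equal(abs(f$normal), c(1, 0, 0), tolerance = 1e-12)
  pts <- random_domain_points(20, seed = 17)
  models <- representative_models()[c("gastropod_system1", "torus", "echinoid", "clam")]
  for (m in models) {
    for (i in seq_len(nrow(pts))) {
      fr <- darboux_frame(m, pts$u[i], pts$v[i], along = if (i %% 2) "u" else "v")
      basis <- rbind(fr$t, fr$normal, fr$tangent_normal)
      expect_equal(basis %*% t(basis), diag(3), tolerance = 1e-9,
                   info = paste(m$label, i))
    }
  }
})

test_that("torus meridians are geodesics: zero geodesic torsion, Frenet-aligned tangent", {
  torus <- surface_model("torus", R = 2, r = 1)
  f <- darboux_frame(torus, 0.3, 0.7, along = "v")
  expect_equal(f$tau_g, 0, tolerance = 1e-6)
  fr <- frenet_frame(torus, 0.3, 0.7, along = "v")
  expect_equal(f$t, fr$t, tolerance = 1e-9)
  expect_equal(fr$kappa, 1, tolerance = 1e-9)  # meridian circle of radius r = 1
})

test_that("grid-averaged Jacobians preserve the element ordering", {
  torus <- surface_model("torus")
  mj <- mean_jacobian(torus, nu = 21, nv = 21)
  # averaged over full periods, du-column means vanish; dz_dv mean stays 0 too
  expect_equal(max(abs(as.numeric(mj))), max(abs(unclass(mj))))
  expect_lt(abs(unclass(mj)["x", "u"]), 0.2)
})
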