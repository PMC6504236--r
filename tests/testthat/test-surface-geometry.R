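# Differential geometry: closed-form curvatures, quadrature, angles.

test_that("closed-form curvatures are recovered on cylinder, sphere, torus", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  cv <- curvature_at(cyl, 1.2, 0.7)
  expect_equal(cv$k1, 2, tolerance = 1e-10)
  expect_equal(cv$k2, 0, tolerance = 1e-10)
  expect_equal(cv$H, 1, tolerance = 1e-10)
  expect_equal(cv$K, 0, tolerance = 1e-10)
  ## circumferential principal direction: no axial component
  expect_lt(abs(cv$d1[3]), 1e-10)

  sph <- make_surface("ellipsoid", a = 1, b = 1, c = 1)
  cs <- curvature_at(sph, 1.1, 2.2)
  expect_equal(cs$k1, 1, tolerance = 1e-8)
  expect_equal(cs$k2, 1, tolerance = 1e-8)
  expect_true(cs$umbilic)

  tor <- make_surface("torus", tube_radius = 0.5, centerline_radius = 5)
  ct <- curvature_at(tor, 2.3, pi)   # inner equator
  expect_equal(ct$k1, 2, tolerance = 1e-10)
  expect_equal(ct$k2, -1 / 4.5, tolerance = 1e-10)
  expect_lt(ct$K, 0)
})

test_that("curvature invariants hold across all reference geometries", {
  for (s in ref_surfaces()) {
    d <- s$domain
    set.seed(42)
    u <- runif(40, d[1] + 0.02 * (d[2] - d[1]), d[2] - 0.02 * (d[2] - d[1]))
    v <- runif(40, d[3], d[4])
    cb <- mrebdyn:::curvature_batch(s, u, v)
    ## trace / determinant consistency
    expect_equal(cb$H, (cb$k1 + cb$k2) / 2, tolerance = 1e-12)
    expect_equal(cb$K, cb$k1 * cb$k2, tolerance = 1e-9)
    expect_true(all(cb$dc >= 0))
    ## principal directions orthonormal in 3D
    i <- !cb$umbilic
    if (any(i)) {
      dots <- abs(rowSums(cb$d1[i, , drop = FALSE] * cb$d2[i, , drop = FALSE]))
      expect_lt(max(dots), 1e-10)
    }
    expect_true(all(abs(rowSums(cb$d1^2) - 1) < 1e-10))
  }
})

test_that("analytic partial derivatives agree with central differences", {
  for (kind in c("cylinder", "torus", "ellipsoid", "helix_tube",
                 "undulating_cylinder")) {
    s <- make_surface(kind)
    d <- s$domain
    set.seed(7)
    u <- runif(12, d[1] + 0.05 * (d[2] - d[1]), d[2] - 0.05 * (d[2] - d[1]))
    v <- runif(12, d[3], d[4])
    ea <- mrebdyn:::sg_eval(s, u, v)
    en <- mrebdyn:::sg_eval_numeric(s, u, v)
    for (f in c("ru", "rv")) {
      rel <- max(abs(ea[[f]] - en[[f]])) / max(abs(ea[[f]]))
      expect_lt(rel, 1e-6)
    }
    for (f in c("ruu", "ruv", "rvv")) {
      scale <- max(max(abs(ea[[f]])), 1)
      expect_lt(max(abs(ea[[f]] - en[[f]])) / scale, 1e-4)
    }
  }
})

test_that("area elements match closed forms and integrals converge", {
  cyl <- make_surface("cylinder", radius = 0.7, length = 2)
  expect_equal(area_element(cyl, 0.3, 1.1), 0.7, tolerance = 1e-12)
  pl <- make_surface("plane")
  expect_equal(area_element(pl, 0.5, 0.5), 1, tolerance = 1e-12)
  ## torus with u = centerline arclength: sqrt(g) = r (Rt + r cos v) / Rt
  tor <- make_surface("torus", tube_radius = 0.5, centerline_radius = 5)
  expect_equal(area_element(tor, 1, 0), 0.5 * 5.5 / 5, tolerance = 1e-12)
  ## spherocylinder area: 2 pi R L + 4 pi R^2
  sc <- make_surface("spherocylinder", radius = 0.5, length = 3)
  expect_equal(surface_area(sc), 2 * pi * 0.5 * 3 + 4 * pi * 0.25,
               tolerance = 1e-4)
})

test_that("Gauss-Bonnet integrals come out at 4 pi (closed) and 0 (torus)", {
  K_of <- function(cb) cb$K
  for (kind in c("spherocylinder", "ellipsoid")) {
    s <- make_surface(kind)
    tot <- surface_integral(s, K_of, n_u = 384, n_v = 96,
                            use_curvature = TRUE)
    expect_equal(tot, 4 * pi, tolerance = 1e-3)
  }
  tor <- make_surface("torus")
  expect_lt(abs(surface_integral(tor, K_of, n_u = 128, n_v = 128,
                                 use_curvature = TRUE)), 1e-3 * 4 * pi)
})

test_that("direction/angle conversion is metric-correct and round-trips", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  cv <- curvature_at(cyl, 1, 0.3)
  th <- direction_to_angle(cyl, 1, 0.3, cv$d1)
  expect_equal(abs(th), pi / 2, tolerance = 1e-10)   # d1 defined up to sign
  pl <- make_surface("plane")
  w <- c(cos(0.3), sin(0.3), 0)
  expect_equal(direction_to_angle(pl, 1, 1, w), 0.3, tolerance = 1e-12)
  ## round trip on the torus, and brute-force metric-angle oracle
  tor <- make_surface("torus")
  u0 <- 2.1; v0 <- 0.8
  cvt <- curvature_at(tor, u0, v0)
  e <- mrebdyn:::sg_eval(tor, u0, v0)
  nin <- mrebdyn:::vcross(e$ru, e$rv)
  nin <- tor$nsign * nin / sqrt(sum(nin^2))
  d1 <- cvt$d1
  tperp <- mrebdyn:::vcross(matrix(nin, 1), matrix(d1, 1))
  eta <- 0.2
  w3 <- cos(eta) * d1 + sin(eta) * drop(tperp)
  th2 <- direction_to_angle(tor, u0, v0, w3)
  ## oracle: scan theta for the tangent whose metric angle with d1 is eta
  thetas <- seq(-pi, pi, length.out = 20001)
  dirs <- angle_to_direction(tor, rep(u0, length(thetas)),
                             rep(v0, length(thetas)), thetas)
  ang <- acos(pmin(pmax(dirs %*% d1, -1), 1))
  best <- thetas[which.min(abs(ang - eta) +
                           (rowSums(dirs * tperp[rep(1, nrow(dirs)), ]) < 0))]
  expect_equal(th2, best, tolerance = 1e-3)
  ## inverse operation
  back <- angle_to_direction(tor, u0, v0, th2)
  expect_equal(drop(back), w3 / sqrt(sum(w3^2)), tolerance = 1e-10)
})

test_that("surface specs validate their invariants", {
  expect_error(surface_spec("torus", tube_radius = 5, centerline_radius = 1),
               "tube_radius")
  expect_error(surface_spec("undulating_cylinder", amplitude = 0.6,
                            radius = 0.5), "amplitude")
  expect_error(surface_spec("cylinder", radius = -1), "positive")
  expect_error(surface_spec("cylinder", bogus_dim = 1), "unknown dimension")
  expect_error(surface_spec("dodecahedron"))
})

test_that("surfaces export as VTK with curvature fields", {
  p <- tempfile(fileext = ".vtk")
  write_surface_vtk(make_surface("torus"), p, n_u = 16, n_v = 12)
  txt <- readLines(p)
  expect_true(any(grepl("DATASET STRUCTURED_GRID", txt)))
  expect_true(any(grepl("SCALARS K float", txt)))
  expect_equal(sum(grepl("SCALARS", txt)), 4L)
})
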