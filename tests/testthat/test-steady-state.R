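# Continuum steady state: jump moments, limiting distributions, conservation,
# grid convergence and symmetry inheritance.

test_that("closed-form drift/diffusion fields behave on canonical surfaces", {
  tp <- translocation_params()
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  g <- surface_grid(cyl, 8, 8)
  f <- drift_diffusion_fields(cyl, tp, g)
  ## drift purely circumferential, constant magnitude
  expect_lt(max(abs(f$Au)), 1e-12)
  expect_equal(diff(range(f$speed)), 0, tolerance = 1e-12)
  expect_equal(unique(round(f$sigma, 12)), 0.3)
  ## sphere: umbilic everywhere, no drift, isotropic second moment L^2/2
  sph <- make_surface("ellipsoid", a = 1, b = 1, c = 1)
  gs <- surface_grid(sph, 8, 8)
  fs <- drift_diffusion_fields(sph, tp, gs)
  expect_true(all(fs$umbilic))
  expect_equal(max(abs(fs$speed)), 0)
  expect_equal(fs$B_par, rep(tp$L^2 / 2, length(fs$B_par)))
})

test_that("exact jump moments match small-step theory on a cylinder", {
  tp <- translocation_params(noise_model = "constant", sigma0 = 0.3)
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  g <- surface_grid(cyl, 6, 6)
  mom <- mrebdyn:::jump_moments(cyl, tp, g$U, g$V)
  ## drift L e^{-sigma^2/2} along v (parameter speed 1/R)
  expect_equal(mom$Av, rep(0.2 * exp(-0.045) / 0.5, length(mom$Av)),
               tolerance = 1e-3)
  expect_lt(max(abs(mom$Au)), 1e-15)
  ## axial second moment L^2 E[sin^2 eta]
  expect_equal(mom$Buu, rep(0.04 * (1 - exp(-0.18)) / 2, length(mom$Buu)),
               tolerance = 2e-3)
})

test_that("uniform concentration solves the limiting regimes", {
  ## strict zero processivity: occupancy equals the activation density
  tor <- make_surface("torus")
  en <- simulate_ensemble(tor, translocation_params(), n_filaments = 2e4,
                          max_steps = 0, n_u = 12, n_v = 24, seed = 7)
  mu_cell <- 2e4 / (12 * 24)
  expect_lt(l1_from_uniform(en$field), 2 * sqrt(2 / (pi * mu_cell)))
  ## ellipsoid with zero noise: uniform at any processivity (continuum)
  ell <- make_surface("ellipsoid")
  for (lam in c(1 / 5, 1 / 30, 0)) {
    fp <- solve_steady_state(ell, translocation_params(
      noise_model = "constant", sigma0 = 0, lambda = lam), 40, 24)
    expect_lt(l1_from_uniform(fp), 1e-8)
  }
  ## and in the Langevin dynamics, within replicate noise
  tpe <- translocation_params(noise_model = "constant", sigma0 = 0,
                              lambda = 1 / 30)
  r1 <- simulate_ensemble(ell, tpe, 3000, n_u = 20, n_v = 16, seed = 1)$field
  r2 <- simulate_ensemble(ell, tpe, 3000, n_u = 20, n_v = 16, seed = 2)$field
  nu <- l1_distance(r1, r2) / sqrt(2)
  M <- r1; M$CF <- (r1$CF + r2$CF) / 2
  expect_lt(l1_from_uniform(M), 3 * nu / sqrt(2))
})

test_that("infinite-processivity torus matches the hoop-uniform density", {
  tor <- make_surface("torus")
  fp <- solve_steady_state(tor, translocation_params(lambda = 0),
                           n_u = 20, n_v = 64)
  prof <- colSums(fp$NF) / colSums(fp$dA)
  pred <- 1 / (5 + 0.5 * cos(fp$grid$v))
  pred <- pred * sum(prof) / sum(pred)
  ## hoop-uniform up to the small drift-speed modulation of sigma(v)
  expect_lt(max(abs(prof - pred) / pred), 0.02)
  part <- region_partition(tor, fp$grid)
  expect_equal(region_enrichment(fp, part, "inner", "midline"), 10 / 9,
               tolerance = 0.02)
})

test_that("discrete mass balance holds to solver precision", {
  for (kind in c("torus", "spherocylinder", "undulating_cylinder")) {
    s <- make_surface(kind)
    fp <- solve_steady_state(s, translocation_params(), 32, 24)
    expect_lt(attr(fp, "residual"), 1e-10)
    ## total filament number: k A / lambda
    expect_equal(sum(fp$NF), 1 * sum(fp$dA) * 30, tolerance = 1e-10)
    expect_true(all(fp$CF >= -1e-12))
  }
})

test_that("steady state is grid-converged at the default resolution", {
  sph <- make_surface("spherocylinder")
  tp <- translocation_params()
  f1 <- solve_steady_state(sph, tp, 64, 48)
  f2 <- solve_steady_state(sph, tp, 128, 96)
  r1 <- region_enrichment(f1, region_partition(sph, f1$grid), "bulk", "pole")
  r2 <- region_enrichment(f2, region_partition(sph, f2$grid), "bulk", "pole")
  expect_equal(r1, r2, tolerance = 0.01)
})

test_that("steady state inherits the symmetries of the geometry", {
  ## axial translation invariance on the cylinder
  cyl <- make_surface("cylinder")
  fc <- solve_steady_state(cyl, translocation_params(), 24, 16)
  expect_lt(diff(range(fc$CF)) / mean(fc$CF), 1e-8)
  ## mirror symmetry of the bulge about its center plane
  bul <- make_surface("bulged_cylinder")
  fb <- solve_steady_state(bul, translocation_params(), 48, 24)
  prof <- rowSums(fb$NF)
  expect_equal(prof, rev(prof), tolerance = 1e-6)
  ## reflection symmetry of the torus about the equatorial plane
  tor <- make_surface("torus")
  ft <- solve_steady_state(tor, translocation_params(lambda = 0), 16, 48)
  pv <- colSums(ft$NF)
  expect_lt(max(abs(pv[-1] - rev(pv[-1]))), 0.01 * mean(pv))
})
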