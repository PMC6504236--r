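# The discrete translocation flow: noise model, step-length equation,
# stepping invariants, activation sampling, lifetimes, reproducibility.

test_that("noise model returns alpha/dc with cap, or the constant", {
  tp <- translocation_params(noise_model = "curvature_dependent", alpha = 0.6)
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  expect_equal(noise_sigma(tp, curvature_at(cyl, 1, 1)), 0.3)
  expect_equal(noise_sigma(tp, 1e-9), tp$sigma_max)     # umbilic cap
  tpc <- translocation_params(noise_model = "constant", sigma0 = 0)
  expect_equal(noise_sigma(tpc, c(0.5, 2)), c(0, 0))
})

test_that("step-length equation matches closed forms", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  expect_equal(step_length_in_parameters(cyl, 1, 0, pi / 2, 0.2), 0.4,
               tolerance = 1e-10)   # circumferential: L / R
  expect_equal(step_length_in_parameters(cyl, 1, 0, 0, 0.2), 0.2,
               tolerance = 1e-12)   # axial: unit-speed coordinate
  pl <- make_surface("plane")
  expect_equal(step_length_in_parameters(pl, 1, 1, 0.83, 0.15), 0.15,
               tolerance = 1e-12)
  tor <- make_surface("torus")
  ## tube direction: L / r, independent of position; oracle via direct
  ## quadrature of the arclength integrand
  ell <- step_length_in_parameters(tor, 1.7, 0.9, pi / 2, 0.2)
  expect_equal(ell, 0.2 / 0.5, tolerance = 1e-8)
  arc <- integrate(function(t) {
    e <- mrebdyn:::sg_eval(tor, rep(1.7, length(t)), 0.9 + t, wrap = FALSE)
    sqrt(rowSums(e$rv^2))
  }, 0, ell)$value
  expect_equal(arc, 0.2, tolerance = 1e-8)
})

test_that("zero noise on a cylinder conserves the axial coordinate exactly", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  tp <- translocation_params(noise_model = "constant", sigma0 = 0, lambda = 0)
  tr <- simulate_filament(cyl, tp, start = c(1.5, 0), max_steps = 300,
                          seed = 5)
  expect_equal(max(abs(tr$u - 1.5)), 0)
  ## and the hoop advances by equal circumferential increments of L
  dv <- abs(diff(mrebdyn:::unwrap_periodic(tr$v, 2 * pi)))
  expect_equal(range(dv * 0.5), c(0.2, 0.2), tolerance = 1e-9)
})

test_that("consecutive trajectory points are a chord of one step length", {
  tor <- make_surface("torus")   # compact, no wrap-induced 3D jumps
  tp <- translocation_params(lambda = 0)
  tr <- simulate_filament(tor, tp, max_steps = 400, seed = 21)
  xyz <- cbind(tr$x, tr$y, tr$z)
  ch <- sqrt(rowSums((xyz[-1, ] - xyz[-nrow(xyz), ])^2))
  L <- tp$L
  kmax <- 2   # largest principal curvature on this torus (um^-1)
  expect_lt(max(ch), L * (1 + 1e-6))
  expect_gt(min(ch), L * (1 - (L * kmax)^2 / 4))
})

test_that("per-step axial spread on a cylinder matches E[sin eta] moments", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  tp <- translocation_params(noise_model = "constant", sigma0 = 0.3,
                             lambda = 0)
  tr <- simulate_filament(cyl, tp, start = c(1.5, 0), max_steps = 4000,
                          seed = 7)
  du <- diff(mrebdyn:::unwrap_periodic(tr$u, 3))
  pred <- 0.2 * sqrt((1 - exp(-2 * 0.3^2)) / 2)   # L sqrt(E[sin^2 eta])
  expect_equal(sd(du), pred, tolerance = 0.05)
  expect_lt(abs(mean(du)), 3 * sd(du) / sqrt(length(du)))
})

test_that("activation sampling follows the area-element density", {
  set.seed(31)
  tp <- translocation_params()
  ## torus: analytic tube-angle marginal density prop. to Rt + r cos v
  tor <- make_surface("torus")
  a <- mrebdyn:::sample_activation(tor, tp, 2e4)
  nb <- 24
  h <- hist(a$v, breaks = seq(0, 2 * pi, length.out = nb + 1), plot = FALSE)
  expd <- 5 + 0.5 * cos(h$mids)
  expd <- expd / sum(expd) * length(a$v)
  chi2 <- sum((h$counts - expd)^2 / expd)
  expect_lt(chi2, qchisq(0.999, nb - 1))
  ## undulating cylinder: axial marginal prop. to rho sqrt(1 + rho'^2)
  und <- make_surface("undulating_cylinder")
  au <- mrebdyn:::sample_activation(und, tp, 2e4)
  hu <- hist(au$u, breaks = seq(0, 4, length.out = nb + 1), plot = FALSE)
  expu <- vapply(hu$mids, function(u) area_element(und, u, 0), numeric(1))
  expu <- expu / sum(expu) * length(au$u)
  expect_lt(sum((hu$counts - expu)^2 / expu), qchisq(0.999, nb - 1))
})

test_that("Gaussian-curvature-weighted activation biases births accordingly", {
  set.seed(5)
  tp <- translocation_params(activation_model = "gaussian_curvature_weighted",
                             activation_weight = function(K) as.numeric(K < 0))
  tor <- make_surface("torus")
  a <- mrebdyn:::sample_activation(tor, tp, 2000)
  ## negative K on the torus means tube angle in (pi/2, 3pi/2)
  expect_true(all(a$v > pi / 2 & a$v < 3 * pi / 2))
})

test_that("lifetimes follow the deactivation rate and caps", {
  set.seed(9)
  expect_true(all(mrebdyn:::draw_lifetimes(100, 1, 1000L) == 1L))
  expect_true(all(mrebdyn:::draw_lifetimes(100, 0, 50L) == 50L))
  lt <- mrebdyn:::draw_lifetimes(20000, 1 / 30, 100000L)
  expect_equal(mean(lt), 30, tolerance = 0.03)
  ## trajectory length equals the cap when lambda = 0
  s <- make_surface("cylinder")
  tr <- simulate_filament(s, translocation_params(lambda = 0),
                          max_steps = 17, seed = 3)
  expect_equal(nrow(tr), 18L)
})

test_that("identical seeds reproduce trajectories and ensembles exactly", {
  s <- make_surface("helix_tube")
  tp <- translocation_params(lambda = 1 / 20)
  t1 <- simulate_filament(s, tp, max_steps = 200, seed = 77)
  t2 <- simulate_filament(s, tp, max_steps = 200, seed = 77)
  expect_identical(t1, t2)
  e1 <- simulate_ensemble(s, tp, n_filaments = 50, seed = 77)
  e2 <- simulate_ensemble(s, tp, n_filaments = 50, seed = 77)
  expect_identical(e1$field$NF, e2$field$NF)
})

test_that("single-step interface advances a filament state", {
  s <- make_surface("torus")
  set.seed(1)
  st <- list(u = 1, v = 1, heading = drop(angle_to_direction(s, 1, 1, 0.4)),
             active = TRUE, n = 0L)
  st2 <- translocation_step(st, s, translocation_params())
  expect_equal(st2$n, 1L)
  expect_false(isTRUE(all.equal(c(st2$u, st2$v), c(1, 1))))
  ## step honours the on-surface step size through the arclength equation
  p1 <- mrebdyn:::sg_eval(s, st$u, st$v)$r
  p2 <- mrebdyn:::sg_eval(s, st2$u, st2$v)$r
  expect_equal(sqrt(sum((p2 - p1)^2)), 0.2, tolerance = 0.01)
})
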