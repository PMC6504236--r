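# Localization summaries: region enrichment, bulge occupancy, curvature
# curves, per-hoop axial displacements.

make_uniform_field <- function(surface, n_u = 24, n_v = 16) {
  g <- surface_grid(surface, n_u, n_v)
  concentration_field(surface, g, g$dA, translocation_params(),
                      source = "langevin")
}

test_that("uniform concentration gives unit ratios and flat curves", {
  tor <- make_surface("torus")
  f <- make_uniform_field(tor, 16, 48)
  part <- region_partition(tor, f$grid)
  expect_equal(region_enrichment(f, part, "inner", "midline"), 1,
               tolerance = 1e-12)
  expect_equal(region_enrichment(f, part, "outer", "inner"), 1,
               tolerance = 1e-12)
  cv <- curvature_enrichment_curve(f, tor, "K", bins = 10)
  expect_equal(range(cv$mean_CF_au, na.rm = TRUE), c(1, 1),
               tolerance = 1e-12)
  ## ratios invariant under uniform rescaling of C_F
  f2 <- f; f2$CF <- f$CF * 7.3; f2$NF <- f$NF * 7.3
  expect_equal(region_enrichment(f2, part, "inner", "midline"), 1,
               tolerance = 1e-12)
})

test_that("hoop-uniform torus density yields the analytic band ratio", {
  tor <- make_surface("torus", tube_radius = 0.5, centerline_radius = 5)
  g <- surface_grid(tor, 16, 96)
  ## C_F prop. 1/(Rt + r cos v): uniform filament number per hoop
  cf <- matrix(1 / (5 + 0.5 * cos(g$V)), 16, 96)
  f <- concentration_field(tor, g, cf * g$dA, translocation_params())
  part <- region_partition(tor, g)
  expect_equal(region_enrichment(f, part, "inner", "midline"), 10 / 9,
               tolerance = 2e-3)
})

test_that("bulge occupancy reduces to the area fraction without a bulge", {
  ## degenerate (vanishing-amplitude) bulge: plain cylinder dynamics
  bul <- make_surface("bulged_cylinder", bulge_amplitude = 1e-9)
  en <- simulate_ensemble(bul, translocation_params(), n_filaments = 2000,
                          n_u = 30, n_v = 16, seed = 13)
  part <- region_partition(bul, en$field$grid)
  oc <- bulge_occupancy(en$field, part)
  expect_equal(oc$percent, oc$area_percent, tolerance = 0.05)
  ## uniform field: exactly the area fraction
  fu <- make_uniform_field(make_surface("bulged_cylinder"), 30, 16)
  pu <- region_partition(make_surface("bulged_cylinder"), fu$grid)
  ou <- bulge_occupancy(fu, pu)
  expect_equal(ou$percent, ou$area_percent, tolerance = 1e-10)
})

test_that("a pronounced bulge attracts filaments beyond its area share", {
  bul <- make_surface("bulged_cylinder")   # amplitude 0.3, width 0.5
  part <- NULL
  for (lam in c(0, 1 / 30)) {
    fp <- solve_steady_state(bul, translocation_params(lambda = lam), 48, 24)
    if (is.null(part)) part <- region_partition(bul, fp$grid)
    oc <- bulge_occupancy(fp, part)
    expect_gt(oc$percent, oc$area_percent)
  }
})

test_that("curvature-enrichment curves anchor at 1 a.u. and capture the
           negative-Gaussian-curvature enrichment of undulating cells", {
  und <- make_surface("undulating_cylinder")
  fp <- solve_steady_state(und, translocation_params(), 48, 32)
  cv <- curvature_enrichment_curve(fp, und, "K", bins = 15)
  anchor_bin <- which.min(abs(cv$bin_center))
  expect_equal(cv$mean_CF_au[anchor_bin], 1, tolerance = 1e-9)
  ## concentration increases toward negative K (area-weighted trend)
  ok <- !is.na(cv$mean_CF_au)
  expect_lt(cor(cv$bin_center[ok], cv$mean_CF_au[ok]), -0.5)
  neg <- cv$bin_center < 0; pos <- cv$bin_center > 0
  expect_gt(weighted.mean(cv$mean_CF_au[neg], cv$area[neg], na.rm = TRUE),
            weighted.mean(cv$mean_CF_au[pos], cv$area[pos], na.rm = TRUE))
  ## mean-curvature curve: enrichment at small H
  ch <- curvature_enrichment_curve(fp, und, "H", bins = 15)
  ok <- !is.na(ch$mean_CF_au)
  expect_lt(cor(ch$bin_center[ok], ch$mean_CF_au[ok]), -0.5)
  expect_error(curvature_enrichment_curve(fp, und, "K", anchor = 100),
               "anchor")
})

test_that("axial displacement per hoop: zero-noise and closed-form limits", {
  cyl <- make_surface("cylinder", radius = 0.5, length = 3)
  tp0 <- translocation_params(noise_model = "constant", sigma0 = 0,
                              lambda = 0)
  en0 <- simulate_ensemble(cyl, tp0, n_filaments = 3, max_steps = 120,
                           record_trajectories = TRUE, seed = 2)
  h0 <- axial_displacement_per_hoop(en0$trajectories, cyl)
  expect_equal(max(abs(h0$displacements)), 0)
  expect_equal(h0$n_hoops, 3 * floor(120 * 0.2 / (2 * pi * 0.5)))
})

test_that("per-hoop axial spread agrees with the renewal closed form
           across step sizes and noise levels", {
  ## independent oracle: var per hoop = (2 pi R / (L E[cos eta])) L^2
  ## E[sin^2 eta], reducing to 2 pi R L sigma^2 in the small-angle limit
  set.seed(55)
  for (cse in list(c(R = 0.5, L = 0.2, s = 0.15),
                   c(R = 0.5, L = 0.1, s = 0.3),
                   c(R = 0.8, L = 0.2, s = 0.2))) {
    cyl <- make_surface("cylinder", radius = cse[["R"]], length = 4)
    tp <- translocation_params(L = cse[["L"]], noise_model = "constant",
                               sigma0 = cse[["s"]], lambda = 0)
    en <- simulate_ensemble(cyl, tp, n_filaments = 12,
                            max_steps = 2500, record_trajectories = TRUE,
                            seed = 100 + round(100 * cse[["s"]]))
    h <- axial_displacement_per_hoop(en$trajectories, cyl)
    s2 <- cse[["s"]]^2
    exact <- sqrt(2 * pi * cse[["R"]] / (cse[["L"]] * exp(-s2 / 2)) *
                    cse[["L"]]^2 * (1 - exp(-2 * s2)) / 2)
    se <- h$sd / sqrt(2 * h$n_hoops)
    expect_lt(abs(h$sd - exact), 3 * se)
    ## small-angle form agrees within its own O(sigma^2/4) truncation
    small <- sqrt(2 * pi * cse[["R"]] * cse[["L"]] * s2)
    expect_lt(abs(h$sd - small), small * s2 / 2 + 3 * se)
    expect_lt(abs(h$mean), 3 * h$sd / sqrt(h$n_hoops))
  }
})
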