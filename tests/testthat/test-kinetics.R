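test_that("substrate dilution arithmetic matches the assay design", {
  expect_equal(final_substrate_concentration(20, 20, 1000), 400)
  expect_equal(final_substrate_concentration(20, 0, 1000), 0)
  expect_equal(final_substrate_concentration(20, 36, 1000), 720)
  expect_error(final_substrate_concentration(20, 1100, 1000), "exceed")
})

test_that("v0 is the OLS slope of concentration on time", {
  t4 <- c(0, 6, 12, 24)
  flat <- compute_v0(t4, rep(3, 4))
  expect_equal(flat$v0_uM_h, 0)
  expect_equal(flat$r_squared, 0)

  lin <- compute_v0(t4, 2.5 * t4)
  expect_equal(lin$v0_uM_h, 2.5)
  expect_equal(lin$r_squared, 1)

  set.seed(4)
  y <- 1 + 0.8 * t4 + rnorm(4, 0, 0.3)
  est <- compute_v0(t4, y)
  o <- ols_oracle(t4, y)
  expect_equal(est$v0_uM_h, o$slope, tolerance = 1e-12)
  expect_equal(est$se, o$slope_se, tolerance = 1e-12)

  expect_error(compute_v0(c(0, 6), c(1, 2)), "3 timepoints")
  expect_error(compute_v0(c(0, 6, 6, 24), 1:4), "duplicate")
  expect_error(compute_v0(c(24, 12, 6, 0), 1:4), "increasing")
})

test_that("v0 is equivariant under scaling and shifts of concentration", {
  set.seed(9)
  t5 <- c(0, 4, 9, 15, 24)
  for (i in 1:5) {
    y <- rnorm(5)
    c_scale <- runif(1, 0.1, 10)
    c_shift <- runif(1, -5, 5)
    base <- compute_v0(t5, y)$v0_uM_h
    expect_equal(compute_v0(t5, c_scale * y)$v0_uM_h, c_scale * base,
                 tolerance = 1e-10)
    expect_equal(compute_v0(t5, y + c_shift)$v0_uM_h, base,
                 tolerance = 1e-10)
  }
})

test_that("the initial-window mode tracks the early linear phase under depletion", {
  tr <- tiny_truth(vmax = 600, km = 50, sigma_f = 0, n_timepoints = 5)
  ds <- generate_assay_dataset(tr, "vmax", depletion = TRUE)
  live <- ds$series[ds$series$treatment == "live" &
                      ds$series$replicate == 1, ]
  conc <- (live$fluorescence - 50) / 1000
  v_all <- compute_v0(live$time_h, conc, method = "all")
  v_win <- compute_v0(live$time_h, conc, method = "initial-window")
  true_v0_uM <- rate_per_gram_to_uM(600 * 400 / (50 + 400), tr$geometry)
  expect_lte(v_win$n, v_all$n)
  expect_gt(v_win$v0_uM_h, v_all$v0_uM_h)
  expect_lt(abs(v_win$v0_uM_h - true_v0_uM),
            abs(v_all$v0_uM_h - true_v0_uM))
})

test_that("unit conversion is the reaction-nmol over reaction-grams quotient", {
  expect_equal(convert_rate_units(0.3, assay_geometry()), 10)
  expect_equal(convert_rate_units(0, assay_geometry()), 0)
  g <- assay_geometry(sediment_g = 6, slurry_ml = 100, reaction_ml = 2)
  set.seed(2)
  v <- runif(5)
  expect_equal(convert_rate_units(v, g), v * 2 / 0.12, tolerance = 1e-12)
  # linear and invertible
  expect_equal(rate_per_gram_to_uM(convert_rate_units(v, g), g), v,
               tolerance = 1e-12)
  expect_error(assay_geometry(sediment_g = 0), "positive")
})

test_that("detection limits come from blanks, the noise model, or an override", {
  expect_equal(detection_limit(blank_rates = rep(0.2, 4)), 0)
  expect_error(detection_limit(blank_rates = c(0, 0.1)), "3 blank")

  cv <- structure(list(slope = 1000, intercept = 0),
                  class = "standard_curve")
  dl <- detection_limit(sigma_f = 20, curve = cv, horizon_h = 24, k = 3)
  expect_equal(dl, 3 * 20 / (1000 * 24) * 100 / 3, tolerance = 1e-12)
  expect_equal(round(dl, 4), 0.0833)

  expect_equal(detection_limit(override = 4.77e-2), 4.77e-2)
  expect_error(detection_limit(sigma_f = 20), "needs")
})

test_that("live-vs-killed comparison is a one-sided Welch test", {
  same <- compare_live_killed(c(5, 5.1, 4.9), c(5, 5.1, 4.9))
  expect_false(same$significant)

  res <- compare_live_killed(c(10, 11, 12), c(1.0, 1.2, 0.8), alpha = 0.05)
  o <- welch_oracle(c(10, 11, 12), c(1.0, 1.2, 0.8))
  expect_equal(res$t, o$t, tolerance = 1e-12)
  expect_equal(res$p, o$p, tolerance = 1e-12)
  expect_true(res$significant)

  zero <- compare_live_killed(c(0, 0, 0), c(0, 0, 0))
  expect_equal(zero$difference, 0)
  expect_equal(zero$p, 1)
  expect_false(zero$significant)
})

test_that("Michaelis-Menten fits recover exact curves and match a grid-search oracle", {
  s <- seq(0, 800, length.out = 11)
  v <- 10 * s / (200 + s)
  fit <- fit_michaelis_menten(s, v)
  expect_true(fit$converged)
  expect_equal(fit$vmax, 10, tolerance = 1e-6)
  expect_equal(fit$km, 200, tolerance = 1e-6)

  # 3-SE coverage is a statistical statement; check it across seeds
  set.seed(14)
  covered <- replicate(20, {
    vn <- v + rnorm(length(s), 0, 0.5)
    fitn <- fit_michaelis_menten(s, vn)
    fitn$converged && abs(fitn$vmax - 10) < 3 * fitn$vmax_se &&
      abs(fitn$km - 200) < 3 * fitn$km_se
  })
  expect_gte(mean(covered), 0.9)

  set.seed(15)
  vn <- v + rnorm(length(s), 0, 0.5)
  fitn <- fit_michaelis_menten(s, vn)
  o <- mm_grid_oracle(s, vn, c(5, 20), c(50, 600))
  expect_equal(fitn$vmax, o$vmax, tolerance = 1e-3)
  expect_equal(fitn$km, o$km, tolerance = 1e-3)

  nofit <- fit_michaelis_menten(s, rep(0, 11))
  expect_false(nofit$converged)
  expect_match(nofit$reason, "no positive signal")
  expect_error(fit_michaelis_menten(c(0, 100, 200, 400), 1:4), "5 distinct")
})

test_that("fitted curves satisfy v(K_m) = V_max/2 and saturate below V_max", {
  set.seed(30)
  for (i in 1:5) {
    vmax_t <- runif(1, 5, 50)
    km_t <- runif(1, 50, 400)
    s <- seq(0, 800, length.out = 11)
    vn <- vmax_t * s / (km_t + s) + rnorm(11, 0, 0.02 * vmax_t)
    fit <- fit_michaelis_menten(s, vn)
    v_at <- function(si) fit$vmax * si / (fit$km + si)
    expect_equal(v_at(fit$km), fit$vmax / 2, tolerance = 1e-12)
    expect_true(all(v_at(seq(1, 1e5, length.out = 50)) < fit$vmax))
  }
})

test_that("single-concentration assays underestimate V_max by S/(K_m+S)", {
  tr <- tiny_truth(vmax = 10, km = 200, sigma_f = 0)
  ds <- generate_assay_dataset(tr, "vmax")
  curves <- fit_standard_curves(generate_standard_curve_data(tr))
  rates <- estimate_rates(ds$series, curves, tr$geometry)
  live <- rates$v0_nmol_g_h[rates$treatment == "live"]
  expect_equal(live, rep(10 * 400 / (200 + 400), length(live)),
               tolerance = 1e-9)
})

test_that("the K_m-depth regression recovers exact trends and sizes its test correctly", {
  d <- c(4.5, 11.1, 17.6, 24.3, 30.9, 48.22)
  tr <- km_depth_trend(d, 100 + 5 * d)
  expect_equal(tr$slope, 5, tolerance = 1e-10)
  expect_equal(tr$n, 6)
  expect_error(km_depth_trend(c(1, 2), c(1, 2)), "3 depths")

  set.seed(77)
  rej <- mean(replicate(1000, {
    km_depth_trend(d, 200 + rnorm(6, 0, 30))$p < 0.05
  }))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("Q10 scaling is exponential in the temperature offset", {
  expect_equal(temperature_adjust(7, 2, 0), 7)
  expect_equal(temperature_adjust(1, 2, 10), 2)
  expect_equal(temperature_adjust(1, 2, 12), 2^1.2)
  expect_equal(temperature_adjust(2^1.2, 2, -12), 1, tolerance = 1e-12)
  expect_error(temperature_adjust(1, -2, 10), "positive")
})
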