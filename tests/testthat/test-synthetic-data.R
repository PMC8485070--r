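test_that("generator is byte-identical under a fixed seed", {
  tr <- small_truth(seed = 11L)
  a1 <- generate_assay_dataset(tr, "vmax")
  a2 <- generate_assay_dataset(tr, "vmax")
  expect_identical(a1$series, a2$series)
  expect_identical(generate_standard_curve_data(tr),
                   generate_standard_curve_data(tr))
  expect_identical(generate_cell_counts(tr, c(5, 20, 60)),
                   generate_cell_counts(tr, c(5, 20, 60)))
  a3 <- generate_assay_dataset(small_truth(seed = 12L), "vmax")
  expect_false(identical(a1$series$fluorescence, a3$series$fluorescence))
})

test_that("noiseless autoclaved/live slope ratio equals rho everywhere", {
  tr <- small_truth(rho = 0.37, sigma_f = 0)
  ds <- generate_assay_dataset(tr, "vmax")
  slopes <- ds$series |>
    dplyr::group_by(enzyme, depth_mbsf, treatment) |>
    dplyr::summarise(
      slope = stats::coef(stats::lm(fluorescence ~ time_h))[2],
      .groups = "drop") |>
    tidyr::pivot_wider(names_from = "treatment", values_from = "slope")
  expect_equal(slopes$autoclaved, 0.37 * slopes$live, tolerance = 1e-12)
})

test_that("zero activity and zero noise give flat series at the intercept", {
  tr <- tiny_truth(vmax = 0, sigma_f = 0)
  ds <- generate_assay_dataset(tr, "vmax")
  expect_true(all(ds$series$fluorescence == 50))
})

test_that("saturation design spans the configured concentration levels", {
  tr <- tiny_truth()
  ds <- generate_assay_dataset(tr, "saturation")
  expect_equal(sort(unique(ds$series$substrate_conc_uM)),
               seq(0, 800, length.out = 11))
  ds2 <- generate_assay_dataset(tr, "vmax")
  expect_equal(unique(ds2$series$substrate_conc_uM), 400)
  expect_error(generate_assay_dataset(tr, "nonsense"), "arg")
})

test_that("standard-curve generator draws exact lines when noiseless and recoverable slopes when noisy", {
  tr0 <- tiny_truth(sigma_f = 0)
  std <- generate_standard_curve_data(tr0, levels = c(0, 1, 2, 4),
                                      n_replicates = 1)
  expect_equal(std$fluorescence, 50 + 1000 * std$concentration_uM)
  expect_equal(range(std$fluorescence), c(50, 4050))

  expect_error(generate_standard_curve_data(tr0, levels = c(0, 0, 0)),
               "distinct")
  expect_error(generate_standard_curve_data(tr0, levels = c(1, 2)),
               "at least 3")

  trn <- tiny_truth(sigma_f = 20, seed = 5L)
  stdn <- generate_standard_curve_data(trn, levels = c(0, 1, 2, 4, 8),
                                       n_replicates = 3)
  o <- ols_oracle(stdn$concentration_uM, stdn$fluorescence)
  expect_lt(abs(o$slope - 1000), 2 * o$slope_se)
})

test_that("cell-count generator follows its segmented log-linear model", {
  flat <- tiny_truth()
  flat$cells <- list(upper = list(ref_depth = 4.35, log10_ref = 8,
                                  slope = 0),
                     lower = list(ref_depth = 54.95, log10_ref = 8,
                                  slope = 0),
                     sigma_log10 = 0)
  cc <- generate_cell_counts(flat, c(5, 20, 45, 60, 75))
  expect_equal(cc$cells_per_g, rep(1e8, 5))

  lin <- tiny_truth()
  lin$cells$sigma_log10 <- 0
  cc2 <- generate_cell_counts(lin, c(4.35, 10, 30, 50))
  expected <- 10^(log10(4.6e8) - 0.0105 * (cc2$depth_mbsf - 4.35))
  expect_equal(cc2$cells_per_g, expected, tolerance = 1e-12)

  expect_error(generate_cell_counts(lin, numeric(0)), "empty")
  expect_error(generate_cell_counts(lin, c(10, 5)), "sorted")
  expect_error(generate_cell_counts(lin, c(-1, 5)), "positive")
})

test_that("specific-activity draws follow their distribution specs", {
  expect_equal(generate_specific_activities(5, dist_spec("point", value = 1e3)),
               rep(1e3, 5))
  expect_equal(
    generate_specific_activities(4, dist_spec("log-normal", meanlog = 2,
                                              sdlog = 0), seed = 1),
    rep(exp(2), 4))
  draws <- generate_specific_activities(
    2e4, dist_spec("log-uniform", lo = 1e2, hi = 1e4), seed = 3)
  expect_equal(median(draws), 1e3, tolerance = 0.05)
  expect_error(dist_spec("log-uniform", lo = -1, hi = 10), "positive")
  expect_error(generate_specific_activities(0, dist_spec("point", value = 1)),
               "at least 1")
})

test_that("truth specs reject inconsistent parameters", {
  bad <- baltic_enzyme_truth()
  bad$vmax_nmol_g_h[1] <- -1
  expect_error(truth_spec(enzymes = bad), "V_max")
  bad2 <- baltic_enzyme_truth()
  bad2$km_uM[3] <- 0
  expect_error(truth_spec(enzymes = bad2), "K_m")
  deep <- baltic_enzyme_truth()
  deep$vmax_nmol_g_h[deep$enzyme == "clostripain" &
                       deep$depth_mbsf > 51.7] <- 5
  expect_error(truth_spec(enzymes = deep), "unconformity")
  expect_error(truth_spec(sigma_f = -1), "sigma_f")
  expect_error(truth_spec(n_timepoints = 2), "timepoints")
  expect_error(truth_spec(horizon_h = 0), "horizon")
})

test_that("the fluorescence pipeline recovers generator truth", {
  # saturation design through calibration + rate estimation + MM fitting;
  # truth must sit within 3 SE of the estimates in nearly all runs
  n_sims <- 30
  hits <- logical(n_sims)
  rel_err <- numeric(n_sims)
  for (i in seq_len(n_sims)) {
    tr <- tiny_truth(vmax = 10, km = 200, rho = 0.5, sigma_f = 5,
                     seed = 1000L + i)
    ds <- generate_assay_dataset(tr, "saturation")
    std <- generate_standard_curve_data(tr, seed = 2000L + i)
    curves <- fit_standard_curves(std)
    rates <- estimate_rates(ds$series, curves, tr$geometry)
    fit <- fit_mm_from_rates(rates, mode = "live-only")
    hits[i] <- fit$converged &&
      abs(fit$vmax - 10) <= 3 * fit$vmax_se &&
      abs(fit$km - 200) <= 3 * fit$km_se
    rel_err[i] <- abs(fit$vmax - 10) / 10
  }
  expect_gte(mean(hits), 0.9)
  expect_lt(mean(rel_err), 0.05)
})

test_that("depletion mode slows apparent product accumulation", {
  tr <- tiny_truth(vmax = 40, km = 100, sigma_f = 0)
  lin <- generate_assay_dataset(tr, "vmax", depletion = FALSE)
  dep <- generate_assay_dataset(tr, "vmax", depletion = TRUE)
  last_lin <- lin$series$fluorescence[lin$series$time_h == 24 &
                                        lin$series$treatment == "live"]
  last_dep <- dep$series$fluorescence[dep$series$time_h == 24 &
                                        dep$series$treatment == "live"]
  expect_true(all(last_dep < last_lin))
  first_dep <- dep$series$fluorescence[dep$series$time_h == 0]
  expect_true(all(first_dep == 50))
})
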