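test_that("retained fraction is the killed/live percent with exclusion rules", {
  expect_equal(fraction_retained(5, 5)$fraction_pct, 100)
  expect_equal(fraction_retained(5, 0, dl = 0.1, exclusion_k = 3)$fraction_pct, 0)
  expect_false(fraction_retained(5, 0, dl = 0.1, exclusion_k = 3)$excluded)

  dead <- fraction_retained(0, 1)
  expect_true(dead$excluded)
  expect_true(is.na(dead$fraction_pct))
  expect_match(dead$reason, "non-positive")

  near <- fraction_retained(0.2, 0.1, dl = 0.1, exclusion_k = 3)
  expect_true(near$excluded)
  expect_match(near$reason, "detection limit")
  # k = 0 disables the proximity exclusion
  expect_false(fraction_retained(0.2, 0.1, dl = 0.1,
                                 exclusion_k = 0)$excluded)
})

test_that("retention summaries use the linear-interpolation quantile convention", {
  one <- tibble::tibble(enzyme = "e", enzyme_class = "peptidase",
                        depth_mbsf = 1, fraction_pct = 40,
                        excluded = FALSE, reason = NA_character_)
  s1 <- summarize_retention(one)
  expect_equal(s1$median_pct, 40)
  expect_equal(c(s1$q25_pct, s1$q75_pct), c(40, 40))

  four <- tibble::tibble(enzyme = "e", enzyme_class = "peptidase",
                         depth_mbsf = 1:4,
                         fraction_pct = c(10, 20, 30, 40),
                         excluded = FALSE, reason = NA_character_)
  s4 <- summarize_retention(four)
  # type-7 hand computation: h = (n-1)p + 1
  expect_equal(s4$median_pct, 25)
  expect_equal(s4$q25_pct, 17.5)
  expect_equal(s4$q75_pct, 32.5)
  expect_equal(s4$quantile_type, 7L)

  mixed <- dplyr::bind_rows(four,
    tibble::tibble(enzyme = "g", enzyme_class = "glycosylase",
                   depth_mbsf = 1, fraction_pct = NA_real_,
                   excluded = TRUE, reason = "non-positive live rate"))
  expect_warning(s <- summarize_retention(mixed, by = "class"), "omitted")
  expect_equal(s$group, "peptidase")
})

test_that("Kruskal-Wallis matches the rank-sum oracle and handles degeneracy", {
  kw <- kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
  expect_equal(kw$H, 7.2, tolerance = 1e-12)
  expect_equal(kw$df, 2)
  expect_equal(kw$p, 1 - pchisq(7.2, 2), tolerance = 1e-12)

  flat <- kruskal_wallis(list(a = c(2, 2), b = c(2, 2), c = c(2, 2)))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)

  set.seed(13)
  for (i in 1:10) {
    g <- list(a = sample(1:5, 6, TRUE), b = rnorm(4), c = sample(1:3, 5, TRUE))
    expect_equal(kruskal_wallis(g)$H, kw_oracle(g), tolerance = 1e-10)
  }
})

test_that("H is invariant under strictly monotone transformations", {
  set.seed(19)
  for (i in 1:5) {
    g <- list(a = runif(6), b = runif(5), c = runif(7))
    h0 <- kruskal_wallis(g)$H
    expect_equal(kruskal_wallis(lapply(g, exp))$H, h0, tolerance = 1e-12)
    expect_equal(kruskal_wallis(lapply(g, function(x) 5 * x - 2))$H, h0,
                 tolerance = 1e-12)
  }
})

test_that("Conover-Iman pairwise statistics match the published-formula oracle", {
  g <- list(a = 1:3, b = 4:6, c = 7:9)
  ci <- conover_iman(g, adjust = "none")
  o <- conover_oracle(g)
  expect_equal(nrow(ci), 3)
  expect_equal(ci$t, o$t, tolerance = 1e-12)
  expect_equal(ci$p, o$p, tolerance = 1e-12)

  set.seed(23)
  for (i in 1:5) {
    g <- list(a = rnorm(6), b = rnorm(8), c = rnorm(5), d = rnorm(7))
    ci <- conover_iman(g, adjust = "none")
    o <- conover_oracle(g)
    expect_equal(nrow(ci), 6)  # k(k-1)/2
    expect_equal(ci$t, o$t, tolerance = 1e-10)
    expect_equal(ci$p, o$p, tolerance = 1e-10)
  }
})

test_that("Conover-Iman is symmetric in group order and degenerate on ties", {
  set.seed(31)
  g <- list(a = rnorm(5), b = rnorm(6), c = rnorm(4))
  fwd <- conover_iman(g)
  rev <- conover_iman(rev(g))
  pair_key <- function(d) {
    apply(cbind(pmin(d$group1, d$group2), pmax(d$group1, d$group2)), 1,
          paste, collapse = "-")
  }
  expect_equal(sort(pair_key(fwd)), sort(pair_key(rev)))
  expect_equal(fwd$p[order(pair_key(fwd))], rev$p[order(pair_key(rev))],
               tolerance = 1e-12)

  tied <- conover_iman(list(a = c(1, 1, 1), b = c(1, 1, 1)))
  expect_equal(tied$t, 0)
  expect_equal(tied$p, 1)
  expect_false(tied$significant)

  expect_error(conover_iman(list(a = 1:3)), "at least 2 groups")
})

test_that("Holm adjustment is applied by default and flags at alpha", {
  g <- list(a = 1:3, b = 4:6, c = 7:9)
  ci <- conover_iman(g)
  raw <- conover_iman(g, adjust = "none")
  expect_equal(ci$p_adjusted, p.adjust(raw$p, method = "holm"),
               tolerance = 1e-12)
  expect_equal(ci$significant, ci$p_adjusted < 0.05)
})

test_that("class medians track the configured retention fraction", {
  tr <- small_truth(rho = 0.5, sigma_f = 2, seed = 41L)
  ds <- generate_assay_dataset(tr, "vmax")
  curves <- fit_standard_curves(generate_standard_curve_data(tr))
  rates <- estimate_rates(ds$series, curves, tr$geometry)
  depths <- sort(unique(ds$series$depth_mbsf))
  cells <- data.frame(depth_mbsf = depths, cells_per_g = 1e8)
  prof <- assemble_depth_profile(rates, cells)
  rec <- retention_table(prof, dl = 0, exclusion_k = 0)
  med <- summarize_retention(rec, by = "class")
  expect_true(all(abs(med$median_pct - 50) < 3))
})
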