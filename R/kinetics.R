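#' Initial hydrolysis rate from a calibrated time series
#'
#' Estimates v0 as the OLS slope of product concentration on incubation
#' time, with time zero at substrate addition. By default all timepoints
#' enter the regression; `method = "initial-window"` instead picks, among
#' all prefixes of at least 3 points, the one maximising r^2, guarding
#' against late-time nonlinearity (substrate depletion, product decay).
#'
#' @param time_h Incubation times (h), strictly increasing, length >= 3.
#' @param conc_uM Calibrated product concentrations (uM), same length.
#' @param method `"all"` or `"initial-window"`.
#' @return A list of class `rate_estimate`: `v0_uM_h`, `se`, `r_squared`,
#'   `n` (timepoints used), `method`. For a perfectly constant series the
#'   slope is 0 and `r_squared` is reported as 0.
#' @examples
#' compute_v0(c(0, 6, 12, 24), 2.5 * c(0, 6, 12, 24))
#' @export
compute_v0 <- function(time_h, conc_uM, method = c("all", "initial-window")) {
  method <- match.arg(method)
  if (length(time_h) != length(conc_uM)) {
    stop("time and concentration vectors differ in length", call. = FALSE)
  }
  if (length(time_h) < 3) {
    stop("need at least 3 timepoints to estimate a rate", call. = FALSE)
  }
  if (anyDuplicated(time_h)) stop("duplicate timepoints", call. = FALSE)
  if (is.unsorted(time_h, strictly = TRUE)) {
    stop("times must be strictly increasing", call. = FALSE)
  }
  fit_window <- function(idx) {
    fit <- stats::lm(conc_uM[idx] ~ time_h[idx])
    # noiseless series trip summary.lm's perfect-fit warning; harmless here
    sm <- suppressWarnings(summary(fit))
    list(v0 = unname(stats::coef(fit)[2]),
         se = unname(sm$coefficients[2, "Std. Error"]),
         r2 = if (is.nan(sm$r.squared)) 0 else sm$r.squared,
         n = length(idx))
  }
  if (method == "all") {
    best <- fit_window(seq_along(time_h))
  } else {
    cands <- lapply(3:length(time_h), function(k) fit_window(seq_len(k)))
    best <- cands[[which.max(vapply(cands, `[[`, numeric(1), "r2"))]]
  }
  structure(list(v0_uM_h = best$v0, se = best$se, r_squared = best$r2,
                 n = best$n, method = method),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("<rate_estimate> v0 = %.4g +/- %.3g uM/h; r^2 = %.3f (n = %d)\n",
              x$v0_uM_h, x$se, x$r_squared, x$n))
  invisible(x)
}

#' Estimate per-cuvette rates for a whole assay table
#'
#' Calibrates a canonical assay table, regresses concentration on time
#' within each cuvette (enzyme x depth x treatment x replicate x
#' substrate concentration), and converts slopes to per-gram-sediment
#' units.
#'
#' @param series Canonical assay tibble (see [generate_assay_dataset()]).
#' @param curves Named list of standard curves keyed by fluorophore.
#' @param geom An [assay_geometry()].
#' @param method Passed to [compute_v0()].
#' @return Tibble with one row per cuvette: identifying columns plus
#'   `v0_nmol_g_h`, `se_nmol_g_h`, `r_squared`, `n_timepoints`.
#' @export
estimate_rates <- function(series, curves, geom = assay_geometry(),
                           method = c("all", "initial-window")) {
  method <- match.arg(method)
  cal <- calibrate_fluorescence(series, curves)
  out <- cal |>
    dplyr::group_by(.data$sample_id, .data$depth_mbsf, .data$enzyme,
                    .data$enzyme_class, .data$fluorophore, .data$treatment,
                    .data$replicate, .data$substrate_conc_uM) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    dplyr::summarise(
      est = list(compute_v0(.data$time_h, .data$conc_uM, method = method)),
      .groups = "drop")
  out |>
    dplyr::mutate(
      v0_nmol_g_h = convert_rate_units(
        vapply(.data$est, `[[`, numeric(1), "v0_uM_h"), geom),
      se_nmol_g_h = convert_rate_units(
        vapply(.data$est, `[[`, numeric(1), "se"), geom),
      r_squared = vapply(.data$est, `[[`, numeric(1), "r_squared"),
      n_timepoints = vapply(.data$est, `[[`, numeric(1), "n")) |>
    dplyr::select(-"est")
}

#' Average replicate rates per assay cell
#'
#' Collapses per-cuvette rates to one row per enzyme x depth x treatment
#' x substrate concentration with the replicate mean, SD and SE.
#'
#' @param rates Output of [estimate_rates()].
#' @return Tibble with `v0_nmol_g_h` (mean), `sd_nmol_g_h`,
#'   `se_nmol_g_h`, `n_replicates`.
#' @export
summarize_rates <- function(rates) {
  rates |>
    dplyr::group_by(.data$sample_id, .data$depth_mbsf, .data$enzyme,
                    .data$enzyme_class, .data$treatment,
                    .data$substrate_conc_uM) |>
    dplyr::summarise(
      sd_nmol_g_h = stats::sd(.data$v0_nmol_g_h),
      se_nmol_g_h = stats::sd(.data$v0_nmol_g_h) /
        sqrt(dplyr::n()),
      n_replicates = dplyr::n(),
      v0_nmol_g_h = mean(.data$v0_nmol_g_h),
      .groups = "drop") |>
    dplyr::relocate("v0_nmol_g_h", .before = "sd_nmol_g_h")
}

#' Detection limit for hydrolysis rates
#'
#' Three modes, in order of precedence:
#' \describe{
#'   \item{override}{return a user-supplied constant unchanged (e.g. a
#'     previously established limit such as 4.77e-2 nmol g^-1 h^-1 for
#'     live or 2.41e-2 for killed slurries).}
#'   \item{empirical}{`k` times the SD of replicate blank rates (>= 3
#'     blanks).}
#'   \item{model}{the smallest slope resolvable from fluorescence noise:
#'     `k * sigma_F / (m * horizon)` in uM h^-1, converted to per-gram
#'     units via the geometry.}
#' }
#'
#' @param blank_rates Optional numeric vector of blank rates
#'   (nmol g^-1 h^-1), length >= 3.
#' @param sigma_f Fluorescence noise SD (model mode).
#' @param curve A [standard_curve][fit_standard_curve()] (model mode).
#' @param horizon_h Assay duration in hours (model mode).
#' @param k Multiplier on the noise scale (default 3).
#' @param geom An [assay_geometry()] for unit conversion (model mode).
#' @param override If non-`NULL`, returned as-is.
#' @return Detection limit in nmol g^-1 h^-1.
#' @export
detection_limit <- function(blank_rates = NULL, sigma_f = NULL, curve = NULL,
                            horizon_h = NULL, k = 3,
                            geom = assay_geometry(), override = NULL) {
  if (!is.null(override)) return(override)
  if (!is.null(blank_rates)) {
    if (length(blank_rates) < 3) {
      stop("empirical detection limit needs at least 3 blank rates",
           call. = FALSE)
    }
    return(k * stats::sd(blank_rates))
  }
  if (is.null(sigma_f) || is.null(curve) || is.null(horizon_h)) {
    stop("model-based detection limit needs sigma_f, curve and horizon_h",
         call. = FALSE)
  }
  stopifnot(inherits(curve, "standard_curve"))
  if (horizon_h <= 0) stop("horizon must be positive", call. = FALSE)
  convert_rate_units(k * sigma_f / (curve$slope * horizon_h), geom)
}

#' Compare live and autoclaved replicate rates
#'
#' One-sided Welch t-test of whether mean live activity exceeds mean
#' killed-control activity, the operational definition of "detectable
#' enzyme activity" for a sample.
#'
#' @param live,killed Numeric vectors of replicate rates (>= 2 each).
#' @param alpha Significance level (default 0.05).
#' @return List: `difference` (mean live - mean killed), `t`, `p`,
#'   `significant`. Degenerate zero-variance inputs are handled without
#'   error: equal constant groups give p = 1.
#' @export
compare_live_killed <- function(live, killed, alpha = 0.05) {
  if (length(live) < 2 || length(killed) < 2) {
    stop("need at least 2 replicates per treatment", call. = FALSE)
  }
  diff <- mean(live) - mean(killed)
  if (stats::sd(live) == 0 && stats::sd(killed) == 0) {
    p <- if (diff > 0) 0 else 1
    return(list(difference = diff, t = if (diff > 0) Inf else 0, p = p,
                significant = p < alpha))
  }
  tt <- stats::t.test(live, killed, alternative = "greater",
                      var.equal = FALSE)
  list(difference = diff, t = unname(tt$statistic), p = tt$p.value,
       significant = tt$p.value < alpha)
}

#' Fit a Michaelis-Menten saturation curve
#'
#' Levenberg-Marquardt least squares of `v = V_max * S / (K_m + S)`,
#' initialised at `V_max0 = max(v)` and `K_m0 =` the substrate level whose
#' rate is nearest half-maximal. Standard errors come from the
#' Jacobian-based covariance at the optimum. Fits that do not converge,
#' or data with no positive signal, are reported as such -- never
#' silently returned as estimates.
#'
#' @param s_uM Substrate concentrations (uM); at least 5 distinct levels.
#' @param v Rates (nmol g^-1 h^-1), same length.
#' @return An object of class `mm_fit`: `vmax`, `vmax_se`, `km`, `km_se`,
#'   `cov` (2x2), `n_levels`, `converged`, `reason` (when not converged).
#' @examples
#' s <- seq(0, 800, 80)
#' fit_michaelis_menten(s, 10 * s / (200 + s))
#' @export
fit_michaelis_menten <- function(s_uM, v) {
  if (length(s_uM) != length(v)) {
    stop("substrate and rate vectors differ in length", call. = FALSE)
  }
  n_levels <- length(unique(s_uM))
  if (n_levels < 5) {
    stop("need at least 5 distinct substrate levels", call. = FALSE)
  }
  no_fit <- function(reason) {
    structure(list(vmax = NA_real_, vmax_se = NA_real_, km = NA_real_,
                   km_se = NA_real_, cov = NULL, n_levels = n_levels,
                   converged = FALSE, reason = reason),
              class = "mm_fit")
  }
  if (all(v <= 0)) return(no_fit("no positive signal"))
  vmax0 <- max(v)
  pos <- s_uM > 0
  km0 <- s_uM[pos][which.min(abs(v[pos] - vmax0 / 2))]
  if (length(km0) == 0 || km0 <= 0) km0 <- stats::median(s_uM[pos])
  df <- data.frame(s = s_uM, v = v)
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ vmax * s / (km + s), data = df,
                      start = list(vmax = vmax0, km = km0),
                      lower = c(0, 1e-9),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(no_fit(conditionMessage(fit)))
  co <- summary(fit)$coefficients
  vc <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  structure(list(
    vmax = unname(co["vmax", "Estimate"]),
    vmax_se = unname(co["vmax", "Std. Error"]),
    km = unname(co["km", "Estimate"]),
    km_se = unname(co["km", "Std. Error"]),
    cov = vc, n_levels = n_levels, converged = TRUE, reason = NA_character_
  ), class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> not converged:", x$reason, "\n")
  } else {
    cat(sprintf(
      "<mm_fit> V_max = %.4g +/- %.3g nmol/g/h; K_m = %.4g +/- %.3g uM (%d levels)\n",
      x$vmax, x$vmax_se, x$km, x$km_se, x$n_levels))
  }
  invisible(x)
}

#' Fit saturation curves from a replicate-level rate table
#'
#' For each enzyme x depth, averages replicate rates per substrate level
#' and fits a Michaelis-Menten curve. By default the autoclaved-control
#' mean is subtracted from the live mean at each level before fitting
#' (killed-corrected); `mode = "live-only"` fits the live means directly.
#'
#' @param rates Output of [estimate_rates()] on a saturation-design
#'   table.
#' @param mode `"live-minus-killed"` (default) or `"live-only"`.
#' @return Tibble with one row per enzyme x depth: identifying columns,
#'   `vmax`, `vmax_se`, `km`, `km_se`, `n_levels`, `converged`, `reason`.
#' @export
fit_mm_from_rates <- function(rates,
                              mode = c("live-minus-killed", "live-only")) {
  mode <- match.arg(mode)
  means <- summarize_rates(rates)
  wide <- tidyr::pivot_wider(
    means,
    id_cols = c("sample_id", "depth_mbsf", "enzyme", "enzyme_class",
                "substrate_conc_uM"),
    names_from = "treatment", values_from = "v0_nmol_g_h")
  if (mode == "live-minus-killed") {
    if (!all(c("live", "autoclaved") %in% names(wide))) {
      stop("killed-corrected fit needs both live and autoclaved rates",
           call. = FALSE)
    }
    wide$v_fit <- wide$live - wide$autoclaved
  } else {
    wide$v_fit <- wide$live
  }
  wide |>
    dplyr::group_by(.data$sample_id, .data$depth_mbsf, .data$enzyme,
                    .data$enzyme_class) |>
    dplyr::summarise(
      fit = list(fit_michaelis_menten(.data$substrate_conc_uM, .data$v_fit)),
      .groups = "drop") |>
    dplyr::mutate(
      vmax = vapply(.data$fit, `[[`, numeric(1), "vmax"),
      vmax_se = vapply(.data$fit, `[[`, numeric(1), "vmax_se"),
      km = vapply(.data$fit, `[[`, numeric(1), "km"),
      km_se = vapply(.data$fit, `[[`, numeric(1), "km_se"),
      n_levels = vapply(.data$fit, `[[`, numeric(1), "n_levels"),
      converged = vapply(.data$fit, `[[`, logical(1), "converged"),
      reason = vapply(.data$fit, `[[`, character(1), "reason")) |>
    dplyr::select(-"fit")
}

#' Trend of the Michaelis constant with depth
#'
#' OLS regression of fitted K_m on depth with a two-sided t-test on the
#' slope; used to ask whether apparent substrate affinity changes
#' downcore even as V_max collapses.
#'
#' @param depth_mbsf Depths (mbsf) of converged saturation-curve fits;
#'   at least 3.
#' @param km Fitted K_m values (uM), same length.
#' @return List: `slope` (uM per m), `se`, `p` (two-sided), `intercept`,
#'   `n`.
#' @export
km_depth_trend <- function(depth_mbsf, km) {
  if (length(depth_mbsf) != length(km)) {
    stop("depth and K_m vectors differ in length", call. = FALSE)
  }
  if (length(depth_mbsf) < 3) {
    stop("need at least 3 depths for a trend", call. = FALSE)
  }
  fit <- stats::lm(km ~ depth_mbsf)
  co <- suppressWarnings(summary(fit))$coefficients
  list(slope = unname(co["depth_mbsf", "Estimate"]),
       se = unname(co["depth_mbsf", "Std. Error"]),
       p = unname(co["depth_mbsf", "Pr(>|t|)"]),
       intercept = unname(co["(Intercept)", "Estimate"]),
       n = length(depth_mbsf))
}

#' Q10 temperature scaling of a rate
#'
#' Projects a rate measured at one temperature to another via
#' `rate * Q10^(dT / 10)`; `dT` = in-situ minus assay temperature gives
#' the in-situ projection (a negative `dT` shrinks the rate).
#'
#' @param rate Rate(s); vectorised.
#' @param q10 Factor per 10 degrees C (> 0); 2 is a common default for
#'   marine enzymes.
#' @param dt_c Temperature difference in degrees C.
#' @return Scaled rate(s).
#' @examples
#' temperature_adjust(1, q10 = 2, dt_c = -12)  # 2^-1.2
#' @export
temperature_adjust <- function(rate, q10, dt_c) {
  if (q10 <= 0) stop("Q10 must be positive", call. = FALSE)
  rate * q10^(dt_c / 10)
}
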