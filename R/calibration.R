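#' Fit a matrix-matched standard curve
#'
#' Ordinary least squares of fluorescence on fluorophore concentration.
#' Standards are prepared in the sample slurry itself (matrix-matched),
#' so each fluorophore x sample combination normally gets its own curve:
#' humic quenching differs between samples and is absorbed into the
#' slope.
#'
#' @param points Data frame with columns `concentration_uM` and
#'   `fluorescence` (one row per reading; replicates are just extra
#'   rows). At least 3 points over at least 2 distinct non-negative
#'   concentrations.
#' @param fluorophore Optional label (`"AMC"`, `"MUB"`, ...) carried on
#'   the result.
#' @return An object of class `standard_curve`: `slope` (fluorescence per
#'   uM), `intercept`, `slope_se`, `intercept_se`, `r_squared`, `sigma_f`
#'   (residual SD), `n`, `fluorophore`.
#' @examples
#' pts <- data.frame(concentration_uM = c(0, 1, 2, 4),
#'                   fluorescence = 50 + 1000 * c(0, 1, 2, 4))
#' fit_standard_curve(pts)
#' @export
fit_standard_curve <- function(points, fluorophore = NA_character_) {
  points <- as.data.frame(points)
  if (!all(c("concentration_uM", "fluorescence") %in% names(points))) {
    stop("`points` needs columns `concentration_uM` and `fluorescence`",
         call. = FALSE)
  }
  if (nrow(points) < 3) {
    stop("a standard curve needs at least 3 points", call. = FALSE)
  }
  if (any(points$concentration_uM < 0)) {
    stop("standard concentrations must be non-negative", call. = FALSE)
  }
  if (length(unique(points$concentration_uM)) < 2) {
    stop("singular design: all standard concentrations identical",
         call. = FALSE)
  }
  fit <- stats::lm(fluorescence ~ concentration_uM, data = points)
  # noiseless standards trip summary.lm's perfect-fit warning; harmless
  sm <- suppressWarnings(summary(fit))
  co <- sm$coefficients
  structure(list(
    fluorophore = fluorophore,
    slope = unname(co["concentration_uM", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["concentration_uM", "Std. Error"]),
    intercept_se = unname(co["(Intercept)", "Std. Error"]),
    r_squared = sm$r.squared,
    sigma_f = sm$sigma,
    n = nrow(points)
  ), class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf(
    "<standard_curve%s> F = %.4g + %.4g * C [uM]; r^2 = %.4f (n = %d)\n",
    if (is.na(x$fluorophore)) "" else paste0(" ", x$fluorophore),
    x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' Fit one standard curve per fluorophore
#'
#' @param standards Tibble as written by [generate_standard_curve_data()]
#'   (columns `fluorophore`, `concentration_uM`, `fluorescence`).
#' @return Named list of [fit_standard_curve()] results, one per
#'   fluorophore.
#' @export
fit_standard_curves <- function(standards) {
  standards <- tibble::as_tibble(standards)
  split(standards, standards$fluorophore) |>
    purrr::imap(function(df, fl) fit_standard_curve(df, fluorophore = fl))
}

#' Convert fluorescence to product concentration
#'
#' Inverts a standard curve: `C = (F - b) / m`. Values are deliberately
#' not clipped at zero -- noisy readings below the intercept become small
#' negative concentrations, which keeps downstream rate regressions
#' unbiased; detection-limit flagging happens later.
#'
#' @param curve A [standard_curve][fit_standard_curve()].
#' @param fluorescence Fluorescence reading(s); vectorised.
#' @return Concentration(s) in uM.
#' @export
fluorescence_to_concentration <- function(curve, fluorescence) {
  stopifnot(inherits(curve, "standard_curve"))
  if (!is.finite(curve$slope) || curve$slope <= 0) {
    stop("standard-curve slope must be positive to invert", call. = FALSE)
  }
  (fluorescence - curve$intercept) / curve$slope
}

#' Calibrate an assay table
#'
#' Adds a `conc_uM` column to a canonical assay table by inverting the
#' matching fluorophore's standard curve row-wise.
#'
#' @param series Canonical assay tibble (see [generate_assay_dataset()]).
#' @param curves Named list of standard curves keyed by fluorophore, as
#'   from [fit_standard_curves()].
#' @return `series` with an added `conc_uM` column.
#' @export
calibrate_fluorescence <- function(series, curves) {
  series <- tibble::as_tibble(series)
  missing_fl <- setdiff(unique(series$fluorophore), names(curves))
  if (length(missing_fl) > 0) {
    stop("no standard curve for fluorophore(s): ",
         paste(missing_fl, collapse = ", "), call. = FALSE)
  }
  series$conc_uM <- NA_real_
  for (fl in unique(series$fluorophore)) {
    idx <- series$fluorophore == fl
    series$conc_uM[idx] <-
      fluorescence_to_concentration(curves[[fl]], series$fluorescence[idx])
  }
  series
}
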