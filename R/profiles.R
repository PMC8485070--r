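#' Segmented cell-count profile
#'
#' Fits locally polynomial interpolators to log10(cell counts) versus
#' depth, separately above and below the stratigraphic unconformity, so
#' that counts at enzyme-assay depths can be read off even though the
#' count data were taken at slightly different horizons. Fitting on the
#' log10 scale reflects the roughly exponential decline of cell
#' abundance with depth; segmenting keeps the marine and lacustrine
#' regimes from contaminating each other.
#'
#' @param counts Data frame with columns `depth_mbsf` and `cells_per_g`
#'   (a `core` column, if present, is ignored for fitting).
#' @param unconformity_mbsf Segment boundary (default 51.7 mbsf).
#' @param degree Polynomial degree per segment (default 2); clamped to
#'   n - 1 when a segment has few points.
#' @return An object of class `cell_count_profile` with per-segment fits
#'   and depth spans.
#' @export
cell_count_profile <- function(counts, unconformity_mbsf = 51.7,
                               degree = 2) {
  counts <- as.data.frame(counts)
  if (!all(c("depth_mbsf", "cells_per_g") %in% names(counts))) {
    stop("`counts` needs columns `depth_mbsf` and `cells_per_g`",
         call. = FALSE)
  }
  if (any(counts$cells_per_g <= 0)) {
    stop("cell counts must be strictly positive", call. = FALSE)
  }
  counts <- counts[order(counts$depth_mbsf), , drop = FALSE]
  fit_segment <- function(df) {
    if (nrow(df) == 0) return(NULL)
    deg <- min(degree, nrow(df) - 1)
    if (deg < 1) return(NULL)
    list(fit = stats::lm(log10(cells_per_g) ~ poly(depth_mbsf, deg,
                                                   raw = TRUE),
                         data = df),
         degree = deg, n = nrow(df),
         span = range(df$depth_mbsf))
  }
  upper <- counts[counts$depth_mbsf <= unconformity_mbsf, , drop = FALSE]
  lower <- counts[counts$depth_mbsf > unconformity_mbsf, , drop = FALSE]
  structure(list(upper = fit_segment(upper), lower = fit_segment(lower),
                 unconformity_mbsf = unconformity_mbsf, degree = degree,
                 n = nrow(counts)),
            class = "cell_count_profile")
}

#' @export
print.cell_count_profile <- function(x, ...) {
  seg_line <- function(s, name) {
    if (is.null(s)) return(sprintf("  %s: no fit\n", name))
    sprintf("  %s: degree %d, n = %d, span %.2f-%.2f mbsf\n",
            name, s$degree, s$n, s$span[1], s$span[2])
  }
  cat("<cell_count_profile> unconformity at", x$unconformity_mbsf, "mbsf\n")
  cat(seg_line(x$upper, "above"))
  cat(seg_line(x$lower, "below"))
  invisible(x)
}

#' Interpolate cell counts at query depths
#'
#' Evaluates the segment containing each query depth and back-transforms
#' from log10. Queries are never extrapolated: a depth outside the
#' measured span of its segment, or in a segment with fewer than 3
#' measured points, is an error.
#'
#' @param profile A [cell_count_profile()].
#' @param query_depths Depths (mbsf) at which counts are needed.
#' @return Numeric vector of counts (cells g^-1) at the query depths.
#' @export
interpolate_cell_counts <- function(profile, query_depths) {
  stopifnot(inherits(profile, "cell_count_profile"))
  vapply(query_depths, function(d) {
    seg <- if (d <= profile$unconformity_mbsf) profile$upper else profile$lower
    side <- if (d <= profile$unconformity_mbsf) "above" else "below"
    if (is.null(seg) || seg$n < 3) {
      stop(sprintf("fewer than 3 measured points %s the unconformity; cannot interpolate at %.2f mbsf",
                   side, d), call. = FALSE)
    }
    if (d < seg$span[1] || d > seg$span[2]) {
      stop(sprintf("query depth %.2f mbsf is outside the measured span (%.2f-%.2f) of its segment; extrapolation is not supported",
                   d, seg$span[1], seg$span[2]), call. = FALSE)
    }
    10^unname(stats::predict(seg$fit,
                             newdata = data.frame(depth_mbsf = d)))
  }, numeric(1))
}

#' Cell-specific enzyme activity
#'
#' Divides a per-gram hydrolysis rate by the cell abundance in the same
#' gram of sediment: `(nmol g^-1 h^-1) / (cells g^-1)`, reported in
#' attomoles per cell per hour (1 nmol = 1e9 amol).
#'
#' @param v_nmol_g_h Rate(s) in nmol g^-1 h^-1.
#' @param cells_per_g Cell abundance(s), strictly positive; recycled.
#' @param scale `"amol"` (default) or `"fmol"` per cell per hour.
#' @return Cell-specific rate(s).
#' @examples
#' cell_specific_activity(1, 1e9)  # 1 amol per cell per hour
#' @export
cell_specific_activity <- function(v_nmol_g_h, cells_per_g,
                                   scale = c("amol", "fmol")) {
  scale <- match.arg(scale)
  if (any(cells_per_g <= 0)) {
    stop("cell counts must be strictly positive", call. = FALSE)
  }
  amol <- v_nmol_g_h / cells_per_g * 1e9
  if (scale == "amol") amol else amol / 1e3
}

#' Assemble a tidy depth-profile table
#'
#' Joins replicate-averaged live and killed rates with interpolated cell
#' counts into one row per enzyme x depth, adding cell-specific
#' activities and below-detection flags. Depths without an interpolated
#' cell count get `NA` specific activity with a warning rather than being
#' dropped.
#'
#' @param rates Replicate-level rate table from [estimate_rates()]
#'   (single-concentration design).
#' @param cells Tibble with columns `depth_mbsf` and `cells_per_g`
#'   (already interpolated at the assay depths).
#' @param dl Detection limit (nmol g^-1 h^-1) used for the
#'   below-detection flag (default 0: nothing flagged).
#' @return Tibble with one row per enzyme x depth: `depth_mbsf`,
#'   `enzyme`, `enzyme_class`, `live_v0`, `live_se`, `killed_v0`,
#'   `killed_se` (nmol g^-1 h^-1), `cells_per_g`, `cell_specific_amol`
#'   (live), `below_detection` (live rate < `dl`), `detection_limit`.
#' @export
assemble_depth_profile <- function(rates, cells, dl = 0) {
  if (nrow(rates) == 0) {
    return(tibble::tibble(
      depth_mbsf = numeric(), enzyme = character(),
      enzyme_class = character(), live_v0 = numeric(),
      live_se = numeric(), killed_v0 = numeric(), killed_se = numeric(),
      cells_per_g = numeric(), cell_specific_amol = numeric(),
      below_detection = logical(), detection_limit = numeric()))
  }
  means <- summarize_rates(rates)
  wide <- tidyr::pivot_wider(
    means,
    id_cols = c("depth_mbsf", "enzyme", "enzyme_class"),
    names_from = "treatment",
    values_from = c("v0_nmol_g_h", "se_nmol_g_h"))
  nm <- c(v0_nmol_g_h_live = "live_v0", se_nmol_g_h_live = "live_se",
          v0_nmol_g_h_autoclaved = "killed_v0",
          se_nmol_g_h_autoclaved = "killed_se")
  present <- intersect(names(nm), names(wide))
  names(wide)[match(present, names(wide))] <- nm[present]
  cells <- tibble::as_tibble(cells)[, c("depth_mbsf", "cells_per_g")]
  out <- dplyr::left_join(wide, cells, by = "depth_mbsf")
  if (anyNA(out$cells_per_g)) {
    missing_d <- sort(unique(out$depth_mbsf[is.na(out$cells_per_g)]))
    warning("no cell count at depth(s) ",
            paste(format(missing_d), collapse = ", "),
            "; cell-specific activity set to NA", call. = FALSE)
  }
  out$cell_specific_amol <- ifelse(
    is.na(out$cells_per_g), NA_real_,
    out$live_v0 / out$cells_per_g * 1e9)
  out$below_detection <- out$live_v0 < dl
  out$detection_limit <- dl
  dplyr::arrange(out, .data$enzyme, .data$depth_mbsf)
}
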