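#' Fraction of activity retained after autoclaving
#'
#' For a paired live/killed measurement of one enzyme at one depth,
#' computes `100 * v_killed / v_live` (percent; may exceed 100). Pairs
#' whose live rate is close to the detection limit (below
#' `exclusion_k * dl`) are excluded with a reason rather than producing a
#' meaningless ratio; non-positive live rates are always excluded.
#'
#' @param live_v0,killed_v0 Paired rates (nmol g^-1 h^-1).
#' @param dl Detection limit (nmol g^-1 h^-1).
#' @param exclusion_k Multiplier defining "close to the detection limit"
#'   (default 3; use 0 to disable the proximity exclusion).
#' @return A list of class `retention_record`: `fraction_pct` (`NA` when
#'   excluded for a non-positive live rate), `excluded`, `reason`.
#' @export
fraction_retained <- function(live_v0, killed_v0, dl = 0, exclusion_k = 3) {
  if (length(live_v0) != 1 || length(killed_v0) != 1) {
    stop("`fraction_retained` works on one live/killed pair; see ",
         "`retention_table()` for tables", call. = FALSE)
  }
  if (!is.finite(live_v0) || live_v0 <= 0) {
    return(structure(list(fraction_pct = NA_real_, excluded = TRUE,
                          reason = "non-positive live rate"),
                     class = "retention_record"))
  }
  frac <- 100 * killed_v0 / live_v0
  if (live_v0 < exclusion_k * dl) {
    return(structure(list(fraction_pct = frac, excluded = TRUE,
                          reason = sprintf(
                            "live rate below %g x detection limit",
                            exclusion_k)),
                     class = "retention_record"))
  }
  structure(list(fraction_pct = frac, excluded = FALSE,
                 reason = NA_character_),
            class = "retention_record")
}

#' @export
print.retention_record <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<retention_record> excluded (%s)\n", x$reason))
  } else {
    cat(sprintf("<retention_record> %.1f%% retained\n", x$fraction_pct))
  }
  invisible(x)
}

#' Retention records for a depth-profile table
#'
#' Applies [fraction_retained()] to every enzyme x depth row of an
#' assembled profile (see [assemble_depth_profile()]).
#'
#' @param profile Tibble with columns `enzyme`, `enzyme_class`,
#'   `depth_mbsf`, `live_v0`, `killed_v0`.
#' @param dl Detection limit (nmol g^-1 h^-1).
#' @param exclusion_k Proximity-exclusion multiplier (default 3).
#' @return Tibble: `enzyme`, `enzyme_class`, `depth_mbsf`,
#'   `fraction_pct`, `excluded`, `reason`.
#' @export
retention_table <- function(profile, dl = 0, exclusion_k = 3) {
  profile <- tibble::as_tibble(profile)
  recs <- purrr::map2(profile$live_v0, profile$killed_v0,
                      fraction_retained, dl = dl,
                      exclusion_k = exclusion_k)
  tibble::tibble(
    enzyme = profile$enzyme,
    enzyme_class = profile$enzyme_class,
    depth_mbsf = profile$depth_mbsf,
    fraction_pct = vapply(recs, `[[`, numeric(1), "fraction_pct"),
    excluded = vapply(recs, `[[`, logical(1), "excluded"),
    reason = vapply(recs, `[[`, character(1), "reason"))
}

#' Summarise retention fractions
#'
#' Median and interquartile range of non-excluded retention fractions,
#' overall or grouped by enzyme class or enzyme. Quantiles use linear
#' interpolation between order statistics ([stats::quantile()] type 7);
#' the convention is recorded in the output so reported IQRs are
#' unambiguous.
#'
#' @param records A [retention_table()].
#' @param by `"all"`, `"class"`, or `"enzyme"`.
#' @return Tibble: `group`, `n`, `median_pct`, `q25_pct`, `q75_pct`,
#'   `quantile_type`. Groups with no usable records are omitted with a
#'   warning.
#' @export
summarize_retention <- function(records, by = c("all", "class", "enzyme")) {
  by <- match.arg(by)
  records <- tibble::as_tibble(records)
  grp <- switch(by,
                all = rep("all", nrow(records)),
                class = records$enzyme_class,
                enzyme = records$enzyme)
  usable <- !records$excluded & is.finite(records$fraction_pct)
  empty <- setdiff(unique(grp), unique(grp[usable]))
  if (length(empty) > 0) {
    warning("group(s) with no usable retention records omitted: ",
            paste(empty, collapse = ", "), call. = FALSE)
  }
  tibble::tibble(group = grp[usable],
                 fraction_pct = records$fraction_pct[usable]) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_pct = stats::median(.data$fraction_pct),
      q25_pct = unname(stats::quantile(.data$fraction_pct, 0.25, type = 7)),
      q75_pct = unname(stats::quantile(.data$fraction_pct, 0.75, type = 7)),
      .groups = "drop") |>
    dplyr::mutate(quantile_type = 7L)
}

# Coerce grouped data (named list of numerics, or value/group vectors)
# to a canonical list form.
as_group_list <- function(groups) {
  if (!is.list(groups)) stop("`groups` must be a list of numeric vectors",
                             call. = FALSE)
  groups <- lapply(groups, as.numeric)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (any(vapply(groups, length, integer(1)) < 1)) {
    stop("every group needs at least one value", call. = FALSE)
  }
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("group", seq_along(groups))
  }
  groups
}

#' Kruskal-Wallis rank test across groups
#'
#' Omnibus nonparametric test for differences among k groups (e.g.
#' retention fractions by enzyme class), with the usual tie correction
#' and a chi-square reference distribution on k - 1 degrees of freedom.
#'
#' @param groups Named list of numeric vectors (k >= 2, total N >= 3).
#' @return A list of class `group_test_result`: `H`, `df`, `p`, `n`
#'   (total), `groups` (sizes). When every pooled value is identical the
#'   test is degenerate and `H = 0`, `p = 1` is returned.
#' @examples
#' kruskal_wallis(list(a = 1:3, b = 4:6, c = 7:9))
#' @export
kruskal_wallis <- function(groups) {
  groups <- as_group_list(groups)
  x <- unlist(groups, use.names = FALSE)
  if (length(x) < 3) stop("need at least 3 observations in total",
                          call. = FALSE)
  g <- factor(rep(names(groups), lengths(groups)), levels = names(groups))
  if (length(unique(x)) == 1L) {
    res <- list(H = 0, df = length(groups) - 1L, p = 1,
                n = length(x), groups = lengths(groups))
    return(structure(res, class = "group_test_result"))
  }
  kt <- stats::kruskal.test(x, g)
  structure(list(H = unname(kt$statistic), df = unname(kt$parameter),
                 p = kt$p.value, n = length(x), groups = lengths(groups)),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("<group_test_result> H = %.4g, df = %d, p = %.4g (N = %d)\n",
              x$H, x$df, x$p, x$n))
  invisible(x)
}

#' Conover-Iman pairwise comparisons after Kruskal-Wallis
#'
#' Pairwise t statistics on mean ranks with the pooled rank variance
#' deflated by `(N - 1 - H) / (N - k)` and a t reference distribution on
#' `N - k` degrees of freedom. Run only after (and conditional on) the
#' omnibus test. Holm-adjusted p-values are reported by default;
#' unadjusted values are always included.
#'
#' @param groups Named list of numeric vectors, the same data given to
#'   [kruskal_wallis()].
#' @param h Optional omnibus H statistic; recomputed if missing.
#' @param adjust `"holm"` (default) or `"none"`.
#' @param alpha Level used for the `significant` flag (default 0.05).
#' @return Tibble with `k(k-1)/2` rows: `group1`, `group2`, `t`, `df`,
#'   `p`, `p_adjusted`, `significant`. If the pooled rank variance is
#'   zero (all values tied) every pair gets `t = 0`, `p = 1`.
#' @export
conover_iman <- function(groups, h = NULL, adjust = c("holm", "none"),
                         alpha = 0.05) {
  adjust <- match.arg(adjust)
  groups <- as_group_list(groups)
  k <- length(groups)
  x <- unlist(groups, use.names = FALSE)
  n_i <- lengths(groups)
  n_tot <- length(x)
  if (n_tot <= k) stop("need more observations than groups", call. = FALSE)
  if (is.null(h)) h <- kruskal_wallis(groups)$H
  r <- rank(x)
  g <- rep(seq_len(k), n_i)
  rank_sums <- tapply(r, g, sum)
  s2 <- (sum(r^2) - n_tot * (n_tot + 1)^2 / 4) / (n_tot - 1)
  pairs <- utils::combn(k, 2)
  df <- n_tot - k
  scale2 <- s2 * (n_tot - 1 - h) / df
  pair_stat <- function(i, j) {
    denom2 <- scale2 * (1 / n_i[[i]] + 1 / n_i[[j]])
    if (s2 <= 0 || denom2 <= 0) return(c(0, 1))
    tstat <- (rank_sums[[i]] / n_i[[i]] - rank_sums[[j]] / n_i[[j]]) /
      sqrt(denom2)
    c(tstat, 2 * stats::pt(-abs(tstat), df))
  }
  res <- vapply(seq_len(ncol(pairs)),
                function(c) pair_stat(pairs[1, c], pairs[2, c]),
                numeric(2))
  out <- tibble::tibble(
    group1 = names(groups)[pairs[1, ]],
    group2 = names(groups)[pairs[2, ]],
    t = res[1, ], df = df, p = res[2, ])
  out$p_adjusted <- if (adjust == "holm") {
    stats::p.adjust(out$p, method = "holm")
  } else {
    out$p
  }
  out$significant <- out$p_adjusted < alpha
  out
}
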