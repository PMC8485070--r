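# Independent oracles, coded from first principles so they share no code
# path with the package implementations they check.

# Simple linear regression via the normal equations.
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  rss <- sum((y - intercept - slope * x)^2)
  s2 <- rss / (n - 2)
  list(slope = slope, intercept = intercept,
       slope_se = sqrt(s2 / sxx),
       intercept_se = sqrt(s2 * (1 / n + mean(x)^2 / sxx)),
       r_squared = if (syy == 0) 0 else 1 - rss / syy)
}

# One-sided Welch t (live > killed) with Welch-Satterthwaite df.
welch_oracle <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 1 - pt(t, df))
}

# Kruskal-Wallis H with tie correction, from the rank-sum definition.
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(x)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Conover-Iman pairwise t statistics and two-sided p-values, coded
# directly from the published formula.
conover_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  k <- length(groups)
  r <- rank(x)
  idx <- rep(seq_along(groups), lengths(groups))
  rbar <- tapply(r, idx, mean)
  ni <- lengths(groups)
  h <- kw_oracle(groups)
  s2 <- (sum(r^2) - n * (n + 1)^2 / 4) / (n - 1)
  out <- NULL
  for (i in 1:(k - 1)) {
    for (j in (i + 1):k) {
      se <- sqrt(s2 * ((n - 1 - h) / (n - k)) * (1 / ni[i] + 1 / ni[j]))
      t <- (rbar[i] - rbar[j]) / se
      out <- rbind(out, data.frame(
        i = i, j = j, t = unname(t),
        p = unname(2 * pt(-abs(t), n - k))))
    }
  }
  out
}

# Dense coarse-to-fine grid search for Michaelis-Menten least squares.
mm_grid_oracle <- function(s, v, vmax_range, km_range, rounds = 4,
                           grid_n = 61) {
  for (r in seq_len(rounds)) {
    vg <- seq(vmax_range[1], vmax_range[2], length.out = grid_n)
    kg <- seq(km_range[1], km_range[2], length.out = grid_n)
    sse <- outer(vg, kg, Vectorize(function(vm, km) {
      sum((v - vm * s / (km + s))^2)
    }))
    best <- arrayInd(which.min(sse), dim(sse))
    vm <- vg[best[1]]; km <- kg[best[2]]
    dv <- diff(vmax_range) / (grid_n - 1)
    dk <- diff(km_range) / (grid_n - 1)
    vmax_range <- c(vm - 2 * dv, vm + 2 * dv)
    km_range <- c(max(1e-6, km - 2 * dk), km + 2 * dk)
  }
  list(vmax = vm, km = km)
}
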