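#' Distribution specifications for scalar model parameters
#'
#' A small algebra of one-dimensional distributions used wherever the
#' pipeline treats a parameter as uncertain: literature compilations of
#' enzyme specific activities, and (optionally) growth efficiency and
#' community respiration in the lifetime model.
#'
#' Three families are supported:
#' \describe{
#'   \item{`point`}{a degenerate distribution; every draw equals `value`.}
#'   \item{`log-uniform`}{log10 of the draws is uniform on
#'     `[log10(lo), log10(hi)]`; the median is the geometric mean
#'     `sqrt(lo * hi)`.}
#'   \item{`log-normal`}{natural-log normal with parameters `meanlog`,
#'     `sdlog` (as in [stats::rlnorm()]).}
#' }
#'
#' @param type One of `"point"`, `"log-uniform"`, `"log-normal"`.
#' @param value Point mass location (`type = "point"`); must be finite.
#' @param lo,hi Strictly positive bounds with `lo <= hi`
#'   (`type = "log-uniform"`).
#' @param meanlog,sdlog Log-scale mean and standard deviation
#'   (`type = "log-normal"`); `sdlog >= 0`.
#'
#' @return An object of class `dist_spec`.
#' @examples
#' dist_spec("log-uniform", lo = 1e2, hi = 1e4)
#' draw_dist(dist_spec("point", value = 3), 5)
#' @export
dist_spec <- function(type = c("point", "log-uniform", "log-normal"),
                      value = NULL, lo = NULL, hi = NULL,
                      meanlog = NULL, sdlog = NULL) {
  type <- match.arg(type)
  spec <- switch(type,
    "point" = {
      if (is.null(value) || !is.finite(value)) {
        stop("point distribution requires a finite `value`", call. = FALSE)
      }
      list(type = type, value = value)
    },
    "log-uniform" = {
      if (is.null(lo) || is.null(hi) || lo <= 0 || hi <= 0) {
        stop("log-uniform bounds must be strictly positive", call. = FALSE)
      }
      if (lo > hi) stop("log-uniform requires lo <= hi", call. = FALSE)
      list(type = type, lo = lo, hi = hi)
    },
    "log-normal" = {
      if (is.null(meanlog) || is.null(sdlog) || sdlog < 0) {
        stop("log-normal requires finite `meanlog` and `sdlog` >= 0",
             call. = FALSE)
      }
      list(type = type, meanlog = meanlog, sdlog = sdlog)
    }
  )
  structure(spec, class = "dist_spec")
}

#' Coerce a scalar or dist_spec to a dist_spec
#'
#' Scalars become point masses, so model interfaces can accept either a
#' fixed value or a full distribution.
#'
#' @param x A numeric scalar or a [dist_spec()].
#' @return A `dist_spec`.
#' @export
as_dist_spec <- function(x) {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dist_spec("point", value = x))
  stop("cannot interpret object as a distribution specification",
       call. = FALSE)
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec()].
#' @param n Number of draws (`n >= 1`).
#' @return Numeric vector of length `n`. Draws consume the global RNG
#'   stream; seed with [set.seed()] (or a `seed` argument upstream) for
#'   reproducibility.
#' @export
draw_dist <- function(spec, n) {
  stopifnot(inherits(spec, "dist_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  switch(spec$type,
    "point"       = rep(spec$value, n),
    "log-uniform" = 10^stats::runif(n, log10(spec$lo), log10(spec$hi)),
    "log-normal"  = stats::rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog)
  )
}

#' Median of a distribution specification (closed form)
#'
#' Used to compare Monte-Carlo summaries against their analytic limits.
#'
#' @param spec A [dist_spec()].
#' @return The median of the distribution.
#' @export
dist_median <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  switch(spec$type,
    "point"       = spec$value,
    "log-uniform" = sqrt(spec$lo * spec$hi),
    "log-normal"  = exp(spec$meanlog)
  )
}

#' @export
print.dist_spec <- function(x, ...) {
  params <- x[setdiff(names(x), "type")]
  cat("<dist_spec> ", x$type, "(",
      paste(names(params), unlist(params), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
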