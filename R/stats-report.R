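# midrank-based U statistic of x against the pooled sample
.uStat <- function(x, y) {
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Two-sided Mann-Whitney U test
#'
#' \code{mode = "exact"} enumerates every assignment of the pooled values
#' to the two groups (ties handled by midranks) and reports
#' \code{p = min(1, 2 * min(P(U <= u), P(U >= u)))}. \code{"asymptotic"}
#' uses the normal approximation with midranks, tie-corrected variance and
#' a 0.5 continuity correction. \code{"auto"} (default) picks exact when
#' \code{n_x + n_y <= 16} and there are no ties.
#'
#' @param x,y numeric samples (non-empty).
#' @param mode \code{"auto"}, \code{"exact"} or \code{"asymptotic"}.
#' @return A one-row data.frame:
#'   \code{U} (of \code{x}), \code{p}, \code{nX}, \code{nY}, \code{mode}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(x, y, mode = c("auto", "exact", "asymptotic")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  ties <- any(duplicated(pooled))
  if (mode == "auto")
    mode <- if (n <= 16L && !ties) "exact" else "asymptotic"
  u <- .uStat(x, y)
  if (mode == "exact") {
    r <- rank(pooled)
    sets <- utils::combn(n, nx)
    uAll <- colSums(matrix(r[sets], nrow = nx)) - nx * (nx + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(uAll <= u + eps), mean(uAll >= u - eps)))
  } else {
    mu <- nx * ny / 2
    tt <- table(pooled)
    tieTerm <- sum(tt^3 - tt)
    sig2 <- nx * ny / 12 * ((n + 1) - tieTerm / (n * (n - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - 0.5 * sign(u - mu)) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
  }
  data.frame(U = u, p = p, nX = nx, nY = ny, mode = mode)
}

#' Bonferroni correction
#'
#' Multiplies each p value by the family size and clamps at 1.
#'
#' @param p numeric vector of p values in \code{[0, 1]}.
#' @param m family size; defaults to \code{length(p)} but should be set to
#'   the number of comparisons in the figure panel when the vector is a
#'   subset of the family.
#' @return Adjusted p values, same length as \code{p}.
#' @export
bonferroni <- function(p, m = length(p)) {
  if (any(p < 0 | p > 1)) stop("p values must lie in [0, 1]")
  if (m < 1) stop("family size m must be >= 1")
  pmin(1, m * p)
}

#' Box-plot summary
#'
#' Median and quartiles by the linear-interpolation quantile rule
#' (quantile type 7); whiskers at the most extreme data points within 1.5
#' interquartile ranges of the box; everything beyond is an outlier.
#'
#' @param values numeric sample (>= 1 value).
#' @return A list: \code{median, q1, q3, whiskerLow, whiskerHigh, outliers}.
#' @export
boxSummary <- function(values) {
  if (!length(values)) stop("empty sample")
  q <- quantile(values, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  loFence <- q[1] - 1.5 * iqr
  hiFence <- q[3] + 1.5 * iqr
  inside <- values >= loFence & values <= hiFence
  list(median = q[2], q1 = q[1], q3 = q[3],
       whiskerLow = min(values[inside]), whiskerHigh = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Pointwise mean and SEM across replicate curves
#'
#' Aggregates per-embryo curves (equal length) into a mean curve with its
#' standard error (sample SD over the square root of the number of curves)
#' at every time point.
#'
#' @param curves a list of equal-length numeric vectors (>= 2), or a
#'   matrix with one curve per row.
#' @return data.frame with columns \code{mean, sem}, one row per point.
#' @export
semCurves <- function(curves) {
  if (is.list(curves)) {
    lens <- lengths(curves)
    if (length(curves) < 2L) stop("need at least 2 curves")
    if (length(unique(lens)) != 1L) stop("curves must have equal length")
    curves <- do.call(rbind, curves)
  }
  if (nrow(curves) < 2L) stop("need at least 2 curves")
  data.frame(mean = colMeans(curves),
             sem = apply(curves, 2L, sd) / sqrt(nrow(curves)))
}
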