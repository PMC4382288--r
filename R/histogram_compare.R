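#' Build a binned histogram
#'
#' Histograms compared by [emd()], [ks_distance()] or [cluster_chi2()] must
#' share identical bin edges; `shared_edges()` builds fixed-width edges
#' covering the pooled range of two samples, and `build_histogram()` bins one
#' sample on given edges, keeping both the count and the normalized form.
#' Distances are reported in *bin units* (adjacent bins are one unit apart).
#'
#' @param values numeric sample (>= 1 value).
#' @param edges ordered bin edges (length >= 2). Values on an interior edge
#'   fall in the lower bin; both boundary values are included.
#' @return object of class `binned_histogram`: list with `edges`, `counts`,
#'   `freq` (counts / total), `total`, `b` (number of bins).
#' @examples
#' h <- build_histogram(c(1, 1, 2), edges = c(0.5, 1.5, 2.5))
#' h$counts  # 2 1
#' h$freq    # 2/3 1/3
#' @export
build_histogram <- function(values, edges) {
  if (length(values) < 1L) stop("empty input")
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE))
    stop("'edges' must be strictly increasing, length >= 2")
  if (any(values < edges[1] | values > edges[length(edges)]))
    stop("values outside the bin range")
  counts <- as.integer(graphics::hist(values, breaks = edges,
                                      plot = FALSE)$counts)
  structure(list(edges = edges, counts = counts,
                 freq = counts / sum(counts),
                 total = sum(counts), b = length(counts)),
            class = "binned_histogram")
}

#' @rdname build_histogram
#' @param x,y the two samples to cover.
#' @param width bin width (a.u.); default `NULL` chooses the pooled range
#'   divided into `nbins` equal bins.
#' @param nbins number of bins when `width` is not given (default 30).
#' @export
shared_edges <- function(x, y, width = NULL, nbins = 30) {
  lo <- min(x, y); hi <- max(x, y)
  if (hi == lo) hi <- lo + 1
  if (is.null(width)) return(seq(lo, hi, length.out = nbins + 1L))
  check_scalar(width, "width", lower = 0, strict_lower = TRUE)
  seq(lo, lo + width * ceiling((hi - lo) / width), by = width)
}

#' Integer-binned histogram of cluster sizes
#'
#' Bins positive integer run lengths on unit bins `1, 2, ..., max_size`
#' (shared support for a pair of size distributions being compared).
#'
#' @param sizes integer run lengths (possibly empty).
#' @param max_size largest size of the shared support (default: largest
#'   observed size).
#' @return a `binned_histogram` on edges `0.5, 1.5, ..., max_size + 0.5`.
#'   Empty input gives all-zero counts (flagged via attribute `empty`).
#' @export
cluster_size_histogram <- function(sizes, max_size = NULL) {
  if (is.null(max_size)) {
    if (length(sizes) == 0L) stop("empty input and no 'max_size' given")
    max_size <- max(sizes)
  }
  stopifnot(max_size >= 1)
  edges <- seq(0.5, max_size + 0.5, by = 1)
  if (length(sizes) == 0L) {
    h <- structure(list(edges = edges, counts = rep(0L, max_size),
                        freq = rep(NA_real_, max_size), total = 0L,
                        b = as.integer(max_size)),
                   class = "binned_histogram")
    attr(h, "empty") <- TRUE
    return(h)
  }
  if (any(sizes > max_size)) stop("size exceeds 'max_size'")
  build_histogram(sizes, edges)
}

check_pair <- function(x, y) {
  stopifnot(inherits(x, "binned_histogram"), inherits(y, "binned_histogram"))
  if (length(x$edges) != length(y$edges) ||
      any(abs(x$edges - y$edges) > 1e-9))
    stop("histograms must share identical bin edges")
}

#' Earth Mover's Distance between two histograms
#'
#' For one-dimensional histograms on shared bins with unit distance between
#' adjacent bins, the Earth Mover's Distance is the total work needed to turn
#' one normalized histogram into the other under the optimal transport scheme,
#' which reduces to the sum of absolute differences of the cumulative
#' distributions:
#' \deqn{EMD(X, Y) = \sum_i |CDX(i) - CDY(i)|.}
#' Unlike the Kolmogorov-Smirnov distance, which retains only the largest
#' cumulative difference, the EMD uses every bin, making it sensitive to how
#' far mass has to move. Smaller EMD means more similar histograms.
#'
#' @param x,y `binned_histogram`s on identical edges (normalized internally).
#' @return list of class `comparison_result`: `statistic`, `metric = "emd"`.
#' @examples
#' e <- c(0, 1, 2)
#' emd(build_histogram(0.5, e), build_histogram(1.5, e))$statistic  # 1
#' @export
emd <- function(x, y) {
  check_pair(x, y)
  if (x$total == 0 || y$total == 0) stop("empty histogram")
  stat <- sum(abs(cumsum(x$freq) - cumsum(y$freq)))
  structure(list(statistic = stat, metric = "emd"),
            class = "comparison_result")
}

#' Kolmogorov-Smirnov distance between two histograms
#'
#' The largest absolute difference between the cumulative distributions of two
#' normalized histograms on shared bins: `D_KS = max_i |CDX(i) - CDY(i)|`.
#' Always bounded by the [emd()] of the same pair (a maximum of non-negative
#' terms cannot exceed their sum).
#'
#' @inheritParams emd
#' @return list of class `comparison_result`: `statistic`, `metric = "ks"`.
#' @export
ks_distance <- function(x, y) {
  check_pair(x, y)
  if (x$total == 0 || y$total == 0) stop("empty histogram")
  stat <- max(abs(cumsum(x$freq) - cumsum(y$freq)))
  structure(list(statistic = stat, metric = "ks"),
            class = "comparison_result")
}

#' Two-sample chi-squared comparison of count histograms
#'
#' For two *count* histograms `n_i` (total `N`) and `m_i` (total `M`) on
#' shared bins, computes the classical two-sample binned statistic
#' \deqn{X^2 = \frac{1}{MN} \sum_i \frac{(M n_i - N m_i)^2}{n_i + m_i},}
#' approximately \eqn{\chi^2_{b-1}}-distributed under the null hypothesis that
#' both histograms are drawn from the same distribution (`b` = number of bins
#' with `n_i + m_i > 0`; empty bins are skipped and the degrees of freedom
#' reduced accordingly). Note the *difference* in the numerator: only that
#' form vanishes for identical histograms and is chi-squared under the null;
#' a printed plus sign occasionally seen for this statistic is a typesetting
#' artifact.
#'
#' @param x,y `binned_histogram`s holding raw counts (not normalized input).
#' @return list of class `comparison_result`: `statistic`, `p_value`, `dof`,
#'   `metric = "chi2"`.
#' @examples
#' e <- c(0, 1, 2)
#' a <- build_histogram(rep(0.5, 10), e); b <- build_histogram(rep(1.5, 10), e)
#' cluster_chi2(a, b)$statistic  # 20
#' @export
cluster_chi2 <- function(x, y) {
  check_pair(x, y)
  n <- x$counts; m <- y$counts
  if (!isTRUE(all.equal(n, round(n))) || !isTRUE(all.equal(m, round(m))))
    stop("cluster_chi2 needs count histograms, not normalized frequencies")
  N <- sum(n); M <- sum(m)
  if (N == 0 || M == 0) stop("empty histogram")
  keep <- (n + m) > 0
  stat <- sum((M * n[keep] - N * m[keep])^2 / (n[keep] + m[keep])) / (M * N)
  dof <- sum(keep) - 1L
  p <- if (dof >= 1L) stats::pchisq(stat, df = dof, lower.tail = FALSE) else
    NA_real_
  structure(list(statistic = stat, p_value = p, dof = dof, metric = "chi2"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s = %.4g", toupper(x$metric), x$statistic))
  if (!is.null(x$p_value)) cat(sprintf(" (dof %d, p = %.3g)", x$dof, x$p_value))
  if (!is.null(x$se)) cat(sprintf(" +/- %.3g", x$se))
  cat("\n")
  invisible(x)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples the underlying observations with replacement (`n_boot` times),
#' recomputes the statistic on each replicate, and returns the standard
#' deviation over replicates as the standard error, together with a
#' percentile confidence interval. The resampling unit is the individual
#' observation handed in — cells for fluorescence histograms, clusters for
#' cluster-size histograms.
#'
#' @param values numeric vector of observations.
#' @param statistic function of a numeric vector returning one number.
#' @param n_boot number of bootstrap replicates (>= 100; typical choices are
#'   1000 for fluorescence-histogram distances, 10000 for cluster-size
#'   distances).
#' @param seed integer seed.
#' @param conf level of the percentile interval (default 0.95).
#' @return list with `se`, `ci` (percentile interval), `n_dropped`
#'   (replicates on which the statistic was undefined).
#' @export
bootstrap_se <- function(values, statistic, n_boot = 1000, seed = 1L,
                         conf = 0.95) {
  if (n_boot < 100) stop("'n_boot' must be >= 100")
  n <- length(values)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      v <- values[sample.int(n, n, replace = TRUE)]
      tryCatch(as.numeric(statistic(v)), error = function(e) NA_real_)
    }, numeric(1))
  })
  dropped <- sum(!is.finite(reps))
  reps <- reps[is.finite(reps)]
  if (length(reps) < 2L) stop("statistic undefined on almost all replicates")
  alpha <- (1 - conf) / 2
  list(se = stats::sd(reps),
       ci = unname(stats::quantile(reps, c(alpha, 1 - alpha))),
       n_dropped = dropped)
}
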