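#' Population noise of a filament set
#'
#' Cell-to-cell variability of expression quantified by the non-dimensional
#' ratio \eqn{\sigma_p^2/\mu_p^2}, pooling all cells of all filaments of the
#' set. The unbiased sample variance is used (the ratio is scale-free either
#' way, but the convention is stated here so results are reproducible).
#'
#' @param set a [filament_set()].
#' @return squared coefficient of variation (numeric scalar).
#' @examples
#' fs <- filament_set(data.frame(run_id = 1, filament_id = 1,
#'                               cell_index = 0:1, fluorescence = c(1, 3)))
#' population_noise(fs)  # var 2, mean 2 -> 0.5
#' @export
population_noise <- function(set) {
  f <- set$fluorescence
  if (length(f) < 2L) stop("need at least 2 cells")
  mu <- mean(f)
  if (mu == 0) stop("mean fluorescence is zero; noise undefined")
  stats::var(f) / mu^2
}

#' Between- vs within-filament noise decomposition
#'
#' Separates population variability into a between-filament component (the
#' squared CV of the per-filament mean fluorescences) and a within-filament
#' component (the average over filaments of each filament's own squared CV),
#' and reports their ratio. A large ratio means cells within a filament
#' resemble each other while filaments differ — the signature of inter-filament
#' heterogeneity dominating expression variation.
#'
#' @param set a [filament_set()]; needs >= 2 filaments, each with >= 2 cells.
#' @return list of class `noise_decomposition` with `between`, `within_avg`,
#'   `ratio` (NA, with a warning, when `within_avg` is 0) and `n_filaments`.
#' @export
noise_decomposition <- function(set) {
  tr <- filament_traces(set)
  if (length(tr) < 2L) stop("need at least 2 filaments")
  if (any(lengths(tr) < 2L)) stop("every filament needs at least 2 cells")
  mu_f <- vapply(tr, mean, numeric(1))
  if (any(mu_f == 0)) stop("filament with zero mean fluorescence")
  between <- stats::var(mu_f) / mean(mu_f)^2
  within_each <- vapply(tr, function(v) stats::var(v) / mean(v)^2, numeric(1))
  within_avg <- mean(within_each)
  ratio <- if (within_avg > 0) between / within_avg else {
    warning("all filaments internally constant; ratio undefined")
    NA_real_
  }
  structure(list(between = between, within_avg = within_avg, ratio = ratio,
                 n_filaments = length(tr)),
            class = "noise_decomposition")
}

#' @export
print.noise_decomposition <- function(x, ...) {
  cat(sprintf(
    "noise decomposition over %d filaments:\n  between = %.4g  within_avg = %.4g  ratio = %.3f\n",
    x$n_filaments, x$between, x$within_avg, x$ratio))
  invisible(x)
}

#' Raw spatial autocorrelation of one filament trace
#'
#' Normalized spatial autocovariance of fluorescence between cells `n`
#' positions apart within a single filament:
#' \deqn{g(n) = \frac{1}{L_f - n} \sum_{m=1}^{L_f - n}
#'   \frac{(F(n+m) - \mu_f)(F(m) - \mu_f)}{\sigma_f^2},}
#' where \eqn{\mu_f} and \eqn{\sigma_f^2} are the filament's mean and
#' *population* (1/L) variance, so that `g(0) = 1` exactly. The estimator is
#' negatively biased for `n >= 1` because \eqn{\mu_f} is estimated from the
#' same short series; see [autocorrelation_corrected()] for the permutation
#' compensation.
#'
#' @param values numeric vector: ordered per-cell fluorescence of one
#'   filament (length > `n_max`, non-constant).
#' @param n_max largest cell distance.
#' @return numeric vector `g(0..n_max)` (names `"0"`, `"1"`, ...).
#' @examples
#' autocorrelation_raw(c(1, 2, 1, 2), 1)  # g(1) = -1
#' @export
autocorrelation_raw <- function(values, n_max) {
  L <- length(values)
  if (n_max < 0 || n_max >= L) stop("'n_max' must be in [0, length - 1]")
  mu <- mean(values)
  s2 <- mean((values - mu)^2)            # population convention: g(0) = 1
  if (s2 == 0) stop("constant filament: autocorrelation undefined")
  d <- values - mu
  g <- vapply(0:n_max, function(n) {
    m <- seq_len(L - n)
    sum(d[m + n] * d[m]) / (L - n) / s2
  }, numeric(1))
  names(g) <- 0:n_max
  g
}

# Filament-averaged raw curve: rows = filaments, cols = distances 0..n_max.
# Filaments too short or constant are dropped (returned via attribute).
per_filament_curves <- function(traces, n_max) {
  usable <- vapply(traces, function(v)
    length(v) > n_max && stats::var(v) > 0, logical(1))
  kept <- traces[usable]
  mat <- matrix(unlist(lapply(kept, autocorrelation_raw, n_max = n_max)),
                ncol = n_max + 1L, byrow = TRUE,
                dimnames = list(names(kept), 0:n_max))
  attr(mat, "n_excluded") <- sum(!usable)
  mat
}

#' Bias-corrected, filament-averaged spatial autocorrelation
#'
#' Computes the filament-averaged autocorrelation curve of a set and
#' compensates its negative estimator bias by within-filament permutation:
#' cell positions are randomized independently within each filament, the
#' filament-averaged curve of the shuffled set is computed, and the average
#' over `n_permutations` such shuffles — an estimate of pure bias, since
#' shuffling destroys all spatial structure — is subtracted from the raw curve
#' for `n >= 1` (`g(0)` stays 1). For exchangeable (shuffled) data the
#' expected raw curve is \eqn{-1/(L_f - 1)} at every positive distance, which
#' is what the permutation average converges to.
#'
#' Filaments shorter than `n_max + 1` cells or with zero variance are
#' excluded (count reported in the result). Every retained filament
#' contributes with equal weight to the average, matching the plain
#' filament average of the definition; length-weighted averaging is available
#' via `weight = "length"`.
#'
#' @param set a [filament_set()].
#' @param n_max largest cell distance.
#' @param n_permutations number of within-filament shuffles for the bias
#'   estimate (default 10).
#' @param seed integer seed for the shuffles.
#' @param weight `"equal"` (default) or `"length"` (weights `L_f - n`).
#' @return data frame of class `correlation_curve` with columns `n`, `g`
#'   (corrected), `g_raw`, `bias`, `se` (standard error over filaments);
#'   attributes `corrected = TRUE`, `n_filaments_used`, `n_excluded`.
#' @export
autocorrelation_corrected <- function(set, n_max, n_permutations = 10,
                                      seed = 1L, weight = c("equal", "length")) {
  if (n_permutations < 1) stop("'n_permutations' must be >= 1")
  if (n_max < 1) stop("'n_max' must be >= 1")
  weight <- match.arg(weight)
  traces <- filament_traces(set)
  mat <- per_filament_curves(traces, n_max)
  if (nrow(mat) == 0L) stop("no usable filament (all too short or constant)")
  wts <- if (weight == "equal") rep(1, nrow(mat)) else
    lengths(traces)[rownames(mat)]
  avg <- function(m) apply(m, 2, stats::weighted.mean, w = wts)
  g_raw <- avg(mat)
  used <- traces[rownames(mat)]
  bias_mat <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(k) {
      shuffled <- lapply(used, sample)
      avg(per_filament_curves(shuffled, n_max))
    }, numeric(n_max + 1L)))
  })
  bias <- colMeans(bias_mat)
  bias[1] <- 0                           # g(0) is exact; no compensation
  g <- g_raw - bias
  se <- apply(mat, 2, stats::sd) / sqrt(nrow(mat))
  out <- data.frame(n = 0:n_max, g = g, g_raw = g_raw, bias = bias, se = se,
                    row.names = NULL)
  class(out) <- c("correlation_curve", "data.frame")
  attr(out, "corrected") <- TRUE
  attr(out, "n_filaments_used") <- nrow(mat)
  attr(out, "n_excluded") <- attr(mat, "n_excluded")
  out
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("correlation curve (%s), %d filament(s)\n",
              if (isTRUE(attr(x, "corrected"))) "bias-corrected" else "raw",
              attr(x, "n_filaments_used")))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Nearest-neighbour fluorescence pairs and their Pearson correlation
#'
#' Pools all adjacent cell pairs `(f(n), f(n+1))` over the filaments of a set
#' — the scatter-plot view of short-range spatial coupling — and returns the
#' Pearson correlation over the pooled pairs. The pooled Pearson coefficient
#' is closely related to the filament-averaged `g(1)` but not identical: it
#' pools all pairs before centring, which makes it less biased on short
#' filaments; both views are reported by the pipeline.
#'
#' @param set a [filament_set()] with filaments of length >= 2.
#' @return list with `pairs` (data frame `f_n`, `f_n1`) and `pearson`.
#' @export
neighbor_pairs <- function(set) {
  tr <- Filter(function(v) length(v) >= 2L, filament_traces(set))
  if (length(tr) == 0L) stop("no filament of length >= 2")
  f_n <- unlist(lapply(tr, function(v) v[-length(v)]), use.names = FALSE)
  f_n1 <- unlist(lapply(tr, function(v) v[-1L]), use.names = FALSE)
  if (stats::sd(f_n) == 0 || stats::sd(f_n1) == 0) {
    warning("zero variance in a margin; Pearson undefined")
    r <- NA_real_
  } else r <- stats::cor(f_n, f_n1)
  list(pairs = data.frame(f_n = f_n, f_n1 = f_n1), pearson = r)
}

#' Average correlation curves over experimental runs
#'
#' Pointwise mean and standard error over the runs' curves, the way replicate
#' experiments are combined into a single curve with error bars.
#'
#' @param curves list of `correlation_curve` data frames on a common `n` grid.
#' @return data frame `n`, `g`, `se` (`se` is 0 and flagged by attribute
#'   `single_run` when only one run is supplied).
#' @export
aggregate_runs <- function(curves) {
  stopifnot(length(curves) >= 1L)
  grids <- lapply(curves, `[[`, "n")
  if (!all(vapply(grids, identical, logical(1), y = grids[[1]])))
    stop("curves are on different distance grids")
  gmat <- vapply(curves, `[[`, numeric(length(grids[[1]])), "g")
  gmat <- matrix(gmat, nrow = length(grids[[1]]))
  g <- rowMeans(gmat)
  se <- if (ncol(gmat) > 1L)
    apply(gmat, 1, stats::sd) / sqrt(ncol(gmat)) else rep(0, nrow(gmat))
  out <- data.frame(n = grids[[1]], g = g, se = se)
  attr(out, "single_run") <- length(curves) == 1L
  out
}
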