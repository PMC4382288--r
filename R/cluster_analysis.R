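#' Binarize a filament set at a population quantile threshold
#'
#' Divides cells into two classes at a fluorescence threshold chosen as the
#' quantile defining the upper `percentile` fraction of all cells pooled over
#' the set (default: upper 15%). Cells strictly above the threshold become 1,
#' the rest 0. The threshold is computed per set — i.e. per strain/run
#' population — with the linear-interpolation sample quantile
#' (`stats::quantile`, type 7); exact ties with the threshold fall below it
#' (strict inequality), so a constant set yields no supra-threshold cells.
#'
#' @param set a [filament_set()].
#' @param percentile upper-tail fraction in (0, 1); default 0.15.
#' @param threshold fixed threshold value overriding the quantile rule.
#' @return list of class `binary_filaments`: `bits` (named list of 0/1
#'   integer vectors per filament), `threshold`, `percentile`,
#'   `fraction_above`.
#' @export
binarize <- function(set, percentile = 0.15, threshold = NULL) {
  check_scalar(percentile, "percentile", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  tr <- filament_traces(set)
  if (sum(lengths(tr)) < 1L) stop("empty set")
  if (is.null(threshold))
    threshold <- unname(stats::quantile(set$fluorescence, 1 - percentile,
                                        type = 7))
  bits <- lapply(tr, function(v) as.integer(v > threshold))
  structure(list(bits = bits, threshold = threshold, percentile = percentile,
                 fraction_above = mean(unlist(bits))),
            class = "binary_filaments")
}

#' Run lengths of supra-threshold cells
#'
#' `cluster_sizes()` returns the lengths of all maximal runs of consecutive
#' 1s in one binary filament; runs touching the filament ends count as
#' ordinary runs, and clusters are never merged across filaments.
#' `all_cluster_sizes()` pools the run lengths of every filament of a
#' [binarize()] result (pooling filaments is exactly concatenating their
#' size lists).
#'
#' @param bits integer/logical vector of 0s and 1s.
#' @return integer vector of run lengths (empty when there is no 1).
#' @examples
#' cluster_sizes(c(0, 1, 1, 0, 1))  # 2 1
#' @export
cluster_sizes <- function(bits) {
  if (length(bits) == 0L) return(integer(0))
  r <- rle(as.integer(bits))
  r$lengths[r$values == 1L]
}

#' @rdname cluster_sizes
#' @param bf a `binary_filaments` object.
#' @export
all_cluster_sizes <- function(bf) {
  stopifnot(inherits(bf, "binary_filaments"))
  unlist(lapply(bf$bits, cluster_sizes), use.names = FALSE)
}

#' Simulate filaments of independent cells (Bernoulli strings)
#'
#' The independent-cell null model: finite strings of `string_length` cells
#' in which 1s are thrown independently with probability `p` among 0s. Their
#' cluster-size distribution is the reference against which observed
#' cluster-size histograms are compared; in the infinite-string limit the
#' number of 1s preceding a 0 is geometric/negative-binomial.
#'
#' @param n_strings number of strings (default 1000).
#' @param string_length cells per string (default 20).
#' @param p per-cell probability of a 1 (default 0.15).
#' @param seed integer seed.
#' @return a `binary_filaments` object (threshold `NA`).
#' @export
simulate_bernoulli_strings <- function(n_strings = 1000, string_length = 20,
                                       p = 0.15, seed = 1L) {
  check_scalar(n_strings, "n_strings", lower = 1)
  check_scalar(string_length, "string_length", lower = 1)
  check_scalar(p, "p", lower = 0, upper = 1)
  bits <- with_seed(seed, {
    lapply(seq_len(n_strings), function(i)
      as.integer(stats::runif(string_length) < p))
  })
  names(bits) <- paste0("sim.", seq_len(n_strings))
  structure(list(bits = bits, threshold = NA_real_, percentile = p,
                 fraction_above = mean(unlist(bits))),
            class = "binary_filaments")
}

#' Closed-form run-length law for finite Bernoulli strings
#'
#' Expected number of maximal 1-runs of each length `k` in a string of `L`
#' iid Bernoulli(`p`) cells, and the corresponding conditional cluster-size
#' probabilities. An interior run of length `k` requires `k` 1s flanked by
#' two 0s (probability `p^k (1-p)^2`, at `L - k - 1` interior positions); a
#' run touching one end needs only one flanking 0 (`2 p^k (1-p)`, for
#' `k < L`); the whole string of 1s has probability `p^L`. In the long-string
#' limit the conditional law is geometric, `P(size = k) = (1-p) p^(k-1)`,
#' with mean cluster size `1/(1-p)`.
#'
#' @param string_length string length `L`.
#' @param p per-cell probability of a 1.
#' @param max_size largest size tabulated (default `L`).
#' @return data frame `size`, `expected_runs` (per string), `prob`
#'   (conditional on observing a run).
#' @export
bernoulli_run_length_law <- function(string_length, p, max_size = string_length) {
  check_scalar(string_length, "string_length", lower = 1)
  check_scalar(p, "p", lower = 0, upper = 1)
  stopifnot(max_size >= 1, max_size <= string_length)
  L <- string_length
  k <- seq_len(max_size)
  expected <- ifelse(k < L,
                     2 * p^k * (1 - p) + pmax(L - k - 1, 0) * p^k * (1 - p)^2,
                     p^L)
  prob <- if (sum(expected) > 0) expected / sum(
    ifelse(seq_len(L) < L,
           2 * p^seq_len(L) * (1 - p) +
             pmax(L - seq_len(L) - 1, 0) * p^seq_len(L) * (1 - p)^2,
           p^L)) else rep(NA_real_, max_size)
  data.frame(size = k, expected_runs = expected, prob = prob)
}

#' Compare an observed cluster-size histogram with the independent-cell null
#'
#' Simulates Bernoulli strings, builds both cluster-size histograms on a
#' shared integer support, and returns their [emd()] with a bootstrap
#' standard error obtained by resampling the observed *clusters* with
#' replacement.
#'
#' @param observed_sizes integer vector of observed cluster sizes.
#' @param n_strings,string_length,p,seed null-model parameters, see
#'   [simulate_bernoulli_strings()] (defaults 1000 strings of 20 cells,
#'   p = 0.15).
#' @param n_boot bootstrap replicates for the standard error (default 10000).
#' @return `comparison_result` with `statistic` (EMD, bin units), `se`, and
#'   the simulated size vector as attribute `null_sizes`.
#' @export
compare_to_independent <- function(observed_sizes, n_strings = 1000,
                                   string_length = 20, p = 0.15, seed = 1L,
                                   n_boot = 10000) {
  if (length(observed_sizes) == 0L) stop("empty observed histogram")
  sim <- simulate_bernoulli_strings(n_strings, string_length, p,
                                    seed = derive_seed(seed, 1))
  sim_sizes <- all_cluster_sizes(sim)
  if (length(sim_sizes) == 0L) stop("null simulation produced no clusters")
  max_size <- max(observed_sizes, sim_sizes)
  h_sim <- cluster_size_histogram(sim_sizes, max_size)
  h_obs <- cluster_size_histogram(observed_sizes, max_size)
  stat <- emd(h_obs, h_sim)$statistic
  bs <- bootstrap_se(observed_sizes, function(s)
    emd(cluster_size_histogram(s, max_size), h_sim)$statistic,
    n_boot = n_boot, seed = derive_seed(seed, 2))
  out <- structure(list(statistic = stat, se = bs$se, metric = "emd"),
                   class = "comparison_result")
  attr(out, "null_sizes") <- sim_sizes
  out
}
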