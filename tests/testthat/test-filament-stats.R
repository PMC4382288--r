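test_that("population noise matches hand computations and is scale invariant", {
  fs <- filament_set(data.frame(run_id = 1, filament_id = 1, cell_index = 0:1,
                                fluorescence = c(1, 3)))
  expect_equal(population_noise(fs), 0.5)   # var 2 (unbiased), mean 2
  const <- filament_set(data.frame(run_id = 1, filament_id = 1,
                                   cell_index = 0:4, fluorescence = rep(4, 5)))
  expect_equal(population_noise(const), 0)
  fs2 <- toy_set()
  scaled <- fs2; scaled$fluorescence <- scaled$fluorescence * 7.3
  expect_equal(population_noise(scaled), population_noise(fs2))
})

test_that("noise decomposition flags degenerate inputs", {
  flat <- filament_set(data.frame(
    run_id = 1, filament_id = rep(1:2, each = 3), cell_index = rep(0:2, 2),
    fluorescence = rep(c(2, 9), each = 3)))
  expect_warning(nd <- noise_decomposition(flat), "undefined")
  expect_true(is.na(nd$ratio))
  expect_equal(nd$within_avg, 0)
  one <- filament_set(data.frame(run_id = 1, filament_id = 1, cell_index = 0:2,
                                 fluorescence = 1:3))
  expect_error(noise_decomposition(one), "2 filaments")
})

test_that("decomposition ratio vanishes for homogeneous filaments", {
  sim <- generate_traces(trace_gen_params(n_filaments = 400, filament_cv = 0,
                                          within_kernel = 1, cell_noise_sd = 0,
                                          seed = 19))
  nd <- noise_decomposition(sim$set)
  # only the finite-length sampling share E[1/L] remains
  expect_lt(nd$ratio, 0.1)
  expect_gt(nd$ratio, 0)
})

test_that("raw autocorrelation matches hand evaluation and the naive oracle", {
  expect_equal(unname(autocorrelation_raw(c(1, 2, 1, 2), 1)), c(1, -1))
  set.seed(8)
  for (i in 1:20) {
    v <- stats::rlnorm(sample(5:30, 1))
    n_max <- min(4, length(v) - 1)
    expect_equal(unname(autocorrelation_raw(v, n_max)),
                 naive_autocorrelation(v, n_max), tolerance = 1e-12)
  }
  expect_error(autocorrelation_raw(rep(2, 6), 2), "constant")
  expect_error(autocorrelation_raw(1:3, 3), "n_max")
})

test_that("autocorrelation is reversal-symmetric and affine-invariant", {
  set.seed(9)
  v <- stats::rgamma(15, 3)
  g <- autocorrelation_raw(v, 5)
  expect_equal(autocorrelation_raw(rev(v), 5), g)
  expect_equal(autocorrelation_raw(2.5 * v + 3, 5), g)
})

test_that("permutation correction removes the iid estimator bias", {
  sim <- generate_traces(trace_gen_params(n_filaments = 150, length_min = 20,
                                          length_max = 20, filament_cv = 0,
                                          within_kernel = 1, cell_noise_sd = 0,
                                          seed = 3))
  cv <- autocorrelation_corrected(sim$set, 3, seed = 12)
  expect_equal(cv$g[1], 1)               # g(0) pinned
  expect_equal(cv$bias[1], 0)
  # raw curve shows the negative bias (~ -1/(L-1)); corrected is within noise
  expect_lt(cv$g_raw[2] + 2 * cv$se[2], 0)
  expect_lt(abs(cv$g[2]), 3 * cv$se[2])
  expect_lt(abs(cv$g[3]), 3 * cv$se[3])
  # the permutation estimate approximates the exchangeability bias -1/(L-1)
  expect_equal(cv$bias[2], -1 / 19, tolerance = 0.2)
})

test_that("corrected curve converges to the analytic MA acf at long lengths", {
  sim <- generate_traces(trace_gen_params(n_filaments = 150, length_min = 400,
                                          length_max = 400, filament_cv = 0,
                                          within_kernel = c(1, 1, 1),
                                          cell_noise_sd = 0, seed = 23))
  cv <- autocorrelation_corrected(sim$set, 4, seed = 5)
  target <- c(1, 2 / 3, 1 / 3, 0, 0)
  for (i in 2:5)
    expect_lt(abs(cv$g[i] - target[i]), 3 * cv$se[i] + 0.01)
})

test_that("shuffled data keep a null corrected curve", {
  sim <- generate_traces(trace_gen_params(n_filaments = 100,
                                          within_kernel = c(1, 1, 1),
                                          seed = 44))
  shuffled <- sim$set
  set.seed(4)
  shuffled$fluorescence <- unlist(lapply(filament_traces(sim$set), sample),
                                  use.names = FALSE)
  cv <- autocorrelation_corrected(shuffled, 4, seed = 6)
  for (i in 2:5) expect_lt(abs(cv$g[i]), 4 * cv$se[i])
})

test_that("constant filaments are excluded from the curve, not zeroed", {
  set <- filament_set(data.frame(
    run_id = 1, filament_id = rep(1:2, each = 10), cell_index = rep(0:9, 2),
    fluorescence = c(rep(5, 10), stats::rgamma(10, 4) + 1)))
  cv <- autocorrelation_corrected(set, 2, seed = 1)
  expect_equal(attr(cv, "n_filaments_used"), 1L)
  expect_equal(attr(cv, "n_excluded"), 1L)
})

test_that("neighbor pairs: limits, pooling and invariances", {
  alt <- filament_set(data.frame(
    run_id = 1, filament_id = rep(1:3, each = 8), cell_index = rep(0:7, 3),
    fluorescence = rep(c(1, 9), 12)))
  np <- neighbor_pairs(alt)
  expect_equal(np$pearson, -1)
  expect_equal(nrow(np$pairs), 3 * 7)
  # duplicating every filament leaves the pooled Pearson unchanged
  dup <- filament_set(data.frame(
    run_id = rep(c("a", "b"), each = nrow(alt)),
    filament_id = c(alt$filament_id, alt$filament_id),
    cell_index = c(alt$cell_index, alt$cell_index),
    fluorescence = c(alt$fluorescence, alt$fluorescence)))
  expect_equal(neighbor_pairs(dup)$pearson, np$pearson)
  # iid cells: pooled Pearson is near zero
  sim <- generate_traces(trace_gen_params(n_filaments = 200, filament_cv = 0,
                                          within_kernel = 1, cell_noise_sd = 0,
                                          seed = 13))
  r <- neighbor_pairs(sim$set)$pearson
  expect_lt(abs(r), 3 / sqrt(nrow(sim$set) - 200))
})

test_that("run aggregation averages pointwise with standard errors", {
  mk <- function(g1) {
    structure(data.frame(n = 0:1, g = c(1, g1), se = 0),
              class = c("correlation_curve", "data.frame"))
  }
  agg <- aggregate_runs(list(mk(0.2), mk(0.3)))
  expect_equal(agg$g[2], 0.25)
  expect_equal(agg$se[2], 0.05)
  single <- aggregate_runs(list(mk(0.2)))
  expect_equal(single$se, c(0, 0))
  expect_true(attr(single, "single_run"))
  expect_equal(aggregate_runs(list(mk(0.4), mk(0.4)))$se[2], 0)
  bad <- mk(0.2); bad$n <- c(0, 2)
  expect_error(aggregate_runs(list(mk(0.1), bad)), "grids")
})

test_that("downstream statistics are invariant under filament reversal", {
  sim <- generate_traces(trace_gen_params(n_filaments = 40, seed = 17))
  rev_set <- sim$set
  rev_set$fluorescence <- unlist(lapply(filament_traces(sim$set), rev),
                                 use.names = FALSE)
  cv_a <- autocorrelation_corrected(sim$set, 4, seed = 2)
  cv_b <- autocorrelation_corrected(rev_set, 4, seed = 2)
  expect_equal(cv_b$g_raw, cv_a$g_raw)
  expect_equal(population_noise(rev_set), population_noise(sim$set))
  ba <- binarize(sim$set); bb <- binarize(rev_set)
  expect_equal(sort(all_cluster_sizes(bb)), sort(all_cluster_sizes(ba)))
  expect_equal(neighbor_pairs(rev_set)$pearson, neighbor_pairs(sim$set)$pearson)
})
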