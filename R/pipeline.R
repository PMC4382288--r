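#' Validate a pipeline configuration
#'
#' Checks every parameter block of a run configuration (a YAML file or an R
#' list) against the invariants of the corresponding stage and returns the
#' list of violations, each naming the offending field.
#'
#' @param config path to a YAML file, or a list.
#' @return character vector of violations; `character(0)` means the
#'   configuration is valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)
  known <- c("simulate", "render", "segment", "stats", "clusters", "compare")
  stages <- config$stages
  if (is.null(stages) || length(stages) == 0L)
    add("stages: at least one stage required")
  else if (length(bad <- setdiff(stages, known)))
    add(paste0("stages: unknown stage(s) ", paste(bad, collapse = ", ")))
  if (is.null(config$seed)) add("seed: required")
  else if (!is.numeric(config$seed) || config$seed < 0 ||
           config$seed != round(config$seed))
    add("seed: must be a non-negative integer")
  if ("simulate" %in% stages) {
    res <- tryCatch({
      a <- config$simulate %||% list(); a$seed <- 1L
      do.call(trace_gen_params, a)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(paste0("simulate: ", res))
  } else if (!is.null(config$input_cells) && !file.exists(config$input_cells))
    add(paste0("input_cells: file not found: ", config$input_cells))
  if ("render" %in% stages) {
    res <- tryCatch({
      a <- config$render %||% list(); a$seed <- 1L
      do.call(image_gen_params, a)
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(paste0("render: ", res))
  }
  if ("segment" %in% stages) {
    res <- tryCatch({
      do.call(segmentation_params, config$segment %||% list())
      NULL
    }, error = function(e) conditionMessage(e))
    if (!is.null(res)) add(paste0("segment: ", res))
  }
  st <- config$stats
  if (!is.null(st$n_max) && (!is.numeric(st$n_max) || st$n_max < 1))
    add("stats.n_max: must be >= 1")
  if (!is.null(st$n_permutations) && st$n_permutations < 1)
    add("stats.n_permutations: must be >= 1")
  if (!is.null(st$min_length) && st$min_length < 1)
    add("stats.min_length: must be >= 1")
  cl <- config$clusters
  if (!is.null(cl$percentile) &&
      (!is.numeric(cl$percentile) || cl$percentile <= 0 || cl$percentile >= 1))
    add("clusters.percentile: must be in (0, 1)")
  if (!is.null(cl$null_p) && (cl$null_p < 0 || cl$null_p > 1))
    add("clusters.null_p: must be in [0, 1]")
  if (!is.null(cl$n_boot) && cl$n_boot < 100)
    add("clusters.n_boot: must be >= 100")
  v
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the analysis pipeline end to end
#'
#' Executes the configured stages in order — simulate (or load a cells CSV),
#' render + segment, spatial statistics, cluster statistics, optional
#' histogram comparison against a second cells file — writing all numeric
#' artifacts (cells CSV, correlation-curve CSV, noise report JSON, cluster
#' report JSON, comparison JSON) plus a manifest recording parameters and
#' the per-stage sub-seeds derived from the global seed, and, optionally,
#' summary plots. Two runs with the same configuration and seed produce
#' byte-identical numeric outputs.
#'
#' @param config path to a YAML file, or a list (see [validate_config()]).
#' @param output_dir overrides `config$output_dir`.
#' @return invisible list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  out_dir <- output_dir %||% config$output_dir %||% stop("no output directory")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- config$stages
  seed <- as.integer(config$seed)
  manifest <- list(package_version = as.character(utils::packageVersion("filamentnoise")),
                   seed = seed, stages = stages, config = config,
                   stage_seeds = list(), outputs = list(), flags = list())
  finish <- function() {
    write_json_file(manifest, file.path(out_dir, "manifest.json"))
  }
  on.exit(finish())        # partial outputs keep a manifest on failure
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # --- simulate / load -------------------------------------------------
  if ("simulate" %in% stages) {
    sim_seed <- derive_seed(seed, 1)
    manifest$stage_seeds$simulate <- sim_seed
    sim <- stage("simulate", {
      a <- config$simulate %||% list(); a$seed <- sim_seed
      p <- do.call(trace_gen_params, a)
      generate_traces(p)
    })
    results$sim <- sim
    set <- sim$set
  } else {
    path <- config$input_cells %||% stop("stage list needs 'simulate' or an 'input_cells' file")
    set <- stage("load", read_cells(path))
  }
  cells_path <- file.path(out_dir, "cells.csv")

  # --- render + segment ------------------------------------------------
  if ("render" %in% stages) {
    ren_seed <- derive_seed(seed, 2)
    manifest$stage_seeds$render <- ren_seed
    fimg <- stage("render", {
      a <- config$render %||% list(); a$seed <- ren_seed
      p <- do.call(image_gen_params, a)
      generate_images(p, set)
    })
    results$image <- fimg
    sc <- write_image_tiff(fimg$image, file.path(out_dir, "image.tif"))
    write_label_tiff(fimg$truth$label_image, file.path(out_dir, "labels_truth.tif"))
    write_json_file(fimg$truth$filament_assignments,
                    file.path(out_dir, "filaments_truth.json"))
    manifest$outputs$image <- "image.tif"
    manifest$outputs$image_scale <- sc
  }
  if ("segment" %in% stages) {
    if (is.null(results$image)) stop("stage 'segment' needs stage 'render'")
    seg <- stage("segment", {
      p <- do.call(segmentation_params, config$segment %||% list())
      s <- segment_cells(results$image$image, p)
      s$cells <- order_into_filaments(s$cells, p)
      s
    })
    results$seg <- seg
    write_label_tiff(seg$labels, file.path(out_dir, "labels_seg.tif"))
    set <- cells_to_filament_set(seg$cells)
    manifest$outputs$labels_seg <- "labels_seg.tif"
  }
  min_length <- config$stats$min_length %||% 8
  set <- filter_filaments(set, min_length, quiet = TRUE)
  write_cells(set, cells_path)
  manifest$outputs$cells <- "cells.csv"

  # --- stats -----------------------------------------------------------
  if ("stats" %in% stages) {
    st_seed <- derive_seed(seed, 3)
    manifest$stage_seeds$stats <- st_seed
    stats_res <- stage("stats", {
      n_max <- config$stats$n_max %||% 8
      curve <- autocorrelation_corrected(
        set, n_max = n_max,
        n_permutations = config$stats$n_permutations %||% 10,
        seed = st_seed)
      np <- neighbor_pairs(set)
      list(curve = curve, pearson = np$pearson, pairs = np$pairs,
           noise = population_noise(set),
           decomposition = noise_decomposition(set))
    })
    results$stats <- stats_res
    utils::write.csv(as.data.frame(stats_res$curve),
                     file.path(out_dir, "curves.csv"), row.names = FALSE)
    write_json_file(list(
      population_noise = stats_res$noise,
      neighbor_pearson = stats_res$pearson,
      decomposition = unclass(stats_res$decomposition)[c("between", "within_avg", "ratio")],
      n_filaments = attr(stats_res$curve, "n_filaments_used")),
      file.path(out_dir, "noise.json"))
    manifest$outputs$curves <- "curves.csv"
    manifest$outputs$noise <- "noise.json"
  }

  # --- clusters --------------------------------------------------------
  if ("clusters" %in% stages) {
    cl_seed <- derive_seed(seed, 4)
    manifest$stage_seeds$clusters <- cl_seed
    cl <- config$clusters %||% list()
    clusters_res <- stage("clusters", {
      bf <- binarize(set, percentile = cl$percentile %||% 0.15)
      sizes <- all_cluster_sizes(bf)
      cmp <- compare_to_independent(
        sizes,
        n_strings = cl$null_n %||% 1000,
        string_length = cl$null_len %||% 20,
        p = cl$null_p %||% 0.15,
        seed = cl_seed,
        n_boot = cl$n_boot %||% 10000)
      list(binary = bf, sizes = sizes, emd_to_independent = cmp)
    })
    results$clusters <- clusters_res
    h <- cluster_size_histogram(clusters_res$sizes)
    write_json_file(list(
      threshold = clusters_res$binary$threshold,
      percentile = clusters_res$binary$percentile,
      fraction_above = clusters_res$binary$fraction_above,
      cluster_size_counts = as.integer(h$counts),
      emd_to_independent = clusters_res$emd_to_independent$statistic,
      emd_bootstrap_se = clusters_res$emd_to_independent$se),
      file.path(out_dir, "clusters.json"))
    manifest$outputs$clusters <- "clusters.json"
  }

  # --- compare (optional second dataset) -------------------------------
  if ("compare" %in% stages) {
    cmp_cfg <- config$compare %||% stop("stage 'compare' needs a 'compare' block")
    other <- stage("compare-load", read_cells(
      cmp_cfg$cells_b %||% stop("compare.cells_b: path required")))
    cmp_seed <- derive_seed(seed, 5)
    manifest$stage_seeds$compare <- cmp_seed
    comparison <- stage("compare", {
      edges <- shared_edges(set$fluorescence, other$fluorescence,
                            width = cmp_cfg$width %||% NULL,
                            nbins = cmp_cfg$nbins %||% 30)
      ha <- build_histogram(set$fluorescence, edges)
      hb <- build_histogram(other$fluorescence, edges)
      e <- emd(ha, hb)
      k <- ks_distance(ha, hb)
      x2 <- cluster_chi2(ha, hb)
      bs <- bootstrap_se(set$fluorescence, function(v)
        emd(build_histogram(pmin(pmax(v, edges[1]), edges[length(edges)]),
                            edges), hb)$statistic,
        n_boot = cmp_cfg$n_boot %||% 1000, seed = cmp_seed)
      list(emd = e$statistic, emd_se = bs$se, ks = k$statistic,
           chi2 = x2$statistic, chi2_p = x2$p_value, chi2_dof = x2$dof)
    })
    results$comparison <- comparison
    write_json_file(comparison, file.path(out_dir, "compare.json"))
    manifest$outputs$compare <- "compare.json"
  }

  # --- plots -----------------------------------------------------------
  if (isTRUE(config$plots %||% FALSE)) {
    ok <- tryCatch({
      plot_pipeline(results, set, out_dir)
      TRUE
    }, error = function(e) {
      warning("plotting failed: ", conditionMessage(e))
      FALSE
    })
    manifest$flags$plots <- ok
  }
  invisible(list(results = results, set = set, manifest = manifest,
                 output_dir = out_dir))
}

# Publication-style summary panels: fluorescence histogram,
# nearest-neighbour scatter, correlation curve, cluster-size histogram.
plot_pipeline <- function(results, set, out_dir) {
  grDevices::png(file.path(out_dir, "summary.png"), width = 1200, height = 900)
  on.exit(grDevices::dev.off())
  graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  graphics::hist(set$fluorescence, breaks = 30, freq = FALSE,
                 main = "Cell fluorescence", xlab = "fluorescence (a.u.)")
  if (!is.null(results$stats)) {
    p <- results$stats$pairs
    graphics::plot(p$f_n, p$f_n1, pch = 16, cex = 0.4,
                   col = grDevices::rgb(0, 0, 0, 0.3),
                   xlab = "f(n)", ylab = "f(n+1)",
                   main = sprintf("Nearest neighbours (Pearson %.2f)",
                                  results$stats$pearson))
    cv <- results$stats$curve
    graphics::plot(cv$n, cv$g, type = "b", pch = 16, ylim = range(c(cv$g, 0)),
                   xlab = "cell distance n", ylab = "g(n)",
                   main = "Spatial autocorrelation (bias-corrected)")
    nz <- cv$se > 0
    if (any(nz))   # arrows of sub-pixel extent trigger a harmless warning
      suppressWarnings(
        graphics::arrows(cv$n[nz], cv$g[nz] - cv$se[nz], cv$n[nz],
                         cv$g[nz] + cv$se[nz], angle = 90, code = 3,
                         length = 0.03))
    graphics::abline(h = 0, lty = 2)
  }
  if (!is.null(results$clusters)) {
    sz <- results$clusters$sizes
    null_sz <- attr(results$clusters$emd_to_independent, "null_sizes")
    mx <- max(sz, null_sz)
    ho <- cluster_size_histogram(sz, mx)
    hn <- cluster_size_histogram(null_sz, mx)
    graphics::barplot(rbind(ho$freq, hn$freq), beside = TRUE,
                      names.arg = seq_len(mx), col = c("steelblue", "grey"),
                      xlab = "cluster size", ylab = "frequency",
                      main = "Cluster sizes vs independent cells",
                      legend.text = c("observed", "independent"))
  }
  invisible(NULL)
}

#' Default demonstration configuration
#'
#' A ready-to-run configuration: simulate 300 filaments with an MA(2)
#' kernel, compute spatial statistics and cluster statistics against the
#' independent-cell null.
#'
#' @param seed global seed.
#' @param output_dir output directory.
#' @return a config list accepted by [run_pipeline()].
#' @export
demo_config <- function(seed = 1L, output_dir = tempfile("filamentnoise_run")) {
  list(seed = as.integer(seed),
       output_dir = output_dir,
       stages = c("simulate", "stats", "clusters"),
       simulate = list(n_filaments = 300, within_kernel = c(1, 1, 1)),
       stats = list(n_max = 8, n_permutations = 10, min_length = 8),
       clusters = list(percentile = 0.15, null_p = 0.15, null_n = 1000,
                       null_len = 20, n_boot = 1000),
       plots = FALSE)
}
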