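#' Parameters for adaptive-threshold cell segmentation
#'
#' The segmentation applies a global initial threshold (Otsu by default) to
#' the fluorescence image and labels connected components; any component
#' larger than `max_area_factor` times a typical cell is re-thresholded
#' locally at a threshold raised in steps of `threshold_step` of the local
#' dynamic range, up to `max_iterations` times, until it breaks into
#' typically-sized cells. This lets cells be recovered correctly even with
#' large intensity variations across the frame. Components smaller than
#' `min_cell_area` are discarded.
#'
#' @param init_threshold_rule `"otsu"` (parameter-free, default) or
#'   `"percentile"` (use the `percentile` quantile of pixel intensities).
#' @param percentile quantile used when `init_threshold_rule = "percentile"`.
#' @param typical_cell_area expected cell area in pixels.
#' @param max_area_factor components above `max_area_factor *
#'   typical_cell_area` are re-thresholded (> 1).
#' @param threshold_step local threshold raise per iteration, as a fraction
#'   of the component's dynamic range (in (0, 1)).
#' @param max_iterations cap on local re-thresholding rounds (>= 1).
#' @param min_cell_area smallest accepted cell, pixels.
#' @param neighbor_max_gap largest centroid distance (pixels) at which two
#'   cells are considered neighbours along a filament.
#' @return list of class `segmentation_params`.
#' @export
segmentation_params <- function(init_threshold_rule = c("otsu", "percentile"),
                                percentile = 0.5,
                                typical_cell_area = 25,
                                max_area_factor = 2,
                                threshold_step = 0.05,
                                max_iterations = 20,
                                min_cell_area = 5,
                                neighbor_max_gap = 14) {
  init_threshold_rule <- match.arg(init_threshold_rule)
  check_scalar(max_area_factor, "max_area_factor", lower = 1,
               strict_lower = TRUE)
  check_scalar(threshold_step, "threshold_step", lower = 0, upper = 1,
               strict_lower = TRUE, strict_upper = TRUE)
  check_scalar(max_iterations, "max_iterations", lower = 1)
  check_scalar(percentile, "percentile", lower = 0, upper = 1)
  structure(list(init_threshold_rule = init_threshold_rule,
                 percentile = percentile,
                 typical_cell_area = typical_cell_area,
                 max_area_factor = max_area_factor,
                 threshold_step = threshold_step,
                 max_iterations = as.integer(max_iterations),
                 min_cell_area = min_cell_area,
                 neighbor_max_gap = neighbor_max_gap),
            class = "segmentation_params")
}

label_matrix <- function(mask) {
  m <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask * 1)))
  matrix(as.integer(m), nrow(mask), ncol(mask))
}

#' Segment cells in a fluorescence image
#'
#' Implements the adaptive-threshold scheme of [segmentation_params()]:
#' global threshold, connected components, iterative local re-thresholding of
#' oversized components, and a minimum-area filter. Mean fluorescence per
#' cell is measured on the *original* image (no background subtraction or
#' flat-field correction is applied; raw region means are reported).
#' Deterministic for fixed input and parameters.
#'
#' @param image 2D numeric matrix, finite values.
#' @param params a [segmentation_params()].
#' @return list with `labels` (integer matrix, 0 = background, cells
#'   labelled 1..K) and `cells` (data frame: `cell_id`, `centroid_y`,
#'   `centroid_x`, `area`, `mean_fluorescence`; filament columns are filled
#'   by [order_into_filaments()]).
#' @export
segment_cells <- function(image, params = segmentation_params()) {
  if (length(dim(image)) != 2L || !is.numeric(image))
    stop("'image' must be a 2D numeric matrix")
  if (any(!is.finite(image))) stop("'image' must be finite")
  rng <- range(image)
  if (rng[1] == rng[2]) {
    warning("constant image: no cells found")
    return(list(labels = matrix(0L, nrow(image), ncol(image)),
                cells = empty_cells()))
  }
  norm <- (image - rng[1]) / (rng[2] - rng[1])
  th0 <- switch(params$init_threshold_rule,
                otsu = EBImage::otsu(EBImage::Image(norm)),
                percentile = stats::quantile(norm, params$percentile,
                                             names = FALSE))
  labels <- label_matrix(norm > th0)
  cap <- params$max_area_factor * params$typical_cell_area
  # iterative local re-thresholding of oversized components
  repeat_needed <- TRUE
  iter <- 0L
  while (repeat_needed && iter < params$max_iterations) {
    iter <- iter + 1L
    repeat_needed <- FALSE
    areas <- tabulate(labels)
    for (lab in which(areas > cap)) {
      idx <- which(labels == lab)
      local <- norm[idx]
      th_loc <- max(th0, min(local)) +
        params$threshold_step * (max(local) - min(local)) * iter
      sub_keep <- local > th_loc
      if (!any(sub_keep) || all(sub_keep)) next
      # relabel the component at the raised threshold
      sub <- matrix(FALSE, nrow(norm), ncol(norm))
      sub[idx[sub_keep]] <- TRUE
      sub_labels <- label_matrix(sub)
      labels[idx] <- 0L
      nz <- sub_labels > 0L
      labels[nz] <- max(labels) + sub_labels[nz]
      repeat_needed <- TRUE
    }
  }
  # drop small components, relabel compactly
  areas <- tabulate(labels)
  keep <- which(areas >= params$min_cell_area)
  remap <- integer(max(labels, 1L))
  remap[keep] <- seq_along(keep)
  pos <- labels > 0L
  labels[pos] <- remap[labels[pos]]
  cells <- cell_records(image, labels)
  list(labels = labels, cells = cells)
}

empty_cells <- function() {
  data.frame(cell_id = integer(0), centroid_y = numeric(0),
             centroid_x = numeric(0), area = integer(0),
             mean_fluorescence = numeric(0))
}

cell_records <- function(image, labels) {
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) == 0L) return(empty_cells())
  idx <- which(labels > 0L)
  lab <- labels[idx]
  rc <- arrayInd(idx, dim(labels))
  data.frame(
    cell_id = ids,
    centroid_y = as.numeric(tapply(rc[, 1], lab, mean)),
    centroid_x = as.numeric(tapply(rc[, 2], lab, mean)),
    area = as.integer(tapply(idx, lab, length)),
    mean_fluorescence = as.numeric(tapply(image[idx], lab, mean)))
}

#' Mean fluorescence per labelled region
#'
#' Mean pixel value of the image over each labelled cell region. Labels
#' covering zero pixels are excluded with a warning. Invariant under any
#' relabelling of cell ids.
#'
#' @param image 2D numeric matrix.
#' @param labels integer matrix of the same dimension (0 = background).
#' @return named numeric vector, one mean per label present.
#' @export
extract_fluorescence <- function(image, labels) {
  if (!all(dim(image) == dim(labels)))
    stop("'image' and 'labels' must have identical dimensions")
  present <- sort(unique(labels[labels > 0L]))
  expected <- seq_len(max(labels, 0L))
  if (length(setdiff(expected, present)) > 0L)
    warning("label(s) covering zero pixels excluded: ",
            paste(setdiff(expected, present), collapse = ", "))
  out <- vapply(present, function(k) mean(image[labels == k]), numeric(1))
  names(out) <- present
  out
}

#' Order segmented cells into filaments
#'
#' Builds the chain graph of cells whose centroids lie within
#' `neighbor_max_gap` of each other. Each connected chain with maximum degree
#' <= 2 becomes one filament, ordered by walking from one endpoint (the
#' orientation is arbitrary; all downstream statistics are
#' reversal-invariant). Chains containing a branch point (degree > 2) are
#' split at the branch: the branch cells are set aside and the remaining
#' sub-chains become filaments flagged as `branched`. Cyclic chains are
#' excluded and flagged.
#'
#' @param cells data frame as returned by [segment_cells()].
#' @param params a [segmentation_params()] (only `neighbor_max_gap` is used).
#' @return `cells` with `filament_id` and `position_in_filament` (0-based)
#'   columns filled; cells excluded as branch points or cycle members get
#'   `NA`. Attributes `n_branched` and `n_cycles` report the flags.
#' @export
order_into_filaments <- function(cells, params = segmentation_params()) {
  n <- nrow(cells)
  cells$filament_id <- rep(NA_integer_, n)
  cells$position_in_filament <- rep(NA_integer_, n)
  n_branched <- 0L; n_cycles <- 0L
  if (n > 0L) {
    d <- as.matrix(stats::dist(cells[, c("centroid_y", "centroid_x")]))
    adj <- d <= params$neighbor_max_gap & d > 0
    deg <- rowSums(adj)
    active <- deg <= 2                    # branch cells set aside
    n_branched <- sum(!active)
    comp <- integer(n); comp_id <- 0L
    for (s in seq_len(n)) {
      if (!active[s] || comp[s] != 0L) next
      comp_id <- comp_id + 1L
      queue <- s; comp[s] <- comp_id
      while (length(queue)) {
        v <- queue[1]; queue <- queue[-1]
        nb <- which(adj[v, ] & active & comp == 0L)
        comp[nb] <- comp_id
        queue <- c(queue, nb)
      }
    }
    fil_id <- 0L
    for (cid in seq_len(comp_id)) {
      members <- which(comp == cid)
      sub_deg <- rowSums(adj[members, members, drop = FALSE])
      ends <- members[sub_deg <= 1]
      if (length(ends) == 0L) { n_cycles <- n_cycles + 1L; next }
      # walk the chain from one endpoint
      order_ <- ends[1]; prev <- -1L
      while (TRUE) {
        cur <- order_[length(order_)]
        nxt <- setdiff(members[adj[cur, members]], c(order_))
        if (length(nxt) == 0L) break
        order_ <- c(order_, nxt[1])
      }
      fil_id <- fil_id + 1L
      cells$filament_id[order_] <- fil_id
      cells$position_in_filament[order_] <- seq_along(order_) - 1L
    }
  }
  attr(cells, "n_branched") <- n_branched
  attr(cells, "n_cycles") <- n_cycles
  cells
}

#' Convert ordered cell records to a filament set
#'
#' @param cells output of [order_into_filaments()] (cells without a filament
#'   assignment are dropped).
#' @param run_id run label for the resulting set.
#' @return a [filament_set()] carrying `area` and centroid columns.
#' @export
cells_to_filament_set <- function(cells, run_id = "run1") {
  ok <- !is.na(cells$filament_id)
  filament_set(data.frame(
    run_id = run_id,
    filament_id = cells$filament_id[ok],
    cell_index = cells$position_in_filament[ok],
    fluorescence = cells$mean_fluorescence[ok],
    area = cells$area[ok],
    centroid_y = cells$centroid_y[ok],
    centroid_x = cells$centroid_x[ok]))
}

#' Match segmented cells to ground-truth labels by IoU
#'
#' Greedy one-to-one matching between ground-truth and segmented label maps
#' by intersection-over-union, the standard segmentation-quality summary for
#' synthetic fixtures with known labels.
#'
#' @param truth,seg integer label matrices of equal dimension.
#' @param iou_min smallest IoU accepted as a recovery (default 0.5).
#' @return list with `recovered` (number of truth cells matched at
#'   `iou_min`), `n_truth`, `fraction`, and `matches` (data frame
#'   `truth_label`, `seg_label`, `iou`).
#' @export
segmentation_recovery <- function(truth, seg, iou_min = 0.5) {
  stopifnot(all(dim(truth) == dim(seg)))
  t_ids <- sort(unique(truth[truth > 0L]))
  matches <- data.frame(truth_label = integer(0), seg_label = integer(0),
                        iou = numeric(0))
  for (tl in t_ids) {
    t_idx <- which(truth == tl)
    cand <- table(seg[t_idx])
    cand <- cand[names(cand) != "0"]
    best_iou <- 0; best <- NA_integer_
    for (sl in names(cand)) {
      inter <- cand[[sl]]
      uni <- length(t_idx) + sum(seg == as.integer(sl)) - inter
      iou <- inter / uni
      if (iou > best_iou) { best_iou <- iou; best <- as.integer(sl) }
    }
    matches <- rbind(matches, data.frame(truth_label = tl, seg_label = best,
                                         iou = best_iou))
  }
  rec <- sum(matches$iou > iou_min & !duplicated(matches$seg_label) &
               !is.na(matches$seg_label))
  list(recovered = rec, n_truth = length(t_ids),
       fraction = if (length(t_ids)) rec / length(t_ids) else NA_real_,
       matches = matches)
}
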