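#' Parameters for the synthetic microscopy image generator
#'
#' Controls the rendering of filament traces as a single-channel
#' fluorescence-microscopy-like image: cells are drawn as axis-aligned
#' ellipses chained along (possibly gently curved) horizontal paths, one
#' filament per row, with intensity proportional to the trace value, then
#' blurred by a Gaussian point-spread function and corrupted by noise.
#' Neighbouring cells are separated by `gap >= 1` pixels, so ground-truth
#' cell regions never overlap.
#'
#' @param image_size `c(height, width)` in pixels.
#' @param cell_axes `c(semi_major, semi_minor)` ellipse semi-axes in pixels
#'   (semi-major along the filament).
#' @param gap pixels between neighbouring cell boundaries along a filament
#'   (>= 1).
#' @param row_gap vertical pixels between filament rows.
#' @param path_curvature amplitude (pixels) of a sinusoidal vertical
#'   undulation of each filament path; 0 gives straight filaments.
#' @param psf_sigma Gaussian blur sigma in pixels (>= 0).
#' @param background_level additive background intensity (a.u.).
#' @param gaussian_sd sd of additive Gaussian read noise (a.u.).
#' @param poisson_scaling if > 0, shot noise: each pixel is replaced by
#'   `rpois(intensity / scaling) * scaling`.
#' @param seed integer seed for the noise.
#' @return list of class `image_gen_params`.
#' @export
image_gen_params <- function(image_size = c(512, 512),
                             cell_axes = c(4, 2),
                             gap = 2,
                             row_gap = 16,
                             path_curvature = 0,
                             psf_sigma = 1,
                             background_level = 1,
                             gaussian_sd = 0.5,
                             poisson_scaling = 0,
                             seed = 1L) {
  stopifnot(length(image_size) == 2L, all(image_size >= 8),
            length(cell_axes) == 2L, all(cell_axes >= 1))
  if (any(2 * cell_axes >= image_size))
    stop("cell axes must be smaller than the image")
  check_scalar(gap, "gap", lower = 1)
  check_scalar(psf_sigma, "psf_sigma", lower = 0)
  check_scalar(gaussian_sd, "gaussian_sd", lower = 0)
  check_scalar(poisson_scaling, "poisson_scaling", lower = 0)
  structure(list(image_size = as.integer(image_size),
                 cell_axes = cell_axes, gap = gap, row_gap = row_gap,
                 path_curvature = path_curvature, psf_sigma = psf_sigma,
                 background_level = background_level,
                 gaussian_sd = gaussian_sd,
                 poisson_scaling = poisson_scaling,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "image_gen_params")
}

#' Render filament traces as a microscopy-like image with ground truth
#'
#' Each filament of `set` is rendered as a chain of elliptical cells whose
#' interior intensity equals the cell's trace value, on a constant
#' background; the frame is then blurred and noise is added according to
#' `params`. The returned ground truth (the unblurred label map, the ordered
#' cell labels of each filament, and the true per-cell values) is the oracle
#' for segmentation tests.
#'
#' @param params an [image_gen_params()].
#' @param set a [filament_set()] with the traces to render (may be empty).
#' @return list of class `filament_image`:
#'   \item{image}{numeric matrix (height x width), noisy rendered frame;}
#'   \item{truth}{list with `label_image` (integer matrix, 0 background,
#'     k = cell k), `filament_assignments` (list of ordered label vectors),
#'     `true_fluorescence` (named per-label vector);}
#'   \item{params}{the parameters used.}
#' @export
generate_images <- function(params, set) {
  stopifnot(inherits(params, "image_gen_params"))
  H <- params$image_size[1]; W <- params$image_size[2]
  a <- params$cell_axes[1]; b <- params$cell_axes[2]
  step <- 2 * a + params$gap
  pitch <- 2 * b + params$row_gap
  img <- matrix(params$background_level, H, W)
  labels <- matrix(0L, H, W)
  traces <- if (nrow(set) > 0L) filament_traces(set) else list()
  assignments <- vector("list", length(traces))
  true_f <- numeric(0)
  margin_x <- a + params$gap
  margin_y <- b + params$row_gap / 2 + abs(params$path_curvature)
  if (length(traces) > 0L) {
    if (margin_y + (length(traces) - 1) * pitch + b + abs(params$path_curvature) > H)
      stop("filaments do not fit the image height; enlarge the image or reduce rows")
    if (any(margin_x + (lengths(traces) - 1) * step + a > W - 1))
      stop("a filament does not fit the image width")
  }
  cell_id <- 0L
  for (f in seq_along(traces)) {
    v <- traces[[f]]
    y0 <- margin_y + (f - 1) * pitch
    ids <- integer(length(v))
    for (j in seq_along(v)) {
      cx <- margin_x + (j - 1) * step
      cy <- y0 + params$path_curvature * sin(2 * pi * cx / W)
      cell_id <- cell_id + 1L
      rows <- max(1L, floor(cy - b)):min(H, ceiling(cy + b))
      cols <- max(1L, floor(cx - a)):min(W, ceiling(cx + a))
      rr <- matrix(rows, length(rows), length(cols))
      cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
      inside <- ((cc - cx) / a)^2 + ((rr - cy) / b)^2 <= 1
      idx <- cbind(rr[inside], cc[inside])
      img[idx] <- params$background_level + v[j]
      labels[idx] <- cell_id
      ids[j] <- cell_id
      true_f[cell_id] <- v[j]
    }
    assignments[[f]] <- ids
  }
  names(assignments) <- names(traces)
  if (params$psf_sigma > 0)
    img <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(img), sigma = params$psf_sigma)))
  img <- with_seed(params$seed, {
    if (params$poisson_scaling > 0)
      img <- stats::rpois(length(img), pmax(img, 0) / params$poisson_scaling) *
        params$poisson_scaling
    if (params$gaussian_sd > 0)
      img <- img + stats::rnorm(length(img), 0, params$gaussian_sd)
    matrix(img, H, W)
  })
  if (length(true_f)) names(true_f) <- seq_along(true_f)
  structure(list(image = img,
                 truth = list(label_image = labels,
                              filament_assignments = assignments,
                              true_fluorescence = true_f),
                 params = params),
            class = "filament_image")
}

#' Read / write single-channel 16-bit TIFF images
#'
#' Intensities are stored scaled to the 16-bit range; the scale factor is
#' chosen from `max_value` (default: the image maximum) and returned so the
#' round trip is lossless up to 16-bit quantization. Label maps round-trip
#' exactly as long as fewer than 65536 labels are used.
#'
#' @param img numeric matrix (intensities) or integer matrix (labels).
#' @param path output file.
#' @param max_value intensity mapped to the top of the 16-bit range.
#' @return `write_image_tiff()`: the scale factor, invisibly.
#'   `read_image_tiff()`: a numeric matrix in original units.
#' @export
write_image_tiff <- function(img, path, max_value = NULL) {
  if (is.null(max_value)) max_value <- max(img, 1e-12)
  scaled <- pmin(pmax(img / max_value, 0), 1)
  tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  invisible(max_value)
}

#' @rdname write_image_tiff
#' @export
read_image_tiff <- function(path, max_value = 1) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  m * max_value
}

#' @rdname write_image_tiff
#' @param labels integer label matrix (0 = background).
#' @export
write_label_tiff <- function(labels, path) {
  if (max(labels) > 65535L) stop("too many labels for 16-bit storage")
  tiff::writeTIFF(labels / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_image_tiff
#' @export
read_label_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1]
  matrix(as.integer(round(m * 65535)), nrow(m), ncol(m))
}
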