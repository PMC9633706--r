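#' Preprocessing configuration
#'
#' @param target_size Output side length in pixels after rescaling.
#' @param focus_threshold Laplacian-variance threshold below which an image
#'   is sorted as blurry.
#' @param grid Numeric `c(lo, hi, step)` for the threshold grid search.
#' @param flip_to Target laterality for orientation normalization.
#' @param equalize Apply histogram equalization.
#' @param laplace_mode `"valid"` (no padding; default) or `"same"`
#'   (reflect-padded) Laplacian response for the focus statistic.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_size = 210, focus_threshold = 350,
                              grid = c(lo = 0, hi = 525, step = 175),
                              flip_to = c("left", "right"), equalize = TRUE,
                              laplace_mode = c("valid", "same")) {
  flip_to <- match.arg(flip_to)
  laplace_mode <- match.arg(laplace_mode)
  if (length(grid) != 3 || grid[1] > grid[2] || grid[3] <= 0)
    stop("grid must be c(lo, hi, step) with lo <= hi and step > 0")
  structure(list(target_size = as.integer(target_size),
                 focus_threshold = focus_threshold, grid = unname(grid),
                 flip_to = flip_to, equalize = isTRUE(equalize),
                 laplace_mode = laplace_mode),
            class = "preprocess_config")
}

#' Histogram equalization of an 8-bit grayscale image
#'
#' Maps each pixel value v to
#' `round(255 * (cdf(v) - cdf_min) / (m*n - cdf_min))`, where `cdf` is the
#' cumulative pixel count over the 256 integer bins and `cdf_min` its
#' smallest non-zero value. The mapping is monotone non-decreasing and the
#' output spans exactly \[0, 255\] whenever the image has at least two
#' distinct values. A constant image (zero denominator) is returned
#' unchanged with a warning.
#'
#' @param img Numeric matrix with integer values in \[0, 255\].
#' @return Equalized image matrix.
#' @export
equalize_histogram <- function(img) {
  stopifnot(is.matrix(img))
  v <- round_half_up(img)
  if (min(v) < 0 || max(v) > 255) stop("pixel values must be in [0, 255]")
  counts <- tabulate(as.integer(v) + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  total <- length(v)
  cdf_min <- min(cdf[cdf > 0])
  if (total - cdf_min == 0) {
    warning("constant image: histogram equalization is undefined; returning input unchanged")
    return(img)
  }
  lut <- round_half_up(255 * (cdf - cdf_min) / (total - cdf_min))
  lut[lut < 0] <- 0  # bins below the first occupied bin (unused)
  out <- matrix(lut[as.integer(v) + 1L], nrow(v), ncol(v))
  out
}

#' Laplacian-variance focus score
#'
#' Convolves the image with the 3x3 Laplacian kernel
#' `[[0,-1,0],[-1,4,-1],[0,-1,0]]` and scores focus as the *sum* of squared
#' deviations of the absolute response from its mean (so the printed
#' blur threshold of 350 refers to this sum statistic). `mode = "valid"`
#' evaluates the kernel only where it fully fits, avoiding artificial
#' border edges; `mode = "same"` reflect-pads to keep the full m x n
#' response.
#'
#' @param img Numeric matrix, at least 3 x 3.
#' @param threshold Focus threshold; `is_focused` is `variance >= threshold`.
#' @param mode `"valid"` or `"same"`.
#' @return A `focus_score` list with fields `variance`, `mean_abs`,
#'   `is_focused`, `threshold`, `mode`.
#' @export
laplace_focus <- function(img, threshold = 350, mode = c("valid", "same")) {
  mode <- match.arg(mode)
  m <- nrow(img); n <- ncol(img)
  if (is.null(m) || m < 3 || n < 3)
    stop("image must be at least 3 x 3 for the Laplacian kernel")
  resp <- if (mode == "same") laplace_response(pad_reflect(img))
          else laplace_response(img)
  a <- abs(resp)
  mu <- mean(a)
  v <- sum((a - mu)^2)
  structure(list(variance = v, mean_abs = mu,
                 is_focused = v >= threshold, threshold = threshold,
                 mode = mode),
            class = "focus_score")
}

# valid-mode 3x3 Laplacian via shifted slices
laplace_response <- function(img) {
  m <- nrow(img); n <- ncol(img)
  4 * img[2:(m - 1), 2:(n - 1)] -
    img[1:(m - 2), 2:(n - 1)] - img[3:m, 2:(n - 1)] -
    img[2:(m - 1), 1:(n - 2)] - img[2:(m - 1), 3:n]
}

pad_reflect <- function(img) {
  m <- nrow(img)
  img <- rbind(img[2, , drop = FALSE], img, img[m - 1, , drop = FALSE])
  cbind(img[, 2, drop = FALSE], img, img[, ncol(img) - 1, drop = FALSE])
}

#' Grid search over focus thresholds
#'
#' For each candidate threshold t in `seq(lo, hi, step)` reports the
#' partition sizes under the rule `variance < t` means blurry. The final
#' threshold choice is a configuration value (the default 350 was picked by
#' qualitative inspection of the partitions).
#'
#' @param variances Numeric vector of focus variances (non-empty).
#' @param grid Numeric `c(lo, hi, step)`; the default yields candidates
#'   0, 175, 350, 525.
#' @return `data.frame` with columns `threshold`, `n_below`, `n_above`.
#' @export
grid_search_threshold <- function(variances, grid = c(0, 525, 175)) {
  if (length(variances) == 0) stop("empty score list")
  cand <- seq(grid[1], grid[2], by = grid[3])
  data.frame(threshold = cand,
             n_below = vapply(cand, function(t) sum(variances < t), 0L),
             n_above = vapply(cand, function(t) sum(variances >= t), 0L))
}

#' Normalize image laterality by horizontal mirroring
#'
#' Mirrors the image iff its laterality differs from the target; applying
#' the operation twice is the identity.
#'
#' @param img Image matrix.
#' @param laterality `"left"`, `"right"`, or `NA` (requires `heuristic`).
#' @param target Target laterality.
#' @param heuristic If `TRUE` and laterality is `NA`, estimate it with
#'   [estimate_laterality()].
#' @return Image matrix in the target orientation.
#' @export
normalize_orientation <- function(img, laterality, target = "left",
                                  heuristic = FALSE) {
  if (is.na(laterality) || !nzchar(laterality)) {
    if (!heuristic) stop("unknown laterality and heuristic disabled")
    laterality <- estimate_laterality(img)
  }
  if (!laterality %in% c("left", "right")) stop("laterality must be left/right")
  if (laterality != target) img <- img[, ncol(img):1] else img
}

#' Estimate laterality from lower-third lateral mass
#'
#' The fibula adds mass on the lateral side of the lower third of a knee
#' crop; the brighter half is taken as the image's laterality.
#'
#' @param img Image matrix.
#' @return `"left"` or `"right"`.
#' @export
estimate_laterality <- function(img) {
  m <- nrow(img); n <- ncol(img)
  lower <- img[round(2 * m / 3):m, , drop = FALSE]
  left_mass <- mean(lower[, 1:floor(0.4 * n)])
  right_mass <- mean(lower[, (n - floor(0.4 * n) + 1):n])
  if (left_mass >= right_mass) "left" else "right"
}

#' Detect and invert a negative (intensity-inverted) radiograph
#'
#' A radiograph crop has dark air background at its borders and bright bone
#' centrally; an image whose border-frame mean exceeds its center mean is
#' classified as a negative and inverted (255 - pixels). Applying the
#' operation to a flagged image twice restores the original polarity.
#'
#' @param img Image matrix in \[0, 255\].
#' @param frame Border frame width as a fraction of the image side.
#' @return List with `img` (possibly inverted) and `inverted` flag.
#' @export
detect_and_invert_negative <- function(img, frame = 0.05) {
  m <- nrow(img); n <- ncol(img)
  w <- max(1L, round(frame * min(m, n)))
  mask <- matrix(FALSE, m, n)
  mask[c(1:w, (m - w + 1):m), ] <- TRUE
  mask[, c(1:w, (n - w + 1):n)] <- TRUE
  border_mean <- mean(img[mask])
  center_mean <- mean(img[!mask])
  if (border_mean > center_mean) list(img = 255 - img, inverted = TRUE)
  else list(img = img, inverted = FALSE)
}

#' Rescale an image with anti-aliased bilinear interpolation
#'
#' Downscaling first applies a Gaussian pre-filter with
#' `sigma = 0.5 * sqrt(r^2 - 1)` (r the shrink factor) to suppress
#' aliasing, then resamples bilinearly.
#'
#' @param img Image matrix.
#' @param target Output side length.
#' @return `target x target` matrix (continuous values; caller clips/rounds).
#' @export
rescale_image <- function(img, target) {
  n <- nrow(img)
  if (target == n) return(img)
  if (target < n) {
    r <- n / target
    sigma <- 0.5 * sqrt(r^2 - 1)
    if (sigma > 0.01)
      img <- EBImage::gblur(img, sigma = sigma, boundary = "replicate")
  }
  as.matrix(EBImage::resize(img, w = target, h = target, filter = "bilinear"))
}

#' Run the full preprocessing pipeline over a manifest
#'
#' Pipeline order: orientation normalization, negative detection/inversion,
#' histogram equalization, anti-aliased rescale to `target_size`, focus
#' scoring. Rows flagged `artifact` or `excluded` are dropped before the
#' focus split. Blurry rows (variance below threshold) are retained in a
#' separate `rejected` manifest because downstream experiments reuse them
#' as their scarce real-data pool.
#'
#' @param manifest `data.frame` with at least `path` and `laterality`
#'   columns; optional logical `artifact` and `excluded` columns.
#' @param config A [preprocess_config()].
#' @param out_dir Optional directory; processed PNGs are written under
#'   `accepted/` and `rejected/` when given.
#' @return List with `accepted`, `rejected` and `dropped` data frames;
#'   accepted/rejected rows gain `focus_variance`, `detected_inverted` and
#'   `status` columns (`status` in `accepted`, `rejected_blur`,
#'   `dropped_artifact`).
#' @export
run_preprocess <- function(manifest, config = preprocess_config(),
                           out_dir = NULL) {
  stopifnot(is.data.frame(manifest), "path" %in% names(manifest))
  missing <- !file.exists(manifest$path)
  if (any(missing))
    stop("missing files in manifest rows: ",
         paste(which(missing), collapse = ", "))
  art <- if ("artifact" %in% names(manifest)) manifest$artifact else FALSE
  exc <- if ("excluded" %in% names(manifest)) manifest$excluded else FALSE
  drop_flag <- art | exc
  dropped <- manifest[drop_flag, , drop = FALSE]
  if (nrow(dropped)) dropped$status <- "dropped_artifact"
  keep <- manifest[!drop_flag, , drop = FALSE]
  if (!is.null(out_dir)) {
    dir.create(file.path(out_dir, "accepted"), recursive = TRUE,
               showWarnings = FALSE)
    dir.create(file.path(out_dir, "rejected"), recursive = TRUE,
               showWarnings = FALSE)
  }
  n <- nrow(keep)
  fv <- numeric(n); inv <- logical(n); outp <- character(n)
  for (i in seq_len(n)) {
    img <- read_gray_png(keep$path[i])
    lat <- if ("laterality" %in% names(keep)) keep$laterality[i] else NA
    img <- normalize_orientation(img, lat, target = config$flip_to,
                                 heuristic = !("laterality" %in% names(keep)))
    di <- detect_and_invert_negative(img)
    img <- di$img; inv[i] <- di$inverted
    if (config$equalize) img <- equalize_histogram(img)
    img <- clip8(round_half_up(rescale_image(img, config$target_size)))
    fs <- laplace_focus(img, threshold = config$focus_threshold,
                        mode = config$laplace_mode)
    fv[i] <- fs$variance
    if (!is.null(out_dir)) {
      sub <- if (fs$is_focused) "accepted" else "rejected"
      outp[i] <- file.path(out_dir, sub, basename(keep$path[i]))
      write_gray_png(img, outp[i])
    }
  }
  keep$focus_variance <- fv
  keep$detected_inverted <- inv
  if (!is.null(out_dir)) keep$processed_path <- outp
  ok <- fv >= config$focus_threshold
  accepted <- keep[ok, , drop = FALSE]
  if (nrow(accepted)) accepted$status <- "accepted"
  rejected <- keep[!ok, , drop = FALSE]
  if (nrow(rejected)) rejected$status <- "rejected_blur"
  list(accepted = accepted, rejected = rejected, dropped = dropped)
}
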