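#' Parameters for a synthetic knee phantom radiograph
#'
#' The phantom emulates the statistical structure of a cropped knee-joint
#' X-ray: two horizontal "bone" bands separated by a joint-space gap, a
#' lateral "fibula" marker, bright semicircular osteophyte bumps at the band
#' edges, optional global intensity inversion (negative image), Gaussian
#' defocus blur, detector noise, and a rare one-pixel bright "scratch"
#' artifact. Class `"B"` (standing for the merged moderate-to-severe grade
#' class) narrows the joint gap by a fixed factor and carries more
#' osteophytes than class `"A"` (none-to-doubtful).
#'
#' @param image_size Side length in pixels (square image, >= 32).
#' @param class_label `"A"` or `"B"`.
#' @param joint_gap Joint-space width in pixels; defaults to 10% of
#'   `image_size` for class A and 0.4 of that for class B. Must be below
#'   `image_size / 4`.
#' @param osteophyte_count Number of bright bumps at the joint margins;
#'   defaults to 1 (A) or 2 (B).
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0).
#' @param invert If `TRUE`, the image is intensity-inverted (negative).
#' @param laterality `"left"` or `"right"`; right images are exact mirrors
#'   of their left-seeded twins.
#' @param artifact If `TRUE`, a one-pixel-wide bright scratch line is drawn.
#' @param noise_sd Additive Gaussian noise SD in gray levels.
#' @param seed Integer seed; same seed and parameters give a bit-identical
#'   image.
#' @return A `phantom_params` list.
#' @export
phantom_params <- function(image_size = 299, class_label = c("A", "B"),
                           joint_gap = NULL, osteophyte_count = NULL,
                           blur_sigma = 0, invert = FALSE,
                           laterality = c("left", "right"), artifact = FALSE,
                           noise_sd = 8, seed = 1L,
                           gap_narrow_factor = 0.4) {
  class_label <- match.arg(class_label)
  laterality <- match.arg(laterality)
  if (image_size < 32) stop("image_size must be >= 32")
  if (blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  base_gap <- round(0.10 * image_size)
  if (is.null(joint_gap))
    joint_gap <- if (class_label == "A") base_gap else
      max(2L, round(gap_narrow_factor * base_gap))
  if (joint_gap >= image_size / 4) stop("joint_gap must be < image_size / 4")
  if (is.null(osteophyte_count))
    osteophyte_count <- if (class_label == "A") 1L else 2L
  if (osteophyte_count < 0) stop("osteophyte_count must be >= 0")
  structure(list(image_size = as.integer(image_size),
                 class_label = class_label,
                 joint_gap = as.integer(joint_gap),
                 osteophyte_count = as.integer(osteophyte_count),
                 blur_sigma = blur_sigma, invert = isTRUE(invert),
                 laterality = laterality, artifact = isTRUE(artifact),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "phantom_params")
}

# Draw a filled disc of given intensity onto img (max-composited).
draw_disc <- function(img, cy, cx, r, value) {
  s <- nrow(img)
  ys <- max(1, floor(cy - r)):min(s, ceiling(cy + r))
  xs <- max(1, floor(cx - r)):min(s, ceiling(cx + r))
  for (y in ys) {
    dx <- sqrt(max(0, r^2 - (y - cy)^2))
    x1 <- max(1, ceiling(cx - dx)); x2 <- min(s, floor(cx + dx))
    if (x1 <= x2) img[y, x1:x2] <- pmax(img[y, x1:x2], value)
  }
  img
}

#' Generate one synthetic phantom radiograph
#'
#' Renders the phantom described by [phantom_params()]. All stochastic
#' elements (bump positions, scratch placement, noise) are drawn from the
#' seed in the parameters, so the output is deterministic. Right-lateral
#' images are produced by mirroring the fully rendered left image, so the
#' two lateralities of one seed are exact mirror images.
#'
#' @param params A `phantom_params` object.
#' @return Numeric matrix `image_size x image_size`, values in \[0, 255\].
#' @export
generate_phantom <- function(params) {
  stopifnot(inherits(params, "phantom_params"))
  p <- params
  s <- p$image_size
  with_seed(p$seed, {
    img <- matrix(18, s, s)
    c0 <- s / 2
    half_gap <- p$joint_gap / 2
    bw <- round(0.18 * s)
    femur <- max(1, round(c0 - half_gap - bw)):round(c0 - half_gap)
    tibia <- round(c0 + half_gap):min(s, round(c0 + half_gap + bw))
    # vertical intensity taper so the bands are not flat plateaus
    img[femur, ] <- 150 + 40 * seq(0, 1, length.out = length(femur))
    img[tibia, ] <- 190 - 40 * seq(0, 1, length.out = length(tibia))
    # fibula marker: a dimmer vertical band near the left edge, lower half
    fib_rows <- round(c0 + half_gap):round(0.92 * s)
    fib_cols <- max(1, round(0.05 * s)):round(0.12 * s)
    img[fib_rows, fib_cols] <- pmax(img[fib_rows, fib_cols], 120)
    # osteophytes: bright semicircular bumps at the joint margins
    if (p$osteophyte_count > 0) {
      for (k in seq_len(p$osteophyte_count)) {
        cx <- stats::runif(1, 0.2 * s, 0.8 * s)
        side <- if (stats::runif(1) < 0.5) "femur" else "tibia"
        cy <- if (side == "femur") round(c0 - half_gap) else round(c0 + half_gap)
        img <- draw_disc(img, cy, cx, max(2, 0.02 * s), 235)
      }
    }
    if (p$artifact) {
      r0 <- sample.int(s, 1)
      img[r0, ] <- 255
    }
    if (p$blur_sigma > 0)
      img <- EBImage::gblur(img, sigma = p$blur_sigma, boundary = "replicate")
    if (p$noise_sd > 0)
      img <- img + matrix(stats::rnorm(s * s, 0, p$noise_sd), s, s)
    img <- clip8(round_half_up(img))
    if (p$laterality == "right") img <- img[, s:1]
    if (p$invert) img <- 255 - img
    img
  })
}

#' Generate a two-class phantom cohort with a ground-truth manifest
#'
#' Writes `2 * n_per_class` phantom PNGs and a CSV manifest carrying the
#' ground-truth per-image flags (class, laterality, inversion, blur sigma,
#' artifact), so preprocessing decisions can be checked against truth.
#'
#' @param n_per_class Images per class (>= 1).
#' @param out_dir Output directory (created if missing).
#' @param mix Named list of fractions in \[0, 1\] for `inverted`, `right`,
#'   `blurred` and `artifact` images.
#' @param blur_sigma Blur sigma applied to the `blurred` fraction.
#' @param noise_sd Noise SD for every image.
#' @param image_size Image side length.
#' @param seed Integer seed; the manifest and images are reproducible.
#' @return The manifest `data.frame` (also written to
#'   `file.path(out_dir, "manifest.csv")`), with columns `path`, `class`,
#'   `laterality`, `inverted`, `blur_sigma`, `artifact`, `excluded`, `split`.
#' @export
generate_cohort <- function(n_per_class, out_dir,
                            mix = list(inverted = 0, right = 0, blurred = 0,
                                       artifact = 0),
                            blur_sigma = 4, noise_sd = 8, image_size = 299,
                            seed = 1L) {
  if (n_per_class < 1) stop("n_per_class must be >= 1")
  frac <- function(nm) { v <- if (is.null(mix[[nm]])) 0 else mix[[nm]]
    if (v < 0 || v > 1) stop("mix fractions must be in [0, 1]"); v }
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stop("cannot create output directory: ", out_dir)
  n <- 2L * n_per_class
  with_seed(seed, {
    cls <- rep(c("A", "B"), each = n_per_class)
    inverted <- stats::runif(n) < frac("inverted")
    right <- stats::runif(n) < frac("right")
    blurred <- stats::runif(n) < frac("blurred")
    artifact <- stats::runif(n) < frac("artifact")
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      p <- phantom_params(image_size = image_size, class_label = cls[i],
                          blur_sigma = if (blurred[i]) blur_sigma else 0,
                          invert = inverted[i],
                          laterality = if (right[i]) "right" else "left",
                          artifact = artifact[i], noise_sd = noise_sd,
                          seed = seeds[i])
      path <- file.path(out_dir, sprintf("phantom_%s_%04d.png", cls[i], i))
      write_gray_png(generate_phantom(p), path)
      rows[[i]] <- data.frame(path = path, class = cls[i],
                              laterality = p$laterality,
                              inverted = p$invert,
                              blur_sigma = p$blur_sigma,
                              artifact = p$artifact, excluded = FALSE,
                              split = "train",
                              stringsAsFactors = FALSE)
    }
    manifest <- do.call(rbind, rows)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    manifest
  })
}
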