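#' Random-projection feature extractor
#'
#' A deterministic, seeded linear projection of flattened pixels to a
#' `d`-dimensional embedding, scaled by `1/sqrt(p)`. It stands in for the
#' InceptionV3 embedding used at full scale: Frechet-distance and
#' nearest-neighbor properties hold for any fixed extractor, and this one
#' needs no pretrained weights.
#'
#' @param input_dim Flattened input dimension (pixels per image).
#' @param d Embedding dimension.
#' @param seed Seed fixing the projection.
#' @return A `feature_extractor`: call it on an (h, w, c, n) array or an
#'   n x p matrix to get an n x d embedding matrix.
#' @export
random_projection_extractor <- function(input_dim, d = 64, seed = 1L) {
  P <- with_seed(seed, matrix(stats::rnorm(input_dim * d), input_dim, d)) /
    sqrt(input_dim)
  f <- function(images) {
    x <- flatten_images(images)
    if (ncol(x) != input_dim)
      stop("extractor expects ", input_dim, " features, got ", ncol(x))
    x %*% P
  }
  structure(f, extractor_id = sprintf("randproj_d%d_seed%d", d, seed),
            class = c("feature_extractor", "function"))
}

# images: (h, w, c, n) array, list of matrices, or n x p matrix -> n x p
flatten_images <- function(images) {
  if (is.list(images))
    return(do.call(rbind, lapply(images, as.vector)))
  d <- dim(images)
  if (length(d) == 4) t(matrix(images, prod(d[1:3]), d[4]))
  else if (length(d) == 2) images
  else matrix(as.vector(images), 1)
}

#' Frechet distance between two feature distributions
#'
#' Fits a Gaussian to each embedding set and computes
#' `||mu_g - mu_r||^2 + tr(S_g) + tr(S_r) - 2 tr((S_g S_r)^(1/2))`
#' with sample covariances (1/(n-1)); small negative eigenvalues of the
#' matrix square root are clipped at 1e-6. This is the standard Frechet
#' Inception Distance form; `form = "printed"` substitutes
#' `tr(sqrt(S_g + S_r))` for the cross term (a variant that is not zero
#' for identical distributions, provided for forensic comparison only).
#'
#' @param fake,real Embedding matrices (n x d, n >= 2, equal d).
#' @param form `"standard"` or `"printed"`.
#' @return A `fid_result` list with `value`, `n_fake`, `n_real`, `form`.
#' @export
compute_fid <- function(fake, real, form = c("standard", "printed")) {
  form <- match.arg(form)
  fake <- as.matrix(fake); real <- as.matrix(real)
  if (ncol(fake) != ncol(real)) stop("feature dimensions differ")
  if (nrow(fake) < 2 || nrow(real) < 2)
    stop("need at least 2 samples per set for covariance estimation")
  if (!all(is.finite(fake)) || !all(is.finite(real)))
    stop("non-finite embeddings")
  mu_g <- colMeans(fake); mu_r <- colMeans(real)
  S_g <- stats::cov(fake); S_r <- stats::cov(real)
  cross <- if (form == "standard") {
    A <- sqrtm_sym(S_g)
    M <- A %*% S_r %*% A
    lam <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
    sum(sqrt(pmax(lam, 0)))
  } else {
    lam <- eigen((S_g + S_r + t(S_g + S_r)) / 2, symmetric = TRUE,
                 only.values = TRUE)$values
    sum(sqrt(pmax(lam, 0)))
  }
  value <- sum((mu_g - mu_r)^2) + sum(diag(S_g)) + sum(diag(S_r)) -
    2 * cross
  structure(list(value = value, n_fake = nrow(fake), n_real = nrow(real),
                 form = form), class = "fid_result")
}

#' Select the best training epoch by Frechet distance
#'
#' For each checkpointed generator, samples `n_fake_per_epoch` images,
#' embeds them and the real set with the same extractor, and computes the
#' Frechet distance; returns the argmin epoch (ties resolved to the
#' earliest) and the full curve.
#'
#' @param generators Named list; each element is a generator `nn_network`,
#'   a `wgan_checkpoint`, or a function `(n, seed) -> images`.
#' @param real_images Real image set (array or matrix; embedded with
#'   `extractor`).
#' @param n_fake_per_epoch Generated sample size per epoch (default: match
#'   the real set size, the convention used at full scale; smaller values
#'   carry extra estimator bias).
#' @param extractor A feature extractor function.
#' @param seed Seed for the generator sampling.
#' @return List with `best_epoch`, `curve` (data.frame epoch/fid/n_fake/
#'   n_real).
#' @export
select_best_epoch <- function(generators, real_images,
                              n_fake_per_epoch = NULL, extractor,
                              seed = 1L) {
  if (length(generators) == 0) stop("need at least one checkpoint")
  real_feat <- extractor(real_images)
  if (is.null(n_fake_per_epoch)) n_fake_per_epoch <- nrow(real_feat)
  epochs <- names(generators)
  if (is.null(epochs)) epochs <- as.character(seq_along(generators))
  fid <- numeric(length(generators))
  for (i in seq_along(generators)) {
    g <- generators[[i]]
    imgs <- if (is.function(g)) g(n_fake_per_epoch, seed + i)
            else {
              gen <- if (inherits(g, "wgan_checkpoint")) g$generator else g
              sample_images(gen, n_fake_per_epoch, seed = seed + i)$images
            }
    fake_feat <- extractor(imgs)
    r <- compute_fid(fake_feat, real_feat)
    if (!is.finite(r$value)) stop("non-finite FID at epoch ", epochs[i])
    fid[i] <- r$value
  }
  curve <- data.frame(epoch = epochs, fid = fid,
                      n_fake = n_fake_per_epoch, n_real = nrow(real_feat))
  list(best_epoch = epochs[which.min(fid)], curve = curve)
}

#' Nearest-neighbor memorization audit
#'
#' Pairs every generated image with its closest real image by Euclidean
#' distance in feature space and returns the `top_k` closest pairs,
#' sorted ascending — the review sheet a domain expert inspects to rule
#' out training-set replication before anonymization-by-replacement. A
#' heuristic warning is emitted when any pair distance falls below the
#' first percentile of real-real distances (no automatic threshold is
#' imposed; the judgment is the expert's).
#'
#' @param fake,real Embedding matrices (n x d / m x d).
#' @param top_k Number of pairs returned (<= number of fakes).
#' @return `data.frame` with `fake_id`, `real_id`, `distance`, `rank`.
#' @export
memorization_audit <- function(fake, real, top_k = 20L) {
  fake <- as.matrix(fake); real <- as.matrix(real)
  if (nrow(fake) == 0 || nrow(real) == 0) stop("empty feature sets")
  if (top_k > nrow(fake)) stop("top_k exceeds number of generated samples")
  d2 <- pairwise_sqdist(fake, real)
  nn <- max.col(-d2, ties.method = "first")
  dist <- sqrt(pmax(d2[cbind(seq_len(nrow(fake)), nn)], 0))
  ord <- order(dist)[seq_len(top_k)]
  pairs <- data.frame(fake_id = ord, real_id = nn[ord],
                      distance = dist[ord], rank = seq_len(top_k))
  if (nrow(real) >= 3) {
    rr <- sqrt(pmax(pairwise_sqdist(real, real), 0))
    rr <- rr[upper.tri(rr)]
    q1 <- stats::quantile(rr, 0.01, names = FALSE)
    if (any(pairs$distance < q1))
      warning("some fake-real pair distances fall below the 1st percentile ",
              "of real-real distances; inspect for memorization")
  }
  pairs
}

pairwise_sqdist <- function(a, b) {
  an <- rowSums(a^2); bn <- rowSums(b^2)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  pmax(d2, 0)
}

#' Export a side-by-side audit montage
#'
#' Writes a PNG grid with one row per pair: generated image on the left,
#' its nearest real neighbor on the right.
#'
#' @param pairs Audit table from [memorization_audit()].
#' @param fake_images,real_images Arrays (h, w, 1, n) in \[0, 255\] or
#'   \[-1, 1\].
#' @param path Output PNG path.
#' @return The path, invisibly.
#' @export
export_audit_montage <- function(pairs, fake_images, real_images, path) {
  to8 <- function(x) if (max(x) <= 1 + 1e-9) tanh_to_uint8(x) else x
  fake_images <- to8(fake_images); real_images <- to8(real_images)
  h <- dim(fake_images)[1]; w <- dim(fake_images)[2]
  rows <- lapply(seq_len(nrow(pairs)), function(i)
    cbind(fake_images[, , 1, pairs$fake_id[i]],
          real_images[, , 1, pairs$real_id[i]]))
  write_gray_png(do.call(rbind, rows), path)
  invisible(path)
}
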