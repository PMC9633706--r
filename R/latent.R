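# Latent-space exploration: single-dimension perturbation sweeps and
# linear interpolation between latent coordinates.

#' Sweep one latent dimension
#'
#' Generates a strip of images from copies of `z` whose `dim`-th
#' coordinate is set to `steps` evenly spaced values in `[lo, hi]`
#' (default -4.2 to +4.2); all other coordinates are untouched.
#'
#' @param generator Generator `nn_network`.
#' @param z Base latent vector.
#' @param dim_index Latent dimension to sweep (1-based).
#' @param lo,hi Sweep range.
#' @param steps Number of strip frames (>= 2).
#' @return List with `values` (the swept coordinate values), `latents`
#'   (latent matrix), `images` (h, w, 1, steps).
#' @export
perturb_dimension <- function(generator, z, dim_index, lo = -4.2,
                              hi = 4.2, steps = 7L) {
  z <- as.numeric(z)
  if (dim_index < 1 || dim_index > length(z))
    stop("dim_index out of range [1, ", length(z), "]")
  if (steps < 2) stop("steps must be >= 2")
  vals <- seq(lo, hi, length.out = steps)
  Z <- matrix(z, length(z), steps)
  Z[dim_index, ] <- vals
  list(values = vals, latents = Z,
       images = generate_strip(generator, Z))
}

# one forward pass per frame: strip frames are then bit-identical to the
# single-latent outputs (batched BLAS paths may round differently)
generate_strip <- function(generator, Z) {
  frames <- lapply(seq_len(ncol(Z)), function(i)
    generate_from_latent(generator, Z[, i]))
  out <- array(0, c(dim(frames[[1]])[1:3], ncol(Z)))
  for (i in seq_along(frames)) out[, , , i] <- frames[[i]]
  out
}

#' Linear interpolation between two latent vectors
#'
#' Images at `z(a) = (1 - a) z_a + a z_b` for `a` evenly spaced in
#' \[0, 1\]; the endpoint images reproduce `generator(z_a)` and
#' `generator(z_b)` bit-exactly.
#'
#' @param generator Generator `nn_network`.
#' @param z_a,z_b Latent vectors of equal length.
#' @param steps Number of frames (>= 2).
#' @return List with `alphas`, `latents`, `images`.
#' @export
interpolate_latent <- function(generator, z_a, z_b, steps = 7L) {
  z_a <- as.numeric(z_a); z_b <- as.numeric(z_b)
  if (length(z_a) != length(z_b)) stop("latent lengths differ")
  if (steps < 2) stop("steps must be >= 2")
  alphas <- seq(0, 1, length.out = steps)
  Z <- vapply(alphas, function(a) (1 - a) * z_a + a * z_b,
              numeric(length(z_a)))
  list(alphas = alphas, latents = Z,
       images = generate_strip(generator, Z))
}

#' Assemble an image strip into one horizontal montage matrix
#'
#' @param images Array (h, w, 1, n) in \[-1, 1\] or \[0, 255\].
#' @param gap Pixel gap between frames (filled with 0).
#' @return Matrix `h x (n*w + (n-1)*gap)` in \[0, 255\].
#' @export
montage_strip <- function(images, gap = 2L) {
  to8 <- if (max(images) <= 1 + 1e-9) tanh_to_uint8 else identity
  n <- dim(images)[4]
  frames <- lapply(seq_len(n), function(i) to8(images[, , 1, i]))
  spacer <- matrix(0, dim(images)[1], gap)
  out <- frames[[1]]
  for (i in seq_len(n - 1)) out <- cbind(out, spacer, frames[[i + 1]])
  out
}
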