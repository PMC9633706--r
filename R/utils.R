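#' @keywords internal
#' @useDynLib koagan, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# Round half away from zero (base round() is banker's rounding).
round_half_up <- function(x) floor(x + 0.5)

clip8 <- function(x) pmin(pmax(x, 0), 255)

#' Read an 8-bit grayscale PNG as an integer matrix
#'
#' @param path PNG file path.
#' @return Numeric matrix with values in \[0, 255\].
#' @export
read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  round_half_up(a * 255)
}

#' Write an integer matrix in \[0, 255\] as an 8-bit grayscale PNG
#'
#' @param img Numeric matrix, values in \[0, 255\].
#' @param path Output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clip8(round_half_up(img)) / 255, target = path)
  invisible(path)
}

# Symmetric-matrix square root via eigendecomposition; small negative
# eigenvalues (numerical) are clipped at -tol and floored to zero.
sqrtm_sym <- function(S, tol = 1e-6) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- e$values
  lam[lam < 0 & lam > -tol] <- 0
  if (any(lam < 0)) lam <- pmax(lam, 0)
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}
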