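# Shared fixtures, generated in code at test time.

# small in-memory phantom batch as an (s, s, 1, n) array in [-1, 1]
phantom_batch <- function(n, image_size = 64, seed = 1, noise_sd = 6,
                          scale = TRUE) {
  imgs <- array(0, c(image_size, image_size, 1, n))
  for (i in seq_len(n)) {
    p <- phantom_params(image_size = image_size,
                        class_label = if (i %% 2 == 0) "B" else "A",
                        noise_sd = noise_sd, seed = seed * 1000 + i)
    m <- generate_phantom(p)
    imgs[, , 1, i] <- if (scale) m / 127.5 - 1 else m
  }
  imgs
}

# tiny critic: flatten + single linear unit, optionally with fixed weights
linear_critic <- function(shape, weights = NULL, seed = 1) {
  spec <- arch_spec("lin", shape, list(
    koagan:::layer("flatten"),
    koagan:::layer("dense", units = 1L, use_bias = FALSE)))
  net <- build_network(spec, seed = seed)
  if (!is.null(weights)) net$layers[[2]]$W <- matrix(weights, ncol = 1)
  net
}

# deterministic tiny cohort on disk; returns the manifest
tmp_cohort <- function(n_per_class, mix = list(), image_size = 48,
                       seed = 1, dir = withr::local_tempdir(
                         .local_envir = parent.frame())) {
  generate_cohort(n_per_class, dir, mix = mix, image_size = image_size,
                  seed = seed)
}
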