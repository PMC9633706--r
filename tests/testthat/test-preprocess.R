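test_that("histogram equalization matches the cdf mapping", {
  # 1x2 image: cdf(0)=1=cdf_min, cdf(255)=2 -> outputs 0 and 255
  expect_equal(equalize_histogram(matrix(c(0, 255), 1)), matrix(c(0, 255), 1))
  expect_warning(out <- equalize_histogram(matrix(7, 4, 4)), "constant")
  expect_equal(out, matrix(7, 4, 4))
  # brute-force check of the mapping on random 8x8 images
  for (s in 1:5) {
    set.seed(s)
    img <- matrix(sample(0:255, 64, TRUE, prob = stats::runif(256)), 8)
    out <- equalize_histogram(img)
    counts <- tabulate(img + 1, 256)
    cdf <- cumsum(counts)
    cdf_min <- min(cdf[cdf > 0])
    expected <- floor(255 * (cdf[img + 1] - cdf_min) / (64 - cdf_min) + 0.5)
    expect_equal(as.vector(out), as.vector(expected))
    expect_equal(range(out), c(0, 255))
    # monotone in input value
    lut <- floor(255 * (cdf - cdf_min) / (64 - cdf_min) + 0.5)
    expect_true(all(diff(lut) >= 0))
  }
})

test_that("Laplacian focus score matches hand convolution", {
  expect_equal(laplace_focus(matrix(5, 6, 6))$variance, 0)
  expect_false(laplace_focus(matrix(5, 6, 6))$is_focused)
  # 5x5 zero image, single center 1: valid response center 4, cross -1
  m <- matrix(0, 5, 5); m[3, 3] <- 1
  resp <- c(4, 1, 1, 1, 1, 0, 0, 0, 0)  # |3x3 valid response|
  mu <- sum(resp) / 9
  expect_equal(laplace_focus(m)$variance, sum((resp - mu)^2))
  expect_equal(laplace_focus(m)$mean_abs, mu)
  expect_error(laplace_focus(matrix(0, 2, 5)), "3 x 3")
  # same-mode reflect padding keeps the m x n response size
  fs <- laplace_focus(m, mode = "same")
  expect_gt(fs$variance, 0)
})

test_that("grid search reports strict-inequality partitions", {
  g <- grid_search_threshold(c(rep(100, 10), rep(700, 10)))
  expect_equal(g$threshold, c(0, 175, 350, 525))
  expect_equal(g$n_below[g$threshold == 0], 0)
  expect_equal(g$n_below[g$threshold == 350], 10)
  expect_equal(g$n_above[g$threshold == 350], 10)
  expect_error(grid_search_threshold(numeric(0)), "empty")
})

test_that("orientation normalization mirrors iff needed and is involutive", {
  img <- generate_phantom(phantom_params(seed = 2, image_size = 48))
  expect_identical(normalize_orientation(img, "left", "left"), img)
  r <- generate_phantom(phantom_params(seed = 2, image_size = 48,
                                       laterality = "right"))
  expect_identical(normalize_orientation(r, "right", "left"), img)
  flip2 <- normalize_orientation(normalize_orientation(img, "right", "left"),
                                 "right", "left")
  expect_identical(flip2, img)
  expect_error(normalize_orientation(img, NA, "left"), "heuristic")
  expect_identical(normalize_orientation(r, NA, "left", heuristic = TRUE),
                   img)
})

test_that("negative images are detected, inverted, and involutive", {
  img <- generate_phantom(phantom_params(seed = 4, image_size = 64))
  neg <- generate_phantom(phantom_params(seed = 4, image_size = 64,
                                         invert = TRUE))
  di <- detect_and_invert_negative(neg)
  expect_true(di$inverted)
  expect_identical(di$img, img)
  expect_false(detect_and_invert_negative(img)$inverted)
  # double application restores the original polarity
  again <- detect_and_invert_negative(di$img)
  expect_false(again$inverted)
})

test_that("run_preprocess conserves rows and resizes to target", {
  m <- tmp_cohort(6, image_size = 64, seed = 3)
  cfg <- preprocess_config(target_size = 48, focus_threshold = 350)
  res <- run_preprocess(m, cfg)
  expect_equal(nrow(res$accepted) + nrow(res$rejected) + nrow(res$dropped),
               nrow(m))
  expect_equal(nrow(res$dropped), 0)
  expect_equal(nrow(res$accepted), nrow(m))  # sharp phantoms pass at 350

  # artifact rows are dropped before the focus split
  m$artifact[1:4] <- TRUE
  out <- withr::local_tempdir()
  res2 <- run_preprocess(m, cfg, out_dir = out)
  expect_equal(nrow(res2$dropped), 4)
  expect_equal(nrow(res2$accepted) + nrow(res2$rejected), nrow(m) - 4)
  img <- read_gray_png(res2$accepted$processed_path[1])
  expect_equal(dim(img), c(48, 48))

  bad <- m; bad$path[2] <- file.path(out, "nope.png")
  expect_error(run_preprocess(bad, cfg), "missing files.*2")
})

test_that("preprocessing restores inverted inputs to positive polarity", {
  dir <- withr::local_tempdir()
  m <- generate_cohort(4, dir, mix = list(inverted = 0.5), image_size = 64,
                       seed = 8)
  res <- run_preprocess(m, preprocess_config(target_size = 64))
  both <- rbind(res$accepted, res$rejected)
  expect_equal(both$detected_inverted[order(both$path)],
               m$inverted[order(m$path)])
})
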