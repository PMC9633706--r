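# in-memory "image store": paths are keys into a generated pool
make_pool <- function(n_per_class, prefix = "real") {
  data.frame(path = paste0(prefix, "_", rep(c("A", "B"), each = n_per_class),
                           "_", seq_len(2 * n_per_class)),
             class = rep(c("A", "B"), each = n_per_class),
             stringsAsFactors = FALSE)
}

fake_sampler_stub <- function(n, class, seed)
  paste0("fake_", class, "_", seed, "_", seq_len(n))

test_that("dataset builder reproduces the published counts", {
  pool <- make_pool(232)
  ds <- build_datasets(pool, fake_sampler_stub, seed = 1)
  counts <- vapply(ds, function(d) sum(d$role == "train"), 0)
  expect_equal(unname(counts[c("real", "aug50", "aug100", "aug150",
                               "aug200", "replace")]),
               c(200, 300, 400, 500, 600, 200))
  for (d in ds) {
    expect_equal(sum(d$role == "val"), 132)
    expect_equal(sum(d$role == "test"), 132)
    # class balance within every role
    for (role in c("train", "val", "test")) {
      sub <- d[d$role == role, ]
      expect_equal(unname(table(sub$class)[["A"]]), nrow(sub) / 2)
    }
  }
})

test_that("real train/val/test splits are pairwise disjoint and fakes
           extend recursively", {
  pool <- make_pool(240)
  ds <- build_datasets(pool, fake_sampler_stub, seed = 2)
  base <- ds$real
  splits <- split(base$path[base$source == "real"],
                  base$role[base$source == "real"])
  expect_length(intersect(splits$train, splits$val), 0)
  expect_length(intersect(splits$train, splits$test), 0)
  expect_length(intersect(splits$val, splits$test), 0)
  # recursive superset property of augmented training sets
  tr <- function(d) d$path[d$role == "train"]
  expect_true(all(tr(ds$real) %in% tr(ds$aug50)))
  expect_true(all(tr(ds$aug50) %in% tr(ds$aug100)))
  expect_true(all(tr(ds$aug100) %in% tr(ds$aug150)))
  expect_true(all(tr(ds$aug150) %in% tr(ds$aug200)))
  # replacement plan trains on no real image at all
  rp <- ds$replace
  expect_length(intersect(tr(rp), pool$path), 0)
  expect_true(all(rp$source[rp$role == "train"] == "fake"))
  # its fakes are exactly the +100% plan's fakes
  expect_setequal(tr(rp), setdiff(tr(ds$aug100), tr(ds$real)))
  # val/test remain real everywhere
  expect_true(all(rp$source[rp$role != "train"] == "real"))
})

test_that("pool exhaustion raises an explicit shortfall error", {
  expect_error(build_datasets(make_pool(100), fake_sampler_stub),
               "exhausted")
})

# deterministic synthetic image store for desk-scale experiment runs:
# class A/B phantoms at 32 px; fake paths re-use the phantom generator
# with a different seed stream (an "ideal" generator drawing from the
# true class distributions)
path_loader <- function(size = 32) function(paths) {
  out <- array(0, c(size, size, 1, length(paths)))
  for (i in seq_along(paths)) {
    parts <- strsplit(paths[i], "_")[[1]]
    cl <- parts[2]
    seed <- sum(utf8ToInt(paths[i]))
    out[, , 1, i] <- generate_phantom(
      phantom_params(image_size = size, class_label = cl, noise_sd = 10,
                     seed = seed)) / 127.5 - 1
  }
  out
}

test_that("the experiment harness emits a six-row results table", {
  pool <- make_pool(30)
  ds <- build_datasets(pool, fake_sampler_stub, n_train_real = 12,
                       n_val = 8, n_test = 10, seed = 3)
  res <- run_experiment(ds[c("real", "aug200", "replace")],
                        loader = path_loader(32), epochs = 2,
                        batch_size = 16, lr = 1e-3, seed = 1)
  expect_equal(res$dataset, c("real", "aug200", "replace"))
  expect_equal(names(res), c("dataset", "test_accuracy", "test_loss",
                             "val_accuracy_best", "val_loss_best"))
  expect_true(all(is.finite(res$test_accuracy)))
  expect_true(all(res$test_accuracy >= 0 & res$test_accuracy <= 100))
  # determinism under a fixed seed
  res2 <- run_experiment(ds[c("real", "aug200", "replace")],
                         loader = path_loader(32), epochs = 2,
                         batch_size = 16, lr = 1e-3, seed = 1)
  expect_identical(res, res2)
})

test_that("identical validation and test sets give identical metrics", {
  pool <- make_pool(30)
  ds <- build_datasets(pool, fake_sampler_stub, n_train_real = 12,
                       n_val = 8, n_test = 10, seed = 4)
  d <- ds$real
  d_test_as_val <- d[d$role != "test", ]
  dup <- d[d$role == "val", ]
  dup$role <- "test"
  d2 <- rbind(d_test_as_val, dup)
  res <- run_experiment(list(same = d2), loader = path_loader(32),
                        epochs = 2, batch_size = 16, lr = 1e-3, seed = 2)
  expect_equal(res$test_accuracy, res$val_accuracy_best)
  expect_equal(res$test_loss, res$val_loss_best, tolerance = 1e-9)
})

test_that("with separable classes, augmentation does not hurt accuracy", {
  # directional analogue of the augmentation trend: fake sampler draws
  # from the true class distributions; augmented accuracy stays within
  # 2 points of baseline in at least 4 of 5 seeds
  pool <- make_pool(30)
  wins <- 0L
  for (s in 1:5) {
    ds <- build_datasets(pool, fake_sampler_stub, n_train_real = 12,
                         n_val = 8, n_test = 10, seed = s)
    res <- run_experiment(ds[c("real", "aug200")],
                          loader = path_loader(32), epochs = 3,
                          batch_size = 12, lr = 2e-3, seed = s)
    base <- res$test_accuracy[res$dataset == "real"]
    aug <- res$test_accuracy[res$dataset == "aug200"]
    if (aug >= base - 2) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
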