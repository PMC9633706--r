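expert_rows <- function(tp, fn, tn, fp) {
  data.frame(
    truth = c(rep("fake", tp + fn), rep("real", tn + fp)),
    call = c(rep("fake", tp), rep("real", fn),
             rep("real", tn), rep("fake", fp)))
}

test_that("balanced accuracy follows the mean-recall definition", {
  s <- score_expert(expert_rows(tp = 3, fn = 1, tn = 1, fp = 1))
  expect_equal(s$balanced_accuracy, 100 * (3 / 4 + 1 / 2) / 2)  # 62.5
  expect_equal(s$accuracy_fake, 75)
  expect_equal(s$accuracy_real, 50)
  expect_equal(s$precision, 100 * 3 / 4)
  expect_equal(s$f1, 100 * 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4))
  perfect <- score_expert(expert_rows(30, 0, 30, 0))
  expect_equal(perfect$balanced_accuracy, 100)
  expect_equal(perfect$f1, 100)
  # undefined (not zero) precision when nothing is called positive
  s0 <- score_expert(expert_rows(0, 5, 5, 0))
  expect_true(is.na(s0$precision))
  expect_error(score_expert(data.frame(truth = "fake", call = "missing")),
               "no answered")
})

test_that("balanced accuracy equals plain accuracy on balanced tables and
           is invariant to class duplication", {
  for (s in 1:20) {
    set.seed(s)
    rows <- data.frame(truth = rep(c("fake", "real"), each = 15),
                       call = sample(c("fake", "real"), 30, TRUE))
    sc <- score_expert(rows)
    plain <- 100 * mean(rows$truth == rows$call)
    expect_equal(sc$balanced_accuracy, plain, tolerance = 1e-12)
    # duplicating one class's rows leaves balanced accuracy unchanged
    dup <- rbind(rows, rows[rows$truth == "fake", ])
    expect_equal(score_expert(dup)$balanced_accuracy, sc$balanced_accuracy,
                 tolerance = 1e-12)
    # per-class accuracies average exactly to the balanced accuracy
    expect_equal((sc$accuracy_fake + sc$accuracy_real) / 2,
                 sc$balanced_accuracy)
  }
})

test_that("missing calls shrink the denominator, not the score", {
  rows <- expert_rows(3, 1, 1, 1)
  rows$call[1] <- "missing"
  s <- score_expert(rows)
  expect_equal(s$n_answered, 5)
  expect_equal(s$balanced_accuracy, 100 * (2 / 3 + 1 / 2) / 2)
})

test_that("group summaries average expert scores with sample SDs", {
  tab <- simulate_survey_responses(n_ortho = 1, n_radio = 1, n_images = 20,
                                   detection_accuracy = 1, seed = 2)
  # force known accuracies: expert E1 60%, E2 70% on 20 items
  flip <- function(v) ifelse(v == "real", "fake", "real")
  i1 <- which(tab$expert_id == "E1")[1:8]
  i2 <- which(tab$expert_id == "E2")[1:6]
  tab$call[i1] <- flip(tab$call[i1])
  tab$call[i2] <- flip(tab$call[i2])
  g <- group_summary(tab)
  all_row <- g[g$group == "all", ]
  expect_equal(all_row$n_experts, 2)
  # 60 and 70 -> mean 65, sample SD sqrt(50)
  expect_equal(all_row$balanced_accuracy_mean, 65, tolerance = 1e-9)
  expect_equal(all_row$balanced_accuracy_sd, sqrt(50), tolerance = 1e-9)
  one <- g[g$group == "orthopedic", ]
  expect_equal(one$n_experts, 1)
  expect_equal(one$balanced_accuracy_sd, 0)  # single expert: SD reported 0
})

test_that("disqualified specialties are excluded from every group", {
  tab <- simulate_survey_responses(n_ortho = 2, n_radio = 2, n_images = 12,
                                   detection_accuracy = 1, seed = 3)
  dentist <- tab[tab$expert_id == "E1", ]
  dentist$expert_id <- "E9"
  dentist$specialty <- "other"
  dentist$call <- ifelse(dentist$truth == "real", "fake", "real")
  g <- group_summary(rbind(tab, dentist))
  expect_equal(g$n_experts[g$group == "all"], 4)
  expect_equal(g$balanced_accuracy_mean[g$group == "all"], 100)
})

test_that("survey tables round-trip through CSV unchanged", {
  tab <- simulate_survey_responses(n_ortho = 5, n_radio = 10,
                                   missing_rate = 0.1, seed = 4)
  path <- file.path(withr::local_tempdir(), "responses.csv")
  utils::write.csv(tab, path, row.names = FALSE)
  back <- utils::read.csv(path, stringsAsFactors = FALSE)
  expect_equal(back, tab, ignore_attr = TRUE)
  expect_identical(group_summary(back), group_summary(tab))
})

test_that("group means equal an independent brute-force recomputation", {
  tab <- simulate_survey_responses(n_ortho = 3, n_radio = 4,
                                   detection_accuracy = 0.6,
                                   missing_rate = 0.05, seed = 5)
  g <- group_summary(tab)
  # independent pass over raw rows
  brute <- vapply(unique(tab$expert_id), function(e) {
    r <- tab[tab$expert_id == e & tab$call != "missing", ]
    rf <- mean(r$call[r$truth == "fake"] == "fake")
    rr <- mean(r$call[r$truth == "real"] == "real")
    100 * (rf + rr) / 2
  }, 0)
  expect_equal(g$balanced_accuracy_mean[g$group == "all"], mean(brute),
               tolerance = 1e-9)
  expect_equal(g$balanced_accuracy_sd[g$group == "all"], stats::sd(brute),
               tolerance = 1e-9)
})

test_that("rating agreement maps grades 0-1 / 2-4 and excludes missing", {
  # an expert rating every image in-class agrees 100% in every cell
  tab <- simulate_survey_responses(n_ortho = 1, n_radio = 0, n_images = 24,
                                   rating_accuracy = 1, seed = 6)
  ra <- rating_agreement(tab)
  cols <- grep("_mean$", names(ra), value = TRUE)
  expect_true(all(ra[ra$group == "all", cols] == 100))
  # one missing rating shrinks that expert's denominator
  tab2 <- tab
  miss <- which(tab2$truth == "real" & tab2$truth_kl_class == "KL01")[1]
  tab2$rated_kl[miss] <- NA
  ra2 <- rating_agreement(tab2)
  expect_true(all(ra2[ra2$group == "all", cols] == 100))
})

test_that("random rating converges to the class-share agreement rates", {
  # uniform ratings over 0-4 agree with KL01 2/5 and KL234 3/5 of the time
  set.seed(7)
  n <- 1e4
  kl01_agree <- mean(sample(0:4, n, TRUE) <= 1)
  kl234_agree <- mean(sample(0:4, n, TRUE) >= 2)
  se <- sqrt(0.4 * 0.6 / n)
  expect_lt(abs(kl01_agree - 0.4), 3 * se)
  expect_lt(abs(kl234_agree - 0.6), 3 * se)
  # the pipeline reproduces those rates for a uniform rater
  tab <- simulate_survey_responses(n_ortho = 1, n_radio = 0,
                                   n_images = 4000, rating_accuracy = 0.4,
                                   seed = 8)
  ra <- rating_agreement(tab)
  expect_equal(ra$fake_KL01_mean[ra$group == "all"], 100 * 0.4,
               tolerance = 0.15)
})
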