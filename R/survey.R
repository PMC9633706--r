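# Scoring of real-vs-DeepFake survey responses: balanced accuracy,
# precision/F1, per-class accuracy, and KL rating agreement, aggregated
# per expert group with sample standard deviations.

#' Score a single expert's real/fake calls
#'
#' Missing calls are excluded (responses are not imputed; the balanced
#' accuracy metric absorbs the resulting class imbalance). Balanced
#' accuracy is the mean of the two per-class recalls
#' `(TP/(TP+FN) + TN/(TN+FP)) / 2`; with equal answered class counts it
#' reduces to plain accuracy. Precision and F1 with a zero denominator are
#' reported as `NA` (undefined), never 0.
#'
#' @param rows Response rows for one expert: data.frame with `truth` and
#'   `call` columns, values in `"real"`/`"fake"` (`call` may be
#'   `"missing"`/`NA`).
#' @param positive_class Class treated as positive for precision/F1
#'   (default `"fake"`, the detection task).
#' @return An `expert_score` list: `balanced_accuracy`, `accuracy_fake`,
#'   `accuracy_real`, `precision`, `f1` (percentages), `n_answered`.
#' @export
score_expert <- function(rows, positive_class = c("fake", "real")) {
  positive_class <- match.arg(positive_class)
  ans <- rows[!is.na(rows$call) & rows$call != "missing", , drop = FALSE]
  if (nrow(ans) == 0) stop("expert has no answered items")
  neg <- setdiff(c("fake", "real"), positive_class)
  tp <- sum(ans$truth == positive_class & ans$call == positive_class)
  fn <- sum(ans$truth == positive_class & ans$call == neg)
  tn <- sum(ans$truth == neg & ans$call == neg)
  fp <- sum(ans$truth == neg & ans$call == positive_class)
  recall_pos <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  recall_neg <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  balacc <- mean(c(recall_pos, recall_neg), na.rm = TRUE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall_pos) &&
            (precision + recall_pos) > 0)
    2 * precision * recall_pos / (precision + recall_pos) else NA_real_
  acc_fake <- if (positive_class == "fake") recall_pos else recall_neg
  acc_real <- if (positive_class == "fake") recall_neg else recall_pos
  structure(list(balanced_accuracy = 100 * balacc,
                 accuracy_fake = 100 * acc_fake,
                 accuracy_real = 100 * acc_real,
                 precision = 100 * precision, f1 = 100 * f1,
                 n_answered = nrow(ans)),
            class = "expert_score")
}

qualified <- function(table) {
  table[table$specialty %in% c("orthopedic", "radiologist"), , drop = FALSE]
}

#' Group summary of expert detection scores
#'
#' Scores each qualifying expert individually ([score_expert()]), then
#' reports the unweighted mean and sample (n-1) standard deviation per
#' specialty group and over all qualifying experts. Experts with a
#' disqualifying specialty (anything outside orthopedic/radiologist) are
#' excluded. Single-expert groups report SD 0.
#'
#' @param table Survey response table: columns `expert_id`, `specialty`,
#'   `image_id`, `truth`, `call` (and optionally the KL rating columns).
#' @param positive_class Passed to [score_expert()].
#' @return `data.frame` with one row per group (`orthopedic`,
#'   `radiologist`, `all`) and mean/SD columns per metric.
#' @export
group_summary <- function(table, positive_class = "fake") {
  table <- qualified(table)
  if (nrow(table) == 0) stop("no qualifying experts")
  experts <- unique(table[, c("expert_id", "specialty")])
  scores <- lapply(experts$expert_id, function(e)
    score_expert(table[table$expert_id == e, , drop = FALSE],
                 positive_class))
  metrics <- c("balanced_accuracy", "accuracy_fake", "accuracy_real",
               "precision", "f1")
  m <- do.call(rbind, lapply(scores, function(s)
    unlist(s[metrics])))
  groups <- list(orthopedic = experts$specialty == "orthopedic",
                 radiologist = experts$specialty == "radiologist",
                 all = rep(TRUE, nrow(experts)))
  out <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (!any(sel)) return(NULL)
    mm <- m[sel, , drop = FALSE]
    mu <- colMeans(mm, na.rm = TRUE)
    sdv <- apply(mm, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) 0 else stats::sd(v)
    })
    df <- data.frame(group = g, n_experts = sum(sel))
    for (k in metrics) {
      df[[paste0(k, "_mean")]] <- mu[[k]]
      df[[paste0(k, "_sd")]] <- sdv[[k]]
    }
    df
  })
  empty <- vapply(out, is.null, TRUE)
  if (any(empty)) warning("empty expert group omitted: ",
                          paste(names(groups)[empty], collapse = ", "))
  do.call(rbind, out[!empty])
}

kl_to_class <- function(kl) ifelse(kl <= 1, "KL01", "KL234")

#' KL rating agreement per group
#'
#' Per expert and per cell (truth source real/fake crossed with true
#' severity class KL01/KL234), the fraction of rated images whose rated
#' KL class (grades 0-1 map to KL01, 2-4 to KL234) matches the true class.
#' Missing ratings are excluded from that expert's denominator; an expert
#' with no ratings in a cell is excluded from that cell's group mean.
#' Group values are means over experts with sample SDs.
#'
#' @param table Survey response table with `truth`, `truth_kl_class`
#'   (`"KL01"`/`"KL234"`) and `rated_kl` (integer 0-4 or `NA`) columns.
#' @return `data.frame`: one row per group, mean/SD/n columns for each of
#'   the four cells.
#' @export
rating_agreement <- function(table) {
  table <- qualified(table)
  rated <- table[!is.na(table$rated_kl), , drop = FALSE]
  if (nrow(rated) == 0) stop("no ratings present")
  rated$agree <- kl_to_class(rated$rated_kl) == rated$truth_kl_class
  cells <- expand.grid(truth = c("fake", "real"),
                       kl = c("KL01", "KL234"), stringsAsFactors = FALSE)
  experts <- unique(rated[, c("expert_id", "specialty")])
  per_expert <- lapply(seq_len(nrow(cells)), function(ci) {
    sub <- rated[rated$truth == cells$truth[ci] &
                   rated$truth_kl_class == cells$kl[ci], , drop = FALSE]
    vapply(experts$expert_id, function(e) {
      v <- sub$agree[sub$expert_id == e]
      if (length(v) == 0) NA_real_ else 100 * mean(v)
    }, 0)
  })
  groups <- list(orthopedic = experts$specialty == "orthopedic",
                 radiologist = experts$specialty == "radiologist",
                 all = rep(TRUE, nrow(experts)))
  out <- lapply(names(groups), function(g) {
    sel <- groups[[g]]
    if (!any(sel)) return(NULL)
    df <- data.frame(group = g)
    for (ci in seq_len(nrow(cells))) {
      v <- per_expert[[ci]][sel]
      v <- v[!is.na(v)]
      tag <- paste0(cells$truth[ci], "_", cells$kl[ci])
      df[[paste0(tag, "_mean")]] <- if (length(v)) mean(v) else NA_real_
      df[[paste0(tag, "_sd")]] <- if (length(v) >= 2) stats::sd(v) else 0
      df[[paste0(tag, "_n")]] <- length(v)
    }
    df
  })
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Simulate a survey response table
#'
#' Fixture generator: experts with configurable detection accuracy and
#' rating accuracy answer a balanced set of real and DeepFake images from
#' both severity classes; responses and ratings can go missing at a given
#' rate.
#'
#' @param n_ortho,n_radio Experts per specialty.
#' @param n_images Total images (half real/half fake, half KL01/KL234).
#' @param detection_accuracy Probability an expert calls an image
#'   correctly.
#' @param rating_accuracy Probability the rated KL class matches truth
#'   (within-class grade drawn uniformly).
#' @param missing_rate Probability a call or rating is missing.
#' @param seed RNG seed.
#' @return A survey response `data.frame`.
#' @export
simulate_survey_responses <- function(n_ortho = 5, n_radio = 10,
                                      n_images = 60,
                                      detection_accuracy = 0.6,
                                      rating_accuracy = 0.7,
                                      missing_rate = 0, seed = 1L) {
  with_seed(seed, {
    imgs <- data.frame(
      image_id = seq_len(n_images),
      truth = rep(c("real", "fake"), length.out = n_images),
      truth_kl_class = rep(c("KL01", "KL01", "KL234", "KL234"),
                           length.out = n_images))
    experts <- data.frame(
      expert_id = paste0("E", seq_len(n_ortho + n_radio)),
      specialty = c(rep("orthopedic", n_ortho), rep("radiologist", n_radio)))
    rows <- lapply(seq_len(nrow(experts)), function(i) {
      correct <- stats::runif(n_images) < detection_accuracy
      call <- ifelse(correct, imgs$truth,
                     ifelse(imgs$truth == "real", "fake", "real"))
      call[stats::runif(n_images) < missing_rate] <- "missing"
      rate_ok <- stats::runif(n_images) < rating_accuracy
      in_class <- ifelse(imgs$truth_kl_class == "KL01",
                         sample(0:1, n_images, TRUE),
                         sample(2:4, n_images, TRUE))
      out_class <- ifelse(imgs$truth_kl_class == "KL01",
                          sample(2:4, n_images, TRUE),
                          sample(0:1, n_images, TRUE))
      rated <- ifelse(rate_ok, in_class, out_class)
      rated[stats::runif(n_images) < missing_rate] <- NA
      data.frame(expert_id = experts$expert_id[i],
                 specialty = experts$specialty[i], imgs,
                 call = call, rated_kl = rated)
    })
    do.call(rbind, rows)
  })
}
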