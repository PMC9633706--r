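# Augmentation / anonymization experiment: six dataset plans built from a
# scarce real pool plus a generator, a transfer classifier, and a
# best-validation-loss training harness.

#' Build the six augmentation/anonymization dataset manifests
#'
#' Reproduces the published dataset design: a scarce baseline of real
#' images (train 100 per class, validation and test 66 per class), four
#' augmented plans that recursively extend the baseline training set with
#' randomly generated fakes (+50%, +100%, +150%, +200% of the baseline
#' training count), and a replacement plan whose training set is the
#' +100% plan's fakes only (anonymization by replacement). Validation and
#' test sets are always real and shared across plans; the three real
#' subsets are pairwise disjoint.
#'
#' @param real_pool `data.frame` with `path` and `class` columns (two
#'   classes); needs at least `n_train_real + n_val + n_test` rows per
#'   class (464 total at the defaults).
#' @param fake_sampler Function `(n, class, seed)` returning `n` fake
#'   image identifiers/paths (character) for the class.
#' @param n_train_real,n_val,n_test Per-class counts.
#' @param seed Selection seed.
#' @return Named list of six manifests (`real`, `aug50`, `aug100`,
#'   `aug150`, `aug200`, `replace`), each a `data.frame` with `path`,
#'   `class`, `source` (real/fake) and `role` (train/val/test).
#' @export
build_datasets <- function(real_pool, fake_sampler, n_train_real = 100,
                           n_val = 66, n_test = 66, seed = 1L) {
  stopifnot(is.data.frame(real_pool),
            all(c("path", "class") %in% names(real_pool)))
  classes <- sort(unique(real_pool$class))
  if (length(classes) != 2) stop("real_pool must contain exactly 2 classes")
  need <- n_train_real + n_val + n_test
  with_seed(seed, {
    parts <- lapply(classes, function(cl) {
      rows <- real_pool[real_pool$class == cl, , drop = FALSE]
      if (nrow(rows) < need)
        stop("real pool exhausted for class ", cl, ": need ", need,
             ", have ", nrow(rows))
      idx <- sample.int(nrow(rows), need)
      list(train = rows[idx[seq_len(n_train_real)], ],
           val = rows[idx[n_train_real + seq_len(n_val)], ],
           test = rows[idx[n_train_real + n_val + seq_len(n_test)], ])
    })
    names(parts) <- classes
    mk <- function(rows, source, role)
      data.frame(path = rows$path, class = rows$class, source = source,
                 role = role, stringsAsFactors = FALSE)
    base_train <- do.call(rbind, lapply(parts, function(p)
      mk(p$train, "real", "train")))
    valtest <- rbind(
      do.call(rbind, lapply(parts, function(p) mk(p$val, "real", "val"))),
      do.call(rbind, lapply(parts, function(p) mk(p$test, "real", "test"))))
    rownames(base_train) <- rownames(valtest) <- NULL
    # fakes added recursively: each augmented train set extends the last
    fake_rows <- function(n_per_class, step_seed) do.call(rbind,
      lapply(classes, function(cl)
        data.frame(path = fake_sampler(n_per_class, cl, step_seed),
                   class = cl, source = "fake", role = "train",
                   stringsAsFactors = FALSE)))
    step <- n_train_real / 2  # +50% of the per-class baseline per step
    fakes <- list()
    acc <- NULL
    for (i in 1:4) {
      acc <- rbind(acc, fake_rows(step, seed + i))
      fakes[[i]] <- acc
    }
    datasets <- list(
      real = rbind(base_train, valtest),
      aug50 = rbind(base_train, fakes[[1]], valtest),
      aug100 = rbind(base_train, fakes[[2]], valtest),
      aug150 = rbind(base_train, fakes[[3]], valtest),
      aug200 = rbind(base_train, fakes[[4]], valtest),
      replace = rbind(fakes[[2]], valtest))
    lapply(datasets, function(d) { rownames(d) <- NULL; d })
  })
}

bce_with_logits <- function(logits, y) {
  # numerically stable binary cross-entropy on raw scores
  mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

#' Train a binary classifier with best-validation-loss checkpointing
#'
#' Adam training of a sigmoid-output network on (image, label) data;
#' after each epoch the validation loss is evaluated and the weights at
#' the best (lowest) validation loss are retained for testing.
#'
#' @param net An `nn_network` whose final layer emits one logit (a
#'   trailing `sigmoid` layer, if present, is applied outside the loss).
#' @param x_train,x_val,x_test Arrays (h, w, c, n).
#' @param y_train,y_val,y_test 0/1 label vectors.
#' @param epochs,batch_size,lr Training hyperparameters.
#' @param seed RNG seed.
#' @return List with `test_accuracy`, `test_loss` (at best validation
#'   loss), `val_accuracy_best`, `val_loss_best`, and the trained `net`.
#' @export
train_classifier <- function(net, x_train, y_train, x_val, y_val,
                             x_test, y_test, epochs = 5, batch_size = 32,
                             lr = 1e-4, seed = 1L) {
  n <- dim(x_train)[4]
  if (n == 0) stop("empty training set")
  has_sigmoid <- net$layers[[length(net$layers)]]$type == "sigmoid"
  logits_of <- function(net, x, training = FALSE) {
    # evaluate up to the logit (drop a trailing sigmoid for the loss)
    nn <- net
    if (has_sigmoid) nn$layers <- nn$layers[-length(nn$layers)]
    net_forward(nn, x, training = training)
  }
  evaluate <- function(net, x, y) {
    z <- as.vector(logits_of(net, x)$out)
    list(loss = bce_with_logits(z, y),
         accuracy = 100 * mean((z > 0) == (y == 1)))
  }
  opt <- adam_state(net)
  best <- list(val_loss = Inf)
  with_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (b in split(ord, ceiling(seq_along(ord) / batch_size))) {
        if (length(b) < 2) next
        xb <- x_train[, , , b, drop = FALSE]
        yb <- y_train[b]
        fw <- logits_of(net, xb, training = TRUE)
        z <- as.vector(fw$out)
        if (!all(is.finite(z))) stop("non-finite logits at epoch ", ep)
        p <- 1 / (1 + exp(-z))
        dz <- matrix((p - yb) / length(b), 1)
        nn <- net
        if (has_sigmoid) nn$layers <- nn$layers[-length(nn$layers)]
        grads <- net_backward(nn, fw$caches, dz)$grads
        if (has_sigmoid) grads <- c(grads, list(NULL))
        res <- adam_update(net, grads, opt, lr = lr, beta1 = 0.9,
                           beta2 = 0.999, schedule = "constant")
        net <- res$net; opt <- res$state
      }
      ev <- evaluate(net, x_val, y_val)
      if (ev$loss < best$val_loss)
        best <- list(val_loss = ev$loss, val_acc = ev$accuracy, net = net)
    }
  })
  te <- evaluate(best$net, x_test, y_test)
  list(test_accuracy = te$accuracy, test_loss = te$loss,
       val_accuracy_best = best$val_acc, val_loss_best = best$val_loss,
       net = best$net)
}

#' Run the augmentation/anonymization experiment
#'
#' Trains one classifier per dataset plan and reports, per dataset, the
#' test accuracy and loss at the best-validation-loss checkpoint plus the
#' best validation accuracy and loss — the four columns of the published
#' results table.
#'
#' @param datasets Named list of manifests from [build_datasets()].
#' @param spec Classifier architecture (default [small_classifier_spec()]
#'   sized to the images; pass [transfer_spec()] for the full-scale
#'   variant).
#' @param loader Function mapping a character vector of manifest paths to
#'   an (h, w, c, n) array in \[-1, 1\].
#' @param label_of Function mapping the manifest `class` column to 0/1
#'   (default: second sorted class level is 1).
#' @param epochs,batch_size,lr,seed Training settings.
#' @return `data.frame` with columns `dataset`, `test_accuracy`,
#'   `test_loss`, `val_accuracy_best`, `val_loss_best`.
#' @export
run_experiment <- function(datasets, spec = NULL, loader,
                           label_of = NULL, epochs = 5, batch_size = 32,
                           lr = 1e-4, seed = 1L) {
  stopifnot(length(datasets) >= 1)
  rows <- vector("list", length(datasets))
  for (i in seq_along(datasets)) {
    d <- datasets[[i]]
    if (nrow(d) == 0) stop("empty dataset: ", names(datasets)[i])
    if (is.null(label_of)) {
      lv <- sort(unique(d$class))
      label_of <- function(cl) as.numeric(cl == lv[2])
    }
    get <- function(role) {
      sub <- d[d$role == role, , drop = FALSE]
      list(x = loader(sub$path), y = label_of(sub$class))
    }
    tr <- get("train"); va <- get("val"); te <- get("test")
    if (is.null(spec))
      spec <- small_classifier_spec(input_size = dim(tr$x)[1])
    net <- build_network(spec, seed = seed)
    res <- train_classifier(net, tr$x, tr$y, va$x, va$y, te$x, te$y,
                            epochs = epochs, batch_size = batch_size,
                            lr = lr, seed = seed + i)
    rows[[i]] <- data.frame(dataset = names(datasets)[i],
                            test_accuracy = res$test_accuracy,
                            test_loss = res$test_loss,
                            val_accuracy_best = res$val_accuracy_best,
                            val_loss_best = res$val_loss_best)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
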