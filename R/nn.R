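# Minimal CPU neural-network engine: declarative layer specs, shape
# inference, parameter counting, forward/backward passes and Adam.
#
# Tensor layout: convolutional activations are 4-D arrays (h, w, c, n);
# dense activations are matrices (features, n). All layers are implemented
# with vectorized slice arithmetic and BLAS matrix products.

layer <- function(type, ...) c(list(type = type), list(...))

#' Declarative network architecture
#'
#' An `arch_spec` is a named list of layers with an input shape; it is the
#' single source of truth for shape inference, parameter counting and
#' network materialization.
#'
#' @param name Architecture name.
#' @param input_shape Integer vector: a single length for dense input or
#'   `c(h, w, c)` for image input.
#' @param layers List of layer descriptions (see `layer()` helpers in the
#'   package sources).
#' @return An `arch_spec` object with per-layer inferred `output_shape`.
#' @export
arch_spec <- function(name, input_shape, layers) {
  spec <- structure(list(name = name, input_shape = input_shape,
                         layers = layers), class = "arch_spec")
  infer_shapes(spec)
}

conv_out_len <- function(len, k, s, padding) {
  if (padding == "same") ceiling(len / s) else floor((len - k) / s) + 1L
}

infer_shapes <- function(spec) {
  shape <- spec$input_shape
  for (i in seq_along(spec$layers)) {
    l <- spec$layers[[i]]
    shape <- switch(l$type,
      dense = {
        stopifnot(length(shape) == 1)
        l$input_dim <- shape
        l$units
      },
      batchnorm = {
        # per-channel over image input, per-feature over flat input
        l$features <- if (length(shape) == 3) shape[3] else prod(shape)
        shape
      },
      elu = , tanh = , sigmoid = , dropout = shape,
      reshape = { stopifnot(prod(shape) == prod(l$shape)); l$shape },
      flatten = prod(shape),
      upsample = c(shape[1:2] * l$factor, shape[3]),
      zeropad = c(shape[1:2] + 2L * l$p, shape[3]),
      crop = c(shape[1:2] - 2L * l$p, shape[3]),
      maxpool = c(shape[1] %/% l$size, shape[2] %/% l$size, shape[3]),
      conv = {
        stopifnot(length(shape) == 3)
        l$input_channels <- shape[3]
        c(conv_out_len(shape[1], l$kernel, l$stride, l$padding),
          conv_out_len(shape[2], l$kernel, l$stride, l$padding), l$filters)
      },
      stop("unknown layer type: ", l$type))
    l$output_shape <- shape
    spec$layers[[i]] <- l
  }
  spec
}

layer_param_counts <- function(l) {
  trainable_layer <- !isFALSE(l$trainable)
  counts <- switch(l$type,
    dense = {
      w <- l$input_dim * l$units
      b <- if (isFALSE(l$use_bias)) 0L else l$units
      c(trainable = w + b, non_trainable = 0L)
    },
    conv = {
      w <- l$kernel^2 * l$input_channels * l$filters
      b <- if (isFALSE(l$use_bias)) 0L else l$filters
      c(trainable = w + b, non_trainable = 0L)
    },
    batchnorm = c(trainable = 2L * l$features, non_trainable = 2L * l$features),
    c(trainable = 0L, non_trainable = 0L))
  if (!trainable_layer) {
    counts <- c(trainable = 0L, non_trainable = unname(sum(counts)))
  }
  counts
}

#' Count the parameters of an architecture
#'
#' @param spec An [arch_spec()] (or a materialized network, whose counts
#'   come from the actual weight arrays).
#' @return List with `total`, `trainable`, `non_trainable` and a per-layer
#'   `data.frame`.
#' @export
count_params <- function(spec) {
  if (inherits(spec, "nn_network")) return(count_params_network(spec))
  stopifnot(inherits(spec, "arch_spec"))
  per <- t(vapply(spec$layers, layer_param_counts, numeric(2)))
  df <- data.frame(layer = vapply(spec$layers, `[[`, "", "type"),
                   trainable = per[, "trainable"],
                   non_trainable = per[, "non_trainable"])
  list(total = sum(per), trainable = sum(per[, "trainable"]),
       non_trainable = sum(per[, "non_trainable"]), per_layer = df)
}

count_params_network <- function(net) {
  tr <- 0; ntr <- 0
  for (l in net$layers) {
    frozen <- isFALSE(l$trainable)
    for (nm in c("W", "b", "gamma", "beta")) {
      if (!is.null(l[[nm]])) {
        if (frozen) ntr <- ntr + length(l[[nm]]) else tr <- tr + length(l[[nm]])
      }
    }
    for (nm in c("moving_mean", "moving_var"))
      if (!is.null(l[[nm]])) ntr <- ntr + length(l[[nm]])
  }
  list(total = tr + ntr, trainable = tr, non_trainable = ntr)
}

glorot <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

#' Materialize a network from an architecture spec
#'
#' Initializes weight arrays (Glorot-uniform, seeded) for every layer.
#'
#' @param spec An [arch_spec()].
#' @param seed Integer seed for weight initialization.
#' @return An `nn_network` object.
#' @export
build_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "arch_spec"))
  with_seed(seed, {
    layers <- lapply(spec$layers, function(l) {
      if (l$type == "dense") {
        l$W <- glorot(l$input_dim, l$units, c(l$input_dim, l$units))
        if (!isFALSE(l$use_bias)) l$b <- numeric(l$units)
      } else if (l$type == "conv") {
        fan_in <- l$kernel^2 * l$input_channels
        fan_out <- l$kernel^2 * l$filters
        l$W <- glorot(fan_in, fan_out,
                      c(l$kernel, l$kernel, l$input_channels, l$filters))
        if (!isFALSE(l$use_bias)) l$b <- numeric(l$filters)
      } else if (l$type == "batchnorm") {
        l$gamma <- rep(1, l$features); l$beta <- numeric(l$features)
        l$moving_mean <- numeric(l$features); l$moving_var <- rep(1, l$features)
        if (is.null(l$eps)) l$eps <- 1e-3
        if (is.null(l$momentum)) l$momentum <- 0.99
      }
      l
    })
    structure(list(name = spec$name, input_shape = spec$input_shape,
                   layers = layers, spec = spec),
              class = "nn_network")
  })
}

# Public tensor layout is (h, w, c, n); internally the network uses
# channel-first (c, h, w, n) so that every channel-major matrix view is a
# free reshape instead of an aperm copy.
as_batch <- function(x, input_shape) {
  if (length(input_shape) == 1) {
    if (is.matrix(x)) x else matrix(x, length(x), 1)
  } else {
    if (length(dim(x)) == 4) x else array(x, c(input_shape, 1))
  }
}

to_internal <- function(x) if (length(dim(x)) == 4) aperm(x, c(3, 1, 2, 4)) else x
to_public <- function(x) if (length(dim(x)) == 4) aperm(x, c(2, 3, 1, 4)) else x

# zero-pad the spatial dims (2, 3) of a (c, h, w, n) tensor
pad_zeros <- function(x, pt, pb, pl, pr) {
  d <- dim(x)
  out <- array(0, c(d[1], d[2] + pt + pb, d[3] + pl + pr, d[4]))
  out[, pt + seq_len(d[2]), pl + seq_len(d[3]), ] <- x
  out
}

conv_pads <- function(len, k, s, padding) {
  if (padding == "valid") return(c(0L, 0L))
  out <- ceiling(len / s)
  total <- max((out - 1) * s + k - len, 0)
  c(total %/% 2, total - total %/% 2)
}

# x is channel-first (c, h, w, n)
conv_forward <- function(l, x) {
  d <- dim(x); cc <- d[1]; h <- d[2]; w <- d[3]; n <- d[4]
  k <- l$kernel; s <- l$stride
  ph <- conv_pads(h, k, s, l$padding); pw <- conv_pads(w, k, s, l$padding)
  xp <- if (sum(ph, pw) > 0) pad_zeros(x, ph[1], ph[2], pw[1], pw[2]) else x
  oh <- conv_out_len(h, k, s, l$padding); ow <- conv_out_len(w, k, s, l$padding)
  f <- l$filters
  out <- conv_fwd_cf(xp, dim(xp), l$W, dim(l$W), l$b, s, oh, ow)
  list(out = out, xp = xp,
       dims = list(h = h, w = w, oh = oh, ow = ow, ph = ph, pw = pw))
}

conv_backward <- function(l, cache, dout, need_param_grads = TRUE) {
  dm <- cache$dims; s <- l$stride
  xp <- cache$xp
  res <- conv_bwd_cf(xp, dim(xp), l$W, dim(l$W), dout, s, dm$oh, dm$ow,
                     need_param_grads, !is.null(l$b))
  dx <- res$dxp[, dm$ph[1] + seq_len(dm$h), dm$pw[1] + seq_len(dm$w), ,
                drop = FALSE]
  grads <- if (need_param_grads) list(W = res$dW, b = res$db)
  list(dx = dx, grads = grads)
}

bn_forward <- function(l, x, training) {
  conv_in <- length(dim(x)) == 4
  if (conv_in) { d <- dim(x); xm <- matrix(x, d[1], prod(d[-1])) } else xm <- x
  nb <- ncol(xm)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    va <- rowMeans(xc^2)
  } else {
    mu <- l$moving_mean; va <- l$moving_var
    xc <- xm - mu
  }
  inv_sd <- 1 / sqrt(va + l$eps)
  xhat <- xc * inv_sd
  outm <- l$gamma * xhat + l$beta
  out <- if (conv_in) array(outm, d) else outm
  list(out = out,
       cache = list(xhat = xhat, xc = xc, inv_sd = inv_sd, nb = nb,
                    conv_in = conv_in, d = if (conv_in) d else NULL,
                    batch_mu = if (training) mu else NULL,
                    batch_var = if (training) va else NULL,
                    training = training))
}

bn_backward <- function(l, cache, dout, need_param_grads = TRUE) {
  dm <- if (cache$conv_in) matrix(dout, cache$d[1], prod(cache$d[-1])) else dout
  g <- l$gamma
  dgamma <- rowSums(dm * cache$xhat)
  dbeta <- rowSums(dm)
  if (cache$training) {
    nb <- cache$nb
    dxhat <- dm * g
    dx <- (cache$inv_sd / nb) *
      (nb * dxhat - rowSums(dxhat) -
         cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dx <- dm * (g * cache$inv_sd)
  }
  if (cache$conv_in) dx <- array(dx, cache$d)
  list(dx = dx,
       grads = if (need_param_grads) list(gamma = dgamma, beta = dbeta))
}

elu_fn <- function(x, a) ifelse(x > 0, x, a * (exp(x) - 1))

#' Forward pass through a network
#'
#' @param net An `nn_network`.
#' @param x Input batch: matrix (features, n) or array (h, w, c, n); single
#'   samples are promoted to a batch of one.
#' @param training Training mode (batch statistics for batch norm, active
#'   dropout).
#' @param dropout If `FALSE`, dropout layers are identity even in training
#'   mode (used by the gradient-penalty evaluation).
#' @return List with `out` and per-layer `caches` for [net_backward()].
#' @export
net_forward <- function(net, x, training = FALSE, dropout = training) {
  x <- to_internal(as_batch(x, net$input_shape))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    res <- switch(l$type,
      dense = {
        out <- crossprod(l$W, x)
        if (!is.null(l$b)) out <- out + l$b
        list(out = out, cache = x)
      },
      conv = { cf <- conv_forward(l, x); list(out = cf$out, cache = cf) },
      batchnorm = { bf <- bn_forward(l, x, training)
                    list(out = bf$out, cache = bf$cache) },
      elu = {
        neg <- x <= 0
        out <- x
        out[neg] <- l$alpha * (exp(x[neg]) - 1)
        list(out = out, cache = list(neg = neg, x_neg = x[neg]))
      },
      tanh = { out <- tanh(x); list(out = out, cache = out) },
      sigmoid = { out <- 1 / (1 + exp(-x)); list(out = out, cache = out) },
      dropout = {
        if (training && dropout && l$rate > 0) {
          mask <- (stats::runif(length(x)) >= l$rate) / (1 - l$rate)
          dim(mask) <- dim(x)
          list(out = x * mask, cache = mask)
        } else list(out = x, cache = NULL)
      },
      flatten = {
        d <- dim(x)
        list(out = matrix(x, prod(d[-length(d)]), d[length(d)]), cache = d)
      },
      reshape = {
        # public shape (h, w, c) maps to internal (c, h, w)
        n <- ncol(x)
        list(out = array(x, c(l$shape[3], l$shape[1], l$shape[2], n)),
             cache = dim(x))
      },
      upsample = {
        d <- dim(x); f <- l$factor
        out <- x[, rep(seq_len(d[2]), each = f),
                 rep(seq_len(d[3]), each = f), , drop = FALSE]
        list(out = out, cache = d)
      },
      zeropad = list(out = pad_zeros(x, l$p, l$p, l$p, l$p), cache = dim(x)),
      crop = {
        d <- dim(x); p <- l$p
        list(out = x[, (p + 1):(d[2] - p), (p + 1):(d[3] - p), ,
                     drop = FALSE], cache = d)
      },
      maxpool = stop("maxpool layers are declarative only (parameter counting)"),
      stop("unknown layer type: ", l$type))
    caches[[i]] <- res$cache
    x <- res$out
  }
  list(out = to_public(x), caches = caches)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Backward pass through a network
#'
#' @param net An `nn_network`.
#' @param caches Caches from [net_forward()].
#' @param dout Gradient of the loss with respect to the network output.
#' @param need_param_grads If `FALSE`, only the input gradient is computed.
#' @return List with `dx` (gradient at the input) and `grads` (per-layer
#'   parameter gradients, parallel to the layer list).
#' @export
net_backward <- function(net, caches, dout, need_param_grads = TRUE) {
  dout <- to_internal(dout)
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- caches[[i]]
    res <- switch(l$type,
      dense = {
        g <- if (need_param_grads)
          list(W = tcrossprod(cache, dout),
               b = if (!is.null(l$b)) rowSums(dout) else NULL)
        list(dx = l$W %*% dout, grads = g)
      },
      conv = conv_backward(l, cache, dout, need_param_grads),
      batchnorm = bn_backward(l, cache, dout, need_param_grads),
      elu = {
        dx <- dout
        dx[cache$neg] <- dx[cache$neg] * (l$alpha * exp(cache$x_neg))
        list(dx = dx, grads = NULL)
      },
      tanh = list(dx = dout * (1 - cache^2), grads = NULL),
      sigmoid = list(dx = dout * cache * (1 - cache), grads = NULL),
      dropout = list(dx = if (is.null(cache)) dout else dout * cache,
                     grads = NULL),
      flatten = list(dx = array(dout, cache), grads = NULL),
      reshape = list(dx = array(dout, cache), grads = NULL),
      upsample = {
        d <- cache; f <- l$factor
        dx <- array(0, d)
        for (a in seq_len(f)) for (b in seq_len(f)) {
          dx <- dx + dout[, seq(a, by = f, length.out = d[2]),
                          seq(b, by = f, length.out = d[3]), ,
                          drop = FALSE]
        }
        list(dx = dx, grads = NULL)
      },
      zeropad = {
        d <- cache; p <- l$p
        list(dx = dout[, (p + 1):(p + d[2]), (p + 1):(p + d[3]), ,
                       drop = FALSE], grads = NULL)
      },
      crop = {
        d <- cache; p <- l$p
        dx <- array(0, d)
        dx[, (p + 1):(d[2] - p), (p + 1):(d[3] - p), ] <- dout
        list(dx = dx, grads = NULL)
      })
    grads[i] <- list(res$grads)  # keep NULL slots for param-free layers
    dout <- res$dx
  }
  list(dx = to_public(dout), grads = grads)
}

# Fold the batch statistics cached by a training-mode forward pass into the
# batch-norm layers' moving mean/variance (Keras update rule).
bn_update_moving <- function(net, caches) {
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    if (l$type == "batchnorm" && !is.null(caches[[i]]$batch_mu)) {
      m <- l$momentum
      net$layers[[i]]$moving_mean <- m * l$moving_mean +
        (1 - m) * caches[[i]]$batch_mu
      net$layers[[i]]$moving_var <- m * l$moving_var +
        (1 - m) * caches[[i]]$batch_var
    }
  }
  net
}

# ---- Adam optimizer with learning-rate decay schedules --------------------

zeros_like <- function(p) if (is.null(dim(p))) numeric(length(p)) else
  array(0, dim(p))

adam_state <- function(net) {
  zl <- function(l) lapply(l[intersect(names(l),
                                       c("W", "b", "gamma", "beta"))],
                           zeros_like)
  list(step = 0L, m = lapply(net$layers, zl), v = lapply(net$layers, zl))
}

adam_lr <- function(lr, decay, step, schedule) {
  switch(schedule,
         inverse_time = lr / (1 + decay * step),
         exponential = lr * exp(-decay * step),
         constant = lr)
}

adam_update <- function(net, grads, state, lr = 2e-4, beta1 = 0.5,
                        beta2 = 0.9, decay = 0, schedule = "inverse_time",
                        eps = 1e-7) {
  state$step <- state$step + 1L
  t <- state$step
  lr_t <- adam_lr(lr, decay, t - 1L, schedule)
  corr <- sqrt(1 - beta2^t) / (1 - beta1^t)
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g) || isFALSE(net$layers[[i]]$trainable)) next
    for (nm in names(g)) {
      if (is.null(g[[nm]])) next
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g[[nm]]
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] +
        (1 - beta2) * g[[nm]]^2
      net$layers[[i]][[nm]] <- net$layers[[i]][[nm]] -
        lr_t * corr * state$m[[i]][[nm]] / (sqrt(state$v[[i]][[nm]]) + eps)
    }
  }
  list(net = net, state = state)
}
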