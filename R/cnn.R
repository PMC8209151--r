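#' Configuration of the 1-D convolutional classifier
#'
#' The classifier treats the 384-long fused descriptor as a length-384,
#' one-channel signal: two valid (unpadded, stride-1) convolutions — 32
#' filters then 64 filters, both with a 3x1 kernel — a 2x1 max-pooling,
#' a flatten, one ReLU dense layer with dropout, and a 2-way softmax
#' output. Filter counts, kernel and pool sizes follow the published
#' architecture; dense width, dropout, optimiser and schedule are package
#' defaults exposed here.
#'
#' @param conv1_filters,conv2_filters Filter counts of the two
#'   convolutional layers.
#' @param kernel Convolution kernel length (3).
#' @param pool Max-pooling length (2).
#' @param dense_units Width of the fully connected hidden layer.
#' @param dropout Dropout rate on the dense layer during training,
#'   in `[0, 1)`.
#' @param learning_rate,epochs,batch_size Adam training schedule.
#' @param seed Mandatory RNG seed.
#' @return A list of class `cnn_config`.
#' @export
cnn_config <- function(conv1_filters = 32, conv2_filters = 64,
                       kernel = 3, pool = 2, dense_units = 64,
                       dropout = 0.5, learning_rate = 1e-3,
                       epochs = 30, batch_size = 128, seed = 1L) {
  stopifnot(conv1_filters > 0, conv2_filters > 0, kernel >= 2, pool >= 2,
            dense_units > 0, dropout >= 0, dropout < 1,
            epochs >= 1, batch_size >= 1)
  structure(
    list(conv1_filters = as.integer(conv1_filters),
         conv2_filters = as.integer(conv2_filters),
         kernel = as.integer(kernel), pool = as.integer(pool),
         dense_units = as.integer(dense_units), dropout = dropout,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "cnn_config"
  )
}

cnn_shapes <- function(input_len, cfg) {
  l1 <- input_len - cfg$kernel + 1L
  l2 <- l1 - cfg$kernel + 1L
  if (input_len < 8L || l2 < cfg$pool) {
    stop_mdlink(paste0("input length ", input_len,
                       " too short for the convolution/pool chain"),
                "mdlink_input_too_short")
  }
  lp <- l2 %/% cfg$pool # trailing positions beyond a full window are dropped
  list(input_len = as.integer(input_len), l1 = l1, l2 = l2, lp = lp,
       flat = lp * cfg$conv2_filters)
}

#' Build an untrained 1-D CNN
#'
#' Initialises (He-uniform, seeded from `cfg$seed`) the weights of the
#' convolutional classifier for a given descriptor length.
#'
#' @param input_len Descriptor length (384 for the fused descriptor).
#' @param cfg A [cnn_config()].
#' @return Object of class `cnn_model` with components `weights`,
#'   `config`, `shapes`, `stages` (architecture summary tibble) and
#'   `n_params`.
#' @export
build_cnn <- function(input_len = 384, cfg = cnn_config()) {
  stopifnot(inherits(cfg, "cnn_config"))
  sh <- cnn_shapes(input_len, cfg)
  k <- cfg$kernel
  f1 <- cfg$conv1_filters
  f2 <- cfg$conv2_filters
  d <- cfg$dense_units
  he <- function(fan_in, nr, nc, seed) {
    lim <- sqrt(6 / fan_in)
    with_seed(seed, matrix(stats::runif(nr * nc, -lim, lim), nr, nc))
  }
  weights <- list(
    W1 = he(k, k, f1, derive_seed(cfg$seed, "cnn-w1")),
    b1 = rep(0, f1),
    W2 = he(k * f1, k * f1, f2, derive_seed(cfg$seed, "cnn-w2")),
    b2 = rep(0, f2),
    Wd = he(sh$flat, sh$flat, d, derive_seed(cfg$seed, "cnn-wd")),
    bd = rep(0, d),
    # output layer initialised small so initial logits are near zero and
    # the first softmax gradients are well-scaled
    Wo = he(d, d, 2, derive_seed(cfg$seed, "cnn-wo")) * 0.1,
    bo = rep(0, 2)
  )
  stages <- tibble::tribble(
    ~stage, ~detail, ~output_shape,
    "input", "descriptor as length-N signal, 1 channel",
    paste0(input_len, " x 1"),
    "conv1", paste0(f1, " filters, ", k, "x1 kernel, ReLU"),
    paste0(sh$l1, " x ", f1),
    "conv2", paste0(f2, " filters, ", k, "x1 kernel, ReLU"),
    paste0(sh$l2, " x ", f2),
    "maxpool", paste0(cfg$pool, "x1 max-pooling"),
    paste0(sh$lp, " x ", f2),
    "flatten", "", as.character(sh$flat),
    "dense", paste0(d, " units, ReLU, dropout ", cfg$dropout),
    as.character(d),
    "output", "2-way softmax", "2"
  )
  n_params <- (k + 1) * f1 + (k * f1 + 1) * f2 + (sh$flat + 1) * d + (d + 1) * 2
  structure(
    list(weights = weights, config = cfg, shapes = sh, stages = stages,
         n_params = as.integer(n_params)),
    class = "cnn_model"
  )
}

#' @export
print.cnn_model <- function(x, ...) {
  cat("<cnn_model> input ", x$shapes$input_len, ", ", x$n_params,
      " parameters\n", sep = "")
  print(as.data.frame(x$stages), row.names = FALSE)
  invisible(x)
}

# Forward pass. Internal layout: position-major row index r = i + (t-1)*n
# so that the im2col of conv2 is three row-shifted views of conv1's output.
cnn_forward <- function(weights, X, cfg, sh, dropout_mask = NULL) {
  n <- nrow(X)
  k <- cfg$kernel
  # fast primitives: column-recycled bias add and leaky-ReLU (slope 0.01;
  # keeps gradients alive so a bad early step cannot kill the network)
  add_bias <- function(M, b) M + rep(b, each = nrow(M))
  relu_ <- function(M) {
    neg <- M < 0
    M[neg] <- 0.01 * M[neg]
    M
  }
  # conv1 im2col: (n*l1) x k
  Xc <- do.call(cbind, lapply(seq_len(k), function(o) {
    as.vector(X[, o:(o + sh$l1 - 1L), drop = FALSE])
  }))
  A1 <- relu_(add_bias(Xc %*% weights$W1, weights$b1))
  # conv2 im2col: offset o shifts the position-major rows by o*n
  n_out2 <- n * sh$l2
  X2 <- do.call(cbind, lapply(0:(k - 1L), function(o) {
    A1[(1:n_out2) + o * n, , drop = FALSE]
  }))
  A2 <- relu_(add_bias(X2 %*% weights$W2, weights$b2))
  # max-pooling over windows of `pool` consecutive positions; ties keep the
  # earliest position (deterministic)
  idx_a <- as.vector(outer(1:n, (seq_len(sh$lp) - 1L) * cfg$pool,
                           function(i, p) i + p * n))
  P <- A2[idx_a, , drop = FALSE]
  arg <- matrix(1L, nrow(P), ncol(P))
  for (o in seq_len(cfg$pool - 1L)) {
    cand <- A2[idx_a + o * n, , drop = FALSE]
    upd <- cand > P
    P[upd] <- cand[upd]
    arg[upd] <- o + 1L
  }
  Fl <- matrix(array(P, c(n, sh$lp, cfg$conv2_filters)), n, sh$flat)
  H <- relu_(add_bias(Fl %*% weights$Wd, weights$bd))
  if (!is.null(dropout_mask)) H <- H * dropout_mask
  logits <- add_bias(H %*% weights$Wo, weights$bo)
  zmax <- do.call(pmax, as.data.frame(logits))
  ez <- exp(logits - zmax)
  probs <- ez / rowSums(ez)
  list(Xc = Xc, A1 = A1, X2 = X2, A2 = A2, arg = arg,
       idx_a = idx_a, Fl = Fl, H = H, probs = probs, n = n)
}

leaky_grad <- function(a) {
  g <- array(1, dim(a))
  g[a < 0] <- 0.01
  g
}

# Backward pass of softmax cross-entropy; returns gradient list matching
# the weights list.
cnn_backward <- function(weights, fw, y, cfg, sh, dropout_mask = NULL) {
  n <- fw$n
  k <- cfg$kernel
  Yhot <- cbind(1 - y, y)
  d_logits <- (fw$probs - Yhot) / n
  gWo <- crossprod(fw$H, d_logits)
  gbo <- colSums(d_logits)
  dH <- tcrossprod(d_logits, weights$Wo)
  if (!is.null(dropout_mask)) dH <- dH * dropout_mask
  dZd <- dH * leaky_grad(fw$H)
  gWd <- crossprod(fw$Fl, dZd)
  gbd <- colSums(dZd)
  dFl <- tcrossprod(dZd, weights$Wd)
  # un-flatten then un-pool
  dP <- matrix(array(dFl, c(n, sh$lp, cfg$conv2_filters)),
               n * sh$lp, cfg$conv2_filters)
  dA2 <- matrix(0, n * sh$l2, cfg$conv2_filters)
  for (o in 0:(cfg$pool - 1L)) {
    sel <- fw$arg == o + 1L
    if (any(sel)) {
      contrib <- dP * sel
      rows <- fw$idx_a + o * n
      dA2[rows, ] <- dA2[rows, ] + contrib
    }
  }
  dZ2 <- dA2 * leaky_grad(fw$A2)
  gW2 <- crossprod(fw$X2, dZ2)
  gb2 <- colSums(dZ2)
  dX2 <- tcrossprod(dZ2, weights$W2)
  f1 <- cfg$conv1_filters
  dA1 <- matrix(0, n * sh$l1, f1)
  n_out2 <- n * sh$l2
  for (o in 0:(k - 1L)) {
    rows <- (1:n_out2) + o * n
    dA1[rows, ] <- dA1[rows, ] + dX2[, (o * f1 + 1):((o + 1) * f1), drop = FALSE]
  }
  dZ1 <- dA1 * leaky_grad(fw$A1)
  gW1 <- crossprod(fw$Xc, dZ1)
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       Wd = gWd, bd = gbd, Wo = gWo, bo = gbo)
}

cnn_loss <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train the convolutional classifier
#'
#' Fits a [build_cnn()] model on a descriptor matrix with binary labels
#' using mini-batch Adam on the softmax cross-entropy, with inverted
#' dropout on the dense layer. All randomness (shuffling, dropout) derives
#' from the model's seed, so refitting with the same config reproduces
#' the classifier.
#'
#' @param object An untrained `cnn_model`.
#' @param X Descriptor matrix (rows = pairs).
#' @param y Binary labels (0/1).
#' @param ... Unused.
#' @return Object of class `cnn_classifier` with the trained weights, the
#'   config and a per-epoch training-loss `history`.
#' @method fit cnn_model
#' @export
fit.cnn_model <- function(object, X, y, ...) {
  cfg <- object$config
  sh <- object$shapes
  y <- as.integer(y)
  if (!is.matrix(X) || ncol(X) != sh$input_len) {
    stop_mdlink(paste0("descriptor width ", ncol(X),
                       " does not match model input ", sh$input_len),
                "mdlink_dim_mismatch")
  }
  if (any(!is.finite(X))) {
    stop_mdlink("non-finite values in descriptor matrix", "mdlink_bad_input")
  }
  if (length(unique(y)) < 2L) {
    stop_mdlink("training labels contain a single class", "mdlink_single_class")
  }
  # per-feature standardisation (training statistics, reapplied at predict)
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  X <- sweep(sweep(X, 2, center), 2, scale, "/")
  weights <- object$weights
  opt <- lapply(weights, function(w) list(m = w * 0, v = w * 0))
  n <- nrow(X)
  batch <- min(cfg$batch_size, n)
  history <- numeric(cfg$epochs)
  t_step <- 0L
  with_seed(derive_seed(cfg$seed, "cnn-train"), {
    for (ep in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      ep_n <- 0L
      for (s0 in seq(1L, n, by = batch)) {
        idx <- perm[s0:min(s0 + batch - 1L, n)]
        nb <- length(idx)
        mask <- if (cfg$dropout > 0) {
          matrix(stats::runif(nb * cfg$dense_units) >= cfg$dropout,
                 nb, cfg$dense_units) / (1 - cfg$dropout)
        } else {
          NULL
        }
        fw <- cnn_forward(weights, X[idx, , drop = FALSE], cfg, sh, mask)
        loss <- cnn_loss(fw$probs, y[idx])
        if (!is.finite(loss)) {
          stop_mdlink(paste0("non-finite CNN loss at epoch ", ep),
                      "mdlink_nonfinite_loss")
        }
        grads <- cnn_backward(weights, fw, y[idx], cfg, sh, mask)
        t_step <- t_step + 1L
        for (nm in names(weights)) {
          g <- grads[[nm]]
          o <- opt[[nm]]
          o$m <- 0.9 * o$m + 0.1 * g
          o$v <- 0.999 * o$v + 0.001 * g^2
          mh <- o$m / (1 - 0.9^t_step)
          vh <- o$v / (1 - 0.999^t_step)
          weights[[nm]] <- weights[[nm]] - cfg$learning_rate * mh / (sqrt(vh) + 1e-8)
          opt[[nm]] <- o
        }
        ep_loss <- ep_loss + loss * nb
        ep_n <- ep_n + nb
      }
      history[ep] <- ep_loss / ep_n
    }
  })
  structure(
    list(weights = weights, config = cfg, shapes = sh,
         stages = object$stages, n_params = object$n_params,
         center = center, scale = scale,
         history = tibble::tibble(epoch = seq_len(cfg$epochs), loss = history)),
    class = "cnn_classifier"
  )
}

#' Predict association probabilities
#'
#' `predict_proba()` is the shared scoring interface of the CNN and every
#' baseline classifier: one probability of association (class 1) per row
#' of `X`, in `[0, 1]`, deterministic for a fixed fitted state.
#'
#' @param clf A fitted classifier (`cnn_classifier` or
#'   `baseline_classifier`).
#' @param X Descriptor matrix with the width the classifier was fit on.
#' @param ... Unused.
#' @return Numeric vector of scores.
#' @export
predict_proba <- function(clf, X, ...) UseMethod("predict_proba")

#' @rdname predict_proba
#' @export
predict_proba.cnn_classifier <- function(clf, X, ...) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (ncol(X) != clf$shapes$input_len) {
    stop_mdlink(paste0("descriptor width ", ncol(X),
                       " does not match model input ", clf$shapes$input_len),
                "mdlink_dim_mismatch")
  }
  X <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
  fw <- cnn_forward(clf$weights, X, clf$config, clf$shapes, NULL)
  unname(fw$probs[, 2])
}

#' @rdname predict_proba
#' @export
predict_proba.default <- function(clf, X, ...) {
  stop_mdlink(paste0("no predict_proba method for class ",
                     paste(class(clf), collapse = "/")),
              "mdlink_bad_input")
}

#' Full 2-way softmax output of the CNN
#'
#' @param clf A `cnn_classifier`.
#' @param X Descriptor matrix.
#' @return Matrix n x 2 of class probabilities (rows sum to 1).
#' @export
predict_proba2 <- function(clf, X) {
  stopifnot(inherits(clf, "cnn_classifier"))
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  X <- sweep(sweep(X, 2, clf$center), 2, clf$scale, "/")
  fw <- cnn_forward(clf$weights, X, clf$config, clf$shapes, NULL)
  unname(fw$probs)
}

#' @export
print.cnn_classifier <- function(x, ...) {
  h <- x$history
  cat("<cnn_classifier> ", x$n_params, " parameters; training loss ",
      format(h$loss[1], digits = 4), " -> ",
      format(h$loss[nrow(h)], digits = 4), " over ", nrow(h), " epochs\n",
      sep = "")
  invisible(x)
}

#' @method tidy cnn_classifier
#' @export
tidy.cnn_classifier <- function(x, ...) x$history

#' @method glance cnn_classifier
#' @export
glance.cnn_classifier <- function(x, ...) {
  tibble::tibble(
    n_params = x$n_params,
    epochs = nrow(x$history),
    initial_loss = x$history$loss[1],
    final_loss = x$history$loss[nrow(x$history)]
  )
}
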