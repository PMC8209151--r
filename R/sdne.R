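#' Configuration of the structural deep network embedding
#'
#' SDNE is a semi-supervised deep autoencoder over the rows of the network
#' adjacency matrix. The unsupervised part reconstructs each node's
#' adjacency row with nonzero entries up-weighted by `beta` (second-order
#' proximity: nodes with similar neighbourhoods embed nearby); the
#' supervised part is a Laplacian penalty pulling connected nodes together
#' in embedding space (first-order proximity), weighted by `alpha`.
#' Weight decay on all encoder/decoder matrices is weighted by `nu`.
#'
#' @param alpha First-order (Laplacian) loss weight, >= 0.
#' @param nu Regularisation weight, >= 0.
#' @param beta Reconstruction penalty applied to nonzero adjacency
#'   entries, >= 1.
#' @param layer_dims Encoder hidden sizes after the input layer; the last
#'   entry is the embedding dimension (128 by default).
#' @param activation Elementwise nonlinearity of all layers.
#' @param learning_rate,epochs,batch_size Adam training schedule; networks
#'   smaller than `batch_size` fall back to full-batch training.
#' @param seed Mandatory RNG seed (initialisation and batch shuffling).
#' @return A list of class `sdne_config`.
#' @export
sdne_config <- function(alpha = 0.05, nu = 1e-4, beta = 5,
                        layer_dims = c(512, 128),
                        activation = "sigmoid",
                        learning_rate = 1e-3, epochs = 50,
                        batch_size = 64, seed = 1L) {
  stopifnot(alpha >= 0, nu >= 0, beta >= 1, length(layer_dims) >= 1,
            all(layer_dims > 0), epochs >= 0, batch_size >= 1)
  structure(
    list(alpha = alpha, nu = nu, beta = beta,
         layer_dims = as.integer(layer_dims), activation = activation,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         batch_size = as.integer(batch_size), seed = as.integer(seed)),
    class = "sdne_config"
  )
}

#' SDNE loss components
#'
#' `first_order_loss()` is the Laplacian penalty
#' `sum_{i,j} s_ij * ||y_i - y_j||^2` over ordered pairs (each undirected
#' edge contributes twice). `second_order_loss()` is the weighted
#' reconstruction error `||(Xhat - X) * B||_F^2` with `B_ij = beta` where
#' `X_ij > 0` and 1 elsewhere. `reg_loss()` is
#' `0.5 * sum_k (||W_k||_F^2 + ||What_k||_F^2)` over encoder and decoder
#' weight matrices (offsets excluded). `total_loss()` combines them as
#' `L2nd + alpha * L1st + nu * Lreg`.
#'
#' @param Y Embedding matrix (nodes x embedding dim).
#' @param s Symmetric adjacency matrix.
#' @return Non-negative scalar.
#' @export
first_order_loss <- function(Y, s) {
  stopifnot(nrow(Y) == nrow(s), nrow(s) == ncol(s))
  deg <- rowSums(s)
  # sum_ij s_ij ||y_i - y_j||^2 = 2 * tr(Y' L Y), L = D - S
  2 * (sum(deg * rowSums(Y^2)) - sum(Y * (s %*% Y)))
}

#' @rdname first_order_loss
#' @param X Adjacency rows (inputs); `Xhat` their reconstructions.
#' @param Xhat Reconstructed rows, same shape as `X`.
#' @param beta Penalty on nonzero entries of `X`.
#' @export
second_order_loss <- function(X, Xhat, beta) {
  stopifnot(identical(dim(X), dim(Xhat)), beta >= 1)
  B <- ifelse(X > 0, beta, 1)
  sum(((Xhat - X) * B)^2)
}

#' @rdname first_order_loss
#' @param state An `sdne_state` (or any list with `encoder` and `decoder`
#'   layer lists).
#' @export
reg_loss <- function(state) {
  ws <- c(lapply(state$encoder, `[[`, "W"), lapply(state$decoder, `[[`, "W"))
  0.5 * sum(vapply(ws, function(W) sum(W^2), 0))
}

#' @rdname first_order_loss
#' @param cfg An [sdne_config()] supplying `alpha`, `nu`, `beta`; the
#'   regularisation term enters `total_loss()` only when `state` is given.
#' @export
total_loss <- function(X, Xhat, Y, s, cfg, state = NULL) {
  l2 <- second_order_loss(X, Xhat, cfg$beta)
  l1 <- first_order_loss(Y, s)
  lr <- if (is.null(state)) 0 else reg_loss(state)
  l2 + cfg$alpha * l1 + cfg$nu * lr
}

#' Encode adjacency rows into behaviour vectors
#'
#' Applies the (trained or untrained) SDNE encoder to one or more
#' adjacency rows.
#'
#' @param x Numeric vector (one adjacency row) or matrix of rows.
#' @param state An `sdne_state` as stored in a [fit_sdne()] result.
#' @return Matrix of embeddings (rows align with `x`).
#' @export
encode <- function(x, state) {
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != nrow(state$encoder[[1]]$W)) {
    stop_mdlink(paste0("input width ", ncol(X), " does not match encoder input ",
                       nrow(state$encoder[[1]]$W)), "mdlink_dim_mismatch")
  }
  h <- nn_forward(state$encoder, X)
  h[[length(h)]]
}

# Build an untrained encoder/decoder pair for an n-node network.
sdne_init_state <- function(n, cfg) {
  dims <- c(n, cfg$layer_dims)
  acts <- rep(cfg$activation, length(cfg$layer_dims))
  enc <- nn_init(dims, acts, derive_seed(cfg$seed, "sdne-enc"))
  dec <- nn_init(rev(dims), acts, derive_seed(cfg$seed, "sdne-dec"))
  list(encoder = enc, decoder = dec)
}

# Loss and analytic gradients on a (sub)batch of nodes. X_b: batch rows of
# the adjacency; s_bb: batch x batch adjacency block (first-order pairs are
# within-batch). Used by the training loop and by the finite-difference
# gradient check in the tests.
sdne_loss_and_grads <- function(state, X_b, s_bb, cfg) {
  henc <- nn_forward(state$encoder, X_b)
  Y <- henc[[length(henc)]]
  hdec <- nn_forward(state$decoder, Y)
  Xhat <- hdec[[length(hdec)]]

  B <- ifelse(X_b > 0, cfg$beta, 1)
  l2 <- sum(((Xhat - X_b) * B)^2)
  l1 <- first_order_loss(Y, s_bb)
  lreg <- reg_loss(state)
  loss <- l2 + cfg$alpha * l1 + cfg$nu * lreg

  d_xhat <- 2 * (Xhat - X_b) * B^2
  back_dec <- nn_backward(state$decoder, hdec, d_xhat)
  # dL1st/dY = 4 (D - S) Y over ordered pairs
  deg <- rowSums(s_bb)
  d_y_first <- 4 * (deg * Y - s_bb %*% Y)
  d_y <- back_dec$d_input + cfg$alpha * d_y_first
  back_enc <- nn_backward(state$encoder, henc, d_y)

  genc <- back_enc$grads
  gdec <- back_dec$grads
  for (k in seq_along(genc)) genc[[k]]$W <- genc[[k]]$W + cfg$nu * state$encoder[[k]]$W
  for (k in seq_along(gdec)) gdec[[k]]$W <- gdec[[k]]$W + cfg$nu * state$decoder[[k]]$W

  list(loss = loss, l2nd = l2, l1st = l1, lreg = lreg,
       grads_enc = genc, grads_dec = gdec, Y = Y, Xhat = Xhat)
}

#' Fit the structural deep network embedding
#'
#' Trains the SDNE autoencoder on the adjacency matrix of a
#' [hetero_network()] and returns one behaviour vector per node (128-long
#' by default). Training is mini-batch Adam; the first-order penalty uses
#' within-batch node pairs, and networks smaller than the batch size are
#' trained full-batch. All randomness (initialisation, batch shuffling)
#' derives from `cfg$seed`, so identical config and seed reproduce the
#' table.
#'
#' @param net A `hetero_network`.
#' @param cfg An [sdne_config()].
#' @return Object of class `sdne_fit`: `embeddings` (nodes x dim matrix,
#'   rownames `type|id`), `history` (tibble `epoch`, `loss`, `l2nd`,
#'   `l1st`, `lreg`; epoch 0 is the untrained state), `state`, `config`.
#' @export
fit_sdne <- function(net, cfg = sdne_config()) {
  stopifnot(inherits(net, "hetero_network"), inherits(cfg, "sdne_config"))
  X <- net$adjacency
  n <- nrow(X)
  if (n == 0L) stop_mdlink("network is empty", "mdlink_empty_network")
  state <- sdne_init_state(n, cfg)
  opt_enc <- adam_init(state$encoder)
  opt_dec <- adam_init(state$decoder)
  batch <- min(cfg$batch_size, n)

  full_eval <- function(state) {
    g <- sdne_loss_and_grads(state, X, X, cfg)
    tibble::tibble(loss = g$loss, l2nd = g$l2nd, l1st = g$l1st, lreg = g$lreg)
  }
  history <- dplyr::bind_rows(tibble::tibble(epoch = 0L, full_eval(state)))

  t_step <- 0L
  if (cfg$epochs > 0L) {
    with_seed(derive_seed(cfg$seed, "sdne-train"), {
      for (ep in seq_len(cfg$epochs)) {
        perm <- sample.int(n)
        starts <- seq(1L, n, by = batch)
        for (s0 in starts) {
          idx <- perm[s0:min(s0 + batch - 1L, n)]
          g <- sdne_loss_and_grads(state, X[idx, , drop = FALSE],
                                   X[idx, idx, drop = FALSE], cfg)
          if (!is.finite(g$loss)) {
            stop_mdlink(paste0("non-finite SDNE loss at epoch ", ep),
                        "mdlink_nonfinite_loss")
          }
          t_step <- t_step + 1L
          up_e <- adam_step(state$encoder, g$grads_enc, opt_enc,
                            cfg$learning_rate, t_step)
          state$encoder <- up_e$layers
          opt_enc <- up_e$state
          up_d <- adam_step(state$decoder, g$grads_dec, opt_dec,
                            cfg$learning_rate, t_step)
          state$decoder <- up_d$layers
          opt_dec <- up_d$state
        }
        history <- dplyr::bind_rows(history,
                                    tibble::tibble(epoch = ep, full_eval(state)))
      }
    })
  }

  emb <- encode(X, state)
  rownames(emb) <- rownames(X)
  colnames(emb) <- paste0("e", seq_len(ncol(emb)))
  structure(
    list(embeddings = emb, history = history, state = state, config = cfg),
    class = "sdne_fit"
  )
}

#' @export
print.sdne_fit <- function(x, ...) {
  h <- x$history
  cat("<sdne_fit> ", nrow(x$embeddings), " nodes -> ", ncol(x$embeddings),
      "-dim embeddings; loss ", format(h$loss[1], digits = 5), " -> ",
      format(h$loss[nrow(h)], digits = 5), " over ", max(h$epoch),
      " epochs\n", sep = "")
  invisible(x)
}

#' @rdname fit_sdne
#' @param x An `sdne_fit`.
#' @param ... Unused.
#' @return `tidy()`: the per-epoch training history as a tibble.
#' @method tidy sdne_fit
#' @export
tidy.sdne_fit <- function(x, ...) x$history

#' @rdname fit_sdne
#' @method glance sdne_fit
#' @export
glance.sdne_fit <- function(x, ...) {
  h <- x$history
  tibble::tibble(
    n_nodes = nrow(x$embeddings),
    dim = ncol(x$embeddings),
    epochs = max(h$epoch),
    initial_loss = h$loss[1],
    final_loss = h$loss[nrow(h)]
  )
}
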