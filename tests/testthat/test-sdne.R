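# A 2-block network small enough for fast SDNE runs: two dense communities
# bridged by nothing, planted over miRNA and disease nodes.
two_block_net <- function(n_per = 30, seed = 31) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  mk <- function(block, offset) {
    m <- sprintf("m%02d", offset + 1:(n_per / 2))
    d <- sprintf("d%02d", offset + 1:(n_per / 2))
    grid <- expand.grid(m = m, d = d, stringsAsFactors = FALSE)
    grid <- grid[runif(nrow(grid)) < 0.5, ]
    tibble::tibble(source_type = "miRNA", source_id = grid$m,
                   target_type = "disease", target_id = grid$d,
                   assoc_type = "mirna_disease")
  }
  hetero_network(dplyr::bind_rows(mk(1, 0), mk(2, 50)))
}

test_that("encoding applies the layered sigmoid map", {
  # zero weights with sigmoid -> 0.5 everywhere
  st0 <- list(encoder = list(list(W = matrix(0, 4, 3), b = rep(0, 3),
                                  act = "sigmoid")))
  expect_equal(unname(encode(c(1, 0, 1, 0), st0)[1, ]), rep(0.5, 3))
  # identity single layer reproduces the input
  st1 <- list(encoder = list(list(W = diag(4), b = rep(0, 4),
                                  act = "identity")))
  expect_equal(unname(encode(c(1, 0, 1, 0), st1)[1, ]), c(1, 0, 1, 0))
  # seeded random two-layer state matches a hand-coded matrix product
  set.seed(5)
  W1 <- matrix(rnorm(12), 4, 3)
  b1 <- rnorm(3)
  W2 <- matrix(rnorm(6), 3, 2)
  b2 <- rnorm(2)
  st2 <- list(encoder = list(list(W = W1, b = b1, act = "sigmoid"),
                             list(W = W2, b = b2, act = "sigmoid")))
  x <- c(0, 1, 1, 0)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(unname(encode(x, st2)[1, ]),
               unname(sig(sig(x %*% W1 + rep(b1, each = 1)) %*% W2 + b2)[1, ]))
  expect_error(encode(c(1, 0), st2), class = "mdlink_dim_mismatch")
})

test_that("loss components evaluate to their hand-derived values", {
  # first-order: ordered pairs, each undirected edge counted twice
  Y <- rbind(c(0, 0), c(1, 0))
  s <- rbind(c(0, 1), c(1, 0))
  expect_equal(first_order_loss(Y, s), 2.0)
  expect_equal(first_order_loss(rbind(c(1, 2), c(1, 2)), s), 0)
  expect_equal(first_order_loss(Y, s * 0), 0)

  # second-order: beta-weighted reconstruction error
  X <- matrix(c(1, 0), 1, 2)
  Xhat <- matrix(c(0, 0), 1, 2)
  expect_equal(second_order_loss(X, Xhat, beta = 5), 25)
  expect_equal(second_order_loss(X, X, beta = 5), 0)
  expect_equal(second_order_loss(X, Xhat, beta = 1), sum((Xhat - X)^2))

  # regularisation: half the squared Frobenius norms, biases excluded
  st <- list(encoder = list(list(W = matrix(2, 1, 1), b = 5, act = "sigmoid")),
             decoder = list(list(W = matrix(2, 1, 1), b = 7, act = "sigmoid")))
  expect_equal(reg_loss(st), 4)
  st2 <- st
  st2$encoder[[1]]$W <- st$encoder[[1]]$W * 3
  st2$decoder[[1]]$W <- st$decoder[[1]]$W * 3
  expect_equal(reg_loss(st2), 9 * reg_loss(st))

  # total loss combines the three with alpha and nu
  cfg <- sdne_config(alpha = 0, nu = 0, beta = 5)
  expect_equal(total_loss(X, Xhat, Y, matrix(0, 2, 2), cfg),
               second_order_loss(X, Xhat, 5))
  cfg2 <- sdne_config(alpha = 0.3, nu = 0.01, beta = 2)
  X3 <- diag(3)
  Xh3 <- matrix(0.2, 3, 3)
  Y3 <- matrix(seq(0.1, 0.6, by = 0.1)[1:6], 3, 2)
  s3 <- matrix(c(0, 1, 0, 1, 0, 1, 0, 1, 0), 3, 3)
  expect_equal(
    total_loss(X3, Xh3, Y3, s3, cfg2, state = st),
    second_order_loss(X3, Xh3, 2) + 0.3 * first_order_loss(Y3, s3) +
      0.01 * reg_loss(st)
  )
  expect_equal(total_loss(X, X, Y * 0, s * 0, cfg), 0)
})

test_that("analytic gradients agree with finite differences", {
  edges <- tibble::tibble(
    source_type = "miRNA", source_id = c("m1", "m1", "m2"),
    target_type = "disease", target_id = c("d1", "d2", "d2"),
    assoc_type = "mirna_disease"
  )
  net <- hetero_network(edges)
  cfg <- sdne_config(alpha = 0.3, nu = 0.01, beta = 2, layer_dims = c(3, 2),
                     seed = 13)
  state <- mdlink:::sdne_init_state(4, cfg)
  X <- net$adjacency
  g <- mdlink:::sdne_loss_and_grads(state, X, X, cfg)
  eps <- 1e-6
  check <- function(part, k) {
    W <- state[[part]][[k]]$W
    for (idx in seq_len(min(6, length(W)))) {
      st_p <- state
      st_p[[part]][[k]]$W[idx] <- W[idx] + eps
      st_m <- state
      st_m[[part]][[k]]$W[idx] <- W[idx] - eps
      num <- (mdlink:::sdne_loss_and_grads(st_p, X, X, cfg)$loss -
                mdlink:::sdne_loss_and_grads(st_m, X, X, cfg)$loss) / (2 * eps)
      ana <- if (part == "encoder") g$grads_enc[[k]]$W[idx] else g$grads_dec[[k]]$W[idx]
      expect_equal(ana, num, tolerance = 1e-4)
    }
  }
  check("encoder", 1)
  check("encoder", 2)
  check("decoder", 1)
  check("decoder", 2)
})

test_that("SDNE training reduces loss and separates planted blocks", {
  net <- two_block_net()
  cfg <- sdne_config(epochs = 20, layer_dims = c(64, 16), seed = 17)
  sf <- fit_sdne(net, cfg)
  expect_equal(nrow(sf$embeddings), nrow(net$nodes))
  expect_equal(ncol(sf$embeddings), 16L)
  h <- sf$history
  expect_equal(nrow(h), 21L) # epoch 0 plus 20 training epochs
  expect_lt(h$loss[nrow(h)], h$loss[1])
  # recorded loss equals total_loss recomputed from the returned state
  X <- net$adjacency
  emb <- encode(X, sf$state)
  hdec <- mdlink:::nn_forward(sf$state$decoder, emb)
  xhat <- hdec[[length(hdec)]]
  expect_equal(h$loss[nrow(h)],
               total_loss(X, xhat, emb, X, cfg, state = sf$state),
               tolerance = 1e-9)

  # block geometry: within-block distances < between-block distances
  block <- as.integer(
    as.integer(sub("^.*\\|[md]", "", rownames(sf$embeddings))) > 50
  ) + 1L
  D <- as.matrix(dist(sf$embeddings))
  same <- outer(block, block, "==") & upper.tri(D)
  diff <- !outer(block, block, "==") & upper.tri(D)
  expect_lt(mean(D[same]), mean(D[diff]))

  # a linear classifier separates the blocks from the embeddings
  fitb <- glmnet::glmnet(sf$embeddings, factor(block), family = "binomial",
                         alpha = 0, lambda = 1e-3)
  pred <- as.integer(predict(fitb, sf$embeddings, type = "response") > 0.5) + 1L
  expect_gt(mean(pred == block), 0.9)
})

test_that("SDNE is reproducible and honours epochs = 0", {
  net <- two_block_net(n_per = 10, seed = 32)
  cfg <- sdne_config(epochs = 5, layer_dims = c(16, 8), seed = 23)
  a <- fit_sdne(net, cfg)
  b <- fit_sdne(net, cfg)
  expect_equal(a$embeddings, b$embeddings, tolerance = 1e-6)
  expect_equal(a$history$loss, b$history$loss, tolerance = 1e-6)

  cfg0 <- sdne_config(epochs = 0, layer_dims = c(16, 8), seed = 23)
  u <- fit_sdne(net, cfg0)
  st <- mdlink:::sdne_init_state(nrow(net$adjacency), cfg0)
  expect_equal(u$embeddings, {
    e <- encode(net$adjacency, st)
    dimnames(e) <- dimnames(u$embeddings)
    e
  })
  expect_equal(nrow(u$history), 1L)
})
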