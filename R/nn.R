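# Minimal dense feed-forward engine with Adam, shared by the SDNE graph
# autoencoder and the stacked autoencoder used for attribute compression.
# Row-vector convention: activations are n x d matrices, weights are
# (d_in x d_out), so a layer computes sigma(H %*% W + b).

nn_act <- function(z, act) {
  switch(act,
    sigmoid = 1 / (1 + exp(-z)),
    relu = pmax(z, 0),
    identity = z,
    stop_mdlink(paste0("unknown activation '", act, "'"), "mdlink_bad_param")
  )
}

# derivative wrt pre-activation, expressed through the activation output a
nn_act_grad <- function(a, act) {
  switch(act,
    sigmoid = a * (1 - a),
    relu = (a > 0) * 1,
    identity = array(1, dim(a))
  )
}

# Glorot-uniform initialisation of a stack of dense layers.
# dims: c(d0, d1, ..., dK); acts: length K character vector.
nn_init <- function(dims, acts, seed) {
  stopifnot(length(acts) == length(dims) - 1L)
  with_seed(seed, {
    layers <- vector("list", length(acts))
    for (k in seq_along(acts)) {
      din <- dims[k]
      dout <- dims[k + 1]
      lim <- sqrt(6 / (din + dout))
      layers[[k]] <- list(
        W = matrix(stats::runif(din * dout, -lim, lim), din, dout),
        b = rep(0, dout),
        act = acts[k]
      )
    }
    layers
  })
}

# Forward pass; returns list of activations (h[[1]] = input, h[[k+1]] =
# output of layer k).
nn_forward <- function(layers, X) {
  h <- vector("list", length(layers) + 1L)
  h[[1]] <- X
  for (k in seq_along(layers)) {
    z <- sweep(h[[k]] %*% layers[[k]]$W, 2, layers[[k]]$b, "+")
    h[[k + 1]] <- nn_act(z, layers[[k]]$act)
  }
  h
}

# Backward pass through a stack given dL/d(output activation) at the top
# and optional extra gradients injected at inner activations
# (inject[[k]] adds to dL/d(h[[k]]), 1-based over activations).
# Returns per-layer gradients and dL/d(input).
nn_backward <- function(layers, h, d_out, inject = NULL) {
  K <- length(layers)
  grads <- vector("list", K)
  da <- d_out
  for (k in K:1) {
    if (!is.null(inject) && !is.null(inject[[k + 1L]])) {
      da <- da + inject[[k + 1L]]
    }
    dz <- da * nn_act_grad(h[[k + 1L]], layers[[k]]$act)
    grads[[k]] <- list(
      W = crossprod(h[[k]], dz),
      b = colSums(dz)
    )
    da <- tcrossprod(dz, layers[[k]]$W)
  }
  list(grads = grads, d_input = da)
}

# Adam optimiser state for a list of layers.
adam_init <- function(layers) {
  lapply(layers, function(l) list(
    mW = array(0, dim(l$W)), vW = array(0, dim(l$W)),
    mb = rep(0, length(l$b)), vb = rep(0, length(l$b))
  ))
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (k in seq_along(layers)) {
    g <- grads[[k]]
    s <- state[[k]]
    s$mW <- beta1 * s$mW + (1 - beta1) * g$W
    s$vW <- beta2 * s$vW + (1 - beta2) * g$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * g$b
    s$vb <- beta2 * s$vb + (1 - beta2) * g$b^2
    mhW <- s$mW / (1 - beta1^t)
    vhW <- s$vW / (1 - beta2^t)
    mhb <- s$mb / (1 - beta1^t)
    vhb <- s$vb / (1 - beta2^t)
    layers[[k]]$W <- layers[[k]]$W - lr * mhW / (sqrt(vhW) + eps)
    layers[[k]]$b <- layers[[k]]$b - lr * mhb / (sqrt(vhb) + eps)
    state[[k]] <- s
  }
  list(layers = layers, state = state)
}
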