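#' Compress a similarity matrix to attribute vectors
#'
#' Trains a stacked autoencoder (input -> `hidden` -> `target_dim`
#' encoder with sigmoid hidden layers and a linear code/output, mirrored
#' decoder, mean-squared reconstruction objective, full-batch Adam) on the
#' rows of a similarity matrix and returns each row's `target_dim`-long
#' code. Rows with identical similarity profiles map to identical codes
#' because the code is a deterministic function of the row.
#'
#' The autoencoder may be fitted on a subset of rows (`fit_ids`) and
#' applied to all — used during cross validation where compression is
#' fitted on training-fold entities only.
#'
#' @param mat Square symmetric similarity matrix with row/col names.
#' @param target_dim Code length (64 by default, the attribute dimension).
#' @param hidden Hidden layer width of the encoder.
#' @param epochs,learning_rate Adam schedule.
#' @param seed Mandatory RNG seed.
#' @param fit_ids Optional row ids used for training; codes are still
#'   produced for every row.
#' @return Object of class `sim_compression`: `codes` (rows x
#'   `target_dim` matrix, rownames preserved), `history` (tibble `epoch`,
#'   `mse`; epoch 0 is the untrained state), `state`, `target_dim`.
#' @export
compress_similarity <- function(mat, target_dim = 64, hidden = 256,
                                epochs = 100, learning_rate = 1e-3,
                                seed = 1L, fit_ids = NULL) {
  if (!is.matrix(mat) || nrow(mat) != ncol(mat)) {
    stop_mdlink("similarity matrix must be square", "mdlink_bad_input")
  }
  if (any(!is.finite(mat))) {
    stop_mdlink("similarity matrix has non-finite entries", "mdlink_bad_input")
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- colnames(mat) <- paste0("r", seq_len(nrow(mat)))
  }
  if (nrow(mat) < target_dim) {
    rlang::warn(paste0("similarity matrix has fewer rows (", nrow(mat),
                       ") than the target dimension (", target_dim, ")"))
  }
  X_fit <- if (is.null(fit_ids)) mat else {
    miss <- setdiff(fit_ids, rownames(mat))
    if (length(miss) > 0L) {
      stop_mdlink(paste0("fit_ids not in matrix: ",
                         paste(utils::head(miss, 3), collapse = ", ")),
                  "mdlink_unknown_id")
    }
    mat[unique(fit_ids), , drop = FALSE]
  }

  d <- ncol(mat)
  dims <- c(d, hidden, target_dim)
  enc <- nn_init(dims, c("sigmoid", "identity"), derive_seed(seed, "sae-enc"))
  dec <- nn_init(rev(dims), c("sigmoid", "identity"), derive_seed(seed, "sae-dec"))
  layers <- c(enc, dec)
  opt <- adam_init(layers)

  mse_of <- function(layers) {
    h <- nn_forward(layers, X_fit)
    mean((h[[length(h)]] - X_fit)^2)
  }
  history <- tibble::tibble(epoch = 0L, mse = mse_of(layers))

  n_fit <- nrow(X_fit)
  for (ep in seq_len(epochs)) {
    h <- nn_forward(layers, X_fit)
    err <- h[[length(h)]] - X_fit
    back <- nn_backward(layers, h, 2 * err / (n_fit * d))
    up <- adam_step(layers, back$grads, opt, learning_rate, ep)
    layers <- up$layers
    opt <- up$state
    history <- dplyr::bind_rows(history,
                                tibble::tibble(epoch = ep, mse = mse_of(layers)))
  }

  enc_trained <- layers[1:2]
  hc <- nn_forward(enc_trained, mat)
  codes <- hc[[length(hc)]]
  rownames(codes) <- rownames(mat)
  colnames(codes) <- paste0("a", seq_len(target_dim))
  structure(
    list(codes = codes, history = history,
         state = list(encoder = enc_trained, decoder = layers[3:4]),
         target_dim = target_dim),
    class = "sim_compression"
  )
}

#' @export
print.sim_compression <- function(x, ...) {
  h <- x$history
  cat("<sim_compression> ", nrow(x$codes), " entities -> ", x$target_dim,
      "-dim codes; reconstruction MSE ", format(h$mse[1], digits = 4),
      " -> ", format(h$mse[nrow(h)], digits = 4), "\n", sep = "")
  invisible(x)
}

#' @method tidy sim_compression
#' @export
tidy.sim_compression <- function(x, ...) x$history

# Resolve a code/embedding matrix from either a matrix or a fitted object.
codes_of <- function(x) {
  if (inherits(x, "sim_compression")) return(x$codes)
  if (inherits(x, "sdne_fit")) return(x$embeddings)
  stopifnot(is.matrix(x))
  x
}

#' Descriptor block boundaries
#'
#' The fused descriptor concatenates, in fixed order, the miRNA behaviour
#' vector (128), the miRNA attribute vector (64), the disease behaviour
#' vector (128) and the disease attribute vector (64): 384 values with
#' block boundaries at 0, 128, 192, 320, 384.
#'
#' @return Named integer vector of cumulative block boundaries.
#' @export
descriptor_blocks <- function() {
  c(mirna_behaviour = 128L, mirna_attribute = 64L,
    disease_behaviour = 128L, disease_attribute = 64L)
}

#' Build the fused feature descriptor of one miRNA-disease pair
#'
#' @param mirna_id,disease_id Pair identity.
#' @param behavior Embedding matrix keyed `type|id` ([fit_sdne()] result
#'   or its `embeddings`).
#' @param attr_m,attr_d Attribute code matrices keyed by raw miRNA /
#'   disease id ([compress_similarity()] results or their `codes`).
#' @return Numeric vector of length 384 (blocks as in
#'   [descriptor_blocks()]).
#' @export
build_descriptor <- function(mirna_id, disease_id, behavior, attr_m, attr_d) {
  emb <- codes_of(behavior)
  am <- codes_of(attr_m)
  ad <- codes_of(attr_d)
  take <- function(mat, key, what) {
    i <- match(key, rownames(mat))
    if (is.na(i)) {
      stop_mdlink(paste0("no ", what, " vector for '", key, "'"),
                  "mdlink_unknown_id")
    }
    mat[i, ]
  }
  out <- c(
    take(emb, node_key("miRNA", mirna_id), "behaviour"),
    take(am, mirna_id, "miRNA attribute"),
    take(emb, node_key("disease", disease_id), "behaviour"),
    take(ad, disease_id, "disease attribute")
  )
  unname(out)
}

#' Enumerate all miRNA x disease pairs
#'
#' @param mirna_ids,disease_ids Character vectors.
#' @return Tibble `mirna_id`, `disease_id` in deterministic order.
#' @export
all_pairs <- function(mirna_ids, disease_ids) {
  out <- tidyr::expand_grid(mirna_id = sort_c(unique(mirna_ids)),
                            disease_id = sort_c(unique(disease_ids)))
  tibble::as_tibble(out)
}

#' Sample negative pairs from the unknown pair space
#'
#' Negatives are drawn uniformly without replacement from the pairs in
#' `universe` that are neither positives nor in `exclude`.
#'
#' @param positives Tibble `mirna_id`, `disease_id` of known pairs.
#' @param universe Tibble of all candidate pairs (see [all_pairs()]).
#' @param ratio Negatives per positive.
#' @param seed Mandatory RNG seed.
#' @param exclude Optional tibble of pairs to keep out of the negative
#'   pool (e.g. negatives already used by another fold).
#' @return Tibble `mirna_id`, `disease_id` of sampled negatives.
#' @export
sample_negatives <- function(positives, universe, ratio = 1, seed = 1L,
                             exclude = NULL) {
  pool <- dplyr::anti_join(universe, positives,
                           by = c("mirna_id", "disease_id"))
  if (!is.null(exclude) && nrow(exclude) > 0L) {
    pool <- dplyr::anti_join(pool, exclude, by = c("mirna_id", "disease_id"))
  }
  n_neg <- round(ratio * nrow(positives))
  if (nrow(pool) < n_neg) {
    stop_mdlink(paste0("not enough unknown pairs (", nrow(pool),
                       ") to sample ", n_neg, " negatives"),
                "mdlink_insufficient_negatives")
  }
  pool <- pool[order_c(pool$mirna_id, pool$disease_id), ]
  with_seed(derive_seed(seed, "neg-sample"), {
    pool[sample.int(nrow(pool), n_neg), ]
  })
}

#' Build a labeled descriptor dataset
#'
#' Combines the known positive pairs with uniformly sampled unknown pairs
#' as negatives (`ratio` negatives per positive), builds the 384-long
#' fused descriptor of every pair and returns the shuffled labeled
#' matrix. Deterministic given `seed`.
#'
#' @inheritParams sample_negatives
#' @inheritParams build_descriptor
#' @param feature_mode `"fused"` (384), `"attributes"` (128: attribute
#'   blocks only) or `"behavior"` (256: behaviour blocks only) — the two
#'   ablations of the fused descriptor.
#' @return Object of class `md_dataset`: `pairs` (tibble `mirna_id`,
#'   `disease_id`, `label` in row order of `X`), `X` (descriptor matrix),
#'   `y` (integer labels).
#' @export
build_dataset <- function(positives, universe, behavior, attr_m, attr_d,
                          ratio = 1, seed = 1L, exclude = NULL,
                          feature_mode = c("fused", "attributes", "behavior")) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(nrow(dplyr::anti_join(positives, universe,
                                  by = c("mirna_id", "disease_id"))) == 0L)
  negs <- sample_negatives(positives, universe, ratio, seed, exclude)
  pairs <- dplyr::bind_rows(
    dplyr::mutate(positives[c("mirna_id", "disease_id")], label = 1L),
    dplyr::mutate(negs[c("mirna_id", "disease_id")], label = 0L)
  )
  pairs <- with_seed(derive_seed(seed, "row-shuffle"), {
    pairs[sample.int(nrow(pairs)), ]
  })
  X <- descriptor_matrix(pairs, behavior, attr_m, attr_d, feature_mode)
  structure(
    list(pairs = pairs, X = X, y = pairs$label, feature_mode = feature_mode),
    class = "md_dataset"
  )
}

# Vectorised descriptor assembly for a pair table.
descriptor_matrix <- function(pairs, behavior, attr_m, attr_d,
                              feature_mode = "fused") {
  emb <- if (feature_mode == "attributes") NULL else codes_of(behavior)
  am <- if (feature_mode == "behavior") NULL else codes_of(attr_m)
  ad <- if (feature_mode == "behavior") NULL else codes_of(attr_d)
  rows_of <- function(mat, keys, what) {
    i <- match(keys, rownames(mat))
    if (anyNA(i)) {
      stop_mdlink(paste0("no ", what, " vector for '", keys[is.na(i)][1], "'"),
                  "mdlink_unknown_id")
    }
    mat[i, , drop = FALSE]
  }
  blocks <- switch(feature_mode,
    fused = list(
      rows_of(emb, node_key("miRNA", pairs$mirna_id), "behaviour"),
      rows_of(am, pairs$mirna_id, "miRNA attribute"),
      rows_of(emb, node_key("disease", pairs$disease_id), "behaviour"),
      rows_of(ad, pairs$disease_id, "disease attribute")
    ),
    attributes = list(
      rows_of(am, pairs$mirna_id, "miRNA attribute"),
      rows_of(ad, pairs$disease_id, "disease attribute")
    ),
    behavior = list(
      rows_of(emb, node_key("miRNA", pairs$mirna_id), "behaviour"),
      rows_of(emb, node_key("disease", pairs$disease_id), "behaviour")
    )
  )
  X <- do.call(cbind, blocks)
  dimnames(X) <- NULL
  X
}

#' @export
print.md_dataset <- function(x, ...) {
  cat("<md_dataset> ", nrow(x$X), " pairs x ", ncol(x$X), " features (",
      sum(x$y == 1), " positive / ", sum(x$y == 0), " negative), mode '",
      x$feature_mode, "'\n", sep = "")
  invisible(x)
}
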