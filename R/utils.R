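# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# Every stochastic operation in the package funnels through this so that a
# single integer seed makes a whole pipeline run reproducible.
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage/fold-specific seed from a master seed. Keeps results for
# different stages decorrelated while remaining a pure function of the master
# seed; result always fits in a 32-bit signed integer.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  h <- 0
  for (p in parts) {
    x <- if (is.character(p)) sum(utf8ToInt(p) * seq_along(utf8ToInt(p))) else as.numeric(p)
    h <- (h * 31 + x + 7) %% 2147483647
  }
  as.integer(h %% 2147483562 + 1)
}

# C-locale deterministic sort (independent of the session's collation).
sort_c <- function(x) sort(x, method = "radix")

order_c <- function(...) order(..., method = "radix")

# Compose the canonical node key used as dimnames of adjacency/embedding
# matrices. Keyed by (type, id) so ids shared across types never collide.
node_key <- function(node_type, node_id) paste(node_type, node_id, sep = "|")

stop_mdlink <- function(msg, class) {
  rlang::abort(msg, class = c(class, "mdlink_error"))
}
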