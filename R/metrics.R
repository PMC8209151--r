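#' Split positive pairs into five disjoint folds
#'
#' Random partition of the known miRNA-disease pairs into `k` subsets of
#' near-equal size (differing by at most one); deterministic per seed.
#'
#' @param positives Tibble `mirna_id`, `disease_id`.
#' @param k Number of folds.
#' @param seed Mandatory RNG seed.
#' @return The input tibble with an integer `fold` column in `1:k`.
#' @export
five_fold_split <- function(positives, k = 5, seed = 1L) {
  stopifnot(is.data.frame(positives), k >= 2)
  n <- nrow(positives)
  if (n < k) {
    stop_mdlink(paste0("need at least ", k, " positives, got ", n),
                "mdlink_too_few")
  }
  positives <- positives[order_c(positives$mirna_id, positives$disease_id), ]
  fold <- with_seed(derive_seed(seed, "fold-split"), {
    sample(rep(seq_len(k), length.out = n))
  })
  dplyr::mutate(tibble::as_tibble(positives), fold = as.integer(fold))
}

#' Classification metrics for scored pairs
#'
#' Computes the confusion matrix at `threshold` plus the derived metrics:
#' accuracy, sensitivity (recall), specificity, precision, Matthews
#' correlation coefficient, AUC (rank-based Mann-Whitney statistic with
#' tie correction) and AUPR (average precision over unique score
#' thresholds). MCC is defined as 0 when any marginal of the confusion
#' matrix is empty.
#'
#' @param labels Binary labels (0/1).
#' @param scores Numeric scores, higher meaning more likely associated.
#' @param threshold Score cut for the confusion matrix.
#' @return One-row tibble with `n`, `tp`, `fp`, `tn`, `fn`, `acc`, `sen`,
#'   `spec`, `prec`, `mcc`, `auc`, `aupr`.
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  labels <- as.integer(labels)
  if (length(labels) == 0L) {
    stop_mdlink("empty input", "mdlink_empty_input")
  }
  if (length(labels) != length(scores)) {
    stop_mdlink("labels and scores differ in length", "mdlink_dim_mismatch")
  }
  if (any(!labels %in% c(0L, 1L)) || any(!is.finite(scores))) {
    stop_mdlink("labels must be 0/1 and scores finite", "mdlink_bad_input")
  }
  if (length(unique(labels)) < 2L) {
    stop_mdlink("AUC undefined: only one class present", "mdlink_single_class")
  }
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mcc_den == 0) 0 else (tp * tn - fp * fn) / mcc_den
  tibble::tibble(
    n = n, tp = tp, fp = fp, tn = tn, fn = fn,
    acc = (tp + tn) / n,
    sen = safe_div(tp, tp + fn),
    spec = safe_div(tn, tn + fp),
    prec = safe_div(tp, tp + fp),
    mcc = mcc,
    auc = auc_rank(labels, scores),
    aupr = average_precision(labels, scores)
  )
}

# Mann-Whitney AUC with midrank tie correction: the probability that a
# random positive outscores a random negative, ties counting 1/2.
auc_rank <- function(labels, scores) {
  r <- rank(scores, ties.method = "average")
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

# Average precision: sum over descending unique thresholds of
# (recall step) x (precision at threshold).
average_precision <- function(labels, scores) {
  ord <- order(-scores, labels)
  lab <- labels[ord]
  sc <- scores[ord]
  tp_cum <- cumsum(lab)
  n_seen <- seq_along(lab)
  last_of_block <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp_b <- tp_cum[last_of_block]
  n_b <- n_seen[last_of_block]
  prec <- tp_b / n_b
  recall <- tp_b / sum(lab)
  sum(diff(c(0, recall)) * prec)
}

#' Summarise per-fold metrics as mean and standard deviation
#'
#' @param fold_metrics Tibble of per-fold metric rows (from [run_cv()]).
#' @return Tibble `metric`, `mean`, `sd`.
#' @export
summarise_folds <- function(fold_metrics) {
  cols <- intersect(c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr"),
                    names(fold_metrics))
  long <- tidyr::pivot_longer(fold_metrics[cols], dplyr::all_of(cols),
                              names_to = "metric", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$metric),
    mean = mean(.data$value), sd = stats::sd(.data$value), .groups = "drop"
  )
  out[match(cols, out$metric), ]
}
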