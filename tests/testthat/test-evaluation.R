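test_that("five-fold splits partition the positives evenly", {
  pos <- all_pairs(sprintf("m%d", 1:5), sprintf("d%d", 1:2))
  expect_equal(nrow(pos), 10L)
  f <- five_fold_split(pos, 5, seed = 3)
  expect_equal(as.integer(table(f$fold)), rep(2L, 5))
  expect_equal(nrow(dplyr::distinct(f[c("mirna_id", "disease_id")])), 10L)
  expect_identical(five_fold_split(pos, 5, seed = 3), f)
  expect_false(identical(five_fold_split(pos, 5, seed = 4)$fold, f$fold))
  expect_error(five_fold_split(pos[1:3, ], 5, seed = 1),
               class = "mdlink_too_few")
})

test_that("metrics reproduce hand-derived confusion values", {
  # perfect classifier
  m <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1))
  expect_equal(unlist(m[c("acc", "sen", "spec", "prec", "mcc", "auc", "aupr")]),
               c(acc = 1, sen = 1, spec = 1, prec = 1, mcc = 1, auc = 1,
                 aupr = 1))

  # TP=3 FP=1 TN=2 FN=0
  labels <- c(1, 1, 1, 0, 0, 0)
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.3, 0.2)
  m2 <- compute_metrics(labels, scores)
  expect_equal(m2$tp, 3)
  expect_equal(m2$fp, 1)
  expect_equal(m2$tn, 2)
  expect_equal(m2$fn, 0)
  expect_equal(m2$acc, 5 / 6)
  expect_equal(m2$prec, 0.75)
  expect_equal(m2$spec, 2 / 3)
  expect_equal(m2$mcc, 6 / sqrt(72))

  # all-positive predictions on balanced labels
  m3 <- compute_metrics(c(1, 1, 0, 0), c(0.9, 0.8, 0.7, 0.6))
  expect_equal(m3$sen, 1)
  expect_equal(m3$spec, 0)
  expect_equal(m3$mcc, 0)

  expect_error(compute_metrics(numeric(0), numeric(0)),
               class = "mdlink_empty_input")
  expect_error(compute_metrics(c(1, 1), c(0.5, 0.6)),
               class = "mdlink_single_class")
  expect_error(compute_metrics(c(1, 0), c(0.5)), class = "mdlink_dim_mismatch")
})

test_that("rank AUC equals the brute-force pairwise probability", {
  brute_auc <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
    tot / (length(pos) * length(neg))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(61)
  for (r in 1:10) {
    n <- sample(20:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    scores <- round(runif(n), 2) # coarse scores force ties
    m <- compute_metrics(labels, scores)
    expect_equal(m$auc, brute_auc(labels, scores))
  }
})

test_that("fold summaries are recomputable means and sds", {
  fake <- tibble::tibble(
    fold = 1:5,
    acc = runif(5), sen = runif(5), spec = runif(5), prec = runif(5),
    mcc = runif(5), auc = runif(5), aupr = runif(5)
  )
  s <- summarise_folds(fake)
  for (metric in s$metric) {
    expect_equal(s$mean[s$metric == metric], mean(fake[[metric]]),
                 tolerance = 1e-12)
    expect_equal(s$sd[s$metric == metric], stats::sd(fake[[metric]]),
                 tolerance = 1e-12)
  }
})

test_that("the CV harness runs per fold with clean leakage audits", {
  fix <- tiny_fixture()
  cv <- suppressWarnings(run_cv(fix$network, fix$sequences, fix$mesh,
                                fix$positives,
                                tiny_config(classifier = "logistic"),
                                seed = 7))
  expect_s3_class(cv, "md_cv")
  expect_equal(nrow(cv$folds), 5L)
  expect_equal(sort(cv$folds$fold), 1:5)
  expect_true(all(cv$leakage$clean))
  expect_equal(cv$leakage$test_edges_in_network, rep(0, 5))
  expect_equal(cv$leakage$test_pos_in_training, rep(0, 5))
  # summary equals independent recomputation from the fold table
  expect_equal(cv$summary$mean[cv$summary$metric == "auc"],
               mean(cv$folds$auc), tolerance = 1e-12)
  # the harness accepts any registry entry unchanged
  cv_nb <- suppressWarnings(run_cv(fix$network, fix$sequences, fix$mesh,
                                   fix$positives,
                                   tiny_config(classifier = "naive_bayes"),
                                   seed = 7))
  expect_equal(nrow(cv_nb$folds), 5L)
  # tidy/glance accessors
  expect_equal(nrow(tidy(cv)), 5L)
  expect_true(glance(cv)$leakage_clean)
})

test_that("candidate ranking excludes knowns and orders deterministically", {
  fix <- tiny_fixture()
  model <- suppressWarnings(fit_pipeline(
    fix$network, fix$sequences, fix$mesh, fix$positives,
    tiny_config(classifier = "logistic"), seed = 7
  ))
  dis <- fix$positives$disease_id[1]
  known <- fix$positives$mirna_id[fix$positives$disease_id == dis]
  rk <- rank_candidates(model, dis, k = 5)
  expect_equal(rk$rank, 1:5)
  expect_equal(nrow(dplyr::filter(rk, .data$mirna_id %in% known)), 0L)
  expect_true(all(diff(rk$score) <= 0))
  # ties break lexicographically by id
  tied <- rk[rk$score == rk$score[1], ]
  expect_equal(tied$mirna_id, sort(tied$mirna_id))
  # k above the pool returns the whole pool
  expect_message(rk_all <- rank_candidates(model, dis, k = 10000),
                 "returning all")
  expect_equal(nrow(rk_all), length(setdiff(unique(fix$sequences$id), known)))
  expect_error(rank_candidates(model, "ghost"),
               class = "mdlink_unknown_disease")
})

test_that("ranking concentrates on the planted block", {
  fix <- default_fixture()
  model <- suppressWarnings(fit_pipeline(
    fix$network, fix$sequences, fix$mesh, fix$positives,
    fixture_pipeline_config(classifier = "bagging"), seed = 7,
    features = "behavior"
  ))
  blocks <- stats::setNames(fix$nodes$block, fix$nodes$node_id)
  dis <- fix$nodes$node_id[fix$nodes$node_type == "disease"][1]
  rk <- rank_candidates(model, dis, k = 10)
  frac_in_block <- mean(blocks[rk$mirna_id] == blocks[dis])
  expect_gte(frac_in_block, 0.8)
})
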