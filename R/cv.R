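#' Pipeline configuration
#'
#' Collects the tunable settings of the full pipeline: the SDNE embedding
#' config, the CNN config, the attribute-compression settings, the
#' negative-sampling ratio, the number of CV folds and the decision
#' threshold for confusion-based metrics.
#'
#' @param sdne An [sdne_config()].
#' @param cnn A [cnn_config()].
#' @param compress List with `dim`, `hidden`, `epochs`, `learning_rate`
#'   for [compress_similarity()].
#' @param negative_ratio Negatives sampled per positive.
#' @param folds Number of cross-validation folds (>= 2).
#' @param threshold Score cut for confusion-based metrics.
#' @param classifier Registry key of the classifier
#'   ([baseline_classifiers()]; `"cnn"` for the convolutional model).
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sdne = sdne_config(), cnn = cnn_config(),
                            compress = list(dim = 64, hidden = 256,
                                            epochs = 100, learning_rate = 1e-3),
                            negative_ratio = 1, folds = 5, threshold = 0.5,
                            classifier = "cnn") {
  stopifnot(inherits(sdne, "sdne_config"), inherits(cnn, "cnn_config"),
            folds >= 2, negative_ratio > 0, threshold > 0, threshold < 1)
  if (!classifier %in% names(baseline_classifiers())) {
    stop_mdlink(paste0("unknown classifier '", classifier, "'"),
                "mdlink_bad_param")
  }
  structure(
    list(sdne = sdne, cnn = cnn, compress = compress,
         negative_ratio = negative_ratio, folds = as.integer(folds),
         threshold = threshold, classifier = classifier),
    class = "pipeline_config"
  )
}

#' Evaluation configuration for the bundled fixture scale
#'
#' [pipeline_config()] defaults target realistically sized networks; for
#' the minute-scale planted-block fixtures ([fixture_spec()], ~200 nodes,
#' a few hundred positive pairs) shorter training schedules suffice and
#' keep a full five-fold run fast: 30 SDNE epochs and 20 CNN epochs, all
#' other settings unchanged. This is the configuration used by the
#' package's own evaluation runs on generated fixtures.
#'
#' @param ... Overrides forwarded to [pipeline_config()].
#' @return A [pipeline_config()].
#' @export
fixture_pipeline_config <- function(...) {
  pipeline_config(
    sdne = sdne_config(epochs = 30),
    cnn = cnn_config(epochs = 20),
    ...
  )
}

# Fit the configured classifier on a labeled descriptor matrix.
fit_configured_classifier <- function(X, y, config, seed) {
  if (config$classifier == "cnn") {
    cfg <- config$cnn
    cfg$seed <- seed
    fit(build_cnn(ncol(X), cfg), X, y)
  } else {
    spec <- baseline_classifiers()[[config$classifier]]
    fit(spec, X, y, seed = seed)
  }
}

# Attribute compression of both similarity matrices, optionally fitted on a
# subset of entities (training-fold rows) and applied to all.
compress_attributes <- function(msim, dsim, config, seed,
                                fit_mirnas = NULL, fit_diseases = NULL) {
  cp <- config$compress
  list(
    m = compress_similarity(msim, target_dim = cp$dim, hidden = cp$hidden,
                            epochs = cp$epochs,
                            learning_rate = cp$learning_rate,
                            seed = derive_seed(seed, "compress-m"),
                            fit_ids = fit_mirnas),
    d = compress_similarity(dsim, target_dim = cp$dim, hidden = cp$hidden,
                            epochs = cp$epochs,
                            learning_rate = cp$learning_rate,
                            seed = derive_seed(seed, "compress-d"),
                            fit_ids = fit_diseases)
  )
}

#' Leakage-controlled cross validation of the full pipeline
#'
#' For each fold the test-fold miRNA-disease edges are removed from the
#' network *before* the SDNE embedding is computed, the attribute
#' compression is fitted on training-fold entities only, train and test
#' negatives are sampled disjointly from the unknown pairs, and the
#' classifier sees training rows only. A programmatic leakage audit of
#' every fold is recorded in the result.
#'
#' @param network A [hetero_network()] containing the known
#'   miRNA-disease edges.
#' @param sequences Tibble `id`, `seq` of miRNA sequences.
#' @param mesh Tibble `disease_id`, `tree_number`.
#' @param positives Tibble `mirna_id`, `disease_id` of known pairs.
#' @param config A [pipeline_config()].
#' @param seed Master seed; all per-fold randomness derives from it.
#' @param features `"fused"` (default), `"attributes"` or `"behavior"` —
#'   the full descriptor or one of the two single-view ablations.
#' @return Object of class `md_cv`: `folds` (per-fold metric tibble),
#'   `summary` (mean/sd per metric), `scores` (per-fold labels and
#'   scores), `leakage` (per-fold audit), `config`, `seed`, `features`.
#' @export
run_cv <- function(network, sequences, mesh, positives,
                   config = pipeline_config(), seed = 1L,
                   features = c("fused", "attributes", "behavior")) {
  features <- match.arg(features)
  stopifnot(inherits(network, "hetero_network"),
            inherits(config, "pipeline_config"))
  positives <- dplyr::distinct(tibble::as_tibble(
    positives[c("mirna_id", "disease_id")]
  ))

  net_mirnas <- network$nodes$node_id[network$nodes$node_type == "miRNA"]
  net_diseases <- network$nodes$node_id[network$nodes$node_type == "disease"]

  use_attr <- features %in% c("fused", "attributes")
  use_behav <- features %in% c("fused", "behavior")

  msim <- NULL
  dsim <- NULL
  if (use_attr) {
    msim <- cgr_similarity_matrix(sequences)
    dsim <- disease_similarity_matrix(mesh,
                                      diseases = unique(positives$disease_id))
  }

  mirna_ids <- intersect(net_mirnas,
                         if (use_attr) rownames(msim) else net_mirnas)
  disease_ids <- intersect(net_diseases,
                           if (use_attr) rownames(dsim) else net_diseases)
  universe <- all_pairs(mirna_ids, disease_ids)
  positives <- dplyr::semi_join(positives, universe,
                                by = c("mirna_id", "disease_id"))

  folds <- five_fold_split(positives, config$folds, seed)
  fold_metrics <- list()
  fold_scores <- list()
  audits <- list()

  for (f in sort(unique(folds$fold))) {
    test_pos <- dplyr::select(dplyr::filter(folds, .data$fold == f),
                              "mirna_id", "disease_id")
    train_pos <- dplyr::select(dplyr::filter(folds, .data$fold != f),
                               "mirna_id", "disease_id")
    if (nrow(test_pos) == 0L) {
      stop_mdlink(paste0("fold ", f, " has an empty test set"),
                  "mdlink_empty_fold")
    }
    net_f <- suppressWarnings(remove_md_edges(network, test_pos))

    behavior <- NULL
    if (use_behav) {
      scfg <- config$sdne
      scfg$seed <- derive_seed(seed, "sdne", f)
      behavior <- fit_sdne(net_f, scfg)
    }

    train_neg <- sample_negatives(train_pos, universe,
                                  ratio = config$negative_ratio,
                                  seed = derive_seed(seed, "train-neg", f),
                                  exclude = positives)
    test_neg <- sample_negatives(test_pos, universe,
                                 ratio = config$negative_ratio,
                                 seed = derive_seed(seed, "test-neg", f),
                                 exclude = dplyr::bind_rows(positives, train_neg))

    attrs <- list(m = NULL, d = NULL)
    if (use_attr) {
      fit_m <- unique(c(train_pos$mirna_id, train_neg$mirna_id))
      fit_d <- unique(c(train_pos$disease_id, train_neg$disease_id))
      attrs <- compress_attributes(msim, dsim, config,
                                   derive_seed(seed, "compress", f),
                                   fit_mirnas = fit_m, fit_diseases = fit_d)
    }

    build_xy <- function(pos, neg, shuffle_seed) {
      pairs <- dplyr::bind_rows(
        dplyr::mutate(pos, label = 1L),
        dplyr::mutate(neg, label = 0L)
      )
      pairs <- with_seed(shuffle_seed, pairs[sample.int(nrow(pairs)), ])
      list(pairs = pairs,
           X = descriptor_matrix(pairs, behavior, attrs$m, attrs$d, features),
           y = pairs$label)
    }
    train <- build_xy(train_pos, train_neg, derive_seed(seed, "shuf-tr", f))
    test <- build_xy(test_pos, test_neg, derive_seed(seed, "shuf-te", f))

    audits[[f]] <- leakage_audit_fold(net_f, train$pairs, test_pos)

    clf <- fit_configured_classifier(train$X, train$y, config,
                                     derive_seed(seed, "clf", f))
    scores <- predict_proba(clf, test$X)
    fold_metrics[[f]] <- dplyr::mutate(
      compute_metrics(test$y, scores, config$threshold),
      fold = f, .before = 1
    )
    fold_scores[[f]] <- tibble::tibble(fold = f, label = test$y, score = scores)
  }

  fold_tbl <- dplyr::bind_rows(fold_metrics)
  structure(
    list(
      folds = fold_tbl,
      summary = summarise_folds(fold_tbl),
      scores = dplyr::bind_rows(fold_scores),
      leakage = dplyr::bind_rows(audits),
      config = config, seed = seed, features = features,
      fold_assignment = folds
    ),
    class = "md_cv"
  )
}

# Programmatic leakage audit of one fold: no test positive present as an
# edge of the embedded network, nor as a training row.
leakage_audit_fold <- function(net_f, train_pairs, test_pos) {
  keys <- rownames(net_f$adjacency)
  i <- match(node_key("miRNA", test_pos$mirna_id), keys)
  j <- match(node_key("disease", test_pos$disease_id), keys)
  ok <- !is.na(i) & !is.na(j)
  edges_present <- sum(net_f$adjacency[cbind(i[ok], j[ok])])
  overlap <- nrow(dplyr::semi_join(train_pairs, test_pos,
                                   by = c("mirna_id", "disease_id")))
  tibble::tibble(
    n_test_pos = nrow(test_pos),
    test_edges_in_network = edges_present,
    test_pos_in_training = overlap,
    clean = edges_present == 0 && overlap == 0
  )
}

#' @export
print.md_cv <- function(x, ...) {
  cat("<md_cv> ", max(x$folds$fold), "-fold cross validation (features: ",
      x$features, ", classifier: ", x$config$classifier, ")\n", sep = "")
  s <- x$summary
  cat(paste0("  ", s$metric, " = ", sprintf("%.4f", s$mean), " ± ",
             sprintf("%.4f", s$sd), collapse = "\n"), "\n", sep = "")
  cat("  leakage audit: ",
      if (all(x$leakage$clean)) "clean on every fold" else "VIOLATIONS FOUND",
      "\n", sep = "")
  invisible(x)
}

#' @rdname run_cv
#' @param x An `md_cv`.
#' @param ... Unused.
#' @return `tidy()`: the per-fold metric tibble; `glance()`: a one-row
#'   tibble of fold means (columns `mean_acc`, ..., `mean_auc`,
#'   `leakage_clean`).
#' @method tidy md_cv
#' @export
tidy.md_cv <- function(x, ...) x$folds

#' @rdname run_cv
#' @method glance md_cv
#' @export
glance.md_cv <- function(x, ...) {
  s <- x$summary
  out <- as.list(s$mean)
  names(out) <- paste0("mean_", s$metric)
  tibble::tibble(!!!out, folds = max(x$folds$fold),
                 leakage_clean = all(x$leakage$clean))
}

#' Fit the full pipeline on all known associations
#'
#' Case-study mode: embeddings, attribute compression and the classifier
#' are trained on the complete network and every known positive pair, so
#' the model can score unknown pairs ([rank_candidates()]).
#'
#' @inheritParams run_cv
#' @return Object of class `md_model` holding the trained components and
#'   the pair universe.
#' @export
fit_pipeline <- function(network, sequences, mesh, positives,
                         config = pipeline_config(), seed = 1L,
                         features = c("fused", "attributes", "behavior")) {
  features <- match.arg(features)
  positives <- dplyr::distinct(tibble::as_tibble(
    positives[c("mirna_id", "disease_id")]
  ))
  use_attr <- features %in% c("fused", "attributes")
  use_behav <- features %in% c("fused", "behavior")

  msim <- NULL
  dsim <- NULL
  attrs <- list(m = NULL, d = NULL)
  if (use_attr) {
    msim <- cgr_similarity_matrix(sequences)
    dsim <- disease_similarity_matrix(mesh,
                                      diseases = unique(positives$disease_id))
    attrs <- compress_attributes(msim, dsim, config,
                                 derive_seed(seed, "compress-full"))
  }
  behavior <- NULL
  if (use_behav) {
    scfg <- config$sdne
    scfg$seed <- derive_seed(seed, "sdne-full")
    behavior <- fit_sdne(network, scfg)
  }

  net_mirnas <- network$nodes$node_id[network$nodes$node_type == "miRNA"]
  net_diseases <- network$nodes$node_id[network$nodes$node_type == "disease"]
  mirna_ids <- intersect(net_mirnas,
                         if (use_attr) rownames(msim) else net_mirnas)
  disease_ids <- intersect(net_diseases,
                           if (use_attr) rownames(dsim) else net_diseases)
  universe <- all_pairs(mirna_ids, disease_ids)
  positives <- dplyr::semi_join(positives, universe,
                                by = c("mirna_id", "disease_id"))

  ds <- build_dataset(positives, universe, behavior, attrs$m, attrs$d,
                      ratio = config$negative_ratio,
                      seed = derive_seed(seed, "full-data"),
                      feature_mode = features)
  clf <- fit_configured_classifier(ds$X, ds$y, config,
                                   derive_seed(seed, "clf-full"))
  structure(
    list(classifier = clf, behavior = behavior, attrs = attrs,
         universe = universe, positives = positives,
         config = config, seed = seed, features = features),
    class = "md_model"
  )
}

#' @export
print.md_model <- function(x, ...) {
  cat("<md_model> trained on ", nrow(x$positives), " positive pairs (",
      x$features, " features, ", x$config$classifier, " classifier)\n",
      sep = "")
  invisible(x)
}

#' Rank candidate miRNAs for a disease
#'
#' Scores every miRNA not already associated with the disease with a
#' trained [fit_pipeline()] model and returns the top `k` candidates by
#' descending score, ties broken by miRNA id (lexicographic).
#'
#' @param model An `md_model`.
#' @param disease_id Disease to rank candidates for.
#' @param k Number of candidates to return; if the candidate pool is
#'   smaller the whole pool is returned with a message.
#' @return Tibble `rank`, `mirna_id`, `score`.
#' @export
rank_candidates <- function(model, disease_id, k = 50) {
  stopifnot(inherits(model, "md_model"))
  if (!disease_id %in% model$universe$disease_id) {
    stop_mdlink(paste0("unknown disease '", disease_id, "'"),
                "mdlink_unknown_disease")
  }
  known <- model$positives$mirna_id[model$positives$disease_id == disease_id]
  cands <- setdiff(unique(model$universe$mirna_id), known)
  if (length(cands) == 0L) {
    stop_mdlink("no candidate miRNAs left for this disease", "mdlink_too_few")
  }
  if (k > length(cands)) {
    rlang::inform(paste0("only ", length(cands),
                         " candidates available; returning all"))
    k <- length(cands)
  }
  pairs <- tibble::tibble(mirna_id = sort_c(cands), disease_id = disease_id)
  X <- descriptor_matrix(pairs, model$behavior, model$attrs$m, model$attrs$d,
                         model$features)
  score <- predict_proba(model$classifier, X)
  out <- tibble::tibble(mirna_id = pairs$mirna_id, score = score)
  out <- out[order(-out$score, xtfrm(out$mirna_id)), ]
  out <- utils::head(out, k)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}
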