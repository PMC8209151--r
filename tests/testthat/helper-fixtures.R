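# Shared fixtures and a session-level cache so expensive end-to-end runs
# (full cross validations) are computed once and reused across test files.

.mdlink_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (is.null(.mdlink_test_cache[[name]])) {
    .mdlink_test_cache[[name]] <- force(expr)
  }
  .mdlink_test_cache[[name]]
}

# The default planted-block fixture used throughout the suite.
default_fixture <- function() {
  cached("fixture", make_fixture(fixture_spec(seed = 11)))
}

# A miniature fixture for fast mechanical tests of the CV harness.
tiny_fixture <- function() {
  cached("tiny", make_fixture(fixture_spec(
    n_mirna = 16, n_disease = 12, n_protein = 12, n_lncrna = 8, n_drug = 8,
    n_blocks = 2, p_in = 0.5, p_out = 0.05, seed = 21
  )))
}

# Lightweight pipeline settings for mechanical tests (not used for the
# signal-recovery checks).
tiny_config <- function(...) {
  pipeline_config(
    sdne = sdne_config(epochs = 3, layer_dims = c(32, 16)),
    cnn = cnn_config(epochs = 2),
    compress = list(dim = 8, hidden = 16, epochs = 10, learning_rate = 1e-3),
    ...
  )
}

# Full-scale evaluation runs shared by the acceptance tests.
cv_fused <- function() {
  fix <- default_fixture()
  cached("cv_fused", suppressWarnings(
    run_cv(fix$network, fix$sequences, fix$mesh, fix$positives,
           fixture_pipeline_config(), seed = 5, features = "fused")
  ))
}

cv_attributes <- function() {
  fix <- default_fixture()
  cached("cv_attributes", suppressWarnings(
    run_cv(fix$network, fix$sequences, fix$mesh, fix$positives,
           fixture_pipeline_config(), seed = 5, features = "attributes")
  ))
}

cv_behavior <- function() {
  fix <- default_fixture()
  cached("cv_behavior", suppressWarnings(
    run_cv(fix$network, fix$sequences, fix$mesh, fix$positives,
           fixture_pipeline_config(), seed = 5, features = "behavior")
  ))
}

# Random edge tibble over typed nodes, for network unit tests.
random_edges <- function(n_edges, seed) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    code
  }
  withr_seed({
    grid <- expand.grid(m = sprintf("m%02d", 1:20), d = sprintf("d%02d", 1:20),
                        stringsAsFactors = FALSE)
    pick <- grid[sample.int(nrow(grid), n_edges), ]
    tibble::tibble(
      source_type = "miRNA", source_id = pick$m,
      target_type = "disease", target_id = pick$d,
      assoc_type = "mirna_disease"
    )
  })
}

write_tsv_lines <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
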