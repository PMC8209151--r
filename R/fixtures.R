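#' Specification of a synthetic planted-block fixture
#'
#' The fixture generators emulate every input of the pipeline with a
#' known planted structure: nodes of all five types are assigned
#' round-robin to `n_blocks` blocks; miRNA-disease edges appear with
#' probability `p_in` inside matched blocks and `p_out` across blocks;
#' the other eight association types are sampled with the same
#' block-correlated pattern (`density_in` / `density_out`); miRNAs of the
#' same block share a planted 6-mer sequence motif; diseases of the same
#' block share deep MeSH ancestors. Because `p_in > p_out`, the signal is
#' recoverable and cross validation on the fixture has a known
#' qualitative outcome.
#'
#' Default scale (60 miRNAs, 40 diseases, 50 proteins, 30 lncRNAs,
#' 30 drugs, 3 blocks, p_in 0.3, p_out 0.02) keeps a full end-to-end run
#' minute-scale.
#'
#' @param n_mirna,n_disease,n_protein,n_lncrna,n_drug Node counts.
#' @param n_blocks Number of planted blocks.
#' @param p_in,p_out Within/between-block miRNA-disease edge
#'   probabilities (`p_in > p_out` plants a signal; equal values give a
#'   null fixture).
#' @param density_in,density_out Within/between-block densities of the
#'   other eight association types.
#' @param seq_len Length range of generated miRNA sequences (nt).
#' @param motif_len Length of the planted per-block sequence motif.
#' @param dag_depth Depth of the per-block MeSH backbone chain.
#' @param seed Mandatory RNG seed; every generator output is a pure
#'   function of spec + seed.
#' @return List of class `fixture_spec`.
#' @export
fixture_spec <- function(n_mirna = 60, n_disease = 40, n_protein = 50,
                         n_lncrna = 30, n_drug = 30, n_blocks = 3,
                         p_in = 0.3, p_out = 0.02,
                         density_in = 0.15, density_out = 0.02,
                         seq_len = c(20, 25), motif_len = 6,
                         dag_depth = 3, seed = 1L) {
  stopifnot(p_in >= 0, p_in <= 1, p_out >= 0, p_out <= 1,
            p_in >= p_out,
            density_in >= 0, density_in <= 1,
            density_out >= 0, density_out <= 1,
            n_blocks >= 1, length(seq_len) == 2, seq_len[1] <= seq_len[2],
            motif_len >= 1, motif_len <= seq_len[1], dag_depth >= 1)
  structure(
    list(n_mirna = n_mirna, n_disease = n_disease, n_protein = n_protein,
         n_lncrna = n_lncrna, n_drug = n_drug, n_blocks = n_blocks,
         p_in = p_in, p_out = p_out,
         density_in = density_in, density_out = density_out,
         seq_len = as.integer(seq_len), motif_len = as.integer(motif_len),
         dag_depth = as.integer(dag_depth), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

fixture_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))

fixture_blocks <- function(n, n_blocks) ((seq_len(n) - 1L) %% n_blocks) + 1L

#' Fixture node roster with block assignment
#'
#' @param spec A [fixture_spec()].
#' @return Tibble `node_type`, `node_id`, `block`.
#' @export
fixture_nodes <- function(spec) {
  counts <- c(miRNA = spec$n_mirna, disease = spec$n_disease,
              protein = spec$n_protein, lncRNA = spec$n_lncrna,
              drug = spec$n_drug)
  prefix <- c(miRNA = "mir", disease = "dis", protein = "pro",
              lncRNA = "lnc", drug = "drg")
  dplyr::bind_rows(lapply(names(counts), function(tp) {
    tibble::tibble(
      node_type = tp,
      node_id = fixture_ids(prefix[[tp]], counts[[tp]]),
      block = fixture_blocks(counts[[tp]], spec$n_blocks)
    )
  }))
}

#' Generate miRNA sequences with planted block motifs
#'
#' Random RNA sequences of 20-25 nt; every miRNA of a block carries that
#' block's 6-mer motif at a random position, giving within-block CGR
#' descriptors a shared signal.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble `id`, `block`, `seq`.
#' @export
generate_sequences <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nodes <- fixture_nodes(spec)
  mir <- nodes[nodes$node_type == "miRNA", ]
  bases <- c("A", "C", "G", "U")
  with_seed(derive_seed(spec$seed, "sequences"), {
    motifs <- vapply(seq_len(spec$n_blocks), function(b) {
      paste(sample(bases, spec$motif_len, replace = TRUE), collapse = "")
    }, "")
    seqs <- vapply(seq_len(nrow(mir)), function(i) {
      len <- sample(spec$seq_len[1]:spec$seq_len[2], 1)
      s <- sample(bases, len, replace = TRUE)
      motif <- strsplit(motifs[mir$block[i]], "")[[1]]
      start <- sample(len - spec$motif_len + 1L, 1)
      s[start:(start + spec$motif_len - 1L)] <- motif
      paste(s, collapse = "")
    }, "")
    tibble::tibble(id = mir$node_id, block = mir$block, seq = seqs)
  })
}

#' Generate a toy MeSH tree-number table
#'
#' Each block owns a rooted backbone chain (`Cbb`, `Cbb.100`,
#' `Cbb.100.100`, ...); every disease of the block attaches a private
#' leaf at a random backbone depth, so diseases of the same block share
#' ancestors (the deeper the attachment, the more) while diseases of
#' different blocks share none.
#'
#' @param spec A [fixture_spec()].
#' @return Tibble `disease_id`, `tree_number`.
#' @export
generate_mesh_table <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  nodes <- fixture_nodes(spec)
  dis <- nodes[nodes$node_type == "disease", ]
  with_seed(derive_seed(spec$seed, "mesh"), {
    backbone <- lapply(seq_len(spec$n_blocks), function(b) {
      root <- sprintf("C%02d", b)
      Reduce(function(acc, k) paste0(acc, ".100"), seq_len(spec$dag_depth - 1L),
             accumulate = TRUE, init = root)
    })
    depth <- sample(spec$dag_depth, nrow(dis), replace = TRUE)
    tibble::tibble(
      disease_id = dis$node_id,
      tree_number = vapply(seq_len(nrow(dis)), function(i) {
        paste0(backbone[[dis$block[i]]][depth[i]], ".", 500 + i)
      }, "")
    )
  })
}

# Sample block-correlated edges between two node tables.
sample_bipartite <- function(a, b, p_in, p_out, assoc_type, seed,
                             same_type = FALSE) {
  grid <- tidyr::expand_grid(i = seq_len(nrow(a)), j = seq_len(nrow(b)))
  if (same_type) grid <- grid[grid$i < grid$j, ]
  p <- ifelse(a$block[grid$i] == b$block[grid$j], p_in, p_out)
  keep <- with_seed(seed, stats::runif(nrow(grid)) < p)
  ends <- assoc_endpoint_types(assoc_type)
  tibble::tibble(
    source_type = ends[1], source_id = a$node_id[grid$i[keep]],
    target_type = ends[2], target_id = b$node_id[grid$j[keep]],
    assoc_type = assoc_type
  )
}

#' Generate the planted-block molecular association network
#'
#' Samples all nine association types over the fixture's node roster.
#' miRNA-disease edges use `p_in`/`p_out`; the other eight types use
#' `density_in`/`density_out` with the same block correlation. The
#' positives table is exactly the sampled miRNA-disease edge set.
#'
#' @param spec A [fixture_spec()].
#' @return List with `edges` (named list of nine edge tibbles),
#'   `positives` (tibble `mirna_id`, `disease_id`), `nodes` (roster with
#'   blocks).
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  for (fld in c("n_mirna", "n_disease", "n_protein", "n_lncrna", "n_drug")) {
    if (spec[[fld]] < 1) {
      stop_mdlink(paste0("fixture needs at least one node of each type (",
                         fld, " = ", spec[[fld]], ")"),
                  "mdlink_degenerate_spec")
    }
  }
  nodes <- fixture_nodes(spec)
  tab <- function(tp) nodes[nodes$node_type == tp, ]
  mi <- tab("miRNA"); di <- tab("disease"); pr <- tab("protein")
  ln <- tab("lncRNA"); dr <- tab("drug")

  edges <- list(
    mirna_disease = sample_bipartite(mi, di, spec$p_in, spec$p_out,
                                     "mirna_disease",
                                     derive_seed(spec$seed, "e-md")),
    mirna_protein = sample_bipartite(mi, pr, spec$density_in, spec$density_out,
                                     "mirna_protein",
                                     derive_seed(spec$seed, "e-mp")),
    mirna_lncrna = sample_bipartite(mi, ln, spec$density_in, spec$density_out,
                                    "mirna_lncrna",
                                    derive_seed(spec$seed, "e-ml")),
    lncrna_disease = sample_bipartite(ln, di, spec$density_in, spec$density_out,
                                      "lncrna_disease",
                                      derive_seed(spec$seed, "e-ld")),
    lncrna_protein = sample_bipartite(ln, pr, spec$density_in, spec$density_out,
                                      "lncrna_protein",
                                      derive_seed(spec$seed, "e-lp")),
    protein_protein = sample_bipartite(pr, pr, spec$density_in,
                                       spec$density_out, "protein_protein",
                                       derive_seed(spec$seed, "e-pp"),
                                       same_type = TRUE),
    protein_disease = sample_bipartite(pr, di, spec$density_in,
                                       spec$density_out, "protein_disease",
                                       derive_seed(spec$seed, "e-pd")),
    drug_protein = sample_bipartite(dr, pr, spec$density_in, spec$density_out,
                                    "drug_protein",
                                    derive_seed(spec$seed, "e-dp")),
    drug_disease = sample_bipartite(dr, di, spec$density_in, spec$density_out,
                                    "drug_disease",
                                    derive_seed(spec$seed, "e-dd"))
  )
  positives <- tibble::tibble(
    mirna_id = edges$mirna_disease$source_id,
    disease_id = edges$mirna_disease$target_id
  )
  positives <- positives[order_c(positives$mirna_id, positives$disease_id), ]
  list(edges = edges, positives = positives, nodes = nodes)
}

#' Generate a complete in-memory fixture
#'
#' Convenience wrapper bundling [generate_network()],
#' [generate_sequences()] and [generate_mesh_table()] plus the assembled
#' [hetero_network()].
#'
#' @param spec A [fixture_spec()].
#' @return List with `network`, `sequences`, `mesh`, `positives`,
#'   `nodes`, `edges`, `spec`.
#' @export
make_fixture <- function(spec = fixture_spec()) {
  gn <- generate_network(spec)
  list(
    network = hetero_network(gn$edges),
    sequences = generate_sequences(spec),
    mesh = generate_mesh_table(spec),
    positives = gn$positives,
    nodes = gn$nodes,
    edges = gn$edges,
    spec = spec
  )
}

#' Write a fixture to disk in the pipeline's input formats
#'
#' Writes `sequences.fasta`, `mesh.tsv`, `positives.tsv` and one
#' `edges/<assoc_type>.tsv` per association type.
#'
#' @param fix Result of [make_fixture()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_dir <- function(fix, dir) {
  dir.create(file.path(dir, "edges"), showWarnings = FALSE, recursive = TRUE)
  fasta <- paste0(">", fix$sequences$id, "\n", fix$sequences$seq)
  writeLines(fasta, file.path(dir, "sequences.fasta"))
  readr::write_tsv(fix$mesh, file.path(dir, "mesh.tsv"), col_names = FALSE)
  readr::write_tsv(fix$positives, file.path(dir, "positives.tsv"),
                   col_names = FALSE)
  for (nm in names(fix$edges)) {
    e <- fix$edges[[nm]]
    readr::write_tsv(e[c("source_id", "target_id")],
                     file.path(dir, "edges", paste0(nm, ".tsv")),
                     col_names = FALSE)
  }
  invisible(dir)
}
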