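test_that("edge lists read, deduplicate and validate", {
  p <- write_tsv_lines(c("m1\td1", "m2\td2"))
  e <- read_edge_list(p, "mirna_disease")
  expect_equal(nrow(e), 2L)
  expect_equal(e$source_type, c("miRNA", "miRNA"))
  expect_equal(e$target_type, c("disease", "disease"))

  # duplicates (including reversed same-type orientation) collapse
  p2 <- write_tsv_lines(c("m1\td1", "m1\td1"))
  expect_equal(nrow(read_edge_list(p2, "mirna_disease")), 1L)
  p3 <- write_tsv_lines(c("p1\tp2", "p2\tp1"))
  expect_equal(nrow(read_edge_list(p3, "protein_protein")), 1L)

  # malformed rows name the line
  p4 <- write_tsv_lines(c("m1\td1", "m1"))
  expect_error(read_edge_list(p4, "mirna_disease"), "line 2",
               class = "mdlink_malformed_row")
  expect_error(read_edge_list(tempfile(), "mirna_disease"),
               class = "mdlink_missing_file")
  expect_error(read_edge_list(p, "not_a_type"), class = "mdlink_bad_assoc_type")
  # comments and headers are skipped
  p5 <- write_tsv_lines(c("# source\ttarget", "m1\td1"))
  expect_equal(nrow(read_edge_list(p5, "mirna_disease")), 1L)
})

test_that("network assembly counts nodes and degrees correctly", {
  e <- tibble::tibble(
    source_type = "miRNA", source_id = c("m1", "m1"),
    target_type = c("disease", "protein"), target_id = c("d1", "p1"),
    assoc_type = c("mirna_disease", "mirna_protein")
  )
  net <- hetero_network(e)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(degree_of(net, "miRNA", "m1"), 2)
  expect_identical(net$adjacency, t(net$adjacency))
  expect_true(all(diag(net$adjacency) == 0))

  # degree sum = 2 x unique edges, on a 100-edge random fixture
  e100 <- random_edges(100, seed = 4)
  net100 <- hetero_network(e100)
  expect_equal(sum(net100$adjacency), 200)
  expect_error(hetero_network(e100[0, ]), class = "mdlink_empty_edges")
  # self-loops rejected
  self <- tibble::tibble(source_type = "protein", source_id = "p1",
                         target_type = "protein", target_id = "p1",
                         assoc_type = "protein_protein")
  expect_error(hetero_network(self), class = "mdlink_self_loop")
})

test_that("removing held-out miRNA-disease edges touches only those entries", {
  fix <- tiny_fixture()
  net <- fix$network
  pos <- fix$positives

  # removing nothing is the identity
  expect_identical(remove_md_edges(net, pos[0, ])$adjacency, net$adjacency)

  held <- pos[1:5, ]
  net2 <- remove_md_edges(net, held)
  expect_equal(sum(net$adjacency) - sum(net2$adjacency), 2 * nrow(held))
  for (i in seq_len(nrow(held))) {
    expect_equal(unname(
      adjacency_row(net2, "miRNA", held$mirna_id[i])[
        paste0("disease|", held$disease_id[i])]), 0)
  }
  # input network is not mutated
  expect_equal(sum(net$adjacency[cbind(
    paste0("miRNA|", held$mirna_id), paste0("disease|", held$disease_id))]),
    nrow(held))

  # every non miRNA-disease block is untouched
  keys <- rownames(net$adjacency)
  not_md <- !grepl("^(miRNA|disease)\\|", keys)
  expect_identical(net$adjacency[not_md, not_md], net2$adjacency[not_md, not_md])
  md_rows <- grepl("^miRNA\\|", keys)
  other <- !grepl("^disease\\|", keys)
  expect_identical(net$adjacency[md_rows, other], net2$adjacency[md_rows, other])

  # absent pairs are tolerated with a warning
  ghost <- tibble::tibble(mirna_id = "nope", disease_id = "nothere")
  expect_warning(net3 <- remove_md_edges(net, ghost), "absent")
  expect_identical(net3$adjacency, net$adjacency)
})

test_that("adjacency rows match a brute-force edge-list scan", {
  fix <- tiny_fixture()
  net <- fix$network
  node <- net$nodes[net$nodes$node_type == "miRNA", ][3, ]
  row <- adjacency_row(net, node$node_type, node$node_id)
  expect_length(row, nrow(net$nodes))
  expect_equal(sum(row), degree_of(net, node$node_type, node$node_id))
  # oracle: membership test over the canonical edge tibble
  for (key in names(row)) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    hit <- any(
      (net$edges$source_type == node$node_type &
         net$edges$source_id == node$node_id &
         net$edges$target_type == parts[1] & net$edges$target_id == parts[2]) |
        (net$edges$target_type == node$node_type &
           net$edges$target_id == node$node_id &
           net$edges$source_type == parts[1] & net$edges$source_id == parts[2])
    )
    expect_equal(unname(row[key]), as.numeric(hit))
  }
  expect_error(adjacency_row(net, "miRNA", "ghost"), class = "mdlink_unknown_node")

  # a node isolated by removal keeps an all-zero row
  one_m <- fix$positives$mirna_id[1]
  mine <- fix$positives[fix$positives$mirna_id == one_m, ]
  net_iso <- remove_md_edges(net, mine)
  md_cols <- grepl("^disease\\|", rownames(net_iso$adjacency))
  expect_equal(sum(adjacency_row(net_iso, "miRNA", one_m)[md_cols]), 0)
})

test_that("network serialisation round-trips the adjacency exactly", {
  fix <- tiny_fixture()
  dir <- tempfile()
  write_network(fix$network, dir)
  back <- read_network(dir)
  expect_identical(back$adjacency, fix$network$adjacency)
  expect_equal(back$nodes, fix$network$nodes)
})

test_that("pair lists read with dedup and label handling", {
  p <- write_tsv_lines(c("m1\td1\t1", "m2\td2\t0", "m1\td1\t1"))
  tab <- read_pair_list(p)
  expect_equal(nrow(tab), 2L)
  expect_equal(sort(tab$label), c(0L, 1L))
  p2 <- write_tsv_lines(c("m1\td1", "m2\td1"))
  expect_true(all(read_pair_list(p2)$label == 1L))
  p3 <- write_tsv_lines(c("m1\td1\t1", "m1\td1\t0"))
  expect_error(read_pair_list(p3), class = "mdlink_duplicate_pairs")
})
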