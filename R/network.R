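#' Node and association types of the molecular association network
#'
#' The molecular association network (MAN) links five molecule types —
#' miRNA, lncRNA, protein, disease and drug — through nine undirected
#' association types. `assoc_types()` returns the registry mapping each
#' association type to its declared endpoint node types; `node_types()`
#' returns the five node types.
#'
#' @return `assoc_types()`: a tibble with columns `assoc_type`, `from_type`,
#'   `to_type`. `node_types()`: a character vector of length 5.
#' @examples
#' assoc_types()
#' @export
assoc_types <- function() {
  tibble::tribble(
    ~assoc_type,       ~from_type, ~to_type,
    "mirna_disease",   "miRNA",    "disease",
    "mirna_protein",   "miRNA",    "protein",
    "mirna_lncrna",    "miRNA",    "lncRNA",
    "lncrna_disease",  "lncRNA",   "disease",
    "lncrna_protein",  "lncRNA",   "protein",
    "protein_protein", "protein",  "protein",
    "protein_disease", "protein",  "disease",
    "drug_protein",    "drug",     "protein",
    "drug_disease",    "drug",     "disease"
  )
}

#' @rdname assoc_types
#' @export
node_types <- function() c("miRNA", "lncRNA", "protein", "disease", "drug")

assoc_endpoint_types <- function(assoc_type) {
  reg <- assoc_types()
  row <- reg[reg$assoc_type == assoc_type, ]
  if (nrow(row) != 1L) {
    stop_mdlink(
      paste0("unknown association type '", assoc_type, "'; known types: ",
             paste(reg$assoc_type, collapse = ", ")),
      "mdlink_bad_assoc_type"
    )
  }
  c(row$from_type, row$to_type)
}

# Canonicalise an edge tibble: typed endpoints, no self-loops, one record per
# unique undirected pair, deterministic order.
canonicalise_edges <- function(edges) {
  self <- edges$source_type == edges$target_type & edges$source_id == edges$target_id
  if (any(self)) {
    stop_mdlink(
      paste0("self-loop edge(s) not allowed: ",
             paste(unique(edges$source_id[self]), collapse = ", ")),
      "mdlink_self_loop"
    )
  }
  # For same-type associations collapse both orientations onto a sorted pair.
  swap <- edges$source_type == edges$target_type &
    rank_pair(edges$source_id) > rank_pair(edges$target_id)
  if (any(swap)) {
    tmp_id <- edges$source_id[swap]
    edges$source_id[swap] <- edges$target_id[swap]
    edges$target_id[swap] <- tmp_id
  }
  edges <- dplyr::distinct(edges)
  edges[order_c(edges$assoc_type, edges$source_type, edges$source_id,
                edges$target_type, edges$target_id), , drop = FALSE]
}

rank_pair <- function(x) xtfrm(x)

#' Read one association edge list from a TSV file
#'
#' Each association type of the MAN is supplied as a tab-separated file with
#' at least two columns: source id and target id (extra columns are
#' ignored). Lines starting with `#` are treated as comments. Endpoint node
#' types come from the association-type registry ([assoc_types()]); the
#' first column holds ids of the registry's `from_type`, the second of its
#' `to_type`. Duplicate rows (including the reverse orientation of
#' same-type pairs) collapse to one undirected edge.
#'
#' @param path Path to a TSV file.
#' @param assoc_type One of the nine association types, see [assoc_types()].
#' @return A tibble of edges with columns `source_type`, `source_id`,
#'   `target_type`, `target_id`, `assoc_type`, in deterministic order.
#' @export
read_edge_list <- function(path, assoc_type) {
  ends <- assoc_endpoint_types(assoc_type)
  if (!file.exists(path)) {
    stop_mdlink(paste0("edge list file not found: ", path), "mdlink_missing_file")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_mdlink(paste0("edge list is empty: ", path), "mdlink_empty_edges")
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad) > 0L) {
    stop_mdlink(
      paste0("line ", idx[bad[1]], " of ", path,
             " has fewer than 2 tab-separated fields"),
      "mdlink_malformed_row"
    )
  }
  src <- trimws(vapply(fields, `[[`, "", 1L))
  tgt <- trimws(vapply(fields, `[[`, "", 2L))
  empty <- !nzchar(src) | !nzchar(tgt)
  if (any(empty)) {
    stop_mdlink(
      paste0("line ", idx[which(empty)[1]], " of ", path, " has an empty id"),
      "mdlink_malformed_row"
    )
  }
  edges <- tibble::tibble(
    source_type = ends[1], source_id = src,
    target_type = ends[2], target_id = tgt,
    assoc_type = assoc_type
  )
  canonicalise_edges(edges)
}

#' Assemble the heterogeneous molecular association network
#'
#' Builds a `hetero_network` from one or more edge tibbles (as returned by
#' [read_edge_list()] or [generate_network()]). The node set is the union of
#' all edge endpoints, ordered deterministically by (type, id); the
#' adjacency matrix is symmetric and binary with a zero diagonal, and is
#' the input to the SDNE embedding ([fit_sdne()]).
#'
#' @param edges A tibble of edges (columns `source_type`, `source_id`,
#'   `target_type`, `target_id`, `assoc_type`), or a list of such tibbles.
#' @return An object of class `hetero_network` with components:
#'   \describe{
#'     \item{nodes}{tibble of `node_type`, `node_id` in matrix order}
#'     \item{adjacency}{symmetric binary matrix, dimnames `type|id`}
#'     \item{edges}{the canonicalised edge tibble}
#'   }
#' @examples
#' e <- tibble::tibble(
#'   source_type = "miRNA", source_id = c("m1", "m1"),
#'   target_type = c("disease", "protein"), target_id = c("d1", "p1"),
#'   assoc_type = c("mirna_disease", "mirna_protein")
#' )
#' net <- hetero_network(e)
#' degree_of(net)
#' @export
hetero_network <- function(edges) {
  if (is.list(edges) && !is.data.frame(edges)) {
    edges <- dplyr::bind_rows(edges)
  }
  if (!is.data.frame(edges) || nrow(edges) == 0L) {
    stop_mdlink("edge set is empty; cannot assemble a network", "mdlink_empty_edges")
  }
  edges <- canonicalise_edges(tibble::as_tibble(edges))
  bad_type <- setdiff(unique(c(edges$source_type, edges$target_type)), node_types())
  if (length(bad_type) > 0L) {
    stop_mdlink(paste0("unknown node type(s): ", paste(bad_type, collapse = ", ")),
                "mdlink_bad_node_type")
  }
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble::tibble(node_type = edges$source_type, node_id = edges$source_id),
    tibble::tibble(node_type = edges$target_type, node_id = edges$target_id)
  ))
  nodes <- nodes[order_c(nodes$node_type, nodes$node_id), , drop = FALSE]
  keys <- node_key(nodes$node_type, nodes$node_id)
  n <- length(keys)
  adj <- matrix(0, n, n, dimnames = list(keys, keys))
  i <- match(node_key(edges$source_type, edges$source_id), keys)
  j <- match(node_key(edges$target_type, edges$target_id), keys)
  adj[cbind(i, j)] <- 1
  adj[cbind(j, i)] <- 1
  net <- structure(
    list(nodes = nodes, adjacency = adj, edges = edges),
    class = "hetero_network"
  )
  validate_network(net)
}

# Invariants asserted after every construction/mutation: symmetric, binary,
# zero diagonal, dimnames consistent with the node table.
validate_network <- function(net) {
  adj <- net$adjacency
  stopifnot(
    is.matrix(adj), nrow(adj) == ncol(adj),
    identical(rownames(adj), node_key(net$nodes$node_type, net$nodes$node_id)),
    all(adj %in% c(0, 1)),
    all(diag(adj) == 0),
    identical(adj, t(adj))
  )
  net
}

#' @export
print.hetero_network <- function(x, ...) {
  cnt <- dplyr::count(x$nodes, .data$node_type)
  cat("<hetero_network> ", nrow(x$nodes), " nodes, ",
      nrow(x$edges), " undirected edges\n", sep = "")
  cat("  nodes: ", paste0(cnt$node_type, "=", cnt$n, collapse = ", "), "\n", sep = "")
  cat("  edge types: ",
      paste(sort_c(unique(x$edges$assoc_type)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Remove held-out miRNA-disease edges from a network
#'
#' Zeroes the adjacency entries (both orientations) of the listed
#' miRNA-disease pairs, leaving every other entry untouched. This is the
#' leakage control of cross validation: test-fold associations are removed
#' before embeddings are computed, so the embedding never sees test labels.
#' Pairs absent from the network are tolerated and reported via a warning.
#' Endpoints that lose all their edges are retained as isolated nodes so
#' the node indexing is stable across folds.
#'
#' @param net A `hetero_network`.
#' @param held_out Tibble with columns `mirna_id`, `disease_id`.
#' @return A new `hetero_network`; the input is not mutated.
#' @export
remove_md_edges <- function(net, held_out) {
  stopifnot(inherits(net, "hetero_network"))
  if (nrow(held_out) == 0L) {
    return(net)
  }
  keys <- rownames(net$adjacency)
  i <- match(node_key("miRNA", held_out$mirna_id), keys)
  j <- match(node_key("disease", held_out$disease_id), keys)
  known <- !is.na(i) & !is.na(j)
  present <- known
  present[known] <- net$adjacency[cbind(i[known], j[known])] > 0
  if (any(!present)) {
    rlang::warn(paste0(
      sum(!present), " held-out pair(s) were not edges of the network ",
      "(already absent); ignored"
    ))
  }
  adj <- net$adjacency
  adj[cbind(i[present], j[present])] <- 0
  adj[cbind(j[present], i[present])] <- 0
  drop_key <- paste(held_out$mirna_id[present], held_out$disease_id[present])
  edges <- net$edges
  is_md <- edges$assoc_type == "mirna_disease"
  edges <- edges[!(is_md & paste(edges$source_id, edges$target_id) %in% drop_key), ,
                 drop = FALSE]
  validate_network(structure(
    list(nodes = net$nodes, adjacency = adj, edges = edges),
    class = "hetero_network"
  ))
}

#' Adjacency row of one node
#'
#' Returns row *i* of the symmetric adjacency matrix — the raw input vector
#' `x_i` that the SDNE autoencoder reconstructs.
#'
#' @param net A `hetero_network`.
#' @param node_type,node_id Node identity.
#' @return Named binary vector of length `nrow(net$adjacency)`.
#' @export
adjacency_row <- function(net, node_type, node_id) {
  key <- node_key(node_type, node_id)
  idx <- match(key, rownames(net$adjacency))
  if (is.na(idx)) {
    stop_mdlink(paste0("node not in network: ", key), "mdlink_unknown_node")
  }
  net$adjacency[idx, ]
}

#' @rdname adjacency_row
#' @export
degree_of <- function(net, node_type = NULL, node_id = NULL) {
  d <- rowSums(net$adjacency)
  if (is.null(node_type)) {
    return(tibble::tibble(net$nodes, degree = unname(d)))
  }
  unname(d[node_key(node_type, node_id)])
}

#' Serialise / deserialise a network
#'
#' Writes the node list and the sparse undirected edge list as two TSV
#' files (`nodes.tsv`, `edges.tsv`); `read_network()` round-trips to an
#' identical adjacency matrix.
#'
#' @param net A `hetero_network`.
#' @param dir Directory to write into (created if needed).
#' @return `write_network()` the directory (invisibly); `read_network()` a
#'   `hetero_network`.
#' @export
write_network <- function(net, dir) {
  stopifnot(inherits(net, "hetero_network"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(net$nodes, file.path(dir, "nodes.tsv"))
  readr::write_tsv(net$edges, file.path(dir, "edges.tsv"))
  invisible(dir)
}

#' @rdname write_network
#' @export
read_network <- function(dir) {
  edges <- readr::read_tsv(file.path(dir, "edges.tsv"),
                           show_col_types = FALSE, progress = FALSE)
  net <- hetero_network(edges)
  nodes_file <- file.path(dir, "nodes.tsv")
  if (file.exists(nodes_file)) {
    nodes <- readr::read_tsv(nodes_file, show_col_types = FALSE, progress = FALSE)
    # Isolated nodes carried in nodes.tsv but absent from the edge list.
    extra <- dplyr::anti_join(nodes, net$nodes, by = c("node_type", "node_id"))
    if (nrow(extra) > 0L) {
      all_nodes <- dplyr::bind_rows(net$nodes, extra)
      all_nodes <- all_nodes[order_c(all_nodes$node_type, all_nodes$node_id), ]
      keys <- node_key(all_nodes$node_type, all_nodes$node_id)
      adj <- matrix(0, length(keys), length(keys), dimnames = list(keys, keys))
      old <- rownames(net$adjacency)
      adj[old, old] <- net$adjacency
      net <- validate_network(structure(
        list(nodes = all_nodes, adjacency = adj, edges = net$edges),
        class = "hetero_network"
      ))
    }
  }
  net
}

#' Read a labeled miRNA-disease pair list
#'
#' @param path TSV with columns miRNA id, disease id and optionally a
#'   0/1 label (missing label column implies all 1, i.e. known positives).
#' @return Tibble `mirna_id`, `disease_id`, `label`.
#' @export
read_pair_list <- function(path) {
  if (!file.exists(path)) {
    stop_mdlink(paste0("pair list file not found: ", path), "mdlink_missing_file")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE,
                         col_names = FALSE)
  if (ncol(tab) < 2L) {
    stop_mdlink("pair list needs at least 2 columns", "mdlink_malformed_row")
  }
  # tolerate a header row
  if (tolower(tab[[1]][1]) %in% c("mirna_id", "mirna", "source_id")) {
    tab <- tab[-1, , drop = FALSE]
  }
  out <- tibble::tibble(
    mirna_id = as.character(tab[[1]]),
    disease_id = as.character(tab[[2]]),
    label = if (ncol(tab) >= 3L) as.integer(tab[[3]]) else 1L
  )
  out <- dplyr::distinct(out)
  dup <- duplicated(out[c("mirna_id", "disease_id")])
  if (any(dup)) {
    stop_mdlink("conflicting duplicate (miRNA, disease) pairs in pair list",
                "mdlink_duplicate_pairs")
  }
  out[order_c(out$mirna_id, out$disease_id), ]
}
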