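#' Disease DAGs from MeSH tree numbers
#'
#' Each disease is described by one or more MeSH tree numbers
#' (dot-separated strings such as `"C04.588.180"`). Its ancestor set is
#' obtained by repeatedly stripping the last dot-component of every tree
#' number; the disease plus its ancestors form a directed acyclic graph
#' (edges parent to child). When the input table itself maps an ancestor
#' prefix to a disease id, that id is used as the term name, so a heading
#' reachable at several depths is a single term.
#'
#' Diseases listed in `diseases` but missing from the table get a
#' self-only DAG (similarity 1 with themselves, 0 elsewhere) and a
#' warning, rather than being dropped.
#'
#' @param mesh A tibble with columns `disease_id`, `tree_number` (one row
#'   per tree number).
#' @param diseases Optional character vector of disease ids that must all
#'   receive a DAG.
#' @return Named list of `disease_dag` objects. Each has `disease` (id),
#'   `terms` (character set L(d)), `self_terms` (term names that denote
#'   the disease itself), and `children` (named list: term -> character
#'   vector of its children within the DAG).
#' @export
disease_dags <- function(mesh, diseases = NULL) {
  stopifnot(is.data.frame(mesh), all(c("disease_id", "tree_number") %in% names(mesh)))
  mesh <- dplyr::distinct(tibble::as_tibble(mesh[c("disease_id", "tree_number")]))
  bad <- !grepl("^[A-Za-z0-9]+(\\.[A-Za-z0-9]+)*$", mesh$tree_number)
  if (any(bad)) {
    stop_mdlink(
      paste0("malformed tree number(s): ",
             paste(utils::head(mesh$tree_number[bad], 3), collapse = ", ")),
      "mdlink_bad_tree_number"
    )
  }
  # canonical term name for a tree-number prefix: the disease id that owns
  # that exact tree number if unique, otherwise the prefix string itself
  owner <- split(mesh$disease_id, mesh$tree_number)
  term_name <- function(prefix) {
    ids <- owner[[prefix]]
    if (length(ids) == 1L) ids else prefix
  }
  ids <- sort_c(unique(c(mesh$disease_id, diseases)))
  missing <- setdiff(ids, mesh$disease_id)
  if (length(missing) > 0L) {
    rlang::warn(paste0(
      length(missing), " disease(s) have no tree numbers; ",
      "using self-only DAGs: ", paste(utils::head(missing, 5), collapse = ", ")
    ))
  }
  dags <- lapply(ids, function(d) {
    tns <- mesh$tree_number[mesh$disease_id == d]
    if (length(tns) == 0L) {
      return(structure(
        list(disease = d, terms = d, self_terms = d,
             children = stats::setNames(list(character()), d)),
        class = "disease_dag"
      ))
    }
    terms <- character()
    children <- list()
    self_terms <- character()
    for (tn in tns) {
      comps <- strsplit(tn, ".", fixed = TRUE)[[1]]
      prefixes <- vapply(seq_along(comps),
                         function(k) paste(comps[1:k], collapse = "."), "")
      nms <- vapply(prefixes, term_name, "")
      # the full tree number denotes the disease itself unless several
      # diseases share that exact tree number (then the heading is the term)
      self_terms <- union(self_terms, nms[length(nms)])
      terms <- union(terms, nms)
      if (length(nms) > 1L) {
        for (k in 2:length(nms)) {
          par <- nms[k - 1]
          children[[par]] <- union(children[[par]], nms[k])
        }
      }
    }
    for (t in setdiff(terms, names(children))) children[[t]] <- character()
    # self-edges can arise if a truncated prefix maps back to the disease
    children <- lapply(stats::setNames(names(children), names(children)),
                       function(t) setdiff(children[[t]], t))
    structure(
      list(disease = d, terms = terms, self_terms = self_terms,
           children = children),
      class = "disease_dag"
    )
  })
  stats::setNames(dags, ids)
}

#' Semantic contribution of every term in a disease DAG
#'
#' The disease itself contributes 1; any ancestor term T contributes
#' `decay * max(contribution of its children in the DAG)`, i.e. the decay
#' factor applied along the shortest downward path to the disease
#' (`decay = 0.5` by default). Values lie in (0, 1].
#'
#' @param dag A `disease_dag`.
#' @param decay Semantic decay factor per generation, in (0, 1).
#' @return Named numeric vector: term -> contribution.
#' @export
contribution <- function(dag, decay = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), decay > 0, decay < 1)
  memo <- new.env(parent = emptyenv())
  visiting <- new.env(parent = emptyenv())
  contrib <- function(term) {
    if (!is.null(memo[[term]])) return(memo[[term]])
    if (!is.null(visiting[[term]])) {
      stop_mdlink(paste0("cycle detected at term '", term, "'"), "mdlink_cyclic_dag")
    }
    visiting[[term]] <- TRUE
    val <- if (term %in% dag$self_terms) {
      1
    } else {
      kids <- dag$children[[term]]
      if (length(kids) == 0L) {
        stop_mdlink(paste0("term '", term, "' has no path to the disease"),
                    "mdlink_disconnected_term")
      }
      decay * max(vapply(kids, contrib, 0))
    }
    rm(list = term, envir = visiting)
    memo[[term]] <- val
    val
  }
  vapply(stats::setNames(dag$terms, dag$terms), contrib, 0)
}

#' Semantic value of a disease
#'
#' The sum of the semantic contributions of all terms in the disease's
#' DAG; at least 1 (the disease's own contribution).
#'
#' @param cmap Named contribution vector from [contribution()].
#' @return Scalar `DV >= 1`.
#' @export
semantic_value <- function(cmap) {
  stopifnot(length(cmap) > 0)
  sum(cmap)
}

#' Semantic similarity between two diseases
#'
#' Diseases sharing a larger, deeper part of their DAGs are more similar:
#' the similarity is the sum over shared terms of both diseases'
#' contributions, normalised by the sum of the two semantic values. Lies
#' in `[0, 1]`, equals 1 for identical DAGs and 0 for disjoint ones.
#'
#' @param a,b Disease ids.
#' @param dags Named list from [disease_dags()].
#' @param decay Semantic decay factor.
#' @return Scalar similarity in `[0, 1]`.
#' @export
semantic_similarity <- function(a, b, dags, decay = 0.5) {
  for (d in c(a, b)) {
    if (is.null(dags[[d]])) {
      stop_mdlink(paste0("no DAG for disease '", d, "'"), "mdlink_unknown_disease")
    }
  }
  ca <- contribution(dags[[a]], decay)
  cb <- contribution(dags[[b]], decay)
  shared <- intersect(names(ca), names(cb))
  if (length(shared) == 0L) return(0)
  sum(ca[shared] + cb[shared]) / (semantic_value(ca) + semantic_value(cb))
}

#' Disease semantic-similarity matrix
#'
#' @param mesh Tibble `disease_id`, `tree_number`, or a prebuilt list from
#'   [disease_dags()].
#' @param diseases Optional ids that must all appear (self-only fallback).
#' @param decay Semantic decay factor.
#' @return Symmetric matrix with unit diagonal, entries in `[0, 1]`,
#'   rows/columns in sorted disease-id order.
#' @export
disease_similarity_matrix <- function(mesh, diseases = NULL, decay = 0.5) {
  dags <- if (is.data.frame(mesh)) disease_dags(mesh, diseases) else mesh
  ids <- sort_c(names(dags))
  if (length(ids) < 2L) {
    stop_mdlink("need at least 2 diseases", "mdlink_too_few")
  }
  if (anyDuplicated(ids)) {
    stop_mdlink("duplicate disease ids", "mdlink_duplicate_ids")
  }
  cmaps <- lapply(dags[ids], contribution, decay = decay)
  dvs <- vapply(cmaps, semantic_value, 0)
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n > 1L) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(cmaps[[i]]), names(cmaps[[j]]))
        s <- if (length(shared) == 0L) 0 else {
          sum(cmaps[[i]][shared] + cmaps[[j]][shared]) / (dvs[i] + dvs[j])
        }
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  m
}

#' Read a disease-to-MeSH tree-number table
#'
#' @param path TSV with two columns: disease id, tree number (one row per
#'   tree number; `#` comments and an optional header tolerated).
#' @return Tibble `disease_id`, `tree_number`.
#' @export
read_mesh_table <- function(path) {
  if (!file.exists(path)) {
    stop_mdlink(paste0("MeSH table not found: ", path), "mdlink_missing_file")
  }
  tab <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(tab) < 2L) {
    stop_mdlink("MeSH table needs 2 columns", "mdlink_malformed_row")
  }
  if (tolower(tab[[1]][1]) %in% c("disease_id", "disease")) {
    tab <- tab[-1, , drop = FALSE]
  }
  tibble::tibble(disease_id = as.character(tab[[1]]),
                 tree_number = as.character(tab[[2]]))
}
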