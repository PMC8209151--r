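#' Chaos game representation of miRNA sequences
#'
#' The chaos game representation (CGR) maps a nucleotide sequence into the
#' unit square: each base pulls the current point half-way (contraction
#' ratio `c = 0.5`) towards its assigned corner — A at (0,0), C at (0,1),
#' U at (1,0) and G at (1,1) — starting from the centre (0.5, 0.5). The
#' resulting point cloud encodes both composition and order of the
#' sequence; an 8x8 partition of the square then yields a 192-long
#' descriptor per sequence (see [cgr_descriptor()]).
#'
#' `nucleotide_corner()` returns the corner of one base (DNA-style `T` is
#' read as `U`; case-insensitive). `cgr_trajectory()` iterates
#' `T_i = T_{i-1} + c * (G_i - T_{i-1})` over a sequence.
#'
#' @param base Single nucleotide character.
#' @return `nucleotide_corner()`: named numeric `c(x, y)`.
#' @examples
#' nucleotide_corner("A")
#' cgr_trajectory("ACGU")
#' @export
nucleotide_corner <- function(base) {
  xy <- corner_coords(base, what = "base")
  c(x = xy[1, 1], y = xy[1, 2])
}

# Vectorised corner lookup; errors name the first offending position.
corner_coords <- function(bases, what = "sequence") {
  b <- toupper(bases)
  b[b == "T"] <- "U"
  corners <- matrix(
    c(0, 0,   # A
      0, 1,   # C
      1, 1,   # G
      1, 0),  # U
    ncol = 2, byrow = TRUE,
    dimnames = list(c("A", "C", "G", "U"), c("x", "y"))
  )
  idx <- match(b, rownames(corners))
  if (anyNA(idx)) {
    pos <- which(is.na(idx))[1]
    stop_mdlink(
      paste0("invalid nucleotide '", bases[pos], "' at position ", pos,
             " of ", what, " (alphabet: A, C, G, U/T)"),
      "mdlink_bad_alphabet"
    )
  }
  corners[idx, , drop = FALSE]
}

#' @rdname nucleotide_corner
#' @param seq Nucleotide sequence (string over A/C/G/U, with T read as U).
#' @param contraction Contraction ratio in (0, 1); 0.5 is the classical
#'   midpoint rule and the package default.
#' @return `cgr_trajectory()`: a tibble of class `cgr_trajectory` with one
#'   row per base: `position`, `base`, `x`, `y`. The start point (0.5, 0.5)
#'   is not emitted.
#' @export
cgr_trajectory <- function(seq, contraction = 0.5) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    stop_mdlink("sequence is empty", "mdlink_empty_sequence")
  }
  if (!(contraction > 0 && contraction < 1)) {
    stop_mdlink("contraction ratio must lie strictly in (0, 1)", "mdlink_bad_param")
  }
  bases <- strsplit(seq, "", fixed = TRUE)[[1]]
  corners <- corner_coords(bases)
  n <- length(bases)
  pts <- matrix(0, n, 2)
  prev <- c(0.5, 0.5)
  for (i in seq_len(n)) {
    prev <- prev + contraction * (corners[i, ] - prev)
    pts[i, ] <- prev
  }
  out <- tibble::tibble(
    position = seq_len(n),
    base = toupper(bases),
    x = pts[, 1],
    y = pts[, 2]
  )
  class(out) <- c("cgr_trajectory", class(out))
  out
}

#' Index of the 8x8 CGR subspace containing a point
#'
#' The unit square is partitioned into 64 half-open cells
#' `[k/8, (k+1)/8)`; a coordinate exactly equal to 1 clamps into the last
#' row/column. Indices are 0-based, running row-major from the lower-left
#' cell: `index = floor(8x) + 8 * floor(8y)`.
#'
#' @param x,y Coordinates in the closed unit square (vectorised).
#' @return Integer vector of cell indices in `[0, 63]`.
#' @export
subspace_index <- function(x, y) {
  if (any(x < 0 | x > 1 | y < 0 | y > 1)) {
    stop_mdlink("point outside the unit square", "mdlink_out_of_bounds")
  }
  ix <- pmin(floor(8 * x), 7)
  iy <- pmin(floor(8 * y), 7)
  as.integer(ix + 8 * iy)
}

#' CGR subspace descriptor of one miRNA sequence
#'
#' Runs the CGR trajectory, bins the points into the 64 subspaces and
#' summarises each cell by the triple (X, Y, Z): X and Y are the sums of
#' the x- and y-coordinates of the points in the cell, and Z is the
#' z-score of the cell's point count against all 64 counts (population
#' standard deviation). If all counts are equal (zero variance) every Z is
#' defined as 0. The 64 triples are flattened, cell-major, into a
#' 192-long attribute vector.
#'
#' @inheritParams cgr_trajectory
#' @return Object of class `cgr_descriptor`: a list with `cells` (tibble
#'   `cell`, `num`, `X`, `Y`, `Z`), `flat` (numeric length 192 in
#'   (X, Y, Z)-per-cell order) and `length` (sequence length).
#' @export
cgr_descriptor <- function(seq, contraction = 0.5) {
  traj <- cgr_trajectory(seq, contraction)
  cell <- subspace_index(traj$x, traj$y)
  num <- tabulate(cell + 1L, nbins = 64L)
  X <- rep(0, 64)
  Y <- rep(0, 64)
  xs <- rowsum(traj$x, cell)
  ys <- rowsum(traj$y, cell)
  occ <- as.integer(rownames(xs)) + 1L
  X[occ] <- xs[, 1]
  Y[occ] <- ys[, 1]
  mu <- mean(num)
  sigma <- sqrt(mean((num - mu)^2))
  Z <- if (sigma == 0) rep(0, 64) else (num - mu) / sigma
  flat <- as.vector(rbind(X, Y, Z))
  names(flat) <- paste0(rep(c("X", "Y", "Z"), times = 64),
                        rep(seq_len(64), each = 3))
  structure(
    list(
      cells = tibble::tibble(cell = 0:63, num = num, X = X, Y = Y, Z = Z),
      flat = flat,
      length = nrow(traj)
    ),
    class = "cgr_descriptor"
  )
}

#' @export
print.cgr_descriptor <- function(x, ...) {
  cat("<cgr_descriptor> sequence length ", x$length, ", ",
      sum(x$cells$num > 0), "/64 occupied subspaces\n", sep = "")
  invisible(x)
}

#' Sequence similarity between two CGR descriptors
#'
#' Pearson correlation of the two flattened 192-long descriptors.
#'
#' @param a,b Objects of class `cgr_descriptor` (or numeric vectors of
#'   length 192).
#' @return Scalar in `[-1, 1]`.
#' @export
mirna_similarity <- function(a, b) {
  va <- if (inherits(a, "cgr_descriptor")) a$flat else a
  vb <- if (inherits(b, "cgr_descriptor")) b$flat else b
  stopifnot(length(va) == 192L, length(vb) == 192L)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop_mdlink("zero-variance descriptor: similarity undefined",
                "mdlink_zero_variance")
  }
  stats::cor(va, vb)
}

#' miRNA sequence-similarity matrix from CGR descriptors
#'
#' @param seqs A tibble with columns `id` and `seq`, or a named character
#'   vector of sequences.
#' @inheritParams cgr_trajectory
#' @return Symmetric matrix with unit diagonal, rows/columns ordered by
#'   sorted miRNA id.
#' @export
cgr_similarity_matrix <- function(seqs, contraction = 0.5) {
  seqs <- as_seq_table(seqs)
  if (nrow(seqs) < 2L) {
    stop_mdlink("need at least 2 sequences", "mdlink_too_few")
  }
  if (anyDuplicated(seqs$id)) {
    stop_mdlink("duplicate sequence ids", "mdlink_duplicate_ids")
  }
  seqs <- seqs[order_c(seqs$id), ]
  desc <- vapply(seqs$seq,
                 function(s) cgr_descriptor(s, contraction)$flat,
                 numeric(192), USE.NAMES = FALSE)
  flat_sd <- apply(desc, 2, stats::sd)
  if (any(flat_sd == 0)) {
    stop_mdlink(
      paste0("zero-variance descriptor for id(s): ",
             paste(seqs$id[flat_sd == 0], collapse = ", ")),
      "mdlink_zero_variance"
    )
  }
  # columns are descriptors; Pearson across descriptor components
  m <- stats::cor(desc)
  dimnames(m) <- list(seqs$id, seqs$id)
  diag(m) <- 1
  m
}

as_seq_table <- function(seqs) {
  if (is.character(seqs)) {
    if (is.null(names(seqs))) {
      stop_mdlink("sequence vector must be named by miRNA id", "mdlink_bad_input")
    }
    return(tibble::tibble(id = names(seqs), seq = unname(seqs)))
  }
  stopifnot(is.data.frame(seqs), all(c("id", "seq") %in% names(seqs)))
  tibble::as_tibble(seqs[c("id", "seq")])
}

#' Read miRNA sequences from a FASTA file
#'
#' @param path FASTA file (RNA or DNA alphabet; T is read as U downstream).
#' @return Tibble `id`, `seq`; the id is the first whitespace-delimited
#'   token of the record header.
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_mdlink(paste0("FASTA file not found: ", path), "mdlink_missing_file")
  }
  set <- Biostrings::readBStringSet(path)
  tibble::tibble(
    id = vapply(strsplit(names(set), "\\s+"), `[[`, "", 1L),
    seq = unname(as.character(set))
  )
}

#' Write similarity matrix as TSV
#'
#' @param mat Square named similarity matrix.
#' @param path Output path; the first column holds the row ids.
#' @export
write_similarity_tsv <- function(mat, path) {
  tab <- tibble::as_tibble(mat, rownames = "id")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_similarity_tsv
#' @export
read_similarity_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(tab[, -1])
  rownames(m) <- tab[[1]]
  m
}
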