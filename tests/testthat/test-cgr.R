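test_that("nucleotide corners match the chaos-game assignment", {
  expect_equal(nucleotide_corner("A"), c(x = 0, y = 0))
  expect_equal(nucleotide_corner("C"), c(x = 0, y = 1))
  expect_equal(nucleotide_corner("U"), c(x = 1, y = 0))
  expect_equal(nucleotide_corner("G"), c(x = 1, y = 1))
  expect_equal(nucleotide_corner("t"), nucleotide_corner("U"))
  expect_error(nucleotide_corner("N"), class = "mdlink_bad_alphabet")
})

test_that("trajectories follow the midpoint contraction from the centre", {
  t1 <- cgr_trajectory("A")
  expect_equal(c(t1$x, t1$y), c(0.25, 0.25))
  t2 <- cgr_trajectory("AC")
  expect_equal(t2$x, c(0.25, 0.125))
  expect_equal(t2$y, c(0.25, 0.625))
  # oracle: independent recursion for a longer sequence
  seq <- "GAUCCGUAAGCUG"
  traj <- cgr_trajectory(seq)
  corners <- list(A = c(0, 0), C = c(0, 1), G = c(1, 1), U = c(1, 0))
  pt <- c(0.5, 0.5)
  for (i in seq_len(nchar(seq))) {
    pt <- pt + 0.5 * (corners[[substr(seq, i, i)]] - pt)
    expect_equal(c(traj$x[i], traj$y[i]), pt)
  }
  # all points strictly inside the unit square; deterministic
  set.seed(8)
  for (r in 1:20) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(20:25, 1), TRUE),
               collapse = "")
    tr <- cgr_trajectory(s)
    expect_true(all(tr$x > 0 & tr$x < 1 & tr$y > 0 & tr$y < 1))
    expect_identical(tr, cgr_trajectory(s))
  }
  expect_error(cgr_trajectory(""), class = "mdlink_empty_sequence")
  expect_error(cgr_trajectory("ACN"), "position 3",
               class = "mdlink_bad_alphabet")
  expect_error(cgr_trajectory("AC", contraction = 1),
               class = "mdlink_bad_param")
})

test_that("subspace indexing agrees with a brute-force interval scan", {
  expect_equal(subspace_index(0.01, 0.01), 0L)
  expect_equal(subspace_index(1, 1), 63L)
  expect_equal(subspace_index(0.125, 0), 1L) # gridline goes to higher cell
  set.seed(9)
  x <- runif(1000)
  y <- runif(1000)
  oracle <- vapply(seq_along(x), function(i) {
    ix <- which(x[i] >= 0:7 / 8 & (x[i] < 1:8 / 8 | (x[i] == 1))) - 1L
    iy <- which(y[i] >= 0:7 / 8 & (y[i] < 1:8 / 8 | (y[i] == 1))) - 1L
    utils::tail(ix, 1) + 8L * utils::tail(iy, 1)
  }, integer(1))
  expect_equal(subspace_index(x, y), oracle)
  expect_error(subspace_index(1.2, 0), class = "mdlink_out_of_bounds")
})

test_that("descriptors conserve counts and z-score the occupancy", {
  set.seed(10)
  for (r in 1:10) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(20:25, 1), TRUE),
               collapse = "")
    d <- cgr_descriptor(s)
    expect_equal(sum(d$cells$num), nchar(s))
    expect_lt(abs(mean(d$cells$Z)), 1e-9)
    expect_length(d$flat, 192L)
    # X and Y are per-cell coordinate sums of the trajectory
    tr <- cgr_trajectory(s)
    cell <- subspace_index(tr$x, tr$y)
    expect_equal(d$cells$X, vapply(0:63, function(k) sum(tr$x[cell == k]), 0))
    expect_equal(d$cells$Y, vapply(0:63, function(k) sum(tr$y[cell == k]), 0))
  }
  # closed-form z-scores: repeated A visits cells 18, 9 once, then stays in
  # cell 0 — counts (64, 1, 1, 0 x 61) for a 66-mer
  d <- cgr_descriptor(strrep("A", 66))
  num <- d$cells$num
  expect_equal(sum(num == 64), 1L)
  expect_equal(sum(num == 1), 2L)
  mu <- 66 / 64
  sigma <- sqrt(mean((num - mu)^2))
  expect_equal(d$cells$Z, (num - mu) / sigma)
})

test_that("CGR similarity is a Pearson correlation of flat descriptors", {
  a <- cgr_descriptor("ACGUACGUACGUACGUACGU")
  b <- cgr_descriptor("GGGCCCAAAUUUGGGCCCAA")
  expect_equal(mirna_similarity(a, a), 1.0)
  expect_equal(mirna_similarity(a, b), mirna_similarity(b, a))
  # direct-formula oracle
  va <- a$flat
  vb <- b$flat
  n <- length(va)
  oracle <- sum((va - mean(va)) * (vb - mean(vb))) /
    (n * sqrt(mean((va - mean(va))^2)) * sqrt(mean((vb - mean(vb))^2)))
  expect_equal(mirna_similarity(a, b), oracle, tolerance = 1e-12)
  expect_error(mirna_similarity(a$flat * 0, b), class = "mdlink_zero_variance")
})

test_that("similarity matrices are symmetric with unit diagonal", {
  seqs <- tibble::tibble(
    id = c("m1", "m2"),
    seq = c("ACGUACGUACGUACGUACGU", "ACGUACGUACGUACGUACGU")
  )
  m <- cgr_similarity_matrix(seqs)
  expect_equal(unname(m), matrix(1, 2, 2))

  fix5 <- tibble::tibble(
    id = paste0("m", 1:5),
    seq = c("ACGUACGUACGUACGUACGU", "GGGCCCAAAUUUGGGCCCAA",
            "AAAAACCCCCGGGGGUUUUU", "ACACACACACACACACACAC",
            "GUGUGUGUGUGUGUGUGUGU")
  )
  m5 <- cgr_similarity_matrix(fix5)
  expect_identical(m5, t(m5))
  expect_equal(unname(diag(m5)), rep(1, 5))
  expect_true(all(m5 >= -1 & m5 <= 1))
  # off-diagonals equal pairwise calls
  for (i in 1:4) {
    for (j in (i + 1):5) {
      expect_equal(m5[fix5$id[i], fix5$id[j]],
                   mirna_similarity(cgr_descriptor(fix5$seq[i]),
                                    cgr_descriptor(fix5$seq[j])))
    }
  }
  expect_error(cgr_similarity_matrix(fix5[1, ]), class = "mdlink_too_few")
  expect_error(cgr_similarity_matrix(dplyr::mutate(fix5, id = "same")),
               class = "mdlink_duplicate_ids")
})

test_that("FASTA round-trip preserves ids and sequences", {
  fix <- tiny_fixture()
  dir <- tempfile()
  write_fixture_dir(fix, dir)
  seqs <- read_mirna_fasta(file.path(dir, "sequences.fasta"))
  expect_equal(seqs$id, fix$sequences$id)
  expect_equal(seqs$seq, fix$sequences$seq)
  expect_error(read_mirna_fasta(tempfile()), class = "mdlink_missing_file")
})
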