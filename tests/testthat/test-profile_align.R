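prof <- function(...) {
  rows <- c(...)
  msaframe:::new_profile(msaframe:::msa_like(rows),
                         setNames(rep(1, length(rows)), names(rows)))
}

test_that("sequence weights follow the root-path rule and normalize to mean 1", {
  # balanced tree, equal branches: all weights equal
  bal <- from_newick("((a:1,b:1):1,(c:1,d:1):1);")
  w <- compute_sequence_weights(bal)
  expect_equal(unname(w), rep(1, 4))
  expect_equal(mean(w), 1)

  # 3-leaf tree: sisters share their parent branch
  gt <- from_newick("((a:2,b:2):2,c:4);")
  w <- compute_sequence_weights(gt)
  # raw: a = 2 + 2/2 = 3, b = 3, c = 4
  expect_equal(unname(w[c("a", "b", "c")]) * mean(c(3, 3, 4)), c(3, 3, 4))
  expect_true(all(w > 0))
})

test_that("zero-length trees fall back to equal weights", {
  gt <- from_newick("((a:0,b:0):0,c:0);")
  expect_equal(unname(compute_sequence_weights(gt)), rep(1, 3))
})

test_that("aligning two single-sequence profiles equals pairwise global alignment", {
  set.seed(41)
  gm <- gap_model(terminal_free = FALSE)
  for (rep in 1:20) {
    s1 <- rand_seq(sample(4:12, 1)); s2 <- rand_seq(sample(4:12, 1))
    aln <- align_profiles(prof(c(a = s1)), prof(c(b = s2)), blosum(), gm)
    pw <- msaframe:::pairwise_gotoh(s1, s2, blosum(), gm$gap_open,
                                    gm$gap_extend)
    # same score: reconstruct the profile-DP score from the alignment
    m <- aln_matrix(aln)
    expect_identical(gsub("-", "", paste(m["a", ], collapse = "")), s1)
    expect_identical(gsub("-", "", paste(m["b", ], collapse = "")), s2)
    got <- msaframe:::wsp(aln, blosum())
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    core <- pw$a > 0 & pw$b > 0
    expect_equal(sum(blosum()[cbind(a[pw$a[core]], b[pw$b[core]])]),
                 got, tolerance = 1e-9)
  }
})

test_that("identical profiles align without new gaps", {
  p1 <- prof(c(a = "ACDE-FG", b = "ACDEKFG"))
  p2 <- prof(c(c = "ACDE-FG", d = "ACDEKFG"))
  aln <- align_profiles(p1, p2)
  expect_equal(aln_length(aln), 7)
})

test_that("profile DP score equals exhaustive enumeration on tiny instances", {
  set.seed(42)
  S <- blosum()
  gm <- gap_model(gap_open = 4, gap_extend = 0.7, terminal_free = FALSE)
  for (rep in 1:60) {
    n1 <- sample(1:2, 1); n2 <- 3 - n1
    L1 <- sample(2:5, 1); L2 <- sample(2:5, 1)
    mk <- function(n, L, ids) {
      m <- matrix(sample(c("A", "C", "D", "W", "-"), n * L, replace = TRUE,
                         prob = c(.24, .24, .24, .18, .1)), n, L,
                  dimnames = list(ids, NULL))
      m[, colSums(m != "-") > 0, drop = FALSE]
    }
    m1 <- mk(n1, L1, paste0("x", 1:n1)); m2 <- mk(n2, L2, paste0("y", 1:n2))
    if (ncol(m1) == 0 || ncol(m2) == 0) next
    p1 <- msaframe:::new_profile(m1, setNames(rep(1, n1), rownames(m1)))
    p2 <- msaframe:::new_profile(m2, setNames(rep(1, n2), rownames(m2)))
    C1 <- msaframe:::profile_counts(p1, rownames(S))
    C2 <- msaframe:::profile_counts(p2, rownames(S))
    M <- (C1 %*% unclass(S) %*% t(C2)) / (n1 * n2)
    ma <- msaframe:::open_multipliers(p1, gm)
    mb <- msaframe:::open_multipliers(p2, gm)
    got <- msaframe:::affine_dp_cpp(M, gm$gap_open, gm$gap_extend, ma, mb,
                                    FALSE)$score
    want <- oracle_affine_best(M, gm$gap_open, gm$gap_extend, ma, mb, FALSE)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("free terminal gaps match the enumeration oracle too", {
  set.seed(43)
  S <- blosum()
  gm <- gap_model(gap_open = 6, gap_extend = 0.4, terminal_free = TRUE)
  for (rep in 1:40) {
    s1 <- rand_seq(sample(2:5, 1)); s2 <- rand_seq(sample(2:5, 1))
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    M <- S[a, b, drop = FALSE]
    got <- msaframe:::affine_dp_cpp(M, gm$gap_open, gm$gap_extend,
                                    rep(1, length(a) + 1),
                                    rep(1, length(b) + 1), TRUE)$score
    want <- oracle_affine_best(M, gm$gap_open, gm$gap_extend,
                               free_ends = TRUE)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("progressive alignment of identical sequences is gap-free", {
  seqs <- aa_seqs(c(a = "MKTWQ", b = "MKTWQ", c = "MKTWQ", d = "MKTWQ"))
  sim <- build_similarity_matrix(seqs, "F")
  aln <- progressive_align(seqs, build_upgma(sim))
  expect_equal(aln_length(aln), 5)
  expect_true(all(aln_matrix(aln) != "-"))
})

test_that("progressive alignment de-gaps to its inputs, rows in input order", {
  set.seed(44)
  for (rep in 1:10) {
    n <- sample(3:6, 1)
    seqs <- aa_seqs(setNames(replicate(n, rand_seq(sample(8:15, 1),
                    c("A","C","D","E","F","G","H","K"))), paste0("s", 1:n)))
    sim <- build_similarity_matrix(seqs, "K", k = 2)
    aln <- progressive_align(seqs, build_guide_tree(sim, "NJ"))
    expect_identical(names(aln), names(seqs))
    expect_identical(unname(as.character(degap(aln))),
                     unname(as.character(seqs)))
    expect_gte(aln_length(aln), max(nchar(seqs)))
  }
})

test_that("gaps committed in an early profile persist to the final alignment", {
  # a/b align tightly and force a gap against each other; c joins later and
  # cannot undo it ("once a gap, always a gap")
  seqs <- aa_seqs(c(a = "WKFEDRHQN", b = "WKFDRHQN", c = "WKFEDRHQN"))
  M <- matrix(c(100, 95, 10, 95, 100, 10, 10, 10, 100), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  gt <- build_upgma(structure(M, method = "F",
                              class = c("sim_matrix", "matrix", "array")))
  aln <- progressive_align(seqs, gt)
  m <- aln_matrix(aln)
  # the a/b merge inserts a gap in b; it must still be there at the end
  expect_true(any(m["b", ] == "-"))
  expect_identical(gsub("-", "", paste(m["b", ], collapse = "")), "WKFDRHQN")
})
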