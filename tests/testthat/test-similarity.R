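test_that("FULL identity hits its anchor cases", {
  expect_equal(score_full("ACDEFG", "ACDEFG"), 100)
  expect_equal(score_full("AAAA", "WWWW", blosum(), 10, 0.5), 0)
  expect_error(score_full("", "ACD"), "empty")
})

test_that("FULL DP score equals brute-force enumeration on short pairs", {
  set.seed(101)
  S <- blosum()
  for (rep in 1:60) {
    s1 <- rand_seq(sample(2:5, 1)); s2 <- rand_seq(sample(2:5, 1))
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    got <- msaframe:::pairwise_gotoh(s1, s2, S, 4, 0.6)$score
    want <- oracle_affine_best(S[a, b, drop = FALSE], 4, 0.6)
    expect_equal(got, want, info = paste(s1, s2))
  }
})

test_that("full-table DP score matches the linear-space scorer on longer pairs", {
  set.seed(102)
  S <- blosum()
  for (rep in 1:200) {
    s1 <- rand_seq(sample(5:40, 1), rownames(S)[1:20])
    s2 <- rand_seq(sample(5:40, 1), rownames(S)[1:20])
    a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
    m <- S[a, b, drop = FALSE]
    full <- msaframe:::affine_dp_cpp(m, 10, 0.5, rep(1, length(a) + 1),
                                     rep(1, length(b) + 1), FALSE)$score
    lin <- msaframe:::affine_score_linear_cpp(m, 10, 0.5)
    expect_equal(full, lin)
  }
})

test_that("QUICK counts shared distinct tuples over the shorter sequence", {
  expect_equal(score_quick("ACDEF", "ACDEF", k = 1), 100)
  expect_equal(score_quick("AAAA", "CCCC", k = 1), 0)
  expect_equal(score_quick("ABAB", "BABA", k = 2), 100 * 2 / 3)
  expect_error(score_quick("AC", "AC", k = 3), "out of range")
})

test_that("KMERS uses min occurrence counts over min(L) - k + 1", {
  expect_equal(score_kmers("ACD", "FGH", k = 2), 0)
  # ABAB vs ABAB, k=2: counts AB:2, BA:1 -> shared 3 over 4-2+1
  expect_equal(score_kmers("ABAB", "ABAB", k = 2), 100 * 3 / 3)
  expect_equal(score_kmers("ABABA", "ABAB", k = 2), 100 * 3 / 3)
  set.seed(103)
  for (rep in 1:20) {
    s1 <- rand_seq(sample(4:10, 1)); s2 <- rand_seq(sample(4:10, 1))
    expect_equal(score_kmers(s1, s2, 3), score_kmers(s2, s1, 3))
    expect_gte(score_kmers(s1, s2, 3), 0)
    expect_lte(score_kmers(s1, s2, 3), 100)
  }
})

test_that("LCS score matches the quadratic DP oracle", {
  expect_equal(score_lcs("ACGT", "AGT"), 100)
  expect_equal(score_lcs("AAA", "CCC"), 0)
  set.seed(104)
  for (rep in 1:300) {
    s1 <- rand_seq(sample(1:25, 1)); s2 <- rand_seq(sample(1:25, 1))
    expect_equal(score_lcs(s1, s2),
                 100 * oracle_lcs(s1, s2) / min(nchar(s1), nchar(s2)))
  }
})

test_that("pair-HMM posteriors equal exhaustive path enumeration on short pairs", {
  params <- pair_hmm_params()
  set.seed(105)
  for (rep in 1:40) {
    s1 <- rand_seq(sample(1:4, 1)); s2 <- rand_seq(sample(1:4, 1))
    got <- pair_posterior(s1, s2, params)
    want <- oracle_pairhmm_posterior(s1, s2, params)
    expect_equal(got, want, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("posterior rows and columns carry at most unit mass", {
  params <- pair_hmm_params()
  set.seed(106)
  for (rep in 1:20) {
    p <- pair_posterior(rand_seq(sample(3:25, 1)), rand_seq(sample(3:25, 1)),
                        params)
    expect_true(all(p >= 0 & p <= 1 + 1e-9))
    expect_true(all(rowSums(p) <= 1 + 1e-9))
    expect_true(all(colSums(p) <= 1 + 1e-9))
  }
})

test_that("near-identical sequences put the posterior mode on the diagonal", {
  p <- pair_posterior("WKF", "WKF", pair_hmm_params())
  expect_identical(apply(p, 1, which.max), 1:3)
})

test_that("MEA value equals exhaustive maximum and PROBA is symmetric", {
  params <- pair_hmm_params()
  set.seed(107)
  for (rep in 1:40) {
    s1 <- rand_seq(sample(1:4, 1)); s2 <- rand_seq(sample(1:4, 1))
    post <- pair_posterior(s1, s2, params)
    expect_equal(msaframe:::mea_score_cpp(post), oracle_mea(post),
                 tolerance = 1e-12)
    expect_equal(score_proba(s1, s2, params), score_proba(s2, s1, params),
                 tolerance = 1e-9)
  }
})

test_that("every similarity method is symmetric and bounded on random pairs", {
  set.seed(108)
  params <- pair_hmm_params()
  scorers <- list(F = function(a, b) score_full(a, b),
                  Q = function(a, b) score_quick(a, b, 1),
                  K = function(a, b) score_kmers(a, b, 2),
                  L = score_lcs,
                  P = function(a, b) score_proba(a, b, params))
  for (rep in 1:10) {
    s1 <- rand_seq(sample(4:12, 1)); s2 <- rand_seq(sample(4:12, 1))
    for (m in names(scorers)) {
      v <- scorers[[m]](s1, s2)
      expect_gte(v, 0); expect_lte(v, 100)
      expect_equal(v, scorers[[m]](s2, s1), info = m)
    }
  }
})

test_that("similarity matrix has the right shape, cache tags and permutation invariance", {
  set.seed(109)
  seqs <- aa_seqs(c(a = "ACDEFGHIK", b = "ACDEFGHIR", c = "MNPQRSTVW",
                    d = "ACDEWGHIK"))
  M <- build_similarity_matrix(seqs, "F")
  expect_equal(dim(unclass(M)), c(4, 4))
  expect_equal(sum(upper.tri(M)), 6)
  expect_identical(attr(M, "method"), "F")
  expect_equal(unclass(M), t(unclass(M)))

  perm <- c("c", "a", "d", "b")
  M2 <- build_similarity_matrix(seqs[perm], "F")
  expect_equal(unclass(M2)[names(seqs), names(seqs)], unclass(M),
               ignore_attr = TRUE)

  ident <- aa_seqs(c(x = "ACDEF", y = "ACDEF", z = "ACDEF"))
  for (m in c("F", "Q", "L", "K")) {
    Mi <- build_similarity_matrix(ident, m)
    expect_true(all(unclass(Mi) == 100), info = m)
  }
  # PROBA posteriors never reach 1 exactly; identical sequences come close
  Mp <- build_similarity_matrix(ident, "P")
  expect_true(all(unclass(Mp) > 99))
})
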