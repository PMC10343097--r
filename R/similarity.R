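# Stage 1: pairwise similarity scoring.
#
# Five techniques, all returning a percent-like value in [0, 100] and
# symmetric in their two arguments:
#   F  global affine-gap alignment identity (Gotoh DP)
#   Q  shared distinct k-tuples (k = 1 default)
#   K  shared k-mer occurrences, MUSCLE-style (k = 3 default)
#   L  longest common subsequence over the shorter length
#   P  maximum-expected-accuracy value over pair-HMM posteriors

# internal: optimal global affine-gap alignment of two residue strings.
# Returns score, identity (% of matched gap-free columns) and the two
# aligned index vectors (0 = gap).
pairwise_gotoh <- function(s1, s2, matrix = blosum(), gap_open = 10,
                           gap_extend = 0.5, free_ends = FALSE) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) == 0 || length(b) == 0) stop("empty sequence")
  a[!a %in% rownames(matrix)] <- "X"
  b[!b %in% rownames(matrix)] <- "X"
  m <- matrix[a, b, drop = FALSE]
  res <- affine_dp_cpp(m, gap_open, gap_extend,
                       rep(1, length(a) + 1), rep(1, length(b) + 1), free_ends)
  core <- res$a > 0 & res$b > 0
  ident <- if (any(core)) 100 * mean(a[res$a[core]] == b[res$b[core]]) else 0
  list(score = res$score, identity = ident, a = res$a, b = res$b,
       res1 = a, res2 = b)
}

#' FULL similarity: global alignment identity
#'
#' Identity percentage of the optimal global affine-gap (Gotoh) alignment:
#' matched residues over columns where neither sequence has a gap.
#'
#' @param s1,s2 residue strings.
#' @param matrix a `subst_matrix` (default BLOSUM62).
#' @param gap_open,gap_extend non-negative affine gap penalties; a gap of
#'   length g costs `gap_open + (g - 1) * gap_extend`.
#' @return percent in `[0, 100]`.
#' @export
score_full <- function(s1, s2, matrix = blosum(), gap_open = 10,
                       gap_extend = 0.5) {
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  pairwise_gotoh(s1, s2, matrix, gap_open, gap_extend)$identity
}

#' QUICK similarity: shared distinct k-tuples
#'
#' Counts the distinct length-`k` tuples present in both sequences, over
#' the number of tuple positions in the shorter sequence.
#'
#' @param s1,s2 residue strings.
#' @param k tuple length, default 1.
#' @return percent in `[0, 100]`.
#' @export
score_quick <- function(s1, s2, k = 1) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (k < 1 || k > min(n1, n2)) stop("k out of range")
  t1 <- unique(kmer_set(s1, k))
  t2 <- unique(kmer_set(s2, k))
  100 * length(intersect(t1, t2)) / (min(n1, n2) - k + 1)
}

#' KMERS similarity: shared k-mer occurrences
#'
#' MUSCLE-style fractional k-mer identity: for each distinct k-mer the
#' smaller of its two occurrence counts is shared, summed and divided by
#' `min(L1, L2) - k + 1`.
#'
#' @param s1,s2 residue strings.
#' @param k k-mer length, default 3.
#' @return percent in `[0, 100]`.
#' @export
score_kmers <- function(s1, s2, k = 3) {
  n1 <- nchar(s1); n2 <- nchar(s2)
  if (k < 1 || k > min(n1, n2)) stop("k out of range")
  c1 <- table(kmer_set(s1, k))
  c2 <- table(kmer_set(s2, k))
  common <- intersect(names(c1), names(c2))
  shared <- sum(pmin(c1[common], c2[common]))
  100 * shared / (min(n1, n2) - k + 1)
}

kmer_set <- function(s, k) {
  n <- nchar(s)
  substring(s, 1:(n - k + 1), k:n)
}

#' LCS similarity
#'
#' Length of the longest common subsequence over the length of the shorter
#' sequence, computed with a linear-space (two-row) DP.
#'
#' @param s1,s2 residue strings.
#' @return percent in `[0, 100]`.
#' @export
score_lcs <- function(s1, s2) {
  if (nchar(s1) == 0 || nchar(s2) == 0) stop("empty sequence")
  a <- utf8ToInt(toupper(s1))
  b <- utf8ToInt(toupper(s2))
  100 * lcs_length_cpp(a, b) / min(length(a), length(b))
}

#' PROBA similarity: maximum expected accuracy
#'
#' Sums pair-HMM posterior match probabilities along the best monotone
#' path (maximum-expected-accuracy alignment) and normalizes by the
#' shorter sequence length.
#'
#' @param s1,s2 residue strings.
#' @param params a [pair_hmm_params()] object.
#' @return percent in `[0, 100]`.
#' @export
score_proba <- function(s1, s2, params = pair_hmm_params()) {
  post <- pair_posterior(s1, s2, params)
  100 * mea_score_cpp(post) / min(nrow(post), ncol(post))
}

#' Build the pairwise similarity matrix (Stage 1)
#'
#' @param seqs an `aa_seqs` set, n >= 2.
#' @param method one of `"F"`, `"Q"`, `"L"`, `"K"`, `"P"`.
#' @param matrix substitution matrix for `"F"`.
#' @param gap_open,gap_extend affine penalties for `"F"`.
#' @param k tuple / k-mer length for `"Q"` (default 1) and `"K"` (default 3).
#' @param hmm_params pair-HMM parameters for `"P"`.
#' @return a `sim_matrix`: symmetric n x n numeric matrix on the 0-100
#'   scale with 100 on the diagonal, sequence ids as dimnames and the
#'   method tag as attribute `method`.
#' @export
build_similarity_matrix <- function(seqs, method = c("F", "Q", "L", "K", "P"),
                                    matrix = blosum(), gap_open = 10,
                                    gap_extend = 0.5, k = NULL,
                                    hmm_params = NULL) {
  method <- match.arg(method)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (method == "P" && is.null(hmm_params)) hmm_params <- pair_hmm_params()
  if (is.null(k)) k <- if (method == "Q") 1L else 3L
  scorer <- switch(method,
    F = function(a, b) score_full(a, b, matrix, gap_open, gap_extend),
    Q = function(a, b) score_quick(a, b, k),
    K = function(a, b) score_kmers(a, b, k),
    L = score_lcs,
    P = function(a, b) score_proba(a, b, hmm_params))
  ids <- names(seqs)
  M <- diag(100, n)
  dimnames(M) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      v <- tryCatch(scorer(seqs[[i]], seqs[[j]]),
                    error = function(e)
                      stop("similarity failed for pair (", ids[i], ", ",
                           ids[j], "): ", conditionMessage(e)))
      M[i, j] <- M[j, i] <- v
    }
  }
  structure(M, method = method, class = c("sim_matrix", class(M)))
}
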