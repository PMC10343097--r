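# Pair hidden Markov model: parameters and forward-backward posteriors.
#
# Three emitting states: M (aligned residue pair), X (residue in the first
# sequence only), Y (residue in the second sequence only).  Transition
# structure: M->X = M->Y = delta, X->X = Y->Y = epsilon, X->M = Y->M =
# 1 - epsilon, no direct X<->Y; the start distribution equals the
# transition distribution out of M.  No end state: a complete monotone
# path through both sequences is weighted by the product of its start,
# transition and emission probabilities.

#' Pair-HMM parameters
#'
#' Builds the parameter set from a YAML file: transition probabilities and
#' background residue frequencies, with match emissions derived from a
#' half-bit substitution matrix as `q_ij = p_i p_j 2^(S_ij/2)` (normalized)
#' and insert emissions set to the marginals of `q`.
#'
#' @param path YAML parameter file; defaults to the bundled set.
#' @param delta,epsilon optional overrides of the gap-open and gap-extend
#'   transition probabilities.
#' @return a `pair_hmm_params` object: list with `em` (joint match emission
#'   matrix), `bg` (insert emissions), `delta`, `epsilon`, `alphabet`.
#' @export
pair_hmm_params <- function(path = NULL, delta = NULL, epsilon = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "pairhmm_default.yaml", package = "msaframe")
  cfg <- yaml::read_yaml(path)
  d <- if (is.null(delta)) cfg$transitions$delta else delta
  e <- if (is.null(epsilon)) cfg$transitions$epsilon else epsilon
  if (d <= 0 || d >= 0.5 || e <= 0 || e >= 1)
    stop("need 0 < delta < 0.5 and 0 < epsilon < 1")
  p <- unlist(cfg$background)
  p <- p / sum(p)
  ab <- names(p)
  S <- blosum(cfg$emission_source)
  S <- S[ab, ab]
  q <- outer(p, p) * 2^(S / 2)
  q <- (q + t(q)) / 2           # numerically symmetric
  q <- q / sum(q)
  structure(list(em = q, bg = rowSums(q), delta = d, epsilon = e,
                 alphabet = ab),
            class = "pair_hmm_params")
}

#' Posterior residue-match probabilities under the pair-HMM
#'
#' Forward-backward in log space; `post[i, j]` is the posterior probability
#' that residue `i` of `s1` is aligned to residue `j` of `s2`.
#'
#' @param s1,s2 residue strings.
#' @param params a [pair_hmm_params()] object.
#' @return numeric matrix `nchar(s1) x nchar(s2)`, entries in `[0, 1]`,
#'   each row and column summing to at most 1.
#' @export
pair_posterior <- function(s1, s2, params = pair_hmm_params()) {
  x <- residue_index(s1, params$alphabet)
  y <- residue_index(s2, params$alphabet)
  pairhmm_posterior_cpp(x, y, log(params$em), log(params$bg), log(params$bg),
                        params$delta, params$epsilon)
}

# 0-based indices into the HMM alphabet; unknowns fall back to 'X'
residue_index <- function(s, alphabet) {
  ch <- strsplit(toupper(s), "")[[1]]
  if (length(ch) == 0) stop("empty sequence")
  i <- match(ch, alphabet)
  i[is.na(i)] <- match("X", alphabet)
  i - 1L
}
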