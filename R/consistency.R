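# Stage 3: residue-pair constraint library and consistency transformation.
#
# For every unordered sequence pair the library holds a (sparse in content,
# dense in storage) matrix of non-negative weights over residue-position
# pairs.  The triplet extension reinforces each pair's weights with the
# evidence routed through every third sequence:
#   W'(i_x, j_y) = W(i_x, j_y) + sum_z sum_k min(W(i_x, z_k), W(z_k, j_y)).

pair_key <- function(i, j) paste0(min(i, j), "|", max(i, j))

#' Build the primary constraint library
#'
#' In `"posterior"` mode the weights are pair-HMM posterior match
#' probabilities (entries below `eps` dropped); in `"alignment"` mode the
#' residue pairs matched by the optimal global affine-gap alignment of the
#' two sequences each get the pair's identity percentage as weight
#' (T-COFFEE style).
#'
#' @param seqs an `aa_seqs` set.
#' @param mode `"posterior"` (default) or `"alignment"`.
#' @param hmm_params pair-HMM parameters for posterior mode.
#' @param matrix,gap_open,gap_extend alignment-mode scoring parameters.
#' @param eps posterior threshold below which entries are dropped.
#' @return a `constraint_library`: list with `ids`, `lens`, `pairs` (one
#'   weight matrix per unordered pair, rows = first id by input order) and
#'   an `extended` flag.
#' @export
build_primary_library <- function(seqs, mode = c("posterior", "alignment"),
                                  hmm_params = NULL, matrix = blosum(),
                                  gap_open = 10, gap_extend = 0.5,
                                  eps = 0.01) {
  mode <- match.arg(mode)
  n <- length(seqs)
  if (n < 2) stop("need at least 2 sequences")
  if (mode == "posterior" && is.null(hmm_params)) hmm_params <- pair_hmm_params()
  ids <- names(seqs)
  lens <- setNames(nchar(seqs), ids)
  pairs <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mode == "posterior") {
        W <- pair_posterior(seqs[[i]], seqs[[j]], hmm_params)
        W[W < eps] <- 0
      } else {
        al <- pairwise_gotoh(seqs[[i]], seqs[[j]], matrix, gap_open, gap_extend)
        W <- base::matrix(0, lens[i], lens[j])
        core <- al$a > 0 & al$b > 0
        W[cbind(al$a[core], al$b[core])] <- al$identity
      }
      pairs[[pair_key(i, j)]] <- W
    }
  }
  structure(list(ids = ids, lens = lens, pairs = pairs, extended = FALSE),
            class = "constraint_library")
}

# weight matrix for the ordered pair (i, j), transposing stored i<j entries
lib_pair_matrix <- function(lib, i, j) {
  W <- lib$pairs[[pair_key(i, j)]]
  if (i <= j) W else t(W)
}

#' Apply the triplet consistency transformation
#'
#' One round of T-COFFEE-style extension over all third sequences; original
#' entries are retained, so the extension is monotone
#' (`W'(e) >= W(e)` for every entry).  With n = 2 the library is unchanged.
#'
#' @param lib a primary `constraint_library`.
#' @return the extended `constraint_library`.
#' @export
consistency_transform <- function(lib) {
  n <- length(lib$ids)
  out <- lib$pairs
  if (n > 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        acc <- lib$pairs[[pair_key(i, j)]]
        for (z in setdiff(seq_len(n), c(i, j)))
          acc <- acc + minplus_relax_cpp(lib_pair_matrix(lib, i, z),
                                         lib_pair_matrix(lib, z, j))
        out[[pair_key(i, j)]] <- acc
      }
    }
  }
  structure(list(ids = lib$ids, lens = lib$lens, pairs = out, extended = TRUE),
            class = "constraint_library")
}

# largest weight in the library (0 for an empty one)
lib_max_weight <- function(lib) {
  m <- vapply(lib$pairs, max, 0)
  if (length(m)) max(m) else 0
}

#' Constraint-library bonus for one residue-position pair
#'
#' The weight is rescaled so that the library's maximum maps to the largest
#' substitution-matrix entry (times `lambda`), keeping the bonus on the
#' same scale as the DP match scores; absent entries give 0 and
#' `lambda = 0` switches the library off entirely.
#'
#' @param lib an extended `constraint_library`.
#' @param pair ids (or indices) of the two sequences.
#' @param positions 1-based residue positions `c(x, y)` in the two sequences.
#' @param matrix substitution matrix defining the target scale.
#' @param lambda scale factor, default 1.
#' @return a single non-negative number.
#' @export
library_bonus <- function(lib, pair, positions, matrix = blosum(),
                          lambda = 1) {
  i <- if (is.character(pair[1])) match(pair[1], lib$ids) else pair[1]
  j <- if (is.character(pair[2])) match(pair[2], lib$ids) else pair[2]
  if (anyNA(c(i, j))) stop("unknown sequence in pair")
  W <- lib_pair_matrix(lib, i, j)
  lib_bonus_scale(lib, matrix, lambda) * W[positions[1], positions[2]]
}

lib_bonus_scale <- function(lib, matrix, lambda) {
  mw <- lib_max_weight(lib)
  if (lambda == 0 || mw == 0) 0 else lambda * max(matrix) / mw
}

#' Dump / load a constraint library as TSV
#'
#' Columns `seq_i pos_i seq_j pos_j weight`, 0-based positions, one row per
#' non-zero entry of each stored (i < j) pair.
#'
#' @param lib a `constraint_library`.
#' @param path TSV file.
#' @param seqs the sequence set the library refers to (for dimensions).
#' @return `write_library()` the path, invisibly; `read_library()` a
#'   `constraint_library`.
#' @export
write_library <- function(lib, path) {
  rows <- list()
  for (key in names(lib$pairs)) {
    ij <- as.integer(strsplit(key, "|", fixed = TRUE)[[1]])
    W <- lib$pairs[[key]]
    nz <- which(W > 0, arr.ind = TRUE)
    if (nrow(nz)) rows[[key]] <- data.frame(
      seq_i = lib$ids[ij[1]], pos_i = nz[, 1] - 1L,
      seq_j = lib$ids[ij[2]], pos_j = nz[, 2] - 1L,
      weight = W[nz])
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq_i = character(), pos_i = integer(), seq_j = character(),
               pos_j = integer(), weight = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_library
#' @export
read_library <- function(path, seqs) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  ids <- names(seqs)
  lens <- setNames(nchar(seqs), ids)
  pairs <- list()
  for (i in seq_len(length(ids) - 1))
    for (j in (i + 1):length(ids))
      pairs[[pair_key(i, j)]] <- base::matrix(0, lens[i], lens[j])
  for (r in seq_len(nrow(df))) {
    i <- match(df$seq_i[r], ids); j <- match(df$seq_j[r], ids)
    if (anyNA(c(i, j))) stop("library row ", r, " names an unknown sequence")
    if (i < j) pairs[[pair_key(i, j)]][df$pos_i[r] + 1L, df$pos_j[r] + 1L] <- df$weight[r]
    else pairs[[pair_key(i, j)]][df$pos_j[r] + 1L, df$pos_i[r] + 1L] <- df$weight[r]
  }
  structure(list(ids = ids, lens = lens, pairs = pairs, extended = FALSE),
            class = "constraint_library")
}
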