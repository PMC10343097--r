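# Stage 4: Clustal W-style progressive profile-profile alignment.
#
# A profile is a set of already-aligned rows with per-sequence weights.
# The column-pair match score is the weight-normalized sum of substitution
# scores over residue pairs (gap residues contribute nothing), plus an
# optional constraint-library bonus averaged over member sequence pairs.
# Gap opening is cheaper inside and next to existing gap columns, and
# terminal gap runs are not charged an opening penalty by default.

#' Gap model for profile alignment
#'
#' @param gap_open,gap_extend non-negative affine penalties; a gap of
#'   length g costs `gap_open * mult + (g - 1) * gap_extend`, with `mult`
#'   the position-specific opening multiplier.
#' @param terminal_free if `TRUE` (default) terminal gap runs are free.
#' @param gap_col_factor opening multiplier next to a column that already
#'   contains gaps.
#' @param adjacent_factor opening multiplier within `adjacent_range`
#'   columns of a gap-containing column.
#' @param adjacent_range reach of `adjacent_factor`, in columns.
#' @return a `gap_model` list.
#' @export
gap_model <- function(gap_open = 10, gap_extend = 0.2, terminal_free = TRUE,
                      gap_col_factor = 0.3, adjacent_factor = 0.5,
                      adjacent_range = 2) {
  stopifnot(gap_open >= 0, gap_extend >= 0, gap_col_factor > 0,
            adjacent_factor > 0, adjacent_range >= 0)
  structure(list(gap_open = gap_open, gap_extend = gap_extend,
                 terminal_free = terminal_free,
                 gap_col_factor = gap_col_factor,
                 adjacent_factor = adjacent_factor,
                 adjacent_range = adjacent_range),
            class = "gap_model")
}

#' Clustal W sequence weights from a guide tree
#'
#' Each leaf's weight is the sum, over the edges on its path to the root,
#' of the edge length divided by the number of leaves below that edge;
#' weights are normalized to mean 1.  A tree with all-zero branch lengths
#' (e.g. identical sequences) gives equal weights.
#'
#' @param tree a `guide_tree`.
#' @return named numeric vector of positive weights, mean 1.
#' @export
compute_sequence_weights <- function(tree) {
  phy <- tree$phylo
  ntip <- length(phy$tip.label)
  el <- phy$edge.length
  if (is.null(el)) el <- rep(1, nrow(phy$edge))
  w <- setNames(rep(0, ntip), phy$tip.label)
  for (e in seq_len(nrow(phy$edge))) {
    lv <- leaves_below(phy, phy$edge[e, 2])
    w[lv] <- w[lv] + el[e] / length(lv)
  }
  if (sum(w) <= 0) w[] <- 1
  w / mean(w)
}

# profile: rows of an alignment (character matrix) plus member weights
new_profile <- function(mat, weights) {
  if (is.null(rownames(mat))) stop("profile rows must be named")
  weights <- weights[rownames(mat)]
  if (any(!is.finite(weights)) || any(weights <= 0))
    stop("profile weights must be positive and finite")
  list(mat = mat, weights = weights)
}

profile_from_seqs <- function(seqs, weights) {
  new_profile(msa_like(seqs), weights)
}

# single sequences / equal-length rows as a degenerate "alignment" matrix
msa_like <- function(seqs) {
  m <- do.call(rbind, strsplit(unclass(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

# weighted residue count matrix (columns x alphabet); gaps excluded
profile_counts <- function(p, alphabet) {
  L <- ncol(p$mat)
  C <- base::matrix(0, L, length(alphabet), dimnames = list(NULL, alphabet))
  for (r in seq_len(nrow(p$mat))) {
    res <- p$mat[r, ]
    res[!res %in% alphabet & res != "-"] <- "X"
    keep <- res != "-"
    idx <- cbind(which(keep), match(res[keep], alphabet))
    C[idx] <- C[idx] + p$weights[r]
  }
  C
}

# position-specific gap-open multipliers, indexed by the gap position
# "after column j" for j = 0..L
open_multipliers <- function(p, gm) {
  L <- ncol(p$mat)
  mult <- rep(1, L + 1)
  has_gap <- colSums(p$mat == "-") > 0
  if (any(has_gap)) {
    gap_adj <- c(FALSE, has_gap) | c(has_gap, FALSE)   # position j touches col j or j+1
    mult[gap_adj] <- gm$gap_col_factor
    if (gm$adjacent_range > 0) {
      near <- rep(FALSE, L + 1)
      for (d in seq_len(gm$adjacent_range))
        near <- near | c(rep(FALSE, d), head(gap_adj, L + 1 - d)) |
                       c(tail(gap_adj, L + 1 - d), rep(FALSE, d))
      mult[near & !gap_adj] <- gm$adjacent_factor
    }
  }
  mult
}

# per-row map from alignment column to residue ordinal (NA at gaps)
residue_ordinals <- function(mat) {
  t(apply(mat, 1, function(row) {
    ord <- cumsum(row != "-")
    ord[row == "-"] <- NA
    ord
  }))
}

# library bonus matrix for a pair of profiles, averaged over member pairs
profile_bonus <- function(p1, p2, lib, matrix, lambda) {
  scale <- lib_bonus_scale(lib, matrix, lambda)
  if (scale == 0) return(NULL)
  L1 <- ncol(p1$mat); L2 <- ncol(p2$mat)
  B <- base::matrix(0, L1, L2)
  ord1 <- residue_ordinals(p1$mat)
  ord2 <- residue_ordinals(p2$mat)
  for (r1 in rownames(p1$mat)) {
    i <- match(r1, lib$ids)
    m1 <- ord1[r1, ]
    c1 <- which(!is.na(m1))
    for (r2 in rownames(p2$mat)) {
      j <- match(r2, lib$ids)
      m2 <- ord2[r2, ]
      c2 <- which(!is.na(m2))
      if (length(c1) && length(c2)) {
        W <- lib_pair_matrix(lib, i, j)
        B[c1, c2] <- B[c1, c2] + W[m1[c1], m2[c2], drop = FALSE]
      }
    }
  }
  scale * B / (nrow(p1$mat) * nrow(p2$mat))
}

#' Align two profiles
#'
#' Global affine-gap DP over column-pair scores.  Gaps are inserted only as
#' whole columns into one profile or the other, so previously aligned
#' columns are preserved ("once a gap, always a gap").
#'
#' @param p1,p2 profiles (see [progressive_align()]) with disjoint members.
#' @param matrix substitution matrix.
#' @param gm a [gap_model()].
#' @param lib optional extended `constraint_library`.
#' @param lambda library bonus scale; 0 disables the library.
#' @return an `msa_aln` containing all members of both profiles.
#' @export
align_profiles <- function(p1, p2, matrix = blosum(), gm = gap_model(),
                           lib = NULL, lambda = 1) {
  if (length(intersect(rownames(p1$mat), rownames(p2$mat))))
    stop("profiles share members")
  if (nrow(p1$mat) == 0 || nrow(p2$mat) == 0) stop("empty profile")
  ab <- rownames(matrix)
  C1 <- profile_counts(p1, ab)
  C2 <- profile_counts(p2, ab)
  M <- (C1 %*% unclass(matrix) %*% t(C2)) /
    (sum(p1$weights) * sum(p2$weights))
  if (!is.null(lib) && lambda != 0) {
    B <- profile_bonus(p1, p2, lib, matrix, lambda)
    if (!is.null(B)) M <- M + B
  }
  res <- affine_dp_cpp(M, gm$gap_open, gm$gap_extend,
                       open_multipliers(p1, gm), open_multipliers(p2, gm),
                       gm$terminal_free)
  ncol_out <- length(res$a)
  take <- function(p, idx) {
    out <- base::matrix("-", nrow(p$mat), ncol_out,
                        dimnames = list(rownames(p$mat), NULL))
    out[, idx > 0] <- p$mat[, idx[idx > 0], drop = FALSE]
    out
  }
  matrix_aln(rbind(take(p1, res$a), take(p2, res$b)))
}

#' Progressive alignment along a guide tree
#'
#' Traverses the tree bottom-up, aligning the profiles of each internal
#' node's children; the result de-gaps to the input sequences exactly.
#'
#' @param seqs an `aa_seqs` set; ids must match the tree leaves.
#' @param tree a `guide_tree`.
#' @param matrix a `subst_matrix`, or `"adaptive"` to pick from the BLOSUM
#'   ladder (80/62/45) by the mean cross-profile similarity of each merge
#'   (requires `sim`).
#' @param gm a [gap_model()].
#' @param lib optional extended `constraint_library` (consistency class).
#' @param lambda library bonus scale.
#' @param sim the Stage-1 `sim_matrix`, needed for `matrix = "adaptive"`.
#' @return an `msa_aln` over all sequences.
#' @export
progressive_align <- function(seqs, tree, matrix = blosum(),
                              gm = gap_model(), lib = NULL, lambda = 1,
                              sim = NULL) {
  phy <- tree$phylo
  if (!setequal(phy$tip.label, names(seqs)))
    stop("tree leaves do not match sequence ids")
  adaptive <- is.character(matrix) && identical(matrix, "adaptive")
  if (adaptive && is.null(sim))
    stop("adaptive matrix choice needs the similarity matrix")
  w <- compute_sequence_weights(tree)
  ntip <- length(phy$tip.label)
  align_node <- function(node) {
    if (node <= ntip) {
      id <- phy$tip.label[node]
      return(profile_from_seqs(seqs[id], w))
    }
    kids <- phy$edge[phy$edge[, 1] == node, 2]
    p1 <- align_node(kids[1])
    p2 <- align_node(kids[2])
    mat <- if (adaptive) adaptive_matrix(sim, rownames(p1$mat),
                                         rownames(p2$mat)) else matrix
    aln <- align_profiles(p1, p2, mat, gm, lib, lambda)
    new_profile(aln_matrix(aln), w)
  }
  prof <- align_node(tree_root(phy))
  matrix_aln(prof$mat[names(seqs)[names(seqs) %in% rownames(prof$mat)], ,
                      drop = FALSE])
}

# BLOSUM ladder keyed on mean cross-profile similarity (percent)
adaptive_matrix <- function(sim, ids1, ids2) {
  m <- mean(unclass(sim)[ids1, ids2])
  if (m >= 60) blosum("BLOSUM80")
  else if (m >= 40) blosum("BLOSUM62")
  else blosum("BLOSUM45")
}
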