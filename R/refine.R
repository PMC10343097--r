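# Stage 5: tree-restricted-partitioning iterative refinement of the WSP.
#
# Each sweep visits every guide-tree edge from the deepest up to the root:
# the alignment rows are split into the leaves below the edge and the rest,
# all-gap columns are dropped on each side, the two profiles are realigned
# with the Stage-4 engine, and the candidate replaces the current best
# only if its WSP is strictly higher.  Sweeps repeat until one finds no
# improvement or the iteration cap is reached.

#' Weighted sum-of-pairs score
#'
#' `WSP(A) = sum_l sum_{i<j} w_ij * S(a_il, a_jl)`; pairs involving a gap
#' contribute 0 (the objective has no affine gap term).
#'
#' @param aln an `msa_aln`.
#' @param matrix substitution matrix.
#' @param weights per-sequence weights; `w_ij` is `w_i * w_j` normalized to
#'   mean 1 over pairs.  `NULL` (default) sets every `w_ij = 1` (plain SP).
#' @return a single number.
#' @export
wsp <- function(aln, matrix = blosum(), weights = NULL) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  if (is.null(weights)) weights <- setNames(rep(1, n), rownames(m))
  wv <- weights[rownames(m)]
  ab <- rownames(matrix)
  S <- unclass(matrix)
  L <- ncol(m)
  # weighted residue indicator sums per column, and the per-row self terms
  C <- base::matrix(0, L, length(ab), dimnames = list(NULL, ab))
  self <- numeric(L)
  for (r in seq_len(n)) {
    res <- m[r, ]
    res[!res %in% ab & res != "-"] <- "X"
    keep <- res != "-"
    idx <- cbind(which(keep), match(res[keep], ab))
    C[idx] <- C[idx] + wv[r]
    self[keep] <- self[keep] + wv[r]^2 * S[cbind(res[keep], res[keep])]
  }
  colterm <- (rowSums((C %*% S) * C) - self) / 2   # sum_{i<j} wi wj S
  # normalize the pair weights to mean 1
  pairs <- utils::combn(n, 2)
  mean_w <- mean(wv[pairs[1, ]] * wv[pairs[2, ]])
  if (mean_w == 0) return(0)
  sum(colterm) / mean_w
}

#' Refinement configuration
#'
#' @param max_iterations cap on full sweeps over the tree edges
#'   (default 100).
#' @param objective `"wsp"` (tree-derived pair weights) or `"sp"`
#'   (all weights 1).
#' @return a `refine_config` list.
#' @export
refine_config <- function(max_iterations = 100, objective = c("wsp", "sp")) {
  stopifnot(max_iterations >= 1)
  list(max_iterations = as.integer(max_iterations),
       objective = match.arg(objective))
}

#' Bipartition the leaves by cutting a guide-tree edge
#'
#' @param tree a `guide_tree`.
#' @param edge the child node of the edge to cut (1-based phylo node
#'   number), or a leaf label.
#' @return list of two character vectors of sequence ids (below, rest).
#' @export
partition_by_edge <- function(tree, edge) {
  phy <- tree$phylo
  if (is.character(edge)) edge <- match(edge, phy$tip.label)
  root <- tree_root(phy)
  if (is.na(edge) || edge == root) stop("no edge above the root")
  if (!edge %in% phy$edge[, 2]) stop("no such edge")
  below <- leaves_below(phy, edge)
  list(below = below, rest = setdiff(phy$tip.label, below))
}

#' Tree-restricted iterative refinement
#'
#' @param aln starting `msa_aln` covering the tree leaves.
#' @param tree the `guide_tree` whose edges define the bipartitions.
#' @param matrix substitution matrix (also the WSP matrix), or
#'   `"adaptive"` with `sim`.
#' @param gm a [gap_model()].
#' @param lib optional extended `constraint_library` (CI class).
#' @param lambda library bonus scale.
#' @param cfg a [refine_config()].
#' @param sim Stage-1 similarity matrix for adaptive matrix choice.
#' @return the refined `msa_aln` with attributes `wsp` (final value),
#'   `wsp_trace` (WSP after each accepted step, starting value first) and
#'   `sweeps` (number of sweeps run).
#' @export
refine <- function(aln, tree, matrix = blosum(), gm = gap_model(),
                   lib = NULL, lambda = 1, cfg = refine_config(),
                   sim = NULL) {
  phy <- tree$phylo
  if (!setequal(phy$tip.label, names(aln)))
    stop("alignment rows do not match tree leaves")
  adaptive <- is.character(matrix) && identical(matrix, "adaptive")
  if (adaptive && is.null(sim))
    stop("adaptive matrix choice needs the similarity matrix")
  w <- compute_sequence_weights(tree)
  wsp_weights <- if (cfg$objective == "wsp") w else NULL
  wsp_matrix <- if (adaptive) blosum() else matrix
  root <- tree_root(phy)
  depth <- node_depths(phy)
  edges <- phy$edge[order(-depth[phy$edge[, 2]], phy$edge[, 2]), 2]
  best <- aln
  best_wsp <- wsp(best, wsp_matrix, wsp_weights)
  trace <- best_wsp
  sweeps <- 0L
  repeat {
    sweeps <- sweeps + 1L
    improved <- FALSE
    for (e in edges) {
      part <- partition_by_edge(tree, e)
      m <- aln_matrix(best)
      side <- function(ids) {
        sub <- m[ids, , drop = FALSE]
        keep <- colSums(sub != "-") > 0   # drop all-gap columns
        new_profile(sub[, keep, drop = FALSE], w)
      }
      p1 <- side(part$below)
      p2 <- side(part$rest)
      mat <- if (adaptive) adaptive_matrix(sim, part$below, part$rest) else matrix
      cand <- align_profiles(p1, p2, mat, gm, lib, lambda)
      cand <- matrix_aln(aln_matrix(cand)[names(aln), , drop = FALSE])
      cand_wsp <- wsp(cand, wsp_matrix, wsp_weights)
      if (cand_wsp > best_wsp) {
        best <- cand
        best_wsp <- cand_wsp
        trace <- c(trace, cand_wsp)
        improved <- TRUE
      }
    }
    if (!improved || sweeps >= cfg$max_iterations) break
  }
  structure(best, wsp = best_wsp, wsp_trace = trace, sweeps = sweeps)
}
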