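# Stage 2: guide-tree construction from the similarity matrix.
#
# Four builders over the Stage-1 similarity matrix: an agglomeration that
# repeatedly joins the most similar pair and propagates the *average* of
# the two removed scores (the WPGMA update, here called UPGMA after common
# usage in alignment tools), its single-linkage-style variants SLMIN
# (propagates the maximum score) and SLMAX (the minimum -- the names follow
# the framework's convention, which is inverted relative to similarity
# intuition), and Neighbor-Joining on the distance transform
# d = (100 - M) / 100.
#
# All builders are deterministic: among equally good join candidates the
# lexicographically smallest pair of cluster representative ids wins, the
# representative being the smallest leaf id in the cluster.

#' @rdname build_upgma
#' @export
build_guide_tree <- function(sim, method = c("UPGMA", "SLMIN", "SLMAX", "NJ")) {
  method <- match.arg(method)
  if (method == "NJ") build_nj(sim) else
    agglomerate(sim, update = switch(method,
      UPGMA = function(a, b) (a + b) / 2,
      SLMIN = pmax,
      SLMAX = pmin))
}

#' Guide-tree builders
#'
#' `build_upgma()` joins the pair with the highest similarity and sets the
#' merged node's similarity to each remaining node to the plain average of
#' the two removed scores.  `build_slink()` uses the same loop but keeps the
#' maximum (`SLMIN`) or minimum (`SLMAX`) of the two scores.  `build_nj()`
#' runs classic Neighbor-Joining on `d = (100 - M)/100` and roots the tree
#' at the midpoint of the final joining edge; negative branch lengths are
#' clamped to zero.  `build_guide_tree()` dispatches on a method tag.
#'
#' @param sim a `sim_matrix` from [build_similarity_matrix()].
#' @param method,variant which builder / single-linkage flavour.
#' @return a `guide_tree`: rooted binary tree (an [ape::read.tree()] phylo
#'   plus the leaf ids), with branch lengths derived from the join scores.
#' @export
build_upgma <- function(sim) build_guide_tree(sim, "UPGMA")

#' @rdname build_upgma
#' @export
build_slink <- function(sim, variant = c("SLMIN", "SLMAX"))
  build_guide_tree(sim, match.arg(variant))

# shared agglomeration loop; `update(sa, sr)` combines the two removed
# similarity vectors into the merged node's similarities
agglomerate <- function(sim, update) {
  M <- unclass(sim)
  ids <- rownames(M)
  n <- length(ids)
  if (n < 2) stop("need at least 2 sequences")
  nwk <- as.list(ids)          # growing newick fragment per active cluster
  rep_id <- ids                # representative (smallest leaf id)
  height <- rep(0, n)          # current node height on the distance scale
  active <- seq_len(n)
  while (length(active) > 1) {
    sub <- M[active, active, drop = FALSE]
    best <- -Inf; bi <- bj <- NA
    for (p in seq_along(active)) {
      for (q in seq_along(active)) {
        if (p >= q) next
        s <- sub[p, q]
        key <- c(rep_id[active[p]], rep_id[active[q]])
        if (s > best ||
            (s == best && lex_less(key, c(rep_id[active[bi]], rep_id[active[bj]])))) {
          best <- s; bi <- p; bj <- q
        }
      }
    }
    i <- active[bi]; j <- active[bj]
    h <- (100 - best) / 200          # distance-scale height of the join
    bl_i <- max(h - height[i], 0)
    bl_j <- max(h - height[j], 0)
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[[i]], fmt_bl(bl_i),
                       nwk[[j]], fmt_bl(bl_j))
    rest <- setdiff(active, c(i, j))
    merged <- update(M[i, rest], M[j, rest])
    M[i, rest] <- merged; M[rest, i] <- merged
    nwk[[i]] <- new_nwk
    rep_id[i] <- min(rep_id[c(i, j)])
    height[i] <- h
    active <- sort(setdiff(c(rest, i), j))
  }
  guide_tree_from_newick(paste0(nwk[[active]], ";"), ids)
}

lex_less <- function(a, b) {
  a <- sort(a); b <- sort(b)
  if (a[1] != b[1]) a[1] < b[1] else a[2] < b[2]
}

fmt_bl <- function(x) format(x, digits = 10, scientific = FALSE, trim = TRUE)

#' @rdname build_upgma
#' @export
build_nj <- function(sim) {
  M <- unclass(sim)
  ids <- rownames(M)
  n <- length(ids)
  if (n < 2) stop("need at least 2 sequences")
  D <- pmin(pmax((100 - M) / 100, 0), 1)
  diag(D) <- 0
  nwk <- as.list(ids)
  rep_id <- ids
  active <- seq_len(n)
  if (n == 2) {
    bl <- D[1, 2] / 2
    return(guide_tree_from_newick(
      sprintf("(%s:%s,%s:%s);", ids[1], fmt_bl(bl), ids[2], fmt_bl(bl)), ids))
  }
  while (length(active) > 2) {
    r <- length(active)
    Dsub <- D[active, active, drop = FALSE]
    R <- rowSums(Dsub)
    best <- Inf; bi <- bj <- NA
    for (p in 1:(r - 1)) {
      for (q in (p + 1):r) {
        Q <- (r - 2) * Dsub[p, q] - R[p] - R[q]
        key <- c(rep_id[active[p]], rep_id[active[q]])
        if (Q < best ||
            (Q == best && lex_less(key, c(rep_id[active[bi]], rep_id[active[bj]])))) {
          best <- Q; bi <- p; bj <- q
        }
      }
    }
    i <- active[bi]; j <- active[bj]
    dij <- D[i, j]
    li <- dij / 2 + (sum(D[i, active]) - sum(D[j, active])) / (2 * (r - 2))
    li <- min(max(li, 0), dij)
    lj <- max(dij - li, 0)
    rest <- setdiff(active, c(i, j))
    dnew <- (D[i, rest] + D[j, rest] - dij) / 2
    dnew <- pmax(dnew, 0)
    nwk[[i]] <- sprintf("(%s:%s,%s:%s)", nwk[[i]], fmt_bl(li),
                        nwk[[j]], fmt_bl(lj))
    rep_id[i] <- min(rep_id[c(i, j)])
    D[i, rest] <- dnew; D[rest, i] <- dnew
    active <- sort(setdiff(c(rest, i), j))
  }
  # root at the midpoint of the final connecting edge
  a <- active[1]; b <- active[2]
  half <- max(D[a, b], 0) / 2
  guide_tree_from_newick(
    sprintf("(%s:%s,%s:%s);", nwk[[a]], fmt_bl(half), nwk[[b]], fmt_bl(half)),
    ids)
}

guide_tree_from_newick <- function(text, ids) {
  phy <- ape::read.tree(text = text)
  gt <- structure(list(phylo = phy, ids = sort(phy$tip.label)),
                  class = "guide_tree")
  validate_guide_tree(gt, ids)
  gt
}

validate_guide_tree <- function(gt, ids = NULL) {
  phy <- gt$phylo
  n <- length(phy$tip.label)
  if (!is.null(ids) && !setequal(phy$tip.label, ids))
    stop("tree leaves do not match sequence ids")
  if (anyDuplicated(phy$tip.label)) stop("duplicate leaf labels")
  if (phy$Nnode != n - 1) stop("guide tree must be strictly binary")
  invisible(gt)
}

#' @export
print.guide_tree <- function(x, ...) {
  cat(sprintf("guide_tree: %d leaves\n", length(x$phylo$tip.label)))
  invisible(x)
}

#' Newick export / import for guide trees
#'
#' @param tree a `guide_tree`.
#' @param text Newick string (a trailing semicolon is required).
#' @return `to_newick()` a Newick string; `from_newick()` a `guide_tree`
#'   (trees without branch lengths get unit lengths).
#' @export
to_newick <- function(tree) ape::write.tree(tree$phylo)

#' @rdname to_newick
#' @export
from_newick <- function(text) {
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$tip.label)) stop("malformed Newick: ", text)
  if (is.null(phy$edge.length)) phy$edge.length <- rep(1, nrow(phy$edge))
  gt <- structure(list(phylo = phy, ids = sort(phy$tip.label)),
                  class = "guide_tree")
  validate_guide_tree(gt)
  gt
}

# --- small phylo helpers shared by later stages ---------------------------

tree_root <- function(phy) length(phy$tip.label) + 1L

# tip labels in the clade below `node`
leaves_below <- function(phy, node) {
  ntip <- length(phy$tip.label)
  if (node <= ntip) return(phy$tip.label[node])
  out <- character(0)
  kids <- phy$edge[phy$edge[, 1] == node, 2]
  for (k in kids) out <- c(out, leaves_below(phy, k))
  out
}

# number of edges between each node and the root
node_depths <- function(phy) {
  ntip <- length(phy$tip.label)
  nn <- ntip + phy$Nnode
  depth <- rep(NA_integer_, nn)
  depth[tree_root(phy)] <- 0L
  # repeatedly assign children of nodes whose depth is known
  repeat {
    todo <- is.na(depth[phy$edge[, 2]]) & !is.na(depth[phy$edge[, 1]])
    if (!any(todo)) break
    depth[phy$edge[todo, 2]] <- depth[phy$edge[todo, 1]] + 1L
  }
  depth
}
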