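# Synthetic protein-family generator with known reference alignments.
#
# A root sequence is evolved down a random binary tree.  Substitutions
# redraw residues from a stationary BLOSUM-derived frequency vector;
# insertions create fresh, unhomologized columns and deletions leave gaps
# in descendants only, so the true multiple alignment is tracked exactly:
# every residue carries a column key (position, creation id) inherited
# from its parent, and the reference alignment orders the union of keys.

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# stationary residue frequencies (shared with the pair-HMM background)
stationary_freqs <- function() {
  if (is.null(.msaframe_cache$freqs)) {
    cfg <- yaml::read_yaml(system.file("extdata", "pairhmm_default.yaml",
                                       package = "msaframe"))
    p <- unlist(cfg$background)[AA20]
    .msaframe_cache$freqs <- p / sum(p)
  }
  .msaframe_cache$freqs
}

#' Evolution parameters for the family generator
#'
#' @param n_leaves number of sequences (>= 2).
#' @param root_length root sequence length.
#' @param sub_rate per-site substitution probability per unit branch
#'   length (redraw from the stationary distribution, so a fraction
#'   resamples the same residue).
#' @param indel_rate expected indel events per site per unit branch
#'   length (split evenly between insertions and deletions).
#' @param indel_mean mean indel length (geometric).
#' @param seed optional RNG seed; `NULL` uses the current RNG state.
#' @return an `evolution_params` list.
#' @export
evolution_params <- function(n_leaves = 6, root_length = 100,
                             sub_rate = 0.12, indel_rate = 0.02,
                             indel_mean = 1.5, seed = NULL) {
  stopifnot(n_leaves >= 2, root_length >= 5, sub_rate >= 0, indel_rate >= 0,
            indel_mean >= 1)
  structure(list(n_leaves = n_leaves, root_length = root_length,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 indel_mean = indel_mean, seed = seed),
            class = "evolution_params")
}

# random binary topology by sequential joining; branch lengths U(0.5, 1.5)
random_topology <- function(n) {
  nodes <- as.list(paste0("s", seq_len(n)))
  while (length(nodes) > 1) {
    pick <- sample(length(nodes), 2)
    merged <- list(left = nodes[[pick[1]]], right = nodes[[pick[2]]],
                   bl_left = runif(1, 0.5, 1.5), bl_right = runif(1, 0.5, 1.5))
    nodes <- c(nodes[-pick], list(merged))
  }
  nodes[[1]]
}

# evolve a keyed sequence down one branch of length bl
evolve_branch <- function(seqdf, bl, params, counter) {
  p_sub <- min(params$sub_rate * bl, 0.95)
  n <- nrow(seqdf)
  if (n > 0 && p_sub > 0) {
    hit <- runif(n) < p_sub
    if (any(hit))
      seqdf$res[hit] <- sample(AA20, sum(hit), replace = TRUE,
                               prob = stationary_freqs())
  }
  n_events <- rpois(1, params$indel_rate * bl * max(n, 1))
  for (ev in seq_len(n_events)) {
    n <- nrow(seqdf)
    if (n <= 2) break
    len <- 1 + rgeom(1, 1 / params$indel_mean)
    if (runif(1) < 0.5) {       # deletion
      len <- min(len, n - 2)
      at <- sample(n - len + 1, 1)
      seqdf <- seqdf[-(at:(at + len - 1)), , drop = FALSE]
    } else {                    # insertion of unhomologized residues
      at <- sample(n + 1, 1)    # insert before position `at`
      lo <- if (at == 1) seqdf$pos[1] - 1 else seqdf$pos[at - 1]
      hi <- if (at == n + 1) seqdf$pos[n] + 1 else seqdf$pos[at]
      pos <- lo + (hi - lo) * seq_len(len) / (len + 1)
      ids <- counter$next_id + seq_len(len) - 1L
      counter$next_id <- counter$next_id + len
      ins <- data.frame(res = sample(AA20, len, replace = TRUE,
                                     prob = stationary_freqs()),
                        pos = pos, id = ids)
      seqdf <- rbind(seqdf[seq_len(at - 1), , drop = FALSE], ins,
                     seqdf[seq(at, length.out = n - at + 1), , drop = FALSE])
    }
  }
  seqdf
}

#' Generate one synthetic protein family
#'
#' @param params an [evolution_params()].
#' @param max_retries regeneration attempts if a lineage degenerates.
#' @return list with `seqs` (unaligned `aa_seqs`), `ref` (the true
#'   `msa_aln`), `meta` (identity of the reference, its band, parameters).
#' @export
generate_family <- function(params = evolution_params(), max_retries = 20) {
  if (!is.null(params$seed)) set.seed(params$seed)
  for (attempt in seq_len(max_retries)) {
    fam <- try_generate_family(params)
    if (!is.null(fam)) return(fam)
  }
  stop("family generation degenerated ", max_retries, " times; ",
       "lower indel_rate or raise root_length")
}

try_generate_family <- function(params) {
  topo <- random_topology(params$n_leaves)
  counter <- new.env()
  counter$next_id <- params$root_length + 1L
  root <- data.frame(res = sample(AA20, params$root_length, replace = TRUE,
                                  prob = stationary_freqs()),
                     pos = as.numeric(seq_len(params$root_length)),
                     id = seq_len(params$root_length))
  leaves <- list()
  walk <- function(node, seqdf) {
    if (is.character(node)) {
      if (nrow(seqdf) < 3) stop("degenerate")
      leaves[[node]] <<- seqdf
      return(invisible())
    }
    walk(node$left, evolve_branch(seqdf, node$bl_left, params, counter))
    walk(node$right, evolve_branch(seqdf, node$bl_right, params, counter))
  }
  ok <- tryCatch({ walk(topo, root); TRUE },
                 error = function(e) {
                   if (identical(conditionMessage(e), "degenerate")) FALSE
                   else stop(e)
                 })
  if (!isTRUE(ok) || length(leaves) < params$n_leaves) return(NULL)
  leaves <- leaves[order(names(leaves))]
  keys <- unique(do.call(rbind, lapply(leaves, function(x) x[, c("pos", "id")])))
  keys <- keys[order(keys$pos, keys$id), ]
  colkey <- paste(keys$pos, keys$id)
  rows <- vapply(leaves, function(x) {
    col <- rep("-", nrow(keys))
    col[match(paste(x$pos, x$id), colkey)] <- x$res
    paste(col, collapse = "")
  }, "")
  ref <- msa_aln(rows)
  seqs <- degap(ref)
  id <- identity_score(ref)
  list(seqs = seqs, ref = ref,
       meta = list(identity = id, band = identity_group(id),
                   n = params$n_leaves, params = unclass(params)))
}

#' Generate a suite of instances inside one identity band
#'
#' Families are rejection-sampled until the reference identity falls in
#' the requested band.  Band presets for the substitution rate: band1
#' 0.37, band2 0.24, band3 0.12 (per unit branch length).
#'
#' @param band 1, 2 or 3 (identity < 20, 20-40, 40-80 percent).
#' @param n_instances number of instances.
#' @param seed RNG seed for the whole suite.
#' @param out_dir optional directory; each instance is written to
#'   `<out_dir>/inst<k>/` as `seqs.fasta`, `ref.fasta` and `meta.yaml`.
#' @param params base [evolution_params()]; the band preset overrides
#'   `sub_rate`.
#' @param max_tries rejection budget per instance.
#' @return invisible list of instances (as from [generate_family()]).
#' @export
generate_band_suite <- function(band, n_instances, seed = 1, out_dir = NULL,
                                params = evolution_params(),
                                max_tries = 200) {
  stopifnot(band %in% 1:3)
  set.seed(seed)
  params$seed <- NULL
  params$sub_rate <- c(0.37, 0.24, 0.12)[band]
  target <- paste0("band", band)
  out <- vector("list", n_instances)
  for (k in seq_len(n_instances)) {
    fam <- NULL
    for (try in seq_len(max_tries)) {
      cand <- generate_family(params)
      if (cand$meta$band == target) { fam <- cand; break }
    }
    if (is.null(fam))
      stop("band ", band, " not reached within ", max_tries,
           " tries for instance ", k,
           " (last identity ", round(cand$meta$identity, 1), ")")
    out[[k]] <- fam
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, sprintf("inst%02d", k))
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      writeLines(paste0(">", names(fam$seqs), "\n", unclass(fam$seqs)),
                 file.path(d, "seqs.fasta"))
      write_alignment(fam$ref, file.path(d, "ref.fasta"))
      yaml::write_yaml(fam$meta, file.path(d, "meta.yaml"))
    }
  }
  invisible(out)
}
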