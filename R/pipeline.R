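# Strategy registry and orchestration with shared-computation reuse.
#
# A *variation* fixes Stage 1 (similarity scorer) and Stage 2 (tree
# builder): "<scoring>.<tree>", e.g. "F.NJ".  A *strategy* adds the
# heuristic class: "+P" progressive only, "+C" consistency, "+I"
# iterative, "+CI" both, e.g. "F.NJ+CI".  Stage 1/2 artifacts (and the
# posterior constraint library) are cached in a workspace so strategies
# sharing a variation never recompute them.

SCORING_METHODS <- c("F", "K", "L", "P", "Q")
TREE_METHODS <- c("NJ", "SLMAX", "SLMIN", "UPGMA")

#' Enumerate the framework's strategies
#'
#' 5 scorers x 4 tree builders = 20 variations; x 4 heuristic classes =
#' 80 strategies, in lexicographic (scoring, tree, class) order.
#'
#' @return data.frame with columns scoring, tree, class, variation,
#'   strategy.
#' @export
enumerate_strategies <- function() {
  g <- expand.grid(class = sort(CLASSES), tree = sort(TREE_METHODS),
                   scoring = sort(SCORING_METHODS),
                   stringsAsFactors = FALSE)[, 3:1]
  g <- g[order(g$scoring, g$tree, g$class), ]
  g$variation <- paste0(g$scoring, ".", g$tree)
  g$strategy <- paste0(g$variation, "+", g$class)
  rownames(g) <- NULL
  g
}

parse_strategy <- function(strategy) {
  m <- regmatches(strategy,
                  regexec("^([FKLPQ])\\.(NJ|SLMAX|SLMIN|UPGMA)\\+(P|C|I|CI)$",
                          strategy))[[1]]
  if (length(m) != 4) stop("not a valid strategy id: ", strategy)
  list(scoring = m[2], tree = m[3], class = m[4])
}

#' Framework configuration
#'
#' @param matrix `"adaptive"` (BLOSUM ladder by merge similarity, the
#'   default) or a fixed `subst_matrix`.
#' @param gm profile-alignment [gap_model()].
#' @param gap_open,gap_extend Stage-1 FULL alignment penalties.
#' @param quick_k,kmers_k tuple lengths for the Q and K scorers.
#' @param hmm_params pair-HMM parameters (P scorer and constraint library).
#' @param library_mode `"posterior"` or `"alignment"` primary library.
#' @param lambda constraint-library bonus scale (0 disables consistency).
#' @param refine a [refine_config()].
#' @return an `msa_config` list.
#' @export
msa_config <- function(matrix = "adaptive", gm = gap_model(),
                       gap_open = 10, gap_extend = 0.5,
                       quick_k = 1, kmers_k = 3,
                       hmm_params = NULL, library_mode = "posterior",
                       lambda = 1, refine = refine_config()) {
  structure(list(matrix = matrix, gm = gm, gap_open = gap_open,
                 gap_extend = gap_extend, quick_k = quick_k,
                 kmers_k = kmers_k, hmm_params = hmm_params,
                 library_mode = library_mode, lambda = lambda,
                 refine = refine),
            class = "msa_config")
}

#' Workspace with cached shared computations
#'
#' @param seqs an `aa_seqs` set.
#' @param config an [msa_config()].
#' @return an `msa_workspace` environment caching similarity matrices,
#'   guide trees and the extended constraint library across strategies.
#' @export
msa_workspace <- function(seqs, config = msa_config()) {
  ws <- new.env(parent = emptyenv())
  ws$seqs <- seqs
  ws$config <- config
  ws$sim <- list()
  ws$tree <- list()
  ws$lib <- NULL
  ws$computed <- character(0)   # log of cache fills, for the reuse contract
  class(ws) <- "msa_workspace"
  ws
}

ws_hmm_params <- function(ws) {
  if (is.null(ws$config$hmm_params)) ws$config$hmm_params <- pair_hmm_params()
  ws$config$hmm_params
}

ws_fixed_matrix <- function(ws) {
  if (is.character(ws$config$matrix)) blosum() else ws$config$matrix
}

ws_sim <- function(ws, scoring) {
  if (is.null(ws$sim[[scoring]])) {
    cfg <- ws$config
    ws$sim[[scoring]] <- build_similarity_matrix(
      ws$seqs, scoring, matrix = ws_fixed_matrix(ws),
      gap_open = cfg$gap_open, gap_extend = cfg$gap_extend,
      k = if (scoring == "Q") cfg$quick_k else cfg$kmers_k,
      hmm_params = if (scoring == "P") ws_hmm_params(ws) else NULL)
    ws$computed <- c(ws$computed, paste0("sim:", scoring))
  }
  ws$sim[[scoring]]
}

ws_tree <- function(ws, scoring, tree_method) {
  key <- paste0(scoring, ".", tree_method)
  if (is.null(ws$tree[[key]])) {
    ws$tree[[key]] <- build_guide_tree(ws_sim(ws, scoring), tree_method)
    ws$computed <- c(ws$computed, paste0("tree:", key))
  }
  ws$tree[[key]]
}

ws_lib <- function(ws) {
  if (is.null(ws$lib)) {
    cfg <- ws$config
    prim <- build_primary_library(ws$seqs, mode = cfg$library_mode,
                                  hmm_params = ws_hmm_params(ws),
                                  matrix = ws_fixed_matrix(ws),
                                  gap_open = cfg$gap_open,
                                  gap_extend = cfg$gap_extend)
    ws$lib <- consistency_transform(prim)
    ws$computed <- c(ws$computed, "lib")
  }
  ws$lib
}

#' Run one MSA strategy
#'
#' @param ws an [msa_workspace()] (or an `aa_seqs` set, in which case a
#'   fresh workspace with the given `config` is used).
#' @param strategy strategy id like `"F.NJ+CI"`.
#' @param config configuration, only used when `ws` is a sequence set.
#' @return the `msa_aln`, with a `provenance` attribute recording the
#'   strategy, stages run and parameters.
#' @export
run_strategy <- function(ws, strategy, config = msa_config()) {
  if (inherits(ws, "aa_seqs")) ws <- msa_workspace(ws, config)
  if (!inherits(ws, "msa_workspace")) stop("need an msa_workspace or aa_seqs")
  st <- parse_strategy(strategy)
  cfg <- ws$config
  sim <- ws_sim(ws, st$scoring)
  tree <- ws_tree(ws, st$scoring, st$tree)
  use_lib <- st$class %in% c("C", "CI") && cfg$lambda != 0
  lib <- if (use_lib) ws_lib(ws) else NULL
  aln <- tryCatch(
    progressive_align(ws$seqs, tree, matrix = cfg$matrix, gm = cfg$gm,
                      lib = lib, lambda = cfg$lambda, sim = sim),
    error = function(e) stop("strategy ", strategy, ": ",
                             conditionMessage(e)))
  stages <- c("similarity", "guidetree",
              if (use_lib) "consistency", "profile_align")
  if (st$class %in% c("I", "CI")) {
    aln <- refine(aln, tree, matrix = cfg$matrix, gm = cfg$gm, lib = lib,
                  lambda = cfg$lambda, cfg = cfg$refine, sim = sim)
    stages <- c(stages, "refine")
  }
  attr(aln, "provenance") <- list(
    strategy = strategy, scoring = st$scoring, tree = st$tree,
    class = st$class, stages = stages,
    matrix = if (is.character(cfg$matrix)) cfg$matrix
             else attr(cfg$matrix, "name"),
    gap_open = cfg$gm$gap_open, gap_extend = cfg$gm$gap_extend,
    lambda = if (use_lib) cfg$lambda else 0,
    max_iterations = cfg$refine$max_iterations,
    package_version = as.character(utils::packageVersion("msaframe")))
  aln
}

#' Score a set of strategies over a benchmark directory
#'
#' Each instance is a subdirectory containing `seqs.fasta` (unaligned) and
#' `ref.fasta` (reference alignment), as written by
#' [generate_band_suite()].  Unreadable instances are skipped with a
#' warning; failures never abort the run.
#'
#' @param dir benchmark directory.
#' @param strategies character vector of strategy ids (default: all 80).
#' @param config an [msa_config()].
#' @param benchmark,band tags recorded in the store.
#' @return score store data.frame (benchmark, band, instance, variation,
#'   class, strategy, ds, identity, wsp).
#' @export
run_benchmark <- function(dir, strategies = enumerate_strategies()$strategy,
                          config = msa_config(), benchmark = "synthetic",
                          band = NA_character_) {
  inst_dirs <- list.dirs(dir, recursive = FALSE)
  if (length(inst_dirs) == 0) stop("no instance directories under ", dir)
  rows <- list()
  for (d in inst_dirs) {
    ins <- basename(d)
    ok <- tryCatch({
      seqs <- read_fasta(file.path(d, "seqs.fasta"))
      ref <- read_alignment(file.path(d, "ref.fasta"))
      TRUE
    }, error = function(e) {
      warning("skipping instance ", ins, ": ", conditionMessage(e))
      FALSE
    })
    if (!ok) next
    ws <- msa_workspace(seqs, config)
    ref_band <- if (is.na(band)) identity_group(identity_score(ref)) else band
    for (s in strategies) {
      aln <- run_strategy(ws, s)
      st <- parse_strategy(s)
      rows[[paste(ins, s)]] <- data.frame(
        benchmark = benchmark, band = ref_band, instance = ins,
        variation = paste0(st$scoring, ".", st$tree), class = st$class,
        strategy = s,
        ds = developer_score(aln, ref),
        identity = identity_score(aln),
        wsp = wsp(aln, ws_fixed_matrix(ws)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
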