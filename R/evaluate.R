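# Alignment-quality metrics: Developer Score, identity, identity bands.

#' Developer Score against a reference alignment
#'
#' Collects every aligned residue pair from reference columns whose gap
#' fraction is below `gap_frac`, and counts how many of those pairs (same
#' two residues, identified by sequence id and residue ordinal) also share
#' a column in the test alignment; the score is matches over total
#' reference pairs.
#'
#' @param test,ref `msa_aln` objects over the same sequences (identical
#'   after de-gapping).
#' @param gap_frac per-column gap-fraction threshold; columns with a gap
#'   fraction `>= gap_frac` are excluded from the reference (default 0.2).
#' @return a value in `[0, 1]`.
#' @export
developer_score <- function(test, ref, gap_frac = 0.2) {
  if (!setequal(names(test), names(ref)))
    stop("test and reference cover different sequences")
  mt <- aln_matrix(test)[names(ref), , drop = FALSE]
  mr <- aln_matrix(ref)
  if (!identical(gsub("-", "", apply(mt, 1, paste, collapse = "")),
                 gsub("-", "", apply(mr, 1, paste, collapse = ""))))
    stop("test and reference de-gap to different sequences")
  n <- nrow(mr)
  ord_r <- residue_ordinals(mr)
  ord_t <- residue_ordinals(mt)
  # test column of each residue ordinal, per sequence
  col_of <- lapply(seq_len(n), function(i) {
    nz <- !is.na(ord_t[i, ])
    setNames(which(nz), ord_t[i, nz])[as.character(seq_len(sum(nz)))]
  })
  qualifying <- colMeans(mr == "-") < gap_frac
  total <- 0L
  matches <- 0L
  for (col in which(qualifying)) {
    present <- which(!is.na(ord_r[, col]))
    if (length(present) < 2) next
    tcols <- vapply(present, function(i) col_of[[i]][[ord_r[i, col]]], 0L)
    pairs <- utils::combn(length(present), 2)
    total <- total + ncol(pairs)
    matches <- matches + sum(tcols[pairs[1, ]] == tcols[pairs[2, ]])
  }
  if (total == 0) stop("no qualifying residue pairs in the reference")
  matches / total
}

#' Mean pairwise identity of an alignment
#'
#' For each sequence pair, matched equal residues over the columns that
#' are not gap-gap for that pair, averaged over all pairs and scaled to
#' percent.
#'
#' @param aln an `msa_aln`, n >= 2.
#' @return percent in `[0, 100]`.
#' @export
identity_score <- function(aln) {
  m <- aln_matrix(aln)
  n <- nrow(m)
  L <- ncol(m)
  pairs <- utils::combn(n, 2)
  vals <- vapply(seq_len(ncol(pairs)), function(p) {
    a <- m[pairs[1, p], ]
    b <- m[pairs[2, p], ]
    gap_only <- a == "-" & b == "-"
    denom <- L - sum(gap_only)
    if (denom == 0)
      stop("pair (", rownames(m)[pairs[1, p]], ", ",
           rownames(m)[pairs[2, p]], ") has only gap-gap columns")
    sum(a == b & a != "-") / denom
  }, 0)
  100 * mean(vals)
}

#' Identity band of an alignment
#'
#' The three benchmark bands, half-open at the printed boundaries:
#' band1 `[0, 20)`, band2 `[20, 40)`, band3 `[40, 80)`; values at or above
#' 80 fall outside the benchmark grouping and are tagged `"high"`.
#'
#' @param id_value identity percent in `[0, 100]`.
#' @return one of `"band1"`, `"band2"`, `"band3"`, `"high"`.
#' @export
identity_group <- function(id_value) {
  stopifnot(id_value >= 0, id_value <= 100)
  if (id_value < 20) "band1"
  else if (id_value < 40) "band2"
  else if (id_value < 80) "band3"
  else "high"
}
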