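# NCBI-format substitution matrix reader and bundled BLOSUM series.

#' Read a substitution matrix in NCBI text format
#'
#' The format used by BLAST's matrix files: '#' comment lines, then a header
#' row of single-letter residue codes, then one labelled row per residue.
#'
#' @param path matrix file.
#' @param name matrix name tag; defaults to the file name.
#' @return a `subst_matrix`: symmetric numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(path, name = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  body <- strsplit(trimws(lines[-1]), "\\s+")
  labels <- vapply(body, `[`, "", 1)
  vals <- t(vapply(body, function(x) as.numeric(x[-1]), numeric(length(header))))
  dimnames(vals) <- list(labels, header)
  vals <- vals[header, header, drop = FALSE]   # canonical order
  if (max(abs(vals - t(vals))) > 0) stop("matrix is not symmetric: ", path)
  structure(vals, name = if (is.null(name)) basename(path) else name,
            class = c("subst_matrix", class(vals)))
}

#' Load a bundled BLOSUM matrix
#'
#' @param name one of `"BLOSUM45"`, `"BLOSUM62"`, `"BLOSUM80"`.
#' @return a `subst_matrix`.
#' @export
blosum <- function(name = "BLOSUM62") {
  name <- toupper(name)
  if (is.null(.msaframe_cache$mats[[name]])) {
    path <- system.file("extdata", "matrices", paste0(name, ".txt"),
                        package = "msaframe")
    if (!nzchar(path)) stop("no bundled matrix called ", name)
    .msaframe_cache$mats[[name]] <- read_score_matrix(path, name = name)
  }
  .msaframe_cache$mats[[name]]
}

# per-session cache for bundled data (matrices, stationary frequencies)
.msaframe_cache <- new.env(parent = emptyenv())

# residue-pair scores for two character vectors, via dimname lookup
subst_lookup <- function(mat, a, b) {
  mat[cbind(match(a, rownames(mat)), match(b, colnames(mat)))]
}
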