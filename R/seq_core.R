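# Sequence / alignment data model and file I/O.
#
# Sequences are stored as a named character vector of uppercase residue
# strings (class "aa_seqs"); alignments as a named character vector of
# equal-length rows with '-' as the only gap symbol (class "msa_aln").
# Readers normalize the '.' and '~' gap dialects to '-'.

AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V","X")

#' Construct a protein sequence set
#'
#' @param residues character vector of residue strings (uppercased on input).
#' @param ids unique sequence identifiers; defaults to `names(residues)`.
#' @param descriptions optional free-text descriptions.
#' @param on_illegal what to do with residues outside the 20 amino acids +
#'   'X': `"map"` replaces them with 'X' (with a warning), `"error"` rejects.
#' @return an `aa_seqs` object: named character vector with a
#'   `descriptions` attribute.
#' @export
aa_seqs <- function(residues, ids = names(residues), descriptions = NULL,
                    on_illegal = c("map", "error")) {
  on_illegal <- match.arg(on_illegal)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  residues <- toupper(as.character(residues))
  if (any(!nzchar(residues))) stop("empty sequence for id ",
                                   paste(ids[!nzchar(residues)], collapse = ", "))
  if (any(grepl("-", residues, fixed = TRUE)))
    stop("unaligned sequences must be gap-free (found '-')")
  bad <- grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), residues)
  if (any(bad)) {
    if (on_illegal == "error")
      stop("illegal residues in: ", paste(ids[bad], collapse = ", "))
    warning("non-standard residues mapped to 'X' in: ",
            paste(ids[bad], collapse = ", "))
    residues[bad] <- gsub(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                          "X", residues[bad])
  }
  names(residues) <- ids
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(ids)), ids)
  structure(residues, descriptions = descriptions, class = "aa_seqs")
}

#' @export
print.aa_seqs <- function(x, ...) {
  cat(sprintf("aa_seqs: %d sequences (lengths %d-%d)\n", length(x),
              min(nchar(x)), max(nchar(x))))
  invisible(x)
}

#' Construct a multiple sequence alignment
#'
#' @param rows named character vector of aligned rows ('-' gaps), all the
#'   same length.
#' @return an `msa_aln` object.
#' @export
msa_aln <- function(rows) {
  if (length(rows) < 2) stop("an alignment needs at least 2 rows")
  if (is.null(names(rows)) || anyDuplicated(names(rows)))
    stop("alignment rows need unique names")
  rows <- setNames(toupper(as.character(rows)), names(rows))
  len <- nchar(rows)
  if (length(unique(len)) != 1)
    stop("ragged alignment rows: ",
         paste(names(rows)[len != len[1]], collapse = ", "))
  if (len[1] < 1) stop("alignment length must be >= 1")
  structure(rows, class = "msa_aln")
}

#' @export
print.msa_aln <- function(x, ...) {
  cat(sprintf("msa_aln: %d sequences x %d columns\n", length(x), nchar(x[[1]])))
  invisible(x)
}

#' Alignment as a character matrix (rows = sequences, columns = positions)
#' @param aln an `msa_aln`.
#' @return character matrix with sequence ids as rownames.
#' @export
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), ""))
  rownames(m) <- names(aln)
  m
}

# inverse of aln_matrix
matrix_aln <- function(m) {
  msa_aln(setNames(apply(m, 1, paste, collapse = ""), rownames(m)))
}

#' Strip gaps from alignment rows
#' @param aln an `msa_aln`.
#' @return `aa_seqs` with the unaligned sequences, row order preserved.
#' @export
degap <- function(aln) {
  aa_seqs(gsub("-", "", unclass(aln), fixed = TRUE), ids = names(aln))
}

#' Number of columns of an alignment
#' @param aln an `msa_aln`.
#' @export
aln_length <- function(aln) nchar(unclass(aln)[[1]])

#' Read unaligned protein sequences from FASTA
#'
#' @param path FASTA file.
#' @param on_illegal see [aa_seqs()].
#' @return an `aa_seqs` object, record order preserved.
#' @export
read_fasta <- function(path, on_illegal = c("map", "error")) {
  recs <- parse_fasta(path)
  if (any(grepl("[-.~]", recs$seq)))
    stop("unaligned FASTA must be gap-free: ",
         paste(recs$id[grepl("[-.~]", recs$seq)], collapse = ", "))
  aa_seqs(recs$seq, ids = recs$id, descriptions = recs$desc,
          on_illegal = match.arg(on_illegal))
}

# Clustal .aln blocks: "<id>  <chunk>" lines, blank/consensus lines ignored
parse_clustal <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !grepl("^CLUSTAL", lines[1], ignore.case = TRUE))
    stop("not a Clustal alignment: ", path)
  body <- lines[-1]
  body <- body[grepl("^\\S+\\s+\\S", body)]   # drops blank and consensus lines
  ids <- sub("^(\\S+)\\s+.*$", "\\1", body)
  chunks <- sub("^\\S+\\s+(\\S+).*$", "\\1", body)
  rows <- vapply(unique(ids), function(id)
    paste(chunks[ids == id], collapse = ""), "")
  if (length(rows) == 0) stop("no sequences in ", path)
  rows
}

# minimal FASTA record splitter shared by the readers
parse_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no records in ", path)
  if (hdr[1] != 1) stop("malformed FASTA: sequence before first header at line 1")
  starts <- hdr + 1
  ends <- c(hdr[-1] - 1, length(lines))
  if (any(starts > ends)) {
    at <- hdr[which(starts > ends)[1]]
    stop("empty record at line ", at, " of ", path)
  }
  ids <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  desc <- sub("^>\\s*\\S+\\s*", "", lines[hdr])
  seqs <- vapply(seq_along(hdr), function(i)
    gsub("\\s", "", paste(lines[starts[i]:ends[i]], collapse = "")), "")
  if (anyDuplicated(ids))
    stop("duplicate ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  list(id = ids, desc = setNames(desc, ids), seq = seqs)
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA, Clustal (`.aln`) and MSF dialects; the `.` and
#' `~` gap symbols are normalized to `-`.
#'
#' @param path alignment file.
#' @param dialect `"fasta"`, `"clustal"` or `"msf"`.
#' @return an `msa_aln` object.
#' @export
read_alignment <- function(path, dialect = c("fasta", "clustal", "msf")) {
  dialect <- match.arg(dialect)
  if (dialect == "fasta") {
    recs <- parse_fasta(path)
    rows <- setNames(recs$seq, recs$id)
  } else if (dialect == "clustal") {
    rows <- parse_clustal(path)
  } else {
    a <- seqinr::read.alignment(path, format = dialect)
    rows <- setNames(toupper(unlist(a$seq)), a$nam)
  }
  rows <- chartr(".~", "--", rows)
  len <- nchar(rows)
  if (length(unique(len)) != 1)
    stop("ragged alignment rows in ", path, ": ",
         paste(names(rows)[len != max(len)], collapse = ", "))
  msa_aln(rows)
}

#' Write an alignment to file
#'
#' @param aln an `msa_aln`.
#' @param path output file.
#' @param dialect `"fasta"` or `"clustal"` (60-column wrapped).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, dialect = c("fasta", "clustal")) {
  dialect <- match.arg(dialect)
  rows <- unclass(aln)
  if (dialect == "fasta") {
    out <- unlist(lapply(names(rows), function(id) {
      s <- rows[[id]]
      c(paste0(">", id),
        substring(s, seq(1, nchar(s), 60), pmin(seq(1, nchar(s), 60) + 59, nchar(s))))
    }))
  } else {
    width <- max(nchar(names(rows))) + 3
    L <- nchar(rows[[1]])
    out <- c("CLUSTAL W multiple sequence alignment", "")
    for (start in seq(1, L, 60)) {
      stop_ <- min(start + 59, L)
      out <- c(out,
               vapply(names(rows), function(id)
                 sprintf("%-*s%s", width, id, substr(rows[[id]], start, stop_)), ""),
               "")
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Drop columns that contain only gaps
#'
#' @param aln an `msa_aln`.
#' @return `msa_aln` without all-gap columns; error if nothing remains.
#' @export
remove_allgap_columns <- function(aln) {
  m <- aln_matrix(aln)
  keep <- colSums(m != "-") > 0
  if (!any(keep)) stop("alignment consists only of gaps")
  matrix_aln(m[, keep, drop = FALSE])
}
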