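#' Construct an alignment object
#'
#' An alignment is an ordered set of gapped sequence records of identical
#' length. Sequences are normalized on construction: letters are uppercased
#' and the alternative gap character `.` becomes `-`. Record order is
#' preserved exactly.
#'
#' @param headers character vector of FASTA description lines (without the
#'   leading `>`), kept verbatim.
#' @param letters character vector of gapped sequences, same length as
#'   `headers`.
#' @return An object of class `alignment`: a list with elements `headers`,
#'   `letters`, `labels` (display names, see Details), `alphabet`
#'   (per-record `"protein"`, `"nucleotide"` or `"unknown"`) and
#'   `n_columns`.
#'
#' @details
#' The display label of a record is the text after the first whitespace of
#' its header (typically the species or protein name); if the header has no
#' whitespace, the database accession recognised by [parse_identity()] is
#' used, and failing that the full header.
#'
#' Alphabet detection is per record: if more than 90% of the non-gap
#' letters are in `A,C,G,T,U,N` the record is classified as nucleotide,
#' otherwise protein; a record with no residues at all is `"unknown"`.
#'
#' @seealso [read_fasta()], [write_fasta()], [consensus()]
#' @export
new_alignment <- function(headers, letters) {
  if (length(headers) != length(letters))
    av_argument_error("headers and letters must have equal length")
  if (length(letters) < 1L)
    av_parse_error("no records: an alignment needs at least one sequence")
  letters <- toupper(letters)
  letters <- gsub(".", "-", letters, fixed = TRUE)
  bad <- grepl("[^A-Z-]", letters)
  if (any(bad))
    av_parse_error(sprintf(
      "record '%s' contains characters outside A-Z and the gap characters '-'/'.'",
      headers[which(bad)[1L]]))
  widths <- nchar(letters)
  if (any(widths < 1L))
    av_parse_error(sprintf("record '%s' has an empty sequence",
                           headers[which(widths < 1L)[1L]]))
  if (length(unique(widths)) > 1L) {
    off <- which(widths != widths[1L])[1L]
    av_parse_error(sprintf(
      "ragged alignment: record '%s' has %d columns where the first record has %d",
      headers[off], widths[off], widths[1L]))
  }
  structure(list(
    headers   = headers,
    letters   = letters,
    labels    = vapply(headers, extract_label, character(1), USE.NAMES = FALSE),
    alphabet  = vapply(letters, detect_alphabet, character(1), USE.NAMES = FALSE),
    n_columns = widths[1L]
  ), class = "alignment")
}

extract_label <- function(header) {
  if (grepl("\\s", header)) {
    lab <- sub("^\\S+\\s+", "", header)
    if (nzchar(lab)) return(lab)
  }
  id <- parse_identity(header)
  if (nzchar(id$accession)) return(id$accession)
  header
}

detect_alphabet <- function(letters) {
  chars <- strsplit(letters, "", fixed = TRUE)[[1L]]
  chars <- chars[chars != "-"]
  if (length(chars) == 0L) return("unknown")
  nuc <- mean(chars %in% c("A", "C", "G", "T", "U", "N"))
  if (nuc > 0.9) "nucleotide" else "protein"
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d sequence(s) x %d column(s)\n",
              length(x$letters), x$n_columns))
  for (i in seq_along(x$letters)) {
    s <- x$letters[i]
    if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
    cat(sprintf("  [%d] %-20s %s\n", i, substr(x$labels[i], 1, 20), s))
  }
  invisible(x)
}

#' @export
length.alignment <- function(x) length(x$letters)

#' Read a pairwise or multiple sequence alignment from FASTA
#'
#' Parses FASTA text into an [new_alignment()] object. Wrapped sequence
#' lines are concatenated, whitespace inside sequence lines is ignored,
#' letters are uppercased and `.` gaps become `-`. All records must have
#' the same gapped length.
#'
#' @param source a path to a FASTA file, or FASTA text itself (anything
#'   containing a newline or starting with `>` is treated as text).
#' @return An `alignment` object; record order follows the input.
#' @examples
#' aln <- read_fasta(">sp|P12345|X Homo sapiens\nAC-GT\n>NP_000001.1 Mus\nACAGT\n")
#' aln$n_columns  # 5
#' @export
read_fasta <- function(source) {
  lines <- fasta_source_lines(source)
  n <- length(lines)
  headers <- character(0)
  chunks <- list()
  cur <- NULL
  for (i in seq_len(n)) {
    line <- lines[i]
    if (grepl("^\\s*$", line)) next
    if (startsWith(line, ">")) {
      headers <- c(headers, sub("^>\\s*", "", line))
      cur <- length(headers)
      chunks[[cur]] <- character(0)
    } else if (is.null(cur)) {
      av_parse_error(sprintf(
        "not FASTA: line %d contains sequence data before any '>' header", i))
    } else {
      chunks[[cur]] <- c(chunks[[cur]], gsub("\\s", "", line))
    }
  }
  if (length(headers) == 0L)
    av_parse_error("no records: input contains no '>' headers")
  letters <- vapply(chunks, paste0, character(1), collapse = "")
  new_alignment(headers, letters)
}

fasta_source_lines <- function(source) {
  if (length(source) != 1L || !is.character(source))
    av_argument_error("source must be a single path or FASTA string")
  if (grepl("\n", source, fixed = TRUE) || startsWith(source, ">")) {
    if (!nzchar(source)) av_parse_error("no records: empty input")
    strsplit(source, "\n", fixed = TRUE)[[1L]]
  } else {
    if (!file.exists(source))
      av_argument_error(sprintf("file not found: %s", source))
    readLines(source, warn = FALSE)
  }
}

#' Write an alignment as FASTA text
#'
#' Headers are emitted verbatim; sequences are wrapped at `width` columns.
#' Reading the result back with [read_fasta()] reproduces headers and
#' letters exactly.
#'
#' @param aln an `alignment`.
#' @param path optional output file; when `NULL` the FASTA text is
#'   returned.
#' @param width line width for sequence wrapping (positive integer).
#' @return The FASTA text, invisibly when written to `path`.
#' @export
write_fasta <- function(aln, path = NULL, width = 60L) {
  stopifnot(inherits(aln, "alignment"))
  if (!is.numeric(width) || length(width) != 1L || width < 1L)
    av_argument_error("width must be a positive integer")
  width <- as.integer(width)
  out <- character(0)
  for (i in seq_along(aln$letters)) {
    s <- aln$letters[i]
    starts <- seq.int(1L, nchar(s), by = width)
    out <- c(out, paste0(">", aln$headers[i]),
             substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(text))
  }
  text
}

#' Parse a sequence identifier into a database cross-reference
#'
#' Applies identifier dialect rules in order and stops at the first match:
#' UniProt (`sp|ACC|NAME` / `tr|ACC|NAME`), NCBI RefSeq (accessions with
#' `NP_`, `XP_`, `NM_`, `XM_` or `YP_` prefixes, optional version suffix)
#' and Ensembl (`ENS...P/G/T` + 11 digits). Unmatched headers yield
#' `database = "unknown"` with empty accession and URL; the function never
#' errors.
#'
#' @param header a FASTA description line without the leading `>`.
#' @return A list with `database` (one of `"uniprot"`, `"ncbi"`,
#'   `"ensembl"`, `"unknown"`), `accession` and `url` (the database page
#'   for the accession, or `""`).
#' @examples
#' parse_identity("NP_001026.2 Homo sapiens RYR2")$database  # "ncbi"
#' parse_identity("sp|Q9Y3I1|FBX25_HUMAN")$accession         # "Q9Y3I1"
#' @export
parse_identity <- function(header) {
  if (length(header) != 1L || !is.character(header) || is.na(header))
    return(sequence_identity("unknown", "", ""))
  m <- regmatches(header, regexec("^(?:sp|tr)\\|([A-Za-z0-9-]+)\\|", header))[[1L]]
  if (length(m) == 2L)
    return(sequence_identity("uniprot", m[2L],
      sprintf("https://www.uniprot.org/uniprotkb/%s", m[2L])))
  m <- regmatches(header, regexec("^((?:NP|XP|NM|XM|YP)_[0-9]+(?:\\.[0-9]+)?)", header))[[1L]]
  if (length(m) == 2L)
    return(sequence_identity("ncbi", m[2L],
      sprintf("https://www.ncbi.nlm.nih.gov/protein/%s", m[2L])))
  m <- regmatches(header, regexec("(ENS[A-Z]*[PGT][0-9]{11})", header))[[1L]]
  if (length(m) == 2L)
    return(sequence_identity("ensembl", m[2L],
      sprintf("https://www.ensembl.org/id/%s", m[2L])))
  sequence_identity("unknown", "", "")
}

sequence_identity <- function(database, accession, url) {
  structure(list(database = database, accession = accession, url = url),
            class = "sequence_identity")
}

#' Compute the consensus row of an alignment
#'
#' For every column the non-gap residues are tallied; the consensus letter
#' is the residue attaining the maximum count, with ties broken
#' alphabetically. A column that is entirely gaps yields `-` — gaps never
#' win a consensus otherwise.
#'
#' @param aln an `alignment`.
#' @return An object of class `consensus_row`: list with `letters` (a
#'   string of length `n_columns`) and `counts` (a residue-by-column
#'   integer matrix of gap-exclusive tallies).
#' @examples
#' aln <- read_fasta(">a\nACGT\n>b\nACGT\n>c\nACGT\n")
#' consensus(aln)$letters  # "ACGT"
#' @export
consensus <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  mat <- do.call(rbind, strsplit(aln$letters, "", fixed = TRUE))
  residues <- sort(setdiff(unique(as.vector(mat)), "-"))
  counts <- matrix(0L, nrow = length(residues), ncol = aln$n_columns,
                   dimnames = list(residues, NULL))
  for (r in residues) counts[r, ] <- colSums(mat == r)
  letters <- vapply(seq_len(aln$n_columns), function(j) {
    col <- counts[, j]
    if (length(col) == 0L || max(col) == 0L) return("-")
    # which.max takes the first maximum; rows are already alphabetical
    residues[which.max(col)]
  }, character(1))
  structure(list(letters = paste(letters, collapse = ""), counts = counts),
            class = "consensus_row")
}

#' @export
print.consensus_row <- function(x, ...) {
  cat("<consensus>", x$letters, "\n")
  invisible(x)
}
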