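#' Build the position map of one aligned sequence
#'
#' A position map is the bidirectional mapping between 1-based ungapped
#' residue positions and 1-based alignment columns for a single record.
#' Gap columns carry the sentinel `NA` on the column-to-position side, so
#' arithmetic on a gap position fails loudly instead of silently.
#'
#' @param aln an `alignment`.
#' @param seq_index 1-based record index.
#' @return An object of class `position_map`: list with `seq_index`,
#'   `col_of_pos` (strictly increasing integer vector, one entry per
#'   residue), `pos_of_col` (integer vector over all columns, `NA` at
#'   gaps) and `ungapped_length`.
#' @examples
#' aln <- read_fasta(">a\nAC-GT\n")
#' position_map(aln, 1)$col_of_pos  # 1 2 4 5
#' @export
position_map <- function(aln, seq_index) {
  stopifnot(inherits(aln, "alignment"))
  if (!is.numeric(seq_index) || length(seq_index) != 1L ||
      seq_index < 1L || seq_index > length(aln$letters))
    av_lookup_error(sprintf("sequence index %s out of range 1..%d",
                            toString(seq_index), length(aln$letters)))
  seq_index <- as.integer(seq_index)
  chars <- strsplit(aln$letters[seq_index], "", fixed = TRUE)[[1L]]
  col_of_pos <- which(chars != "-")
  pos_of_col <- rep(NA_integer_, length(chars))
  pos_of_col[col_of_pos] <- seq_along(col_of_pos)
  structure(list(
    seq_index       = seq_index,
    col_of_pos      = as.integer(col_of_pos),
    pos_of_col      = pos_of_col,
    ungapped_length = length(col_of_pos)
  ), class = "position_map")
}

#' Map an ungapped residue position to its alignment column
#'
#' @param map a [position_map()].
#' @param pos 1-based ungapped position.
#' @return The 1-based alignment column of the `pos`-th residue.
#' @export
ungapped_to_column <- function(map, pos) {
  stopifnot(inherits(map, "position_map"))
  if (!is.numeric(pos) || length(pos) != 1L || is.na(pos) ||
      pos < 1L || pos > map$ungapped_length)
    av_lookup_error(sprintf(
      "position %s beyond sequence: ungapped length is %d",
      toString(pos), map$ungapped_length))
  map$col_of_pos[as.integer(pos)]
}

#' Map an alignment column to an ungapped residue position
#'
#' @param map a [position_map()].
#' @param col 1-based alignment column.
#' @return The 1-based residue position at that column, or `NA` when the
#'   sequence has a gap there.
#' @export
column_to_ungapped <- function(map, col) {
  stopifnot(inherits(map, "position_map"))
  if (!is.numeric(col) || length(col) != 1L || is.na(col) ||
      col < 1L || col > length(map$pos_of_col))
    av_lookup_error(sprintf("column %s out of range 1..%d",
                            toString(col), length(map$pos_of_col)))
  map$pos_of_col[as.integer(col)]
}

#' Resolve a sequence selector against an alignment
#'
#' Matching order: integer index; exact label; exact header; unique
#' case-insensitive label prefix. Ambiguity and misses raise lookup errors
#' listing the candidate labels.
#'
#' @param aln an `alignment`.
#' @param selector 1-based integer index or (partial) label text.
#' @return The 1-based record index.
#' @export
resolve_sequence <- function(aln, selector) {
  stopifnot(inherits(aln, "alignment"))
  if (is.numeric(selector)) {
    if (length(selector) != 1L || is.na(selector) ||
        selector < 1L || selector > length(aln$letters))
      av_lookup_error(sprintf("sequence index %s out of range 1..%d",
                              toString(selector), length(aln$letters)))
    return(as.integer(selector))
  }
  if (!is.character(selector) || length(selector) != 1L || is.na(selector))
    av_lookup_error("sequence selector must be an index or a label")
  hit <- which(aln$labels == selector)
  if (length(hit) == 0L) hit <- which(aln$headers == selector)
  if (length(hit) == 0L)
    hit <- which(startsWith(tolower(aln$labels), tolower(selector)))
  if (length(hit) == 1L) return(hit)
  if (length(hit) == 0L)
    av_lookup_error(sprintf("no sequence matches '%s'; labels are: %s",
                            selector, paste(aln$labels, collapse = ", ")))
  av_lookup_error(sprintf("selector '%s' is ambiguous; candidates: %s",
                          selector, paste(aln$labels[hit], collapse = ", ")))
}

#' Find the alignment column of a residue position in a named sequence
#'
#' The position-search primitive: given a sequence (by index or label) and
#' a 1-based ungapped position, returns where that residue sits in the
#' alignment so a renderer or the command line can jump there.
#'
#' @param aln an `alignment`.
#' @param selector sequence index or (partial) label, see
#'   [resolve_sequence()].
#' @param pos 1-based ungapped position within the selected sequence.
#' @return A list with `seq_index`, `position` and `column`.
#' @examples
#' aln <- read_fasta(">first\nAC-GTA\n>second\nACAGTA\n")
#' find_position(aln, 1, 4)$column  # 5
#' @export
find_position <- function(aln, selector, pos) {
  i <- resolve_sequence(aln, selector)
  map <- position_map(aln, i)
  col <- ungapped_to_column(map, pos)
  list(seq_index = i, position = as.integer(pos), column = col)
}
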