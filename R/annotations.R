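#' Load and bind a JSON annotation document to an alignment
#'
#' The annotation document is a JSON object with up to three optional
#' top-level keys, each holding a list of objects:
#'
#' * `variants`: `sequence` (1-based index or label), `position` (1-based
#'   ungapped), optional `token` (HGVS-like, e.g. `"p.C4957Y"`), `source`,
#'   `note` (free text or an HTML fragment for the pop-up), `id` (variant
#'   identifier such as an rs number), `url`, plus any further keys, which
#'   are preserved verbatim in `attributes` (allele frequency, clinical
#'   significance, phenotype, ...).
#' * `modifications`: `sequence`, `position`, `type` (e.g.
#'   `"ubiquitination"`), optional `note`, `url`.
#' * `regions`: `sequence` (or omitted/`"global"` for whole-alignment
#'   intervals in column coordinates), `start`, `end` (1-based inclusive),
#'   `label`, optional `color`, `url`.
#'
#' Positions are always native ungapped sequence coordinates, never
#' alignment columns; this is what lets the same biological site carry
#' different residue numbers in different species yet land on one column.
#' Every reference is resolved and every position bounds-checked here, so
#' later stages need no validation. The machine-readable schema ships at
#' `system.file("schema", "annotations-schema.json", package = "alnvista")`.
#'
#' @param source JSON text, or a path to a JSON file.
#' @param aln the `alignment` the annotations refer to.
#' @return An object of class `annotation_set`: list with `variants`,
#'   `modifications` and `regions`, each a list of bound records carrying
#'   a resolved `seq_index` (`NA` for global regions).
#' @seealso [index_by_column()], [ortho_groups()], [validate_changes()]
#' @export
load_annotations <- function(source, aln) {
  stopifnot(inherits(aln, "alignment"))
  txt <- if (length(source) == 1L && !grepl("[{\\[\n]", source) &&
             file.exists(source)) {
    paste(readLines(source, warn = FALSE), collapse = "\n")
  } else source
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) av_parse_error(
                    sprintf("annotation JSON is not valid: %s",
                            conditionMessage(e))))
  if (!is.list(doc))
    av_parse_error("annotation JSON must be an object")
  lens <- vapply(seq_along(aln$letters), function(i)
    position_map(aln, i)$ungapped_length, integer(1))

  variants <- lapply(seq_along(doc$variants %||% list()), function(k)
    bind_variant(doc$variants[[k]], k, aln, lens))
  modifications <- lapply(seq_along(doc$modifications %||% list()), function(k)
    bind_modification(doc$modifications[[k]], k, aln, lens))
  regions <- lapply(seq_along(doc$regions %||% list()), function(k)
    bind_region(doc$regions[[k]], k, aln, lens))

  structure(list(variants = variants, modifications = modifications,
                 regions = regions),
            class = "annotation_set")
}

bind_seq_ref <- function(ref, what, aln) {
  if (is.null(ref))
    av_validation_error(sprintf("%s lacks a 'sequence' reference", what))
  tryCatch(resolve_sequence(aln, ref),
           alnvista_lookup_error = function(e) av_validation_error(
             sprintf("%s: %s", what, conditionMessage(e))))
}

check_pos <- function(pos, what, limit) {
  if (is.null(pos) || !is.numeric(pos) || length(pos) != 1L || pos < 1L)
    av_validation_error(sprintf("%s needs a positive 1-based position", what))
  if (pos > limit)
    av_validation_error(sprintf(
      "%s: position %d beyond sequence (ungapped length %d)",
      what, as.integer(pos), limit))
  as.integer(pos)
}

bind_variant <- function(v, k, aln, lens) {
  what <- sprintf("variant %d", k)
  i <- bind_seq_ref(v$sequence, what, aln)
  pos <- check_pos(v$position, what, lens[i])
  known <- c("sequence", "position", "token", "source", "note", "id", "url")
  change <- NULL
  if (!is.null(v$token))
    change <- tryCatch(parse_change(v$token),
                       alnvista_parse_error = function(e) NULL)
  if (!is.null(change) && change$position != pos)
    av_validation_error(sprintf(
      "%s: token '%s' encodes position %d but the position field is %d",
      what, v$token, change$position, pos))
  list(kind = "variant", seq_index = i, position = pos,
       token = v$token %||% "", change = change,
       source = v$source %||% "", note = v$note %||% "",
       variant_id = v$id %||% "", url = v$url %||% "",
       attributes = v[setdiff(names(v), known)])
}

bind_modification <- function(m, k, aln, lens) {
  what <- sprintf("modification %d", k)
  i <- bind_seq_ref(m$sequence, what, aln)
  pos <- check_pos(m$position, what, lens[i])
  list(kind = "modification", seq_index = i, position = pos,
       mod_type = m$type %||% "", note = m$note %||% "", url = m$url %||% "")
}

bind_region <- function(r, k, aln, lens) {
  what <- sprintf("region %d", k)
  global <- is.null(r$sequence) ||
    (is.character(r$sequence) && tolower(r$sequence) == "global")
  i <- if (global) NA_integer_ else bind_seq_ref(r$sequence, what, aln)
  limit <- if (global) aln$n_columns else lens[i]
  if (is.null(r$start) || is.null(r$end))
    av_validation_error(sprintf("%s needs 'start' and 'end'", what))
  start <- check_pos(r$start, what, limit)
  end <- check_pos(r$end, what, limit)
  if (start > end)
    av_validation_error(sprintf("%s: start %d > end %d", what, start, end))
  list(kind = "region", seq_index = i, start = start, end = end,
       label = r$label %||% "", color = r$color %||% "", url = r$url %||% "")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation set> %d variant(s), %d modification(s), %d region(s)\n",
              length(x$variants), length(x$modifications), length(x$regions)))
  invisible(x)
}

#' Project positional annotations onto alignment columns
#'
#' Every variant and modification is pushed through its sequence's
#' [position_map()] to the alignment column its residue occupies. The
#' result is the per-column bucket structure behind pop-ups, circled
#' cells, the notification row and orthologous-variant grouping. Bucket
#' contents are ordered by (sequence index, kind with variants first,
#' insertion order), so serializations are deterministic.
#'
#' @param set a bound `annotation_set`.
#' @param aln the `alignment` it was bound against.
#' @return An object of class `column_index`: list with `buckets`, a list
#'   named by column number, each element a list of annotation records
#'   augmented with their `column`.
#' @export
index_by_column <- function(set, aln) {
  stopifnot(inherits(set, "annotation_set"), inherits(aln, "alignment"))
  maps <- lapply(seq_along(aln$letters), function(i) position_map(aln, i))
  entries <- c(set$variants, set$modifications)
  if (length(entries) == 0L)
    return(structure(list(buckets = list()), class = "column_index"))
  cols <- vapply(entries, function(a)
    ungapped_to_column(maps[[a$seq_index]], a$position), integer(1))
  kind_rank <- vapply(entries, function(a)
    if (a$kind == "variant") 1L else 2L, integer(1))
  seqs <- vapply(entries, `[[`, integer(1), "seq_index")
  ord <- order(cols, seqs, kind_rank, seq_along(entries))
  buckets <- list()
  for (idx in ord) {
    key <- as.character(cols[idx])
    rec <- entries[[idx]]
    rec$column <- cols[idx]
    buckets[[key]] <- c(buckets[[key]], list(rec))
  }
  buckets <- buckets[order(as.integer(names(buckets)))]
  structure(list(buckets = buckets), class = "column_index")
}

#' Group cross-sequence co-located variants
#'
#' Two variants in different sequences whose native positions land on the
#' same alignment column are counterparts of one another across species
#' (orthologous variants). This builds one group per column whose bucket
#' holds variants from at least two distinct sequences. Modifications
#' never join a group, and multiple variants on one sequence count as a
#' single member (the first bound one represents that sequence).
#'
#' @param index a [index_by_column()] result.
#' @return A list of groups sorted by column, each a list with `column`
#'   and `members` (variant records from pairwise-distinct sequences).
#' @export
ortho_groups <- function(index) {
  stopifnot(inherits(index, "column_index"))
  groups <- list()
  for (key in names(index$buckets)) {
    vars <- Filter(function(a) a$kind == "variant", index$buckets[[key]])
    if (length(vars) < 2L) next
    seqs <- vapply(vars, `[[`, integer(1), "seq_index")
    members <- vars[!duplicated(seqs)]
    if (length(members) < 2L) next
    groups[[length(groups) + 1L]] <-
      list(column = as.integer(key), members = members)
  }
  groups[order(vapply(groups, `[[`, integer(1), "column"))]
}

#' Check variant tokens against the residues they claim to change
#'
#' For every variant whose token parses, compares the token's reference
#' letter with the actual residue at the variant's position. Mismatches —
#' commonly caused by isoform or sequence-version drift — are reported as
#' warnings, never as errors, so the alignment still renders.
#'
#' @param set a bound `annotation_set`.
#' @param aln the `alignment`.
#' @return A character vector of warning messages (empty when everything
#'   is consistent).
#' @export
validate_changes <- function(set, aln) {
  stopifnot(inherits(set, "annotation_set"), inherits(aln, "alignment"))
  maps <- lapply(seq_along(aln$letters), function(i) position_map(aln, i))
  warnings <- character(0)
  for (v in set$variants) {
    if (is.null(v$change)) next
    col <- ungapped_to_column(maps[[v$seq_index]], v$position)
    found <- substr(aln$letters[v$seq_index], col, col)
    if (found != v$change$ref)
      warnings <- c(warnings, sprintf(
        "sequence %d ('%s') position %d: token '%s' expects %s but the sequence has %s",
        v$seq_index, aln$labels[v$seq_index], v$position, v$token,
        v$change$ref, found))
  }
  warnings
}
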