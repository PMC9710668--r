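#' Resolve rendering options into a plan
#'
#' A render plan bundles everything the HTML and SVG emitters consume: the
#' colour scheme, the column window, excluded sequences and geometry. The
#' scheme defaults to `clustal` for protein alignments and `nucleotide`
#' for nucleotide alignments (majority vote over records).
#'
#' @param aln an `alignment`.
#' @param scheme scheme name (see [list_schemes()]) or a `color_scheme`;
#'   `NULL` picks the family default.
#' @param window inclusive 1-based column range `c(start, end)`; `NULL`
#'   means all columns.
#' @param show_consensus draw the consensus row?
#' @param exclude sequences to hide: indices or labels.
#' @param cell_px cell size in pixels (SVG/PNG geometry).
#' @param mark_annotated draw annotated cells with a distinct (circled)
#'   shape?
#' @param sanitize strip HTML tags from annotation notes before they reach
#'   pop-ups; off by default so notes may carry images and links.
#' @return An object of class `render_plan`.
#' @export
render_plan <- function(aln, scheme = NULL, window = NULL,
                        show_consensus = TRUE, exclude = NULL,
                        cell_px = 18L, mark_annotated = TRUE,
                        sanitize = FALSE) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(scheme)) {
    nuc <- mean(aln$alphabet == "nucleotide") > 0.5
    scheme <- if (nuc) "nucleotide" else "clustal"
  }
  if (!inherits(scheme, "color_scheme")) scheme <- get_scheme(scheme)
  if (is.null(window)) window <- c(1L, aln$n_columns)
  if (length(window) != 2L || !is.numeric(window) ||
      window[1L] < 1L || window[2L] > aln$n_columns ||
      window[1L] > window[2L])
    av_argument_error(sprintf(
      "window must be an inclusive column range within 1..%d", aln$n_columns))
  excluded <- integer(0)
  for (sel in exclude %||% list())
    excluded <- c(excluded, resolve_sequence(aln, sel))
  excluded <- sort(unique(excluded))
  if (!is.numeric(cell_px) || cell_px < 4L)
    av_argument_error("cell_px must be at least 4")
  structure(list(
    scheme = scheme, window = as.integer(window),
    show_consensus = isTRUE(show_consensus), excluded = excluded,
    cell_px = as.integer(cell_px), mark_annotated = isTRUE(mark_annotated),
    sanitize = isTRUE(sanitize)
  ), class = "render_plan")
}

#' Partition alignment columns into consecutive windows
#'
#' The static analogue of scroll-driven lazy rendering: instead of
#' emitting the whole alignment at once, callers can emit one bounded
#' window per page. Windows are inclusive, consecutive, of width at most
#' `chunk`, and cover `1..n_columns` exactly once.
#'
#' @param aln an `alignment`, or the number of columns directly.
#' @param chunk maximum window width (positive integer; default 500).
#' @return A data.frame with integer columns `start` and `end`.
#' @examples
#' paginate(10, 4)  # 1-4, 5-8, 9-10
#' @export
paginate <- function(aln, chunk = 500L) {
  n <- if (inherits(aln, "alignment")) aln$n_columns else aln
  if (!is.numeric(n) || length(n) != 1L || n < 1L)
    av_argument_error("need an alignment or a positive column count")
  if (!is.numeric(chunk) || length(chunk) != 1L || chunk < 1L)
    av_argument_error("chunk must be a positive integer")
  n <- as.integer(n); chunk <- as.integer(chunk)
  start <- seq.int(1L, n, by = chunk)
  data.frame(start = start, end = pmin(start + chunk - 1L, n))
}

# Shared geometry between the HTML and SVG emitters -------------------------

# Region spans in column coordinates, clipped to the window and stacked
# into lanes by greedy first-fit on start column.
region_lanes <- function(set, aln, plan) {
  win <- plan$window
  spans <- list()
  for (r in set$regions %||% list()) {
    if (is.na(r$seq_index)) {
      c1 <- r$start; c2 <- r$end
    } else {
      map <- position_map(aln, r$seq_index)
      c1 <- ungapped_to_column(map, r$start)
      c2 <- ungapped_to_column(map, r$end)
    }
    if (c2 < win[1L] || c1 > win[2L]) next
    spans[[length(spans) + 1L]] <- list(
      start = max(c1, win[1L]), end = min(c2, win[2L]),
      label = r$label, color = if (nzchar(r$color)) r$color else "#c8d8f8",
      url = r$url)
  }
  if (length(spans) == 0L) return(list())
  ord <- order(vapply(spans, `[[`, integer(1), "start"),
               vapply(spans, `[[`, integer(1), "end"))
  spans <- spans[ord]
  lane_end <- integer(0)
  for (i in seq_along(spans)) {
    lane <- which(lane_end < spans[[i]]$start)
    lane <- if (length(lane) == 0L) length(lane_end) + 1L else lane[1L]
    spans[[i]]$lane <- lane
    lane_end[lane] <- spans[[i]]$end
  }
  spans
}

# Layout facts consumed by both emitters; `index` may be NULL.
render_layout <- function(aln, set, plan, index = NULL) {
  if (is.null(index)) index <- index_by_column(set, aln)
  rows <- setdiff(seq_along(aln$letters), plan$excluded)
  if (length(rows) == 0L)
    av_argument_error("nothing to render: all sequences excluded")
  cols <- seq.int(plan$window[1L], plan$window[2L])
  spans <- region_lanes(set, aln, plan)
  n_lanes <- if (length(spans)) max(vapply(spans, `[[`, integer(1), "lane")) else 0L
  bucket_cols <- as.integer(names(index$buckets))
  # columns with >= 1 modification get the notification asterisk
  notif_cols <- bucket_cols[vapply(index$buckets, function(b)
    any(vapply(b, function(a) a$kind == "modification", logical(1))),
    logical(1))]
  # (seq, col) pairs carrying any positional annotation -> circled cells
  marked <- list()
  for (key in names(index$buckets))
    for (a in index$buckets[[key]])
      marked[[paste(a$seq_index, key, sep = ":")]] <- TRUE
  list(rows = rows, cols = cols, spans = spans, n_lanes = n_lanes,
       notif_cols = intersect(notif_cols, cols), marked = marked,
       index = index)
}

escape_html <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

strip_tags <- function(x) gsub("<[^>]*>", "", x)
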