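#' Render an annotated alignment window as self-contained HTML
#'
#' Emits one HTML document with no scripts and no network fetches. Layout,
#' top to bottom: the region track (labelled interval bars, hyperlinked
#' when a URL is given, stacked into lanes when intervals overlap); the
#' notification row with a red asterisk above every column carrying a
#' modification; the alignment grid, cells coloured by the plan's scheme,
#' annotated cells drawn as circles and plain cells as squares; the
#' consensus row. Row labels are hyperlinked to their sequence database
#' when [parse_identity()] recognises the header. Hovering an annotated
#' cell opens a pop-up (pure CSS `:hover`) listing the variants and
#' modifications at that position; notes may contain raw HTML unless the
#' plan's `sanitize` flag is set.
#'
#' Only columns inside the plan's window and rows not excluded are
#' emitted. Output is byte-deterministic for fixed inputs.
#'
#' @param aln an `alignment`.
#' @param set a bound `annotation_set` (may be empty).
#' @param plan a [render_plan()].
#' @param path optional output file; the HTML text is returned either way
#'   (invisibly when written).
#' @return The HTML document as a single string.
#' @export
render_html <- function(aln, set, plan, path = NULL) {
  stopifnot(inherits(aln, "alignment"), inherits(set, "annotation_set"),
            inherits(plan, "render_plan"))
  lay <- render_layout(aln, set, plan)
  cell <- plan$cell_px
  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))

  push("<!DOCTYPE html>")
  push("<html><head><meta charset=\"utf-8\"><title>alignment</title>")
  push("<style>")
  push("body{font-family:monospace;margin:12px}")
  push(".grid{border-collapse:collapse}")
  push(".lbl{text-align:right;padding-right:8px;white-space:nowrap}")
  push(".cell{display:inline-block;width:%dpx;height:%dpx;line-height:%dpx;text-align:center;position:relative}",
       cell, cell, cell)
  push(".circ{border-radius:50%%;box-shadow:0 0 2px #333}")
  push(".notif{color:#cc0000;font-weight:bold}")
  push(".region{display:inline-block;height:%dpx;line-height:%dpx;text-align:center;overflow:hidden;border-radius:3px;font-size:%dpx}",
       cell, cell, max(8L, cell - 8L))
  push(".popup{display:none;position:absolute;left:%dpx;top:0;z-index:9;background:#ffffff;border:1px solid #888;padding:6px;text-align:left;white-space:nowrap;font-size:12px;box-shadow:2px 2px 4px #aaa}",
       cell + 2L)
  push(".cell:hover .popup{display:block}")
  push("</style></head><body>")

  w0 <- plan$window[1L]

  # region track: one div per lane, absolute spans padded with blanks
  if (lay$n_lanes > 0L) {
    for (lane in seq_len(lay$n_lanes)) {
      push("<div class=\"trk\"><span class=\"lbl cell\" style=\"width:120px\">&nbsp;</span>")
      cur <- w0
      for (sp in lay$spans) {
        if (sp$lane != lane) next
        if (sp$start > cur)
          push("<span class=\"region\" style=\"width:%dpx\">&nbsp;</span>",
               (sp$start - cur) * cell)
        body <- escape_html(sp$label)
        if (nzchar(sp$url))
          body <- sprintf("<a href=\"%s\">%s</a>", escape_html(sp$url), body)
        push("<span class=\"region\" style=\"width:%dpx;background:%s\" title=\"%s\">%s</span>",
             (sp$end - sp$start + 1L) * cell, sp$color,
             escape_html(sp$label), body)
        cur <- sp$end + 1L
      }
      push("</div>")
    }
  }

  # notification row: red asterisk per modified column
  push("<div class=\"notifrow\"><span class=\"lbl cell\" style=\"width:120px\">&nbsp;</span>%s</div>",
       paste(vapply(lay$cols, function(cc) {
         if (cc %in% lay$notif_cols)
           "<span class=\"cell notif\">*</span>"
         else "<span class=\"cell\">&nbsp;</span>"
       }, character(1)), collapse = ""))

  # alignment grid; the plain-cell fast path is vectorized, annotated
  # cells (the rare ones) are rebuilt individually with their pop-ups
  for (i in lay$rows) {
    id <- parse_identity(aln$headers[i])
    lbl <- escape_html(aln$labels[i])
    if (nzchar(id$url))
      lbl <- sprintf("<a href=\"%s\">%s</a>", escape_html(id$url), lbl)
    chs <- strsplit(aln$letters[i], "", fixed = TRUE)[[1L]][lay$cols]
    cells <- sprintf("<span class=\"cell sq\" style=\"background:%s\">%s</span>",
                     unname(scheme_color(plan$scheme, chs)), chs)
    if (plan$mark_annotated) {
      annotated <- vapply(paste(i, lay$cols, sep = ":"),
                          function(k) isTRUE(lay$marked[[k]]), logical(1))
      for (j in which(annotated))
        cells[j] <- html_cell(aln, plan, lay, i, lay$cols[j])
    }
    push("<div class=\"seqrow\"><span class=\"lbl cell\" style=\"width:120px\">%s</span>%s</div>",
         lbl, paste(cells, collapse = ""))
  }

  # consensus row
  if (plan$show_consensus) {
    cons <- consensus(aln)
    push("<div class=\"consrow\"><span class=\"lbl cell\" style=\"width:120px\">Consensus</span>%s</div>",
         paste(vapply(lay$cols, function(cc) {
           ch <- substr(cons$letters, cc, cc)
           sprintf("<span class=\"ccell cell\" style=\"background:%s\">%s</span>",
                   scheme_color(plan$scheme, ch), ch)
         }, character(1)), collapse = ""))
  }

  push("</body></html>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

html_cell <- function(aln, plan, lay, i, cc) {
  ch <- substr(aln$letters[i], cc, cc)
  color <- scheme_color(plan$scheme, ch)
  key <- paste(i, cc, sep = ":")
  annotated <- plan$mark_annotated && isTRUE(lay$marked[[key]])
  if (!annotated)
    return(sprintf("<span class=\"cell sq\" style=\"background:%s\">%s</span>",
                   color, ch))
  entries <- Filter(function(a) a$seq_index == i,
                    lay$index$buckets[[as.character(cc)]])
  sprintf("<span class=\"cell circ\" style=\"background:%s\">%s<div class=\"popup\">%s</div></span>",
          color, ch, popup_body(entries, plan))
}

popup_body <- function(entries, plan) {
  note_of <- function(a) {
    n <- a$note
    if (plan$sanitize) escape_html(strip_tags(n)) else n
  }
  parts <- vapply(entries, function(a) {
    if (a$kind == "variant") {
      bits <- c(
        sprintf("<b>%s</b>", escape_html(
          if (nzchar(a$token)) a$token else sprintf("variant @%d", a$position))),
        if (nzchar(a$variant_id)) escape_html(a$variant_id),
        if (nzchar(a$source)) escape_html(a$source),
        if (nzchar(a$note)) note_of(a),
        if (nzchar(a$url))
          sprintf("<a href=\"%s\">link</a>", escape_html(a$url)),
        vapply(names(a$attributes %||% list()), function(k)
          sprintf("%s: %s", escape_html(k),
                  escape_html(format(a$attributes[[k]]))), character(1))
      )
    } else {
      bits <- c(
        sprintf("<b>%s @%d</b>",
                escape_html(if (nzchar(a$mod_type)) a$mod_type else "modification"),
                a$position),
        if (nzchar(a$note)) note_of(a),
        if (nzchar(a$url))
          sprintf("<a href=\"%s\">link</a>", escape_html(a$url))
      )
    }
    paste(bits, collapse = "<br>")
  }, character(1))
  paste(sprintf("<div class=\"entry\">%s</div>", parts), collapse = "")
}
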