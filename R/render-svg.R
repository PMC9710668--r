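#' Render an annotated alignment window as a static SVG figure
#'
#' Same grid and track semantics as [render_html()] — region lanes,
#' notification asterisks, scheme-coloured cells with annotated positions
#' drawn as rounded (circled) cells, optional consensus row — but as a
#' publication-ready vector figure without pop-ups.
#'
#' Geometry contract: canvas width is `gutter + window_width * cell_px`
#' (the label gutter is 120 px) and height is
#' `(region_lanes + 1) * cell_px` for the tracks plus one `cell_px` row
#' per shown sequence, plus one for the consensus when enabled. Output is
#' byte-deterministic for fixed inputs.
#'
#' @inheritParams render_html
#' @return The SVG document as a single string.
#' @export
render_svg <- function(aln, set, plan, path = NULL) {
  stopifnot(inherits(aln, "alignment"), inherits(set, "annotation_set"),
            inherits(plan, "render_plan"))
  lay <- render_layout(aln, set, plan)
  cell <- plan$cell_px
  gutter <- 120L
  ncol_win <- length(lay$cols)
  n_rows <- length(lay$rows) + if (plan$show_consensus) 1L else 0L
  width <- gutter + ncol_win * cell
  height <- (lay$n_lanes + 1L + n_rows) * cell
  fs <- max(8L, round(cell * 0.6))

  out <- character(0)
  push <- function(...) out <<- c(out, sprintf(...))
  push("<svg xmlns=\"http://www.w3.org/2000/svg\" width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\">",
       width, height, width, height)
  push("<rect x=\"0\" y=\"0\" width=\"%d\" height=\"%d\" fill=\"#ffffff\"/>",
       width, height)

  x_of <- function(cc) gutter + (cc - plan$window[1L]) * cell

  # region lanes
  for (sp in lay$spans) {
    y <- (sp$lane - 1L) * cell
    x <- x_of(sp$start)
    w <- (sp$end - sp$start + 1L) * cell
    open_a <- nzchar(sp$url)
    if (open_a) push("<a href=\"%s\">", escape_html(sp$url))
    push("<rect class=\"regionbar\" x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" rx=\"3\" fill=\"%s\"/>",
         x, y + 2L, w, cell - 4L, sp$color)
    push("<text x=\"%d\" y=\"%d\" font-size=\"%d\" font-family=\"monospace\" text-anchor=\"middle\" fill=\"#202020\">%s</text>",
         x + w %/% 2L, y + cell - 5L, fs - 1L, escape_html(sp$label))
    if (open_a) push("</a>")
  }

  # notification row
  y_notif <- lay$n_lanes * cell
  for (cc in lay$notif_cols)
    push("<text class=\"notif\" x=\"%d\" y=\"%d\" font-size=\"%d\" font-family=\"monospace\" text-anchor=\"middle\" fill=\"#cc0000\">*</text>",
         x_of(cc) + cell %/% 2L, y_notif + cell - 4L, fs + 2L)

  # sequence rows (vectorized over the window to keep large renders fast)
  xs <- gutter + (lay$cols - plan$window[1L]) * cell
  row_cells <- function(letters_str, y, cell_class, marked_keys) {
    chs <- strsplit(letters_str, "", fixed = TRUE)[[1L]][lay$cols]
    colors <- unname(scheme_color(plan$scheme, chs))
    annotated <- if (is.null(marked_keys)) rep(FALSE, length(chs)) else
      vapply(marked_keys, function(k) isTRUE(lay$marked[[k]]), logical(1))
    rects <- sprintf(
      "<rect class=\"%s\" x=\"%d\" y=\"%d\" width=\"%d\" height=\"%d\" rx=\"%d\" fill=\"%s\" stroke=\"%s\"/>",
      cell_class, xs, y, cell, cell,
      ifelse(annotated, cell %/% 2L, 0L), colors,
      ifelse(annotated, "#333333", "none"))
    texts <- sprintf(
      "<text x=\"%d\" y=\"%d\" font-size=\"%d\" font-family=\"monospace\" text-anchor=\"middle\" fill=\"#000000\">%s</text>",
      xs + cell %/% 2L, y + cell - 5L, fs, chs)
    paste(rects, texts, sep = "\n", collapse = "\n")
  }
  y <- (lay$n_lanes + 1L) * cell
  for (i in lay$rows) {
    push("<text class=\"rowlabel\" x=\"%d\" y=\"%d\" font-size=\"%d\" font-family=\"monospace\" text-anchor=\"end\" fill=\"#000000\">%s</text>",
         gutter - 6L, y + cell - 5L, fs, escape_html(aln$labels[i]))
    keys <- if (plan$mark_annotated)
      paste(i, lay$cols, sep = ":") else NULL
    push("%s", row_cells(aln$letters[i], y, "cell", keys))
    y <- y + cell
  }

  # consensus row
  if (plan$show_consensus) {
    cons <- consensus(aln)
    push("<text class=\"rowlabel\" x=\"%d\" y=\"%d\" font-size=\"%d\" font-family=\"monospace\" text-anchor=\"end\" fill=\"#000000\">Consensus</text>",
         gutter - 6L, y + cell - 5L, fs)
    push("%s", row_cells(cons$letters, y, "ccell", NULL))
  }

  push("</svg>")
  doc <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(doc, path, sep = "")
    return(invisible(doc))
  }
  doc
}

#' Rasterize an SVG figure to PNG
#'
#' Renders the SVG subset emitted by [render_svg()] (`rect`, `circle`,
#' `line`, `text` and `a` elements) onto a cairo PNG device. Pixel
#' dimensions are the SVG dimensions scaled by `dpi / 96`, rounded.
#'
#' @param svg SVG text, as produced by [render_svg()].
#' @param path optional output file for the PNG.
#' @param dpi resolution; 96 gives a pixel-per-unit rendering.
#' @return The PNG file content as a raw vector (invisibly when `path` is
#'   given).
#' @export
rasterize_png <- function(svg, path = NULL, dpi = 96L) {
  if (!is.numeric(dpi) || length(dpi) != 1L || dpi < 1L)
    av_argument_error("dpi must be a positive integer")
  doc <- xml2::read_xml(svg)
  w <- as.numeric(xml2::xml_attr(doc, "width"))
  h <- as.numeric(xml2::xml_attr(doc, "height"))
  if (is.na(w) || is.na(h))
    av_argument_error("svg root needs numeric width/height attributes")
  px_w <- max(1L, as.integer(round(w * dpi / 96)))
  px_h <- max(1L, as.integer(round(h * dpi / 96)))
  tf <- tempfile(fileext = ".png")
  on.exit(unlink(tf), add = TRUE)
  grDevices::png(tf, width = px_w, height = px_h, type = "cairo")
  ok <- FALSE
  tryCatch({
    graphics::par(mar = c(0, 0, 0, 0), xaxs = "i", yaxs = "i")
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, w), ylim = c(h, 0))
    draw_svg_node(doc)
    ok <- TRUE
  }, finally = grDevices::dev.off())
  if (!ok) av_argument_error("failed to rasterize svg")
  bytes <- readBin(tf, "raw", file.info(tf)$size)
  if (!is.null(path)) {
    writeBin(bytes, path)
    return(invisible(bytes))
  }
  bytes
}

# Vectorized drawing of the render_svg element subset. Shapes are drawn
# before glyphs (rects, then circles/lines, then text), matching the
# layering render_svg emits; within each class document order is kept.
draw_svg_node <- function(doc) {
  num_attr <- function(nodes, a, default = 0) {
    v <- suppressWarnings(as.numeric(xml2::xml_attr(nodes, a)))
    v[is.na(v)] <- default
    v
  }
  chr_attr <- function(nodes, a, default = "") {
    v <- xml2::xml_attr(nodes, a)
    v[is.na(v)] <- default
    v
  }
  find <- function(tag)
    xml2::xml_find_all(doc, sprintf(".//*[local-name()='%s']", tag))

  rects <- find("rect")
  if (length(rects) > 0) {
    x <- num_attr(rects, "x"); y <- num_attr(rects, "y")
    wd <- num_attr(rects, "width"); ht <- num_attr(rects, "height")
    rx <- num_attr(rects, "rx")
    fill <- chr_attr(rects, "fill", "#000000")
    fill[fill == "none"] <- NA
    stroke <- chr_attr(rects, "stroke", "none")
    stroke[stroke %in% c("none", "")] <- NA
    round_cell <- rx >= wd / 2.5  # rounded cell: draw an inscribed disc
    if (any(!round_cell))
      graphics::rect(x[!round_cell], y[!round_cell],
                     (x + wd)[!round_cell], (y + ht)[!round_cell],
                     col = fill[!round_cell], border = stroke[!round_cell])
    if (any(round_cell))
      graphics::symbols((x + wd / 2)[round_cell], (y + ht / 2)[round_cell],
                        circles = (wd / 2)[round_cell], inches = FALSE,
                        add = TRUE, bg = fill[round_cell],
                        fg = stroke[round_cell])
  }

  circles <- find("circle")
  if (length(circles) > 0) {
    fill <- chr_attr(circles, "fill", "#000000")
    fill[fill == "none"] <- NA
    graphics::symbols(num_attr(circles, "cx"), num_attr(circles, "cy"),
                      circles = num_attr(circles, "r", 1), inches = FALSE,
                      add = TRUE, bg = fill, fg = NA)
  }

  lines <- find("line")
  if (length(lines) > 0)
    graphics::segments(num_attr(lines, "x1"), num_attr(lines, "y1"),
                       num_attr(lines, "x2"), num_attr(lines, "y2"),
                       col = chr_attr(lines, "stroke", "#000000"))

  texts <- find("text")
  if (length(texts) > 0) {
    anchor <- chr_attr(texts, "text-anchor", "start")
    adj <- ifelse(anchor == "middle", 0.5, ifelse(anchor == "end", 1, 0))
    size <- num_attr(texts, "font-size", 12)
    # draw in batches sharing (anchor, size) so text() stays vectorized
    grp <- paste(adj, size)
    for (g in unique(grp)) {
      sel <- grp == g
      graphics::text(num_attr(texts, "x")[sel], num_attr(texts, "y")[sel],
                     xml2::xml_text(texts[sel]),
                     adj = c(adj[sel][1L], 0),
                     cex = size[sel][1L] * 0.75 / 12,
                     col = chr_attr(texts, "fill", "#000000")[sel],
                     family = "mono")
    }
  }
  invisible(NULL)
}
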