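test_that("the scheme registry holds 13 total, uniquely named palettes", {
  names <- list_schemes()
  expect_length(names, 13)
  expect_equal(anyDuplicated(names), 0)
  for (nm in names) {
    sc <- get_scheme(nm)
    alphabet <- if (sc$family == "protein")
      c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
        "T","V","W","Y","X","-")
    else c("A","C","G","T","U","N","-")
    expect_setequal(names(sc$colors), alphabet)
    expect_true(all(nzchar(sc$colors)))
  }
})

test_that("get_scheme is case-insensitive and lists valid names on a miss", {
  expect_identical(get_scheme("CLUSTAL"), get_scheme("clustal"))
  expect_error(get_scheme("rainbow-unknown"), "zappo.*nucleotide",
               class = "alnvista_argument_error")
})

test_that("render_html draws one circled cell with a pop-up per annotated position", {
  aln <- read_fasta(">a one\nMKCVA\n>b two\nMKCVA\n")
  set <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":3,"token":"p.C3Y",',
    '"note":"my special note"}]}'), aln)
  html <- render_html(aln, set, render_plan(aln))
  expect_equal(count_matches('class="cell circ"', html), 1)
  expect_equal(count_matches('class="popup"', html), 1)
  expect_match(html, "my special note", fixed = TRUE)
  expect_match(html, "p.C3Y", fixed = TRUE)
  # 2 sequence rows x 5 columns, square cells everywhere else
  expect_equal(count_matches('class="cell sq"', html), 9)
})

test_that("render_html honors exclusion, windows and the sanitize flag", {
  aln <- read_fasta(">a one\nMKCVA\n>b two\nMKCVA\n>c three\nMKCVA\n")
  set <- load_annotations("{}", aln)
  html <- render_html(aln, set, render_plan(aln, exclude = list(2)))
  expect_equal(count_matches('class="seqrow"', html), 2)
  expect_no_match(html, ">two<")

  wide <- new_alignment("w wide", paste(rep("MKCVA", 20), collapse = ""))
  html <- render_html(wide, load_annotations("{}", wide),
                      render_plan(wide, window = c(1, 5)))
  expect_equal(count_matches('class="cell sq"', html), 5)

  noted <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":1,',
    '"note":"<img src=x> raw html"}]}'), aln)
  html_raw <- render_html(aln, noted, render_plan(aln))
  expect_match(html_raw, "<img src=x>", fixed = TRUE)
  html_clean <- render_html(aln, noted, render_plan(aln, sanitize = TRUE))
  expect_no_match(html_clean, "<img", fixed = TRUE)

  expect_error(render_plan(aln, window = c(2, 99)),
               class = "alnvista_argument_error")
})

test_that("row labels and regions carry their cross-reference links", {
  aln <- read_fasta(">sp|Q9Y3I1|FBX25_HUMAN Homo sapiens\nMKCVA\n>plain other\nMKCVA\n")
  set <- load_annotations(paste0(
    '{"regions":[{"sequence":1,"start":2,"end":4,"label":"SH3",',
    '"url":"https://example.org/dom"}],',
    '"modifications":[{"sequence":1,"position":3,"type":"ubiquitination"}]}'),
    aln)
  html <- render_html(aln, set, render_plan(aln))
  expect_match(html, "https://www.uniprot.org/uniprotkb/Q9Y3I1", fixed = TRUE)
  expect_match(html, "https://example.org/dom", fixed = TRUE)
  expect_match(html, "SH3", fixed = TRUE)
  # the modified column gets a red asterisk in the notification row
  expect_equal(count_matches('class="cell notif"', html), 1)
})

test_that("render_svg obeys the width contract and is byte-deterministic", {
  aln <- read_fasta(">a one\nMKCVAMKCVA\n>b two\nMKCVAMKCVA\n")
  set <- load_annotations("{}", aln)
  plan <- render_plan(aln, cell_px = 16, show_consensus = FALSE)
  svg <- render_svg(aln, set, plan)
  expect_match(svg, 'width="280"', fixed = TRUE)  # 120 + 10*16
  expect_identical(render_svg(aln, set, plan), svg)
  expect_identical(render_html(aln, set, plan),
                   render_html(aln, set, plan))
  expect_error(render_plan(aln, exclude = list(1, 2)) |>
                 render_svg(aln = aln, set = set),
               "nothing to render", class = "alnvista_argument_error")
})

test_that("cell counts and circled cells equal rows x window and the bucket set", {
  set.seed(23)
  fx <- make_fixture(toy_spec(n_sequences = 5, ungapped_length = 40,
                              gap_rate = 0.2, n_variant_pairs = 3,
                              n_lone_variants = 2, n_modifications = 2,
                              n_regions = 1, seed = 23))
  aln <- read_fasta(fx$fasta)
  set <- load_annotations(fx$json, aln)
  idx <- index_by_column(set, aln)
  win <- c(5, 30)
  plan <- render_plan(aln, window = win, exclude = list(2))
  rows <- setdiff(seq_len(5), 2)

  in_window <- 0L
  for (key in names(idx$buckets)) {
    col <- as.integer(key)
    if (col < win[1] || col > win[2]) next
    pairs <- unique(vapply(idx$buckets[[key]], `[[`, integer(1), "seq_index"))
    in_window <- in_window + sum(pairs %in% rows)
  }

  html <- render_html(aln, set, plan)
  n_cells_html <- count_matches('class="cell sq"', html) +
    count_matches('class="cell circ"', html)
  expect_equal(n_cells_html, length(rows) * (win[2] - win[1] + 1))
  expect_equal(count_matches('class="cell circ"', html), in_window)

  svg <- render_svg(aln, set, plan)
  expect_equal(count_matches('<rect class="cell"', svg),
               length(rows) * (win[2] - win[1] + 1))
  # circled = rounded cells, recognizable by their nonzero corner radius
  expect_equal(count_matches(sprintf('rx="%d"', plan$cell_px %/% 2), svg),
               in_window)
})

test_that("rasterize_png scales pixel dimensions by dpi/96", {
  aln <- read_fasta(">a one\nMKCVAMKCVA\n>b two\nMKCVAMKCVA\n")
  set <- load_annotations("{}", aln)
  svg <- render_svg(aln, set, render_plan(aln, cell_px = 16,
                                          show_consensus = FALSE))
  # canvas is 280 x (0 lanes + notif + 2 rows) * 16 = 280 x 48
  at96 <- png::readPNG(rasterize_png(svg, dpi = 96))
  expect_equal(dim(at96)[2:1], c(280, 48))
  at192 <- png::readPNG(rasterize_png(svg, dpi = 192))
  expect_equal(dim(at192)[2:1], c(560, 96))
  expect_error(rasterize_png(svg, dpi = 0), class = "alnvista_argument_error")
})

test_that("paginate partitions the columns exactly once", {
  expect_equal(paginate(10, 4),
               data.frame(start = c(1L, 5L, 9L), end = c(4L, 8L, 10L)))
  expect_equal(nrow(paginate(10, 25)), 1)
  expect_equal(nrow(paginate(10, 1)), 10)
  expect_error(paginate(10, 0), class = "alnvista_argument_error")

  set.seed(31)
  for (i in 1:20) {
    n <- sample(1:500, 1); chunk <- sample(1:50, 1)
    w <- paginate(n, chunk)
    covered <- unlist(Map(seq, w$start, w$end))
    expect_equal(covered, 1:n)
    expect_true(all(w$end - w$start + 1 <= chunk))
  }
})
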