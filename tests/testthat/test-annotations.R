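test_that("load_annotations binds, validates bounds and rejects bad documents", {
  aln <- read_fasta(">a tiny\nAC-GT\n")
  set <- load_annotations('{"variants":[{"sequence":1,"position":3}]}', aln)
  expect_s3_class(set, "annotation_set")
  expect_length(set$variants, 1)
  expect_equal(set$variants[[1]]$seq_index, 1)

  expect_error(
    load_annotations('{"variants":[{"sequence":1,"position":9}]}', aln),
    "beyond sequence.*4", class = "alnvista_validation_error")
  expect_error(
    load_annotations('{"regions":[{"sequence":1,"start":5,"end":2}]}',
                     aln),
    class = "alnvista_validation_error")
  expect_error(
    load_annotations('{"regions":[{"sequence":1,"start":3,"end":2}]}',
                     aln),
    "start 3 > end 2", class = "alnvista_validation_error")
  expect_error(
    load_annotations('{"variants":[{"sequence":"nobody","position":1}]}',
                     aln),
    "nobody", class = "alnvista_validation_error")
  expect_error(load_annotations('{"variants": [}', aln),
               class = "alnvista_parse_error")
})

test_that("sequence refs accept labels, unknown extra keys survive in attributes", {
  aln <- read_fasta(">x Homo sapiens\nMKCV\n")
  set <- load_annotations(paste0(
    '{"variants":[{"sequence":"Homo sapiens","position":2,',
    '"id":"rs121912606","allele_frequency":"3.98e-6",',
    '"clinical_significance":"pathogenic"}]}'), aln)
  v <- set$variants[[1]]
  expect_equal(v$seq_index, 1)
  expect_equal(v$variant_id, "rs121912606")
  expect_equal(v$attributes$allele_frequency, "3.98e-6")
  expect_equal(v$attributes$clinical_significance, "pathogenic")
})

test_that("global regions use column coordinates and are bounds-checked", {
  aln <- read_fasta(">a\nAC-GT\n")
  set <- load_annotations('{"regions":[{"start":2,"end":5,"label":"dom"}]}',
                          aln)
  expect_true(is.na(set$regions[[1]]$seq_index))
  expect_error(
    load_annotations('{"regions":[{"start":1,"end":6,"label":"dom"}]}', aln),
    class = "alnvista_validation_error")
})

test_that("parse_change handles protein and coding-DNA substitutions", {
  ch <- parse_change("p.C4957Y")
  expect_equal(ch$level, "protein")
  expect_equal(ch$ref, "C")
  expect_equal(ch$position, 4957)
  expect_equal(ch$alt, "Y")

  # whitespace-tolerant, as tokens are often printed with a space
  expect_equal(parse_change("p. C4956Y")$position, 4956)
  expect_equal(parse_change(" p.R79Q ")$position, 79)

  nt <- parse_change("c.88C>G")
  expect_equal(nt$level, "nucleotide")
  expect_equal(nt$position, 88)
  expect_equal(nt$ref, "C")
  expect_equal(nt$alt, "G")

  expect_equal(parse_change("p.K2563*")$alt, "*")

  for (bad in c("p.C4957", "q.C1Y", "c.88C>Z", "p.C19del", "", "p.CxY"))
    expect_error(parse_change(bad), class = "alnvista_parse_error")
})

test_that("a parseable token must agree with the position field", {
  aln <- read_fasta(">a\nMKCV\n")
  expect_error(
    load_annotations('{"variants":[{"sequence":1,"position":2,"token":"p.C3Y"}]}',
                     aln),
    "token", class = "alnvista_validation_error")
  # unparseable tokens are kept as display-only text
  set <- load_annotations(
    '{"variants":[{"sequence":1,"position":2,"token":"p.K2_V4del"}]}', aln)
  expect_null(set$variants[[1]]$change)
})

test_that("index_by_column projects annotations through each gap pattern", {
  aln <- read_fasta(">a\nAC-GT\n")
  set <- load_annotations('{"variants":[{"sequence":1,"position":3}]}', aln)
  idx <- index_by_column(set, aln)
  expect_equal(names(idx$buckets), "4")

  empty <- index_by_column(load_annotations("{}", aln), aln)
  expect_length(empty$buckets, 0)

  # variant and modification at the same residue share one bucket, variant first
  both <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":4}],',
    '"modifications":[{"sequence":1,"position":4,"type":"ub"}]}'), aln)
  idx <- index_by_column(both, aln)
  expect_equal(names(idx$buckets), "5")
  expect_equal(vapply(idx$buckets[["5"]], `[[`, character(1), "kind"),
               c("variant", "modification"))
})

test_that("every positional annotation lands in exactly one bucket", {
  set.seed(17)
  for (i in 1:20) {
    fx <- make_fixture(toy_spec(
      n_sequences = sample(2:6, 1), ungapped_length = sample(20:50, 1),
      gap_rate = runif(1, 0, 0.3), n_variant_pairs = sample(0:3, 1),
      n_lone_variants = sample(0:3, 1), n_modifications = sample(0:4, 1),
      n_regions = 1, seed = i))
    aln <- read_fasta(fx$fasta)
    set <- load_annotations(fx$json, aln)
    idx <- index_by_column(set, aln)
    expect_equal(sum(lengths(idx$buckets)),
                 length(set$variants) + length(set$modifications))
  }
})

test_that("index ordering is deterministic for identical inputs", {
  fx <- make_fixture(toy_spec(seed = 4))
  aln <- read_fasta(fx$fasta)
  i1 <- index_by_column(load_annotations(fx$json, aln), aln)
  i2 <- index_by_column(load_annotations(fx$json, aln), aln)
  expect_identical(i1, i2)
})

test_that("ortho_groups groups only cross-sequence co-located variants", {
  # same native position, different gap patterns: columns 3 vs 4 -> no group
  aln <- toy_two_seq()  # MKCV- / MK-CV
  set <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":3},',
    '{"sequence":2,"position":3}]}'), aln)
  expect_length(ortho_groups(index_by_column(set, aln)), 0)

  # identity mapping: one group in column 3 with 2 members
  aln2 <- read_fasta(">a one\nMKCV\n>b two\nMKCV\n")
  set2 <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":3},',
    '{"sequence":2,"position":3}]}'), aln2)
  g <- ortho_groups(index_by_column(set2, aln2))
  expect_length(g, 1)
  expect_equal(g[[1]]$column, 3)
  expect_length(g[[1]]$members, 2)

  # the gapped counterpart: positions 3 and 4 share column 4
  set3 <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":4},',
    '{"sequence":2,"position":3}]}'), aln)
  g3 <- ortho_groups(index_by_column(set3, aln))
  expect_length(g3, 1)
  expect_equal(g3[[1]]$column, 4)

  # two variants on one sequence never form a group alone
  set4 <- load_annotations(paste0(
    '{"variants":[{"sequence":1,"position":3},',
    '{"sequence":1,"position":3}]}'), aln2)
  expect_length(ortho_groups(index_by_column(set4, aln2)), 0)
})

test_that("validate_changes warns on reference-letter drift, never errors", {
  aln <- read_fasta(">a\nMKCV\n")
  ok <- load_annotations(
    '{"variants":[{"sequence":1,"position":3,"token":"p.C3Y"}]}', aln)
  expect_length(validate_changes(ok, aln), 0)

  drift <- load_annotations(
    '{"variants":[{"sequence":1,"position":3,"token":"p.A3Y"}]}', aln)
  w <- validate_changes(drift, aln)
  expect_length(w, 1)
  expect_match(w, "expects A but the sequence has C")

  display_only <- load_annotations(
    '{"variants":[{"sequence":1,"position":3,"token":"p.C3_V4del"}]}', aln)
  expect_length(validate_changes(display_only, aln), 0)
})
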