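---
title: "Methods: projecting annotations onto alignment columns"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: projecting annotations onto alignment columns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(alnvista)
```

## The model

An alignment is an ordered list of gapped sequences of equal length; a
column is the unit of homology. Annotations — variants, post-translational
modifications, interval regions — arrive in *native* coordinates: the
1-based position of a residue in the ungapped sequence, exactly as
variant databases and HGVS-style tokens report them. The package's
central operation is the change of coordinates between the two systems.

For each sequence we build a position map in one linear scan:
`col_of_pos` (strictly increasing, one entry per residue) and
`pos_of_col` (one entry per column, `NA` at gaps). On non-gap columns the
two arrays are mutually inverse; the number of `NA` sentinels plus the
ungapped length equals the column count. These three properties are
checked as property-style tests over randomly gapped strings.

Native-coordinate input is what makes cross-species comparison work: a
substitution at residue 4957 of a human protein and one at residue 4956
of the mouse orthologue differ in native position, but if the alignment
places them in one column they are the same site. `ortho_groups()`
formalises this: a group is a column whose annotation bucket contains
variants from at least two distinct sequences. Three deliberate
restrictions apply:

* only variants group — a variant co-located with a PTM is visible in the
  shared pop-up bucket but is not called an orthologous pair;
* members must come from pairwise-distinct sequences; when one sequence
  carries several variants in the same column, its first bound variant
  represents it;
* two variants on a single sequence never form a group alone.

## Consensus

The consensus letter of a column is the residue with the highest gap-
exclusive count. Ties are broken alphabetically: the rule is arbitrary
but total, deterministic and easy to state, which matters more for a
viewer than any particular tie philosophy. A gap wins only when the
column is entirely gaps — a residue, even a minority one, is always more
informative to display than a gap. The implementation tallies a residue ×
column count matrix; the test suite compares it against an independently
coded per-column `table()` oracle on hundreds of random alignments
(including forced ties) and against `Biostrings::consensusMatrix`.

## Token parsing and validation

`parse_change()` accepts the two compact substitution forms,
`p.<aa><pos><aa>` and `c.<pos><base>><base>`, with whitespace tolerated
after the prefix because tokens are frequently quoted as `p. C4957Y`.
Everything else — indels, delins, frameshifts — is deliberately out of
grammar and kept as display-only text; a full HGVS parser is a project of
its own and the viewer only needs the position.

Validation is two-tiered. Structural problems (unresolvable sequence
references, out-of-bounds positions, inverted intervals, a parseable
token whose encoded position contradicts the `position` field) are hard
errors at load time. Reference-letter drift — the token says `C` but the
sequence shows `S` — is only a warning, because isoform and
sequence-version mismatches are routine and a viewer that refuses to draw
in that situation would be useless.

## Rendering

Both emitters consume the same resolved plan (scheme, window, exclusions,
cell size) and the same column index, so their annotated-cell sets agree
by construction; the tests assert the cell-count and annotated-cell
contracts on both outputs independently.

The HTML document is fully static: inline CSS only, hover pop-ups via
`:hover` rules, no scripts, no network fetches, no timestamps — repeated
renders are byte-identical. Scroll-driven lazy rendering of the
interactive original maps, in a static tool, to windowing: `paginate()`
partitions columns into consecutive inclusive windows (default chunk 500)
and the `--window A-B` option renders any one of them. Hiding sequences
interactively maps to `--exclude`.

The 13 colour schemes are the classic community palette set (clustal,
clustalx, zappo, taylor, hydrophobicity, helix/strand/turn propensity,
buried index, cinema, lesk, mae, plus one nucleotide scheme). Totality —
every letter of the family alphabet plus the gap has a colour — is an
asserted invariant; unknown letters fall back to a neutral grey at
render time. Default geometry (cell 18 px, label gutter 120 px) keeps a
500-column window under a few megabytes of HTML.

The SVG emitter writes a restricted element set (`rect`, `circle`,
`line`, `text`, `a`), and `rasterize_png()` rasterizes exactly that
subset by replaying it onto a cairo PNG device, with pixel dimensions
`round(svg_dim * dpi / 96)`. Rounded annotated cells become inscribed
discs; glyphs are drawn with the device's monospace font, so rasterized
text metrics are approximate while geometry is exact. Overlapping region
intervals are stacked into lanes by greedy first-fit on start column —
simple, deterministic and visually compact.

## The synthetic-fixture generator

`make_fixture()` produces alignments with *known* answers rather than
realistic evolution. One ancestral sequence (residues uniform over the
20-letter alphabet, or ACGT in nucleotide mode) is copied `n_sequences`
times; each copy receives independent gap insertions at `gap_rate` (gaps
are inserted, never substituted, so every row retains the full ancestral
residue content and planted-position bookkeeping stays exact; the column
count is `ceiling(L / (1 - gap_rate))`). Variant pairs are planted by
choosing two sequences and a fresh column gap-free in both, then
recomputing each sequence's native position through its own gap pattern.
All planted columns are pairwise distinct, so the expected group count is
exactly `n_variant_pairs` with no false groups — this is the ground truth
the recovery tests check across 100 random fixture shapes (gap rates 0 to
0.3). Infeasible requests (more planted columns than residues, or no
shared gap-free column after repeated draws) raise a generation error.

What the generator does *not* emulate: substitution models, phylogenetic
correlation between rows, indel length distributions, alignment-program
artefacts. Passing the recovery tests therefore demonstrates coordinate
bookkeeping is exact, not that the viewer has been exercised against the
quirks of real aligner output.

Default fixture shape (6 sequences × 120 residues, gap rate 0.1, 4
planted pairs, 3 lone variants, 3 modifications, 2 regions) is small
enough to generate in milliseconds while containing every annotation
kind. The throughput test uses 50 sequences × 1000 columns with 200
annotations, rendered to HTML and PNG — sizes chosen to match a large
single-protein-family alignment.

## Numerical and interface choices

* All user-facing coordinates are 1-based and inclusive, matching how
  positions appear in change tokens; sequence indices are 1-based as is
  idiomatic in R (including in the JSON `sequence` field).
* The gap sentinel in `pos_of_col` is `NA`, not 0 or −1, so accidental
  arithmetic on a gap position propagates `NA` instead of silently
  producing a wrong column.
* Out-of-range position searches error (reporting the valid limit) rather
  than clamp: silently jumping to the nearest residue would misreport
  what the user asked for.
* Sequence selectors resolve by index, exact label, exact header, then
  unique case-insensitive label prefix; ambiguity is an error listing the
  candidates.
* Pop-up notes may carry raw HTML (images, links) by design; `sanitize`
  strips tags for untrusted annotation sources.
* CLI exit codes: 0 success, 1 "not found" (failed lookups), 2 usage or
  input errors; warnings never change the exit code.

## Known limitations

No aligner is included — the input must already be aligned. Only
substitution tokens parse; other HGVS forms are display-only. There is no
genomic-to-protein coordinate lifting, no strand handling, and no
alignment-to-alignment projection. Rasterized PNG text uses device font
metrics, so label kerning can differ slightly from an SVG viewer's
rendering.
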