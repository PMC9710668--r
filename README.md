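# alnvista

Annotate and visualize variants on sequence alignments.

## The problem

Pairwise and multiple sequence alignments (PSA/MSA) put homologous
positions of DNA, RNA or protein sequences into shared columns, but the
things biologists know *about* those positions — genetic variants with
their clinical significance and allele frequencies, post-translational
modifications (PTMs), protein domains, CRISPR sgRNA targets — live in
per-sequence coordinates and are hard to co-view on the alignment.
`alnvista` is a scriptable toolkit that joins the two: it reads a FASTA
alignment and a JSON annotation document, projects every annotation onto
its alignment column, and renders the result as self-contained interactive
HTML or as a static SVG/PNG figure.

The projection is the core of the package. For sequence *s* with gapped
letters *L(s)*, the position map is the bijection between 1-based ungapped
residue positions *p* and 1-based alignment columns *c*:

```
col_of_pos[p] = index of the p-th non-gap character of L(s)
pos_of_col[c] = p  if L(s)[c] is the p-th non-gap character, NA at gaps
```

Because annotations are given in native (ungapped) coordinates, a variant
at residue 4957 of a human protein and one at residue 4956 of its mouse
orthologue can land on the *same* column — such cross-species co-located
variants are orthologous variants ("OrthoVars"), and `ortho_groups()`
detects them: one group per column whose annotations include variants
from at least two distinct sequences.

Around that core the package provides a consensus row (per-column
majority residue, alphabetical tie-break, gap only for all-gap columns),
HGVS-style substitution token parsing (`p.C4957Y`, `c.88C>G`), database
cross-links inferred from UniProt/NCBI/Ensembl identifiers, 13 classic
colour schemes, windowed (paged) rendering for large alignments, a
command-line interface, and a deterministic synthetic-fixture generator
with planted ground truth.

## Worked example

The package ships a small synthetic pairwise alignment in which the mouse
sequence lacks the human residue 10, so downstream residue numbers are
offset by one — the classic situation that makes orthologous variants
carry different native positions:

```r
library(alnvista)

fa <- system.file("extdata", "synthetic_pair.fasta", package = "alnvista")
js <- system.file("extdata", "synthetic_pair.json",  package = "alnvista")

aln <- read_fasta(fa)
aln
#> <alignment> 2 sequence(s) x 40 column(s)
#>   [1] Homo sapiens SYNX1 ( MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRV
#>   [2] Mus musculus Synx1 ( MKTAYIAKQ-QISFVKSHFSRQLEERLGLIEVQAPILSRV

set <- load_annotations(js, aln)
set
#> <annotation set> 2 variant(s), 1 modification(s), 1 region(s)

# the human p.S20C and mouse p.S19C variants share alignment column 20:
ortho_groups(index_by_column(set, aln))[[1]]$column
#> [1] 20

# jump to a residue: mouse position 19 sits in column 20
find_position(aln, "Mus", 19)$column
#> [1] 20

# consensus row (both sequences agree everywhere they align)
consensus(aln)$letters
#> [1] "MKTAYIAKQRQISFVKSHFSRQLEERLGLIEVQAPILSRV"

# render: interactive HTML with hover pop-ups, or a static figure
plan <- render_plan(aln, scheme = "clustal")
render_html(aln, set, plan, path = "pair.html")
rasterize_png(render_svg(aln, set, plan), path = "pair.png")
```

The HTML document is fully self-contained (inline CSS, no scripts): the
domain track sits above the grid, modified columns carry a red asterisk,
annotated cells are circled and reveal their variant details on hover,
and row labels link to the sequence database recognised from the FASTA
header.

The same pipeline is available from the shell via the bundled CLI
(`inst/cli/alnvista`):

```sh
alnvista render --fasta pair.fasta --annotations pair.json --out pair.html
alnvista orthovars --fasta pair.fasta --annotations pair.json
#> column  sequence              position  token
#> 20      Homo sapiens SYNX1 (synthetic)  20  p.S20C
#> 20      Mus musculus Synx1 (synthetic)  19  p.S19C
alnvista find --fasta pair.fasta Mus 19
#> Mus musculus Synx1 (synthetic)  19  20
```

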