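#' Specification for a synthetic annotated-alignment fixture
#'
#' Describes a deterministic fixture: an alignment of `n_sequences` copies
#' of one ancestral sequence, each copy receiving independent gap
#' insertions, plus planted annotations with known ground truth. Planted
#' co-located variant pairs are the key feature: each pair occupies one
#' alignment column on two distinct sequences, with positions recomputed
#' through each sequence's own gap pattern — by construction these are the
#' orthologous-variant groups [ortho_groups()] must recover.
#'
#' @param n_sequences number of sequences (>= 2 when pairs are planted).
#' @param ungapped_length residues per sequence (gaps are inserted, not
#'   substituted, so every sequence keeps the full ancestral content).
#' @param gap_rate target fraction of gap characters per row, in `[0, 1)`.
#' @param n_variant_pairs planted co-located variant pairs (ground-truth
#'   groups).
#' @param n_lone_variants variants on columns of their own; never part of
#'   a group.
#' @param n_modifications modifications at random valid positions.
#' @param n_regions interval annotations at random valid spans.
#' @param seed RNG seed; equal seeds give byte-identical fixtures.
#' @param alphabet `"protein"` (uniform over the 20 amino acids) or
#'   `"nucleotide"` (uniform over ACGT).
#' @return A `toy_spec` list.
#' @seealso [make_fixture()]
#' @export
toy_spec <- function(n_sequences = 6L, ungapped_length = 120L,
                     gap_rate = 0.1, n_variant_pairs = 4L,
                     n_lone_variants = 3L, n_modifications = 3L,
                     n_regions = 2L, seed = 1L, alphabet = "protein") {
  counts <- c(n_sequences, ungapped_length, n_variant_pairs,
              n_lone_variants, n_modifications, n_regions)
  if (any(!is.finite(counts)) || any(counts < 0L))
    av_argument_error("all fixture counts must be non-negative")
  if (n_sequences < 1L || ungapped_length < 1L)
    av_argument_error("need at least one sequence and one residue")
  if (gap_rate < 0 || gap_rate >= 1)
    av_argument_error("gap_rate must be in [0, 1)")
  if (n_variant_pairs > 0L && n_sequences < 2L)
    av_argument_error("variant pairs need at least two sequences")
  if (!alphabet %in% c("protein", "nucleotide"))
    av_argument_error("alphabet must be 'protein' or 'nucleotide'")
  structure(list(
    n_sequences = as.integer(n_sequences),
    ungapped_length = as.integer(ungapped_length),
    gap_rate = gap_rate,
    n_variant_pairs = as.integer(n_variant_pairs),
    n_lone_variants = as.integer(n_lone_variants),
    n_modifications = as.integer(n_modifications),
    n_regions = as.integer(n_regions),
    seed = as.integer(seed),
    alphabet = alphabet
  ), class = "toy_spec")
}

#' Generate a synthetic alignment and annotation fixture
#'
#' Builds, fully reproducibly from the spec's seed: (1) a FASTA alignment
#' of gapped copies of a common ancestral sequence; (2) a JSON annotation
#' document with the planted variant pairs, lone variants, modifications
#' and regions; (3) a ground-truth table. All planted variant columns
#' (pair and lone) are pairwise distinct, so the expected
#' [ortho_groups()] output is exactly one group per planted pair and none
#' for the lone variants.
#'
#' @param spec a [toy_spec()].
#' @return A list with `fasta` (text), `json` (text), `truth` (data.frame
#'   with columns `kind`, `group`, `column`, `seq_index`, `label`,
#'   `position`, `token`) and `aln` (the parsed `alignment`).
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "toy_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed)

  residues <- if (spec$alphabet == "protein")
    PROTEIN_ALPHABET[PROTEIN_ALPHABET != "X"] else c("A", "C", "G", "T")
  L <- spec$ungapped_length
  n_cols <- max(L, ceiling(L / (1 - spec$gap_rate)))
  ancestral <- sample(residues, L, replace = TRUE)

  rows <- vector("list", spec$n_sequences)
  for (i in seq_len(spec$n_sequences)) {
    gap_cols <- if (n_cols > L) sort(sample.int(n_cols, n_cols - L)) else integer(0)
    row <- character(n_cols)
    row[] <- "-"
    row[setdiff(seq_len(n_cols), gap_cols)] <- ancestral
    rows[[i]] <- row
  }
  headers <- sprintf("synthetic%02d Synthetic organism %d",
                     seq_len(spec$n_sequences), seq_len(spec$n_sequences))
  letters <- vapply(rows, paste0, character(1), collapse = "")
  aln <- new_alignment(headers, letters)
  maps <- lapply(seq_len(spec$n_sequences), function(i) position_map(aln, i))

  n_planted <- spec$n_variant_pairs + spec$n_lone_variants
  if (n_planted > spec$ungapped_length)
    av_argument_error(sprintf(
      "infeasible fixture: %d planted variant columns requested but sequences hold only %d residues",
      n_planted, spec$ungapped_length))
  nongap_cols <- lapply(maps, function(m) which(!is.na(m$pos_of_col)))
  used_cols <- integer(0)
  # pick the sequences first, then a fresh column gap-free in all of them;
  # every planted column (pair or lone) is distinct, so the expected group
  # count is exact by construction
  plant_column <- function(n_seqs) {
    for (try in 1:50) {
      seqs <- sample.int(spec$n_sequences, n_seqs)
      cand <- Reduce(intersect, nongap_cols[seqs])
      cand <- setdiff(cand, used_cols)
      if (length(cand) > 0L) {
        col <- cand[sample.int(length(cand), 1L)]
        used_cols <<- c(used_cols, col)
        return(list(seqs = seqs, col = col))
      }
    }
    av_argument_error(
      "infeasible fixture: could not place all planted variant columns on gap-free sites")
  }

  mutate_token <- function(i, col) {
    pos <- maps[[i]]$pos_of_col[col]
    ref <- substr(aln$letters[i], col, col)
    alt <- sample(setdiff(residues, ref), 1L)
    if (spec$alphabet == "protein")
      list(pos = pos, token = sprintf("p.%s%d%s", ref, pos, alt))
    else
      list(pos = pos, token = sprintf("c.%d%s>%s", pos, ref, alt))
  }

  variants <- list()
  truth <- list()
  add_truth <- function(kind, group, column, i, pos, token)
    truth[[length(truth) + 1L]] <<- data.frame(
      kind = kind, group = group, column = column, seq_index = i,
      label = aln$labels[i], position = pos, token = token,
      stringsAsFactors = FALSE)

  for (g in seq_len(spec$n_variant_pairs)) {
    pl <- plant_column(2L)
    for (i in pl$seqs) {
      mt <- mutate_token(i, pl$col)
      variants[[length(variants) + 1L]] <- list(
        sequence = i, position = mt$pos, token = mt$token,
        source = "planted", note = sprintf("planted pair %d", g))
      add_truth("pair", g, pl$col, i, mt$pos, mt$token)
    }
  }
  for (j in seq_len(spec$n_lone_variants)) {
    pl <- plant_column(1L)
    mt <- mutate_token(pl$seqs, pl$col)
    variants[[length(variants) + 1L]] <- list(
      sequence = pl$seqs, position = mt$pos, token = mt$token,
      source = "planted", note = sprintf("lone variant %d", j))
    add_truth("lone", NA_integer_, pl$col, pl$seqs, mt$pos, mt$token)
  }

  modifications <- lapply(seq_len(spec$n_modifications), function(j) {
    i <- sample.int(spec$n_sequences, 1L)
    list(sequence = i, position = sample.int(L, 1L),
         type = sample(c("phosphorylation", "ubiquitination",
                         "methylation", "acetylation"), 1L),
         note = sprintf("planted modification %d", j))
  })
  regions <- lapply(seq_len(spec$n_regions), function(j) {
    i <- sample.int(spec$n_sequences, 1L)
    a <- sort(sample.int(L, 2L))
    list(sequence = i, start = a[1L], end = a[2L],
         label = sprintf("domain %d", j))
  })

  json <- jsonlite::toJSON(
    list(variants = variants, modifications = modifications,
         regions = regions),
    auto_unbox = TRUE, pretty = TRUE)
  truth_df <- if (length(truth)) do.call(rbind, truth) else
    data.frame(kind = character(0), group = integer(0), column = integer(0),
               seq_index = integer(0), label = character(0),
               position = integer(0), token = character(0),
               stringsAsFactors = FALSE)

  list(fasta = write_fasta(aln), json = as.character(json),
       truth = truth_df, aln = aln)
}
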