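# Fixture builders and independent oracles used across the suite.

AA20 <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")

random_gapped_string <- function(len, gap_rate = 0.3) {
  paste(sample(c(AA20, rep("-", ceiling(length(AA20) * gap_rate / (1 - gap_rate)))),
               len, replace = TRUE), collapse = "")
}

random_alignment <- function(n_seq = NULL, n_col = NULL, gap_rate = 0.2) {
  if (is.null(n_seq)) n_seq <- sample(1:10, 1)
  if (is.null(n_col)) n_col <- sample(1:50, 1)
  letters <- replicate(n_seq, random_gapped_string(n_col, gap_rate))
  new_alignment(sprintf("rand%02d random sequence %d", seq_len(n_seq),
                        seq_len(n_seq)), letters)
}

# Independent consensus oracle: per-column table() tally, ties broken by
# taking the alphabetically first winner, all-gap columns give '-'.
oracle_consensus <- function(aln) {
  mat <- do.call(rbind, strsplit(aln$letters, "", fixed = TRUE))
  paste(vapply(seq_len(ncol(mat)), function(j) {
    chars <- mat[, j]
    chars <- chars[chars != "-"]
    if (length(chars) == 0) return("-")
    tb <- table(chars)
    sort(names(tb)[tb == max(tb)])[1]
  }, character(1)), collapse = "")
}

toy_two_seq <- function() {
  read_fasta(">first Homo sapiens\nMKCV-\n>second Mus musculus\nMK-CV\n")
}

# Run the CLI in-process, capturing exit code and both streams.
run_cli <- function(args) {
  stderr_lines <- character(0)
  stdout_lines <- capture.output(
    code <- withCallingHandlers(
      cli_main(args),
      message = function(m) {
        stderr_lines <<- c(stderr_lines, sub("\n$", "", conditionMessage(m)))
        invokeRestart("muffleMessage")
      }))
  list(code = code, stdout = stdout_lines, stderr = stderr_lines)
}

count_matches <- function(pattern, text) {
  m <- gregexpr(pattern, text, fixed = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1) 0L else length(m)
}
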