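#' Parse an HGVS-like substitution token
#'
#' Supports the two compact substitution forms commonly attached to
#' alignment annotations: protein (`p.C4957Y`) and coding-DNA (`c.88C>G`).
#' Whitespace around and after the `p.`/`c.` prefix is tolerated, so the
#' spaced form `p. C4957Y` parses too. Protein letters are restricted to
#' the 20 amino-acid one-letter codes plus `X` and `*`; bases to `ACGTU`.
#' Anything else (indels, delins, frameshifts) is rejected and should be
#' kept as display-only text by the caller.
#'
#' @param token the token text.
#' @return An object of class `sequence_change`: list with `level`
#'   (`"protein"` or `"nucleotide"`), `ref`, `position` (1-based integer)
#'   and `alt`.
#' @examples
#' parse_change("p.C4957Y")$position  # 4957
#' parse_change("c.88C>G")$ref        # "C"
#' @export
parse_change <- function(token) {
  if (!is.character(token) || length(token) != 1L || is.na(token))
    av_parse_error("change token must be a single string")
  tok <- trimws(token)
  aa <- "[ACDEFGHIKLMNPQRSTVWYX*]"
  m <- regmatches(tok, regexec(
    sprintf("^p\\.\\s*(%s)([0-9]+)(%s)$", aa, aa), tok))[[1L]]
  if (length(m) == 4L)
    return(structure(list(level = "protein", ref = m[2L],
                          position = as.integer(m[3L]), alt = m[4L]),
                     class = "sequence_change"))
  m <- regmatches(tok, regexec("^c\\.\\s*([0-9]+)([ACGTU])>([ACGTU])$", tok))[[1L]]
  if (length(m) == 4L)
    return(structure(list(level = "nucleotide", ref = m[3L],
                          position = as.integer(m[2L]), alt = m[4L]),
                     class = "sequence_change"))
  av_parse_error(sprintf(
    "cannot parse change token '%s' (expected p.<aa><pos><aa> or c.<pos><base>><base>)",
    token))
}

#' @export
print.sequence_change <- function(x, ...) {
  cat(sprintf("<%s change> %s%d%s\n", x$level, x$ref, x$position, x$alt))
  invisible(x)
}
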