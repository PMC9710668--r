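# Colour-scheme registry. Twelve protein palettes plus one nucleotide
# palette, the classic viewer set. Every scheme is total over its family
# alphabet plus the gap character; totality is asserted by the test suite
# over the whole registry.

PROTEIN_ALPHABET <- c("A","C","D","E","F","G","H","I","K","L","M","N","P",
                      "Q","R","S","T","V","W","Y","X")
NUCLEOTIDE_ALPHABET <- c("A","C","G","T","U","N")
GAP_COLOR <- "#ffffff"

scheme_def <- function(name, family, colors) {
  alphabet <- if (family == "protein") PROTEIN_ALPHABET else NUCLEOTIDE_ALPHABET
  colors["-"] <- GAP_COLOR
  missing <- setdiff(c(alphabet, "-"), names(colors))
  if (length(missing) > 0)
    stop(sprintf("scheme %s misses letters: %s", name,
                 paste(missing, collapse = ",")))
  structure(list(name = name, family = family,
                 colors = colors[c(alphabet, "-")]),
            class = "color_scheme")
}

# expand group definitions ("AILM" = one color) into per-letter maps
groups <- function(..., default = "#ffffff") {
  spec <- c(...)
  out <- character(0)
  for (k in names(spec))
    for (ch in strsplit(k, "", fixed = TRUE)[[1L]]) out[ch] <- spec[[k]]
  structure(out, default = default)
}

fill_total <- function(cols, alphabet) {
  default <- attr(cols, "default") %||% "#ffffff"
  out <- stats::setNames(rep(default, length(alphabet)), alphabet)
  out[names(cols)[names(cols) %in% alphabet]] <-
    cols[names(cols) %in% alphabet]
  out
}

protein_scheme <- function(name, cols)
  scheme_def(name, "protein", fill_total(cols, PROTEIN_ALPHABET))
nucleotide_scheme <- function(name, cols)
  scheme_def(name, "nucleotide", fill_total(cols, NUCLEOTIDE_ALPHABET))

build_registry <- function() {
  list(
    clustal = protein_scheme("clustal", groups(
      "AILMFWV" = "#80a0f0", "KR" = "#f01505", "ED" = "#c048c0",
      "NQST" = "#15c015", "C" = "#f08080", "G" = "#f09048",
      "P" = "#c0c000", "HY" = "#15a4a4")),
    clustalx = protein_scheme("clustalx", groups(
      "ACILMFWV" = "#197fe5", "KR" = "#e53319", "DE" = "#c04cc0",
      "NQST" = "#19cc19", "G" = "#e5994c", "P" = "#cccc00",
      "HY" = "#19b2b2")),
    zappo = protein_scheme("zappo", groups(
      "ILVAM" = "#ffafaf", "FWY" = "#ffc800", "KRH" = "#6464ff",
      "DE" = "#ff0000", "STNQ" = "#00ff00", "PG" = "#ff00ff",
      "C" = "#ffff00")),
    taylor = protein_scheme("taylor", groups(
      "A" = "#ccff00", "V" = "#99ff00", "I" = "#66ff00", "L" = "#33ff00",
      "M" = "#00ff00", "F" = "#00ff66", "Y" = "#00ffcc", "W" = "#00ccff",
      "H" = "#0066ff", "R" = "#0000ff", "K" = "#6600ff", "N" = "#cc00ff",
      "Q" = "#ff00cc", "E" = "#ff0066", "D" = "#ff0000", "S" = "#ff3300",
      "T" = "#ff6600", "G" = "#ff9900", "P" = "#ffcc00", "C" = "#ffff00")),
    hydrophobicity = protein_scheme("hydrophobicity", groups(
      "I" = "#ff0000", "V" = "#f60009", "L" = "#ea0015", "F" = "#cb0034",
      "C" = "#c2003d", "M" = "#b0004f", "A" = "#ad0052", "G" = "#6a0095",
      "X" = "#680097", "T" = "#61009e", "S" = "#5e00a1", "W" = "#5b00a4",
      "Y" = "#4f00b0", "P" = "#4600b9", "H" = "#1500ea", "E" = "#0c00f3",
      "Q" = "#0c00f3", "D" = "#0c00f3", "N" = "#0c00f3", "K" = "#0000ff",
      "R" = "#0000ff")),
    `helix-propensity` = protein_scheme("helix-propensity", groups(
      "E" = "#ff00ff", "M" = "#ef10ef", "A" = "#e718e7", "L" = "#ae51ae",
      "K" = "#a05fa0", "F" = "#986798", "Q" = "#926d92", "I" = "#8a758a",
      "W" = "#8a758a", "V" = "#857a85", "D" = "#778877", "X" = "#758a75",
      "H" = "#708f70", "R" = "#6f906f", "T" = "#38c738", "S" = "#36c936",
      "C" = "#23dc23", "Y" = "#21de21", "N" = "#1be41b", "G" = "#00ff00",
      "P" = "#00ff00")),
    `strand-propensity` = protein_scheme("strand-propensity", groups(
      "V" = "#ffff00", "I" = "#ecec13", "Y" = "#d3d31f", "C" = "#a2a24c",
      "W" = "#c0c030", "F" = "#c8c832", "T" = "#9d9d59", "X" = "#797982",
      "L" = "#b2b24c", "M" = "#82827d", "Q" = "#8c8c73", "R" = "#6b6b94",
      "N" = "#64649b", "H" = "#60609f", "A" = "#5858a7", "S" = "#4949b6",
      "G" = "#4949b6", "K" = "#4747b8", "P" = "#2323dc", "D" = "#2121de",
      "E" = "#0000ff")),
    `turn-propensity` = protein_scheme("turn-propensity", groups(
      "N" = "#ff0000", "G" = "#ff0000", "P" = "#f60409", "D" = "#e81b17",
      "S" = "#e11e1e", "C" = "#a85757", "Y" = "#9d9d62", "K" = "#7e7e81",
      "X" = "#7c7c83", "Q" = "#778888", "W" = "#738888", "T" = "#738c8c",
      "R" = "#708f8f", "H" = "#708f8f", "E" = "#5f5fa0", "A" = "#5c5ca3",
      "F" = "#5858a7", "M" = "#4d4db2", "L" = "#1c1ce3", "V" = "#0707f8",
      "I" = "#0000ff")),
    `buried-index` = protein_scheme("buried-index", groups(
      "C" = "#0000ff", "I" = "#0054ab", "V" = "#005fa0", "L" = "#007b84",
      "F" = "#008778", "M" = "#009768", "G" = "#009d62", "A" = "#00a35c",
      "W" = "#00a857", "X" = "#00b649", "S" = "#00d52a", "H" = "#00d52a",
      "T" = "#00db24", "P" = "#00e01f", "Y" = "#00e619", "N" = "#00eb14",
      "D" = "#00eb14", "Q" = "#00f10e", "E" = "#00f10e", "R" = "#00fc03",
      "K" = "#00ff00")),
    cinema = protein_scheme("cinema", groups(
      "HKR" = "#00ffff", "DE" = "#ff0000", "STNQ" = "#00ff00",
      "AVLIM" = "#ffffff", "FWY" = "#ff00ff", "PG" = "#996600",
      "C" = "#ffff00", "X" = "#bebebe")),
    lesk = protein_scheme("lesk", groups(
      "GAST" = "#ffa500", "CVILPFYMW" = "#00ff00", "NQH" = "#ff00ff",
      "DE" = "#ff0000", "KR" = "#0000ff", "X" = "#bebebe")),
    mae = protein_scheme("mae", groups(
      "ALVIMF" = "#77dd88", "GP" = "#99ee66", "ST" = "#66bb77",
      "NQ" = "#55bb33", "C" = "#99ee66", "DE" = "#55bb33",
      "KRH" = "#5599ff", "WY" = "#9999ff", "X" = "#aaaaaa")),
    nucleotide = nucleotide_scheme("nucleotide", groups(
      "A" = "#64f73f", "C" = "#ffb340", "G" = "#eb413c", "TU" = "#3c88ee",
      "N" = "#bebebe"))
  )
}

SCHEME_REGISTRY <- build_registry()

#' List the predefined colour schemes
#'
#' The registry holds 13 schemes: twelve protein palettes (clustal,
#' clustalx, zappo, taylor, hydrophobicity, helix-propensity,
#' strand-propensity, turn-propensity, buried-index, cinema, lesk, mae)
#' and one nucleotide palette. Order is fixed.
#'
#' @return Character vector of the 13 scheme names.
#' @export
list_schemes <- function() names(SCHEME_REGISTRY)

#' Retrieve a colour scheme by name
#'
#' @param name scheme name; matching is case-insensitive.
#' @return A `color_scheme`: list with `name`, `family` (`"protein"` or
#'   `"nucleotide"`) and `colors`, a named map from every letter of the
#'   family alphabet plus `-` to a CSS colour.
#' @export
get_scheme <- function(name) {
  if (!is.character(name) || length(name) != 1L || is.na(name))
    av_argument_error("scheme name must be a single string")
  hit <- match(tolower(name), names(SCHEME_REGISTRY))
  if (is.na(hit))
    av_argument_error(sprintf("unknown colour scheme '%s'; valid schemes: %s",
                              name, paste(list_schemes(), collapse = ", ")))
  SCHEME_REGISTRY[[hit]]
}

scheme_color <- function(scheme, letter) {
  col <- scheme$colors[letter]
  ifelse(is.na(col), "#dddddd", col)
}
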