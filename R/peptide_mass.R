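# Standard amino-acid residue masses (g/mol): monoisotopic and average.
RESIDUE_MASS_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

RESIDUE_MASS_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)

WATER_MONO <- 18.010565
WATER_AVG  <- 18.01528
ACETYL_MONO <- 42.010565
ACETYL_AVG  <- 42.0367

#' Peptide mass from a one-letter sequence
#'
#' Sum of residue masses plus one water, plus the N-terminal modification
#' mass when requested (acetyl adds 42.01057 Da monoisotopic). Synthetic
#' titration peptides are often N-terminally acetylated, but the default is
#' the free peptide: vendor-printed masses frequently correspond to the
#' unmodified monoisotopic sum, so check which form a printed mass refers
#' to before comparing. Rounding happens only at display; the returned
#' value is exact to the mass table.
#'
#' @param sequence One-letter amino-acid sequence (20 standard residues).
#' @param n_terminal `"free"` (default) or `"acetyl"`.
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return Mass in g/mol.
#' @export
#' @examples
#' peptide_mass("MFRDFDYIADWC") # 1580.64
peptide_mass <- function(sequence, n_terminal = c("free", "acetyl"),
                         kind = c("monoisotopic", "average")) {
  n_terminal <- match.arg(n_terminal)
  kind <- match.arg(kind)
  if (!is.character(sequence) || length(sequence) != 1L ||
      nchar(sequence) == 0) {
    abort("sequence must be a non-empty one-letter string")
  }
  aa <- strsplit(toupper(sequence), "")[[1]]
  tab <- if (kind == "monoisotopic") RESIDUE_MASS_MONO else RESIDUE_MASS_AVG
  bad <- which(!aa %in% names(tab))
  if (length(bad)) {
    abort(paste0("illegal residue '", aa[bad[1]], "' at position ", bad[1]))
  }
  m <- sum(tab[aa]) + if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  if (n_terminal == "acetyl") {
    m <- m + if (kind == "monoisotopic") ACETYL_MONO else ACETYL_AVG
  }
  unname(m)
}
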