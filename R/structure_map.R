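#' Write per-residue CSP values into a PDB B-factor column
#'
#' Paints per-residue perturbations onto a structure for colour-gradient
#' visualisation: every atom of a mapped residue gets the residue's value
#' in the B-factor field (columns 61-66 of ATOM/HETATM records). With
#' `scale = "max"` values are scaled linearly to \[0, 99.99\]
#' (`value / max * 99.99`), matching relative colour gradients; with
#' `scale = "raw"` values are written as-is. Residues of the chain without
#' a value get the sentinel (default -1.00, a distinct "no data" class that
#' viewers can colour gray) under `missing_policy = "gray-sentinel"`, or
#' keep their original B-factors under `"skip"`. Everything outside the
#' touched B-factor fields is byte-preserved, so coordinates, headers and
#' connectivity survive untouched.
#'
#' @param pdb_in Input PDB file path.
#' @param values Named numeric vector (names = residue indices) or a data
#'   frame with columns `residue_index`, `value`; values finite, >= 0.
#' @param pdb_out Output PDB file path.
#' @param chain Chain identifier to annotate.
#' @param offset Numbering offset added to the residue indices of `values`
#'   before matching the structure numbering.
#' @param missing_policy `"gray-sentinel"` (default) or `"skip"`.
#' @param scale `"max"` (default) or `"raw"`.
#' @param sentinel B-factor written for unmapped residues (default -1).
#' @return `pdb_out`, invisibly.
#' @export
map_to_bfactor <- function(pdb_in, values, pdb_out, chain = "A",
                           offset = 0L,
                           missing_policy = c("gray-sentinel", "skip"),
                           scale = c("max", "raw"), sentinel = -1.0) {
  missing_policy <- match.arg(missing_policy)
  scale <- match.arg(scale)
  if (is.data.frame(values)) {
    values <- setNames(values$value, values$residue_index)
  }
  vals <- as.double(values)
  if (length(vals) == 0) abort("no residue overlap: empty value map")
  if (any(!is.finite(vals)) || any(vals < 0)) {
    abort("values must be finite and >= 0")
  }
  resid_map <- as.integer(names(values)) + as.integer(offset)
  if (scale == "max" && max(vals) > 0) vals <- vals / max(vals) * 99.99
  names(vals) <- resid_map

  lines <- readLines(pdb_in, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  rec_chain <- substr(lines, 22, 22)
  rec_resid <- suppressWarnings(as.integer(substr(lines, 23, 26)))
  on_chain <- is_atom & rec_chain == chain
  if (!any(on_chain)) abort(paste0("chain '", chain, "' absent from ", pdb_in))
  mapped <- on_chain & rec_resid %in% resid_map
  if (!any(mapped)) abort("no residue overlap after offset correction")

  put_b <- function(ln, b) {
    b <- sprintf("%6.2f", b)
    if (nchar(b) > 6) b <- substr(b, 1, 6)
    paste0(substr(ln, 1, 60), b, substr(ln, 67, nchar(ln)))
  }
  lines[mapped] <- mapply(put_b, lines[mapped],
                          vals[as.character(rec_resid[mapped])])
  if (missing_policy == "gray-sentinel") {
    unmapped <- on_chain & !mapped
    lines[unmapped] <- vapply(lines[unmapped], put_b, character(1),
                              b = sentinel)
  }
  writeLines(lines, pdb_out)
  invisible(pdb_out)
}
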