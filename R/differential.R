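#' Differential CSP between two matched conditions
#'
#' Residue-by-residue weighted shift difference between two conditions of
#' the same construct — e.g. an isolated domain versus the same domain
#' inside a tandem construct, apo versus apo, or complex versus complex.
#' The statistic is the same weighted CSP applied to the inter-condition
#' shift differences, so it is symmetric: swapping A and B changes nothing.
#' Residues missing from either condition (or missing a resonance) are kept
#' in the result but marked not comparable, with `NA` delta — absence of a
#' peak is not evidence of absence of change.
#'
#' @param table_A,table_B [shift_table()] objects for the two conditions.
#' @param nitrogen_scale Weighting divisor, see [weighted_csp()].
#' @param offset_B Numbering offset applied to `table_B` before matching,
#'   for constructs whose assignments are renumbered by a constant.
#' @param rule A [selection_rule()] applied to the comparable deltas to call
#'   the significant set (threshold mode by default).
#' @return A tibble of class `csp_diff` with columns `residue_index`,
#'   `delta` (ppm), `comparable`, `significant`; the rule is an attribute.
#' @export
compare_conditions <- function(table_A, table_B, nitrogen_scale = 5,
                               offset_B = 0L, rule = selection_rule()) {
  table_B <- apply_offset(table_B, offset_B)
  j <- dplyr::full_join(
    dplyr::select(table_A, "residue_index", type_A = "residue_type",
                  H_A = "shift_H", N_A = "shift_N"),
    dplyr::select(table_B, "residue_index", type_B = "residue_type",
                  H_B = "shift_H", N_B = "shift_N"),
    by = "residue_index")
  shared <- !is.na(j$H_A) & !is.na(j$N_A) & !is.na(j$H_B) & !is.na(j$N_B)
  if (!any(shared)) abort("conditions share no comparable residue")
  mism <- shared & !is.na(j$type_A) & !is.na(j$type_B) &
    j$type_A != "X" & j$type_B != "X" & j$type_A != j$type_B
  if (any(mism)) {
    warn(paste0("residue type mismatch at index ",
                paste(j$residue_index[mism], collapse = ", "),
                " (matching by index only)"))
  }
  delta <- ifelse(shared,
                  weighted_csp(ifelse(shared, j$H_A - j$H_B, 0),
                               ifelse(shared, j$N_A - j$N_B, 0),
                               nitrogen_scale),
                  NA_real_)
  out <- tibble(residue_index = j$residue_index, delta = delta,
                comparable = shared)
  out <- dplyr::arrange(out, .data$residue_index)
  sig <- tryCatch(
    apply_rule(tibble(residue_index = out$residue_index, csp = out$delta),
               rule),
    error = function(e) integer(0))
  out$significant <- out$residue_index %in% sig
  attr(out, "rule") <- rule
  attr(out, "nitrogen_scale") <- nitrogen_scale
  class(out) <- c("csp_diff", class(tibble()))
  out
}

#' Extract an interface/allosteric patch from a differential-CSP result
#'
#' Returns the significant residues minus a user-supplied exclusion list —
#' typically the canonical binding-cleft residues, known from prior
#' structural work, so that the remaining patch reflects perturbation
#' outside the cleft (a candidate inter-domain interface or allosteric
#' surface suitable for docking restraints).
#'
#' @param result A `csp_diff` from [compare_conditions()].
#' @param exclude Integer residue indices to remove (e.g. cleft residues).
#' @return Sorted integer vector; empty with a warning when nothing
#'   survives.
#' @export
interface_patch <- function(result, exclude = integer(0)) {
  sig <- result$residue_index[result$significant]
  patch <- sort(setdiff(sig, as.integer(exclude)))
  if (length(patch) == 0) warn("interface patch is empty")
  patch
}

#' @rdname compare_conditions
#' @param x A `csp_diff` object.
#' @param ... Unused.
#' @method tidy csp_diff
#' @export
tidy.csp_diff <- function(x, ...) {
  as_tibble(x)[c("residue_index", "delta", "comparable", "significant")]
}

#' Write a differential-CSP report as CSV
#'
#' Columns: `residue_index`, `delta_ppm` (6 decimals), `significant`,
#' `comparable`.
#'
#' @param result A `csp_diff`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_diff_report <- function(result, path) {
  out <- tibble(residue_index = result$residue_index,
                delta_ppm = ifelse(is.na(result$delta), "",
                                   sprintf("%.6f", result$delta)),
                significant = result$significant,
                comparable = result$comparable)
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}
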