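#' Assemble a titration series
#'
#' A titration series is the ordered set of sample conditions of one
#' protein-ligand titration: the apo reference (ligand:protein ratio 0)
#' followed by points of increasing total ligand concentration, each carrying
#' its HSQC-derived [shift_table()]. Concentrations are in mM throughout;
#' the ligand concentration may be given explicitly or derived as
#' `molar_ratio * protein_conc`.
#'
#' @param tables List of [shift_table()] objects, one per titration point.
#' @param protein_conc Total protein concentration (mM), either a scalar
#'   (constant across points, the default assumption — dilution on ligand
#'   addition is ignored) or one value per point.
#' @param molar_ratio Ligand:protein molar ratios (dimensionless, >= 0).
#'   Optional when `ligand_conc` is given.
#' @param ligand_conc Total ligand concentrations (mM). Optional when
#'   `molar_ratio` is given; when both are given they must agree to a
#'   relative tolerance of 1e-6.
#' @param protein_name,ligand_sequence Metadata: construct name and
#'   one-letter peptide sequence.
#'
#' @return A tibble of class `titration_series` with columns `molar_ratio`,
#'   `protein_conc`, `ligand_conc` and a `table` list-column, sorted by
#'   ascending ligand concentration; `protein_name` and `ligand_sequence`
#'   are attributes.
#' @export
titration_series <- function(tables, protein_conc, molar_ratio = NULL,
                             ligand_conc = NULL, protein_name = "protein",
                             ligand_sequence = "") {
  n <- length(tables)
  protein_conc <- rep_len(as.double(protein_conc), n)
  if (any(protein_conc <= 0)) abort("protein_conc must be > 0")
  if (is.null(ligand_conc) && is.null(molar_ratio)) {
    abort("give molar_ratio or ligand_conc")
  }
  if (is.null(ligand_conc)) ligand_conc <- molar_ratio * protein_conc
  if (is.null(molar_ratio)) molar_ratio <- ligand_conc / protein_conc
  ligand_conc <- as.double(ligand_conc)
  molar_ratio <- as.double(molar_ratio)
  if (any(ligand_conc < 0)) abort("ligand_conc must be >= 0")
  rel <- abs(ligand_conc - molar_ratio * protein_conc) /
    pmax(ligand_conc, .Machine$double.eps)
  if (any(ligand_conc > 0 & rel > 1e-6)) {
    abort("ligand_conc inconsistent with molar_ratio * protein_conc")
  }
  pts <- tibble(molar_ratio = molar_ratio, protein_conc = protein_conc,
                ligand_conc = ligand_conc, table = tables)
  pts <- dplyr::arrange(pts, .data$ligand_conc)
  attr(pts, "protein_name") <- protein_name
  attr(pts, "ligand_sequence") <- ligand_sequence
  class(pts) <- c("titration_series", class(tibble()))
  validate_titration_series(pts)
}

validate_titration_series <- function(series) {
  if (nrow(series) < 3L) {
    abort("at least 3 titration points are required for fitting")
  }
  if (series$ligand_conc[1] != 0) {
    abort("apo reference required: first point must have ligand_conc = 0")
  }
  idx <- purrr::map(series$table, "residue_index")
  if (length(Reduce(intersect, idx)) == 0L) {
    abort("titration points share no common residue")
  }
  series
}

#' @export
print.titration_series <- function(x, ...) {
  cat("<titration_series>", attr(x, "protein_name"), "+",
      attr(x, "ligand_sequence"), "-", nrow(x), "points\n")
  NextMethod()
}

#' Read a titration-series manifest
#'
#' The manifest is a YAML file describing one titration: fields
#' `protein_name`, `ligand_sequence`, `protein_conc_mM`, optional
#' `numbering_offset`, and `points`, a list of entries each with
#' `molar_ratio` or `ligand_conc_mM` plus `table` (a shift-table CSV path,
#' relative to the manifest) and optional `format`. Points are sorted by
#' ligand concentration; an apo point (ratio 0) is required.
#'
#' @param path Manifest file path.
#' @return A [titration_series()].
#' @export
read_series_manifest <- function(path) {
  if (!file.exists(path)) abort(paste0("no such manifest: ", path))
  m <- yaml::read_yaml(path)
  need <- c("protein_name", "ligand_sequence", "protein_conc_mM", "points")
  missing <- setdiff(need, names(m))
  if (length(missing)) {
    abort(paste0("manifest lacks field(s): ", paste(missing, collapse = ", ")))
  }
  if (length(m$points) < 3L) abort("at least 3 titration points are required")
  offset <- as.integer(m$numbering_offset %||% 0L)
  dir <- dirname(path)
  pts <- purrr::map(m$points, function(p) {
    if (is.null(p$table)) abort("every manifest point needs a table path")
    tp <- p$table
    if (!file.exists(tp)) tp <- file.path(dir, p$table)
    if (!file.exists(tp)) abort(paste0("unreadable table path: ", p$table))
    list(
      molar_ratio = if (!is.null(p$molar_ratio)) as.double(p$molar_ratio),
      ligand_conc = if (!is.null(p$ligand_conc_mM)) as.double(p$ligand_conc_mM),
      table = read_shift_table(tp, format = p$format %||% "wide-csv",
                               offset = offset)
    )
  })
  P <- as.double(m$protein_conc_mM)
  mr <- purrr::map(pts, "molar_ratio")
  lc <- purrr::map(pts, "ligand_conc")
  if (any(purrr::map_lgl(mr, is.null) & purrr::map_lgl(lc, is.null))) {
    abort("every point needs molar_ratio or ligand_conc_mM")
  }
  lig <- purrr::map2_dbl(mr, lc, function(r, l) l %||% (r * P))
  rat <- purrr::map2_dbl(mr, lc, function(r, l) r %||% (l / P))
  if (!any(lig == 0)) abort("apo reference required (a point with ratio 0)")
  titration_series(purrr::map(pts, "table"), protein_conc = P,
                   molar_ratio = rat, ligand_conc = lig,
                   protein_name = m$protein_name,
                   ligand_sequence = m$ligand_sequence)
}

#' Write a titration series to disk as manifest plus shift-table CSVs
#'
#' Inverse of [read_series_manifest()]: writes one wide-csv shift table per
#' point and a `manifest.yaml` referencing them.
#'
#' @param series A [titration_series()].
#' @param dir Output directory (created if needed).
#' @return Path of the written manifest, invisibly.
#' @export
write_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("point_%02d.csv", seq_len(nrow(series)))
  purrr::walk2(series$table, files,
               ~ write_shift_table(.x, file.path(dir, .y)))
  m <- list(
    protein_name = attr(series, "protein_name"),
    ligand_sequence = attr(series, "ligand_sequence"),
    protein_conc_mM = series$protein_conc[1],
    points = purrr::map2(series$molar_ratio, files,
                         ~ list(molar_ratio = .x, table = .y))
  )
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m, path)
  invisible(path)
}
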