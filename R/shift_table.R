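#' Build a per-residue chemical shift table
#'
#' A shift table holds one backbone amide resonance per residue for a single
#' sample condition (one 2D 1H-15N HSQC peak list): the amide proton shift
#' (`shift_H`, ppm) and the amide nitrogen shift (`shift_N`, ppm). Missing
#' resonances (prolines, overlapped or broadened peaks) are `NA`, never 0 —
#' 0 ppm is a legal chemical shift.
#'
#' @param residue_index Integer residue sequence positions (>= 1, unique).
#' @param residue_type One-letter amino-acid codes (or `"X"` for unknown).
#'   Prolines have no backbone amide, so a `"P"` row must carry `NA` shifts.
#' @param shift_H,shift_N Chemical shifts in ppm; `NA` = missing.
#' @param label Condition name, e.g. `"apo"` or `"ratio_1_10"`.
#'
#' @return A tibble of class `shift_table` with columns `residue_index`,
#'   `residue_type`, `shift_H`, `shift_N` and a `label` attribute.
#' @export
#' @examples
#' shift_table(c(19L, 20L), c("L", "T"), c(8.21, 7.95), c(121.4, 110.2))
shift_table <- function(residue_index, residue_type = "X",
                        shift_H = NA_real_, shift_N = NA_real_,
                        label = "condition") {
  tbl <- tibble(
    residue_index = as.integer(residue_index),
    residue_type  = as.character(residue_type),
    shift_H       = as.double(shift_H),
    shift_N       = as.double(shift_N)
  )
  new_shift_table(tbl, label = label)
}

new_shift_table <- function(tbl, label = "condition") {
  tbl <- as_tibble(tbl)
  attr(tbl, "label") <- label
  class(tbl) <- c("shift_table", class(tibble()))
  validate_shift_table(tbl)
}

AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
         "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

validate_shift_table <- function(tbl) {
  stopifnot(all(c("residue_index", "residue_type", "shift_H", "shift_N") %in%
                  names(tbl)))
  if (nrow(tbl) == 0) abort("shift table must be non-empty")
  if (anyDuplicated(tbl$residue_index)) {
    dup <- tbl$residue_index[duplicated(tbl$residue_index)]
    abort(paste0("duplicate residue index: ",
                 paste(unique(dup), collapse = ", ")))
  }
  if (any(tbl$residue_index < 1L)) abort("residue_index must be >= 1")
  bad <- !tbl$residue_type %in% c(AA1, "X")
  if (any(bad)) {
    abort(paste0("unknown residue type: ",
                 paste(unique(tbl$residue_type[bad]), collapse = ", ")))
  }
  pro <- tbl$residue_type == "P"
  if (any(pro & (!is.na(tbl$shift_H) | !is.na(tbl$shift_N)))) {
    abort("proline rows cannot carry backbone amide shifts")
  }
  tbl
}

#' @export
print.shift_table <- function(x, ...) {
  cat("<shift_table> condition:", attr(x, "label"),
      "-", nrow(x), "residues\n")
  NextMethod()
}

#' Apply a residue-numbering offset
#'
#' Assignment sources for the same construct can differ by a constant
#' renumbering (for example a table whose T30 corresponds to T31 in another
#' numbering). The offset is added to `residue_index` on import; applying
#' `offset` then `-offset` is the identity.
#'
#' @param table A [shift_table()].
#' @param offset Signed integer added to every `residue_index`.
#' @return The table with shifted residue numbering.
#' @export
apply_offset <- function(table, offset) {
  offset <- as.integer(offset)
  stopifnot(length(offset) == 1L, !is.na(offset))
  table$residue_index <- table$residue_index + offset
  table
}

#' Read a per-residue chemical shift table from CSV
#'
#' Two dialects are supported. `"long-csv"` has one row per observed atom:
#' header `residue_index,residue_type,atom,shift_ppm` with `atom` H or N.
#' `"wide-csv"` has one row per residue: header
#' `residue_index,residue_type,shift_H_ppm,shift_N_ppm`. Empty shift fields
#' are missing values; they are preserved as `NA`, never coerced to zero.
#'
#' @param path CSV file path.
#' @param format `"long-csv"` or `"wide-csv"`.
#' @param offset Numbering offset added to residue indices on import.
#' @param label Condition label; defaults to the file stem.
#' @return A [shift_table()].
#' @export
read_shift_table <- function(path, format = c("wide-csv", "long-csv"),
                             offset = 0L, label = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  tbl <- switch(format,
    "long-csv" = parse_long_shift_csv(raw, path),
    "wide-csv" = parse_wide_shift_csv(raw, path)
  )
  apply_offset(new_shift_table(tbl, label = label), offset)
}

parse_shift_num <- function(x, path, what) {
  x[!is.na(x) & trimws(x) == ""] <- NA_character_
  out <- suppressWarnings(as.double(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    abort(paste0("non-numeric ", what, " in ", path, " at data row ", bad[1],
                 ": '", x[bad[1]], "'"))
  }
  out
}

parse_long_shift_csv <- function(raw, path) {
  need <- c("residue_index", "residue_type", "atom", "shift_ppm")
  if (!all(need %in% names(raw))) {
    abort(paste0("long-csv header must be ", paste(need, collapse = ",")))
  }
  if (!all(raw$atom %in% c("H", "N"))) abort("atom column must be H or N")
  raw$shift_ppm <- parse_shift_num(raw$shift_ppm, path, "shift")
  dup <- duplicated(raw[c("residue_index", "atom")])
  if (any(dup)) {
    abort(paste0("duplicate residue index: ",
                 raw$residue_index[dup][1], " (atom ", raw$atom[dup][1], ")"))
  }
  wide <- tidyr::pivot_wider(raw, id_cols = c("residue_index", "residue_type"),
                             names_from = "atom", values_from = "shift_ppm")
  if (anyDuplicated(wide$residue_index)) {
    d <- wide$residue_index[duplicated(wide$residue_index)][1]
    abort(paste0("duplicate residue index: ", d,
                 " (conflicting residue_type rows)"))
  }
  tibble(
    residue_index = as.integer(wide$residue_index),
    residue_type  = wide$residue_type,
    shift_H       = if ("H" %in% names(wide)) wide$H else NA_real_,
    shift_N       = if ("N" %in% names(wide)) wide$N else NA_real_
  )
}

parse_wide_shift_csv <- function(raw, path) {
  need <- c("residue_index", "residue_type", "shift_H_ppm", "shift_N_ppm")
  if (!all(need %in% names(raw))) {
    abort(paste0("wide-csv header must be ", paste(need, collapse = ",")))
  }
  tibble(
    residue_index = as.integer(raw$residue_index),
    residue_type  = raw$residue_type,
    shift_H       = parse_shift_num(raw$shift_H_ppm, path, "shift_H"),
    shift_N       = parse_shift_num(raw$shift_N_ppm, path, "shift_N")
  )
}

#' Write a chemical shift table to CSV
#'
#' Inverse of [read_shift_table()] for both dialects: a written table reads
#' back identical (shifts preserved well beyond 4 decimals). Missing shifts
#' are emitted as empty fields; in long format a fully missing residue (e.g.
#' proline) still gets its H and N rows, with empty shift fields, so the
#' residue survives the round trip.
#'
#' @inheritParams read_shift_table
#' @param table A [shift_table()].
#' @return `path`, invisibly.
#' @export
write_shift_table <- function(table, path, format = c("wide-csv", "long-csv")) {
  format <- match.arg(format)
  table <- validate_shift_table(table)
  fmt <- function(x) ifelse(is.na(x), "", sprintf("%.6f", x))
  if (format == "wide-csv") {
    out <- tibble(
      residue_index = table$residue_index,
      residue_type  = table$residue_type,
      shift_H_ppm   = fmt(table$shift_H),
      shift_N_ppm   = fmt(table$shift_N)
    )
  } else {
    out <- tibble(
      residue_index = rep(table$residue_index, each = 2L),
      residue_type  = rep(table$residue_type, each = 2L),
      atom          = rep(c("H", "N"), nrow(table)),
      shift_ppm     = as.vector(rbind(fmt(table$shift_H), fmt(table$shift_N)))
    )
  }
  tryCatch(readr::write_csv(out, path, na = "", progress = FALSE),
           error = function(e) abort(paste0("cannot write ", path, ": ",
                                            conditionMessage(e))))
  invisible(path)
}
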