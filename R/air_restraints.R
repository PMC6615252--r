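#' Build an ambiguous-interaction-restraint set
#'
#' Packages the active residues of two molecules (typically the
#' differential-CSP patches from [interface_patch()]) together with optional
#' passive residues and the restraint distance triple, for serialisation as
#' CNS-style ambiguous distance restraints that drive data-guided docking.
#' An ambiguous restraint ties each active residue of one molecule to the
#' union of the partner's active and passive residues. Passive residues are
#' caller-supplied (docking engines usually derive them from solvent
#' accessibility, which is out of scope here).
#'
#' @param active_A,active_B Non-empty integer residue lists (actives).
#' @param segid_A,segid_B Distinct segment identifiers.
#' @param passive_A,passive_B Optional passive residue lists; must not
#'   overlap the same molecule's actives.
#' @param distance_bound,lower_bound,upper_correction Restraint distance
#'   triple in Angstrom (defaults 2.0 / 0.0 / 2.0, the common convention).
#' @return An `air_set` list.
#' @export
#' @examples
#' air_set(c(14, 15, 16, 18, 70, 94, 95), c(17, 18, 19, 20, 98, 100))
air_set <- function(active_A, active_B, segid_A = "A", segid_B = "B",
                    passive_A = integer(0), passive_B = integer(0),
                    distance_bound = 2.0, lower_bound = 0.0,
                    upper_correction = 2.0) {
  active_A <- sort(unique(as.integer(active_A)))
  active_B <- sort(unique(as.integer(active_B)))
  passive_A <- sort(unique(as.integer(passive_A)))
  passive_B <- sort(unique(as.integer(passive_B)))
  if (length(active_A) == 0 || length(active_B) == 0) {
    abort("active residue lists must be non-empty")
  }
  if (identical(segid_A, segid_B)) abort("segids must be distinct")
  if (length(intersect(active_A, passive_A)) ||
      length(intersect(active_B, passive_B))) {
    abort("active and passive residues overlap within a molecule")
  }
  structure(list(
    molecule_A = list(segid = segid_A, active = active_A, passive = passive_A),
    molecule_B = list(segid = segid_B, active = active_B, passive = passive_B),
    distance_bound = distance_bound, lower_bound = lower_bound,
    upper_correction = upper_correction), class = "air_set")
}

#' @export
print.air_set <- function(x, ...) {
  cat("<air_set>", x$molecule_A$segid, ":", length(x$molecule_A$active),
      "active /", length(x$molecule_A$passive), "passive;",
      x$molecule_B$segid, ":", length(x$molecule_B$active), "active /",
      length(x$molecule_B$passive), "passive\n")
  invisible(x)
}

air_selection <- function(segid, resids) {
  paste0("(", paste0("(segid ", segid, " and resid ", resids, ")",
                     collapse = " or "), ")")
}

#' Write an AIR set as a CNS-style .tbl restraint file
#'
#' One `assign` statement per active residue of each molecule, selecting
#' that residue against the OR-combination of the partner's active and
#' passive residues, followed by the distance triple:
#'
#' ```
#' assign (segid A and resid 14)
#'        ((segid B and resid 17) or (segid B and resid 18) ...) 2.00 0.00 2.00
#' ```
#'
#' Selections are residue-level. The block count is always
#' `length(active_A) + length(active_B)`, and [read_air_tbl()] inverts the
#' serialisation exactly.
#'
#' @param airset An [air_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_air_tbl <- function(airset, path) {
  stopifnot(inherits(airset, "air_set"))
  A <- airset$molecule_A; B <- airset$molecule_B
  triple <- sprintf("%.2f %.2f %.2f", airset$distance_bound,
                    airset$lower_bound, airset$upper_correction)
  block <- function(seg, res, partner) {
    partner_sel <- air_selection(partner$segid,
                                 sort(c(partner$active, partner$passive)))
    sprintf("assign (segid %s and resid %d) %s %s", seg, res, partner_sel,
            triple)
  }
  lines <- c(
    "! ambiguous interaction restraints",
    sprintf("! actives %s: %s", A$segid, paste(A$active, collapse = " ")),
    sprintf("! passives %s: %s", A$segid, paste(A$passive, collapse = " ")),
    sprintf("! actives %s: %s", B$segid, paste(B$active, collapse = " ")),
    sprintf("! passives %s: %s", B$segid, paste(B$passive, collapse = " ")),
    vapply(A$active, function(r) block(A$segid, r, B), character(1)),
    vapply(B$active, function(r) block(B$segid, r, A), character(1))
  )
  ok <- tryCatch({writeLines(lines, path); TRUE},
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) abort(paste0("cannot write ", path))
  invisible(path)
}

#' Read a CNS-style AIR .tbl file
#'
#' Inverse of [write_air_tbl()] on its own output: actives are the residues
#' appearing on the left side of `assign` blocks per segid; passives are
#' the partner-selection residues not accounted for by the partner's
#' actives. Comment lines (`!`) are ignored. Malformed blocks raise an
#' error naming the line.
#'
#' @param path Restraint file path.
#' @return An [air_set()].
#' @export
read_air_tbl <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(!.*)?$", lines))
  head_re <- paste0(
    "^assign \\(segid (\\S+) and resid (\\d+)\\) \\((.*)\\)",
    " ([0-9.]+) ([0-9.]+) ([0-9.]+)\\s*$")
  sel_re <- "^\\(segid (\\S+) and resid (\\d+)\\)$"
  blocks <- purrr::map(keep, function(i) {
    ln <- lines[i]
    if (sum(gregexpr("\\(", ln)[[1]] > 0) !=
        sum(gregexpr("\\)", ln)[[1]] > 0)) {
      abort(paste0("mismatched parentheses at line ", i))
    }
    m <- regmatches(ln, regexec(head_re, ln))[[1]]
    if (length(m) == 0) abort(paste0("malformed assign block at line ", i))
    parts <- strsplit(m[4], " or ", fixed = TRUE)[[1]]
    sel <- purrr::map(parts, function(p) {
      s <- regmatches(p, regexec(sel_re, trimws(p)))[[1]]
      if (length(s) == 0) abort(paste0("malformed selection at line ", i))
      list(segid = s[2], resid = as.integer(s[3]))
    })
    segs <- unique(purrr::map_chr(sel, "segid"))
    if (length(segs) != 1) abort(paste0("mixed partner segids at line ", i))
    list(segid = m[2], resid = as.integer(m[3]), partner_segid = segs,
         partner_resids = purrr::map_int(sel, "resid"),
         triple = as.double(m[5:7]))
  })
  if (length(blocks) == 0) abort("no assign blocks found")
  segids <- unique(purrr::map_chr(blocks, "segid"))
  if (length(segids) != 2) {
    abort("expected assign blocks for exactly two segids")
  }
  side <- function(seg) {
    mine <- purrr::keep(blocks, ~ .x$segid == seg)
    actives <- sort(unique(purrr::map_int(mine, "resid")))
    # partner selection seen from the other side = my actives + my passives
    other <- purrr::keep(blocks, ~ .x$partner_segid == seg)
    seen <- sort(unique(unlist(purrr::map(other, "partner_resids"))))
    list(active = actives, passive = setdiff(seen, actives))
  }
  A <- side(segids[1]); B <- side(segids[2])
  triple <- blocks[[1]]$triple
  air_set(A$active, B$active, segids[1], segids[2], A$passive, B$passive,
          distance_bound = triple[1], lower_bound = triple[2],
          upper_correction = triple[3])
}
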