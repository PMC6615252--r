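#' Specify a synthetic fast-exchange titration
#'
#' Describes the generative model for a synthetic HSQC titration with the
#' statistical structure the analysis assumes: 1:1 binding with exact
#' ligand depletion, fast exchange (peaks move continuously as
#' `apo + sign * delta_max * f_b`), a responding subset of residues with
#' per-residue saturation amplitudes and random shift directions, Gaussian
#' peak-position noise on both axes, and optionally missing residues
#' (prolines, overlap). Defaults emulate a typical 15N-HSQC titration of a
#' small domain at 0.25 mM with ligand:protein ratios 0 to 30.
#'
#' @param K_D_true_uM Ground-truth dissociation constant, uM.
#' @param n_residues Number of residues in the construct.
#' @param protein_conc Protein concentration, mM.
#' @param molar_ratios Ligand:protein ratios; must include 0 (apo).
#' @param responding_fraction Fraction of residues with nonzero amplitude.
#' @param delta_max_H_range,delta_max_N_range Ranges (ppm) from which the
#'   per-residue saturation amplitudes are drawn uniformly.
#' @param delta_max_H,delta_max_N Optional explicit per-residue amplitude
#'   vectors (length `n_residues`; zero = non-responding); override the
#'   ranges and `responding_fraction`.
#' @param noise_sd_H,noise_sd_N Gaussian peak-position noise SDs, ppm.
#' @param apo_range_H,apo_range_N Uniform ranges for apo peak positions.
#' @param missing_residues Residue indices absent from every table.
#' @param seed Integer RNG seed; generation is fully deterministic given it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(K_D_true_uM, n_residues = 100,
                           protein_conc = 0.25,
                           molar_ratios = c(0, 1, 3, 5, 10, 20, 30),
                           responding_fraction = 0.06,
                           delta_max_H_range = c(0.02, 0.3),
                           delta_max_N_range = c(0.1, 1.5),
                           delta_max_H = NULL, delta_max_N = NULL,
                           noise_sd_H = 0.002, noise_sd_N = 0.01,
                           apo_range_H = c(6, 10), apo_range_N = c(100, 135),
                           missing_residues = integer(0), seed = 1L) {
  if (K_D_true_uM <= 0) abort("K_D_true_uM must be > 0")
  if (!0 %in% molar_ratios) abort("molar_ratios must include 0 (apo)")
  if (responding_fraction < 0 || responding_fraction > 1) {
    abort("responding_fraction must be in [0, 1]")
  }
  if (noise_sd_H < 0 || noise_sd_N < 0) abort("noise SDs must be >= 0")
  structure(list(
    K_D_true_uM = K_D_true_uM, n_residues = as.integer(n_residues),
    protein_conc = protein_conc, molar_ratios = sort(molar_ratios),
    responding_fraction = responding_fraction,
    delta_max_H_range = delta_max_H_range,
    delta_max_N_range = delta_max_N_range,
    delta_max_H = delta_max_H, delta_max_N = delta_max_N,
    noise_sd_H = noise_sd_H, noise_sd_N = noise_sd_N,
    apo_range_H = apo_range_H, apo_range_N = apo_range_N,
    missing_residues = as.integer(missing_residues),
    seed = as.integer(seed)), class = "synthetic_spec")
}

#' Generate a synthetic titration series with its ground truth
#'
#' Realises a [synthetic_spec()]: apo positions drawn uniformly, a random
#' responding subset, per-residue amplitudes and random shift directions
#' (+/- per residue and axis, so the sign-invariance of the CSP statistic
#' is exercised), fraction bound from the exact depletion model, and fresh
#' Gaussian noise at every non-apo point. With zero noise the weighted CSP
#' of a responding residue is exactly `weighted_csp(dH, dN) * f_b`.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `series` (a [titration_series()]) and `truth` (tibble
#'   of per-residue `delta_max_H/N`, signs, responding flag, plus the spec
#'   as attribute).
#' @export
generate_series <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_residues
  idx <- seq_len(n)
  present <- setdiff(idx, spec$missing_residues)
  types <- sample(setdiff(AA1, "P"), n, replace = TRUE)
  apo_H <- runif(n, spec$apo_range_H[1], spec$apo_range_H[2])
  apo_N <- runif(n, spec$apo_range_N[1], spec$apo_range_N[2])
  if (!is.null(spec$delta_max_H)) {
    dH <- rep_len(spec$delta_max_H, n)
    dN <- rep_len(spec$delta_max_N %||% 0, n)
    responding <- dH > 0 | dN > 0
  } else {
    n_resp <- round(spec$responding_fraction * n)
    resp_idx <- sort(sample(idx, n_resp))
    responding <- idx %in% resp_idx
    dH <- ifelse(responding,
                 runif(n, spec$delta_max_H_range[1], spec$delta_max_H_range[2]),
                 0)
    dN <- ifelse(responding,
                 runif(n, spec$delta_max_N_range[1], spec$delta_max_N_range[2]),
                 0)
  }
  sign_H <- sample(c(-1, 1), n, replace = TRUE)
  sign_N <- sample(c(-1, 1), n, replace = TRUE)
  P <- spec$protein_conc
  tables <- purrr::map(spec$molar_ratios, function(r) {
    L <- r * P
    fb <- fraction_bound(P, L, spec$K_D_true_uM / 1000)
    noise_H <- if (r == 0) 0 else rnorm(n, 0, spec$noise_sd_H)
    noise_N <- if (r == 0) 0 else rnorm(n, 0, spec$noise_sd_N)
    tab <- shift_table(
      residue_index = idx, residue_type = types,
      shift_H = apo_H + sign_H * dH * fb + noise_H,
      shift_N = apo_N + sign_N * dN * fb + noise_N,
      label = if (r == 0) "apo" else sprintf("ratio_1_%g", r))
    tab[tab$residue_index %in% present, ]
  })
  truth <- tibble(residue_index = idx, residue_type = types,
                  delta_max_H = dH, delta_max_N = dN,
                  sign_H = sign_H, sign_N = sign_N,
                  responding = responding,
                  present = idx %in% present)
  attr(truth, "spec") <- spec
  series <- titration_series(tables, protein_conc = P,
                             molar_ratio = spec$molar_ratios,
                             protein_name = "synthetic",
                             ligand_sequence = "XXXXXXXXXXXX")
  list(series = series, truth = truth)
}

#' Preset titration scenarios for the PDZ2/PDZ3 peptide interactions
#'
#' One named [synthetic_spec()] per measured domain-peptide pair, with the
#' ground-truth K_D set to the reported affinity: `pdz2_apc` (286 uM),
#' `pdz3_apc` (721 uM), `pdz2_in_tandem_apc` (211 uM), `pdz3_in_tandem_apc`
#' (2574 uM), `pdz2_prk2` (661 uM), `pdz3_prk2` (318 uM). All use 0.25 mM
#' protein and six responding residues among 100; the PDZ3-PRK2 series uses
#' the shorter ratio schedule 0-10 (ratios 0, 2, 4, 6, 8, 10), the others
#' 0, 1, 3, 5, 10, 20, 30. The `pdz3_in_tandem_apc` design ends at about
#' 74% bound — by construction a partial-saturation case.
#'
#' @param seed Base seed; each scenario derives its own offset seed.
#' @param noise_sd_H,noise_sd_N Noise levels shared by all scenarios
#'   (set to 0 for noise-free parameter-recovery checks).
#' @return Named list of `synthetic_spec` objects.
#' @export
pdz_scenarios <- function(seed = 1L, noise_sd_H = 0.002, noise_sd_N = 0.01) {
  kd <- c(pdz2_apc = 286, pdz3_apc = 721, pdz2_in_tandem_apc = 211,
          pdz3_in_tandem_apc = 2574, pdz2_prk2 = 661, pdz3_prk2 = 318)
  purrr::imap(kd, function(k, name) {
    ratios <- if (name == "pdz3_prk2") c(0, 2, 4, 6, 8, 10)
              else c(0, 1, 3, 5, 10, 20, 30)
    synthetic_spec(K_D_true_uM = k, molar_ratios = ratios,
                   noise_sd_H = noise_sd_H, noise_sd_N = noise_sd_N,
                   seed = seed + match(name, names(kd)))
  })
}

#' Simulate a matched pair of conditions for differential-CSP analysis
#'
#' Two shift tables of the same construct in which a chosen residue subset
#' is displaced by fixed amounts while all residues in both tables carry
#' independent Gaussian peak-position noise — the null-plus-patch structure
#' that differential comparison must resolve.
#'
#' @param n_residues Construct size.
#' @param displaced Residue indices displaced between conditions.
#' @param displacement_H,displacement_N Displacement (ppm) applied to the
#'   chosen residues in condition B.
#' @param noise_sd_H,noise_sd_N Per-condition peak-position noise SDs, ppm.
#' @param seed RNG seed.
#' @return List of two [shift_table()]s, `A` and `B`.
#' @export
simulate_condition_pair <- function(n_residues = 100, displaced = integer(0),
                                    displacement_H = 0.1,
                                    displacement_N = 0,
                                    noise_sd_H = 0.001, noise_sd_N = 0.005,
                                    seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  idx <- seq_len(n_residues)
  types <- sample(setdiff(AA1, "P"), n_residues, replace = TRUE)
  H <- runif(n_residues, 6, 10)
  N <- runif(n_residues, 100, 135)
  disp <- idx %in% displaced
  A <- shift_table(idx, types,
                   H + rnorm(n_residues, 0, noise_sd_H),
                   N + rnorm(n_residues, 0, noise_sd_N), label = "A")
  B <- shift_table(idx, types,
                   H + disp * displacement_H + rnorm(n_residues, 0, noise_sd_H),
                   N + disp * displacement_N + rnorm(n_residues, 0, noise_sd_N),
                   label = "B")
  list(A = A, B = B)
}

#' Write a synthetic dataset to disk
#'
#' Emits the manifest + per-point shift-table CSVs via [write_series()]
#' plus a `truth.yaml` recording the generating parameters and per-residue
#' amplitudes, for test harnesses.
#'
#' @param spec A [synthetic_spec()].
#' @param dir Output directory.
#' @return The manifest path, invisibly.
#' @export
write_synthetic_dataset <- function(spec, dir) {
  g <- generate_series(spec)
  path <- write_series(g$series, dir)
  tr <- g$truth
  yaml::write_yaml(list(
    spec = unclass(spec),
    responding_residues = tr$residue_index[tr$responding],
    delta_max_H = tr$delta_max_H, delta_max_N = tr$delta_max_N,
    sign_H = tr$sign_H, sign_N = tr$sign_N),
    file.path(dir, "truth.yaml"))
  invisible(path)
}
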