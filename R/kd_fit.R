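#' Residue selection rule for K_D fitting and significance calls
#'
#' Two modes. `"explicit"` takes a fixed residue list — the usual practice
#' of fitting resonances in or next to the binding cleft chosen by the
#' spectroscopist. `"threshold"` selects residues whose endpoint CSP exceeds
#' both `mean + threshold_sigmas * SD` of all observed endpoint CSPs and an
#' absolute floor `min_csp`. The floor keeps the data-driven rule from
#' flagging pure measurement noise: a relative mean + k*SD cut alone always
#' crosses some tail of a continuous noise distribution, and on an all-zero
#' profile it degenerates to selecting everything.
#'
#' @param mode `"threshold"` or `"explicit"`.
#' @param residues Integer residue indices (required for explicit mode).
#' @param threshold_sigmas Number of SDs above the mean (default 1).
#' @param min_csp Absolute significance floor, ppm (default 0.01).
#' @return A `selection_rule` list.
#' @export
selection_rule <- function(mode = c("threshold", "explicit"), residues = NULL,
                           threshold_sigmas = 1, min_csp = 0.01) {
  mode <- match.arg(mode)
  if (mode == "explicit" && length(residues) == 0) {
    abort("explicit mode requires a non-empty residue list")
  }
  structure(list(mode = mode, residues = as.integer(residues),
                 threshold_sigmas = threshold_sigmas, min_csp = min_csp),
            class = "selection_rule")
}

apply_rule <- function(values, rule) {
  # values: tibble(residue_index, csp); returns selected residue indices
  obs <- dplyr::filter(values, !is.na(.data$csp))
  if (rule$mode == "explicit") {
    absent <- setdiff(rule$residues, obs$residue_index)
    if (length(absent)) {
      warn(paste0("residues absent from profile: ",
                  paste(absent, collapse = ", ")))
    }
    sel <- intersect(rule$residues, obs$residue_index)
    if (length(sel) == 0) abort("no listed residue present in the profile")
    return(sort(sel))
  }
  cut <- mean(obs$csp) + rule$threshold_sigmas * sd(obs$csp)
  if (is.na(cut)) cut <- Inf
  sort(obs$residue_index[obs$csp >= cut & obs$csp >= rule$min_csp])
}

#' Select residues for fitting from a CSP profile
#'
#' Applies a [selection_rule()] to the endpoint perturbations of a profile.
#'
#' @param profile A [csp_profile()].
#' @param rule A [selection_rule()].
#' @return Sorted integer vector of residue indices.
#' @export
select_residues <- function(profile, rule = selection_rule()) {
  apply_rule(endpoint_csp(profile), rule)
}

#' Fit a single residue's binding curve
#'
#' Nonlinear least squares of `csp ~ delta_max * fraction_bound(P, L, K_D)`
#' over `(K_D, delta_max)` with positivity bounds (K_D in \[1e-3, 1e3\] mM,
#' delta_max in \[0, 10\] ppm), by bounded Levenberg-Marquardt. A
#' deterministic multistart over K_D in \{0.05, 0.2, 0.5, 2, 5\} mM (with
#' delta_max started at the endpoint CSP) guards against the shallow
#' likelihood valley of weakly saturated curves; the lowest-RSS start wins,
#' so identical inputs give identical estimates. Residuals are unweighted.
#'
#' @param curve Data frame with columns `ligand_conc` (mM) and `csp` (ppm),
#'   including the apo zero; `NA` entries are dropped.
#' @param protein_conc Total protein concentration, mM.
#' @param kind Binding model variant, see [fraction_bound()].
#' @param residue_index Optional label carried into the result.
#' @return One-row tibble: `residue_index`, `K_D_uM`, `delta_max`, `rss`,
#'   `converged`, `identifiable` (FALSE when K_D collapses onto a bound),
#'   `endpoint_fraction_bound` (at the largest ligand concentration, using
#'   the fitted K_D), `n_points_used`, `note`.
#' @export
fit_residue <- function(curve, protein_conc,
                        kind = c("quadratic", "hyperbolic"),
                        residue_index = NA_integer_) {
  kind <- match.arg(kind)
  curve <- dplyr::filter(as_tibble(curve), !is.na(.data$csp))
  n <- nrow(curve)
  empty <- tibble(residue_index = as.integer(residue_index),
                  K_D_uM = NA_real_, delta_max = NA_real_, rss = NA_real_,
                  converged = FALSE, identifiable = FALSE,
                  endpoint_fraction_bound = NA_real_,
                  n_points_used = n, note = "")
  if (n < 3 || !any(curve$ligand_conc == 0)) {
    abort("need >= 3 non-missing points including the apo zero")
  }
  if (all(curve$csp == 0) || !any(curve$csp > 0)) {
    empty$note <- "no perturbation"
    return(empty)
  }
  lower <- c(K = 1e-3, dmax = 0)
  upper <- c(K = 1e3, dmax = 10)
  d0 <- curve$csp[which.max(curve$ligand_conc)]
  if (!is.finite(d0) || d0 <= 0) d0 <- max(curve$csp)
  starts <- c(0.05, 0.2, 0.5, 2, 5)
  best <- NULL
  for (K0 in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        csp ~ dmax * fraction_bound(protein_conc, ligand_conc, K, kind),
        data = curve, start = list(K = K0, dmax = d0),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss - 1e-15) {
      best <- list(par = stats::coef(fit), rss = rss)
    }
  }
  if (is.null(best)) {
    empty$note <- "optimizer failed for every start"
    return(empty)
  }
  K <- unname(best$par["K"])
  dmax <- unname(best$par["dmax"])
  at_bound <- K <= lower["K"] * (1 + 1e-6) || K >= upper["K"] * (1 - 1e-6)
  fb_end <- fraction_bound(protein_conc, max(curve$ligand_conc), K, kind)
  tibble(residue_index = as.integer(residue_index),
         K_D_uM = K * 1000, delta_max = dmax, rss = best$rss,
         converged = TRUE, identifiable = !at_bound,
         endpoint_fraction_bound = fb_end, n_points_used = n,
         note = if (at_bound) "non-identifiable: K_D at parameter bound" else "")
}

#' Aggregate per-residue K_D estimates
#'
#' The reported dissociation constant is the arithmetic mean of the
#' converged per-residue estimates; its error is their sample standard
#' deviation (n - 1 denominator; 0 when a single residue contributes,
#' flagged in `note`). `partial_saturation_flag` is set when the median
#' endpoint fraction bound falls below `saturation_floor`, marking series
#' whose K_D rests on an unsaturated curve (an extrapolation, not an
#' interpolation).
#'
#' @param fits Tibble of per-residue fits from [fit_residue()].
#' @param saturation_floor Median endpoint fraction bound below which the
#'   partial-saturation flag is raised (default 0.8).
#' @return One-row tibble: `K_D_uM`, `error_uM`, `n_converged`,
#'   `residues_used` (list-column), `partial_saturation_flag`, `note`.
#' @export
aggregate_kd <- function(fits, saturation_floor = 0.8) {
  ok <- dplyr::filter(as_tibble(fits), .data$converged)
  if (nrow(ok) == 0) abort("no converged fits to aggregate")
  err <- if (nrow(ok) > 1) sd(ok$K_D_uM) else 0
  tibble(
    K_D_uM = mean(ok$K_D_uM),
    error_uM = err,
    n_converged = nrow(ok),
    residues_used = list(sort(ok$residue_index)),
    partial_saturation_flag =
      median(ok$endpoint_fraction_bound) < saturation_floor,
    note = if (nrow(ok) == 1) "single residue: spread undefined, error 0" else ""
  )
}

#' Fit a titration series end to end
#'
#' The full pipeline behind an averaged dissociation constant:
#' [csp_profile()] relative to apo, residue selection by a
#' [selection_rule()], a per-residue (K_D, delta_max) fit for every selected
#' residue, and [aggregate_kd()]. The alternative `method = "global"` fits
#' one shared K_D with per-residue amplitudes (profiled analytically, since
#' the model is linear in delta_max at fixed K_D) — useful as a
#' cross-check, but the default mirrors the per-residue-then-average
#' convention, whose spread is the reported error.
#'
#' @param series A [titration_series()].
#' @param rule A [selection_rule()].
#' @param kind Binding model variant.
#' @param method `"per-residue"` (default) or `"global"`.
#' @param saturation_floor Passed to [aggregate_kd()].
#' @return An object of class `kd_fit`: list with `fits` (per-residue
#'   tibble), `aggregate` (one-row tibble), `profile`, `settings`. Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
fit_series <- function(series, rule = selection_rule(),
                       kind = c("quadratic", "hyperbolic"),
                       method = c("per-residue", "global"),
                       saturation_floor = 0.8) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  prof <- csp_profile(series)
  sel <- select_residues(prof, rule)
  P <- attr(prof, "protein_conc")
  fits <- purrr::map_dfr(sel, function(r) {
    cv <- dplyr::filter(prof, .data$residue_index == r)
    fit_residue(cv[c("ligand_conc", "csp")], P, kind, residue_index = r)
  })
  agg <- if (method == "global") {
    global_kd_fit(prof, sel, P, kind, saturation_floor)
  } else {
    aggregate_kd(fits, saturation_floor)
  }
  structure(list(fits = fits, aggregate = agg, profile = prof,
                 settings = list(rule = rule, kind = kind, method = method,
                                 protein_conc = P,
                                 saturation_floor = saturation_floor)),
            class = "kd_fit")
}

# shared-K_D fit: delta_max per residue is linear at fixed K, so profile it
# out and minimise the pooled RSS over K alone (log-scale golden search).
global_kd_fit <- function(prof, sel, P, kind, saturation_floor) {
  curves <- purrr::map(sel, function(r) {
    cv <- dplyr::filter(prof, .data$residue_index == r, !is.na(.data$csp))
    cv[c("ligand_conc", "csp")]
  })
  rss_at <- function(logK) {
    K <- exp(logK)
    sum(purrr::map_dbl(curves, function(cv) {
      f <- fraction_bound(P, cv$ligand_conc, K, kind)
      d <- max(sum(cv$csp * f) / max(sum(f^2), .Machine$double.eps), 0)
      sum((cv$csp - d * f)^2)
    }))
  }
  opt <- stats::optimize(rss_at, interval = log(c(1e-3, 1e3)), tol = 1e-10)
  K <- exp(opt$minimum)
  Lmax <- max(prof$ligand_conc)
  tibble(K_D_uM = K * 1000, error_uM = NA_real_, n_converged = length(sel),
         residues_used = list(sort(sel)),
         partial_saturation_flag =
           fraction_bound(P, Lmax, K, kind) < saturation_floor,
         note = "global fit: shared K_D, no per-residue spread")
}

#' @export
print.kd_fit <- function(x, ...) {
  a <- x$aggregate
  cat(sprintf("<kd_fit> K_D = %.0f +/- %.0f uM (%d residue%s, %s %s fit)\n",
              a$K_D_uM, ifelse(is.na(a$error_uM), 0, a$error_uM),
              a$n_converged, ifelse(a$n_converged == 1, "", "s"),
              x$settings$method, x$settings$kind))
  if (a$partial_saturation_flag) {
    cat("  warning: partial saturation - endpoint fraction bound below",
        x$settings$saturation_floor, "\n")
  }
  invisible(x)
}

#' Write a per-residue fit report as CSV
#'
#' One row per fitted residue plus a `summary` row carrying the aggregate,
#' and a sidecar YAML run report capturing the selection rule, model kind
#' and settings.
#'
#' @param fit A `kd_fit` object.
#' @param path Output CSV path; the run report goes to `<path>.run.yaml`.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  per <- dplyr::mutate(fit$fits, row = as.character(.data$residue_index))
  agg <- fit$aggregate
  out <- dplyr::bind_rows(
    dplyr::select(per, "row", "K_D_uM", delta_max_ppm = "delta_max", "rss",
                  "converged", "endpoint_fraction_bound", "note"),
    tibble(row = "summary", K_D_uM = agg$K_D_uM, delta_max_ppm = NA_real_,
           rss = NA_real_, converged = NA,
           endpoint_fraction_bound = NA_real_,
           note = sprintf("error_uM=%.6g; n=%d; partial_saturation=%s",
                          agg$error_uM, agg$n_converged,
                          agg$partial_saturation_flag)))
  readr::write_csv(out, path, na = "", progress = FALSE)
  s <- fit$settings
  yaml::write_yaml(list(rule = unclass(s$rule), model_kind = s$kind,
                        method = s$method, protein_conc_mM = s$protein_conc,
                        saturation_floor = s$saturation_floor),
                   paste0(path, ".run.yaml"))
  invisible(path)
}

#' @rdname fit_series
#' @param x A `kd_fit` object.
#' @param ... Unused.
#' @method tidy kd_fit
#' @export
tidy.kd_fit <- function(x, ...) x$fits

#' @rdname fit_series
#' @method glance kd_fit
#' @export
glance.kd_fit <- function(x, ...) x$aggregate
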