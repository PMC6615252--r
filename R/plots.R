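#' Plot a CSP profile
#'
#' Weighted CSP against ligand concentration, one line per residue.
#' Residues can be restricted to the responding subset via `residues`.
#'
#' @param object A [csp_profile()].
#' @param residues Optional residue indices to show (default: all).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csp_profile
#' @export
autoplot.csp_profile <- function(object, residues = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(residues)) {
    df <- dplyr::filter(df, .data$residue_index %in% residues)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ligand_conc, y = .data$csp,
                                   group = .data$residue_index,
                                   colour = factor(.data$residue_index))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "ligand concentration (mM)",
                  y = expression(Delta * delta[obs] ~ "(ppm)"),
                  colour = "residue") +
    ggplot2::theme_minimal()
}

#' Plot fitted binding curves
#'
#' Observed per-residue CSPs with the fitted fast-exchange isotherms
#' overlaid, faceted by residue.
#'
#' @param object A `kd_fit` from [fit_series()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kd_fit
#' @export
autoplot.kd_fit <- function(object, ...) {
  fits <- dplyr::filter(object$fits, .data$converged)
  prof <- dplyr::filter(as_tibble(object$profile),
                        .data$residue_index %in% fits$residue_index)
  P <- object$settings$protein_conc
  kind <- object$settings$kind
  grid <- tidyr::crossing(
    fits[c("residue_index", "K_D_uM", "delta_max")],
    ligand_conc = seq(0, max(prof$ligand_conc), length.out = 80))
  grid$csp <- predicted_csp(grid$delta_max, P, grid$ligand_conc,
                            grid$K_D_uM / 1000, kind)
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$ligand_conc, y = .data$csp)) +
    ggplot2::geom_line(data = grid, colour = "grey40") +
    ggplot2::geom_point(colour = "firebrick", size = 1.2) +
    ggplot2::facet_wrap(~residue_index, scales = "free_y") +
    ggplot2::labs(x = "ligand concentration (mM)",
                  y = expression(Delta * delta[obs] ~ "(ppm)")) +
    ggplot2::theme_minimal()
}

#' Plot a differential-CSP result
#'
#' Per-residue inter-condition weighted shift differences as a bar chart;
#' significant residues highlighted, non-comparable residues omitted.
#'
#' @param object A `csp_diff` from [compare_conditions()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot csp_diff
#' @export
autoplot.csp_diff <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), .data$comparable)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residue_index, y = .data$delta,
                                   fill = .data$significant)) +
    ggplot2::geom_col(width = 0.8) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "residue", y = expression(Delta * delta ~ "(ppm)"),
                  fill = "significant") +
    ggplot2::theme_minimal()
}
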