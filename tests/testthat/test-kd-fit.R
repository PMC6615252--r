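noise_free_curve <- function(K_D_uM, delta_max, P = 0.25,
                             ratios = c(0, 1, 3, 5, 10, 20, 30)) {
  L <- ratios * P
  tibble::tibble(ligand_conc = L,
                 csp = predicted_csp(delta_max, P, L, K_D_uM / 1000))
}

test_that("a noise-free curve returns the generating parameters", {
  fit <- fit_residue(noise_free_curve(286, 0.12), protein_conc = 0.25)
  expect_true(fit$converged)
  expect_equal(fit$K_D_uM, 286, tolerance = 1e-3)
  expect_equal(fit$delta_max, 0.12, tolerance = 1e-3)
  expect_lt(abs(fit$K_D_uM - 286) / 286, 0.001)
})

test_that("degenerate curves are flagged instead of fitted", {
  flat <- tibble::tibble(ligand_conc = c(0, 0.25, 0.75, 2.5), csp = 0)
  out <- fit_residue(flat, 0.25)
  expect_false(out$converged)
  expect_match(out$note, "no perturbation")
  # instant saturation: every non-zero point already at delta_max
  sat <- tibble::tibble(ligand_conc = c(0, 0.25, 0.75, 2.5, 7.5),
                        csp = c(0, rep(0.2, 4)))
  out2 <- fit_residue(sat, 0.25)
  expect_false(out2$identifiable)
  expect_match(out2$note, "non-identifiable")
  expect_error(fit_residue(tibble::tibble(ligand_conc = c(0, 1), csp = c(0, 1)),
                           0.25), ">= 3")
})

test_that("fitting is deterministic", {
  curve <- noise_free_curve(661, 0.08)
  curve$csp <- curve$csp + withr::with_seed(1, rnorm(7, 0, 0.003))
  f1 <- fit_residue(curve, 0.25)
  f2 <- fit_residue(curve, 0.25)
  expect_identical(f1$K_D_uM, f2$K_D_uM)
  expect_identical(f1$delta_max, f2$delta_max)
})

test_that("explicit selection returns the listed residues present in the profile", {
  prof <- csp_profile(toy_series(seed = 4, n_residues = 90)$series)
  listed <- c(23L, 50L, 52L, 73L, 80L, 81L)
  sel <- select_residues(prof, selection_rule("explicit", residues = listed))
  expect_equal(sel, listed)
  expect_warning(
    select_residues(prof, selection_rule("explicit",
                                         residues = c(listed, 999L))),
    "absent")
  expect_error(
    suppressWarnings(
      select_residues(prof, selection_rule("explicit", residues = 999L))),
    "no listed residue")
})

test_that("threshold selection picks outliers and rejects all-zero profiles", {
  # 99 residues at ~0, one at 0.5 ppm: mean + 1*SD sits far below 0.5
  vals <- tibble::tibble(residue_index = 1:100,
                         csp = c(rep(0.001, 99), 0.5))
  cut <- mean(vals$csp) + sd(vals$csp)
  expect_lt(cut, 0.5)
  sel <- cspkit:::apply_rule(vals, selection_rule("threshold"))
  expect_equal(sel, 100L)
  zero <- tibble::tibble(residue_index = 1:50, csp = 0)
  expect_equal(cspkit:::apply_rule(zero, selection_rule("threshold")),
               integer(0))
})

test_that("aggregation averages converged fits with a sample-SD spread", {
  fits <- purrr::map_dfr(c(286, 286, 286), ~ fit_residue(
    noise_free_curve(.x, 0.1), 0.25, residue_index = .x))
  agg <- aggregate_kd(fits)
  expect_equal(agg$K_D_uM, 286, tolerance = 1e-3)
  expect_equal(agg$error_uM, 0, tolerance = 0.5)
  two <- tibble::tibble(residue_index = 1:2, K_D_uM = c(200, 300),
                        delta_max = 0.1, rss = 0, converged = TRUE,
                        identifiable = TRUE,
                        endpoint_fraction_bound = 0.9, n_points_used = 7L,
                        note = "")
  agg2 <- aggregate_kd(two)
  expect_equal(agg2$K_D_uM, 250)
  expect_equal(agg2$error_uM, sqrt(((200 - 250)^2 + (300 - 250)^2) / 1))
  expect_equal(agg2$error_uM, 70.71068, tolerance = 1e-6)
  expect_error(aggregate_kd(dplyr::mutate(two, converged = FALSE)),
               "no converged")
})

test_that("aggregation is permutation-invariant", {
  fits <- purrr::map_dfr(c(211, 286, 721), ~ fit_residue(
    noise_free_curve(.x, 0.1), 0.25, residue_index = round(.x)))
  a <- aggregate_kd(fits)
  b <- aggregate_kd(fits[c(3, 1, 2), ])
  expect_equal(a$K_D_uM, b$K_D_uM)
  expect_equal(a$error_uM, b$error_uM)
  expect_equal(a$residues_used, b$residues_used)
})

test_that("weak binding left unsaturated at the end of the titration is flagged", {
  # endpoint fraction bound ~0.74 for K_D = 2574 uM at 0.25 mM, ratio 30
  fit <- fit_residue(noise_free_curve(2574, 0.15), 0.25)
  expect_equal(fit$endpoint_fraction_bound,
               fraction_bound(0.25, 7.5, 2.574), tolerance = 1e-4)
  agg <- aggregate_kd(fit)
  expect_true(agg$partial_saturation_flag)
  # a tight binder saturates and is not flagged
  agg2 <- aggregate_kd(fit_residue(noise_free_curve(286, 0.15), 0.25))
  expect_false(agg2$partial_saturation_flag)
})

test_that("noise-free round trip through the full pipeline recovers every Table-style K_D", {
  for (kd in c(211, 2574)) {
    g <- toy_series(K_D_uM = kd, seed = 10 + kd)
    fit <- fit_series(g$series, selection_rule("threshold"))
    expect_lt(abs(glance(fit)$K_D_uM - kd) / kd, 0.005)
    expect_lt(glance(fit)$error_uM / kd, 0.005)
  }
})

test_that("global shared-K_D mode agrees with per-residue mean on clean data", {
  g <- toy_series(K_D_uM = 318, seed = 77)
  per <- fit_series(g$series, method = "per-residue")
  glob <- fit_series(g$series, method = "global")
  expect_equal(glance(glob)$K_D_uM, glance(per)$K_D_uM, tolerance = 1e-3)
})

test_that("tidy and glance expose per-residue fits and the aggregate", {
  g <- toy_series(seed = 13)
  fit <- fit_series(g$series)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("residue_index", "K_D_uM", "delta_max", "rss",
                    "converged", "endpoint_fraction_bound") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$K_D_uM >= min(td$K_D_uM) && gl$K_D_uM <= max(td$K_D_uM))
})

test_that("fit report CSV carries per-residue rows plus a summary row", {
  g <- toy_series(seed = 21)
  fit <- fit_series(g$series)
  f <- withr::local_tempfile(fileext = ".csv")
  write_fit_report(fit, f)
  rep <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(nrow(rep), nrow(fit$fits) + 1L)
  expect_equal(rep$row[nrow(rep)], "summary")
  expect_true(file.exists(paste0(f, ".run.yaml")))
})
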