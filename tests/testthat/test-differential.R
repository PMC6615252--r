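test_that("identical tables give all-zero deltas and an empty significant set", {
  tab <- random_shift_table(n = 20, seed = 31)
  res <- compare_conditions(tab, tab)
  expect_true(all(res$delta[res$comparable] == 0))
  expect_false(any(res$significant))
})

test_that("a displaced back-of-domain patch is flagged exactly", {
  pair <- simulate_condition_pair(n_residues = 100,
                                  displaced = c(19, 94, 95, 97),
                                  displacement_H = 0.1, noise_sd_H = 0,
                                  noise_sd_N = 0, seed = 5)
  res <- compare_conditions(pair$A, pair$B)
  expect_equal(res$residue_index[res$significant], c(19L, 94L, 95L, 97L))
})

test_that("comparison is symmetric in its two conditions", {
  pair <- simulate_condition_pair(displaced = c(10, 40), seed = 8)
  ab <- compare_conditions(pair$A, pair$B)
  ba <- compare_conditions(pair$B, pair$A)
  expect_equal(ab$delta, ba$delta)
  expect_equal(ab$significant, ba$significant)
})

test_that("zero-difference pairs with realistic noise are not flagged", {
  flags <- purrr::map_int(1:20, function(s) {
    pair <- simulate_condition_pair(displaced = integer(0),
                                    noise_sd_H = 0.001, noise_sd_N = 0.005,
                                    seed = s)
    sum(compare_conditions(pair$A, pair$B)$significant)
  })
  expect_true(mean(flags == 0) >= 0.95)
})

test_that("residues displaced far above the noise are flagged essentially always", {
  # displacement = 5x the weighted noise SD of the inter-condition delta
  hits <- purrr::map_lgl(1:100, function(s) {
    pair <- simulate_condition_pair(displaced = c(50, 60),
                                    displacement_H = 5 * sqrt(2) * 0.004,
                                    noise_sd_H = 0.004, noise_sd_N = 0.02,
                                    seed = 1000 + s)
    res <- compare_conditions(pair$A, pair$B)
    all(c(50L, 60L) %in% res$residue_index[res$significant])
  })
  expect_gte(mean(hits), 0.99)
})

test_that("residues missing in either condition are not comparable, not zero", {
  A <- shift_table(1:4, c("A", "G", "P", "L"),
                   c(8.0, 7.5, NA, 8.3), c(120, 112, NA, 125))
  B <- shift_table(1:3, c("A", "G", "P"),
                   c(8.0, 7.6, NA), c(120, 112.5, NA))
  res <- compare_conditions(A, B)
  expect_equal(res$residue_index, 1:4)
  expect_equal(res$comparable, c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(is.na(res$delta[!res$comparable])))
})

test_that("numbering offsets align renumbered constructs before comparison", {
  A <- shift_table(11:15, "X", 8 + (1:5) / 10, 110 + 1:5)
  B <- shift_table(10:14, "X", 8 + (1:5) / 10, 110 + 1:5)  # shifted by one
  res <- compare_conditions(A, B, offset_B = 1L)
  expect_true(all(res$delta[res$comparable] == 0))
  expect_error(compare_conditions(A, shift_table(50:54, "X", 8, 110)),
               "no comparable residue")
})

test_that("residue type disagreement warns but does not block matching", {
  A <- shift_table(1:2, c("A", "G"), c(8, 8.2), c(120, 121))
  B <- shift_table(1:2, c("A", "S"), c(8, 8.2), c(120, 121))
  expect_warning(compare_conditions(A, B), "type mismatch at index 2")
})

test_that("interface patch removes the cleft exclusion list", {
  res <- structure(
    tibble::tibble(residue_index = c(14L, 15L, 16L, 18L, 23L, 70L, 94L, 95L),
                   delta = 0.2, comparable = TRUE, significant = TRUE),
    class = c("csp_diff", class(tibble::tibble())))
  expect_equal(interface_patch(res, exclude = 23L),
               c(14L, 15L, 16L, 18L, 70L, 94L, 95L))
  expect_equal(interface_patch(res, exclude = c(300L, 301L)),
               res$residue_index)   # disjoint exclusion changes nothing
  none <- dplyr::mutate(res, significant = FALSE)
  class(none) <- class(res)
  expect_warning(out <- interface_patch(none), "empty")
  expect_length(out, 0)
})

test_that("differential report CSV round-trips flags and deltas", {
  pair <- simulate_condition_pair(displaced = c(5, 9), seed = 3)
  res <- compare_conditions(pair$A, pair$B)
  f <- withr::local_tempfile(fileext = ".csv")
  write_diff_report(res, f)
  rep <- readr::read_csv(f, show_col_types = FALSE)
  expect_equal(rep$residue_index, res$residue_index)
  expect_equal(rep$significant, res$significant)
})
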