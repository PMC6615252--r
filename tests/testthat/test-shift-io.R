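test_that("long-csv rows for one residue collapse into one record", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_index,residue_type,atom,shift_ppm",
               "19,L,H,8.21", "19,L,N,121.4"), f)
  tab <- read_shift_table(f, format = "long-csv")
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$residue_index, 19L)
  expect_equal(tab$residue_type, "L")
  expect_equal(tab$shift_H, 8.21)
  expect_equal(tab$shift_N, 121.4)
})

test_that("numbering offset shifts indices on import and is invertible", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_index,residue_type,atom,shift_ppm",
               "30,T,H,8.10", "30,T,N,115.0"), f)
  tab <- read_shift_table(f, format = "long-csv", offset = 1L)
  expect_equal(tab$residue_index, 31L)   # T30 in the old numbering is T31
  back <- apply_offset(tab, -1L)
  expect_equal(back$residue_index, 30L)
  expect_equal(back$shift_H, tab$shift_H)  # only the index changes
  expect_equal(back$shift_N, tab$shift_N)
})

test_that("duplicate residue indices and bad numbers are hard errors", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_index,residue_type,atom,shift_ppm",
               "12,A,H,8.0", "12,A,H,8.1"), f)
  expect_error(read_shift_table(f, format = "long-csv"),
               "duplicate residue index: 12")
  g <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("residue_index,residue_type,shift_H_ppm,shift_N_ppm",
               "5,G,8.0,110.2", "6,A,oops,115.0"), g)
  expect_error(read_shift_table(g, format = "wide-csv"), "non-numeric")
  expect_error(read_shift_table(g, format = "wide-csv"), "row 2")
})

test_that("round trip is the identity for both dialects on random tables", {
  for (seed in 1:5) {
    tab <- random_shift_table(n = 10, seed = seed)
    for (fmt in c("wide-csv", "long-csv")) {
      f <- withr::local_tempfile(fileext = ".csv")
      write_shift_table(tab, f, format = fmt)
      back <- read_shift_table(f, format = fmt)
      expect_equal(back$residue_index, tab$residue_index)
      expect_equal(back$residue_type, tab$residue_type)
      expect_equal(back$shift_H, tab$shift_H, tolerance = 1e-8)
      expect_equal(back$shift_N, tab$shift_N, tolerance = 1e-8)
    }
  }
})

test_that("missing proline shifts survive the round trip as missing", {
  tab <- shift_table(c(3L, 4L), c("P", "G"),
                     c(NA, 8.5), c(NA, 109.8))
  f <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(tab, f, format = "long-csv")
  back <- read_shift_table(f, format = "long-csv")
  expect_true(is.na(back$shift_H[1]) && is.na(back$shift_N[1]))
  expect_false(any(back$shift_H == 0, na.rm = TRUE))  # never coerced to 0
})

test_that("wide and long serialisations of the same table agree record-by-record", {
  tab <- random_shift_table(n = 12, seed = 9)
  fw <- withr::local_tempfile(fileext = ".csv")
  fl <- withr::local_tempfile(fileext = ".csv")
  write_shift_table(tab, fw, "wide-csv")
  write_shift_table(tab, fl, "long-csv")
  expect_equal(st_cols(read_shift_table(fw, "wide-csv")),
               st_cols(read_shift_table(fl, "long-csv")))
})

test_that("proline rows with amide shifts are rejected", {
  expect_error(shift_table(1L, "P", 8.0, 120), "proline")
})

manifest_fixture <- function(dir, ratios) {
  tabs <- purrr::map(seq_along(ratios), function(i) {
    shift_table(1:5, "X", 8 + 0.01 * i * (1:5 %% 3), 110 + 0.1 * i)
  })
  files <- sprintf("t%02d.csv", seq_along(ratios))
  purrr::walk2(tabs, files, ~ write_shift_table(.x, file.path(dir, .y)))
  m <- list(protein_name = "PDZ2", ligand_sequence = "KRHSGSYLVTSV",
            protein_conc_mM = 0.25,
            points = purrr::map2(ratios, files,
                                 ~ list(molar_ratio = .x, table = .y)))
  path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(m, path)
  path
}

test_that("manifest with the standard ratio schedule yields the right ligand concentrations", {
  dir <- withr::local_tempdir()
  path <- manifest_fixture(dir, c(0, 1, 3, 5, 10, 20, 30))
  series <- read_series_manifest(path)
  expect_equal(nrow(series), 7L)
  expect_equal(series$ligand_conc, c(0, 0.25, 0.75, 1.25, 2.5, 5.0, 7.5))
  expect_equal(attr(series, "ligand_sequence"), "KRHSGSYLVTSV")
})

test_that("out-of-order manifest points come back sorted and sorting is idempotent", {
  dir <- withr::local_tempdir()
  path <- manifest_fixture(dir, c(10, 0, 30, 3, 1))
  series <- read_series_manifest(path)
  expect_equal(series$molar_ratio, c(0, 1, 3, 10, 30))
  expect_false(is.unsorted(series$ligand_conc))
})

test_that("a manifest without an apo point or with too few points is rejected", {
  dir <- withr::local_tempdir()
  expect_error(read_series_manifest(manifest_fixture(dir, c(1, 3, 5))),
               "apo reference required")
  dir2 <- withr::local_tempdir()
  expect_error(read_series_manifest(manifest_fixture(dir2, c(0, 1))),
               "at least 3")
})

test_that("series round trip through write_series/read_series_manifest", {
  g <- toy_series(seed = 7)
  dir <- withr::local_tempdir()
  read_back <- read_series_manifest(write_series(g$series, dir))
  expect_equal(read_back$ligand_conc, g$series$ligand_conc)
  expect_equal(as.data.frame(read_back$table[[3]])[c("shift_H", "shift_N")],
               as.data.frame(g$series$table[[3]])[c("shift_H", "shift_N")],
               tolerance = 1e-5)
})
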