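# Programmatic fixtures shared across test files.

# A random but valid shift table (prolines carry NA shifts).
random_shift_table <- function(n = 8, seed = 1) {
  withr::with_seed(seed, {
    types <- sample(cspkit:::AA1, n, replace = TRUE)
    pro <- types == "P"
    shift_table(
      residue_index = sort(sample(1:500, n)),
      residue_type  = types,
      shift_H = ifelse(pro, NA_real_, round(runif(n, 6, 10), 4)),
      shift_N = ifelse(pro, NA_real_, round(runif(n, 100, 135), 4)),
      label = paste0("rand", seed))
  })
}

# A small noise-free titration series with known truth.
toy_series <- function(K_D_uM = 286, n_residues = 12, seed = 42,
                       noise_sd_H = 0, noise_sd_N = 0, ...) {
  generate_series(synthetic_spec(
    K_D_true_uM = K_D_uM, n_residues = n_residues,
    responding_fraction = 0.5, noise_sd_H = noise_sd_H,
    noise_sd_N = noise_sd_N, seed = seed, ...))
}

# Minimal synthetic two-chain PDB text (fixed-width per the PDB standard);
# residues given as list(chain=, resid=, n_atoms=).
toy_pdb_lines <- function(residues) {
  serial <- 0L
  out <- c("HEADER    SYNTHETIC TEST STRUCTURE")
  atoms <- c(" N  ", " CA ", " C  ", " O  ")
  for (r in residues) {
    for (k in seq_len(r$n_atoms)) {
      serial <- serial + 1L
      out <- c(out, sprintf(
        "ATOM  %5d %s ALA %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %s",
        serial, atoms[(k - 1L) %% 4L + 1L], r$chain, r$resid,
        serial * 1.1, serial * 0.9, serial * 1.3, 1.00, 20.00,
        substr(trimws(atoms[(k - 1L) %% 4L + 1L]), 1, 1)))
    }
  }
  c(out, "END")
}

write_toy_pdb <- function(path, residues = list(
                            list(chain = "A", resid = 19L, n_atoms = 4L),
                            list(chain = "A", resid = 94L, n_atoms = 4L))) {
  writeLines(toy_pdb_lines(residues), path)
  path
}

# Column-wise view of a shift table, dropping condition labels and classes,
# for round-trip comparisons where the label is allowed to differ.
st_cols <- function(x) {
  y <- as.data.frame(x)
  attributes(y) <- attributes(y)[c("names", "row.names")]
  y
}
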