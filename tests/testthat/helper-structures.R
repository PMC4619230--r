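# Shared fixture builders. Everything is generated in code; seeds make
# every structure reproducible.

# protein-like random globule: anisotropic Gaussian cloud with a
# realistic mix of category tags
random_cloud <- function(n, seed, entry_id = paste0("rc", seed)) {
  withr::with_seed(seed, {
    r <- 1.6 * n^(1 / 3)
    p <- matrix(stats::rnorm(3 * n), ncol = 3) %*%
      diag(stats::runif(3, 0.4, 1.6)) * r / sqrt(3)
    tags <- sample(c("all", "hydrophobic", "positive", "negative"), n,
                   replace = TRUE, prob = c(0.55, 0.30, 0.08, 0.07))
    make_point_cloud(p, tags, entry_id = entry_id)
  })
}

# ready-to-fingerprint version
random_cloud_fp <- function(n, seed, mode = "grid") {
  fingerprint_3dp(assign_categories(random_cloud(n, seed)), mode = mode)
}

# a small database of coil fingerprints (cached per test file run)
coil_db <- local({
  cache <- NULL
  function(n = 20) {
    if (is.null(cache) || nrow(cache) < n) {
      cache <<- dplyr::bind_rows(lapply(seq_len(n), function(i) {
        fingerprint_3dp(assign_categories(
          make_coil("GSTNQKLEDVRF", seed = i, entry_id = sprintf("coil%02d", i))
        ))
      }))
    }
    cache[seq_len(n), ]
  }
})

bits_of <- function(fp) as.numeric(unlist(fp[paste0("B", 1:136)]))

# hand-written raw PDB text fixtures
write_lines_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(lines, path)
  path
}

single_atom_pdb <- function() {
  write_lines_pdb(c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"
  ))
}

two_model_pdb <- function() {
  atoms <- function(offset) sprintf(
    "ATOM  %5d  CA  GLY A%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
    1:5, 1:5, offset + (1:5) * 3.8, 0, 0
  )
  write_lines_pdb(c("MODEL        1", atoms(0), "ENDMDL",
                    "MODEL        2", atoms(100), "ENDMDL", "END"))
}
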