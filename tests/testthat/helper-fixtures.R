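# Shared fixtures, all generated in code.

# Write a two-column MetaPhlAn-style profile file and return its path.
write_profile_file <- function(lines, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- tempfile("profile", tmpdir = dir, fileext = ".tsv")
  writeLines(lines, path)
  path
}

# Random wide abundance tibble with rows summing to 1.
random_abundance <- function(n_samples, n_features, seed = NULL,
                             prefix = "sp", sparsity = 0.4) {
  gen <- function() {
    m <- matrix(stats::rexp(n_samples * n_features), n_samples, n_features)
    m[stats::runif(length(m)) < sparsity] <- 0
    zero <- rowSums(m) == 0
    m[zero, 1] <- 1
    m <- m / rowSums(m)
    colnames(m) <- sprintf("%s%03d", prefix, seq_len(n_features))
    rownames(m) <- sprintf("s%04d", seq_len(n_samples))
    dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                     tibble::as_tibble(m, .name_repair = "minimal"))
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

simple_metadata <- function(sample_ids, groups, phenotypes = groups) {
  tibble::tibble(sample_id = sample_ids, phenotype = phenotypes,
                 group = groups, study_id = "test")
}

# Abundance table in which each sample has exactly the requested number of
# present species from two disjoint sets (plus a filler feature absorbing
# the rest of the mass). Presence abundance is 1e-3 >> the 1e-5 threshold.
richness_table <- function(r_h, r_n, n_h_set = 10, n_n_set = 10) {
  n <- length(r_h)
  feats <- c(sprintf("h%02d", seq_len(n_h_set)), sprintf("n%02d", seq_len(n_n_set)),
             "filler")
  m <- matrix(0, n, length(feats), dimnames = list(sprintf("s%03d", seq_len(n)), feats))
  for (i in seq_len(n)) {
    if (r_h[i] > 0) m[i, seq_len(r_h[i])] <- 1e-3
    if (r_n[i] > 0) m[i, n_h_set + seq_len(r_n[i])] <- 1e-3
    m[i, "filler"] <- 1 - sum(m[i, ])
  }
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

# Independent brute-force Bray-Curtis (loop form, no shared code path).
bc_brute <- function(a, b) {
  num <- 0; den <- 0
  for (j in seq_along(a)) {
    num <- num + min(a[j], b[j])
    den <- den + a[j] + b[j]
  }
  1 - 2 * num / den
}
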