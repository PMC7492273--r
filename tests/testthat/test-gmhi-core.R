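test_that("collective abundance matches the hand-evaluated formula", {
  # set {A,B,C}, A = 0.1, B = 0.2, C absent, effective size 3:
  # psi = (2/3) * (|0.1 ln 0.1| + |0.2 ln 0.2|) = (2/3) * 0.552146 = 0.368097
  out <- collective_abundance(c(A = 0.1, B = 0.2, D = 0.7), c("A", "B", "C"), 3)
  expect_identical(out$richness, 2L)
  expect_equal(out$psi, (2 / 3) * (abs(0.1 * log(0.1)) + abs(0.2 * log(0.2))))
  expect_equal(out$psi, 0.368097, tolerance = 1e-5)

  # no set species present
  none <- collective_abundance(c(X = 1), c("A", "B"), 2)
  expect_equal(none$psi, 0)
  expect_identical(none$richness, 0L)

  # a single set species at abundance 1 contributes nothing (ln 1 = 0)
  one <- collective_abundance(c(A = 1), "A", 1)
  expect_identical(one$richness, 1L)
  expect_equal(one$psi, 0)

  # below-threshold species are absent
  sub <- collective_abundance(c(A = 9e-6, B = 0.5), c("A", "B"), 2)
  expect_identical(sub$richness, 1L)
  expect_error(collective_abundance(c(A = 1), "A", 0), "positive")
})

test_that("psi never decreases when a present set species is added", {
  withr::with_seed(33, {
    for (i in 1:20) {
      k <- sample(3:6, 1)
      ab <- stats::runif(k, 1e-4, 0.3)
      names(ab) <- paste0("s", seq_len(k))
      set_small <- paste0("s", seq_len(k - 1))
      set_big <- paste0("s", seq_len(k))
      psi_small <- collective_abundance(ab, set_small, 10)$psi
      psi_big <- collective_abundance(ab, set_big, 10)$psi
      expect_gte(psi_big, psi_small)
    }
  })
})

test_that("extreme-rank counts use closest-integer rounding with a floor of 1", {
  expect_identical(extreme_sample_count(2636), 26L)
  expect_identical(extreme_sample_count(1711), 17L)
  expect_identical(extreme_sample_count(10), 1L)   # floor at 1
  expect_identical(extreme_sample_count(150), 2L)  # 1.5 rounds away from zero
  expect_identical(extreme_sample_count(149), 1L)
})

test_that("effective set sizes come from the two-key extreme ranking", {
  # all samples identical with R_H = 5, R_N = 2
  tab <- richness_table(rep(5, 12), rep(2, 12))
  md <- simple_metadata(tab$sample_id, rep(c("healthy", "nonhealthy"), 6))
  sz <- estimate_effective_set_sizes(tab, md, sprintf("h%02d", 1:10),
                                     sprintf("n%02d", 1:10))
  expect_equal(sz$size_h_eff, 5)
  expect_equal(sz$size_n_eff, 2)
  expect_identical(sz$k_h, 1L)
  expect_identical(sz$k_n, 1L)
})

test_that("degenerate zero medians error unless the nominal fallback is requested", {
  tab <- richness_table(rep(0, 8), rep(2, 8))
  md <- simple_metadata(tab$sample_id, rep(c("healthy", "nonhealthy"), 4))
  expect_error(
    estimate_effective_set_sizes(tab, md, sprintf("h%02d", 1:10),
                                 sprintf("n%02d", 1:10)),
    "fallback_to_nominal"
  )
  sz <- estimate_effective_set_sizes(tab, md, sprintf("h%02d", 1:10),
                                     sprintf("n%02d", 1:10),
                                     fallback_to_nominal = TRUE)
  expect_equal(sz$size_h_eff, 10)
})

test_that("effective sizes match an independent sort-and-median oracle", {
  withr::with_seed(37, {
    r_h <- sample(0:10, 40, replace = TRUE)
    r_n <- sample(0:10, 40, replace = TRUE)
    r_h[r_h == 0 & r_n == 0] <- 1  # avoid fully empty samples
  })
  tab <- richness_table(r_h, r_n)
  n_h_grp <- 25
  md <- simple_metadata(tab$sample_id,
                        rep(c("healthy", "nonhealthy"), c(n_h_grp, 40 - n_h_grp)))
  sz <- estimate_effective_set_sizes(tab, md, sprintf("h%02d", 1:10),
                                     sprintf("n%02d", 1:10),
                                     fallback_to_nominal = TRUE)
  # oracle: explicit data-frame sort, then medians over the k extremes
  df <- data.frame(r_h = r_h, r_n = r_n)
  df <- df[order(df$r_n, -df$r_h), ]
  k_h <- max(1, round(n_h_grp / 100))
  k_n <- max(1, round((40 - n_h_grp) / 100))
  expect_identical(sz$k_h, as.integer(k_h))
  expect_identical(sz$k_n, as.integer(k_n))
  expect_equal(sz$size_h_eff, stats::median(utils::head(df$r_h, k_h)))
  expect_equal(sz$size_n_eff, stats::median(utils::tail(df$r_n, k_n)))
})

test_that("a balanced sample scores exactly 0 and classifies as neither", {
  sig <- gmhi_signature(m_h = c("A", "B"), m_n = c("C", "D"),
                        size_h_eff = 2, size_n_eff = 2)
  sample <- c(A = 0.1, B = 0.2, C = 0.1, D = 0.2, E = 0.4)
  sc <- gmhi_score(sample, sig)
  expect_identical(sc$gmhi, 0)
  expect_identical(sc$label, "neither")
  expect_equal(sc$psi_h, sc$psi_n)
})

test_that("a sample with only health-prevalent species classifies healthy", {
  sig <- gmhi_signature(m_h = "A", m_n = "B")
  sc <- gmhi_score(c(A = 1e-3, X = 1 - 1e-3), sig)
  expect_gt(sc$gmhi, 0)
  expect_identical(sc$label, "healthy")
  # with a zero pseudo-count the literal formula diverges, with a warning
  sig0 <- gmhi_signature(m_h = "A", m_n = "B", pseudo_count = 0)
  expect_warning(sc0 <- gmhi_score(c(A = 1e-3, X = 1 - 1e-3), sig0), "infinite")
  expect_identical(sc0$gmhi, Inf)
})

test_that("exchanging the two sets negates the index exactly", {
  withr::with_seed(41, {
    for (i in 1:10) {
      ab <- stats::runif(8, 1e-4, 0.2)
      names(ab) <- paste0("s", 1:8)
      sig <- gmhi_signature(paste0("s", 1:3), paste0("s", 4:8),
                            size_h_eff = 2.5, size_n_eff = 4)
      swapped <- gmhi_signature(paste0("s", 4:8), paste0("s", 1:3),
                                size_h_eff = 4, size_n_eff = 2.5)
      expect_equal(gmhi_score(ab, swapped)$gmhi, -gmhi_score(ab, sig)$gmhi,
                   tolerance = 1e-12)
    }
  })
})

test_that("scaling both effective sizes leaves the index unchanged (eps = 0)", {
  ab <- c(s1 = 0.05, s2 = 0.1, s3 = 0.02, s4 = 0.4, s5 = 0.43)
  sig <- gmhi_signature(c("s1", "s2"), c("s3", "s4"),
                        size_h_eff = 2, size_n_eff = 2, pseudo_count = 0)
  sig_scaled <- gmhi_signature(c("s1", "s2"), c("s3", "s4"),
                               size_h_eff = 1, size_n_eff = 1, pseudo_count = 0)
  # same constant (1/2) multiplies both psi values: the ratio is unchanged
  expect_equal(gmhi_score(ab, sig)$gmhi, gmhi_score(ab, sig_scaled)$gmhi,
               tolerance = 1e-12)
})

test_that("score_samples equals looped gmhi_score and preserves order", {
  co <- generate_cohort(cohort_spec(n_h = 50, n_n = 50, n_species = 40, seed = 43))
  sig <- fit_signature(co$abundance, co$metadata)
  sc <- score_samples(co$abundance, sig)
  expect_identical(sc$sample_id, co$abundance$sample_id)
  for (i in c(1, 25, 77, 100)) {
    row <- as.numeric(co$abundance[i, -1])
    names(row) <- names(co$abundance)[-1]
    one <- gmhi_score(row, sig)
    expect_equal(sc$gmhi[i], one$gmhi, tolerance = 1e-12)
    expect_identical(sc$r_h[i], one$r_h)
    expect_equal(sc$psi_n[i], one$psi_n, tolerance = 1e-12)
  }
})

test_that("a table missing every signature species scores 0 with a warning", {
  tab <- random_abundance(3, 4, seed = 47, prefix = "other")
  sig <- gmhi_signature(c("absent1"), c("absent2"))
  expect_warning(sc <- score_samples(tab, sig), "No signature species")
  expect_equal(sc$gmhi, rep(0, 3))
  expect_identical(sc$label, rep("neither", 3))
})

test_that("signature species match across naming conventions", {
  tab <- tibble::tibble(
    sample_id = "s1",
    `k__Bacteria|g__Gemella|s__Gemella_morbillorum` = 0.4,
    `s__Streptococcus_mitis_oralis_pneumoniae` = 0.6
  )
  sig <- gmhi_signature(m_h = "Gemella morbillorum",
                        m_n = "Streptococcus mitis/oralis/pneumoniae")
  sc <- suppressMessages(score_samples(tab, sig))
  expect_identical(sc$r_h, 1L)
  expect_identical(sc$r_n, 1L)
})

test_that("the packaged 50-species model loads with its printed prevalences", {
  sig <- suppressMessages(load_packaged_signature())
  expect_length(sig$m_h, 7)
  expect_length(sig$m_n, 43)
  expect_length(c(sig$m_h, sig$m_n), 50)
  expect_equal(sig$theta_f, 1.4)
  expect_equal(sig$theta_d, 0.10)
  ang <- sig$prevalence[sig$prevalence$feature_id == "Bifidobacterium angulatum", ]
  expect_equal(ang$p_h, 11.9)
  expect_equal(ang$p_n, 1.5)
  expect_true("Bifidobacterium angulatum" %in% sig$m_h)
  expect_error(load_packaged_signature("nope"), "Unknown packaged signature")
})

test_that("every packaged species passes its own thresholds on printed prevalences", {
  sig <- suppressMessages(load_packaged_signature())
  prev <- sig$prevalence
  # printed prevalences are percentages rounded to one decimal: allow the
  # +/-0.05 rounding envelope on each prevalence
  for (i in seq_len(nrow(prev))) {
    hp <- prev$feature_id[i] %in% sig$m_h
    big <- if (hp) prev$p_h[i] else prev$p_n[i]
    small <- if (hp) prev$p_n[i] else prev$p_h[i]
    expect_gte(big - small, 10 - 0.1 - 1e-9)          # difference >= 10%
    expect_gte((big + 0.05) / max(small - 0.05, 0.05), 1.4)  # fold >= 1.4
  }
})

test_that("signature files round-trip through write/read", {
  withr::local_tempdir() -> dir
  sig <- gmhi_signature(c("Alpha one", "Beta two"), c("Gamma three"),
                        theta_f = 1.5, theta_d = 0.075,
                        size_h_eff = 1.5, size_n_eff = 1,
                        prevalence = tibble::tibble(
                          feature_id = c("Alpha one", "Beta two", "Gamma three"),
                          p_h = c(0.5, 0.4, 0.1), p_n = c(0.1, 0.2, 0.4)
                        ))
  path <- file.path(dir, "sig.tsv")
  write_signature(sig, path)
  sig2 <- read_signature(path)
  expect_identical(sig2$m_h, sig$m_h)
  expect_identical(sig2$m_n, sig$m_n)
  expect_equal(sig2$theta_f, sig$theta_f)
  expect_equal(sig2$theta_d, sig$theta_d)
  expect_equal(sig2$size_h_eff, sig$size_h_eff)
  expect_equal(sig2$size_n_eff, sig$size_n_eff)
  expect_equal(sig2$pseudo_count, sig$pseudo_count)
  expect_equal(as.data.frame(sig2$prevalence), as.data.frame(sig$prevalence))
})

test_that("gmhi_signature validates its invariants", {
  expect_error(gmhi_signature(c("A"), c("A")), "disjoint")
  expect_error(gmhi_signature("A", "B", size_h_eff = 0), "size_h_eff")
  expect_error(gmhi_signature("A", "B", size_n_eff = 2), "size_n_eff")
  expect_error(gmhi_signature("A", "B", pseudo_count = -1), "nonnegative")
})
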