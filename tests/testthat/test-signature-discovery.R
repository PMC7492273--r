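test_that("prevalence counts presence with an inclusive threshold", {
  tab <- tibble::tibble(
    sample_id = c("a", "b", "c"),
    sp1 = c(0, 2e-5, 0.5),
    sp2 = c(1e-5, 0, 0),      # exactly at the threshold counts as present
    sp3 = c(9.9e-6, 0, 0)     # just below does not
  )
  prev <- compute_prevalence(tab)
  expect_equal(prev$prevalence, c(2 / 3, 1 / 3, 0))
  expect_error(compute_prevalence(tab, sample_ids = character(0)), "empty group")
  expect_error(compute_prevalence(tab, sample_ids = "nope"), "not in the table")
})

test_that("prevalence matches a naive counting loop on a random table", {
  tab <- random_abundance(30, 50, seed = 23)
  ids <- tab$sample_id[1:17]
  prev <- compute_prevalence(tab, ids)
  m <- as.matrix(tab[tab$sample_id %in% ids, -1])
  for (j in seq_len(ncol(m))) {
    cnt <- 0
    for (i in seq_len(nrow(m))) if (m[i, j] >= 1e-5) cnt <- cnt + 1
    expect_equal(prev$prevalence[j], cnt / nrow(m))
  }
})

test_that("prevalence records satisfy their algebraic invariants", {
  co <- generate_cohort(cohort_spec(n_h = 60, n_n = 40, n_species = 30, seed = 2))
  prev <- prevalence_table(co$abundance, co$metadata)
  expect_equal(prev$d_hn, -prev$d_nh)
  both_pos <- prev$p_h > 0 & prev$p_n > 0
  expect_equal(prev$f_hn[both_pos] * prev$f_nh[both_pos],
               rep(1, sum(both_pos)), tolerance = 1e-12)
  expect_true(all(prev$p_h >= 0 & prev$p_h <= 1 & prev$p_n >= 0 & prev$p_n <= 1))
})

test_that("signature selection applies the joint fold/difference criteria", {
  # a species present in every healthy sample and no nonhealthy sample is
  # selected for any finite fold threshold (fold = +Inf by convention)
  tab <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:20),
    always_h = c(rep(0.5, 10), rep(0, 10)),
    noise = rep(0.5, 20),
    filler = c(rep(0, 10), rep(0.5, 10))
  )
  md <- simple_metadata(tab$sample_id, rep(c("healthy", "nonhealthy"), each = 10))
  sig <- select_signature(tab, md, theta_f = 100, theta_d = 1)
  expect_identical(sig$m_h, "always_h")
  expect_identical(sig$m_n, "filler")
})

test_that("the published example prevalences pass the published thresholds", {
  # health-prevalent membership at p_H = 30.8%, p_N = 13.5%:
  # fold ~ 2.28 >= 1.4 and difference ~ 17.3% >= 10%
  n_h <- 500; n_n <- 1000
  mk <- function(n, n_present) c(rep(1e-3, n_present), rep(0, n - n_present))
  tab <- tibble::tibble(
    sample_id = sprintf("s%04d", seq_len(n_h + n_n)),
    bifido = c(mk(n_h, 154), mk(n_n, 135)),   # 0.308 vs 0.135
    filler = 1 - c(mk(n_h, 154), mk(n_n, 135))
  )
  md <- simple_metadata(tab$sample_id,
                        rep(c("healthy", "nonhealthy"), c(n_h, n_n)))
  expect_warning(sig <- select_signature(tab, md, theta_f = 1.4, theta_d = 0.10),
                 "health-scarce")
  expect_true("bifido" %in% sig$m_h)
  prev <- sig$prevalence[sig$prevalence$feature_id == "bifido", ]
  expect_equal(prev$p_h, 0.308)
  expect_equal(prev$p_n, 0.135)
})

test_that("swapping group labels swaps the two species sets exactly", {
  co <- generate_cohort(cohort_spec(n_h = 80, n_n = 80, n_species = 40, seed = 5))
  sig <- suppressWarnings(select_signature(co$abundance, co$metadata, 1.2, 0.05))
  md_swapped <- co$metadata
  md_swapped$group <- ifelse(md_swapped$group == "healthy", "nonhealthy", "healthy")
  sig_sw <- suppressWarnings(select_signature(co$abundance, md_swapped, 1.2, 0.05))
  expect_setequal(sig_sw$m_h, sig$m_n)
  expect_setequal(sig_sw$m_n, sig$m_h)
})

test_that("the two selected sets are always disjoint", {
  for (seed in 1:5) {
    co <- generate_cohort(cohort_spec(n_h = 40, n_n = 40, n_species = 30,
                                      prevalence_gap = 0.2, seed = seed))
    sig <- suppressWarnings(select_signature(co$abundance, co$metadata, 1.1, 0.025))
    expect_length(intersect(sig$m_h, sig$m_n), 0)
  }
})

test_that("balanced accuracy follows the strict-sign definition", {
  expect_equal(balanced_accuracy(c(1, 1, -1, -1),
                                 c("healthy", "healthy", "nonhealthy", "nonhealthy"))$chi, 1)
  expect_equal(balanced_accuracy(c(1, -1, 1, -1),
                                 c("healthy", "healthy", "nonhealthy", "nonhealthy"))$chi, 0.5)
  # h = 0 is incorrect for both groups
  acc0 <- balanced_accuracy(c(0, 0), c("healthy", "nonhealthy"))
  expect_equal(acc0$chi, 0)
  expect_equal(acc0$h_zero_h + acc0$h_zero_n, 2L)
  expect_error(balanced_accuracy(c(1, 2), c("healthy", "healthy")), "Both groups")
})

test_that("balanced accuracy equals a direct proportion computation", {
  withr::with_seed(29, {
    scores <- stats::rnorm(200)
    groups <- sample(c("healthy", "nonhealthy"), 200, replace = TRUE,
                     prob = c(0.6, 0.4))
  })
  acc <- balanced_accuracy(scores, groups)
  ph <- sum(scores > 0 & groups == "healthy") / sum(groups == "healthy")
  pn <- sum(scores < 0 & groups == "nonhealthy") / sum(groups == "nonhealthy")
  expect_equal(acc$chi, (ph + pn) / 2)
  expect_equal(acc$chi, (acc$prop_h_correct + acc$prop_n_correct) / 2)
  # invariant to sample order
  perm <- withr::with_seed(2, sample(200))
  expect_equal(balanced_accuracy(scores[perm], groups[perm])$chi, acc$chi)
})

test_that("grid search returns the single cell of a one-cell grid", {
  co <- generate_cohort(cohort_spec(n_h = 60, n_n = 60, n_species = 40, seed = 7))
  gs <- gmhi_grid_search(co$abundance, co$metadata,
                         theta_f_grid = 1.4, theta_d_grid = 0.10)
  expect_equal(nrow(gs$grid), 1)
  expect_equal(gs$best_signature$theta_f, 1.4)
  expect_equal(gs$best_signature$theta_d, 0.10)
})

test_that("grid-search ties break toward larger thresholds", {
  # perfectly separating planted structure: the same sets are selected in
  # every cell of a small grid, so every chi ties and the most stringent
  # cell must win
  co <- generate_cohort(cohort_spec(n_h = 50, n_n = 50, n_species = 20,
                                    prevalence_base = 0.05,
                                    prevalence_gap = 0.9, seed = 9))
  gs <- gmhi_grid_search(co$abundance, co$metadata,
                         theta_f_grid = c(1.1, 1.2),
                         theta_d_grid = c(0.05, 0.10))
  chis <- gs$grid$chi
  expect_true(max(chis) - min(chis) < 1e-12)
  expect_equal(gs$best_signature$theta_f, 1.2)
  expect_equal(gs$best_signature$theta_d, 0.10)
})

test_that("empty-set grid cells record NA rather than aborting", {
  co <- generate_cohort(cohort_spec(n_h = 40, n_n = 40, n_species = 20,
                                    prevalence_gap = 0, seed = 11))
  gs <- suppressWarnings(gmhi_grid_search(co$abundance, co$metadata,
                                          theta_f_grid = c(1.2, 50),
                                          theta_d_grid = c(0.025, 0.9)))
  expect_true(any(is.na(gs$grid$chi)))
  expect_false(is.na(gs$chi_max))
})

test_that("cross-validation is deterministic under a fixed seed", {
  co <- generate_cohort(cohort_spec(n_h = 60, n_n = 60, n_species = 40, seed = 13))
  cv1 <- suppressWarnings(gmhi_cross_validate(co$abundance, co$metadata, k = 3,
                                              seed = 42))
  cv2 <- suppressWarnings(gmhi_cross_validate(co$abundance, co$metadata, k = 3,
                                              seed = 42))
  expect_equal(tidy(cv1), tidy(cv2))
  expect_equal(cv1$mean_chi, cv2$mean_chi)
  expect_error(gmhi_cross_validate(co$abundance, co$metadata, k = 100),
               "exceeds")
})

test_that("cross-validated accuracy is high on separable cohorts and ~0.5 under the null", {
  co <- generate_cohort(cohort_spec(n_h = 150, n_n = 150, n_species = 60,
                                    prevalence_base = 0.1,
                                    prevalence_gap = 0.7, seed = 17))
  cv <- suppressWarnings(gmhi_cross_validate(co$abundance, co$metadata, k = 5,
                                             seed = 1))
  expect_gt(cv$mean_chi, 0.9)

  # permutation null: shuffled labels, loose thresholds so sets stay
  # nonempty (theta_d must stay positive to keep the two sets disjoint)
  md_null <- co$metadata
  md_null$group <- withr::with_seed(99, sample(md_null$group))
  cv_null <- suppressWarnings(
    gmhi_cross_validate(co$abundance, md_null, k = 5, theta_f = 1,
                        theta_d = 0.01, seed = 1)
  )
  expect_lt(abs(cv_null$mean_chi - 0.5), 0.12)
})
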