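# Prevalence-based discovery of the health-prevalent / health-scarce
# species sets, balanced-accuracy threshold search, and cross-validation.

#' Per-feature prevalence within a set of samples
#'
#' Prevalence is the proportion of the group's samples in which the feature
#' is present, i.e. its relative abundance is at or above
#' `presence_threshold` (inclusive comparison).
#'
#' @param abundance Wide abundance tibble.
#' @param sample_ids Samples defining the group (default: all samples).
#' @param presence_threshold Presence threshold (default 1e-5).
#' @return A tibble with `feature_id` and `prevalence`.
#' @export
compute_prevalence <- function(abundance, sample_ids = NULL,
                               presence_threshold = 1e-5) {
  check_abundance(abundance)
  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, abundance$sample_id)
    if (length(missing)) {
      abort(sprintf("Samples not in the table: %s", paste(missing, collapse = ", ")))
    }
    abundance <- abundance[abundance$sample_id %in% sample_ids, , drop = FALSE]
  }
  if (nrow(abundance) == 0) abort("Cannot compute prevalence over an empty group.")
  m <- abund_matrix(abundance)
  tibble(feature_id = colnames(m),
         prevalence = unname(colMeans(m >= presence_threshold)))
}

#' Two-group prevalence records with effect sizes
#'
#' For every feature, the prevalence in the healthy group (`p_h`) and the
#' nonhealthy group (`p_n`), with the fold changes and differences in both
#' directions: `f_hn = p_h / p_n`, `d_hn = p_h - p_n`, and the mirrored
#' `f_nh`, `d_nh`. A fold change with a zero denominator and positive
#' numerator is `Inf` (it passes any finite threshold); 0/0 is `NaN` and the
#' feature is ineligible in that direction.
#'
#' @inheritParams compute_prevalence
#' @param metadata Metadata with `group` in healthy / nonhealthy.
#' @return A tibble with one row per feature: `feature_id`, `p_h`, `p_n`,
#'   `f_hn`, `f_nh`, `d_hn`, `d_nh`.
#' @export
prevalence_table <- function(abundance, metadata, presence_threshold = 1e-5) {
  check_metadata(metadata)
  ids_h <- group_sample_ids(metadata, "healthy")
  ids_n <- group_sample_ids(metadata, "nonhealthy")
  if (!length(ids_h) || !length(ids_n)) {
    abort("Both healthy and nonhealthy groups must be nonempty.")
  }
  ids_h <- intersect(ids_h, abundance$sample_id)
  ids_n <- intersect(ids_n, abundance$sample_id)
  ph <- compute_prevalence(abundance, ids_h, presence_threshold)
  pn <- compute_prevalence(abundance, ids_n, presence_threshold)
  tibble(
    feature_id = ph$feature_id,
    p_h = ph$prevalence,
    p_n = pn$prevalence,
    f_hn = ph$prevalence / pn$prevalence,
    f_nh = pn$prevalence / ph$prevalence,
    d_hn = ph$prevalence - pn$prevalence,
    d_nh = pn$prevalence - ph$prevalence
  )
}

#' Select health-prevalent and health-scarce species sets
#'
#' A feature joins the health-prevalent set `M_H` when its prevalence fold
#' change and difference toward the healthy group jointly satisfy
#' `f_hn >= theta_f` and `d_hn >= theta_d`; the health-scarce set `M_N` uses
#' the mirrored criteria. The two sets are disjoint by construction whenever
#' `theta_d > 0`.
#'
#' @inheritParams prevalence_table
#' @param theta_f Fold-change threshold (>= 1).
#' @param theta_d Difference threshold in \[0, 1\].
#' @param pseudo_count Pseudo-count recorded in the returned signature.
#' @return A [gmhi_signature()] whose effective set sizes default to the
#'   nominal cardinalities (fit them with
#'   [estimate_effective_set_sizes()] or use [fit_signature()]). Either set
#'   may be empty, with a warning.
#' @export
select_signature <- function(abundance, metadata, theta_f = 1.4,
                             theta_d = 0.10, presence_threshold = 1e-5,
                             pseudo_count = 1e-5) {
  if (!is.numeric(theta_f) || theta_f < 1) abort("`theta_f` must be >= 1.")
  if (!is.numeric(theta_d) || theta_d < 0 || theta_d > 1) {
    abort("`theta_d` must be in [0, 1].")
  }
  prev <- prevalence_table(abundance, metadata, presence_threshold)
  in_h <- !is.nan(prev$f_hn) & prev$f_hn >= theta_f & prev$d_hn >= theta_d
  in_n <- !is.nan(prev$f_nh) & prev$f_nh >= theta_f & prev$d_nh >= theta_d
  if (!any(in_h)) warn("No health-prevalent species passed the thresholds.")
  if (!any(in_n)) warn("No health-scarce species passed the thresholds.")
  m_h <- prev$feature_id[in_h]
  m_n <- prev$feature_id[in_n]
  gmhi_signature(
    m_h = m_h, m_n = m_n, theta_f = theta_f, theta_d = theta_d,
    size_h_eff = max(length(m_h), 1), size_n_eff = max(length(m_n), 1),
    presence_threshold = presence_threshold, pseudo_count = pseudo_count,
    prevalence = prev[in_h | in_n, , drop = FALSE],
    note = "selected by joint prevalence fold-change/difference thresholds"
  )
}

#' Balanced classification accuracy of an index
#'
#' The mean of the proportion of healthy samples with a strictly positive
#' index and the proportion of nonhealthy samples with a strictly negative
#' index; an index of exactly 0 is counted incorrect for both groups.
#'
#' @param scores Numeric index values (e.g. the `gmhi` column of
#'   [score_samples()]).
#' @param groups Group labels aligned with `scores`.
#' @param healthy,nonhealthy The two labels.
#' @return A one-row tibble: `chi`, `prop_h_correct`, `prop_n_correct`,
#'   group sizes and the counts of positive / negative / zero scores per
#'   group.
#' @export
balanced_accuracy <- function(scores, groups, healthy = "healthy",
                              nonhealthy = "nonhealthy") {
  if (length(scores) != length(groups)) {
    abort("`scores` and `groups` must be aligned.")
  }
  h <- scores[groups == healthy]
  n <- scores[groups == nonhealthy]
  if (!length(h) || !length(n)) {
    abort("Both groups must be represented in `groups`.")
  }
  prop_h <- mean(h > 0)
  prop_n <- mean(n < 0)
  tibble(
    chi = (prop_h + prop_n) / 2,
    prop_h_correct = prop_h, prop_n_correct = prop_n,
    n_h = length(h), n_n = length(n),
    h_pos_h = sum(h > 0), h_neg_h = sum(h < 0), h_zero_h = sum(h == 0),
    h_pos_n = sum(n > 0), h_neg_n = sum(n < 0), h_zero_n = sum(n == 0)
  )
}

#' Grid search of the prevalence thresholds by balanced accuracy
#'
#' For every pair of thresholds, selects the species sets, fits the
#' effective set sizes, scores all samples and records the balanced
#' accuracy; a cell whose selection yields an empty set records `NA` rather
#' than aborting. The winner is the cell with maximal accuracy, ties broken
#' deterministically toward larger `theta_f`, then larger `theta_d` (the
#' more parsimonious signature).
#'
#' @inheritParams select_signature
#' @param theta_f_grid,theta_d_grid Threshold grids.
#' @param fallback_to_nominal Passed to [estimate_effective_set_sizes()].
#' @return An object of class `gmhi_grid`: list with `grid` (tibble of
#'   `theta_f`, `theta_d`, `n_mh`, `n_mn`, `chi`), `best_signature` (a fully
#'   fitted [gmhi_signature()]), `chi_max` and `accuracy` (the winner's
#'   [balanced_accuracy()] report).
#' @export
gmhi_grid_search <- function(abundance, metadata,
                             theta_f_grid = seq(1.1, 2.0, by = 0.1),
                             theta_d_grid = seq(0.025, 0.200, by = 0.025),
                             presence_threshold = 1e-5, pseudo_count = 1e-5,
                             fallback_to_nominal = FALSE) {
  if (!length(theta_f_grid) || !length(theta_d_grid)) {
    abort("Threshold grids must be nonempty.")
  }
  check_abundance(abundance)
  check_metadata(metadata)
  grp <- metadata$group[match(abundance$sample_id, metadata$sample_id)]
  prev <- prevalence_table(abundance, metadata, presence_threshold)
  cells <- tidyr::expand_grid(theta_f = sort(theta_f_grid),
                              theta_d = sort(theta_d_grid))
  eval_cell <- function(theta_f, theta_d) {
    in_h <- !is.nan(prev$f_hn) & prev$f_hn >= theta_f & prev$d_hn >= theta_d
    in_n <- !is.nan(prev$f_nh) & prev$f_nh >= theta_f & prev$d_nh >= theta_d
    n_mh <- sum(in_h); n_mn <- sum(in_n)
    if (n_mh == 0 || n_mn == 0) {
      return(tibble(n_mh = n_mh, n_mn = n_mn, chi = NA_real_))
    }
    m_h <- prev$feature_id[in_h]
    m_n <- prev$feature_id[in_n]
    sz <- tryCatch(
      estimate_effective_set_sizes(abundance, metadata, m_h, m_n,
                                   presence_threshold, fallback_to_nominal),
      error = function(e) NULL
    )
    if (is.null(sz)) return(tibble(n_mh = n_mh, n_mn = n_mn, chi = NA_real_))
    sig <- gmhi_signature(m_h, m_n, theta_f, theta_d,
                          sz$size_h_eff, sz$size_n_eff,
                          presence_threshold, pseudo_count)
    sc <- suppressMessages(score_samples(abundance, sig))
    acc <- balanced_accuracy(sc$gmhi, grp)
    tibble(n_mh = n_mh, n_mn = n_mn, chi = acc$chi)
  }
  res <- purrr::pmap_dfr(cells, eval_cell)
  grid <- dplyr::bind_cols(cells, res)
  if (all(is.na(grid$chi))) {
    abort("Every grid cell produced an empty species set; widen the grids.")
  }
  best_row <- grid |>
    dplyr::filter(.data$chi == max(.data$chi, na.rm = TRUE)) |>
    dplyr::arrange(dplyr::desc(.data$theta_f), dplyr::desc(.data$theta_d)) |>
    dplyr::slice(1)
  best_sig <- fit_signature(abundance, metadata,
                            theta_f = best_row$theta_f,
                            theta_d = best_row$theta_d,
                            presence_threshold = presence_threshold,
                            pseudo_count = pseudo_count,
                            fallback_to_nominal = fallback_to_nominal)
  sc <- suppressMessages(score_samples(abundance, best_sig))
  structure(list(
    grid = grid,
    best_signature = best_sig,
    chi_max = best_row$chi,
    accuracy = balanced_accuracy(sc$gmhi, grp)
  ), class = "gmhi_grid")
}

#' @export
print.gmhi_grid <- function(x, ...) {
  cat("GMHI threshold grid search\n")
  cat(sprintf("  %d cells; best balanced accuracy %.4f at fold change >= %.3g, difference >= %.3g\n",
              nrow(x$grid), x$chi_max,
              x$best_signature$theta_f, x$best_signature$theta_d))
  cat(sprintf("  best signature: %d health-prevalent, %d health-scarce species\n",
              length(x$best_signature$m_h), length(x$best_signature$m_n)))
  invisible(x)
}

#' Stratified k-fold cross-validation of the GMHI pipeline
#'
#' Folds are stratified by group with seeded shuffling. Within each fold,
#' the species sets and the effective set sizes are fitted on the training
#' folds only, and balanced accuracy is computed on the held-out fold.
#'
#' @inheritParams select_signature
#' @param k Number of folds (default 10); must not exceed either group size.
#' @param seed Integer seed for the fold shuffle (restored on exit).
#' @param fallback_to_nominal Passed to the per-fold size estimation.
#' @return An object of class `gmhi_cv`: list with `folds` (per-fold
#'   accuracy reports), `mean_chi` and the call parameters.
#' @export
gmhi_cross_validate <- function(abundance, metadata, k = 10, theta_f = 1.4,
                                theta_d = 0.10, seed = NULL,
                                presence_threshold = 1e-5,
                                pseudo_count = 1e-5,
                                fallback_to_nominal = TRUE) {
  check_abundance(abundance)
  check_metadata(metadata)
  ids_h <- intersect(group_sample_ids(metadata, "healthy"), abundance$sample_id)
  ids_n <- intersect(group_sample_ids(metadata, "nonhealthy"), abundance$sample_id)
  if (k > length(ids_h) || k > length(ids_n)) {
    abort("`k` exceeds the size of a group; reduce the number of folds.")
  }
  assign_folds <- function(ids) {
    ids <- sample(ids)
    stats::setNames(rep_len(seq_len(k), length(ids)), ids)
  }
  folds <- with_local_seed(seed, c(assign_folds(ids_h), assign_folds(ids_n)))
  grp <- metadata$group[match(abundance$sample_id, metadata$sample_id)]
  per_fold <- purrr::map_dfr(seq_len(k), function(fold) {
    test_ids <- names(folds)[folds == fold]
    train <- abundance[!abundance$sample_id %in% test_ids, , drop = FALSE]
    test <- abundance[abundance$sample_id %in% test_ids, , drop = FALSE]
    sig <- tryCatch(
      fit_signature(train, metadata, theta_f, theta_d,
                    presence_threshold, pseudo_count, fallback_to_nominal),
      error = function(e) NULL
    )
    if (is.null(sig)) {
      warn(sprintf("Fold %d: signature fitting failed; recorded as NA.", fold))
      return(tibble(fold = fold, n_test = nrow(test), chi = NA_real_))
    }
    sc <- suppressMessages(score_samples(test, sig))
    acc <- balanced_accuracy(sc$gmhi, grp[match(test$sample_id, abundance$sample_id)])
    dplyr::bind_cols(tibble(fold = fold, n_test = nrow(test)), acc)
  })
  structure(list(
    folds = per_fold,
    mean_chi = mean(per_fold$chi, na.rm = TRUE),
    k = k, theta_f = theta_f, theta_d = theta_d, seed = seed
  ), class = "gmhi_cv")
}

#' @export
print.gmhi_cv <- function(x, ...) {
  cat(sprintf("GMHI %d-fold cross-validation (fold thresholds %.3g / %.3g)\n",
              x$k, x$theta_f, x$theta_d))
  cat(sprintf("  mean balanced accuracy: %.4f\n", x$mean_chi))
  invisible(x)
}
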