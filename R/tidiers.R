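# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a GMHI signature
#'
#' @param x A [gmhi_signature()].
#' @param ... Unused.
#' @return A tibble with one row per signature species: `species`, `set`
#'   (`H+` / `H-`) and, when discovery prevalences are attached, the
#'   prevalence and effect-size columns.
#' @method tidy gmhi_signature
#' @export
tidy.gmhi_signature <- function(x, ...) {
  out <- tibble(
    species = c(x$m_h, x$m_n),
    set = c(rep("H+", length(x$m_h)), rep("H-", length(x$m_n)))
  )
  if (!is.null(x$prevalence)) {
    out <- dplyr::left_join(
      out, dplyr::rename(x$prevalence, species = "feature_id"), by = "species"
    )
  }
  out
}

#' @rdname tidy.gmhi_signature
#' @method glance gmhi_signature
#' @export
glance.gmhi_signature <- function(x, ...) {
  tibble(
    n_mh = length(x$m_h), n_mn = length(x$m_n),
    theta_f = x$theta_f, theta_d = x$theta_d,
    size_h_eff = x$size_h_eff, size_n_eff = x$size_n_eff,
    presence_threshold = x$presence_threshold, pseudo_count = x$pseudo_count
  )
}

#' Tidy a threshold grid search
#'
#' @param x A `gmhi_grid` object from [gmhi_grid_search()].
#' @param ... Unused.
#' @return `tidy()`: the full grid tibble (`theta_f`, `theta_d`, set sizes,
#'   `chi`); `glance()`: a one-row summary of the winning cell.
#' @method tidy gmhi_grid
#' @export
tidy.gmhi_grid <- function(x, ...) x$grid

#' @rdname tidy.gmhi_grid
#' @method glance gmhi_grid
#' @export
glance.gmhi_grid <- function(x, ...) {
  dplyr::bind_cols(
    tibble(chi_max = x$chi_max,
           theta_f = x$best_signature$theta_f,
           theta_d = x$best_signature$theta_d),
    glance(x$best_signature)[c("n_mh", "n_mn", "size_h_eff", "size_n_eff")]
  )
}

#' Tidy a cross-validation result
#'
#' @param x A `gmhi_cv` object from [gmhi_cross_validate()].
#' @param ... Unused.
#' @return `tidy()`: per-fold accuracy reports; `glance()`: a one-row
#'   summary with the mean and spread of the fold accuracies.
#' @method tidy gmhi_cv
#' @export
tidy.gmhi_cv <- function(x, ...) x$folds

#' @rdname tidy.gmhi_cv
#' @method glance gmhi_cv
#' @export
glance.gmhi_cv <- function(x, ...) {
  tibble(
    k = x$k, mean_chi = x$mean_chi,
    sd_chi = stats::sd(x$folds$chi, na.rm = TRUE),
    theta_f = x$theta_f, theta_d = x$theta_d
  )
}

#' Heatmap of balanced accuracy over the threshold grid
#'
#' @param object A `gmhi_grid` object.
#' @param ... Unused.
#' @return A ggplot: tiles of balanced accuracy by the two thresholds, with
#'   the winning cell outlined.
#' @method autoplot gmhi_grid
#' @export
autoplot.gmhi_grid <- function(object, ...) {
  g <- object$grid
  best <- tibble(theta_f = object$best_signature$theta_f,
                 theta_d = object$best_signature$theta_d)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$theta_f, y = .data$theta_d,
                                  fill = .data$chi)) +
    ggplot2::geom_tile() +
    ggplot2::geom_tile(data = best, fill = NA, colour = "black",
                       linewidth = 0.8) +
    ggplot2::scale_fill_viridis_c(name = "balanced\naccuracy", na.value = "grey85") +
    ggplot2::labs(x = "prevalence fold-change threshold",
                  y = "prevalence difference threshold") +
    ggplot2::theme_minimal()
}

#' Per-fold accuracy plot for a cross-validation
#'
#' @param object A `gmhi_cv` object.
#' @param ... Unused.
#' @return A ggplot of fold-level balanced accuracies with the mean marked.
#' @method autoplot gmhi_cv
#' @export
autoplot.gmhi_cv <- function(object, ...) {
  ggplot2::ggplot(object$folds, ggplot2::aes(x = factor(.data$fold), y = .data$chi)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$mean_chi, linetype = 2) +
    ggplot2::labs(x = "fold", y = "balanced accuracy") +
    ggplot2::theme_minimal()
}

#' Index distributions by group
#'
#' @param scores Tibble from [score_samples()].
#' @param metadata Sample metadata with a `group` column.
#' @param group_col Metadata column to plot by.
#' @return A ggplot: boxplots of the index by group over jittered samples.
#' @export
plot_score_groups <- function(scores, metadata, group_col = "group") {
  check_metadata(metadata)
  d <- dplyr::inner_join(scores, metadata[c("sample_id", group_col)],
                         by = "sample_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data[[group_col]], y = .data$gmhi)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3) +
    ggplot2::labs(x = NULL, y = "GMHI") +
    ggplot2::theme_minimal()
}
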