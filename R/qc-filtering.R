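# Sample-level and feature-level quality filters and BMI reclassification.

#' Flag unclassified / unknown features
#'
#' @param feature_id Character vector of feature names or lineages.
#' @return Logical vector: `TRUE` for names marking unknown or unclassified
#'   species-level entities.
#' @export
is_unclassified_feature <- function(feature_id) {
  grepl("unclassified|unknown", feature_id, ignore.case = TRUE)
}

#' Flag viral features
#'
#' Detection uses the clade lineage (kingdom `k__Viruses`) when available,
#' either embedded in the feature name or supplied through a `lineages`
#' lookup table.
#'
#' @param feature_id Character vector of feature names or lineages.
#' @param lineages Optional tibble with columns `feature_id`, `lineage`
#'   (see [lineage_table()]).
#' @return Logical vector.
#' @export
is_viral_feature <- function(feature_id, lineages = NULL) {
  x <- feature_id
  if (!is.null(lineages)) {
    i <- match(feature_id, lineages$feature_id)
    x <- ifelse(is.na(i), feature_id, lineages$lineage[i])
  }
  grepl("k__Viruses", x, fixed = TRUE)
}

#' Reclassify healthy-labeled samples by reported BMI
#'
#' Subjects labeled healthy whose reported body mass index falls in the
#' underweight (BMI < 18.5), overweight (25 <= BMI < 30) or obese
#' (BMI >= 30) range are moved to the nonhealthy group with the matching
#' abnormal-bodyweight phenotype. Samples without a BMI are unchanged.
#'
#' @param metadata Sample metadata tibble with columns `group`, `phenotype`
#'   and (optionally) `bmi`.
#' @return The metadata tibble with updated `phenotype` and `group`.
#' @export
reclassify_by_bmi <- function(metadata) {
  check_metadata(metadata)
  if (!"bmi" %in% names(metadata)) return(metadata)
  bmi <- metadata$bmi
  if (any(!is.na(bmi) & bmi < 0)) abort("BMI values must be nonnegative.")
  healthy <- !is.na(metadata$group) & metadata$group == "healthy" & !is.na(bmi)
  cls <- rep(NA_character_, nrow(metadata))
  cls[healthy & bmi < 18.5] <- "underweight"
  cls[healthy & bmi >= 25 & bmi < 30] <- "overweight"
  cls[healthy & bmi >= 30] <- "obese"
  move <- !is.na(cls)
  metadata$phenotype[move] <- cls[move]
  metadata$group[move] <- "nonhealthy"
  metadata
}

#' Per-sample unclassified fraction
#'
#' @param abundance Wide abundance tibble.
#' @param unclassified_features Optional character vector naming the
#'   unclassified feature columns; defaults to pattern matching with
#'   [is_unclassified_feature()].
#' @return A tibble with `sample_id` and `unclassified_frac` (fraction of
#'   the sample's total abundance assigned to unclassified entities).
#' @export
unclassified_fraction <- function(abundance, unclassified_features = NULL) {
  check_abundance(abundance)
  m <- abund_matrix(abundance)
  uf <- unclassified_features %||% colnames(m)[is_unclassified_feature(colnames(m))]
  tot <- rowSums(m)
  frac <- if (length(uf)) {
    rowSums(m[, colnames(m) %in% uf, drop = FALSE]) / pmax(tot, .Machine$double.eps)
  } else {
    rep(0, nrow(m))
  }
  tibble(sample_id = rownames(m), unclassified_frac = unname(frac))
}

#' Remove samples dominated by unclassified taxonomies
#'
#' Samples whose unclassified fraction strictly exceeds
#' `max_unclassified_frac` (default 5%) are dropped; a sample at exactly the
#' threshold is retained.
#'
#' @inheritParams unclassified_fraction
#' @param max_unclassified_frac Removal threshold on the unclassified
#'   fraction (strict `>` comparison).
#' @return The filtered abundance tibble. The removed sample IDs are attached
#'   as attribute `"removed"`.
#' @export
filter_unclassified_samples <- function(abundance, max_unclassified_frac = 0.05,
                                        unclassified_features = NULL) {
  fr <- unclassified_fraction(abundance, unclassified_features)
  drop <- fr$sample_id[fr$unclassified_frac > max_unclassified_frac]
  out <- abundance[!abundance$sample_id %in% drop, , drop = FALSE]
  if (nrow(out) == 0) warn("All samples exceeded the unclassified-fraction threshold.")
  attr(out, "removed") <- drop
  out
}

# Bray-Curtis distance from each row of matrix m to vector ref.
bc_to_ref <- function(m, ref) {
  shared <- m
  for (j in seq_len(ncol(m))) shared[, j] <- pmin(m[, j], ref[j])
  denom <- rowSums(m) + sum(ref)
  ifelse(denom == 0, NA_real_, 1 - 2 * rowSums(shared) / denom)
}

#' Flag phenotype-level outlier samples by distance to the median profile
#'
#' Within each phenotype, a hypothetical reference sample is built from the
#' feature-wise medians (used as-is, without renormalization); each sample's
#' Bray-Curtis distance to this reference is computed, and samples whose
#' distance lies more than 1.5 interquartile ranges above the upper quartile
#' or below the lower quartile are flagged. Phenotypes with fewer than
#' `min_group_size` samples are skipped with a warning.
#'
#' @param abundance Wide abundance tibble.
#' @param metadata Sample metadata with the grouping column.
#' @param group_by Metadata column defining the phenotype groups.
#' @param min_group_size Minimum group size for fencing (default 4).
#' @return A tibble with one row per sample: grouping value, distance to the
#'   median profile, the two fences, and an `outlier` flag (`NA` for skipped
#'   groups).
#' @export
detect_outliers <- function(abundance, metadata, group_by = "phenotype",
                            min_group_size = 4L) {
  check_abundance(abundance)
  check_metadata(metadata)
  if (!group_by %in% names(metadata)) {
    abort(sprintf("Metadata has no '%s' column.", group_by))
  }
  m <- abund_matrix(abundance)
  grp <- metadata[[group_by]][match(rownames(m), metadata$sample_id)]
  if (anyNA(grp)) abort("Every sample must appear in `metadata`.")
  res <- lapply(split(seq_len(nrow(m)), grp), function(idx) {
    sub <- m[idx, , drop = FALSE]
    med <- apply(sub, 2, stats::median)
    d <- unname(bc_to_ref(sub, med))
    out <- tibble(sample_id = rownames(sub), group = grp[idx][1], distance = d)
    if (length(idx) < min_group_size) {
      warn(sprintf("Group '%s' has fewer than %d samples; outlier fencing skipped.",
                   grp[idx][1], min_group_size))
      out$lower_fence <- NA_real_
      out$upper_fence <- NA_real_
      out$outlier <- NA
      return(out)
    }
    q <- stats::quantile(d, c(0.25, 0.75), names = FALSE)  # linear interpolation
    iqr <- q[2] - q[1]
    out$lower_fence <- q[1] - 1.5 * iqr
    out$upper_fence <- q[2] + 1.5 * iqr
    out$outlier <- d > out$upper_fence | d < out$lower_fence
    out
  })
  out <- dplyr::bind_rows(res)
  out[match(rownames(m), out$sample_id), , drop = FALSE]
}

#' Remove flagged outlier samples
#'
#' @inheritParams detect_outliers
#' @return The abundance tibble without samples flagged by
#'   [detect_outliers()]; removed IDs attached as attribute `"removed"`.
#' @export
filter_outliers <- function(abundance, metadata, group_by = "phenotype",
                            min_group_size = 4L) {
  rep_ <- detect_outliers(abundance, metadata, group_by, min_group_size)
  drop <- rep_$sample_id[!is.na(rep_$outlier) & rep_$outlier]
  out <- abundance[!abundance$sample_id %in% drop, , drop = FALSE]
  attr(out, "removed") <- drop
  out
}

#' Remove viral, unclassified and rare features
#'
#' Implements the feature-removal step applied before signature discovery:
#' features of viral origin, unknown/unclassified entities, and features
#' present (relative abundance at or above `presence_threshold`) in fewer
#' than `min_prevalence` of the samples are dropped. Remaining samples are
#' renormalized to proportions by default so that downstream scoring sees
#' rows summing to 1.
#'
#' @param abundance Wide abundance tibble.
#' @param min_prevalence Prevalence floor; features present in a strictly
#'   smaller fraction of samples are removed (default 1%).
#' @param drop_viruses,drop_unclassified Toggle the two categorical filters.
#' @param lineages Optional `feature_id` -> `lineage` lookup for virus
#'   detection when feature names do not embed the lineage.
#' @param presence_threshold Abundance at or above which a feature counts as
#'   present (default 1e-5; set to 0 to count any positive abundance).
#' @param renormalize Renormalize retained rows to sum to 1 (default TRUE).
#' @return The filtered abundance tibble; removed features attached as
#'   attribute `"removed_features"`, a list with elements `virus`,
#'   `unclassified` and `low_prevalence`.
#' @export
filter_features <- function(abundance, min_prevalence = 0.01,
                            drop_viruses = TRUE, drop_unclassified = TRUE,
                            lineages = NULL, presence_threshold = 1e-5,
                            renormalize = TRUE) {
  check_abundance(abundance)
  m <- abund_matrix(abundance)
  feats <- colnames(m)
  viral <- if (drop_viruses) is_viral_feature(feats, lineages) else rep(FALSE, length(feats))
  uncls <- if (drop_unclassified) is_unclassified_feature(feats) & !viral else rep(FALSE, length(feats))
  prev <- colMeans(m >= presence_threshold)
  rare <- prev < min_prevalence & !viral & !uncls
  removed <- list(
    virus = feats[viral],
    unclassified = feats[uncls],
    low_prevalence = feats[rare]
  )
  keep <- !(viral | uncls | rare)
  if (!any(keep)) abort("All features were removed by the feature filters.")
  m <- m[, keep, drop = FALSE]
  if (renormalize) {
    rs <- rowSums(m)
    m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  out <- matrix_to_abund(m)
  attr(out, "removed_features") <- removed
  out
}

#' Run the full QC pipeline
#'
#' Applies, in order: BMI-based group reclassification, removal of samples
#' dominated by unclassified taxonomies, phenotype-level outlier removal, and
#' the feature filters (viruses, unclassified entities, rare features).
#'
#' @inheritParams filter_features
#' @inheritParams detect_outliers
#' @param metadata Sample metadata tibble.
#' @param max_unclassified_frac Threshold for the unclassified-sample filter.
#' @return An object of class `gmhi_qc`: a list with the filtered
#'   `abundance`, the (possibly reclassified, subsetted) `metadata`, and a
#'   `report` list recording every removal with its reason.
#' @export
run_qc <- function(abundance, metadata, max_unclassified_frac = 0.05,
                   group_by = "phenotype", min_prevalence = 0.01,
                   drop_viruses = TRUE, drop_unclassified = TRUE,
                   lineages = NULL, presence_threshold = 1e-5,
                   renormalize = TRUE) {
  check_abundance(abundance)
  check_metadata(metadata)
  metadata <- reclassify_by_bmi(metadata)
  ab <- filter_unclassified_samples(abundance, max_unclassified_frac)
  removed_uncls <- attr(ab, "removed")
  md <- metadata[metadata$sample_id %in% ab$sample_id, , drop = FALSE]
  outl <- detect_outliers(ab, md, group_by = group_by)
  drop <- outl$sample_id[!is.na(outl$outlier) & outl$outlier]
  ab <- ab[!ab$sample_id %in% drop, , drop = FALSE]
  md <- md[md$sample_id %in% ab$sample_id, , drop = FALSE]
  ab <- filter_features(ab, min_prevalence = min_prevalence,
                        drop_viruses = drop_viruses,
                        drop_unclassified = drop_unclassified,
                        lineages = lineages,
                        presence_threshold = presence_threshold,
                        renormalize = renormalize)
  structure(list(
    abundance = ab,
    metadata = md,
    report = list(
      samples_removed_unclassified = removed_uncls,
      samples_removed_outlier = drop,
      features_removed = attr(ab, "removed_features"),
      outlier_distances = outl
    )
  ), class = "gmhi_qc")
}

#' @export
print.gmhi_qc <- function(x, ...) {
  fr <- x$report$features_removed
  cat("Gut-microbiome QC report\n")
  cat(sprintf("  samples retained: %d\n", nrow(x$abundance)))
  cat(sprintf("  samples removed (unclassified > threshold): %d\n",
              length(x$report$samples_removed_unclassified)))
  cat(sprintf("  samples removed (outlier fence): %d\n",
              length(x$report$samples_removed_outlier)))
  cat(sprintf("  features removed: %d viral, %d unclassified, %d low-prevalence\n",
              length(fr$virus), length(fr$unclassified), length(fr$low_prevalence)))
  cat(sprintf("  features retained: %d\n", ncol(x$abundance) - 1L))
  invisible(x)
}
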