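# Synthetic labeled cohorts with planted prevalence differentials on a
# sparse compositional species table.

#' Specify a synthetic cohort
#'
#' The generator emulates the statistical structure the prevalence-based
#' discovery procedure assumes: every species is present in a sample with a
#' group-specific probability (planted health-prevalent species are more
#' frequent in the healthy group by `prevalence_gap`, planted health-scarce
#' species mirrored, background species identical in both groups); present
#' species draw abundances from a log-normal law spanning several orders of
#' magnitude, and each sample is closed to sum to 1.
#'
#' @param n_h,n_n Healthy / nonhealthy sample counts (default 500 each).
#' @param n_species Total species count (default 200, a realistic
#'   post-filter species count for stool metagenomes).
#' @param n_planted_h,n_planted_n Planted signature sizes (default 10 each).
#' @param prevalence_base Background presence probability (default 0.3).
#' @param prevalence_gap Between-group presence-probability difference for
#'   planted species (default 0.25).
#' @param abundance_meanlog,abundance_sdlog Log-normal location and scale of
#'   positive abundances before closure (defaults -7 and 1.5).
#' @param n_phenotypes Number of pseudo-phenotypes the nonhealthy samples
#'   are evenly assigned to (default 3), so intra-study comparisons are
#'   exercisable.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_h = 500, n_n = 500, n_species = 200,
                        n_planted_h = 10, n_planted_n = 10,
                        prevalence_base = 0.3, prevalence_gap = 0.25,
                        abundance_meanlog = -7, abundance_sdlog = 1.5,
                        n_phenotypes = 3, seed = NULL) {
  if (n_h < 1 || n_n < 1 || n_species < 1) abort("Counts must be positive.")
  if (n_planted_h + n_planted_n > n_species) {
    abort("Planted species counts exceed `n_species`.")
  }
  if (prevalence_gap < 0 || prevalence_base < 0 ||
      prevalence_base + prevalence_gap > 1) {
    abort("Need 0 <= prevalence_base and prevalence_base + prevalence_gap <= 1.")
  }
  structure(list(
    n_h = n_h, n_n = n_n, n_species = n_species,
    n_planted_h = n_planted_h, n_planted_n = n_planted_n,
    prevalence_base = prevalence_base, prevalence_gap = prevalence_gap,
    abundance_meanlog = abundance_meanlog, abundance_sdlog = abundance_sdlog,
    n_phenotypes = n_phenotypes, seed = seed
  ), class = "cohort_spec")
}

#' Generate a synthetic labeled cohort
#'
#' @param spec A [cohort_spec()].
#' @return An object of class `gmhi_cohort`: list with the wide `abundance`
#'   tibble (rows closed to sum 1), the `metadata` tibble (phenotype, group,
#'   study ID), the planted `truth` (species lists and realized per-group
#'   prevalences from the presence draws), and the `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_local_seed(spec$seed, {
    n_bg <- spec$n_species - spec$n_planted_h - spec$n_planted_n
    species <- c(
      sprintf("planted_h_%02d", seq_len(spec$n_planted_h)),
      sprintf("planted_n_%02d", seq_len(spec$n_planted_n)),
      sprintf("background_%03d", seq_len(max(n_bg, 0)))
    )
    kind <- rep(c("planted_h", "planted_n", "background"),
                c(spec$n_planted_h, spec$n_planted_n, n_bg))
    p_in_h <- ifelse(kind == "planted_h",
                     spec$prevalence_base + spec$prevalence_gap,
                     spec$prevalence_base)
    p_in_n <- ifelse(kind == "planted_n",
                     spec$prevalence_base + spec$prevalence_gap,
                     spec$prevalence_base)
    draw_group <- function(n, probs, prefix) {
      pres <- matrix(stats::rbinom(n * length(probs), 1,
                                   rep(probs, each = n)) == 1,
                     nrow = n)
      ab <- matrix(0, nrow = n, ncol = length(probs))
      npos <- sum(pres)
      ab[pres] <- stats::rlnorm(npos, spec$abundance_meanlog, spec$abundance_sdlog)
      rs <- rowSums(ab)
      ab[rs > 0, ] <- ab[rs > 0, , drop = FALSE] / rs[rs > 0]
      rownames(ab) <- sprintf("%s_%04d", prefix, seq_len(n))
      colnames(ab) <- species
      ab
    }
    mh <- draw_group(spec$n_h, p_in_h, "healthy")
    mn <- draw_group(spec$n_n, p_in_n, "nonhealthy")
    abundance <- matrix_to_abund(rbind(mh, mn))
    pheno_n <- rep_len(sprintf("disease_%02d", seq_len(spec$n_phenotypes)),
                       spec$n_n)
    metadata <- tibble(
      sample_id = c(rownames(mh), rownames(mn)),
      phenotype = c(rep("healthy", spec$n_h), pheno_n),
      group = rep(c("healthy", "nonhealthy"), c(spec$n_h, spec$n_n)),
      study_id = "synthetic"
    )
    realized <- tibble(
      feature_id = species,
      kind = kind,
      p_h_specified = p_in_h, p_n_specified = p_in_n,
      p_h_realized = colMeans(mh > 0),
      p_n_realized = colMeans(mn > 0)
    )
    structure(list(
      abundance = abundance,
      metadata = metadata,
      truth = list(
        planted_h = species[kind == "planted_h"],
        planted_n = species[kind == "planted_n"],
        realized = realized
      ),
      spec = spec
    ), class = "gmhi_cohort")
  })
}

#' @export
print.gmhi_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d healthy + %d nonhealthy samples, %d species\n",
              x$spec$n_h, x$spec$n_n, x$spec$n_species))
  cat(sprintf("  planted: %d health-prevalent, %d health-scarce (base %.3g, gap %.3g)\n",
              x$spec$n_planted_h, x$spec$n_planted_n,
              x$spec$prevalence_base, x$spec$prevalence_gap))
  invisible(x)
}

#' Precision and recall of a discovered signature against planted truth
#'
#' @param truth The `truth` element of a [generate_cohort()] result (or any
#'   list with `planted_h` and `planted_n`).
#' @param m_h,m_n Discovered species sets (a [gmhi_signature()] may be
#'   passed as `m_h`, in which case its two sets are used).
#' @return A tibble with one row per set: `set`, `n_true`, `n_found`, `tp`,
#'   `precision` (`NA` for an empty found set) and `recall`.
#' @export
evaluate_recovery <- function(truth, m_h, m_n = NULL) {
  if (inherits(m_h, "gmhi_signature")) {
    m_n <- m_h$m_n
    m_h <- m_h$m_h
  }
  one <- function(set_name, planted, found) {
    tp <- length(intersect(planted, found))
    tibble(
      set = set_name,
      n_true = length(planted), n_found = length(found), tp = tp,
      precision = if (length(found)) tp / length(found) else NA_real_,
      recall = if (length(planted)) tp / length(planted) else NA_real_
    )
  }
  dplyr::bind_rows(
    one("m_h", truth$planted_h, m_h),
    one("m_n", truth$planted_n, m_n)
  )
}
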