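# Collective abundance, effective set sizes, the GMHI score and the
# packaged 50-species signature.

#' Construct a GMHI signature
#'
#' A signature bundles the two species sets with every parameter needed to
#' score a sample: the health-prevalent set `m_h`, the health-scarce set
#' `m_n`, the discovery thresholds, the effective set sizes that replace the
#' nominal cardinalities in the collective-abundance denominator, the
#' presence threshold and the pseudo-count that keeps the log-ratio finite
#' when one set is entirely absent.
#'
#' @param m_h,m_n Character vectors of species names (disjoint).
#' @param theta_f,theta_d Prevalence fold-change and difference thresholds
#'   used at discovery (recorded for provenance).
#' @param size_h_eff,size_n_eff Effective set sizes; positive, at most the
#'   nominal cardinality. Default to the nominal sizes.
#' @param presence_threshold Relative abundance at or above which a species
#'   counts as present (default 1e-5).
#' @param pseudo_count Symmetric pseudo-count added to both collective
#'   abundances in the log ratio (default 1e-5; 0 restores the literal
#'   formula, which is undefined when one set is absent).
#' @param prevalence Optional tibble of per-species discovery prevalences.
#' @param note Free-text provenance note.
#' @return An object of class `gmhi_signature`.
#' @export
gmhi_signature <- function(m_h, m_n, theta_f = NA_real_, theta_d = NA_real_,
                           size_h_eff = length(m_h), size_n_eff = length(m_n),
                           presence_threshold = 1e-5, pseudo_count = 1e-5,
                           prevalence = NULL, note = "") {
  m_h <- as.character(m_h); m_n <- as.character(m_n)
  if (length(intersect(normalize_species_name(m_h),
                       normalize_species_name(m_n)))) {
    abort("`m_h` and `m_n` must be disjoint.")
  }
  if (length(m_h) && (!is.numeric(size_h_eff) || size_h_eff <= 0 ||
                      size_h_eff > length(m_h) + 1e-9)) {
    abort("`size_h_eff` must be in (0, |m_h|].")
  }
  if (length(m_n) && (!is.numeric(size_n_eff) || size_n_eff <= 0 ||
                      size_n_eff > length(m_n) + 1e-9)) {
    abort("`size_n_eff` must be in (0, |m_n|].")
  }
  if (pseudo_count < 0) abort("`pseudo_count` must be nonnegative.")
  structure(list(
    m_h = m_h, m_n = m_n,
    theta_f = theta_f, theta_d = theta_d,
    size_h_eff = as.numeric(size_h_eff), size_n_eff = as.numeric(size_n_eff),
    presence_threshold = presence_threshold, pseudo_count = pseudo_count,
    prevalence = prevalence, note = note
  ), class = "gmhi_signature")
}

#' @export
print.gmhi_signature <- function(x, ...) {
  cat("GMHI signature\n")
  cat(sprintf("  health-prevalent species: %d (effective size %.4g)\n",
              length(x$m_h), x$size_h_eff))
  cat(sprintf("  health-scarce species:    %d (effective size %.4g)\n",
              length(x$m_n), x$size_n_eff))
  cat(sprintf("  thresholds: fold change >= %.3g, difference >= %.3g\n",
              x$theta_f, x$theta_d))
  cat(sprintf("  presence threshold %.3g, pseudo-count %.3g\n",
              x$presence_threshold, x$pseudo_count))
  if (nzchar(x$note)) cat(" ", x$note, "\n")
  invisible(x)
}

#' Collective abundance of a species set in one sample
#'
#' The collective abundance is the within-set richness fraction times the
#' Shannon-weighted abundance sum:
#' `psi = (R / effective_size) * sum(|n * ln(n)|)` over the set species
#' present in the sample (relative abundance at or above
#' `presence_threshold`); absent species contribute nothing.
#'
#' @param sample Named numeric vector of relative abundances (proportions).
#' @param species_set Character vector of species names; matching against
#'   the sample uses normalized names (lineage and `s__` prefixes stripped,
#'   underscores/slashes as spaces).
#' @param effective_size Positive denominator replacing the nominal set
#'   cardinality.
#' @param presence_threshold Presence threshold.
#' @return A list with `psi` and `richness`.
#' @export
#' @examples
#' collective_abundance(c(A = 0.1, B = 0.2), c("A", "B", "C"), 3)
collective_abundance <- function(sample, species_set, effective_size,
                                 presence_threshold = 1e-5) {
  if (!is.numeric(effective_size) || effective_size <= 0) {
    abort("`effective_size` must be positive.")
  }
  if (is.null(names(sample))) abort("`sample` must be a named abundance vector.")
  idx <- match(normalize_species_name(species_set),
               normalize_species_name(names(sample)))
  n <- ifelse(is.na(idx), 0, sample[idx])
  present <- n >= presence_threshold
  r <- sum(present)
  np <- n[present]
  psi <- (r / effective_size) * sum(abs(np * log(np)))
  list(psi = psi, richness = as.integer(r))
}

#' Number of extreme-ranked samples used for an effective set size
#'
#' The closest integer to `fraction` (default 1%) of the group size, with
#' halves rounded away from zero and a floor of 1.
#'
#' @param n_group Group sample count.
#' @param fraction Fraction of the group (default 0.01).
#' @return Positive integer.
#' @export
#' @examples
#' extreme_sample_count(2636) # 26
#' extreme_sample_count(1711) # 17
extreme_sample_count <- function(n_group, fraction = 0.01) {
  if (n_group < 1) abort("`n_group` must be at least 1.")
  max(1L, as.integer(round_half_away(n_group * fraction)))
}

#' Estimate effective set sizes from extreme-ranked samples
#'
#' Nominal set cardinalities bias the index when the two sets differ greatly
#' in size, because full within-set richness is rarely observed. The
#' replacement sizes are estimated from the data: every sample's within-set
#' richness pair `(R_H, R_N)` is computed; samples are rank-ordered first by
#' `R_N` ascending, then by `R_H` descending (stable for residual ties);
#' `size_h_eff` is the median `R_H` among the top `k_h` samples and
#' `size_n_eff` the median `R_N` among the bottom `k_n`, where each `k` is
#' the closest integer to 1% of its group's size (see
#' [extreme_sample_count()]).
#'
#' @param abundance Wide abundance tibble.
#' @param metadata Metadata with a `group` column (healthy / nonhealthy).
#' @param m_h,m_n Species sets.
#' @param presence_threshold Presence threshold for richness.
#' @param fallback_to_nominal If a median richness comes out 0 (degenerate
#'   data), fall back to the nominal cardinality instead of erroring.
#' @return A list with `size_h_eff`, `size_n_eff`, `k_h`, `k_n`.
#' @export
estimate_effective_set_sizes <- function(abundance, metadata, m_h, m_n,
                                         presence_threshold = 1e-5,
                                         fallback_to_nominal = FALSE) {
  check_abundance(abundance)
  check_metadata(metadata)
  if (!length(m_h) || !length(m_n)) abort("`m_h` and `m_n` must be nonempty.")
  ids_h <- group_sample_ids(metadata, "healthy")
  ids_n <- group_sample_ids(metadata, "nonhealthy")
  if (!length(ids_h) || !length(ids_n)) {
    abort("Both healthy and nonhealthy groups must be nonempty.")
  }
  use <- abundance$sample_id %in% c(ids_h, ids_n)
  m <- abund_matrix(abundance[use, , drop = FALSE])
  rich <- set_richness_matrix(m, m_h, m_n, presence_threshold)
  ord <- order(rich$r_n, -rich$r_h)  # stable two-key sort
  r_h_sorted <- rich$r_h[ord]
  r_n_sorted <- rich$r_n[ord]
  k_h <- extreme_sample_count(length(ids_h))
  k_n <- extreme_sample_count(length(ids_n))
  n_all <- length(ord)
  if (k_h > n_all || k_n > n_all) abort("Fewer samples than extreme-rank count.")
  size_h <- stats::median(r_h_sorted[seq_len(k_h)])
  size_n <- stats::median(r_n_sorted[seq.int(n_all - k_n + 1L, n_all)])
  if (size_h <= 0) {
    if (fallback_to_nominal) size_h <- length(m_h)
    else abort(paste("Median health-prevalent richness of the top-ranked samples is 0;",
                     "set `fallback_to_nominal = TRUE` to use the nominal set size."))
  }
  if (size_n <= 0) {
    if (fallback_to_nominal) size_n <- length(m_n)
    else abort(paste("Median health-scarce richness of the bottom-ranked samples is 0;",
                     "set `fallback_to_nominal = TRUE` to use the nominal set size."))
  }
  list(size_h_eff = as.numeric(size_h), size_n_eff = as.numeric(size_n),
       k_h = k_h, k_n = k_n)
}

# Per-sample richness of the two sets over an abundance matrix.
set_richness_matrix <- function(m, m_h, m_n, presence_threshold) {
  cols <- normalize_species_name(colnames(m))
  ih <- match(normalize_species_name(m_h), cols)
  in_ <- match(normalize_species_name(m_n), cols)
  pres <- m >= presence_threshold
  count_set <- function(idx) {
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(integer(nrow(m)))
    as.integer(rowSums(pres[, idx, drop = FALSE]))
  }
  list(r_h = count_set(ih), r_n = count_set(in_),
       n_missing_h = sum(is.na(ih)), n_missing_n = sum(is.na(in_)))
}

#' Score one sample with a GMHI signature
#'
#' The index is `h = log10((psi_H + eps) / (psi_N + eps))` with the
#' signature's pseudo-count `eps`; a sample is classified healthy when
#' `h > 0`, nonhealthy when `h < 0`, and neither when `h = 0` (an exact
#' balance of the two sets).
#'
#' @param sample Named numeric abundance vector (proportions).
#' @param signature A [gmhi_signature()].
#' @return A one-row tibble: `r_h`, `r_n`, `psi_h`, `psi_n`, `gmhi`,
#'   `label`.
#' @export
gmhi_score <- function(sample, signature) {
  stopifnot(inherits(signature, "gmhi_signature"))
  ch <- collective_abundance(sample, signature$m_h, signature$size_h_eff,
                             signature$presence_threshold)
  cn <- collective_abundance(sample, signature$m_n, signature$size_n_eff,
                             signature$presence_threshold)
  h <- gmhi_log_ratio(ch$psi, cn$psi, signature$pseudo_count)
  tibble(r_h = ch$richness, r_n = cn$richness,
         psi_h = ch$psi, psi_n = cn$psi,
         gmhi = h, label = gmhi_label(h))
}

gmhi_log_ratio <- function(psi_h, psi_n, eps) {
  num <- psi_h + eps
  den <- psi_n + eps
  out <- numeric(length(num))
  zero_both <- num == 0 & den == 0
  if (any(zero_both)) {
    warn("Both collective abundances are 0 with a zero pseudo-count; GMHI set to 0.")
    out[zero_both] <- 0
  }
  inf_pos <- den == 0 & num > 0
  inf_neg <- num == 0 & den > 0
  if (any(inf_pos | inf_neg)) {
    warn("A collective abundance is 0 with a zero pseudo-count; GMHI is infinite.")
    out[inf_pos] <- Inf
    out[inf_neg] <- -Inf
  }
  fin <- !(zero_both | inf_pos | inf_neg)
  out[fin] <- log10(num[fin] / den[fin])
  out
}

gmhi_label <- function(h) {
  dplyr::case_when(h > 0 ~ "healthy", h < 0 ~ "nonhealthy", TRUE ~ "neither")
}

#' Score every sample of an abundance table
#'
#' Vectorized application of [gmhi_score()]; signature species absent from
#' the table are treated as abundance 0 (a message reports how many).
#'
#' @param abundance Wide abundance tibble.
#' @param signature A [gmhi_signature()].
#' @return A tibble with one row per sample, in input order: `sample_id`,
#'   `r_h`, `r_n`, `psi_h`, `psi_n`, `gmhi`, `label`.
#' @export
score_samples <- function(abundance, signature) {
  check_abundance(abundance)
  stopifnot(inherits(signature, "gmhi_signature"))
  m <- abund_matrix(abundance)
  cols <- normalize_species_name(colnames(m))
  psi_set <- function(set, eff) {
    idx <- match(normalize_species_name(set), cols)
    missing <- sum(is.na(idx))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) {
      return(list(psi = numeric(nrow(m)), r = integer(nrow(m)), missing = missing))
    }
    sub <- m[, idx, drop = FALSE]
    pres <- sub >= signature$presence_threshold
    contrib <- ifelse(pres & sub > 0, abs(sub * log(pmax(sub, .Machine$double.xmin))), 0)
    r <- as.integer(rowSums(pres))
    list(psi = unname((r / eff) * rowSums(contrib)), r = r, missing = missing)
  }
  ph <- psi_set(signature$m_h, signature$size_h_eff)
  pn <- psi_set(signature$m_n, signature$size_n_eff)
  n_missing <- ph$missing + pn$missing
  if (n_missing > 0) {
    inform(sprintf("%d signature species absent from the table (abundance 0).",
                   n_missing))
  }
  if (n_missing == length(signature$m_h) + length(signature$m_n)) {
    warn("No signature species found in the table; all scores are 0.")
  }
  h <- gmhi_log_ratio(ph$psi, pn$psi, signature$pseudo_count)
  tibble(sample_id = rownames(m),
         r_h = ph$r, r_n = pn$r,
         psi_h = ph$psi, psi_n = pn$psi,
         gmhi = h, label = gmhi_label(h))
}

#' Fit a full GMHI signature from labeled data
#'
#' Convenience wrapper: selects the species sets at the given thresholds
#' with [select_signature()] and estimates the effective set sizes with
#' [estimate_effective_set_sizes()].
#'
#' @inheritParams estimate_effective_set_sizes
#' @param theta_f,theta_d Discovery thresholds.
#' @param pseudo_count Pseudo-count stored in the signature.
#' @return A [gmhi_signature()] ready for [score_samples()].
#' @export
fit_signature <- function(abundance, metadata, theta_f = 1.4, theta_d = 0.10,
                          presence_threshold = 1e-5, pseudo_count = 1e-5,
                          fallback_to_nominal = FALSE) {
  sig <- select_signature(abundance, metadata, theta_f, theta_d,
                          presence_threshold = presence_threshold,
                          pseudo_count = pseudo_count)
  if (!length(sig$m_h) || !length(sig$m_n)) {
    abort("Signature selection produced an empty species set at these thresholds.")
  }
  sz <- estimate_effective_set_sizes(abundance, metadata, sig$m_h, sig$m_n,
                                     presence_threshold = presence_threshold,
                                     fallback_to_nominal = fallback_to_nominal)
  sig$size_h_eff <- sz$size_h_eff
  sig$size_n_eff <- sz$size_n_eff
  sig$k_h <- sz$k_h
  sig$k_n <- sz$k_n
  sig
}

#' Write / read a GMHI signature file
#'
#' The format is a TSV with columns `species`, `set` (`H+` / `H-`) and any
#' prevalence columns, preceded by `# key: value` header lines holding the
#' scalar parameters.
#'
#' @param signature A [gmhi_signature()].
#' @param path File path.
#' @return `write_signature()` returns `path` invisibly; `read_signature()`
#'   returns the signature.
#' @export
write_signature <- function(signature, path) {
  stopifnot(inherits(signature, "gmhi_signature"))
  hdr <- c(
    sprintf("# theta_f: %.10g", signature$theta_f),
    sprintf("# theta_d: %.10g", signature$theta_d),
    sprintf("# size_h_eff: %.10g", signature$size_h_eff),
    sprintf("# size_n_eff: %.10g", signature$size_n_eff),
    sprintf("# presence_threshold: %.10g", signature$presence_threshold),
    sprintf("# pseudo_count: %.10g", signature$pseudo_count)
  )
  tab <- tibble(
    species = c(signature$m_h, signature$m_n),
    set = c(rep("H+", length(signature$m_h)), rep("H-", length(signature$m_n)))
  )
  if (!is.null(signature$prevalence)) {
    tab <- dplyr::left_join(
      tab, dplyr::rename(signature$prevalence, species = "feature_id"),
      by = "species"
    )
  }
  writeLines(hdr, path)
  suppressWarnings(readr::write_tsv(tab, path, append = TRUE, col_names = TRUE,
                                    progress = FALSE))
  invisible(path)
}

#' @rdname write_signature
#' @export
read_signature <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read signature file '%s'.", path))
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- strsplit(sub("^# ", "", hdr), ": ")
  vals <- stats::setNames(
    vapply(kv, function(p) as.numeric(p[2]), numeric(1)),
    vapply(kv, `[[`, character(1), 1)
  )
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    species = readr::col_character(), set = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  prev_cols <- setdiff(names(tab), c("species", "set"))
  prevalence <- if (length(prev_cols)) {
    dplyr::rename(tab[c("species", prev_cols)], feature_id = "species")
  } else NULL
  gmhi_signature(
    m_h = tab$species[tab$set == "H+"],
    m_n = tab$species[tab$set == "H-"],
    theta_f = vals[["theta_f"]], theta_d = vals[["theta_d"]],
    size_h_eff = vals[["size_h_eff"]], size_n_eff = vals[["size_n_eff"]],
    presence_threshold = vals[["presence_threshold"]],
    pseudo_count = vals[["pseudo_count"]],
    prevalence = prevalence,
    note = sprintf("read from %s", path)
  )
}

#' Load the packaged 50-species GMHI signature
#'
#' Returns the published model: 7 health-prevalent and 43 health-scarce
#' species selected at fold-change threshold 1.4 and difference threshold
#' 10%, with the discovery prevalences attached as provenance.
#'
#' The effective set sizes used by the published model were never reported;
#' unless you supply `size_h_eff` / `size_n_eff` (e.g. re-derived from your
#' own training data with [estimate_effective_set_sizes()]), the nominal
#' cardinalities (7 and 43) are used and a message says so.
#'
#' @param name Signature name; only `"GMHI-Table2"` is packaged.
#' @param size_h_eff,size_n_eff Optional effective set sizes.
#' @param presence_threshold,pseudo_count Scoring parameters.
#' @return A [gmhi_signature()].
#' @export
load_packaged_signature <- function(name = "GMHI-Table2",
                                    size_h_eff = NULL, size_n_eff = NULL,
                                    presence_threshold = 1e-5,
                                    pseudo_count = 1e-5) {
  if (name != "GMHI-Table2") abort(sprintf("Unknown packaged signature '%s'.", name))
  path <- system.file("extdata", "gmhi_table2_signature.tsv", package = "gmhi")
  if (!nzchar(path)) abort("Packaged signature file is missing.")
  expected_md5 <- "ff517063a286e44bb08032955a130b4b"
  actual_md5 <- unname(tools::md5sum(path))
  if (!identical(actual_md5, expected_md5)) {
    abort("Packaged signature file failed its checksum; reinstall the package.")
  }
  tab <- readr::read_tsv(path, comment = "#", col_types = readr::cols(
    species = readr::col_character(), set = readr::col_character(),
    .default = readr::col_double()
  ), progress = FALSE)
  m_h <- tab$species[tab$set == "H+"]
  m_n <- tab$species[tab$set == "H-"]
  if (is.null(size_h_eff) || is.null(size_n_eff)) {
    inform(paste("Effective set sizes for the packaged model are not published;",
                 "using the nominal cardinalities (7 and 43). Supply",
                 "`size_h_eff`/`size_n_eff` to override."))
  }
  gmhi_signature(
    m_h = m_h, m_n = m_n, theta_f = 1.4, theta_d = 0.10,
    size_h_eff = size_h_eff %||% length(m_h),
    size_n_eff = size_n_eff %||% length(m_n),
    presence_threshold = presence_threshold, pseudo_count = pseudo_count,
    prevalence = dplyr::rename(tab[setdiff(names(tab), "set")],
                               feature_id = "species"),
    note = "packaged 50-species model (discovery prevalences attached)"
  )
}
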