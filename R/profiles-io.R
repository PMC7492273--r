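# Reading, merging and writing MetaPhlAn-style taxonomic abundance tables.

RANK_PREFIXES <- c(
  kingdom = "k", phylum = "p", class = "c", order = "o",
  family = "f", genus = "g", species = "s", strain = "t"
)

rank_prefix <- function(rank) {
  rank <- as.character(rank)[1]
  if (rank %in% RANK_PREFIXES) return(rank)
  if (!rank %in% names(RANK_PREFIXES)) {
    abort(sprintf("Unknown taxonomic rank '%s'. Use one of: %s.",
                  rank, paste(names(RANK_PREFIXES), collapse = ", ")))
  }
  unname(RANK_PREFIXES[rank])
}

#' Parse a pipe-delimited clade lineage
#'
#' Splits a MetaPhlAn-style lineage string such as
#' `"k__Bacteria|p__Firmicutes|...|s__Blautia_producta"` into its ranked
#' components. Prefixes must appear in canonical kingdom-to-strain order and
#' every name must be non-empty.
#'
#' @param lineage A single lineage string.
#' @return A tibble with columns `prefix` (one of k, p, c, o, f, g, s, t) and
#'   `name`.
#' @seealso [build_lineage()] for the inverse operation.
#' @export
#' @examples
#' parse_lineage("k__Bacteria|s__Blautia_producta")
parse_lineage <- function(lineage) {
  stopifnot(is.character(lineage), length(lineage) == 1L)
  parts <- strsplit(lineage, "|", fixed = TRUE)[[1]]
  if (!length(parts) || !all(grepl("^[kpcofgst]__", parts))) {
    abort(sprintf("Malformed clade lineage: '%s'", lineage))
  }
  prefix <- substr(parts, 1, 1)
  name <- substring(parts, 4)
  if (any(!nzchar(name))) {
    abort(sprintf("Lineage '%s' contains an empty clade name.", lineage))
  }
  ord <- match(prefix, unname(RANK_PREFIXES))
  if (anyNA(ord) || is.unsorted(ord, strictly = TRUE)) {
    abort(sprintf("Lineage '%s' has rank prefixes out of canonical order.", lineage))
  }
  tibble(prefix = prefix, name = name)
}

#' Serialize ranked clade components back into a lineage string
#'
#' @param ranks A data frame with columns `prefix` and `name`, as returned by
#'   [parse_lineage()].
#' @return A single lineage string; `build_lineage(parse_lineage(x))`
#'   round-trips exactly.
#' @export
build_lineage <- function(ranks) {
  stopifnot(is.data.frame(ranks), all(c("prefix", "name") %in% names(ranks)))
  paste0(ranks$prefix, "__", ranks$name, collapse = "|")
}

# Deepest rank prefix of each lineage string (vectorized).
lineage_deepest_rank <- function(lineage) {
  last <- sub(".*\\|", "", lineage)
  substr(last, 1, 1)
}

#' Read a single-sample MetaPhlAn profile at one taxonomic rank
#'
#' Reads the classic two-column MetaPhlAn output (clade lineage, relative
#' abundance; `#` comment lines ignored) and keeps only clades whose deepest
#' rank equals `rank`, so a species-level extraction contains no strain rows
#' and no duplicated lineage prefixes. MetaPhlAn reports percentages; the
#' scale is auto-detected from the column sum and abundances are always
#' returned as proportions.
#'
#' @param path Path to the profile TSV.
#' @param rank Taxonomic rank to extract (`"species"` by default; full names
#'   or single-letter prefixes accepted).
#' @return A tibble with columns `feature_id` (terminal clade name),
#'   `lineage` (full clade string) and `abundance` (proportion). Rows whose
#'   name marks an unknown or unclassified entity are retained (column
#'   `unclassified` flags them) so that downstream QC can compute the
#'   unclassified fraction before removal.
#' @export
read_metaphlan_profile <- function(path, rank = "species") {
  pfx <- rank_prefix(rank)
  if (!file.exists(path)) abort(sprintf("Cannot read profile file '%s'.", path))
  raw <- readr::read_tsv(path, comment = "#", col_names = FALSE,
                         col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (nrow(raw) == 0 || ncol(raw) < 2) {
    abort(sprintf("Profile '%s' has no clade/abundance rows.", path))
  }
  clade <- raw[[1]]
  abundance <- suppressWarnings(as.numeric(raw[[2]]))
  bad <- which(is.na(abundance))
  if (length(bad)) {
    abort(sprintf("Profile '%s': non-numeric abundance on data line %d ('%s').",
                  path, bad[1], clade[bad[1]]))
  }
  neg <- which(abundance < 0)
  if (length(neg)) {
    abort(sprintf("Profile '%s': negative abundance on data line %d ('%s').",
                  path, neg[1], clade[neg[1]]))
  }
  keep <- lineage_deepest_rank(clade) == pfx | (clade == "UNKNOWN" & pfx == "s")
  # Plain "UNKNOWN" rows (unassigned fraction) carry no rank; treat them as
  # species-level so the unclassified fraction is visible at the rank used
  # for scoring.
  if (!any(keep)) {
    abort(sprintf("Profile '%s' has no rows at rank '%s'.", path, rank))
  }
  clade <- clade[keep]
  abundance <- abundance[keep]
  # Percent output sums to ~100; proportions to ~1.
  if (sum(abundance) > 1.5) abundance <- abundance / 100
  feature_id <- ifelse(clade == "UNKNOWN", "UNKNOWN",
                       sub("^[kpcofgst]__", "", sub(".*\\|", "", clade)))
  tibble(
    feature_id = feature_id,
    lineage = clade,
    abundance = abundance,
    unclassified = is_unclassified_feature(feature_id)
  )
}

#' Merge per-sample profiles into a wide abundance table
#'
#' Takes the union of features across samples, fills missing entries with 0,
#' and renormalizes each sample to sum to 1.
#'
#' @param profiles A list of per-sample profiles: either tibbles as returned
#'   by [read_metaphlan_profile()] or named numeric vectors.
#' @param sample_ids Character vector of unique sample IDs, one per profile.
#' @return A wide abundance tibble: `sample_id` plus one numeric column per
#'   feature, rows summing to 1 (all-zero profiles are kept as zero rows with
#'   a warning).
#' @export
merge_profiles <- function(profiles, sample_ids) {
  stopifnot(is.list(profiles), length(profiles) == length(sample_ids))
  if (anyDuplicated(sample_ids)) abort("`sample_ids` must be unique.")
  as_map <- function(p) {
    if (is.data.frame(p)) stats::setNames(p$abundance, p$feature_id)
    else if (is.numeric(p) && !is.null(names(p))) p
    else abort("Each profile must be a profile tibble or a named numeric vector.")
  }
  maps <- lapply(profiles, as_map)
  features <- unique(unlist(lapply(maps, names), use.names = FALSE))
  m <- matrix(0, nrow = length(maps), ncol = length(features),
              dimnames = list(sample_ids, features))
  for (i in seq_along(maps)) m[i, names(maps[[i]])] <- maps[[i]]
  if (any(m < 0)) abort("Profiles contain negative abundances.")
  rs <- rowSums(m)
  if (any(rs == 0)) {
    warn(sprintf("%d sample(s) have all-zero profiles and were left unnormalized.",
                 sum(rs == 0)))
  }
  m[rs > 0, , drop = FALSE] -> pos
  m[rs > 0, ] <- pos / rs[rs > 0]
  matrix_to_abund(m)
}

#' Collect feature lineages from a list of profiles
#'
#' @param profiles List of tibbles as returned by [read_metaphlan_profile()].
#' @return A tibble mapping `feature_id` to `lineage` (first occurrence wins).
#' @export
lineage_table <- function(profiles) {
  dplyr::distinct(
    dplyr::bind_rows(lapply(profiles, function(p) p[c("feature_id", "lineage")])),
    .data$feature_id, .keep_all = TRUE
  )
}

#' Write / read a merged abundance table
#'
#' The on-disk format is the conventional merged-table layout: TSV with the
#' feature ID in the first column and one column per sample. An optional
#' companion metadata TSV (columns `sample_id`, `phenotype`, `group`,
#' `study_id`, `bmi`) can be written alongside.
#'
#' @param abundance Wide abundance tibble (`sample_id` first column).
#' @param path Output TSV path.
#' @param metadata Optional sample metadata tibble written to `metadata_path`.
#' @param metadata_path Companion metadata path; defaults to `path` with a
#'   `_metadata.tsv` suffix.
#' @return `write_abundance_table()` returns `path` invisibly;
#'   `read_abundance_table()` returns the wide abundance tibble.
#' @export
write_abundance_table <- function(abundance, path, metadata = NULL,
                                  metadata_path = NULL) {
  check_abundance(abundance)
  if (ncol(abundance) < 2 || nrow(abundance) == 0) {
    abort("Refusing to write an empty abundance table.")
  }
  m <- abund_matrix(abundance)
  out <- dplyr::bind_cols(tibble(feature_id = colnames(m)),
                          as_tibble(t(m), .name_repair = "minimal"))
  readr::write_tsv(out, path, progress = FALSE)
  if (!is.null(metadata)) {
    check_metadata(metadata)
    metadata_path <- metadata_path %||% default_metadata_path(path)
    readr::write_tsv(metadata, metadata_path, progress = FALSE)
  }
  invisible(path)
}

default_metadata_path <- function(path) {
  sub("(\\.tsv)?$", "_metadata.tsv", path, perl = TRUE)
}

#' @rdname write_abundance_table
#' @export
read_abundance_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read abundance table '%s'.", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
  if (nrow(x) == 0 || ncol(x) < 2) abort(sprintf("Abundance table '%s' is empty.", path))
  m <- t(as.matrix(x[-1]))
  colnames(m) <- x$feature_id
  out <- matrix_to_abund(m)
  check_abundance(out)
  out
}

#' Read / write a sample metadata table
#'
#' @param metadata Metadata tibble with at least a `sample_id` column;
#'   conventional columns are `phenotype`, `group` (healthy / nonhealthy /
#'   unassigned), `study_id` and `bmi`.
#' @param path TSV path.
#' @return The metadata tibble (reader) or `path` invisibly (writer).
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cannot read metadata '%s'.", path))
  x <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), .default = readr::col_guess()
  ), progress = FALSE)
  if ("bmi" %in% names(x)) x$bmi <- as.numeric(x$bmi)
  check_metadata(x)
  x
}

#' @rdname read_sample_metadata
#' @export
write_sample_metadata <- function(metadata, path) {
  check_metadata(metadata)
  readr::write_tsv(metadata, path, progress = FALSE)
  invisible(path)
}

#' Renormalize each sample to proportions
#'
#' @param abundance Wide abundance tibble.
#' @return The same tibble with each row rescaled to sum to 1; all-zero rows
#'   are left untouched with a warning.
#' @export
renormalize_samples <- function(abundance) {
  check_abundance(abundance)
  m <- abund_matrix(abundance)
  rs <- rowSums(m)
  if (any(rs == 0)) warn("All-zero samples cannot be renormalized; left as zeros.")
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  matrix_to_abund(m)
}
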