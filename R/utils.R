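# Internal helpers shared across modules.

#' @importFrom rlang abort warn inform .data %||%
#' @importFrom tibble tibble as_tibble
NULL

# Validate a wide abundance tibble: first column `sample_id` (unique character),
# remaining columns numeric and nonnegative. Returns invisibly.
check_abundance <- function(x, arg = "abundance") {
  if (!is.data.frame(x) || ncol(x) < 1L) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column.", arg))
  }
  if (names(x)[1] != "sample_id") {
    abort(sprintf("`%s` must have `sample_id` as its first column.", arg))
  }
  ids <- x$sample_id
  if (anyDuplicated(ids)) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  vals <- x[-1]
  if (ncol(vals) > 0) {
    ok <- vapply(vals, is.numeric, logical(1))
    if (!all(ok)) {
      abort(sprintf("`%s` has non-numeric feature columns: %s",
                    arg, paste(names(vals)[!ok], collapse = ", ")))
    }
    m <- as.matrix(vals)
    if (anyNA(m)) abort(sprintf("`%s` contains missing values.", arg))
    if (any(m < 0)) abort(sprintf("`%s` contains negative abundances.", arg))
  }
  invisible(x)
}

# Abundance tibble -> numeric matrix with sample IDs as rownames.
abund_matrix <- function(x) {
  m <- as.matrix(x[-1])
  rownames(m) <- x$sample_id
  storage.mode(m) <- "double"
  m
}

# Matrix (samples x features) -> wide abundance tibble.
matrix_to_abund <- function(m) {
  out <- as_tibble(m, .name_repair = "minimal")
  dplyr::bind_cols(tibble(sample_id = rownames(m)), out)
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Round half away from zero (base round() rounds half to even).
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

# Canonical species-name form used when matching signature species against
# feature columns: drop any lineage prefix and the s__ marker, and treat
# underscores and slashes as spaces (MetaPhlAn writes
# "s__Streptococcus_mitis_oralis_pneumoniae" for the composite species
# printed as "Streptococcus mitis/oralis/pneumoniae").
normalize_species_name <- function(x) {
  x <- sub("^.*\\|", "", x)
  x <- sub("^[kpcofgst]__", "", x)
  x <- gsub(".", "", x, fixed = TRUE)  # "sp." vs MetaPhlAn's "sp"
  x <- gsub("[_/]+", " ", x)
  trimws(gsub("[[:space:]]+", " ", x))
}

group_sample_ids <- function(metadata, group) {
  metadata$sample_id[!is.na(metadata$group) & metadata$group == group]
}

check_metadata <- function(metadata, arg = "metadata") {
  if (!is.data.frame(metadata) || !"sample_id" %in% names(metadata)) {
    abort(sprintf("`%s` must be a data frame with a `sample_id` column.", arg))
  }
  if (anyDuplicated(metadata$sample_id)) {
    abort(sprintf("`%s` has duplicated sample IDs.", arg))
  }
  invisible(metadata)
}
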