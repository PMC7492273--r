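# Per-sample ecology metrics and nonparametric comparison statistics.

#' Shannon diversity of one sample
#'
#' `H' = -sum(p * log(p))` over strictly positive proportions, natural log by
#' default (the ecology convention); the input is renormalized internally.
#'
#' @param x Nonnegative abundance vector with a positive sum.
#' @param base Logarithm base (default `exp(1)` for nats).
#' @return The Shannon index.
#' @export
#' @examples
#' shannon_index(c(0.5, 0.3, 0.2))
shannon_index <- function(x, base = exp(1)) {
  x <- as.numeric(x)
  if (any(x < 0) || anyNA(x)) abort("Abundances must be nonnegative and non-missing.")
  s <- sum(x)
  if (s <= 0) abort("Cannot compute Shannon diversity of an all-zero sample.")
  p <- x[x > 0] / s
  -sum(p * log(p, base = base))
}

#' Species richness of one sample
#'
#' @param x Abundance vector.
#' @param mode `"positive"` counts any positive abundance (the observed
#'   number of species); `"threshold"` counts abundances at or above
#'   `presence_threshold`.
#' @param presence_threshold Presence threshold for `mode = "threshold"`.
#' @return Integer count.
#' @export
species_richness <- function(x, mode = c("positive", "threshold"),
                             presence_threshold = 1e-5) {
  mode <- match.arg(mode)
  x <- as.numeric(x)
  if (mode == "positive") sum(x > 0) else sum(x >= presence_threshold)
}

#' Minimum number of species covering a target abundance fraction
#'
#' Sorts abundances in descending order and returns the smallest prefix
#' length whose cumulative proportion reaches at least `target` (inclusive
#' comparison, so ten species at 0.1 each give `coverage80 = 8`).
#'
#' @param x Abundance vector (renormalized internally).
#' @param target Coverage target in (0, 1]; default 0.80.
#' @return Integer count.
#' @export
coverage80 <- function(x, target = 0.80) {
  if (!is.numeric(target) || length(target) != 1 || target <= 0 || target > 1) {
    abort("`target` must be in (0, 1].")
  }
  x <- as.numeric(x)
  if (any(x < 0)) abort("Abundances must be nonnegative.")
  s <- sum(x)
  if (s <= 0) abort("Cannot compute coverage of an all-zero sample.")
  p <- sort(x[x > 0], decreasing = TRUE) / s
  # guard against cumulative rounding just below the target
  cs <- cumsum(p)
  cs[length(cs)] <- max(cs[length(cs)], 1)
  which(cs >= target - 1e-12)[1]
}

#' Bray-Curtis dissimilarity between two samples
#'
#' `1 - 2 * sum(min(a, b)) / (sum(a) + sum(b))`, in \[0, 1\] for nonnegative
#' vectors.
#'
#' @param a,b Aligned nonnegative abundance vectors.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) abort("`a` and `b` must have the same length.")
  if (any(a < 0) || any(b < 0)) abort("Abundances must be nonnegative.")
  denom <- sum(a) + sum(b)
  if (denom == 0) abort("Bray-Curtis is undefined for two all-zero samples.")
  1 - 2 * sum(pmin(a, b)) / denom
}

#' Cliff's Delta effect size
#'
#' The difference between the probability that a value drawn from `x`
#' exceeds one drawn from `y` and the reverse probability:
#' `d = (#(x_i > y_j) - #(x_i < y_j)) / (|x| * |y|)`, in \[-1, 1\].
#'
#' @param x,y Numeric samples (both nonempty).
#' @return Cliff's Delta.
#' @export
cliffs_delta <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (!length(x) || !length(y)) abort("Both samples must be nonempty.")
  # rank-based O((n+m) log(n+m)) formulation: sum of pairwise signs equals
  # 2 * (rank-sum of x in the pooled midranks) - nx*(nx + n + 1) ... use the
  # direct relation through the Mann-Whitney U with tie halving.
  u <- mw_u(x, y)
  nx <- length(x); ny <- length(y)
  (2 * u - nx * ny) / (nx * ny)
}

# Mann-Whitney U for x vs y with ties counted 1/2 (midrank formulation).
mw_u <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))  # midranks
  sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
}

#' Two-sample Mann-Whitney U test
#'
#' Computes the rank-sum U statistic with midranks for ties. When the
#' smaller sample has at most `exact_max` observations (default 8) the
#' p-value is obtained by exact enumeration of all label assignments of the
#' pooled values; otherwise the tie-corrected normal approximation (without
#' continuity correction) is used.
#'
#' @param x,y Numeric samples (both nonempty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`,
#'   stated for `x` relative to `y`.
#' @param exact Force (`TRUE`) or forbid (`FALSE`) exact enumeration;
#'   `NULL` (default) decides by `exact_max`.
#' @param exact_max Sample-size cutoff for the exact mode.
#' @return A one-row tibble with `statistic` (U for `x`), `p_value` and
#'   `method`.
#' @export
mann_whitney <- function(x, y, alternative = c("two.sided", "less", "greater"),
                         exact = NULL, exact_max = 8L) {
  alternative <- match.arg(alternative)
  x <- as.numeric(x); y <- as.numeric(y)
  nx <- length(x); ny <- length(y)
  if (!nx || !ny) abort("Both samples must be nonempty.")
  u <- mw_u(x, y)
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0
  use_exact <- exact %||% (min(nx, ny) <= exact_max)
  if (use_exact && has_ties && choose(nx + ny, min(nx, ny)) > 5e5) {
    # enumeration over tied data is infeasible at this size
    inform("Tied data too large for exact enumeration; using normal approximation.")
    use_exact <- FALSE
  }
  if (use_exact) {
    if (has_ties) {
      idx <- utils::combn(nx + ny, nx)
      us <- apply(idx, 2, function(i) mw_u(pooled[i], pooled[-i]))
      tol <- 1e-9
      p_le <- mean(us <= u + tol)
      p_ge <- mean(us >= u - tol)
      method <- "exact enumeration"
    } else {
      # tie-free: the exact U distribution in closed form
      p_le <- stats::pwilcox(u, nx, ny)
      p_ge <- stats::pwilcox(u - 1, nx, ny, lower.tail = FALSE)
      method <- "exact distribution"
    }
    p <- switch(alternative,
      two.sided = min(1, 2 * min(p_le, p_ge)),
      less = p_le,
      greater = p_ge
    )
  } else {
    n <- nx + ny
    r <- rank(c(x, y))
    ties <- table(r)
    mu <- nx * ny / 2
    sigma2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) abort("All pooled values are tied; U test is degenerate.")
    z <- (u - mu) / sqrt(sigma2)
    p <- switch(alternative,
      two.sided = 2 * stats::pnorm(-abs(z)),
      less = stats::pnorm(z),
      greater = stats::pnorm(z, lower.tail = FALSE)
    )
    method <- "normal approximation (tie-corrected)"
  }
  tibble(statistic = u, p_value = min(p, 1), method = method)
}

#' Spearman rank correlation with confidence interval
#'
#' Rank correlation with average ranks for ties; the p-value (null: rho = 0)
#' uses a t-distribution with n - 2 degrees of freedom, and the confidence
#' interval comes from the Fisher z transform.
#'
#' @param x,y Numeric vectors of equal length, at least 4 observations.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble: `rho`, `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
spearman_ci <- function(x, y, level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n || n < 4) abort("`x` and `y` must have equal length >= 4.")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("Spearman correlation is undefined for a constant vector.")
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (abs(rho) >= 1) {
    p <- 0
    ci <- c(rho, rho)
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    z <- atanh(rho)
    se <- 1 / sqrt(n - 3)
    q <- stats::qnorm(1 - (1 - level) / 2)
    ci <- tanh(c(z - q * se, z + q * se))
  }
  tibble(rho = rho, conf_low = ci[1], conf_high = ci[2], p_value = p, n = n)
}

#' Per-sample ecology metrics table
#'
#' @param abundance Wide abundance tibble.
#' @param richness_mode Passed to [species_richness()].
#' @param presence_threshold Presence threshold for `"threshold"` richness.
#' @param target Coverage target for [coverage80()].
#' @return A tibble with `sample_id`, `shannon`, `richness` and `coverage80`.
#' @export
ecology_metrics <- function(abundance, richness_mode = "positive",
                            presence_threshold = 1e-5, target = 0.80) {
  check_abundance(abundance)
  m <- abund_matrix(abundance)
  tibble(
    sample_id = rownames(m),
    shannon = unname(apply(m, 1, shannon_index)),
    richness = unname(apply(m, 1, species_richness, mode = richness_mode,
                            presence_threshold = presence_threshold)),
    coverage80 = unname(apply(m, 1, coverage80, target = target))
  )
}

#' Compare per-sample metrics between healthy and nonhealthy groups
#'
#' For each metric column, reports group sizes and medians, the two-sided
#' Mann-Whitney U statistic and p-value, and Cliff's Delta
#' (healthy vs nonhealthy).
#'
#' @param metrics Tibble with `sample_id` and one column per metric (e.g.
#'   the output of [ecology_metrics()] joined with a GMHI column).
#' @param metadata Sample metadata with a `group` column.
#' @param group_col Metadata column holding the two group labels.
#' @param healthy,nonhealthy The two labels to compare.
#' @return A tibble with one row per metric.
#' @export
compare_metrics <- function(metrics, metadata, group_col = "group",
                            healthy = "healthy", nonhealthy = "nonhealthy") {
  check_metadata(metadata)
  grp <- metadata[[group_col]][match(metrics$sample_id, metadata$sample_id)]
  cols <- setdiff(names(metrics), "sample_id")
  cols <- cols[vapply(metrics[cols], is.numeric, logical(1))]
  purrr::map_dfr(cols, function(cn) {
    v <- metrics[[cn]]
    xh <- v[!is.na(grp) & grp == healthy]
    xn <- v[!is.na(grp) & grp == nonhealthy]
    if (length(xh) < 2 || length(xn) < 2) {
      warn(sprintf("Metric '%s': a group has fewer than 2 samples; skipped.", cn))
      return(tibble())
    }
    mw <- mann_whitney(xh, xn)
    tibble(
      metric = cn,
      n_healthy = length(xh), n_nonhealthy = length(xn),
      median_healthy = stats::median(xh), median_nonhealthy = stats::median(xn),
      statistic = mw$statistic, p_value = mw$p_value,
      cliffs_delta = cliffs_delta(xh, xn)
    )
  })
}
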