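#' Pearson chi-square test of homogeneity for a two-arm contingency table
#'
#' Tests whether the category distribution is the same in both arms, using
#' the Pearson statistic without continuity correction — the convention that
#' reproduces multi-category baseline-balance rows of randomized-trial
#' tables. The p-value is also returned in percent, the scale such tables
#' print.
#'
#' @param counts integer matrix, categories x arms (>= 2 rows, >= 2 columns),
#'   no zero row or column totals.
#' @return list with `statistic`, `df`, `p`, `p_percent`, `expected`.
#' @export
chi_square_homogeneity <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("need at least 2 categories and 2 arms")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column total: expected counts undefined")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ct$statistic),
       df = unname(ct$parameter),
       p = unname(ct$p.value),
       p_percent = 100 * unname(ct$p.value),
       expected = ct$expected)
}

#' Baseline-characteristics balance report
#'
#' For each categorical variable, cross-tabulates categories against the two
#' arms (complete cases per variable, so denominators may differ across
#' variables), computes column percentages and the homogeneity p-value in
#' percent. Variables observed in a single category get `p_percent = NA`
#' (df = 0: not applicable).
#'
#' @param covariates data frame with a `group` column (2 levels) and the
#'   named variables; or a `synth_cohort`.
#' @param variables character vector of column names to report.
#' @return data frame with columns `variable`, `category`, `count_arm1`,
#'   `pct_arm1`, `count_arm2`, `pct_arm2`, `p_percent` (repeated down each
#'   variable block); arm 1 is the first factor level of `group`.
#' @export
characteristics_report <- function(covariates, variables) {
  if (inherits(covariates, "synth_cohort")) covariates <- covariates$covariates
  stopifnot(is.data.frame(covariates), "group" %in% names(covariates))
  arms <- sort(unique(as.character(covariates$group)))
  if (length(arms) != 2) stop("group must have exactly 2 levels")
  rows <- list()
  for (v in variables) {
    if (!v %in% names(covariates)) stop("variable not present: ", v)
    x <- covariates[[v]]
    keep <- !is.na(x)
    if (!any(keep)) stop("variable has no observed values: ", v)
    tab <- table(factor(as.character(x[keep])),
                 factor(as.character(covariates$group[keep]), levels = arms))
    counts <- matrix(as.integer(tab), nrow = nrow(tab),
                     dimnames = dimnames(tab))
    pp <- if (nrow(counts) < 2 || any(colSums(counts) == 0)) NA_real_
          else chi_square_homogeneity(counts)$p_percent
    rows[[v]] <- data.frame(
      variable = v,
      category = rownames(counts),
      count_arm1 = counts[, 1],
      pct_arm1 = 100 * counts[, 1] / sum(counts[, 1]),
      count_arm2 = counts[, 2],
      pct_arm2 = 100 * counts[, 2] / sum(counts[, 2]),
      p_percent = pp,
      row.names = NULL
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "arms") <- arms
  out
}

#' Dispersion of per-site sample means
#'
#' Computes the sample mean of a per-subject scalar (typically the
#' whole-volume mean tissue density) for each clinic site, then four
#' dispersion measures across those site means: interquartile range (IQR,
#' linear-interpolation quantiles), mean absolute deviation about the mean
#' (MAD), range, and sample standard deviation (STD). Used to quantify how
#' much residual between-site variation remains before vs after
#' nuisance-covariate correction.
#'
#' @param values numeric per-subject scalars.
#' @param sites per-subject site labels (>= 2 distinct sites).
#' @return list with `site_means`, `iqr`, `mad`, `range`, `std`.
#' @export
site_dispersion <- function(values, sites) {
  stopifnot(length(values) == length(sites))
  sites <- as.character(sites)
  if (length(unique(sites)) < 2)
    stop("need at least 2 distinct sites")
  m <- tapply(values, sites, mean)
  list(site_means = m,
       iqr = unname(stats::quantile(m, 0.75) - stats::quantile(m, 0.25)),
       mad = mean(abs(m - mean(m))),
       range = max(m) - min(m),
       std = stats::sd(m))
}
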