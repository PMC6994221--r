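#' Spark mass
#'
#' Composite measure of the calcium released by one spark:
#' amplitude (dF/F0) x FDHM (ms) x FWHM (um).
#'
#' @param amplitude spark amplitude, dF/F0 (> 0).
#' @param fdhm full duration at half maximum, ms (> 0).
#' @param fwhm full width at half maximum, um (> 0).
#' @return spark mass (dF/F0 * ms * um), vectorised.
#' @export
spark_mass <- function(amplitude, fdhm, fwhm) {
  if (any(!is.finite(amplitude) | amplitude <= 0) ||
      any(!is.finite(fdhm) | fdhm <= 0) ||
      any(!is.finite(fwhm) | fwhm <= 0))
    stop("spark parameters must be positive and finite")
  amplitude * fdhm * fwhm
}

#' SR-content-normalized spark frequency
#'
#' Divides a cell's spark rate by its SR calcium content (the
#' caffeine-transient amplitude) to isolate effects on the receptor array
#' from effects of SR filling.
#'
#' @param spark_rate sparks s^-1 (100 um)^-1, >= 0.
#' @param sr_content caffeine-transient amplitude, dF/F0 (> 0).
#' @return normalized rate, vectorised.
#' @export
normalize_frequency <- function(spark_rate, sr_content) {
  if (any(!is.finite(sr_content) | sr_content <= 0))
    stop("sr_content must be positive")
  if (any(!is.finite(spark_rate) | spark_rate < 0))
    stop("spark_rate must be non-negative")
  spark_rate / sr_content
}

#' Hierarchical pairwise group comparison (three-level bootstrap)
#'
#' Compares a spark parameter between every pair of treatment groups while
#' respecting the rat -> cell -> spark nesting: a nonparametric
#' hierarchical bootstrap resamples rats with replacement, then cells
#' within each sampled rat, then sparks within each sampled cell, and
#' tracks the difference of group means (each group mean is the mean of
#' rat means of cell means, so no rat or cell dominates by its spark
#' count). The two-sided p-value is the tail fraction of the bootstrap
#' difference distribution around zero, with the usual +1 small-sample
#' correction.
#'
#' @param records data.frame with columns \code{rat}, \code{cell},
#'   \code{group} and the parameter column named by \code{parameter};
#'   cells are nested in rats (cell ids are taken per rat).
#' @param parameter name of the value column to compare.
#' @param log_transform compare on the log scale (appropriate for the
#'   log-normal spark parameters; frequency/SR content is analysed
#'   untransformed).
#' @param B number of bootstrap resamples (>= 2000).
#' @param groups optional subset/order of groups to compare.
#' @return data.frame with columns \code{comparison}, \code{group_a},
#'   \code{group_b}, \code{p}; one row per unordered group pair.
#' @export
hierarchical_pairwise <- function(records, parameter,
                                  log_transform = TRUE, B = 2000,
                                  groups = NULL) {
  stopifnot(B >= 2000)
  records <- as.data.frame(records)
  if (!parameter %in% names(records))
    stop("parameter column not found: ", parameter)
  vals <- records[[parameter]]
  if (log_transform) {
    if (any(vals <= 0)) stop("log transform needs positive values")
    vals <- log(vals)
  }
  if (is.null(groups)) groups <- unique(as.character(records$group))
  if (length(groups) < 2L) stop("need at least 2 groups")
  nested <- lapply(groups, function(g) {
    sub <- records$group == g
    rats <- split(data.frame(cell = records$cell[sub], v = vals[sub]),
                  as.character(records$rat[sub]))
    if (length(rats) < 2L)
      stop("group ", g, " has fewer than 2 rats")
    lapply(rats, function(r) {
      cells <- split(r$v, as.character(r$cell))
      if (length(cells) < 2L)
        stop("a rat in group ", g, " has fewer than 2 cells")
      cells
    })
  })
  names(nested) <- groups
  combs <- utils::combn(groups, 2)
  rows <- lapply(seq_len(ncol(combs)), function(c) {
    ga <- combs[1, c]; gb <- combs[2, c]
    d <- hier_boot_diff(nested[[ga]], nested[[gb]], B)
    p <- 2 * min(sum(d <= 0) + 1, sum(d >= 0) + 1) / (B + 1)
    data.frame(comparison = paste(ga, "vs", gb),
               group_a = ga, group_b = gb, p = min(p, 1))
  })
  do.call(rbind, rows)
}

#' Holm-Bonferroni comparison ledger
#'
#' Sequentially rejective multiple-testing correction: p-values are ranked
#' ascending, the critical value at rank r (1-based) among m comparisons is
#' \code{alpha / (m - r + 1)}, and rejections proceed while
#' \code{p < critical}; the first failure stops all later rejections.
#' The returned five-column table mirrors the statistical ledgers used for
#' spark-parameter comparisons: comparison, p, unadjusted significance,
#' Holm critical value, reject flag.
#'
#' @param pvalues numeric vector of p-values in [0, 1].
#' @param alpha family-wise error level (default 0.05).
#' @param comparisons optional labels (defaults to "1", "2", ...).
#' @return data.frame of class \code{"holm_ledger"}, sorted by ascending p,
#'   with columns \code{comparison}, \code{p}, \code{significant_unadj},
#'   \code{holm_critical_p}, \code{reject}.
#' @examples
#' holm_bonferroni(c(0.01, 0.04, 0.02), alpha = 0.05)
#' @export
holm_bonferroni <- function(pvalues, alpha = 0.05, comparisons = NULL) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stopifnot(alpha > 0, alpha < 1)
  m <- length(pvalues)
  if (is.null(comparisons)) comparisons <- as.character(seq_len(m))
  ord <- order(pvalues)
  p <- pvalues[ord]
  crit <- alpha / (m - seq_len(m) + 1)
  pass <- p < crit
  reject <- cumprod(pass) == 1   # stop at the first failure
  out <- data.frame(comparison = comparisons[ord], p = p,
                    significant_unadj = p < alpha,
                    holm_critical_p = crit, reject = reject)
  class(out) <- c("holm_ledger", "data.frame")
  out
}

#' @export
print.holm_ledger <- function(x, ...) {
  cat(sprintf("Holm-Bonferroni ledger: %d comparisons, %d rejected\n",
              nrow(x), sum(x$reject)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Full spark-parameter comparison with Holm correction
#'
#' Runs \code{\link{hierarchical_pairwise}} for one parameter across all
#' groups and wraps the p-values in a \code{\link{holm_bonferroni}} ledger.
#'
#' @inheritParams hierarchical_pairwise
#' @param alpha family-wise error level for the Holm step.
#' @return a \code{holm_ledger}.
#' @export
spark_comparison_ledger <- function(records, parameter,
                                    log_transform = TRUE, B = 2000,
                                    alpha = 0.05) {
  pw <- hierarchical_pairwise(records, parameter,
                              log_transform = log_transform, B = B)
  holm_bonferroni(pw$p, alpha = alpha, comparisons = pw$comparison)
}
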