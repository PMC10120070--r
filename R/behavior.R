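## Site-level aggregation of approach counts from the polarization
## discrimination field experiment.

#' Per-site differences between polarized and depolarized approaches
#'
#' Sites are the unit of replication: for each site of the requested
#' treatment the signed difference (polarized minus depolarized approach
#' count) is returned. Negative values mean the depolarized model was
#' approached more often.
#'
#' @param counts data.frame with columns \code{site_id}, \code{treatment},
#'   \code{n_polarized}, \code{n_depolarized} (e.g. from
#'   [generateBehaviorCounts()]).
#' @param treatment Treatment label to select.
#' @return Named numeric of per-site differences.
#' @export
siteDifferences <- function(counts, treatment) {
  need <- c("site_id", "treatment", "n_polarized", "n_depolarized")
  stopifnot(all(need %in% names(counts)))
  sel <- counts[counts$treatment == treatment, , drop = FALSE]
  if (nrow(sel) == 0)
    stop("unknown treatment '", treatment, "' (have: ",
      paste(unique(counts$treatment), collapse = ", "), ")")
  if (any(sel$n_polarized < 0 | sel$n_depolarized < 0))
    stop("counts must be non-negative")
  stats::setNames(sel$n_polarized - sel$n_depolarized, sel$site_id)
}

#' One-sample Student's t-test against zero
#'
#' Tests whether the mean of the per-site differences departs from zero:
#' \code{t = mean(x) / (sd(x) / sqrt(n))} on \code{n - 1} degrees of
#' freedom, two-sided.
#'
#' @param differences Numeric vector (length >= 2, non-zero sd).
#' @return List with \code{t}, \code{df}, \code{p}, \code{mean}.
#' @export
#' @examples
#' oneSampleT(c(-1, 1))$t  # 0
oneSampleT <- function(differences) {
  if (length(differences) < 2) stop("need at least two differences")
  if (stats::sd(differences) == 0)
    stop("zero standard deviation: t statistic undefined")
  tt <- stats::t.test(differences, mu = 0)
  list(
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    mean = unname(tt$estimate)
  )
}

#' Whole-number percentage of depolarized approaches
#'
#' Proportion of total approaches directed at depolarized models, reported
#' as a truncated (floored) whole-number percentage — 113 of 183 gives 61.
#' The exact fraction is attached as attribute \code{"fraction"}.
#'
#' @param n_depolarized_total,n_total Non-negative counts with
#'   \code{n_depolarized_total <= n_total} and \code{n_total > 0}.
#' @return Integer-valued percentage in [0, 100].
#' @export
#' @examples
#' approachProportion(113, 183)  # 61
approachProportion <- function(n_depolarized_total, n_total) {
  if (n_total <= 0) stop("n_total must be positive")
  if (n_depolarized_total < 0 || n_depolarized_total > n_total)
    stop("n_depolarized_total must lie in [0, n_total]")
  structure(truncPercent(n_depolarized_total / n_total),
    fraction = n_depolarized_total / n_total)
}
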