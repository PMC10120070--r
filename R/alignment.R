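#' Estimate the microvillar principal axis from an intensity series
#'
#' The principal axis Sigma of an ommatidium is the roll angle (between 0
#' and 90 degrees) at which its depolarized eyeshine is minimal. For the
#' model class \eqn{I(\theta) = a + b\,\sin^2(2(\theta - \Sigma))} the
#' signal contains only a DC term and the 4-theta harmonic, so the Fourier
#' component at that harmonic recovers Sigma exactly from any uniform theta
#' grid covering whole 90-degree periods:
#' \deqn{c_4 = \sum_k I(\theta_k)\, e^{-i 4 \theta_k \pi / 180}, \qquad
#'       \hat\Sigma = \left(-\arg(c_4)/4 + 45\right) \bmod 90.}
#' A duplicated endpoint (e.g. theta = 0 and theta = 180 of the standard
#' 37-frame acquisition) is dropped before the transform. The modulation
#' depth \code{b / (a + b)} serves as a quality score: ommatidia outside the
#' illumination cone show little modulated eyeshine and fail QC.
#'
#' @param thetas Roll angles in degrees, near-uniformly spaced, covering at
#'   least one full 90-degree period; at least 8 samples.
#' @param values Mean ROI intensities, same length as \code{thetas}.
#' @param qc_threshold Minimum modulation for \code{qc_pass} (default 0.2).
#' @return List with \code{sigma_deg} (in [0, 90), \code{NA} if the series
#'   is unmodulated), \code{modulation}, \code{baseline} (fitted a),
#'   \code{amplitude} (fitted b), \code{residual_rms} and \code{qc_pass}.
#' @seealso [estimatePatch()], [deltaSigma()], [eyeshineModel()]
#' @export
#' @examples
#' th <- seq(0, 180, by = 5)
#' est <- estimateSigma(th, eyeshineModel(th, sigma = 27))
#' est$sigma_deg
estimateSigma <- function(thetas, values, qc_threshold = 0.2) {
  stopifnot(length(thetas) == length(values))
  if (length(thetas) < 8) stop("too few samples (need >= 8)")
  if (is.unsorted(thetas, strictly = TRUE))
    stop("thetas must be strictly increasing")
  ## drop trailing duplicates of the first sample (period 90 in theta)
  tol <- 1e-9
  while (length(thetas) > 1) {
    span <- (thetas[length(thetas)] - thetas[1]) %% 90
    if (span < tol || span > 90 - tol) {
      thetas <- thetas[-length(thetas)]
      values <- values[-length(values)]
    } else break
  }
  n <- length(thetas)
  if (n < 8) stop("too few samples (need >= 8)")
  step <- stats::median(diff(thetas))
  if (max(thetas) - min(thetas) + step < 90 - 1e-6)
    stop("series must cover at least one full 90-degree period")

  c4 <- sum(values * exp(-1i * 4 * thetas * pi / 180))
  b <- 4 * Mod(c4) / n
  scale <- max(abs(values), 1)
  if (b < 1e-10 * scale) {
    return(list(
      sigma_deg = NA_real_, modulation = 0,
      baseline = mean(values), amplitude = 0,
      residual_rms = stats::sd(values) * sqrt((n - 1) / n),
      qc_pass = FALSE
    ))
  }
  sigma <- (-Arg(c4) * 180 / pi / 4 + 45) %% 90
  a <- mean(values) - b / 2
  modulation <- min(max(b / (a + b), 0), 1)
  fitted <- a + b * sin(2 * (thetas - sigma) * pi / 180)^2
  list(
    sigma_deg = sigma,
    modulation = modulation,
    baseline = a,
    amplitude = b,
    residual_rms = sqrt(mean((values - fitted)^2)),
    qc_pass = modulation >= qc_threshold
  )
}

#' Axial difference between two principal axes
#'
#' The difference in principal axes of two ommatidia is an axial distance
#' with period 90 degrees:
#' \code{min(|a - b| mod 90, 90 - |a - b| mod 90)}, in [0, 45]. It is
#' symmetric and invariant under adding any multiple of 90 degrees to
#' either input.
#'
#' @param sigma_a,sigma_b Principal axes in degrees (vectorised).
#' @return Axial differences in degrees, in [0, 45].
#' @export
#' @examples
#' deltaSigma(10, 40)  # 30
#' deltaSigma(5, 85)   # 10 (wrap-around)
deltaSigma <- function(sigma_a, sigma_b) {
  if (any(!is.finite(sigma_a)) || any(!is.finite(sigma_b)))
    stop("inputs must be finite")
  d <- abs(sigma_a - sigma_b) %% 90
  pmin(d, 90 - d)
}

#' Estimate principal axes for a whole patch
#'
#' Runs [estimateSigma()] on every per-ommatidium series of a long-format
#' series table (one channel) and assembles a [SigmaField-class] containing
#' the QC-passing ommatidia, plus the full estimate table.
#'
#' @param series data.frame as returned by [extractIntensitySeries()]
#'   (columns \code{q}, \code{r}, \code{theta_deg}, \code{intensity};
#'   a \code{channel} column, if present, must be single-valued).
#' @param qc_threshold Minimum modulation for inclusion in the field.
#' @param metadata Optional patch metadata for the resulting field.
#' @return List with \code{field} (a [SigmaField-class]; \code{measured}
#'   equals QC pass) and \code{estimates} (data.frame with one row per
#'   ommatidium: \code{q}, \code{r}, \code{sigma_deg}, \code{modulation},
#'   \code{residual_rms}, \code{qc_pass}).
#' @export
estimatePatch <- function(series, qc_threshold = 0.2, metadata = list()) {
  if (is.null(series) || nrow(series) == 0) stop("empty series input")
  need <- c("q", "r", "theta_deg", "intensity")
  if (!all(need %in% names(series)))
    stop("series must have columns ", paste(need, collapse = ", "))
  if ("channel" %in% names(series) && length(unique(series$channel)) > 1)
    stop("series mixes channels; estimate one channel at a time")
  key <- interaction(series$q, series$r, drop = TRUE)
  th0 <- sort(unique(series$theta_deg))
  parts <- split(series, key)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$theta_deg), ]
    if (!isTRUE(all.equal(d$theta_deg, th0)))
      stop("all series must share the same theta grid")
    est <- estimateSigma(d$theta_deg, d$intensity, qc_threshold)
    data.frame(
      q = d$q[1], r = d$r[1],
      sigma_deg = est$sigma_deg, modulation = est$modulation,
      residual_rms = est$residual_rms, qc_pass = est$qc_pass
    )
  })
  est <- do.call(rbind, rows)
  est <- est[order(est$r, est$q), ]
  rownames(est) <- NULL
  sigma <- ifelse(est$qc_pass, est$sigma_deg, NA_real_)
  field <- SigmaField(est$q, est$r, sigma,
    measured = est$qc_pass, metadata = metadata)
  list(field = field, estimates = est)
}
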