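#' Generate a synthetic polarization image pair of known DoP
#'
#' Produces a pair of images (horizontal- and vertical-polarized intensity)
#' whose noiseless degree of polarization is exactly \code{dop}, with the
#' horizontal channel dominant: per-pixel expectations are
#' \code{total_intensity * (1 + dop) / 2} for H and
#' \code{total_intensity * (1 - dop) / 2} for V.
#'
#' @param dop Degree of polarization in [0, 1].
#' @param total_intensity Expected per-pixel sum of the two channels, counts.
#' @param shape Integer length-2, image (height, width).
#' @param noise_sd Additive Gaussian noise sd, counts.
#' @param seed Integer seed.
#' @return List with matrices \code{i_h}, \code{i_v} and the generating
#'   \code{dop}.
#' @seealso [imagePairDop()]
#' @export
#' @examples
#' p <- generatePolarizationImagePair(0.5, noise_sd = 0)
#' imagePairDop(p$i_h, p$i_v)$dop
generatePolarizationImagePair <- function(dop, total_intensity = 200,
                                          shape = c(64, 64), noise_sd = 0,
                                          seed = 1L) {
  if (!is.numeric(dop) || length(dop) != 1 || dop < 0 || dop > 1)
    stop("dop must lie in [0, 1]")
  stopifnot(total_intensity > 0, length(shape) == 2, noise_sd >= 0)
  withSeed(seed, {
    i_h <- matrix(total_intensity * (1 + dop) / 2, shape[1], shape[2])
    i_v <- matrix(total_intensity * (1 - dop) / 2, shape[1], shape[2])
    if (noise_sd > 0) {
      i_h <- i_h + matrix(stats::rnorm(length(i_h), 0, noise_sd),
        shape[1], shape[2])
      i_v <- i_v + matrix(stats::rnorm(length(i_v), 0, noise_sd),
        shape[1], shape[2])
    }
    list(i_h = i_h, i_v = i_v, dop = dop)
  })
}

#' Generate a Gaussian-peaked wing reflectance spectrum
#'
#' Template reflectance spectrum: a Gaussian bump of given peak wavelength,
#' full width at half maximum and amplitude, on a small flat pedestal.
#'
#' @param peak_nm Peak wavelength, nm; must lie inside \code{range_nm}.
#' @param fwhm_nm Full width at half maximum, nm.
#' @param amplitude Peak reflectance above the pedestal (fraction of a unit
#'   reflectance standard).
#' @param pedestal Flat baseline reflectance.
#' @param range_nm Numeric length-2, sampled wavelength range, nm.
#' @param step_nm Grid spacing, nm (> 0).
#' @return data.frame with columns \code{wavelength_nm}, \code{reflectance}.
#' @seealso [forewingTemplate()], [spectralPeak()]
#' @export
generateReflectanceSpectrum <- function(peak_nm, fwhm_nm = 100,
                                        amplitude = 0.35, pedestal = 0.02,
                                        range_nm = c(350, 700),
                                        step_nm = 1) {
  if (!is.numeric(step_nm) || step_nm <= 0) stop("step_nm must be > 0")
  stopifnot(length(range_nm) == 2, range_nm[1] < range_nm[2])
  if (peak_nm < range_nm[1] || peak_nm > range_nm[2])
    stop("peak_nm must lie inside range_nm")
  wl <- seq(range_nm[1], range_nm[2], by = step_nm)
  s <- fwhm_nm / (2 * sqrt(2 * log(2)))
  data.frame(
    wavelength_nm = wl,
    reflectance = pedestal + amplitude * exp(-(wl - peak_nm)^2 / (2 * s^2))
  )
}

#' Synthetic forewing reflectance templates
#'
#' Default spectral templates for the sexually dimorphic forewing
#' reflectance: the female template peaks at 521 nm, the male at 545 nm,
#' on the standard 350-700 nm, 1-nm grid.
#'
#' @param sex \code{"female"} or \code{"male"}.
#' @param ... Passed on to [generateReflectanceSpectrum()].
#' @return data.frame with columns \code{wavelength_nm}, \code{reflectance}.
#' @export
#' @examples
#' spectralPeak(forewingTemplate("female"))$peak_nm
forewingTemplate <- function(sex = c("female", "male"), ...) {
  sex <- match.arg(sex)
  generateReflectanceSpectrum(
    peak_nm = if (sex == "female") 521 else 545, ...
  )
}

#' Generate Gaussian photoreceptor sensitivity templates
#'
#' Gaussian stand-in sensitivity curves for the four photoreceptor classes
#' of a tetrachromat (u = ultraviolet, s = short, m = medium, l = long
#' wavelength), each with unit peak height. These are synthetic fixtures,
#' not estimates of measured opsin curves.
#'
#' @param peaks_nm Four strictly increasing peak wavelengths (u < s < m < l).
#' @param fwhm_nm Full width at half maximum shared by the four curves, nm.
#' @param range_nm Numeric length-2, sampled wavelength range, nm.
#' @param step_nm Grid spacing, nm.
#' @return data.frame with columns \code{wavelength_nm}, \code{u}, \code{s},
#'   \code{m}, \code{l}.
#' @seealso [quantumCatches()]
#' @export
generateSensitivityTemplates <- function(peaks_nm = c(360, 450, 520, 600),
                                         fwhm_nm = 80,
                                         range_nm = c(350, 700),
                                         step_nm = 1) {
  if (length(peaks_nm) != 4 || anyDuplicated(peaks_nm) ||
      is.unsorted(peaks_nm, strictly = TRUE))
    stop("peaks_nm must be four distinct increasing wavelengths (u<s<m<l)")
  if (step_nm <= 0) stop("step_nm must be > 0")
  wl <- seq(range_nm[1], range_nm[2], by = step_nm)
  s <- fwhm_nm / (2 * sqrt(2 * log(2)))
  out <- data.frame(wavelength_nm = wl)
  cls <- c("u", "s", "m", "l")
  for (i in 1:4)
    out[[cls[i]]] <- exp(-(wl - peaks_nm[i])^2 / (2 * s^2))
  out
}

#' Generate synthetic site-level approach counts
#'
#' Simulates per-site counts of approaches to polarized and depolarized wing
#' models: the depolarized count at each site is Binomial(total, p_depol).
#' Defaults reproduce the blue-treatment study condition of 183 total
#' approaches across 7 sites with an overall depolarized proportion of
#' 113/183.
#'
#' @param n_sites Number of sites.
#' @param p_depol Probability an approach targets the depolarized model.
#' @param totals_per_site Integer vector of per-site approach totals
#'   (recycled to \code{n_sites}).
#' @param treatment Treatment label (one of \code{"blue"}, \code{"yellow"},
#'   \code{"red"}).
#' @param seed Integer seed; the table is deterministic per seed.
#' @return data.frame with columns \code{site_id}, \code{treatment},
#'   \code{n_polarized}, \code{n_depolarized}.
#' @seealso [siteDifferences()], [approachProportion()]
#' @export
generateBehaviorCounts <- function(n_sites = 7, p_depol = 113 / 183,
                                   totals_per_site = c(27, rep(26, 6)),
                                   treatment = c("blue", "yellow", "red"),
                                   seed = 1L) {
  treatment <- match.arg(treatment)
  if (!is.numeric(p_depol) || p_depol < 0 || p_depol > 1)
    stop("p_depol must lie in [0, 1]")
  totals <- rep_len(as.integer(totals_per_site), n_sites)
  if (any(totals <= 0)) stop("totals_per_site must be positive")
  withSeed(seed, {
    dep <- stats::rbinom(n_sites, totals, p_depol)
    data.frame(
      site_id = sprintf("site%02d", seq_len(n_sites)),
      treatment = treatment,
      n_polarized = totals - dep,
      n_depolarized = dep
    )
  })
}
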