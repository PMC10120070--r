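#' Pipeline configuration
#'
#' Validates and assembles the configuration for [runPipeline()]. Elevation
#' and azimuth outside the standard acquisition sets (elevations -30, 0,
#' 30, 60 degrees; azimuths 10, 15 degrees) are accepted with a warning.
#'
#' @param rows,cols Synthetic patch extent.
#' @param seed Integer seed for every stochastic stage (mandatory).
#' @param p_align,jitter_sd,mixture Field-generation parameters, see
#'   [generateSigmaField()].
#' @param optics Optics parameter list from [opticsParams()].
#' @param thetas Acquisition roll angles, degrees.
#' @param roi_radius ROI radius in pixels.
#' @param channel Channel to profile.
#' @param qc_threshold Modulation QC threshold for [estimatePatch()].
#' @param ed_tol,min_len,pd_threshold Classification parameters, see
#'   [patchMetrics()].
#' @param patch_id,sex,elevation_deg,azimuth_deg Patch metadata carried
#'   into all outputs.
#' @return Validated configuration list of class \code{"ommapolConfig"}.
#' @export
pipelineConfig <- function(rows = 10, cols = 10, seed = 1L,
                           p_align = 0.8, jitter_sd = 3, mixture = NULL,
                           optics = opticsParams(),
                           thetas = seq(0, 180, by = 5),
                           roi_radius = 8, channel = "R",
                           qc_threshold = 0.2,
                           ed_tol = 5, min_len = 3, pd_threshold = 20,
                           patch_id = "patch1", sex = NA_character_,
                           elevation_deg = NA_real_,
                           azimuth_deg = NA_real_) {
  if (is.null(seed) || !is.finite(seed))
    stop("config field 'seed' is mandatory")
  if (!is.numeric(rows) || !is.numeric(cols) || rows < 1 || cols < 1)
    stop("config fields 'rows'/'cols' must be >= 1")
  if (roi_radius >= optics$spacing / 2)
    stop("config field 'roi_radius' must be < spacing / 2")
  if (!is.na(elevation_deg) && !elevation_deg %in% c(-30, 0, 30, 60))
    warning("elevation_deg outside the standard set {-30, 0, 30, 60}")
  if (!is.na(azimuth_deg) && !azimuth_deg %in% c(10, 15))
    warning("azimuth_deg outside the standard set {10, 15}")
  structure(list(
    rows = rows, cols = cols, seed = as.integer(seed),
    p_align = p_align, jitter_sd = jitter_sd, mixture = mixture,
    optics = optics, thetas = thetas, roi_radius = roi_radius,
    channel = channel, qc_threshold = qc_threshold,
    ed_tol = ed_tol, min_len = min_len, pd_threshold = pd_threshold,
    patch_id = patch_id, sex = sex, elevation_deg = elevation_deg,
    azimuth_deg = azimuth_deg
  ), class = "ommapolConfig")
}

## Stable hash of a configuration (md5 of its canonical JSON).
configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = 12,
    null = "null")
  unname(tools::md5sum(f))
}

#' Run the full simulate-extract-estimate-classify pipeline
#'
#' Executes the pipeline stages in order: simulate a Sigma field, render
#' the eyeshine stack, place the ROI grid, extract intensity series,
#' estimate per-ommatidium principal axes, classify the lattice and report
#' patch metrics. Every stage is deterministic for a fixed configuration;
#' outputs carry the configuration hash and seed.
#'
#' @param config Configuration from [pipelineConfig()].
#' @param outdir Optional output directory; when given, the true and
#'   estimated fields, the series table and the metrics JSON are written
#'   there.
#' @return List with \code{field_true}, \code{stack}, \code{series},
#'   \code{estimates}, \code{field}, \code{metrics}, \code{config},
#'   \code{config_hash}, \code{seed} and a per-stage \code{log} of counts.
#' @export
#' @examples
#' res <- runPipeline(pipelineConfig(rows = 6, cols = 6, seed = 1))
#' res$metrics$n_interior
runPipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "ommapolConfig"))
    stop("config must come from pipelineConfig()")
  hash <- configHash(config)
  meta <- list(
    patch_id = config$patch_id, sex = config$sex,
    elevation_deg = config$elevation_deg,
    azimuth_deg = config$azimuth_deg,
    config_hash = hash, seed = config$seed
  )
  log <- list()

  field_true <- generateSigmaField(config$rows, config$cols,
    p_align = config$p_align, jitter_sd = config$jitter_sd,
    mixture = config$mixture, seed = config$seed, metadata = meta)
  log$simulate <- sum(isMeasured(field_true))

  stack <- renderEyeshineStack(field_true, thetas = config$thetas,
    optics = config$optics, seed = config$seed + 1L)
  log$render <- length(rollAngles(stack))

  grid <- roiGridForStack(stack, config$roi_radius)
  series <- extractIntensitySeries(stack, grid, config$channel)
  log$extract <- nrow(series)

  est <- estimatePatch(series, qc_threshold = config$qc_threshold,
    metadata = meta)
  log$estimate <- sum(est$estimates$qc_pass)

  metrics <- patchMetrics(est$field, ed_tol = config$ed_tol,
    min_len = config$min_len, pd_threshold = config$pd_threshold)
  log$classify <- metrics$n_interior

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    writeSigmaField(field_true,
      file.path(outdir, "sigma_true.csv"), config$patch_id)
    writeSigmaField(est$field,
      file.path(outdir, "sigma_estimated.csv"), config$patch_id)
    writeIntensitySeries(series,
      file.path(outdir, "series.csv"), config$patch_id)
    writeMetricsJSON(metrics, file.path(outdir, "metrics.json"),
      metadata = meta)
  }

  list(
    field_true = field_true, stack = stack, series = series,
    estimates = est$estimates, field = est$field, metrics = metrics,
    config = config, config_hash = hash, seed = config$seed, log = log
  )
}
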