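#' Default run configuration
#'
#' The full, serialisable configuration: the model parameter set
#' ([default_params()]), the protocol defaults ([protocol()]) and the
#' analysis settings (spark thresholds, analysis window). Published defaults:
#' k24 = 8 s^-1 uM^-1, CaM_T = 24 uM, k_on = 30, k_off = 71.4, spark
#' thresholds 25/5 uM, beta scalings 1.2/1.3, 49 RyR2 and 7 LCC per CRU,
#' non-junctional DHPR fraction 0.15, record fraction 0.10.
#'
#' @param variant Variant specification for the embedded parameter set.
#' @return A `crusim_config` nested list with components `params`, `protocol`
#'   and `analysis`.
#' @export
default_config <- function(variant = "WT") {
  cfg <- list(
    params = unclass(default_params(variant = variant)),
    protocol = unclass(protocol()),
    analysis = list(spark_start_thresh = 25, spark_end_thresh = 5,
                    spark_window_s = 1, apd_fractions = c(0.5, 0.8, 0.9))
  )
  cfg$protocol$clamp <- NULL
  class(cfg) <- "crusim_config"
  cfg
}

merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    key <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base)) {
      stop("config: unknown key '", key, "'")
    }
    if (is.list(base[[nm]]) && !is.null(names(base[[nm]]))) {
      if (!is.list(over[[nm]])) stop("config: '", key, "' must be a mapping")
      base[[nm]] <- merge_config(base[[nm]], over[[nm]], key)
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Load a run configuration from a YAML file
#'
#' Reads a (possibly partial) YAML configuration, validates every key against
#' the schema of [default_config()] (unknown keys are rejected with the
#' offending key path) and fills unspecified values with the defaults. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a YAML file.
#' @return A `crusim_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  over <- yaml::read_yaml(path)
  cfg <- default_config()
  if (is.null(over)) return(cfg)
  if (!is.list(over)) stop("load_config: top level must be a mapping")
  out <- merge_config(unclass(cfg), over)
  class(out) <- "crusim_config"
  validate_config(out)
  out
}

#' Write a configuration to YAML
#' @param cfg A `crusim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "crusim_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

validate_config <- function(cfg) {
  p <- cfg$params
  stopifnot(p$variant$cdi_factor > 0, p$variant$cdi_factor <= 1,
            p$lcc$k24_base > 0, p$cam$cam_total > 0,
            cfg$analysis$spark_start_thresh > cfg$analysis$spark_end_thresh)
  invisible(cfg)
}

#' Build protocol and parameters from a configuration
#' @param cfg A `crusim_config`.
#' @return List with `params` (`crusim_params`) and `protocol`
#'   (`crusim_protocol`).
#' @export
realize_config <- function(cfg) {
  stopifnot(inherits(cfg, "crusim_config"))
  pars <- cfg$params
  class(pars) <- "crusim_params"
  pr <- cfg$protocol
  prot <- protocol(pacing_hz = pr$pacing_hz, duration = pr$duration,
                   n_cru = pr$n_cru, beta_adrenergic = pr$beta_adrenergic,
                   lcc_scale = pr$lcc_scale, serca_scale = pr$serca_scale,
                   stim_amplitude = pr$stim_amplitude,
                   stim_width = pr$stim_width, stim_start = pr$stim_start,
                   seed = pr$seed, record_fraction = pr$record_fraction,
                   out_dt = pr$out_dt)
  list(params = pars, protocol = prot)
}

#' Write a run manifest
#'
#' JSON snapshot sufficient to reproduce a run bit-exactly: the
#' configuration, the seed(s), the package version, a timestamp, and md5
#' checksums of the outputs.
#'
#' @param path Manifest path (.json).
#' @param config Configuration (any serialisable list).
#' @param seed Seed or seed vector.
#' @param outputs Character vector of output file paths to checksum.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config, seed, outputs = character(0)) {
  ex <- outputs[file.exists(outputs)]
  man <- list(
    package = "crusim",
    version = as.character(utils::packageVersion("crusim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    outputs = if (length(ex)) {
      data.frame(file = basename(ex), md5 = unname(tools::md5sum(ex)))
    } else NULL)
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write the whole-cell time series of a run as CSV
#' @param ts A `crusim_ts`.
#' @param path Output CSV path.
#' @param manifest Also write `<path>.manifest.json`.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path, manifest = TRUE) {
  stopifnot(inherits(ts, "crusim_ts"))
  utils::write.csv(ts$data, path, row.names = FALSE)
  if (manifest) {
    write_manifest(paste0(path, ".manifest.json"),
                   config = list(protocol = unclass(ts$protocol),
                                 params = unclass(ts$params)),
                   seed = ts$seed, outputs = path)
  }
  invisible(path)
}

#' Deterministic miniature fixtures
#'
#' Builds the inputs (parameters + protocol) for one of the bundled presets
#' and, for the quick presets, a cached summary of a deterministic preview
#' run for regression testing: regenerating a fixture with the same seed
#' reproduces the cached summary bit-exactly.
#'
#' @param preset One of `"single-cru"` (1 CRU, 2 s), `"desk-small"`
#'   (200 CRUs, 10 s), `"desk-standard"` (800 CRUs, 10 s).
#' @param seed Integer seed.
#' @param run_preview Run the preview simulation (default TRUE for
#'   `"single-cru"`, FALSE otherwise).
#' @return List with `params`, `protocol`, and (when previewed) `preview`
#'   (final state + spark count of a short run).
#' @export
make_fixture <- function(preset = "single-cru", seed = 1,
                         run_preview = preset == "single-cru") {
  spec <- switch(preset,
    `single-cru` = list(n_cru = 1, duration = 2),
    `desk-small` = list(n_cru = 200, duration = 10),
    `desk-standard` = list(n_cru = 800, duration = 10),
    stop("make_fixture: unknown preset: ", preset))
  pars <- default_params()
  prot <- protocol(pacing_hz = 1, duration = spec$duration,
                   n_cru = spec$n_cru, seed = seed, record_fraction = 1)
  out <- list(preset = preset, params = pars, protocol = prot)
  if (run_preview) {
    pv_prot <- protocol(pacing_hz = 1, duration = min(spec$duration, 1),
                        n_cru = spec$n_cru, seed = seed, record_fraction = 1)
    ts <- simulate(pv_prot, pars)
    ev <- detect_sparks_ts(ts, from = 0)
    out$preview <- list(final = ts$final, n_sparks = nrow(ev),
                        n_steps = ts$stats$n_steps)
  }
  out
}
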