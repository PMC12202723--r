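#' Default run configuration
#'
#' The structured configuration driving the simulation pipelines: grid
#' specification, flow ensemble, simulation settings, constraints, named
#' protocol presets and output options. All fields carry units in their
#' names. `reduced = TRUE` selects the small ensemble used for quick runs.
#'
#' @return a named list (class `pcasl_config`)
#' @export
default_config <- function() {
  structure(list(
    grid = list(
      tr_pcasl_us = c(500, 600, 700, 800, 1060),
      b1_ave_uT = c(0.1, 2.0, 0.1),     # min, max, step
      g_max_mT_m = c(3.0, 15.0, 0.5),
      g_ave_mT_m = c(0.0, 2.0, 0.1),
      rf_duty = 0.5),
    ensemble = list(
      n_streamlines = 50,
      n_shifts = 10),
    simulation = list(
      dt_us = 10,
      t1_s = 2.1,
      t2_s = 0.06,
      db0_values_hz = seq(-50, 50, by = 10)),
    constraints = list(
      max_grad_mT_m = 80,
      max_slew_T_m_s = 200,
      static_threshold = 0.001,
      exclusion_distance_cm = 1.8),
    protocols = lapply(pcasl_protocols(), function(p)
      list(b1_ave_uT = p$params$b1_ave, t_rf_us = p$params$t_rf,
           tr_pcasl_us = p$params$tr_pcasl, g_max_mT_m = p$params$g_max,
           g_ave_mT_m = p$params$g_ave, verse = p$verse)),
    output = list(dir = "results"),
    reduced = FALSE
  ), class = "pcasl_config")
}

validate_config <- function(cfg, path = "config") {
  ref <- unclass(default_config())
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config field: ", path, "$", unknown[1])
  extra <- list(ensemble = "waveform_file")   # optional fields, no default
  for (nm in intersect(names(cfg), c("grid", "ensemble", "simulation",
                                     "constraints", "output"))) {
    bad <- setdiff(names(cfg[[nm]]), c(names(ref[[nm]]), extra[[nm]]))
    if (length(bad))
      stop("unknown config field: ", path, "$", nm, "$", bad[1])
  }
  num_pos <- list(c("simulation", "dt_us"), c("simulation", "t1_s"),
                  c("simulation", "t2_s"), c("constraints", "max_grad_mT_m"),
                  c("constraints", "max_slew_T_m_s"))
  for (p in num_pos) {
    v <- cfg[[p[1]]][[p[2]]]
    if (!is.null(v) && (!is.numeric(v) || any(v <= 0)))
      stop("invalid value for ", path, "$", p[1], "$", p[2],
           ": must be a positive number")
  }
  if (!is.null(cfg$grid$tr_pcasl_us) &&
      (!is.numeric(cfg$grid$tr_pcasl_us) || any(cfg$grid$tr_pcasl_us <= 0)))
    stop("invalid value for ", path, "$grid$tr_pcasl_us",
         ": must be positive durations in us")
  if (!is.null(cfg$ensemble$n_streamlines) &&
      cfg$ensemble$n_streamlines < 1)
    stop("invalid value for ", path, "$ensemble$n_streamlines")
  invisible(TRUE)
}

#' Load a run configuration
#'
#' Reads a YAML configuration, validates it (unknown keys and invalid
#' values are rejected with the offending field path) and fills defaults.
#'
#' @param path YAML file path
#' @return a validated `pcasl_config`
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  validate_config(cfg)
  out <- modifyList(unclass(default_config()), cfg)
  class(out) <- "pcasl_config"
  out
}

#' Write a configuration to YAML
#'
#' @param config a `pcasl_config`
#' @param path output path
#' @return invisibly, `path`
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Grid specification from a configuration
#'
#' @param config a `pcasl_config`
#' @return a [grid_spec()]
#' @export
config_grid_spec <- function(config) {
  r <- function(v) seq(v[1], v[2], by = v[3])
  grid_spec(tr_pcasl = config$grid$tr_pcasl_us,
            b1_ave = r(config$grid$b1_ave_uT),
            g_max = r(config$grid$g_max_mT_m),
            g_ave = r(config$grid$g_ave_mT_m),
            rf_duty = config$grid$rf_duty)
}

#' Write tabular results with a manifest
#'
#' Writes each element of `results` (data frames) as a CSV under `out_dir`
#' with deterministic names, and a `manifest.csv` listing every artifact
#' with its MD5 content hash and row count.
#'
#' @param results named list of data.frames
#' @param out_dir output directory (created if needed)
#' @return the manifest data.frame, invisibly
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0); hashes <- character(0); rows <- integer(0)
  for (nm in names(results)) {
    f <- file.path(out_dir, paste0(nm, ".csv"))
    write.csv(results[[nm]], f, row.names = FALSE)
    files <- c(files, basename(f))
    hashes <- c(hashes, unname(tools::md5sum(f)))
    rows <- c(rows, nrow(results[[nm]]))
  }
  manifest <- data.frame(file = files, md5 = hashes, rows = rows)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
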