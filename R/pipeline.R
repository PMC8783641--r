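# Configuration and the end-to-end pipeline binding the stages together:
# simulate/load -> preprocess -> immobility/theta epochs -> event detection
# -> spectra -> coupling -> session report.

#' Pipeline configuration
#'
#' Builds a validated configuration from a YAML file and/or overrides.
#' Recognized sections: `input` (path, target_rate_hz, exclude_channels,
#' channel_pyr, channel_rad), `simulate` (any [synth_config()] field),
#' `detection` (any [detection_params()] field), `spectral`
#' (ratio_threshold, speed_threshold_cm_s, min_epoch_s, bank_n,
#' bank_range_hz), `coupling` (n_bins, profile_bins, signal = "lfp"|"csd"),
#' `seed`. Unknown keys are rejected.
#'
#' @param path optional YAML file.
#' @param overrides named list merged over the file contents.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("no config file at '%s'", path),
                                 call. = FALSE)
    cfg <- yaml::read_yaml(path)
    if (is.null(cfg)) cfg <- list()
  }
  for (nm in names(overrides)) cfg[[nm]] <- overrides[[nm]]
  known <- c("input", "simulate", "detection", "spectral", "coupling", "seed")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop(sprintf("unknown config section(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  defaults <- list(
    input = list(path = NULL, target_rate_hz = NULL,
                 exclude_channels = character(0),
                 channel_pyr = NULL, channel_rad = NULL),
    simulate = NULL,
    detection = list(),
    spectral = list(ratio_threshold = 2, speed_threshold_cm_s = 2,
                    min_epoch_s = 1, bank_n = 100, bank_range_hz = c(2, 100)),
    coupling = list(n_bins = 18, profile_bins = 16, signal = "lfp"),
    seed = 1L)
  for (sec in c("input", "spectral", "coupling")) {
    user <- if (is.null(cfg[[sec]])) list() else cfg[[sec]]
    bad <- setdiff(names(user), names(defaults[[sec]]))
    if (length(bad))
      stop(sprintf("unknown key(s) in config section '%s': %s", sec,
                   paste(bad, collapse = ", ")), call. = FALSE)
    merged <- defaults[[sec]]
    for (nm in names(user)) merged[[nm]] <- user[[nm]]
    cfg[[sec]] <- merged
  }
  if (is.null(cfg$detection)) cfg$detection <- list()
  cfg$detection_params <- do.call(detection_params, cfg$detection)
  if (is.null(cfg$seed)) cfg$seed <- defaults$seed
  if (!is.null(cfg$simulate)) {
    cfg$simulate$seed <- cfg$seed
    cfg$synth <- do.call(synth_config, cfg$simulate)
  }
  structure(cfg, class = "pipeline_config")
}

pick_layer_channel <- function(map, layer, override = NULL) {
  if (!is.null(override)) return(as.character(override))
  hit <- map$channel_id[map$layer == layer]
  if (!length(hit))
    stop(sprintf("no channel labelled '%s' in the probe map (use an override)",
                 layer), call. = FALSE)
  hit[1L]
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, optional preprocessing, immobility and
#' theta-epoch segmentation, event detection, spectral analysis, coupling
#' analysis, and the session summary, writing every artifact (TSV/JSON)
#' plus the resolved configuration snapshot into `out_dir`. Rerunning with
#' the same configuration and seed reproduces identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return the session summary, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "load"
  res <- tryCatch({
    if (!is.null(config$synth)) {
      stage <- "simulate"
      ses <- generate_session(config$synth)
      rec <- ses$recording; map <- ses$map; speed <- ses$speed
      write_events(cbind(ses$ground_truth),
                   file.path(out_dir, "ground_truth.tsv"))
    } else {
      if (is.null(config$input$path))
        stop("config has neither an input path nor a simulate section")
      io <- read_recording(config$input$path)
      rec <- io$recording; map <- io$map; speed <- io$speed
    }

    stage <- "preprocess"
    if (length(config$input$exclude_channels)) {
      ex <- exclude_channels(rec, map, config$input$exclude_channels)
      rec <- ex$recording; map <- ex$map
    }
    if (!is.null(config$input$target_rate_hz) &&
        config$input$target_rate_hz < rec$rate_hz)
      rec <- lowpass_downsample(rec, config$input$target_rate_hz)

    params <- config$detection_params
    ch_pyr <- pick_layer_channel(map, "str_pyramidale", config$input$channel_pyr)
    ch_rad <- pick_layer_channel(map, "str_radiatum", config$input$channel_rad)
    x_pyr <- get_channel(rec, ch_pyr)
    x_rad <- get_channel(rec, ch_rad)

    stage <- "segmentation"
    ratio_at_speed <- theta_delta_ratio(x_pyr, rec$rate_hz,
                                        at_times_s = speed$times_s,
                                        window_s = params$immobility_ratio_window_s,
                                        t_start_s = rec$t_start_s)
    immobility <- find_immobility_periods(speed, ratio_at_speed, params)
    utils::write.table(immobility, file.path(out_dir, "immobility.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    epochs <- detect_theta_epochs(x_pyr, rec$rate_hz, speed,
                                  ratio_threshold = config$spectral$ratio_threshold,
                                  speed_threshold_cm_s = config$spectral$speed_threshold_cm_s,
                                  min_epoch_s = config$spectral$min_epoch_s,
                                  t_start_s = rec$t_start_s)
    utils::write.table(epochs, file.path(out_dir, "theta_epochs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    stage <- "detection"
    ripples <- detect_ripples(x_pyr, rec$rate_hz, immobility, params,
                              rec$t_start_s)
    ripples <- ripple_features(ripples, x_pyr, rec$rate_hz, params,
                               rec$t_start_s)
    spws <- detect_spws(x_rad, rec$rate_hz, immobility, params, rec$t_start_s)
    swrs <- pair_swr(ripples, spws, params)
    bursts <- classify_bursts(swrs, params)
    ev <- rbind(
      if (nrow(swrs)) data.frame(type = "swr", start_s = swrs$start_s,
                                 end_s = swrs$end_s, peak_s = swrs$peak_s,
                                 channel = ch_pyr,
                                 amplitude_sd = swrs$peak_power_sd,
                                 freq_hz = swrs$peak_freq_hz),
      data.frame(type = character(0), start_s = numeric(0),
                 end_s = numeric(0), peak_s = numeric(0),
                 channel = character(0), amplitude_sd = numeric(0),
                 freq_hz = numeric(0)))
    write_events(ev, file.path(out_dir, "events.tsv"))

    stage <- "spectra"
    spectra <- NULL
    if (nrow(epochs)) {
      bank <- make_bank(config$spectral$bank_range_hz[1],
                        config$spectral$bank_range_hz[2],
                        config$spectral$bank_n, 6, rec$rate_hz)
      tf <- wavelet_transform(x_pyr, bank)
      spectra <- relative_power(tf, epochs, rec$t_start_s)
      utils::write.table(spectra, file.path(out_dir, "spectra.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      prof <- laminar_theta_profile(rec, map, epochs, ch_pyr)
      utils::write.table(prof, file.path(out_dir, "laminar_profile.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }

    stage <- "coupling"
    comod <- NULL
    if (nrow(epochs)) {
      cycles <- extract_theta_cycles(x_pyr, rec$rate_hz, epochs,
                                     t_start_s = rec$t_start_s)
      if (nrow(cycles$cycles)) {
        sig <- if (identical(config$coupling$signal, "csd")) {
          csd <- compute_csd(rec, map)
          lm_id <- csd$channel_ids[match("str_LM", csd$layer)]
          if (is.na(lm_id)) csd$values[1L, ] else get_csd_channel(csd, lm_id)
        } else x_pyr
        profile <- gamma_by_theta_phase(sig, rec$rate_hz, cycles,
                                        n_bins = config$coupling$profile_bins)
        ptab <- data.frame(freq_hz = profile$freqs_hz, profile$values)
        names(ptab) <- c("freq_hz", sprintf("bin%02d", seq_len(ncol(profile$values))))
        utils::write.table(ptab, file.path(out_dir, "phase_profile.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        if (any((epochs$end_s - epochs$start_s) > 1.5)) {
          comod <- modulation_index(sig, sig, rec$rate_hz, epochs,
                                    n_bins = config$coupling$n_bins,
                                    t_start_s = rec$t_start_s)
          utils::write.table(comod, file.path(out_dir, "comodulogram.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
    }

    stage <- "report"
    summary <- summarize_session(swrs, bursts, immobility)
    scal <- summary[!vapply(summary, is.list, logical(1))]
    jsonlite::write_json(scal, file.path(out_dir, "session.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    snapshot <- config
    snapshot$detection_params <- unclass(snapshot$detection_params)
    snapshot$synth <- NULL
    jsonlite::write_json(list(config = lapply(unclass(snapshot), unclass),
                              seed = config$seed,
                              version = as.character(utils::packageVersion("lfpkit"))),
                         file.path(out_dir, "config_snapshot.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    summary
  }, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(res)
}
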