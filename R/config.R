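#' Default pipeline run configuration
#'
#' The full parameter sheet of the pipeline, with defaults set to the study
#' conditions (session sizes, filter bands, rejection rules, component
#' settings, spectral windows, staircase schedules, statistics settings).
#' Every stage echoes the configuration it ran with into a JSON sidecar next
#' to its outputs.
#'
#' @return Nested named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    seed = 1,
    ci_side = "right",
    passive = list(n_per_rate = 60, am_rates_hz = c(4, 20, 40),
                   tone_dur_s = 2, isi_range_s = c(0.5, 1.5), max_run = 3),
    attention = list(n_blocks = 6, trials_per_block = 50,
                     cue_front_per_block = 25, cue_side_per_block = 25,
                     cue_dur_s = 0.5, anticipation_range_s = c(1.0, 1.8),
                     number_dur_s = 0.5),
    neural = list(fs_hz = 1000, assr_amp_per_rate = c(`4` = 1.5, `20` = 0.8,
                                                      `40` = 1.0),
                  onset_amp = 15, ci_artifact_amp = 150, ci_topo_width = 0.4,
                  alpha_base_power = 10, alpha_lateralization = 0.2,
                  alpha_asymmetry = 1.5, noise_1f_amp = 5,
                  blink_rate_hz = 0.1, phase_jitter_sd = 0),
    filters = list(passive = c(0.1, 100), attention = c(1, 100)),
    epochs = list(passive_window_s = c(-0.5, 2.5),
                  attention_window_s = c(-1, 4)),
    rejection = list(range_limit = 300, range_window_s = c(0, 2),
                     percentile_fraction = 0.10),
    ica = list(var_target = 0.90, method = "logcosh", seed = 1),
    classifier = list(onset_ratio = 3, ci_latency_s = 0.035,
                      ci_concentration = 0.20, fc_concentration = 0.22,
                      frontal_concentration = 0.45, brain_slope = -0.5),
    spectral = list(assr_window_s = c(0.5, 2), assr_freqs_hz = c(1, 60),
                    attention_window_s = c(0.75, 1.5),
                    attention_freqs_hz = c(1, 30), smoothing_hz = 2,
                    alpha_band_hz = c(7, 13)),
    staircase = list(amrd = list(start_level = 2.0, step_initial = 0.5,
                                 step_final = 0.25,
                                 reversals_step_change = 4,
                                 reversals_stop = 10,
                                 threshold_reversals = 6,
                                 observer_threshold = 1.0,
                                 observer_slope = 8, n_runs = 100),
                     srt = list(start_snr_db = 10, step_db = 2,
                                observer_threshold = -2,
                                observer_slope = 0.5, n_sessions = 20)),
    stats = list(n_permutations = 10000, p_method = "proportion")
  ), class = "run_config")
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, overlays it on [default_config()], and
#' rejects keys that the pipeline does not know (a misspelled parameter must
#' fail loudly, not be silently ignored).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  check_keys <- function(user, ref, prefix = "") {
    extra <- setdiff(names(user), names(ref))
    if (length(extra) > 0) {
      stop("unknown configuration key(s): ",
           paste0(prefix, extra, collapse = ", "))
    }
    for (k in names(user)) {
      if (is.list(ref[[k]]) && is.list(user[[k]]) &&
          !is.null(names(ref[[k]]))) {
        check_keys(user[[k]], ref[[k]], paste0(prefix, k, "."))
      }
    }
  }
  check_keys(user, cfg)
  merged <- utils::modifyList(cfg, user)
  class(merged) <- "run_config"
  merged
}

#' Provenance sidecar
#'
#' Writes `<stem>.provenance.json` next to a stage output: configuration
#' echo and hash, seed, stage name and package version.
#'
#' @param stage Stage name.
#' @param config The `run_config` used.
#' @param seed Seed used.
#' @param out_path Output file or directory the sidecar describes.
#' @return Sidecar path, invisibly.
#' @export
write_sidecar <- function(stage, config, seed, out_path) {
  tmp <- tempfile()
  yaml::write_yaml(unclass(config), tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  sidecar <- paste0(sub("/$", "", out_path), ".provenance.json")
  jsonlite::write_json(
    list(stage = stage, seed = seed, config_md5 = hash,
         package_version = as.character(utils::packageVersion("cilisten")),
         config = unclass(config)),
    sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sidecar)
}
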