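# Orchestration: structured run configuration, the two experiments
# (simulated phantom run; synthetic static/dynamic recordings), the analysis
# chain, and JSON reports.

#' Default run configuration
#'
#' Reads the configuration shipped with the package, which carries the
#' reference values of every model parameter (dynamics, diffusion
#' coefficients, stimulation protocol, morphology/noise presets and the two
#' filter arms).
#'
#' @return Nested configuration list.
#' @export
default_run_config <- function() {
  yaml::read_yaml(system.file("extdata", "default_config.yaml",
                              package = "uniecg", mustWork = TRUE))
}

# recursively check `cfg` against the default structure; unknown keys error
check_config_keys <- function(cfg, ref, path = "") {
  for (nm in names(cfg)) {
    here <- paste0(path, nm)
    if (!nm %in% names(ref))
      stop("unknown configuration key: ", here)
    if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
        !is.null(names(ref[[nm]])))
      check_config_keys(cfg[[nm]], ref[[nm]], paste0(here, "."))
  }
  invisible(TRUE)
}

# deep merge of `cfg` over `ref`
merge_config <- function(ref, cfg) {
  for (nm in names(cfg)) {
    ref[[nm]] <- if (is.list(cfg[[nm]]) && is.list(ref[[nm]]) &&
                     !is.null(names(ref[[nm]])))
      merge_config(ref[[nm]], cfg[[nm]]) else cfg[[nm]]
  }
  ref
}

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys, and merges it over the
#' package defaults.
#'
#' @param path Path to a YAML file, or `NULL` for the defaults.
#' @return Validated configuration list.
#' @export
load_run_config <- function(path = NULL) {
  ref <- default_run_config()
  if (is.null(path)) return(ref)
  cfg <- yaml::read_yaml(path)
  check_config_keys(cfg, ref)
  merge_config(ref, cfg)
}

# constructors from a configuration
config_params <- function(config) {
  p <- config$params
  dynamic_params(alpha = p$alpha, beta = p$beta, gamma = p$gamma,
                 delta = p$delta, theta = p$theta,
                 epsilon = unlist(p$epsilon),
                 diffusion = unlist(p$diffusion))
}

config_phantom <- function(config) {
  ph <- config$phantom
  build_phantom(phantom_config(
    rows = ph$rows, cols = ph$cols,
    include_electrode_layer = ph$include_electrode_layer,
    heart = ph$heart, params = config_params(config)))
}

config_protocol <- function(config) {
  s <- config$stimulus
  stimulus_protocol(target = s$target, period = s$period,
                    amplitude = s$amplitude, pulse_width = s$pulse_width,
                    start = s$start)
}

config_filter_spec <- function(config, arm = c("standard", "modified")) {
  arm <- match.arg(arm)
  f <- config$filters[[arm]]
  filter_chain_spec(highpass_cutoff_hz = f$highpass_cutoff_hz,
                    notch_freqs_hz = unlist(f$notch_freqs_hz),
                    lowpass_cutoff_hz = f$lowpass_cutoff_hz,
                    hp_order = f$hp_order, lp_order = f$lp_order,
                    notch_q = f$notch_q)
}

#' Run the phantom simulation experiment
#'
#' Builds the phantom from the configuration, runs the simulation, and
#' (optionally) writes the conventional-lead and single-position traces as
#' CSV plus an activation-time JSON sidecar. Step counts and the stability
#' bound are logged to stderr.
#'
#' @param config Configuration list (see [load_run_config()]).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return List with the `field_recording` and the extracted
#'   [ecg_signal()]s (`conventional`, and `single` when the phantom has an
#'   electrode layer).
#' @export
run_simulation_experiment <- function(config = default_run_config(),
                                      out_dir = NULL) {
  phantom <- config_phantom(config)
  protocol <- config_protocol(config)
  sim <- config$simulation
  message(sprintf("phantom %dx%d, stability bound %.4g time units",
                  nrow(phantom$labels), ncol(phantom$labels),
                  stability_bound(phantom)))
  rec <- run_simulation(phantom, protocol,
                        duration_s = sim$duration_s, fs = sim$fs,
                        seconds_per_cycle = sim$seconds_per_cycle)
  message(sprintf("recorded %d frames over %.3g s of mapped time",
                  length(rec$times), max(rec$times)))
  out <- list(recording = rec,
              conventional = extract_conventional_lead(rec))
  if (config$phantom$include_electrode_layer)
    out$single <- extract_single_position(rec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal(out$conventional, file.path(out_dir, "conventional_lead.csv"))
    if (!is.null(out$single))
      write_signal(out$single, file.path(out_dir, "single_position.csv"))
    jsonlite::write_json(as.list(rec$activation_times),
                         file.path(out_dir, "activation_times.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Generate the static paired recording of the control experiment
#'
#' One RR sequence drives both channels; the experimental channel carries
#' the single-position wave morphology and the control channel the
#' conventional PQRST morphology, each with its configured noise preset.
#'
#' @param config Configuration list.
#' @param seed Integer seed (default: the configured seed).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A `paired_recording`.
#' @export
synthesize_static_pair <- function(config = default_run_config(),
                                   seed = config$seed, out_dir = NULL) {
  sy <- config$synthesis
  n_beats <- ceiling(sy$static_duration_s / 0.2) # covers any truncated draw
  rr <- generate_rr_sequence(sy$mean_bpm, sy$sdnn_s, n_beats, seed = seed)
  pair <- make_paired_recording(
    rr, fs = sy$fs,
    exp_preset = noise_preset(sy$experimental_preset),
    ctrl_preset = noise_preset(sy$control_preset),
    seed = seed, duration_s = sy$static_duration_s)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal(pair$experimental, file.path(out_dir, "experimental.csv"))
    write_signal(pair$control, file.path(out_dir, "control.csv"))
  }
  pair
}

#' Generate the dynamic four-posture recording
#'
#' @param config Configuration list.
#' @param seed Integer seed (default: the configured seed).
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return A noisy [ecg_signal()] (see [synthesize_dynamic_recording()]).
#' @export
synthesize_dynamic <- function(config = default_run_config(),
                               seed = config$seed, out_dir = NULL) {
  sy <- config$synthesis
  dur <- 4 * sy$dynamic_segment_s
  n_beats <- ceiling(dur / 0.2)
  rr <- generate_rr_sequence(sy$mean_bpm, sy$sdnn_s, n_beats, seed = seed)
  dyn <- synthesize_dynamic_recording(rr, fs = sy$fs, seed = seed,
                                      segment_s = sy$dynamic_segment_s)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_signal(dyn, file.path(out_dir, "dynamic_experimental.csv"))
  }
  dyn
}

#' Full analysis of a paired recording
#'
#' Filters each channel with its arm's chain, detects beats, builds the
#' heart-rate curves, and reports their Pearson correlation, the extremum
#' deviations, the estimated SNR and the unrecognizable fraction per
#' channel.
#'
#' @param experimental,control [ecg_signal()]s sharing a sampling rate.
#' @param exp_spec,ctrl_spec [filter_chain_spec()]s for the two channels.
#' @return A `comparison_report` list.
#' @export
analyze_pair <- function(experimental, control,
                         exp_spec = filter_chain_spec(highpass_cutoff_hz = 0.5),
                         ctrl_spec = exp_spec) {
  fs <- 1 / experimental$T
  if (abs(fs - 1 / control$T) > 1e-9)
    stop("the two channels must share a sampling rate")
  fe <- apply_filter_chain(design_filter_chain(exp_spec, fs), experimental)
  fc <- apply_filter_chain(design_filter_chain(ctrl_spec, fs), control)
  te <- detect_beats(fe)
  tc <- detect_beats(fc)
  he <- compute_heart_rate_curve(te)
  hc <- compute_heart_rate_curve(tc)
  dev <- extremum_deviation(he, hc)
  structure(list(
    pearson_r = correlate_heart_rate(he, hc),
    max_hr_deviation_bpm = unname(dev["max_dev_bpm"]),
    min_hr_deviation_bpm = unname(dev["min_dev_bpm"]),
    snr_db = list(experimental = estimate_snr(fe, te),
                  control = estimate_snr(fc, tc)),
    unrecognizable_fraction = list(
      experimental = unrecognizable_fraction(fe),
      control = unrecognizable_fraction(fc)),
    beats = list(experimental = length(te$peak_times),
                 control = length(tc$peak_times)),
    filter_arms = list(
      experimental = exp_spec$highpass_cutoff_hz,
      control = ctrl_spec$highpass_cutoff_hz)),
    class = "comparison_report")
}

#' Bundle comparison reports with provenance
#'
#' @param reports Named list of `comparison_report`s.
#' @param config The configuration used.
#' @param seed The seed used.
#' @return An `evaluation_report` serializable with [write_report()].
#' @export
evaluation_report <- function(reports, config, seed) {
  tmp <- tempfile(fileext = ".yaml")
  yaml::write_yaml(config, tmp)
  hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  structure(list(
    reports = reports,
    provenance = list(
      config_md5 = hash, seed = seed,
      package_version = as.character(utils::packageVersion("uniecg")))),
    class = "evaluation_report")
}

#' Write a report as JSON
#' @param report An `evaluation_report` or `comparison_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Read a report back from JSON
#' @param path Input path.
#' @return The report list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
}
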