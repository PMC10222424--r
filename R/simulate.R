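#' Stimulation protocol for the sinoatrial node
#'
#' The sinoatrial node is driven by a periodic suprathreshold current pulse
#' (the reference parameter set is not self-oscillatory). One stimulus
#' period is mapped onto one cardiac cycle when the simulation is run, so
#' the default mapping of 0.8 s per cycle corresponds to 75 beats per
#' minute, inside the normal sinus range of 60-100.
#'
#' @param target Region receiving the stimulus (default sinoatrial node).
#' @param period Time between stimuli, in simulation time units.
#' @param amplitude Stimulus current density (dimensionless); 0 disables
#'   stimulation.
#' @param pulse_width Pulse duration in time units; must be below `period`.
#' @param start Time of the first pulse.
#' @return A `stimulus_protocol`.
#' @export
stimulus_protocol <- function(target = "sinoatrial_node", period = 1000,
                              amplitude = 0.5, pulse_width = 5, start = 20) {
  region_id(target)
  if (period <= 0) stop("stimulus period must be positive")
  if (amplitude < 0) stop("stimulus amplitude must be non-negative")
  if (pulse_width >= period) stop("pulse width must be shorter than the period")
  structure(list(target = target, period = period, amplitude = amplitude,
                 pulse_width = pulse_width, start = start),
            class = "stimulus_protocol")
}

#' Resting field state for a phantom
#'
#' @param phantom A `tissue_phantom`.
#' @param t Simulation time attached to the state.
#' @return A `field_state` with `u1 = u2 = 0` everywhere.
#' @export
field_state <- function(phantom, t = 0) {
  z <- matrix(0, nrow(phantom$labels), ncol(phantom$labels))
  structure(list(u1 = z, u2 = z, t = t), class = "field_state")
}

#' Explicit stability bound of the diffusion step
#'
#' For the 5-point Laplacian with explicit Euler time stepping in two
#' dimensions the step must satisfy `dt <= h^2 / (4 * Dmax)`, with `Dmax`
#' the largest diffusion coefficient present on the grid.
#'
#' @param phantom A `tissue_phantom`.
#' @return The bound, in simulation time units.
#' @export
stability_bound <- function(phantom) {
  present <- region_names()[sort(unique(as.vector(phantom$labels)))]
  Dmax <- max(phantom$params$diffusion_by_region[present])
  phantom$spacing^2 / (4 * Dmax)
}

# per-cell model fields derived from the labels
phantom_fields <- function(phantom) {
  lab <- phantom$labels
  p <- phantom$params
  nr <- nrow(lab); nc <- ncol(lab)
  D <- matrix(p$diffusion_by_region[region_names()][lab], nr, nc)
  eps <- matrix(p$epsilon_by_region[region_names()][lab], nr, nc)
  th <- matrix(p$theta_by_region[region_names()][lab], nr, nc)
  act <- matrix(as.integer(lab <= 7L), nr, nc)
  hmean <- function(a, b) ifelse(a > 0 & b > 0, 2 * a * b / (a + b), 0)
  list(D = D, eps = eps, theta = th, active = act,
       Gr = hmean(D[, -nc, drop = FALSE], D[, -1, drop = FALSE]),
       Gd = hmean(D[-nr, , drop = FALSE], D[-1, , drop = FALSE]))
}

null_protocol <- list(amplitude = 0, start = 0, period = 1, pulse_width = 0)

#' Advance the field by one explicit time step
#'
#' One step of the scheme: diffusion by the 5-point Laplacian with
#' harmonic-mean face diffusivities (zero-flux at the outer boundary and at
#' non-conducting faces), plus the reaction sources of [reaction_term()] in
#' active cells. Deterministic.
#'
#' @param state A `field_state`.
#' @param phantom A `tissue_phantom`.
#' @param dt Time step; must satisfy [stability_bound()].
#' @param protocol Optional `stimulus_protocol` applied during the step.
#' @return The advanced `field_state`.
#' @export
step_field <- function(state, phantom, dt, protocol = NULL) {
  bound <- stability_bound(phantom)
  if (dt > bound)
    stop(sprintf(
      "dt = %g violates the explicit stability bound h^2/(4 Dmax) = %g",
      dt, bound))
  f <- phantom_fields(phantom)
  pr <- if (is.null(protocol)) null_protocol else protocol
  stim_idx <- if (pr$amplitude > 0)
    which(phantom$labels == region_id(pr$target)) - 1L else integer(0)
  out <- fhn_run_cpp(state$u1, state$u2, f$Gr, f$Gd, f$eps, f$active,
                     f$theta, phantom$labels,
                     phantom$params$alpha, phantom$params$beta,
                     phantom$params$gamma, phantom$params$delta,
                     phantom$spacing, dt, state$t, 1L, 0L,
                     stim_idx, pr$amplitude, pr$start, pr$period,
                     pr$pulse_width, integer(0), 12L, integer(0),
                     matrix(0, 0, 0))
  structure(list(u1 = out$u1, u2 = out$u2, t = out$t), class = "field_state")
}

# advance a state by `nsteps` steps without recording (internal)
advance_field <- function(state, phantom, dt, nsteps, protocol = NULL) {
  bound <- stability_bound(phantom)
  if (dt > bound)
    stop(sprintf(
      "dt = %g violates the explicit stability bound h^2/(4 Dmax) = %g",
      dt, bound))
  f <- phantom_fields(phantom)
  pr <- if (is.null(protocol)) null_protocol else protocol
  stim_idx <- if (pr$amplitude > 0)
    which(phantom$labels == region_id(pr$target)) - 1L else integer(0)
  out <- fhn_run_cpp(state$u1, state$u2, f$Gr, f$Gd, f$eps, f$active,
                     f$theta, phantom$labels,
                     phantom$params$alpha, phantom$params$beta,
                     phantom$params$gamma, phantom$params$delta,
                     phantom$spacing, dt, state$t, as.integer(nsteps), 0L,
                     stim_idx, pr$amplitude, pr$start, pr$period,
                     pr$pulse_width, integer(0), 12L, integer(0),
                     matrix(0, 0, 0))
  structure(list(u1 = out$u1, u2 = out$u2, t = out$t), class = "field_state")
}

# interpolated first upward crossing of `thr` in a sampled series
first_crossing <- function(times, values, thr = 0.5) {
  n <- length(values)
  i <- which(values[-1] >= thr & values[-n] < thr)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  times[i] + (thr - values[i]) / (values[i + 1] - values[i]) *
    (times[i + 1] - times[i])
}

# number of upward crossings of `thr`
count_crossings <- function(values, thr = 0.5) {
  n <- length(values)
  sum(values[-1] >= thr & values[-n] < thr)
}

#' Run the phantom simulation and record surface traces
#'
#' Integrates the reaction-diffusion model under periodic sinoatrial
#' stimulation and records, at the output sampling rate: the lead-field
#' projection of the cardiac impressed current at each point of every
#' conventional probe pair (the quasi-static volume-conductor potential a
#' distant differential amplifier sees), the raw diffused trace at every
#' single-position probe (the accumulated induced signal a charge sensor
#' sees at its contact), and the mean and maximum of `u1` over every
#' region. One stimulus period is mapped onto `seconds_per_cycle` seconds
#' of output time.
#'
#' @param phantom A `tissue_phantom`.
#' @param protocol A [stimulus_protocol()].
#' @param probes List of [probe_spec()]s; default [default_probes()].
#' @param duration_s Output duration in mapped seconds; must cover at least
#'   two stimulus periods.
#' @param fs Output sampling rate in Hz (default 500).
#' @param seconds_per_cycle Mapped seconds per stimulus period (default
#'   0.8 s, i.e. 75 beats per minute).
#' @param dt Time step in simulation units; by default the largest step
#'   that divides the recording interval and respects 90% of
#'   [stability_bound()].
#' @return A `field_recording` with elements `times` (seconds), `traces`
#'   (named list: `<name>.det` / `<name>.ref` for pairs, `<name>` for
#'   single-position probes), `activation_times` (mapped seconds per
#'   region), `region_means`, `region_max`, `fs`, `time_scale`,
#'   `stimulus_count` and `propagation_failure`.
#' @export
run_simulation <- function(phantom, protocol = stimulus_protocol(),
                           probes = default_probes(phantom),
                           duration_s = 2, fs = 500,
                           seconds_per_cycle = 0.8, dt = NULL) {
  lab <- phantom$labels
  nr <- nrow(lab); nc <- ncol(lab)
  time_scale <- seconds_per_cycle / protocol$period     # seconds per time unit
  duration_tu <- duration_s / time_scale
  if (duration_tu < 2 * protocol$period)
    stop("duration must cover at least two stimulus periods")
  rec_tu <- (1 / fs) / time_scale
  if (is.null(dt)) {
    dtmax <- 0.9 * stability_bound(phantom)
    dt <- rec_tu / ceiling(rec_tu / dtmax)
  } else if (dt > stability_bound(phantom)) {
    stop(sprintf("dt = %g violates the explicit stability bound h^2/(4 Dmax) = %g",
                 dt, stability_bound(phantom)))
  }
  record_every <- max(1L, round(rec_tu / dt))
  nrec <- floor(duration_tu / (record_every * dt))
  nsteps <- nrec * record_every

  cell_of <- function(pt) (pt[1]) + (pt[2] - 1L) * nr
  # validate probes and collect recording targets
  phi_cols <- character(0); phi_pts <- list()
  u1_cols <- character(0); u1_pts <- integer(0)
  for (p in probes) {
    if (!inherits(p, "probe_spec")) stop("probes must be probe_spec objects")
    if (p$kind == "conventional_pair") {
      for (pt in list(p$point_a, p$point_b)) {
        if (lab[pt[1], pt[2]] != region_id("torso"))
          stop("conventional probe points must lie on torso tissue (probe '",
               p$name, "')")
      }
      phi_cols <- c(phi_cols, paste0(p$name, c(".det", ".ref")))
      phi_pts <- c(phi_pts, list(p$point_a, p$point_b))
    } else {
      if (!any(lab == region_id("electrode_layer")))
        stop("single-position probe '", p$name,
             "' requires a phantom with an electrode layer")
      if (lab[p$point_a[1], p$point_a[2]] != region_id("electrode_layer"))
        stop("single-position probe '", p$name,
             "' must sit on the electrode layer")
      u1_cols <- c(u1_cols, p$name)
      u1_pts <- c(u1_pts, cell_of(p$point_a) - 1L)
    }
  }
  f <- phantom_fields(phantom)
  card <- which(f$active == 1L)
  W <- matrix(0, length(card), length(phi_pts))
  if (length(phi_pts)) {
    cr <- (card - 1L) %% nr + 1L
    cc <- (card - 1L) %/% nr + 1L
    hsp <- phantom$spacing
    for (q in seq_along(phi_pts)) {
      pt <- phi_pts[[q]]
      r <- sqrt(((cr - pt[1]) * hsp)^2 + ((cc - pt[2]) * hsp)^2)
      # 2-D volume-conductor kernel, regularised at one cell
      W[, q] <- -log(pmax(r, hsp) / (max(nr, nc) * hsp)) / (2 * pi)
    }
  }
  stim_idx <- if (protocol$amplitude > 0)
    which(lab == region_id(protocol$target)) - 1L else integer(0)
  out <- fhn_run_cpp(matrix(0, nr, nc), matrix(0, nr, nc), f$Gr, f$Gd,
                     f$eps, f$active, f$theta, lab,
                     phantom$params$alpha, phantom$params$beta,
                     phantom$params$gamma, phantom$params$delta,
                     phantom$spacing, dt, 0, nsteps, record_every,
                     stim_idx, protocol$amplitude, protocol$start,
                     protocol$period, protocol$pulse_width,
                     u1_pts, 12L, card - 1L, W)
  times_tu <- out$times
  colnames(out$region_means) <- region_names()
  colnames(out$region_max) <- region_names()
  traces <- list()
  for (q in seq_along(u1_cols)) traces[[u1_cols[q]]] <- out$probes[, q]
  for (q in seq_along(phi_cols)) traces[[phi_cols[q]]] <- out$probes_phi[, q]
  act_t <- vapply(active_regions(), function(rg)
    first_crossing(times_tu, out$region_means[, rg]) * time_scale,
    numeric(1))
  stim_count <- if (protocol$amplitude > 0)
    length(seq(protocol$start, nsteps * dt, by = protocol$period)) else 0L
  failed <- protocol$amplitude > 0 && is.na(act_t[["ventricles"]])
  if (failed)
    warning("propagation failure: the ventricles never activated")
  structure(
    list(times = times_tu * time_scale, times_tu = times_tu,
         traces = traces, probes = probes,
         activation_times = act_t,
         region_means = out$region_means, region_max = out$region_max,
         fs = fs, time_scale = time_scale,
         stimulus_count = stim_count, propagation_failure = failed,
         final_state = structure(list(u1 = out$u1, u2 = out$u2, t = out$t),
                                 class = "field_state")),
    class = "field_recording")
}

#' Number of beats seen by a region
#'
#' Counts upward crossings of a threshold by the region-mean action
#' potential, e.g. sinoatrial firings or ventricular activations.
#'
#' @param recording A `field_recording`.
#' @param region Region name.
#' @param threshold Crossing level (default 0.5).
#' @return Integer count.
#' @export
count_activations <- function(recording, region = "ventricles",
                              threshold = 0.5) {
  count_crossings(recording$region_means[, region], threshold)
}

#' Extract the conventional differential lead
#'
#' Pointwise difference of the detection and reference traces of a
#' conventional probe pair, mean-removed, packaged as a uniformly sampled
#' ECG signal.
#'
#' @param recording A `field_recording`.
#' @param probe Name of the conventional probe (default `"conventional"`).
#' @return An [ecg_signal()].
#' @export
extract_conventional_lead <- function(recording, probe = "conventional") {
  det <- recording$traces[[paste0(probe, ".det")]]
  ref <- recording$traces[[paste0(probe, ".ref")]]
  if (is.null(det) || is.null(ref))
    stop("no conventional probe named '", probe, "' in the recording")
  x <- det - ref
  ecg_signal(x - mean(x), T = 1 / recording$fs, channel = probe,
             provenance = "simulated")
}

#' Extract the single-position trace
#'
#' The raw single-point trace recorded at the electrode contact (no
#' reference subtraction), mean-removed.
#'
#' @param recording A `field_recording`.
#' @param probe Name of the single-position probe (default `"single"`).
#' @return An [ecg_signal()].
#' @export
extract_single_position <- function(recording, probe = "single") {
  x <- recording$traces[[probe]]
  if (is.null(x))
    stop("no single-position probe named '", probe, "' in the recording")
  ecg_signal(x - mean(x), T = 1 / recording$fs, channel = probe,
             provenance = "simulated")
}
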