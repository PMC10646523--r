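# Synthetic dyadic wearable fixtures.
#
# The latent layer of every channel is a pair of coupled linear damped
# oscillators (the same model family as the simulation study) propagated
# *exactly* with the matrix exponential of the system matrix, so the planted
# coupling structure is free of integration error. One model time unit maps
# to `time_scale` seconds of wall time. Randomness enters through a shared
# per-incident phase and frequency jitter (identical for both persons, which
# keeps the uncoupled null mirror-symmetric) and through the observation
# layer: a slow sinusoidal drift and white measurement noise, drawn
# independently per person.

empatica_channels <- function() {
  data.frame(channel = c("ACC", "BVP", "EDA", "HR", "TEMP"),
             rate = c(32, 64, 4, 1, 4),
             eta = c(0.45, 0.60, 0.20, 0.35, 0.15),
             stringsAsFactors = FALSE)
}

# gamma constants implied by a planted direction (person X = client)
direction_gammas <- function(direction, strength) {
  switch(direction,
    none          = c(0, 0),
    client        = c(+strength, 0),
    caregiver     = c(0, -strength),
    bidirectional = c(+strength, -strength),
    stop("direction must be one of none, client, caregiver, bidirectional")
  )
}

# Latent coupled-oscillator pair sampled at 1 Hz.
# State (x, dx, y, dy); velocities are per model time unit. With
# sigma_process = 0 the propagation is exact (matrix exponential); otherwise
# a semi-implicit Euler-Maruyama scheme with fine substeps is used.
latent_dyad <- function(gamma_xy, gamma_yx, eta, zeta = -0.05,
                        n_seconds = 2100, time_scale = 10,
                        sigma_process = 0, amp = 3, phase = 0) {
  a_mat <- rbind(c(0, 1, 0, 0),
                 c(-eta, zeta, gamma_yx, 0),
                 c(0, 0, 0, 1),
                 c(gamma_xy, 0, -eta, zeta))
  x0 <- amp * cos(phase)
  dx0 <- -amp * sqrt(eta) * sin(phase)
  state <- c(x0, dx0, -x0, -dx0)
  dt <- 1 / time_scale
  xs <- numeric(n_seconds)
  ys <- numeric(n_seconds)
  if (sigma_process == 0) {
    p_mat <- as.matrix(Matrix::expm(Matrix::Matrix(a_mat * dt)))
    for (i in seq_len(n_seconds)) {
      xs[i] <- state[1]
      ys[i] <- state[3]
      state <- p_mat %*% state
    }
  } else {
    nsub <- ceiling(dt / 0.02)
    h <- dt / nsub
    for (i in seq_len(n_seconds)) {
      xs[i] <- state[1]
      ys[i] <- state[3]
      for (k in seq_len(nsub)) {
        acc <- a_mat %*% state
        state[2] <- state[2] + acc[2] * h + sigma_process * sqrt(h) * stats::rnorm(1)
        state[4] <- state[4] + acc[4] * h + sigma_process * sqrt(h) * stats::rnorm(1)
        state[1] <- state[1] + state[2] * h
        state[3] <- state[3] + state[4] * h
      }
    }
  }
  if (any(!is.finite(c(xs, ys)))) stop("latent dyad diverged (non-finite state)")
  list(x = xs, y = ys)
}

# slow sinusoidal drift + white noise, scaled to the signal's sd
observe <- function(latent, times_rel, drift_amp, meas_sd) {
  s <- stats::sd(latent)
  v <- if (length(times_rel) == length(latent) &&
           all(times_rel == seq_along(latent) - 1)) {
    latent
  } else {
    stats::approx(seq_along(latent) - 1, latent, xout = times_rel, rule = 2)$y
  }
  if (drift_amp > 0) {
    period <- stats::runif(1, 600, 1800)
    ph <- stats::runif(1, 0, 2 * pi)
    v <- v + drift_amp * s * sin(2 * pi * times_rel / period + ph)
  }
  if (meas_sd > 0) v <- v + stats::rnorm(length(v), 0, meas_sd * s)
  v
}

#' Generate one synthetic dyad series pair at 1 Hz
#'
#' Convenience generator for a single channel observed in two interacting
#' persons: a coupled damped-oscillator latent pair with a planted coupling
#' direction, observed through slow drift and measurement noise. Person X is
#' the client, person Y the caregiver; planting `"client"` couples X into
#' the acceleration of Y.
#'
#' @param direction Planted ground truth: `"none"`, `"client"`,
#'   `"caregiver"` or `"bidirectional"`.
#' @param strength Coupling magnitude (default 0.05, comparable to the
#'   simulation-study scenarios).
#' @param n_seconds Series length in seconds (1 Hz samples).
#' @param eta Latent frequency parameter.
#' @param time_scale Seconds of wall time per model time unit.
#' @param sigma_process Process-noise level of the latent layer (default 0:
#'   deterministic transient skeleton).
#' @param drift_amp Drift amplitude as a fraction of the signal sd.
#' @param meas_sd Measurement noise sd as a fraction of the signal sd.
#' @param eta_jitter Relative frequency jitter, shared by both persons.
#' @param amp Initial amplitude of the antiphase latent state.
#' @param seed Optional seed (caller's RNG stream is preserved).
#' @return List with `x` (client series), `y` (caregiver series) and
#'   `truth` (the planted direction).
#' @export
generate_dyad_series <- function(direction = "none", strength = 0.05,
                                 n_seconds = 2100, eta = 0.3,
                                 time_scale = 10, sigma_process = 0,
                                 drift_amp = 0.005, meas_sd = 0.01,
                                 eta_jitter = 0.1, amp = 3, seed = NULL) {
  with_seed(seed, {
    gam <- direction_gammas(direction, strength)
    eta_i <- eta * (1 + stats::runif(1, -eta_jitter, eta_jitter))
    phase <- stats::runif(1, 0, 2 * pi)
    lat <- latent_dyad(gam[1], gam[2], eta_i, n_seconds = n_seconds,
                       time_scale = time_scale,
                       sigma_process = sigma_process, amp = amp,
                       phase = phase)
    t_rel <- seq_len(n_seconds) - 1
    list(x = observe(lat$x, t_rel, drift_amp, meas_sd),
         y = observe(lat$y, t_rel, drift_amp, meas_sd),
         truth = direction)
  })
}

default_coupling_spec <- function() {
  data.frame(variable = c("ACC", "BVP", "EDA", "HR", "TEMP"),
             direction = c("client", "none", "caregiver", "client",
                           "bidirectional"),
             strength = 0.05,
             stringsAsFactors = FALSE)
}

#' Generate a cohort of synthetic dyad recordings
#'
#' Emulates a two-person, five-channel wearable recording (ACC 32 Hz, BVP
#' 64 Hz, EDA 4 Hz, HR 1 Hz, TEMP 4 Hz) around each of `n_incidents`
#' incident timestamps, with a configurable ground-truth coupling direction
#' per channel. Native-rate channels are sampled from the 1 Hz latent dyad
#' by interpolation (the latent band lies far below 1 Hz) plus per-person
#' drift and measurement noise. Incidents listed in `short_incidents` start
#' recording only `short_lead_minutes` before the incident, so that all of
#' their series violate a `min_minutes = 25` quality rule — this exercises
#' [qc_filter()].
#'
#' @param n_incidents Number of incidents.
#' @param coupling_spec Data frame with columns `variable`, `direction`,
#'   `strength` (recycled over incidents), a list of such data frames (one
#'   per incident), or a function of the incident index returning one.
#'   Default: a mixed spec covering all four direction types.
#' @param seed Seed for reproducible cohorts.
#' @param window_minutes Analysis window the recording must cover.
#' @param lead_minutes Recording lead time before each incident.
#' @param short_lead_minutes Lead time of planted-short incidents.
#' @param short_incidents Indices of incidents recorded short.
#' @param post_minutes Recording time after each incident.
#' @param start_time Unix time of the first incident.
#' @inheritParams generate_dyad_series
#' @return List of `dyad_recording` objects: per person and channel a data
#'   frame of timestamped samples at the channel's native rate, the incident
#'   time, and the planted ground truth in `$truth`.
#' @export
generate_fixture <- function(n_incidents, coupling_spec = default_coupling_spec(),
                             seed = NULL, window_minutes = 35,
                             lead_minutes = 40, short_lead_minutes = 20,
                             short_incidents = integer(0), post_minutes = 5,
                             start_time = 1690000000, strength = 0.05,
                             time_scale = 10, sigma_process = 0,
                             drift_amp = 0.005, meas_sd = 0.01,
                             eta_jitter = 0.1, amp = 3) {
  channels <- empatica_channels()
  spec_for <- function(i) {
    s <- if (is.function(coupling_spec)) coupling_spec(i)
         else if (is.data.frame(coupling_spec)) coupling_spec
         else coupling_spec[[i]]
    stopifnot(all(c("variable", "direction") %in% names(s)))
    if (is.null(s$strength)) s$strength <- strength
    s
  }
  with_seed(seed, {
    lapply(seq_len(n_incidents), function(i) {
      spec <- spec_for(i)
      incident_time <- start_time + (i - 1) * 7200
      lead <- if (i %in% short_incidents) short_lead_minutes else lead_minutes
      rec_start <- incident_time - lead * 60
      n_seconds <- (lead + post_minutes) * 60
      chans <- list(client = list(), caregiver = list())
      for (k in seq_len(nrow(channels))) {
        ch <- channels$channel[k]
        row <- spec[spec$variable == ch, , drop = FALSE]
        dir <- if (nrow(row)) row$direction[1] else "none"
        str <- if (nrow(row)) row$strength[1] else strength
        gam <- direction_gammas(dir, str)
        eta_i <- channels$eta[k] * (1 + stats::runif(1, -eta_jitter, eta_jitter))
        phase <- stats::runif(1, 0, 2 * pi)
        lat <- latent_dyad(gam[1], gam[2], eta_i, n_seconds = n_seconds,
                           time_scale = time_scale,
                           sigma_process = sigma_process, amp = amp,
                           phase = phase)
        t_native <- seq(0, n_seconds - 1 / channels$rate[k],
                        by = 1 / channels$rate[k])
        chans$client[[ch]] <- data.frame(
          time = rec_start + t_native,
          value = observe(lat$x, t_native, drift_amp, meas_sd))
        chans$caregiver[[ch]] <- data.frame(
          time = rec_start + t_native,
          value = observe(lat$y, t_native, drift_amp, meas_sd))
      }
      structure(list(incident_id = sprintf("incident%03d", i),
                     incident_time = incident_time,
                     channels = chans, truth = spec,
                     rates = stats::setNames(channels$rate, channels$channel)),
                class = "dyad_recording")
    })
  })
}

#' @export
print.dyad_recording <- function(x, ...) {
  cat(sprintf("Dyad recording %s: incident at %s\n", x$incident_id,
              format(x$incident_time)))
  for (person in names(x$channels)) {
    spans <- vapply(x$channels[[person]], function(df) {
      if (nrow(df)) diff(range(df$time)) / 60 else 0
    }, numeric(1))
    cat(sprintf("  %s: %s\n", person,
                paste(sprintf("%s %.0fmin", names(spans), spans),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Write a fixture cohort as per-channel CSV files
#'
#' One CSV per person and channel (columns `unix_time_s`, `value`) plus an
#' `incidents.csv` index — the on-disk exchange format the pipeline reads.
#'
#' @param recordings List of `dyad_recording` objects.
#' @param dir Output directory (created if needed).
#' @export
write_fixture <- function(recordings, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(incident_id = character(), incident_time = numeric())
  for (rec in recordings) {
    for (person in names(rec$channels)) {
      for (ch in names(rec$channels[[person]])) {
        df <- rec$channels[[person]][[ch]]
        path <- file.path(dir, sprintf("%s_%s_%s.csv", rec$incident_id,
                                       person, ch))
        utils::write.csv(data.frame(unix_time_s = df$time, value = df$value),
                         path, row.names = FALSE)
      }
    }
    idx <- rbind(idx, data.frame(incident_id = rec$incident_id,
                                 incident_time = rec$incident_time))
  }
  utils::write.csv(idx, file.path(dir, "incidents.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read a cohort of dyad recordings from a fixture directory
#'
#' Inverse of [write_fixture()]: expects `incidents.csv` plus
#' `<incident>_<person>_<channel>.csv` files.
#'
#' @param dir Directory written by [write_fixture()] (or data laid out the
#'   same way).
#' @return List of `dyad_recording` objects.
#' @export
read_fixture <- function(dir) {
  idx <- utils::read.csv(file.path(dir, "incidents.csv"),
                         stringsAsFactors = FALSE)
  files <- list.files(dir, pattern = "_.*_.*\\.csv$")
  lapply(seq_len(nrow(idx)), function(i) {
    id <- idx$incident_id[i]
    mine <- files[startsWith(files, paste0(id, "_"))]
    chans <- list()
    for (f in mine) {
      parts <- strsplit(sub("\\.csv$", "", f), "_")[[1]]
      person <- parts[length(parts) - 1L]
      ch <- parts[length(parts)]
      df <- utils::read.csv(file.path(dir, f))
      chans[[person]][[ch]] <- data.frame(time = df$unix_time_s,
                                          value = df$value)
    }
    # person X (client) must come first for the direction semantics
    pref <- intersect(c("client", "caregiver"), names(chans))
    chans <- chans[c(pref, setdiff(names(chans), pref))]
    structure(list(incident_id = id, incident_time = idx$incident_time[i],
                   channels = chans, truth = NULL, rates = NULL),
              class = "dyad_recording")
  })
}
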