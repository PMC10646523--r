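#' Analysis configuration for the dyadic pipeline
#'
#' Bundles every tunable parameter of the incident-centred analysis. The
#' defaults correspond to the reference configuration: a 35-minute
#' pre-incident window resampled to 1 Hz, delay embedding with lag 100
#' samples and dimension 5, auto recurrence rate 5%, cross recurrence rate
#' 4%, and the fixed +-0.01 direction rule.
#'
#' @param window_minutes Pre-incident window length (minutes).
#' @param min_minutes Minimum usable series length for quality control.
#' @param lag,dim Shared delay-embedding parameters.
#' @param rr_auto,rr_cross Target recurrence rates.
#' @param norm Distance norm.
#' @param closure Triangle-closure convention, see [analyze_pair()].
#' @param direction_threshold Direction-rule threshold.
#' @param max_gap_seconds Longest sensor gap bridged by interpolation.
#' @param seed Optional seed recorded for reproducible runs.
#' @return An `irn_config` list.
#' @export
irn_config <- function(window_minutes = 35, min_minutes = 25,
                       lag = 100, dim = 5,
                       rr_auto = 0.05, rr_cross = 0.04,
                       norm = "euclidean", closure = "scale_matched",
                       direction_threshold = 0.01,
                       max_gap_seconds = 5, seed = NULL) {
  structure(list(window_minutes = window_minutes, min_minutes = min_minutes,
                 lag = lag, dim = dim, rr_auto = rr_auto, rr_cross = rr_cross,
                 norm = norm, closure = closure,
                 direction_threshold = direction_threshold,
                 max_gap_seconds = max_gap_seconds, seed = seed),
            class = "irn_config")
}

#' Read an analysis configuration from a YAML file
#'
#' Unknown keys are rejected; missing keys take the [irn_config()] defaults.
#'
#' @param path YAML file.
#' @return An `irn_config` list.
#' @export
irn_config_from_yaml <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(irn_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(irn_config, vals)
}

#' Resample a timestamped series to 1 Hz
#'
#' One value per whole second: the mean of the samples falling within the
#' second for native rates above 1 Hz, linear interpolation onto the second
#' marks for rates below 1 Hz (a native 1 Hz series on an aligned grid
#' passes through unchanged). Missing seconds are bridged by linear
#' interpolation up to `max_gap_seconds`; longer gaps remain `NA` and are
#' counted in the `long_gaps` attribute.
#'
#' @param x Data frame with numeric columns `time` (seconds) and `value`.
#' @param grid Integer second marks of the output (default: every whole
#'   second spanned by the data).
#' @param max_gap_seconds Longest gap bridged by interpolation.
#' @return Numeric vector along `grid` (attribute `grid` holds the times,
#'   `long_gaps` the number of unbridged gap runs).
#' @export
resample_1hz <- function(x, grid = NULL, max_gap_seconds = 5) {
  stopifnot(is.data.frame(x), all(c("time", "value") %in% names(x)))
  if (nrow(x) == 0) stop("empty input series")
  if (is.unsorted(x$time)) stop("timestamps must be monotone")
  if (is.null(grid)) grid <- seq(floor(min(x$time)), floor(max(x$time)))
  rate <- if (nrow(x) > 1) 1 / stats::median(diff(x$time)) else 1
  if (rate >= 1) {
    sec <- floor(x$time)
    keep <- sec >= grid[1] & sec <= grid[length(grid)]
    v <- as.numeric(tapply(x$value[keep],
                           factor(sec[keep], levels = grid), mean))
  } else {
    v <- stats::approx(x$time, x$value, xout = grid, rule = 1)$y
  }
  long_gaps <- 0L
  if (anyNA(v) && any(!is.na(v))) {
    runs <- rle(is.na(v))
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    filled <- stats::approx(grid[!is.na(v)], v[!is.na(v)], xout = grid,
                            rule = 1)$y
    for (r in which(runs$values)) {
      if (runs$lengths[r] <= max_gap_seconds) {
        v[starts[r]:ends[r]] <- filled[starts[r]:ends[r]]
      } else {
        long_gaps <- long_gaps + 1L
      }
    }
  }
  attr(v, "grid") <- grid
  attr(v, "long_gaps") <- long_gaps
  v
}

#' Extract and align the pre-incident window of a dyad recording
#'
#' Clips every channel to `[incident - window, incident)`, resamples to 1 Hz
#' and aligns the two persons on the shared second grid. Channels whose
#' usable (non-missing) duration falls short of the window are flagged in
#' the `qc` table rather than raising an error.
#'
#' @param rec A `dyad_recording` (see [generate_fixture()]).
#' @param minutes Window length before the incident.
#' @param max_gap_seconds Passed to [resample_1hz()].
#' @return An `incident_window`: 1 Hz series per person and channel (length
#'   `60 * minutes`, `NA` where unobserved), the time grid, and a `qc` table
#'   with the usable minutes per series.
#' @export
extract_window <- function(rec, minutes = 35, max_gap_seconds = 5) {
  stopifnot(inherits(rec, "dyad_recording"))
  t_inc <- rec$incident_time
  if (is.null(t_inc) || !is.finite(t_inc)) stop("incident_time is not set")
  grid <- seq(t_inc - 60 * minutes, t_inc - 1)
  series <- list()
  qc <- NULL
  any_data <- FALSE
  for (person in names(rec$channels)) {
    for (ch in names(rec$channels[[person]])) {
      df <- rec$channels[[person]][[ch]]
      if (is.null(df) || nrow(df) == 0) {
        series[[person]][[ch]] <- rep(NA_real_, length(grid))
        qc <- rbind(qc, data.frame(person = person, channel = ch,
                                   minutes = 0, missing = TRUE))
        next
      }
      clip <- df[df$time >= grid[1] & df$time < t_inc, , drop = FALSE]
      v <- if (nrow(clip) == 0) rep(NA_real_, length(grid)) else {
        any_data <- TRUE
        resample_1hz(clip, grid = grid, max_gap_seconds = max_gap_seconds)
      }
      series[[person]][[ch]] <- as.numeric(v)
      qc <- rbind(qc, data.frame(person = person, channel = ch,
                                 minutes = sum(!is.na(v)) / 60,
                                 missing = FALSE))
    }
  }
  if (!any_data) stop("empty window: no samples before the incident")
  structure(list(incident_id = rec$incident_id, series = series, time = grid,
                 window_minutes = minutes, qc = qc),
            class = "incident_window")
}

#' Quality-control filter over incident windows
#'
#' Drops an incident when two or more of its series are shorter than
#' `min_minutes`; every exclusion is logged with its cause.
#'
#' @param windows List of `incident_window` objects.
#' @param min_minutes Minimum usable series length (minutes).
#' @return List with elements `retained` (windows) and `excluded` (data
#'   frame: `incident_id`, `n_short`, `reason`).
#' @export
qc_filter <- function(windows, min_minutes = 25) {
  excluded <- data.frame(incident_id = character(), n_short = integer(),
                         reason = character())
  keep <- logical(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    n_short <- sum(w$qc$minutes < min_minutes)
    if (n_short >= 2) {
      short <- w$qc[w$qc$minutes < min_minutes, ]
      excluded <- rbind(excluded, data.frame(
        incident_id = as.character(w$incident_id), n_short = n_short,
        reason = sprintf("%d series shorter than %g min (%s)", n_short,
                         min_minutes,
                         paste(short$person, short$channel, sep = ".",
                               collapse = ", "))))
    } else {
      keep[i] <- TRUE
    }
  }
  list(retained = windows[keep], excluded = excluded)
}

#' Per-variable IRN analysis of one incident window
#'
#' For every channel observed in both persons, runs [analyze_pair()] on the
#' aligned 1 Hz series (person X = first person in the recording, typically
#' the client) and collects the coupling summaries into a tidy table;
#' channels with missing samples are recorded as failures rather than
#' aborting the incident. When at least two channels are complete, the
#' variable-level multiplex network is built as well.
#'
#' @param window An `incident_window`.
#' @param config An [irn_config()].
#' @return List with `summaries` (tidy data frame: `incident_id`,
#'   `variable`, `c_xy`, `c_yx`, `delta_c`, `rho_xy`, `direction`),
#'   `multiplex` (igraph or NULL) and `failures` (data frame).
#' @export
analyze_incident <- function(window, config = irn_config()) {
  stopifnot(inherits(window, "incident_window"))
  persons <- names(window$series)
  if (length(persons) != 2) stop("an incident window needs exactly 2 persons")
  channels <- intersect(names(window$series[[1]]), names(window$series[[2]]))
  rows <- list()
  failures <- data.frame(variable = character(), reason = character())
  complete <- list()
  for (ch in channels) {
    sx <- window$series[[1]][[ch]]
    sy <- window$series[[2]][[ch]]
    if (anyNA(sx) || anyNA(sy)) {
      failures <- rbind(failures, data.frame(
        variable = ch, reason = "missing samples in window"))
      rows[[ch]] <- data.frame(incident_id = window$incident_id, variable = ch,
                               c_xy = NA_real_, c_yx = NA_real_,
                               delta_c = NA_real_, rho_xy = NA_real_,
                               direction = NA_character_)
      next
    }
    cs <- tryCatch(
      analyze_pair(sx, sy, lag = config$lag, dim = config$dim,
                   rr_auto = config$rr_auto, rr_cross = config$rr_cross,
                   norm = config$norm, closure = config$closure,
                   direction_threshold = config$direction_threshold),
      error = function(e) e)
    if (inherits(cs, "error")) {
      failures <- rbind(failures, data.frame(variable = ch,
                                             reason = conditionMessage(cs)))
      rows[[ch]] <- data.frame(incident_id = window$incident_id, variable = ch,
                               c_xy = NA_real_, c_yx = NA_real_,
                               delta_c = NA_real_, rho_xy = NA_real_,
                               direction = NA_character_)
      next
    }
    complete[[ch]] <- list(x = sx, y = sy)
    rows[[ch]] <- data.frame(incident_id = window$incident_id, variable = ch,
                             c_xy = cs$c_xy, c_yx = cs$c_yx,
                             delta_c = cs$delta_c, rho_xy = cs$rho_xy,
                             direction = cs$direction)
  }
  multiplex <- if (length(complete) >= 2) {
    build_multiplex(complete, lag = config$lag, dim = config$dim,
                    rr_auto = config$rr_auto, rr_cross = config$rr_cross,
                    norm = config$norm, closure = config$closure,
                    direction_threshold = config$direction_threshold)
  } else NULL
  list(summaries = do.call(rbind, rows), multiplex = multiplex,
       failures = failures)
}

#' Frequency table of implied coupling directions
#'
#' Summarises per-incident coupling summaries into the percentage of
#' incidents in which person X (client) leads, person Y (caregiver) leads,
#' or the interaction is read as bidirectional/uncoupled, per variable and
#' averaged over variables. Percentages are computed over the incidents with
#' a defined direction and sum to 100 per variable.
#'
#' @param summaries Tidy data frame from [analyze_incident()] (rows from
#'   several incidents can simply be row-bound).
#' @return Data frame with one row per variable plus a `Mean` row; columns
#'   `variable`, `client_leading`, `caregiver_leading`,
#'   `bidirectional_uncoupled` (percent) and `n`.
#' @export
summarize_directions <- function(summaries) {
  stopifnot(all(c("variable", "direction") %in% names(summaries)))
  ok <- !is.na(summaries$direction)
  if (!any(ok)) stop("no incidents with a defined direction")
  s <- summaries[ok, ]
  vars <- sort(unique(s$variable))
  pct <- function(d, lab) 100 * mean(d == lab)
  rows <- lapply(vars, function(v) {
    d <- s$direction[s$variable == v]
    data.frame(variable = v,
               client_leading = pct(d, "X_leads"),
               caregiver_leading = pct(d, "Y_leads"),
               bidirectional_uncoupled = pct(d, "bidirectional_or_uncoupled"),
               n = length(d))
  })
  out <- do.call(rbind, rows)
  mean_row <- data.frame(variable = "Mean",
                         client_leading = mean(out$client_leading),
                         caregiver_leading = mean(out$caregiver_leading),
                         bidirectional_uncoupled = mean(out$bidirectional_uncoupled),
                         n = sum(out$n))
  rbind(out, mean_row)
}

#' Run the full incident-centred pipeline over a cohort
#'
#' Extract windows, apply quality control, analyse every retained incident
#' and summarise direction frequencies.
#'
#' @param recordings List of `dyad_recording` objects.
#' @param config An [irn_config()].
#' @return List with `results` (tidy per-incident, per-variable table),
#'   `summary` (direction frequency table), `excluded` (QC log) and
#'   `multiplexes` (named list of igraph objects).
#' @export
analyze_cohort <- function(recordings, config = irn_config()) {
  windows <- list()
  excluded <- data.frame(incident_id = character(), n_short = integer(),
                         reason = character())
  for (rec in recordings) {
    w <- tryCatch(
      extract_window(rec, minutes = config$window_minutes,
                     max_gap_seconds = config$max_gap_seconds),
      error = function(e) e)
    if (inherits(w, "error")) {
      excluded <- rbind(excluded, data.frame(
        incident_id = as.character(rec$incident_id), n_short = NA_integer_,
        reason = conditionMessage(w)))
    } else {
      windows[[length(windows) + 1L]] <- w
    }
  }
  qc <- qc_filter(windows, min_minutes = config$min_minutes)
  excluded <- rbind(excluded, qc$excluded)
  if (length(qc$retained) == 0) {
    stop("no incidents retained after quality control (min_minutes = ",
         config$min_minutes, ", window_minutes = ", config$window_minutes, ")")
  }
  analyses <- lapply(qc$retained, analyze_incident, config = config)
  results <- do.call(rbind, lapply(analyses, `[[`, "summaries"))
  multiplexes <- lapply(analyses, `[[`, "multiplex")
  names(multiplexes) <- vapply(qc$retained, function(w) as.character(w$incident_id), "")
  list(results = results,
       summary = summarize_directions(results),
       excluded = excluded,
       multiplexes = multiplexes)
}
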