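#' Stimulus schedule for the startle battery
#'
#' The behavioural assay is a 1-h dark acclimation followed by `n_cycles`
#' repeats of a 60-s acoustic/light startle string and an intermission.
#' Analysis windows are derived from the schedule: SRB (startle response
#' behaviour) spans each 60-s string, PSRB (post-startle response
#' behaviour) spans the first `psrb_s` seconds of the recovery that
#' follows it.
#'
#' @param acclimation_s dark acclimation before cycle 1 (seconds).
#' @param n_cycles number of startle cycles.
#' @param startle_s duration of the startle string (seconds).
#' @param intermission_s recovery between startle strings (seconds).
#' @param psrb_s length of the post-startle analysis window (seconds);
#'   must not exceed `intermission_s`.
#' @param events data frame of within-string stimulus events
#'   (`onset_s`, `kind`, `duration_s`), seconds relative to string onset.
#' @return An object of class `stimulus_schedule`.
#' @seealso [battery_windows()], [default_startle_events()]
#' @export
stimulus_schedule <- function(acclimation_s = 3600, n_cycles = 5,
                              startle_s = 60, intermission_s = 1740,
                              psrb_s = 600,
                              events = default_startle_events()) {
  stopifnot(acclimation_s >= 0, n_cycles >= 1, startle_s > 0,
            intermission_s >= 0)
  if (psrb_s > intermission_s)
    stop("psrb_s (", psrb_s, ") exceeds intermission_s (", intermission_s, ")")
  stopifnot(is.data.frame(events),
            all(c("onset_s", "kind", "duration_s") %in% names(events)))
  if (any(events$onset_s < 0 | events$onset_s + events$duration_s > startle_s))
    stop("stimulus events must lie within [0, startle_s]")
  structure(list(acclimation_s = acclimation_s, n_cycles = n_cycles,
                 startle_s = startle_s, intermission_s = intermission_s,
                 psrb_s = psrb_s, events = events),
            class = "stimulus_schedule")
}

#' Default 60-s tap/light stimulus string
#'
#' Reconstructs the standard startle minute: blocks of low (L) and high (H)
#' intensity taps separated by pauses (each tap occupies 0.5 s including
#' its inter-tap break, so the printed block/pause durations close the
#' minute exactly), overlaid with six 10-s light epochs
#' (dark, red, blue, purple, white, flicker).
#'
#' @return Data frame with columns `onset_s`, `kind`, `duration_s`.
#' @export
default_startle_events <- function() {
  tap_block <- function(start, n, kind)
    data.frame(onset_s = start + 0.5 * (seq_len(n) - 1), kind = kind,
               duration_s = 0.5)
  taps <- rbind(
    tap_block(1,  6,  "tap_L"),   # 1 s pause, 6 x L
    tap_block(8,  4,  "tap_H"),   # 4 s pause, 4 x H
    tap_block(11, 8,  "tap_L"),   # 1 s pause, 8 x L
    tap_block(23, 2,  "tap_L"),   # 8 s pause, 2 x L
    tap_block(24, 10, "tap_H"),   # then 10 x H
    tap_block(36, 2,  "tap_H"),   # 7 s pause, 2 x H
    tap_block(50, 14, "tap_H"))   # 13 s pause, 14 x H; 3 s pause closes 60 s
  lights <- data.frame(
    onset_s = seq(0, 50, by = 10),
    kind = c("dark", "light_red", "light_blue", "light_purple",
             "light_white", "light_flicker"),
    duration_s = 10)
  out <- rbind(taps, lights)
  out[order(out$onset_s), , drop = FALSE]
}

#' Derive SRB and PSRB analysis windows from a schedule
#'
#' SRB cycle k spans `[acclimation + (k-1)(startle + intermission),
#' + startle]`; PSRB cycle k spans the first `psrb_s` seconds after it.
#'
#' @param schedule a [stimulus_schedule()].
#' @return Data frame with columns `label` ("SRB"/"PSRB"), `cycle`,
#'   `start_s`, `end_s` (absolute experiment seconds), ordered in time.
#' @export
battery_windows <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  k <- seq_len(schedule$n_cycles)
  srb_start <- schedule$acclimation_s +
    (k - 1) * (schedule$startle_s + schedule$intermission_s)
  srb <- data.frame(label = "SRB", cycle = k,
                    start_s = srb_start,
                    end_s = srb_start + schedule$startle_s)
  psrb <- data.frame(label = "PSRB", cycle = k,
                     start_s = srb$end_s,
                     end_s = srb$end_s + schedule$psrb_s)
  out <- rbind(srb, psrb)
  out <- out[order(out$start_s, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Total duration of an experiment defined by a schedule
#' @param schedule a [stimulus_schedule()].
#' @return seconds from t = 0 to the end of the last intermission.
#' @export
schedule_duration <- function(schedule) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  schedule$acclimation_s +
    schedule$n_cycles * (schedule$startle_s + schedule$intermission_s)
}

#' Default P1-P6 peak windows within the startle minute
#'
#' The six motility peak clusters are quantified over the six 10-s light
#' epochs of the startle string, the only printed six-way partition of the
#' minute.  Times are relative to startle onset.
#'
#' @param startle_s duration of the startle string.
#' @return Data frame with columns `peak` ("P1".."P6"), `start_s`, `end_s`.
#' @export
peak_windows <- function(startle_s = 60) {
  b <- seq(0, startle_s, length.out = 7)
  data.frame(peak = paste0("P", 1:6), start_s = b[1:6], end_s = b[2:7])
}

#' Square-well geometry with a centered inner zone
#'
#' Thigmotaxis is scored against an inner rectangle whose width and height
#' are `inner_fraction` of the well's; positions outside it count as
#' wall-proximal.  Well size is instrument-specific and must come from
#' configuration; the default is a 9-mm square well.
#'
#' @param x_min,x_max,y_min,y_max well borders (mm).
#' @param inner_fraction linear fraction of the well spanned by the inner
#'   zone (default 0.40).
#' @return An object of class `well_geometry`.
#' @export
well_geometry <- function(x_min = 0, x_max = 9, y_min = 0, y_max = 9,
                          inner_fraction = 0.4) {
  stopifnot(x_min < x_max, y_min < y_max,
            inner_fraction > 0, inner_fraction < 1)
  structure(list(x_min = x_min, x_max = x_max, y_min = y_min, y_max = y_max,
                 inner_fraction = inner_fraction),
            class = "well_geometry")
}

#' Classify positions as inside the inner (non-thigmotactic) zone
#' @param x,y coordinates (mm).
#' @param geom a [well_geometry()].
#' @return Logical vector, `TRUE` for positions inside the inner zone.
#' @export
in_inner_zone <- function(x, y, geom) {
  stopifnot(inherits(geom, "well_geometry"))
  cx <- (geom$x_min + geom$x_max) / 2
  cy <- (geom$y_min + geom$y_max) / 2
  hw <- geom$inner_fraction * (geom$x_max - geom$x_min) / 2
  hh <- geom$inner_fraction * (geom$y_max - geom$y_min) / 2
  x >= cx - hw & x <= cx + hw & y >= cy - hh & y <= cy + hh
}

#' Read / write a stimulus schedule as YAML
#' @param path file path.
#' @rdname schedule_yaml
#' @export
read_schedule <- function(path) {
  y <- yaml::read_yaml(path)
  ev <- if (is.null(y$events)) default_startle_events() else
    do.call(rbind, lapply(y$events, as.data.frame))
  stimulus_schedule(acclimation_s = y$acclimation_s %||% 3600,
                    n_cycles = y$n_cycles %||% 5,
                    startle_s = y$startle_s %||% 60,
                    intermission_s = y$intermission_s %||% 1740,
                    psrb_s = y$psrb_s %||% 600,
                    events = ev)
}

#' @param schedule a [stimulus_schedule()].
#' @rdname schedule_yaml
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  y <- unclass(schedule)
  y$events <- lapply(seq_len(nrow(schedule$events)), function(i)
    as.list(schedule$events[i, ]))
  yaml::write_yaml(y, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
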