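#' Behavioural archetypes for the track simulator
#'
#' An archetype is a set of multiplicative effects, applied at the top
#' dose (level 3) and interpolated linearly toward 1 at dose 0, on the
#' simulator's levers: baseline cruise speed, pause-entry rate, spurt
#' (bout-peak) velocity scale, turning noise, wall attraction
#' (thigmotaxis bias), and per-peak startle gain.  The `AA`
#' (antidepressant/anxiolytic) archetype lowers distance, thigmotaxis and
#' spurting and raises turning; `other` applies the reciprocal effects;
#' `stressor` exaggerates wall hugging and startle reactivity.
#'
#' @param name one of `"control"`, `"AA"`, `"other"`, `"stressor"`, or a
#'   list with fields `speed`, `pause`, `spurt`, `turn`, `thigmo`,
#'   `startle` (length-6) to define a custom archetype.
#' @return Object of class `behaviour_archetype`.
#' @export
behaviour_archetype <- function(name = "control") {
  if (is.list(name)) {
    a <- name
    a$name <- a$name %||% "custom"
  } else {
    a <- switch(name,
      control = list(speed = 1, pause = 1, spurt = 1, turn = 1,
                     thigmo = 1, startle = rep(1, 6)),
      AA = list(speed = 0.7, pause = 1.3, spurt = 0.8, turn = 1.4,
                thigmo = 0.7, startle = rep(0.8, 6)),
      other = list(speed = 1 / 0.7, pause = 1 / 1.3, spurt = 1.25,
                   turn = 1 / 1.4, thigmo = 1 / 0.7,
                   startle = rep(1.25, 6)),
      stressor = list(speed = 0.9, pause = 1.2, spurt = 1, turn = 1.2,
                      thigmo = 1.8, startle = rep(1.3, 6)),
      stop("unknown archetype '", name, "'"))
    a$name <- name
  }
  stopifnot(all(unlist(a[c("speed", "pause", "spurt", "turn", "thigmo",
                           "startle")]) > 0),
            length(a$startle) == 6)
  structure(a, class = "behaviour_archetype")
}

# dose interpolation: multiplier 1 at dose 0, full effect at dose 3
.dose_mult <- function(m, dose_level) 1 + (m - 1) * dose_level / 3

# baseline simulator parameters of an untreated larva
.baseline_params <- function() {
  list(v_base = 2,          # cruise speed, mm/s
       v_peak = 14,         # median bout-peak velocity, mm/s
       v_peak_sdlog = 0.3,  # lognormal spread of bout peaks
       pause_rate = 0.5,    # pause entries per second of movement
       resume_rate = 2,     # bout starts per second of pausing
       turn_sd = 18,        # heading noise, deg per frame at 60 fps
       wall_bias = 1.2,     # wall-attraction drift, deg per frame at 60 fps
       gain_p = c(2.5, 2.2, 2.0, 1.9, 1.8, 1.6),  # startle gain P1..P6
       fish_cv = 0.08)      # per-fish lognormal parameter jitter
}

# per-frame speed gain vector over the whole experiment
.gain_vector <- function(schedule, frame_rate, gain_p) {
  n <- ceiling(schedule_duration(schedule) * frame_rate)
  t <- (seq_len(n) - 1) / frame_rate
  gain <- rep(1, n)
  win <- battery_windows(schedule)
  srb <- win[win$label == "SRB", , drop = FALSE]
  pk <- peak_windows(schedule$startle_s)
  for (i in seq_len(nrow(srb))) {
    rel <- t - srb$start_s[i]
    for (j in 1:6) {
      sel <- rel >= pk$start_s[j] & rel < pk$end_s[j]
      gain[sel] <- gain_p[j]
    }
  }
  gain
}

#' Simulate one fish's track
#'
#' A paused/spurting correlated random walk with wall attraction and
#' reflective well boundaries, whose sufficient statistics are exactly
#' the six behavioural syllables: a two-state pause/move process (bout
#' lengths geometric), lognormal bout-peak velocities with a burst-decay
#' speed profile, Gaussian heading noise with a drift toward the nearest
#' wall, and a per-peak speed/arousal gain inside each startle minute.
#' Archetype-by-dose multipliers modulate every lever; each fish also
#' receives small lognormal parameter jitter (biological variability).
#'
#' @param archetype a [behaviour_archetype()] or its name.
#' @param dose_level ordinal dose (0-3).
#' @param schedule a [stimulus_schedule()].
#' @param geom a [well_geometry()].
#' @param frame_rate frames per second (default 60, the acquisition rate).
#' @param fish_id,plate_id,well_id,treatment,dose_value,dose_unit metadata.
#' @param baseline list of baseline parameters (see source); override for
#'   calibration experiments.
#' @param seed optional integer seed.
#' @return A [track()].
#' @export
simulate_track <- function(archetype = "control", dose_level = 0,
                           schedule = stimulus_schedule(),
                           geom = well_geometry(), frame_rate = 60,
                           fish_id = "fish1", plate_id = "plate1",
                           well_id = "A1", treatment = "control",
                           dose_value = 0, dose_unit = "uM",
                           baseline = .baseline_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (!inherits(archetype, "behaviour_archetype"))
    archetype <- behaviour_archetype(archetype)
  bp <- baseline
  d <- dose_level
  jit <- function(v) v * stats::rlnorm(1, 0, bp$fish_cv)
  v_base <- jit(bp$v_base * .dose_mult(archetype$speed, d))
  v_peak <- jit(bp$v_peak * .dose_mult(archetype$spurt, d))
  pause_rate <- jit(bp$pause_rate * .dose_mult(archetype$pause, d))
  turn_sd <- jit(bp$turn_sd * .dose_mult(archetype$turn, d)) *
    sqrt(60 / frame_rate)
  wall_bias <- jit(bp$wall_bias * .dose_mult(archetype$thigmo, d)) *
    60 / frame_rate
  gain_p <- bp$gain_p * .dose_mult(archetype$startle, d)

  dt <- 1 / frame_rate
  gain <- .gain_vector(schedule, frame_rate, gain_p)
  w <- c(geom$x_max - geom$x_min, geom$y_max - geom$y_min)
  sim <- .walk_sim(length(gain), dt, gain,
                   p_enter = pause_rate * dt,
                   p_exit = bp$resume_rate * dt,
                   v_base = v_base, v_peak_meanlog = log(v_peak),
                   v_peak_sdlog = bp$v_peak_sdlog,
                   turn_sd = turn_sd, wall_bias = wall_bias,
                   burst_t_peak = max(0.06, dt), burst_sd = max(0.06, dt),
                   x_min = geom$x_min, x_max = geom$x_max,
                   y_min = geom$y_min, y_max = geom$y_max,
                   x0 = geom$x_min + stats::runif(1) * w[1],
                   y0 = geom$y_min + stats::runif(1) * w[2],
                   h0 = stats::runif(1, 0, 360))
  track(fish_id, t = (seq_along(gain) - 1) * dt,
        x = sim$x, y = sim$y, heading = sim$heading,
        step_dist = sim$step_dist,
        plate_id = plate_id, well_id = well_id, treatment = treatment,
        dose_level = dose_level, dose_value = dose_value,
        dose_unit = dose_unit, frame_rate = frame_rate)
}

#' Simulate a full plate of treated and control fish
#'
#' @param panel data frame with one row per arm: `treatment`,
#'   `archetype` (name or listable), `dose_level`; must contain a
#'   control arm (dose level 0).
#' @param n_fish fish per arm (scalar or per-arm vector); arms with 0
#'   fish are dropped with a warning.
#' @param schedule,geom,frame_rate,baseline passed to [simulate_track()].
#' @param plate_id plate identifier.
#' @param seed integer seed; identical seeds give identical plates.
#' @return List with `tracks` (list of [track()]), `metadata` (data
#'   frame) and `truth` (per-fish archetype and dose).
#' @export
simulate_plate <- function(panel, n_fish = 10,
                           schedule = stimulus_schedule(),
                           geom = well_geometry(), frame_rate = 60,
                           baseline = .baseline_params(),
                           plate_id = "plate1", seed = 1) {
  stopifnot(is.data.frame(panel),
            all(c("treatment", "archetype", "dose_level") %in% names(panel)))
  if (!any(panel$dose_level == 0))
    stop("panel must include a control (dose level 0) arm")
  n_fish <- rep_len(n_fish, nrow(panel))
  if (any(n_fish == 0)) {
    warning("dropping arm(s) with 0 fish: ",
            paste(panel$treatment[n_fish == 0], collapse = ", "))
    panel <- panel[n_fish > 0, , drop = FALSE]
    n_fish <- n_fish[n_fish > 0]
  }
  set.seed(seed)
  wells <- paste0(rep(LETTERS[1:8], each = 12), rep(1:12, 8))
  tracks <- list()
  truth <- list()
  k <- 0
  for (i in seq_len(nrow(panel))) {
    for (j in seq_len(n_fish[i])) {
      k <- k + 1
      fid <- sprintf("%s_f%03d", plate_id, k)
      tracks[[fid]] <- simulate_track(
        archetype = if (is.list(panel$archetype)) panel$archetype[[i]]
                    else panel$archetype[i],
        dose_level = panel$dose_level[i], schedule = schedule,
        geom = geom, frame_rate = frame_rate, fish_id = fid,
        plate_id = plate_id,
        well_id = wells[(k - 1) %% length(wells) + 1],
        treatment = panel$treatment[i], dose_value = panel$dose_level[i],
        dose_unit = "level", baseline = baseline)
      truth[[fid]] <- data.frame(
        fish_id = fid, treatment = panel$treatment[i],
        archetype = if (is.list(panel$archetype)) "custom"
                    else panel$archetype[i],
        dose_level = panel$dose_level[i])
    }
  }
  list(tracks = tracks, metadata = track_metadata(tracks),
       truth = do.call(rbind, truth))
}
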