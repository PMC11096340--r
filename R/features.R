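#' Turning magnitude between two headings
#'
#' The angle between consecutive headings, converted to the magnitude of
#' the smaller arc on the circle, so the result is in [0, 180].
#'
#' @param h_prev,h_curr headings in degrees, [0, 360).  Vectorized.
#' @return Turning magnitude(s) in degrees.
#' @export
step_turning <- function(h_prev, h_curr) {
  abs(((h_curr - h_prev + 180) %% 360) - 180)
}

# indices of frames falling in [start_s, end_s); errors if the window is
# not covered by the track
.window_idx <- function(track, window) {
  if (window$start_s < min(track$t) - 1e-9 ||
      window$end_s > max(track$t) + 1 / track$frame_rate + 1e-9)
    stop("window [", window$start_s, ", ", window$end_s,
         ") outside track span for fish ", track$fish_id)
  which(track$t >= window$start_s - 1e-9 & track$t < window$end_s - 1e-9)
}

#' Relative turning over a window
#'
#' Sum of frame-to-frame turning magnitudes (from the heading channel),
#' normalized to the distance travelled in the same window.  Frames with
#' zero step distance still contribute their heading change.
#'
#' @param track a [track()].
#' @param window one row of [battery_windows()] (needs `start_s`, `end_s`).
#' @return degrees/mm, or `NA` when the fish travelled no distance.
#' @export
relative_turning <- function(track, window) {
  i <- .window_idx(track, window)
  if (length(i) < 2) return(NA_real_)
  turn <- sum(step_turning(track$heading[i[-length(i)]],
                           track$heading[i[-1]]))
  dist <- sum(track$step_dist[i])
  if (dist <= 0) return(NA_real_)
  turn / dist
}

#' Total pause time over a window
#'
#' Frames whose step distance is at or below `eps` (default 0, i.e. the
#' tracker reported no movement) count as paused; their frame durations
#' are summed.
#'
#' @inheritParams relative_turning
#' @param eps movement threshold in mm (default 0).
#' @return seconds.
#' @export
pause_time <- function(track, window, eps = 0) {
  stopifnot(eps >= 0)
  i <- .window_idx(track, window)
  sum(track$step_dist[i] <= eps) / track$frame_rate
}

#' Mean spurt (bout-peak) velocity over a window
#'
#' Movement bouts are maximal runs of consecutive non-pause frames; each
#' bout's maximum frame velocity is recorded and the bout maxima averaged.
#'
#' @inheritParams pause_time
#' @return mm/s, or `NA` when the fish never moved.
#' @export
spurt_velocity <- function(track, window, eps = 0) {
  i <- .window_idx(track, window)
  moving <- track$step_dist[i] > eps
  if (!any(moving)) return(NA_real_)
  v <- track$step_dist[i] * track$frame_rate
  runs <- rle(moving)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  keep <- runs$values
  mean(mapply(function(s, e) max(v[s:e]), starts[keep], ends[keep]))
}

#' Thigmotaxis ratios over a window
#'
#' Fraction of time and of distance spent outside the centered inner zone
#' (a rectangle spanning `inner_fraction` of the well's width and height).
#' A frame is classified by its own endpoint coordinates.
#'
#' @inheritParams relative_turning
#' @param geom a [well_geometry()].
#' @return Named list `time_ratio`, `dist_ratio`, both in [0, 1];
#'   `dist_ratio` is `NA` when total distance is 0.
#' @export
thigmotaxis <- function(track, window, geom) {
  i <- .window_idx(track, window)
  outside <- !in_inner_zone(track$x[i], track$y[i], geom)
  total <- sum(track$step_dist[i])
  list(time_ratio = mean(outside),
       dist_ratio = if (total > 0) sum(track$step_dist[i][outside]) / total
                    else NA_real_)
}

#' Extract the six behavioural syllables for one fish in one window
#'
#' @inheritParams thigmotaxis
#' @param eps pause threshold in mm.
#' @return One-row data frame: identifiers, window label/cycle, and
#'   `distance_mm`, `turning_rel`, `pause_s`, `spurt_mms`, `thigmo_time`,
#'   `thigmo_dist`.  Undefined features (e.g. turning of a stationary
#'   fish) are `NA`.
#' @export
extract_features <- function(track, window, geom, eps = 0) {
  i <- .window_idx(track, window)
  th <- thigmotaxis(track, window, geom)
  data.frame(fish_id = track$fish_id, plate_id = track$plate_id,
             treatment = track$treatment, dose_level = track$dose_level,
             label = window$label, cycle = window$cycle,
             distance_mm = sum(track$step_dist[i]),
             turning_rel = relative_turning(track, window),
             pause_s = pause_time(track, window, eps),
             spurt_mms = spurt_velocity(track, window, eps),
             thigmo_time = th$time_ratio,
             thigmo_dist = th$dist_ratio)
}

#' Feature table for many fish over many windows
#' @param tracks list of [track()] objects.
#' @param windows data frame from [battery_windows()].
#' @param geom a [well_geometry()].
#' @param eps pause threshold in mm.
#' @return Tidy data frame, one row per fish x window x cycle.
#' @export
extract_feature_table <- function(tracks, windows, geom, eps = 0) {
  out <- do.call(rbind, lapply(tracks, function(tr)
    do.call(rbind, lapply(seq_len(nrow(windows)), function(w)
      extract_features(tr, windows[w, ], geom, eps)))))
  rownames(out) <- NULL
  out
}

.feature_cols <- c("distance_mm", "turning_rel", "pause_s", "spurt_mms",
                   "thigmo_time", "thigmo_dist")

#' Normalize features to same-plate controls
#'
#' Each feature is expressed as the percent change against the mean of the
#' control (dose level 0) fish measured on the same plate, in the same
#' window label and cycle: `100 * (f - mean_ctrl) / mean_ctrl`.  Missing
#' feature values are excluded from control means pairwise.
#'
#' @param features tidy feature table from [extract_feature_table()].
#' @return The same table with feature columns replaced by percent
#'   changes; a control-mean of zero yields `NA` with a warning.
#' @export
normalize_to_controls <- function(features) {
  stopifnot(all(.feature_cols %in% names(features)))
  key <- interaction(features$plate_id, features$label, features$cycle,
                     drop = TRUE)
  out <- features
  for (k in levels(key)) {
    rows <- key == k
    ctrl <- rows & features$dose_level == 0
    if (!any(ctrl))
      stop("no control (dose level 0) fish on plate ",
           features$plate_id[rows][1], " [", k, "]")
    for (f in .feature_cols) {
      m <- mean(features[[f]][ctrl], na.rm = TRUE)
      if (!is.finite(m) || m == 0) {
        warning("control mean of ", f, " is 0 or undefined in ", k,
                "; feature flagged undefined")
        out[[f]][rows] <- NA_real_
      } else {
        out[[f]][rows] <- 100 * (features[[f]][rows] - m) / m
      }
    }
  }
  out
}
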