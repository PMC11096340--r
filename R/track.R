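#' Construct a single-fish tracking record
#'
#' A `track` holds one fish's time series (time, position, heading, step
#' distance) together with its plate/well/treatment metadata.  Heading is
#' in degrees in [0, 360), 0 along +x, counter-clockwise positive;
#' coordinates are mm with the origin at the well's lower-left corner.
#'
#' @param fish_id,plate_id,well_id,treatment identifiers.
#' @param dose_level ordinal dose level (0 = control, 1..3).
#' @param dose_value,dose_unit numeric dose and its unit string.
#' @param frame_rate acquisition rate, frames per second (default 60).
#' @param t time stamps (seconds), strictly increasing.
#' @param x,y positions (mm).
#' @param heading heading (degrees, [0, 360)).
#' @param step_dist distance travelled since the previous frame (mm);
#'   recomputed from positions when `NULL`; `step_dist[1]` is 0.
#' @return An object of class `track`.
#' @export
track <- function(fish_id, t, x, y, heading, step_dist = NULL,
                  plate_id = "plate1", well_id = "A1",
                  treatment = "control", dose_level = 0L,
                  dose_value = 0, dose_unit = "uM", frame_rate = 60) {
  n <- length(t)
  if (n < 2) stop("track '", fish_id, "': needs at least 2 frames")
  if (any(diff(t) <= 0))
    stop("track '", fish_id, "': time is not strictly increasing")
  if (length(x) != n || length(y) != n || length(heading) != n)
    stop("track '", fish_id, "': array lengths differ")
  if (is.null(step_dist))
    step_dist <- c(0, sqrt(diff(x)^2 + diff(y)^2))
  if (length(step_dist) != n)
    stop("track '", fish_id, "': step_dist length differs")
  if (any(step_dist < 0, na.rm = TRUE))
    stop("track '", fish_id, "': negative step_dist")
  step_dist[1] <- 0
  heading <- heading %% 360
  structure(list(fish_id = as.character(fish_id),
                 plate_id = as.character(plate_id),
                 well_id = as.character(well_id),
                 treatment = as.character(treatment),
                 dose_level = as.integer(dose_level),
                 dose_value = dose_value, dose_unit = dose_unit,
                 frame_rate = frame_rate,
                 t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 heading = as.numeric(heading),
                 step_dist = as.numeric(step_dist)),
            class = "track")
}

#' @exportS3Method base::print
print.track <- function(x, ...) {
  cat(sprintf("<track %s> %s/%s %s dose %d; %d frames @ %g fps, %.1f s\n",
              x$fish_id, x$plate_id, x$well_id, x$treatment, x$dose_level,
              length(x$t), x$frame_rate, max(x$t) - min(x$t)))
  invisible(x)
}

#' Metadata table for a list of tracks
#' @param tracks list of [track()] objects.
#' @return Data frame with one row per fish.
#' @export
track_metadata <- function(tracks) {
  do.call(rbind, lapply(tracks, function(tr)
    data.frame(fish_id = tr$fish_id, plate_id = tr$plate_id,
               well_id = tr$well_id, treatment = tr$treatment,
               dose_level = tr$dose_level, dose_value = tr$dose_value,
               dose_unit = tr$dose_unit)))
}

.track_cols <- c("fish_id", "t_s", "x_mm", "y_mm", "heading_deg", "dist_mm")

#' Read tracking data
#'
#' Two dialects are supported: a tidy long CSV (one file per plate, columns
#' `fish_id, t_s, x_mm, y_mm, heading_deg, dist_mm`) or a directory of
#' per-fish CSVs (same columns minus `fish_id`, taken from the file name).
#' The `dist_mm` column is optional and recomputed from positions when
#' absent.  Rows with missing position are dropped with a message and the
#' step distance is recomputed across the gap.
#'
#' @param path CSV file or directory of per-fish CSVs.
#' @param metadata metadata data frame or path to a metadata CSV with
#'   columns `fish_id, plate_id, well_id, treatment, dose_level,
#'   dose_value, dose_unit`.
#' @param frame_rate acquisition rate (frames/s).
#' @return List of [track()] objects.
#' @export
read_tracks <- function(path, metadata = NULL, frame_rate = 60) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.csv$", full.names = TRUE)
    raw <- do.call(rbind, lapply(files, function(f) {
      d <- utils::read.csv(f)
      d$fish_id <- sub("\\.csv$", "", basename(f))
      d
    }))
  } else {
    raw <- utils::read.csv(path)
  }
  need <- setdiff(.track_cols, c("dist_mm", if (!is.null(raw$fish_id)) "fish_id"))
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("tracking file missing column(s): ", paste(miss, collapse = ", "))
  if (is.character(metadata)) metadata <- utils::read.csv(metadata)
  lapply(split(raw, raw$fish_id), function(d) {
    d <- d[order(seq_len(nrow(d))), ]
    bad <- is.na(d$x_mm) | is.na(d$y_mm) | is.na(d$t_s)
    if (any(bad)) {
      message("fish ", d$fish_id[1], ": dropping ", sum(bad),
              " frame(s) with missing position")
      d <- d[!bad, , drop = FALSE]
    }
    if (any(diff(d$t_s) <= 0))
      stop("fish ", d$fish_id[1], ": time is not strictly increasing")
    sd <- if (!is.null(d$dist_mm) && !any(bad)) d$dist_mm else NULL
    meta <- list(plate_id = "plate1", well_id = "A1", treatment = "control",
                 dose_level = 0L, dose_value = 0, dose_unit = "uM")
    if (!is.null(metadata)) {
      m <- metadata[metadata$fish_id == d$fish_id[1], , drop = FALSE]
      if (nrow(m) == 1)
        meta <- list(plate_id = m$plate_id, well_id = m$well_id,
                     treatment = m$treatment, dose_level = m$dose_level,
                     dose_value = m$dose_value, dose_unit = m$dose_unit)
    }
    track(d$fish_id[1], t = d$t_s, x = d$x_mm, y = d$y_mm,
          heading = d$heading_deg, step_dist = sd,
          plate_id = meta$plate_id, well_id = meta$well_id,
          treatment = meta$treatment, dose_level = meta$dose_level,
          dose_value = meta$dose_value, dose_unit = meta$dose_unit,
          frame_rate = frame_rate)
  })
}

#' Write tracks to the tidy long CSV dialect
#' @param tracks list of [track()] objects.
#' @param path output CSV path.
#' @param metadata_path optional path for the companion metadata CSV.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(tracks, path, metadata_path = NULL) {
  long <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(fish_id = tr$fish_id, t_s = tr$t, x_mm = tr$x, y_mm = tr$y,
               heading_deg = tr$heading, dist_mm = tr$step_dist)))
  utils::write.csv(long, path, row.names = FALSE)
  if (!is.null(metadata_path))
    utils::write.csv(track_metadata(tracks), metadata_path, row.names = FALSE)
  invisible(path)
}
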