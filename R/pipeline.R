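#' Run configuration for the two pipeline arms
#'
#' Collects paths, thresholds and seeds for [run_behavior()] and
#' [run_phospho()].  Every stochastic stage has an explicit seed and the
#' configuration round-trips through YAML; output tables carry a hash of
#' the configuration in a header comment so reruns are verifiable.
#'
#' @param tracks,metadata,phospho,network,universe input paths (tracking
#'   CSV + metadata CSV; phosphopeptide TSV; edge-list TSV; universe
#'   list, one accession per line).  Unused entries may stay `NULL`.
#' @param schedule_path optional schedule YAML (default schedule used
#'   when `NULL`).
#' @param geometry named list `x_min, x_max, y_min, y_max,
#'   inner_fraction`.
#' @param assignment named list drug -> class ("AA"/"other"/"test").
#' @param putative named list: putative class of each test drug.
#' @param frame_rate acquisition rate of the tracking data (frames/s).
#' @param eps,ratio_thresh,p_thresh,k_min,k_high,w_high,B thresholds (see
#'   the respective stage functions).
#' @param seed integer seed used by all stochastic stages.
#' @return Object of class `run_config`.
#' @export
run_config <- function(tracks = NULL, metadata = NULL, phospho = NULL,
                       network = NULL, universe = NULL,
                       schedule_path = NULL,
                       geometry = list(x_min = 0, x_max = 9, y_min = 0,
                                       y_max = 9, inner_fraction = 0.4),
                       assignment = as.list(default_assignment()),
                       putative = list(), frame_rate = 60,
                       eps = 0, ratio_thresh = 2, p_thresh = 0.05,
                       k_min = 7, k_high = 3, w_high = 0.04,
                       B = 1000, seed = 1) {
  if (B < 1) stop("B must be a positive number of background replicates")
  structure(list(tracks = tracks, metadata = metadata, phospho = phospho,
                 network = network, universe = universe,
                 schedule_path = schedule_path, geometry = geometry,
                 assignment = assignment, putative = putative,
                 frame_rate = frame_rate, eps = eps,
                 ratio_thresh = ratio_thresh, p_thresh = p_thresh,
                 k_min = k_min, k_high = k_high, w_high = w_high,
                 B = B, seed = seed),
            class = "run_config")
}

#' Read / write a run configuration as YAML
#' @param path YAML path.
#' @rdname config_yaml
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

#' @param config a [run_config()].
#' @rdname config_yaml
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# rolling polynomial hash of the YAML rendering of the config
# (dependency-free, 31-bit so it stays in exact double arithmetic)
config_hash <- function(config) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(config)))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% (2^31 - 1)
  sprintf("%08x", h)
}

# write a table with the config hash as a header comment
.write_stamped <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by the pipeline (skipping the hash header)
#' @param path CSV path.
#' @return Data frame.
#' @export
read_stamped <- function(path) utils::read.csv(path, comment.char = "#")

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the behavioural arm end to end
#'
#' read tracks -> derive windows -> extract features -> normalize to
#' plate controls -> rank-sum statistics -> train classifiers -> paired
#' ROC.  All intermediate tables are written to `out_dir` with the
#' configuration hash stamped in a header comment.
#'
#' @param config a [run_config()] with `tracks` and `metadata` set.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, list with `features`, `normalized`, `stats`,
#'   `auc` data frames.
#' @export
run_behavior <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  sched <- .stage("schedule",
    if (is.null(config$schedule_path)) stimulus_schedule()
    else read_schedule(config$schedule_path))
  tracks <- .stage("read_tracks", {
    if (is.null(config$tracks) || !file.exists(config$tracks))
      stop("tracking file not found: ", config$tracks %||% "<unset>")
    read_tracks(config$tracks, config$metadata,
                frame_rate = config$frame_rate)
  })
  geom <- do.call(well_geometry, config$geometry)
  windows <- battery_windows(sched)
  feats <- .stage("extract_features",
    extract_feature_table(tracks, windows, geom, eps = config$eps))
  norm <- .stage("normalize", normalize_to_controls(feats))
  stats_tab <- .stage("stats", {
    drugs <- setdiff(unique(norm$treatment[norm$dose_level > 0]), character())
    do.call(rbind, lapply(drugs, function(dr) {
      sub <- norm[norm$treatment == dr | norm$dose_level == 0, , drop = FALSE]
      st <- feature_stats_table(sub)
      cbind(treatment = dr, st)
    }))
  })
  auc <- .stage("classify", {
    assignment <- unlist(config$assignment)
    mats <- lapply(c(SRB = "SRB", PSRB = "PSRB"), function(w)
      build_training_matrix(norm, assignment, w))
    models <- lapply(mats, train_models, seed = config$seed)
    if (length(config$putative) && nrow(mats$SRB$test))
      auc_summary(models, mats, unlist(config$putative))
    else data.frame(drug = character(), model = character(),
                    window = character(), auc = numeric(),
                    call = character())
  })
  .write_stamped(feats, file.path(out_dir, "features.csv"), hash)
  .write_stamped(norm, file.path(out_dir, "features_normalized.csv"), hash)
  .write_stamped(stats_tab, file.path(out_dir, "stats.csv"), hash)
  .write_stamped(auc, file.path(out_dir, "auc_summary.csv"), hash)
  invisible(list(features = feats, normalized = norm, stats = stats_tab,
                 auc = auc))
}

#' Run the phosphoproteomics arm end to end
#'
#' merge -> missingness filter -> rank-product test -> differential set
#' -> hub candidates -> background null -> significance.
#'
#' @param config a [run_config()] with `phospho`, `network`, `universe`
#'   set.
#' @param out_dir output directory.
#' @return Invisibly, list with `results` (per-entry differential table),
#'   `diff_set`, `hubs`.
#' @export
run_phospho <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(config)
  tab <- .stage("read_phospho", {
    if (is.null(config$phospho) || !file.exists(config$phospho))
      stop("phospho table not found: ", config$phospho %||% "<unset>")
    read_phospho(config$phospho)
  })
  merged <- .stage("merge", merge_entries(tab))
  kept <- .stage("filter", filter_missing(merged))
  res <- .stage("rank_product",
    rank_product_test(kept, B = config$B, seed = config$seed))
  dset <- .stage("differential",
    differential_set(res, config$ratio_thresh, config$p_thresh))
  hubs <- .stage("hubs", {
    net <- read_network(config$network)
    universe <- readLines(config$universe)
    if (!length(dset)) {
      warning("empty differential set; hub table will be empty")
      hub_scan(net, character(), universe, candidates = character(),
               B = config$B, seed = config$seed)
    } else {
      hub_scan(net, dset, universe, k_min = config$k_min,
               k_high = config$k_high, w_high = config$w_high,
               B = config$B, seed = config$seed)
    }
  })
  .write_stamped(res, file.path(out_dir, "differential.csv"), hash)
  .write_stamped(data.frame(protein = dset),
                 file.path(out_dir, "differential_set.csv"), hash)
  .write_stamped(hubs, file.path(out_dir, "hubs.csv"), hash)
  invisible(list(results = res, diff_set = dset, hubs = hubs))
}
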