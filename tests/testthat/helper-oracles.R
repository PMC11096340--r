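# Independent, deliberately naive reference implementations used as
# oracles.  These share no code with the package: everything is plain
# loops and first-principles formulas.

# --- behavioural features ---------------------------------------------------

oracle_smaller_angle <- function(a, b) {
  d <- abs(b - a)
  d <- d %% 360
  if (d > 180) 360 - d else d
}

oracle_features <- function(tr, win, geom, eps = 0) {
  idx <- which(tr$t >= win$start_s - 1e-9 & tr$t < win$end_s - 1e-9)
  dt <- 1 / tr$frame_rate
  cx <- (geom$x_min + geom$x_max) / 2
  cy <- (geom$y_min + geom$y_max) / 2
  hw <- geom$inner_fraction * (geom$x_max - geom$x_min) / 2
  hh <- geom$inner_fraction * (geom$y_max - geom$y_min) / 2
  dist <- 0; pause <- 0; turn <- 0; t_out <- 0; d_out <- 0
  bout_maxes <- c(); cur_max <- NULL
  for (j in seq_along(idx)) {
    i <- idx[j]
    s <- tr$step_dist[i]
    dist <- dist + s
    if (s <= eps) {
      pause <- pause + dt
      if (!is.null(cur_max)) { bout_maxes <- c(bout_maxes, cur_max); cur_max <- NULL }
    } else {
      v <- s / dt
      cur_max <- if (is.null(cur_max)) v else max(cur_max, v)
    }
    if (j > 1)
      turn <- turn + oracle_smaller_angle(tr$heading[idx[j - 1]], tr$heading[i])
    inside <- tr$x[i] >= cx - hw && tr$x[i] <= cx + hw &&
              tr$y[i] >= cy - hh && tr$y[i] <= cy + hh
    if (!inside) { t_out <- t_out + dt; d_out <- d_out + s }
  }
  if (!is.null(cur_max)) bout_maxes <- c(bout_maxes, cur_max)
  list(distance_mm = dist,
       turning_rel = if (dist > 0) turn / dist else NA_real_,
       pause_s = pause,
       spurt_mms = if (length(bout_maxes)) mean(bout_maxes) else NA_real_,
       thigmo_time = t_out / (length(idx) * dt),
       thigmo_dist = if (dist > 0) d_out / dist else NA_real_)
}

# random piecewise track with pauses, wraps and wall contact; arbitrary
# data (not from the simulator) so the oracle comparison is adversarial
random_track <- function(n = 200, frame_rate = 5, geom = well_geometry()) {
  s <- ifelse(runif(n) < 0.3, 0, rexp(n, 1))
  s[1] <- 0
  h <- runif(n, 0, 360)
  x <- pmin(pmax(cumsum(rnorm(n, 0, 1)) + 5, geom$x_min), geom$x_max)
  y <- pmin(pmax(cumsum(rnorm(n, 0, 1)) + 5, geom$y_min), geom$y_max)
  track(paste0("rf", sample.int(1e6, 1)), t = (0:(n - 1)) / frame_rate,
        x = x, y = y, heading = h, step_dist = s, frame_rate = frame_rate)
}

# --- rank statistics --------------------------------------------------------

# exact two-sided rank-sum p by enumeration of all splits
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  obs <- sum(rank(pooled)[seq_len(n1)])
  splits <- utils::combn(length(pooled), n1)
  stats_all <- apply(splits, 2, function(i) sum(rank(pooled)[i]))
  mu <- mean(stats_all)
  mean(abs(stats_all - mu) >= abs(obs - mu) - 1e-9)
}

# BH step-up from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# rank-product p by full enumeration of non-identity 3v3 label splits,
# pooled across entries (independent re-derivation)
oracle_rp_p <- function(xm) {
  rp_of <- function(wt, ko, up = TRUE) {
    fc <- matrix(NA_real_, nrow(wt), 9)
    k <- 0
    for (r in 1:3) for (s in 1:3) {
      k <- k + 1
      fc[, k] <- log(ko[, r]) - log(wt[, s])
    }
    if (up) fc <- -fc
    rk <- apply(fc, 2, rank)
    apply(rk, 1, function(v) exp(mean(log(v))))
  }
  obs_up <- rp_of(xm[, 1:3], xm[, 4:6], TRUE)
  obs_down <- rp_of(xm[, 1:3], xm[, 4:6], FALSE)
  splits <- utils::combn(6, 3)
  null_up <- c(); null_down <- c()
  for (b in seq_len(ncol(splits))) {
    ko_i <- splits[, b]
    if (identical(ko_i, 4:6)) next
    wt_i <- setdiff(1:6, ko_i)
    null_up <- c(null_up, rp_of(xm[, wt_i, drop = FALSE],
                                xm[, ko_i, drop = FALSE], TRUE))
    null_down <- c(null_down, rp_of(xm[, wt_i, drop = FALSE],
                                    xm[, ko_i, drop = FALSE], FALSE))
  }
  list(p_up = sapply(obs_up, function(v) (1 + sum(null_up <= v)) /
                       (length(null_up) + 1)),
       p_down = sapply(obs_down, function(v) (1 + sum(null_down <= v)) /
                         (length(null_down) + 1)))
}

# --- hypergeometric upper tail by direct enumeration ------------------------

oracle_hyper_upper <- function(N, K, n, k) {
  tot <- choose(N, n)
  sum(sapply(k:min(K, n), function(j)
    choose(K, j) * choose(N - K, n - j))) / tot
}

# --- AUC by brute-force pair counting ---------------------------------------

oracle_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# --- shared fixtures --------------------------------------------------------

# short schedule used throughout the tests: real 60-s startle minute,
# shortened acclimation/recovery, 10 fps
test_schedule <- function(n_cycles = 1, psrb_s = 600)
  stimulus_schedule(acclimation_s = 5, n_cycles = n_cycles,
                    intermission_s = psrb_s, psrb_s = psrb_s)

# hand-built normalized feature table (gaussian clouds) for classifier
# tests: AA-like drugs shifted one way, other-like the opposite
toy_norm_table <- function(drugs, n_fish = 15, cycles = 1, shift = 30,
                           labels = c("SRB", "PSRB"), seed = 1) {
  set.seed(seed)
  rows <- list()
  for (d in names(drugs)) {
    dir <- switch(drugs[[d]], AA = -1, other = 1, 0)
    for (i in seq_len(n_fish)) for (lab in labels) for (cy in seq_len(cycles))
      rows[[length(rows) + 1]] <- data.frame(
        fish_id = sprintf("%s_%03d", d, i), plate_id = "p1", treatment = d,
        dose_level = sample(1:3, 1), label = lab, cycle = cy,
        distance_mm = rnorm(1, dir * shift, 10),
        turning_rel = rnorm(1, -dir * shift, 10),
        pause_s = rnorm(1, dir * shift, 10),
        spurt_mms = rnorm(1, dir * shift, 10),
        thigmo_time = rnorm(1, dir * shift / 3, 5),
        thigmo_dist = rnorm(1, dir * shift / 3, 5))
  }
  do.call(rbind, rows)
}
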