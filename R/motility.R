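#' Relative motility index
#'
#' Percent change of treated motility versus control motility measured on
#' the same plate: `100 * (Mcx - Mc0) / Mc0`.
#'
#' @param mcx treated motility (mm).  Vectorized.
#' @param mc0 control motility (mm); must be positive.
#' @return percent.
#' @export
motility_index <- function(mcx, mc0) {
  if (any(mc0 <= 0)) stop("control motility must be positive")
  100 * (mcx - mc0) / mc0
}

#' Binned motility series for one fish
#'
#' Sums step distance into fixed-width time bins across a window.
#'
#' @param track a [track()].
#' @param window one row of [battery_windows()].
#' @param bin_s bin width in seconds (default 1).
#' @return Data frame `fish_id`, `cycle`, `rel_s` (bin start, seconds from
#'   window onset), `M` (mm per bin).
#' @export
motility_series <- function(track, window, bin_s = 1) {
  i <- .window_idx(track, window)
  rel <- track$t[i] - window$start_s
  bin <- floor(rel / bin_s) * bin_s
  m <- tapply(track$step_dist[i], bin, sum)
  data.frame(fish_id = track$fish_id, cycle = window$cycle,
             rel_s = as.numeric(names(m)), M = as.numeric(m),
             row.names = NULL)
}

#' Relative peak analysis over the startle minute
#'
#' For each of the six peak clusters P1-P6 the mean treated motility is
#' compared to the mean control motility via [motility_index()], pooling
#' all cycles.
#'
#' @param treated,control data frames of binned motility (rows from
#'   [motility_series()] over the SRB windows, concatenated across fish
#'   and cycles).
#' @param peaks peak definition, default [peak_windows()].
#' @return Data frame `peak`, `mi_percent`, `n_treated`, `n_control`.
#' @export
relative_peak_analysis <- function(treated, control, peaks = peak_windows()) {
  if (is.null(control) || nrow(control) == 0) stop("empty control group")
  out <- do.call(rbind, lapply(seq_len(nrow(peaks)), function(j) {
    p <- peaks[j, ]
    ti <- treated$rel_s >= p$start_s & treated$rel_s < p$end_s
    ci <- control$rel_s >= p$start_s & control$rel_s < p$end_s
    data.frame(peak = p$peak,
               mi_percent = motility_index(mean(treated$M[ti]),
                                           mean(control$M[ci])),
               n_treated = sum(ti), n_control = sum(ci))
  }))
  rownames(out) <- NULL
  out
}

#' Rank-sum tests against control with Benjamini-Hochberg adjustment
#'
#' Two-sided Wilcoxon rank-sum test of each dose group against the control
#' group; p-values are BH-adjusted across the whole comparison family
#' passed in (all doses, and all features when called through
#' [feature_stats_table()]).
#'
#' @param x numeric values.
#' @param g grouping vector (dose levels); `control` names the reference.
#' @param control reference level of `g` (default `0`).
#' @return Data frame `group`, `n`, `estimate` (difference of medians vs
#'   control), `p_raw`, `p_adj`.
#' @export
ranksum_bh <- function(x, g, control = 0) {
  g <- as.character(g)
  ctrl <- x[g == as.character(control)]
  if (length(ctrl) < 2) stop("need >= 2 control observations")
  lev <- setdiff(unique(g), as.character(control))
  out <- do.call(rbind, lapply(lev, function(l) {
    xi <- x[g == l]
    p <- if (all(is.na(xi)) || length(xi) < 2) NA_real_ else if
      (length(unique(c(xi, ctrl))) == 1) 1 else
      suppressWarnings(stats::wilcox.test(xi, ctrl)$p.value)
    data.frame(group = l, n = sum(!is.na(xi)),
               estimate = stats::median(xi, na.rm = TRUE) -
                          stats::median(ctrl, na.rm = TRUE),
               p_raw = p)
  }))
  out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-feature dose-response statistics for one panel
#'
#' Runs [ranksum_bh()] for every behavioural feature of a normalized
#' feature table, one treatment at a time, with BH adjustment across the
#' full feature x dose family of that panel.
#'
#' @param norm normalized feature table ([normalize_to_controls()]),
#'   subset to one treatment plus its plate controls.
#' @return Data frame `feature`, `group`, `n`, `estimate`, `p_raw`, `p_adj`.
#' @export
feature_stats_table <- function(norm) {
  res <- do.call(rbind, lapply(.feature_cols, function(f) {
    r <- ranksum_bh(norm[[f]], norm$dose_level)
    r$feature <- f
    r
  }))
  res$p_adj <- stats::p.adjust(res$p_raw, method = "BH")
  res[, c("feature", "group", "n", "estimate", "p_raw", "p_adj")]
}

#' ANOVA with post-hoc contrasts
#'
#' One-way ANOVA with Tukey HSD, or two-way ANOVA with Dunnett contrasts
#' of the treatment factor against its first level.
#'
#' @param x response values.
#' @param g treatment factor.
#' @param block second factor for the two-way design.
#' @param design `"oneway_tukey"` or `"twoway_dunnett"`.
#' @return List with `anova_p` (F-test p for `g`) and `posthoc` (data
#'   frame `contrast`, `estimate`, `p_adj`; family-wise adjusted).
#' @export
anova_posthoc <- function(x, g, block = NULL,
                          design = c("oneway_tukey", "twoway_dunnett")) {
  design <- match.arg(design)
  g <- factor(g)
  if (nlevels(g) < 2) stop("need >= 2 groups")
  if (design == "oneway_tukey") {
    fit <- stats::aov(x ~ g)
    tab <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$g
    posthoc <- data.frame(contrast = rownames(tk), estimate = tk[, "diff"],
                          p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    if (is.null(block)) stop("twoway_dunnett requires a block factor")
    block <- factor(block)
    dat <- data.frame(x = x, g = g, block = block)
    fit <- stats::aov(x ~ g + block, data = dat)
    tab <- summary(fit)[[1]]
    gl <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Dunnett"))
    sm <- summary(gl)
    posthoc <- data.frame(contrast = names(sm$test$coefficients),
                          estimate = as.numeric(sm$test$coefficients),
                          p_adj = as.numeric(sm$test$pvalues),
                          row.names = NULL)
  }
  list(anova_p = tab[["Pr(>F)"]][1], posthoc = posthoc)
}
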