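#' Simulate a phosphopeptide intensity table with planted differentials
#'
#' Intensities are log-normal (2 genotypes x 3 replicates); a planted
#' subset is shifted by `effect_fold` in the KO genotype (alternating up
#' and down); a fraction of entries is duplicated across gel slices (to
#' exercise merging) and values go missing completely at random.
#'
#' @param n_entries number of unique phosphopeptide entries.
#' @param n_true number of planted differential entries.
#' @param effect_fold KO/WT fold change of planted entries (> 1).
#' @param missing_rate per-cell missingness probability.
#' @param dup_rate fraction of entries split across two gel slices.
#' @param rep_sdlog replicate noise on the log scale.
#' @param seed integer seed.
#' @return List with `table` (phosphopeptide data frame, one row per
#'   entry x slice) and `truth` (`key`, `protein`, `true_diff`,
#'   `direction`).
#' @export
simulate_phosphoproteome <- function(n_entries = 500, n_true = 20,
                                     effect_fold = 4, missing_rate = 0.1,
                                     dup_rate = 0.15, rep_sdlog = 0.25,
                                     seed = 1) {
  stopifnot(n_true <= n_entries, effect_fold > 1)
  set.seed(seed)
  protein <- sprintf("P%05d", seq_len(n_entries))
  sequence <- vapply(seq_len(n_entries), function(i)
    paste0(paste(sample(c("A", "C", "D", "E", "G", "K", "L", "S", "T"),
                        10, replace = TRUE), collapse = ""), "K"),
    character(1))
  site_positions <- vapply(seq_len(n_entries), function(i)
    paste(sort(sample(1:11, sample(1:2, 1))), collapse = ";"), character(1))
  true_idx <- sample.int(n_entries, n_true)
  direction <- rep(0L, n_entries)
  direction[true_idx] <- rep_len(c(1L, -1L), n_true)
  base <- stats::rnorm(n_entries, 17, 1.5)   # log-scale abundance
  make_side <- function(shift)
    vapply(1:3, function(r)
      exp(base + shift + stats::rnorm(n_entries, 0, rep_sdlog)),
      numeric(n_entries))
  wt <- make_side(0)
  ko <- make_side(direction * log(effect_fold))
  tab <- data.frame(sequence = sequence, protein = protein,
                    site_positions = site_positions,
                    slice = sample.int(5, n_entries, replace = TRUE))
  tab[.wt_cols] <- wt
  tab[.ko_cols] <- ko
  # split a fraction of entries across two slices (intensity halves sum
  # back to the original on merging)
  dup <- sample.int(n_entries, round(dup_rate * n_entries))
  if (length(dup)) {
    frac <- stats::runif(length(dup), 0.3, 0.7)
    extra <- tab[dup, , drop = FALSE]
    extra$slice <- (extra$slice %% 5L) + 1L
    for (cc in .int_cols) {
      extra[[cc]] <- tab[[cc]][dup] * (1 - frac)
      tab[[cc]][dup] <- tab[[cc]][dup] * frac
    }
    tab <- rbind(tab, extra)
  }
  for (cc in .int_cols)
    tab[[cc]][stats::runif(nrow(tab)) < missing_rate] <- NA_real_
  rownames(tab) <- NULL
  truth <- data.frame(key = paste(sequence, protein, site_positions,
                                  sep = "|"),
                      protein = protein,
                      true_diff = direction != 0L, direction = direction)
  list(table = tab, truth = truth)
}

#' Simulate an interaction network with planted hubs
#'
#' An Erdos-Renyi background with uniform weights in (0, 0.1]; planted
#' hub nodes receive `density_boost`-fold edge probability toward the
#' planted differential set (hubs are members of that set, so they are
#' candidates under the default candidate rule).
#'
#' @param n_nodes number of proteins in the universe.
#' @param mean_degree expected background degree.
#' @param n_hubs number of planted hubs.
#' @param diff_size size of the planted differential set (>= `n_hubs`).
#' @param density_boost edge-probability multiplier from hubs into the
#'   differential set (> 1; 1 plants no signal).
#' @param seed integer seed.
#' @return List with `network` ([interaction_network()]), `universe`,
#'   `diff_set`, and `truth` (`protein`, `is_hub`).
#' @export
simulate_network <- function(n_nodes = 500, mean_degree = 100, n_hubs = 5,
                             diff_size = 100, density_boost = 3, seed = 1) {
  stopifnot(n_hubs <= diff_size, diff_size <= n_nodes, density_boost >= 1)
  set.seed(seed)
  nodes <- sprintf("N%04d", seq_len(n_nodes))
  p <- mean_degree / (n_nodes - 1)
  pairs <- t(utils::combn(n_nodes, 2))
  diff_idx <- sample.int(n_nodes, diff_size)
  hub_idx <- diff_idx[seq_len(n_hubs)]
  p_edge <- rep(p, nrow(pairs))
  boosted <- (pairs[, 1] %in% hub_idx & pairs[, 2] %in% diff_idx) |
             (pairs[, 2] %in% hub_idx & pairs[, 1] %in% diff_idx)
  p_edge[boosted] <- pmin(1, p * density_boost)
  keep <- stats::runif(nrow(pairs)) < p_edge
  edges <- data.frame(protein_a = nodes[pairs[keep, 1]],
                      protein_b = nodes[pairs[keep, 2]],
                      weight = stats::runif(sum(keep), 0, 0.1))
  edges$weight[edges$weight == 0] <- 0.05
  list(network = interaction_network(edges),
       universe = nodes,
       diff_set = nodes[diff_idx],
       truth = data.frame(protein = nodes,
                          is_hub = seq_len(n_nodes) %in% hub_idx,
                          in_diff = seq_len(n_nodes) %in% diff_idx))
}
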