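.wt_cols <- paste0("WT_", 1:3)
.ko_cols <- paste0("KO_", 1:3)
.int_cols <- c(.wt_cols, .ko_cols)

#' Read / write a phosphopeptide intensity table
#'
#' Tab-separated, columns `sequence`, `protein`, `site_positions`
#' (semicolon-separated residue positions), `slice`, `WT_1..WT_3`,
#' `KO_1..KO_3`; empty cells are missing intensities.
#'
#' @param path TSV path.
#' @rdname phospho_io
#' @export
read_phospho <- function(path) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  miss <- setdiff(c("sequence", "protein", "site_positions", "slice",
                    .int_cols), names(d))
  if (length(miss))
    stop("phospho table missing column(s): ", paste(miss, collapse = ", "))
  for (cc in .int_cols) d[[cc]] <- as.numeric(d[[cc]])
  d
}

#' @param table phosphopeptide data frame.
#' @rdname phospho_io
#' @export
write_phospho <- function(table, path) {
  utils::write.table(table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

.n_sites <- function(site_positions)
  lengths(strsplit(as.character(site_positions), ";", fixed = TRUE))

.entry_key <- function(d)
  paste(d$sequence, d$protein, d$site_positions, sep = "|")

#' Merge identical phosphopeptide entries across gel slices
#'
#' Entries with identical peptide sequence, protein accession and
#' phospho-site positions are merged by summing their per-replicate
#' intensities over the available values; a replicate stays missing only
#' when it is missing in every merged entry.
#'
#' @param entries phosphopeptide data frame (see [read_phospho()]).
#' @return One row per unique (sequence, protein, site_positions) key,
#'   `slice` dropped, with an `n_sites` column.
#' @export
merge_entries <- function(entries) {
  key <- .entry_key(entries)
  ns <- .n_sites(entries$site_positions)
  if (any(tapply(ns, key, function(v) length(unique(v))) > 1))
    stop("conflicting n_sites within an entry key")
  rows <- lapply(split(seq_along(key), key), function(i) {
    out <- entries[i[1], c("sequence", "protein", "site_positions"),
                   drop = FALSE]
    for (cc in .int_cols) {
      v <- entries[[cc]][i]
      out[[cc]] <- if (all(is.na(v))) NA_real_ else sum(v, na.rm = TRUE)
    }
    out
  })
  out <- do.call(rbind, rows)
  out$n_sites <- .n_sites(out$site_positions)
  rownames(out) <- NULL
  out
}

#' Remove entries with too many missing replicates
#'
#' An entry is removed when either genotype has more than one missing
#' intensity across its three replicates.
#'
#' @param entries merged phosphopeptide data frame.
#' @return Filtered data frame; removed keys and the offending genotype
#'   are attached as attribute `"removed"` and reported via [message()].
#' @export
filter_missing <- function(entries) {
  miss_wt <- rowSums(is.na(entries[, .wt_cols, drop = FALSE]))
  miss_ko <- rowSums(is.na(entries[, .ko_cols, drop = FALSE]))
  drop <- miss_wt > 1 | miss_ko > 1
  removed <- data.frame(key = .entry_key(entries)[drop],
                        genotype = ifelse(miss_wt[drop] > 1, "WT", "KO"))
  if (nrow(removed))
    message("filter_missing: removed ", nrow(removed),
            " entr", if (nrow(removed) == 1) "y" else "ies",
            " with > 1 missing replicate")
  out <- entries[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- removed
  out
}

# rank-product statistics for a 2-class intensity matrix.
# fc[i, (r,s)] = log KO_r - log WT_s over all replicate pairs; per
# comparison the entries with both cells present are ranked (rank 1 =
# most extreme in the tested direction) and RP is the geometric mean of
# the ranks over the entry's available comparisons.  "up" = KO > WT.
.rp_stat <- function(wt, ko) {
  n <- nrow(wt)
  pairs <- expand.grid(r = seq_len(ncol(ko)), s = seq_len(ncol(wt)))
  lr_up <- matrix(NA_real_, n, nrow(pairs))
  for (j in seq_len(nrow(pairs)))
    lr_up[, j] <- log(ko[, pairs$r[j]]) - log(wt[, pairs$s[j]])
  rp_dir <- function(fc) {
    rk <- apply(fc, 2, rank, na.last = "keep")
    rk <- matrix(rk, nrow = n)
    exp(rowMeans(log(rk), na.rm = TRUE))
  }
  list(up = rp_dir(-lr_up), down = rp_dir(lr_up))  # rank 1 = most extreme
}

#' Two-class rank-product test with permutation p-values
#'
#' For every entry and each direction (up = higher in KO, down = lower in
#' KO), the rank product is the geometric mean of the entry's fold-change
#' ranks over all KO x WT replicate-pair comparisons.  Significance comes
#' from a sample-label permutation null pooled across entries: group
#' labels are reassigned (all non-identity splits enumerated exhaustively
#' when there are at most `B`, otherwise `B` random splits), the rank
#' products recomputed, and `p = (1 + #(null RP <= observed)) /
#' (#null + 1)`.  For the 3-vs-3 design the 19 non-identity splits are
#' always enumerated, so p-values are deterministic.
#'
#' @param entries merged, filtered phosphopeptide data frame.
#' @param B maximum number of label permutations (default 1000).
#' @param seed integer seed (only used when splits are sampled).
#' @return Data frame: entry key columns, `ratio` (mean KO / mean WT
#'   intensity), `rp_up`, `rp_down`, `p_up`, `p_down`.  Entries with no
#'   complete replicate pair get `NA` statistics.
#' @export
rank_product_test <- function(entries, B = 1000, seed = NULL) {
  if (nrow(entries) < 2) stop("need >= 2 entries")
  if (B < 100) stop("B must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  xm <- as.matrix(entries[, .int_cols, drop = FALSE])
  obs <- .rp_stat(xm[, .wt_cols, drop = FALSE], xm[, .ko_cols, drop = FALSE])

  splits <- utils::combn(6L, 3L)                    # columns taken as "KO"
  identity <- which(apply(splits, 2, identical, y = 4:6))
  splits <- splits[, -identity, drop = FALSE]
  if (ncol(splits) > B)
    splits <- splits[, sample.int(ncol(splits), B), drop = FALSE]
  null_up <- null_down <- vector("list", ncol(splits))
  for (b in seq_len(ncol(splits))) {
    ko_i <- splits[, b]
    wt_i <- setdiff(1:6, ko_i)
    rp <- .rp_stat(xm[, wt_i, drop = FALSE], xm[, ko_i, drop = FALSE])
    null_up[[b]] <- rp$up
    null_down[[b]] <- rp$down
  }
  null_up <- unlist(null_up); null_down <- unlist(null_down)
  p_of <- function(o, null) {
    null <- null[!is.na(null)]
    vapply(o, function(v) if (is.na(v)) NA_real_ else
      (1 + sum(null <= v)) / (length(null) + 1), numeric(1))
  }
  mean_wt <- rowMeans(xm[, .wt_cols, drop = FALSE], na.rm = TRUE)
  mean_ko <- rowMeans(xm[, .ko_cols, drop = FALSE], na.rm = TRUE)
  data.frame(entries[, c("sequence", "protein", "site_positions"),
                     drop = FALSE],
             ratio = mean_ko / mean_wt,
             rp_up = obs$up, rp_down = obs$down,
             p_up = p_of(obs$up, null_up),
             p_down = p_of(obs$down, null_down),
             row.names = NULL)
}

#' Threshold the rank-product results into the differential set
#'
#' An entry is differential when its KO/WT intensity ratio exceeds
#' `ratio_thresh` (or falls below its reciprocal) and the
#' direction-matched rank-product p-value is below `p_thresh`.
#'
#' @param results output of [rank_product_test()].
#' @param ratio_thresh fold-change gate (default 2; some analyses use 1.5).
#' @param p_thresh p-value gate (default 0.05).
#' @param mode `"protein"` collapses to unique protein accessions,
#'   `"peptide"` keeps per-peptide rows.
#' @return Character vector of protein accessions, or the significant
#'   rows when `mode = "peptide"`.
#' @export
differential_set <- function(results, ratio_thresh = 2, p_thresh = 0.05,
                             mode = c("protein", "peptide")) {
  mode <- match.arg(mode)
  sig <- (!is.na(results$ratio)) &
    ((results$ratio > ratio_thresh & !is.na(results$p_up) &
        results$p_up < p_thresh) |
     (results$ratio < 1 / ratio_thresh & !is.na(results$p_down) &
        results$p_down < p_thresh))
  if (mode == "protein") unique(results$protein[sig])
  else results[sig, , drop = FALSE]
}
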