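.entry <- function(seq, prot, sites, slice, wt, ko) {
  d <- data.frame(sequence = seq, protein = prot, site_positions = sites,
                  slice = slice)
  d[phenoscreen:::.wt_cols] <- as.list(wt)
  d[phenoscreen:::.ko_cols] <- as.list(ko)
  d
}

test_that("merging sums replicate intensities across slices", {
  two <- rbind(.entry("PEPK", "P1", "3", 1, c(100, 200, NA), c(10, 20, 30)),
               .entry("PEPK", "P1", "3", 2, c(50, 50, 50), c(1, 2, NA)))
  m <- merge_entries(two)
  expect_equal(nrow(m), 1)
  expect_equal(unlist(m[phenoscreen:::.wt_cols], use.names = FALSE),
               c(150, 250, 50))
  expect_equal(unlist(m[phenoscreen:::.ko_cols], use.names = FALSE),
               c(11, 22, 30))
  # value stays missing only when missing everywhere
  both_na <- rbind(.entry("A", "P2", "1", 1, c(NA, 1, 1), c(1, 1, 1)),
                   .entry("A", "P2", "1", 2, c(NA, 1, 1), c(1, 1, 1)))
  expect_true(is.na(merge_entries(both_na)$WT_1))
  # single entries pass through unchanged
  one <- .entry("B", "P3", "2;5", 4, c(1, 2, 3), c(4, 5, 6))
  m1 <- merge_entries(one)
  expect_equal(m1$n_sites, 2)
  expect_equal(unlist(m1[phenoscreen:::.int_cols], use.names = FALSE),
               1:6 + 0)
})

test_that("merge is idempotent, order-invariant and counts keys", {
  set.seed(6)
  fix <- do.call(rbind, lapply(1:20, function(i)
    .entry(paste0("SEQ", ((i - 1) %% 17) + 1), "P1",
           as.character(((i - 1) %% 17) + 1), ((i - 1) %/% 17) + 1,
           runif(3, 10, 100), runif(3, 10, 100))))
  m <- merge_entries(fix)
  expect_equal(nrow(m), 17)       # 20 rows, 3 duplicated keys
  dupkey <- paste0("SEQ", 1)
  expect_equal(m$WT_1[m$sequence == dupkey],
               sum(fix$WT_1[fix$sequence == dupkey]))
  expect_equal(merge_entries(m)[phenoscreen:::.int_cols],
               m[phenoscreen:::.int_cols])
  shuf <- fix[sample(nrow(fix)), ]
  m2 <- merge_entries(shuf)
  expect_equal(m2[order(m2$sequence), ], m[order(m$sequence), ],
               ignore_attr = TRUE)
  conf <- rbind(.entry("S", "P9", "1;2", 1, 1:3, 1:3),
                .entry("S", "P9", "1;2", 2, 1:3, 1:3))
  expect_silent(merge_entries(conf))
})

test_that("the >1-missing-of-3 rule removes the right entries", {
  tab <- rbind(.entry("A", "P1", "1", 1, c(100, NA, NA), c(1, 2, 3)),
               .entry("B", "P2", "1", 1, c(100, NA, 120), c(1, 2, 3)),
               .entry("C", "P3", "1", 1, c(100, 90, 120), c(NA, NA, NA)),
               .entry("D", "P4", "1", 1, c(100, 90, 120), c(1, NA, 3)),
               .entry("E", "P5", "1", 1, c(1, 2, 3), c(4, 5, 6)))
  expect_message(kept <- filter_missing(tab), "removed 2")
  expect_setequal(kept$sequence, c("B", "D", "E"))
  expect_equal(nrow(attr(kept, "removed")), 2)
  # complete table passes through
  full <- filter_missing(tab[tab$sequence == "E", ])
  expect_equal(nrow(full), 1)
})

test_that("rank product is 1 for an entry ranked first everywhere", {
  set.seed(33)
  base <- do.call(rbind, lapply(1:9, function(i)
    .entry(paste0("S", i), paste0("P", i), "1", 1,
           exp(rnorm(3, 10, 0.1)), exp(rnorm(3, 10, 0.1)))))
  top <- .entry("TOP", "PT", "1", 1, exp(rnorm(3, 10, 0.1)),
                exp(rnorm(3, 16, 0.1)))   # dominates every comparison
  res <- rank_product_test(rbind(base, top), B = 1000, seed = 1)
  expect_equal(res$rp_up[res$sequence == "TOP"], 1)
  expect_equal(min(res$rp_up), 1)
  expect_lt(res$p_up[res$sequence == "TOP"], 0.01)
})

test_that("permutation p-values match exhaustive enumeration on a toy table", {
  set.seed(41)
  toy <- do.call(rbind, lapply(1:4, function(i)
    .entry(paste0("S", i), paste0("P", i), "1", 1,
           exp(rnorm(3, 10, 0.5)), exp(rnorm(3, 10 + (i == 1), 0.5)))))
  res <- rank_product_test(toy, B = 1000, seed = 1)
  xm <- as.matrix(toy[, phenoscreen:::.int_cols])
  or <- oracle_rp_p(xm)
  expect_equal(res$p_up, unname(or$p_up), tolerance = 1e-12)
  expect_equal(res$p_down, unname(or$p_down), tolerance = 1e-12)
})

test_that("rank product is invariant to monotone intensity transforms", {
  set.seed(43)
  tab <- do.call(rbind, lapply(1:8, function(i)
    .entry(paste0("S", i), paste0("P", i), "1", 1,
           exp(rnorm(3, 10, 1)), exp(rnorm(3, 10, 1)))))
  r1 <- rank_product_test(tab, B = 1000, seed = 2)
  tab2 <- tab
  for (cc in phenoscreen:::.int_cols) tab2[[cc]] <- tab2[[cc]]^3
  r2 <- rank_product_test(tab2, B = 1000, seed = 2)
  expect_equal(r1$rp_up, r2$rp_up)
  expect_equal(r1$p_up, r2$p_up)
})

test_that("differential gate applies ratio and direction-matched p together", {
  res <- data.frame(sequence = c("a", "b", "c", "d"),
                    protein = c("Pa", "Pb", "Pc", "Pa"),
                    site_positions = "1",
                    ratio = c(3, 1.2, 0.3, 2.5),
                    rp_up = 1, rp_down = 1,
                    p_up = c(0.01, 0.001, 0.9, 0.2),
                    p_down = c(0.9, 0.9, 0.01, 0.01))
  expect_setequal(differential_set(res), c("Pa", "Pc"))
  pep <- differential_set(res, mode = "peptide")
  expect_setequal(pep$sequence, c("a", "c"))
  expect_false("b" %in% pep$sequence)
  # loosening the fold gate does not admit entries failing the p gate
  expect_setequal(differential_set(res, ratio_thresh = 1.5), c("Pa", "Pc"))
})

test_that("synthetic phosphoproteome drives the full differential pipeline", {
  sim <- simulate_phosphoproteome(n_entries = 120, n_true = 10,
                                  effect_fold = 6, missing_rate = 0.05,
                                  seed = 7)
  merged <- merge_entries(sim$table)
  expect_equal(nrow(merged), 120)
  kept <- suppressMessages(filter_missing(merged))
  res <- rank_product_test(kept, B = 1000, seed = 8)
  hits <- differential_set(res)
  truth <- sim$truth$protein[sim$truth$true_diff]
  recovered <- mean(truth %in% hits)
  expect_gt(recovered, 0.7)
  fdr <- if (length(hits)) mean(!hits %in% truth) else 0
  expect_lt(fdr, 0.3)
})

test_that("missingness filter removes the binomially expected fraction", {
  sim <- simulate_phosphoproteome(n_entries = 400, n_true = 0,
                                  effect_fold = 2, missing_rate = 0.5,
                                  dup_rate = 0, seed = 9)
  kept <- suppressMessages(filter_missing(merge_entries(sim$table)))
  # P(genotype survives) = P(Binom(3, .5) missing <= 1) = 0.5
  p_keep <- 0.5^2
  se <- sqrt(p_keep * (1 - p_keep) / 400)
  expect_lt(abs(nrow(kept) / 400 - p_keep), 4 * se)
})
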