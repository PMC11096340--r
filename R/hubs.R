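#' Construct a weighted undirected interaction network
#'
#' @param edges data frame with columns `protein_a`, `protein_b`,
#'   `weight`; weights in (0, 1], no self-loops, at most one edge per
#'   unordered pair.
#' @return Object of class `interaction_network` with `nodes` and the
#'   canonicalized edge list.
#' @export
interaction_network <- function(edges) {
  stopifnot(all(c("protein_a", "protein_b", "weight") %in% names(edges)))
  if (any(edges$protein_a == edges$protein_b)) stop("self-loops not allowed")
  if (any(edges$weight <= 0 | edges$weight > 1))
    stop("edge weights must lie in (0, 1]")
  a <- pmin(edges$protein_a, edges$protein_b)
  b <- pmax(edges$protein_a, edges$protein_b)
  if (anyDuplicated(paste(a, b)))
    stop("duplicate edges for the same protein pair")
  structure(list(nodes = sort(unique(c(a, b))),
                 edges = data.frame(protein_a = a, protein_b = b,
                                    weight = edges$weight)),
            class = "interaction_network")
}

#' @exportS3Method base::print
print.interaction_network <- function(x, ...) {
  cat(sprintf("<interaction_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read an edge-list TSV (`protein_a`, `protein_b`, `weight`)
#' @param path TSV path.
#' @return An [interaction_network()].
#' @export
read_network <- function(path)
  interaction_network(utils::read.delim(path, sep = "\t",
                                        stringsAsFactors = FALSE))

# neighbours of a node with weights
.neighbours <- function(net, node) {
  e <- net$edges
  i <- e$protein_a == node
  j <- e$protein_b == node
  data.frame(protein = c(e$protein_b[i], e$protein_a[j]),
             weight = c(e$weight[i], e$weight[j]))
}

#' Interaction counts of a candidate into the differential set
#'
#' @param net an [interaction_network()].
#' @param diff_set character vector of differential protein accessions.
#' @param candidate protein accession; must be a network node.
#' @param w_high weight threshold for "high weight" edges (strict `>`).
#' @return Named list `count` (edges between candidate and
#'   `diff_set` excluding itself) and `high_weight_count`.
#' @export
induced_counts <- function(net, diff_set, candidate, w_high = 0.04) {
  stopifnot(inherits(net, "interaction_network"))
  if (!candidate %in% net$nodes)
    stop("candidate '", candidate, "' is not a network node")
  nb <- .neighbours(net, candidate)
  hit <- nb$protein %in% setdiff(diff_set, candidate)
  list(count = sum(hit),
       high_weight_count = sum(hit & nb$weight > w_high))
}

#' Select candidate hubs by interaction-count criteria
#'
#' A protein qualifies when it has at least `k_min` physical interactions
#' with the differential set, or strictly more than `k_high` high-weight
#' (weight > `w_high`) interactions.
#'
#' @param net an [interaction_network()].
#' @param diff_set differential protein accessions.
#' @param candidates proteins to evaluate; defaults to the members of
#'   `diff_set` present in the network.  An optional user-supplied gene
#'   list (e.g. a disease-association panel) can be intersected here.
#' @param k_min minimum interaction count (default 7, inclusive).
#' @param k_high high-weight count that must be exceeded (default 3,
#'   strict).
#' @param w_high high-weight threshold (default 0.04, strict).
#' @return Data frame `protein`, `count`, `high_weight_count`, `selected`.
#' @export
select_candidates <- function(net, diff_set, candidates = NULL,
                              k_min = 7, k_high = 3, w_high = 0.04) {
  if (is.null(candidates))
    candidates <- intersect(diff_set, net$nodes)
  out <- do.call(rbind, lapply(candidates, function(p) {
    ic <- induced_counts(net, diff_set, p, w_high)
    data.frame(protein = p, count = ic$count,
               high_weight_count = ic$high_weight_count)
  }))
  if (is.null(out))
    return(data.frame(protein = character(), count = integer(),
                      high_weight_count = integer(), selected = logical()))
  out$selected <- out$count >= k_min | out$high_weight_count > k_high
  out
}

#' Null interaction counts from random background sets
#'
#' For each of `B` replicates, `n` proteins are sampled uniformly without
#' replacement from the universe (excluding the candidate, so it cannot
#' count itself) and the candidate's edge count into the sample is
#' recorded.
#'
#' @param net an [interaction_network()].
#' @param universe character vector of background proteins (the whole
#'   phosphoproteome).
#' @param n size of each random background set.
#' @param candidate protein accession.
#' @param B number of background replicates (default 1000).
#' @param seed optional integer seed.
#' @return Integer vector of length `B`.
#' @export
null_counts <- function(net, universe, n, candidate, B = 1000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pool <- setdiff(universe, candidate)
  if (n > length(pool))
    stop("background set size n exceeds |universe| - 1")
  nb <- .neighbours(net, candidate)$protein
  is_nb <- pool %in% nb
  vapply(seq_len(B),
         function(b) sum(is_nb[sample.int(length(pool), n)]),
         integer(1))
}

#' Hypergeometric and empirical hub significance
#'
#' `p_hyper = P(X >= k)` for `X ~ Hypergeometric(N, K, n)` with `N` the
#' universe size, `K` the candidate's degree in the full network and `n`
#' the differential-set size; `p_empirical = (1 + #(null >= observed)) /
#' (B + 1)`.
#'
#' @param observed observed interaction count `k`.
#' @param null integer vector of null counts ([null_counts()]).
#' @param N,K,n hypergeometric parameters.
#' @return Named list `p_hyper`, `p_empirical`.
#' @export
hub_significance <- function(observed, null, N, K, n) {
  if (observed > min(K, n))
    stop("observed count exceeds min(candidate degree, set size)")
  list(p_hyper = stats::phyper(observed - 1, K, N - K, n,
                               lower.tail = FALSE),
       p_empirical = (1 + sum(null >= observed)) / (length(null) + 1))
}

#' Full hub scan of a differential set against a background null
#'
#' Runs candidate selection, per-candidate background nulls,
#' hypergeometric and empirical significance, and BH adjustment across
#' candidates.
#'
#' @inheritParams select_candidates
#' @param universe background proteins (all phosphoproteome accessions).
#' @param B background replicates per candidate.
#' @param seed integer seed.
#' @param alpha significance level on BH-adjusted p (default 0.05).
#' @return Data frame: `protein`, `count`, `high_weight_count`,
#'   `candidate` (passed the count criteria), `degree`, `p_hyper`,
#'   `p_empirical`, `p_hyper_adj`, `p_emp_adj`, `selected`
#'   (candidate and adjusted empirical p below `alpha`).
#' @export
hub_scan <- function(net, diff_set, universe, candidates = NULL,
                     k_min = 7, k_high = 3, w_high = 0.04,
                     B = 1000, seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  sel <- select_candidates(net, diff_set, candidates, k_min, k_high, w_high)
  if (!nrow(sel)) {
    warning("no candidates to evaluate; returning empty hub table")
    return(cbind(sel[, c("protein", "count", "high_weight_count")],
                 candidate = logical(), degree = integer(),
                 p_hyper = numeric(), p_empirical = numeric(),
                 p_hyper_adj = numeric(), p_emp_adj = numeric(),
                 selected = logical()))
  }
  names(sel)[names(sel) == "selected"] <- "candidate"
  N <- length(universe)
  res <- do.call(rbind, lapply(seq_len(nrow(sel)), function(i) {
    p <- sel$protein[i]
    K <- length(intersect(.neighbours(net, p)$protein, universe))
    n <- length(setdiff(diff_set, p))
    nc <- null_counts(net, universe, n, p, B)
    hs <- hub_significance(sel$count[i], nc, N, K, n)
    data.frame(degree = K, p_hyper = hs$p_hyper,
               p_empirical = hs$p_empirical)
  }))
  out <- cbind(sel, res)
  out$p_hyper_adj <- stats::p.adjust(out$p_hyper, method = "BH")
  out$p_emp_adj <- stats::p.adjust(out$p_empirical, method = "BH")
  out$selected <- out$candidate & out$p_emp_adj < alpha
  out
}
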