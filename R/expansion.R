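# One-gene-at-a-time network expansion with dual hypergeometric filtering.
#
# Candidate genes adjacent to the currently ranked set are tested for
# over-representation of interactions with ranked genes; a candidate must
# pass both tests (p1e < alpha AND p2e < alpha) and the best one --- by a
# confidence-weighted expansion score --- is added per iteration.
# Throughout, interactions are counted without regard to direction.

neighbor_map <- function(net) {
  split(c(net$edges$to, net$edges$from),
        c(net$edges$from, net$edges$to))
}

#' Candidate pool for expansion
#'
#' Genes of the global interaction collection adjacent to at least one
#' currently ranked gene and not themselves ranked.
#'
#' @param ranked character vector of currently ranked genes.
#' @param global_net the full interaction collection ([gene_network]).
#' @return character vector of candidate gene identifiers (sorted).
#' @export
candidate_pool <- function(ranked, global_net) {
  missing <- setdiff(ranked, global_net$nodes)
  if (length(missing)) {
    warning(sprintf("%d ranked gene(s) absent from the global collection",
                    length(missing)))
  }
  e <- global_net$edges
  hit_from <- e$from %in% ranked
  hit_to <- e$to %in% ranked
  pool <- unique(c(e$to[hit_from], e$from[hit_to]))
  sort(setdiff(pool, ranked))
}

#' Upper-tail hypergeometric probability
#'
#' P\[X >= k\] for X hypergeometric: `n` draws without replacement from a
#' universe of `N` objects of which `K` are marked.
#'
#' @param N universe size.
#' @param K number of marked objects.
#' @param n number of draws.
#' @param k threshold count.
#' @return the tail probability.
#' @export
hypergeom_upper_tail <- function(N, K, n, k) {
  if (K < 0 || K > N || n < 0 || n > N || k < 0 || k > min(n, K)) {
    stop(sprintf("invalid hypergeometric arguments N=%d K=%d n=%d k=%d",
                 N, K, n, k))
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Tail helper tolerant of k beyond min(n, K): such a count is impossible
# under the reference, so the tail is 0 (maximal enrichment evidence).
hyper_tail_clamped <- function(N, K, n, k) {
  if (k > min(n, K)) return(0)
  hypergeom_upper_tail(N, K, n, k)
}

expansion_counts <- function(candidate, ranked, global_net, nbrs = NULL) {
  if (is.null(nbrs)) nbrs <- neighbor_map(global_net)
  nb <- unique(nbrs[[candidate]])
  list(neighbors = nb, degree = length(nb),
       seed_links = sum(nb %in% ranked))
}

#' Expansion test 1: seeded interactions vs the candidate's degree
#'
#' Tests whether the candidate's interactions hit ranked genes more often
#' than uniform draws from the global gene universe would: the universe is
#' every gene but the candidate (`N`), of which the ranked genes are the
#' marked ones (`K`); the candidate's distinct neighbours are the draws
#' (`n`) and its ranked neighbours the observed count (`k`).
#'
#' @param candidate gene identifier, not itself ranked.
#' @param ranked character vector of currently ranked genes.
#' @param global_net the full interaction collection.
#' @param nbrs optional precomputed neighbour map (internal reuse).
#' @return the upper-tail p-value `p1e` (1 for a candidate with no
#'   interactions).
#' @export
expansion_test1 <- function(candidate, ranked, global_net, nbrs = NULL) {
  cnt <- expansion_counts(candidate, ranked, global_net, nbrs)
  if (cnt$degree == 0) return(1)
  N <- length(global_net$nodes) - 1
  K <- length(setdiff(intersect(ranked, global_net$nodes), candidate))
  hyper_tail_clamped(N, K, cnt$degree, cnt$seed_links)
}

#' Expansion test 2: seeded interactions vs a degree-matched ranked gene
#'
#' The reference is the ranked gene closest in degree to the candidate
#' (ties: larger degree, then lexicographically smaller identifier). When
#' the candidate's degree does not exceed the reference's, the candidate's
#' ranked-neighbour count is tested against drawing its `n = degree`
#' interactions from the reference's `N = degree` interactions of which
#' `K` hit ranked genes. When the candidate has the larger degree the
#' parameterization is swapped (the candidate becomes the universe) and
#' the complementary tail `1 - P[X <= k - 1]` is used, clipped to \[0, 1\].
#'
#' @inheritParams expansion_test1
#' @return list with `p2e` and `matched_seed`. `p2e` is 1 when the
#'   reference has no ranked neighbours or the candidate none.
#' @export
expansion_test2 <- function(candidate, ranked, global_net, nbrs = NULL) {
  stopifnot(length(ranked) >= 1)
  if (is.null(nbrs)) nbrs <- neighbor_map(global_net)
  cnt <- expansion_counts(candidate, ranked, global_net, nbrs)
  in_net <- intersect(ranked, global_net$nodes)
  if (!length(in_net)) return(list(p2e = 1, matched_seed = NA_character_))
  degs <- vapply(in_net, function(g) length(unique(nbrs[[g]])), 0L)
  links <- vapply(in_net, function(g) {
    sum(unique(nbrs[[g]]) %in% setdiff(ranked, g))
  }, 0L)
  ord <- order(abs(degs - cnt$degree), -degs, in_net)
  star <- ord[1]
  g_star <- in_net[star]
  d_star <- degs[star]
  k_star <- links[star]
  if (k_star == 0 || cnt$seed_links == 0) {
    return(list(p2e = 1, matched_seed = g_star))
  }
  if (cnt$degree <= d_star) {
    p <- hyper_tail_clamped(d_star, k_star, cnt$degree, cnt$seed_links)
  } else {
    p <- hyper_tail_clamped(cnt$degree, cnt$seed_links, d_star,
                            cnt$seed_links)
  }
  list(p2e = min(1, max(0, p)), matched_seed = g_star)
}

#' Filter the candidate pool by both expansion tests
#'
#' @param pool character vector of candidate genes (see
#'   [candidate_pool()]).
#' @param ranked currently ranked genes.
#' @param global_net the full interaction collection.
#' @param alpha significance cut applied to both tests; default 0.05.
#' @param keep_all also return failing candidates (flagged)?
#' @return data.frame with one row per candidate: `gene`, `degree_global`,
#'   `seed_links`, `matched_seed`, `p1e`, `p2e`, `pe = max(p1e, p2e)` and
#'   `pass`. With `keep_all = FALSE` (default) only passing rows.
#' @export
filter_candidates <- function(pool, ranked, global_net, alpha = 0.05,
                              keep_all = FALSE) {
  stopifnot(alpha > 0, alpha < 1)
  if (!length(pool)) {
    out <- data.frame(gene = character(), degree_global = integer(),
                      seed_links = integer(), matched_seed = character(),
                      p1e = numeric(), p2e = numeric(), pe = numeric(),
                      pass = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  nbrs <- neighbor_map(global_net)
  rows <- lapply(pool, function(g) {
    cnt <- expansion_counts(g, ranked, global_net, nbrs)
    p1 <- expansion_test1(g, ranked, global_net, nbrs)
    t2 <- expansion_test2(g, ranked, global_net, nbrs)
    data.frame(gene = g, degree_global = cnt$degree,
               seed_links = cnt$seed_links, matched_seed = t2$matched_seed,
               p1e = p1, p2e = t2$p2e, pe = max(p1, t2$p2e),
               pass = p1 < alpha && t2$p2e < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!keep_all) out <- out[out$pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Expansion score of a candidate
#'
#' e = sum over ranked neighbours j of c(candidate, j) * S(j) / W(j), where
#' c is the interaction confidence, S(j) the ranked gene's current score
#' and W(j) its total interaction confidence in the global collection
#' (unlike the within-network w(j) used during propagation).
#'
#' @param candidate gene identifier.
#' @param ranked currently ranked genes.
#' @param scores named scores of the ranked genes.
#' @param global_net the full interaction collection.
#' @return the expansion score (0 for a candidate without ranked
#'   neighbours).
#' @export
expansion_score <- function(candidate, ranked, scores, global_net) {
  e <- global_net$edges
  touch <- (e$from == candidate & e$to %in% ranked) |
    (e$to == candidate & e$from %in% ranked)
  if (!any(touch)) return(0)
  ej <- e[touch, , drop = FALSE]
  j <- ifelse(ej$from == candidate, ej$to, ej$from)
  W <- node_stats(global_net)$W
  names(W) <- global_net$nodes
  Wj <- W[j]
  Wj[Wj == 0] <- Inf    # cannot happen for a gene with a neighbour; guard
  sum(ej$confidence * scores[j] / Wj)
}

#' Expand a seed network one gene at a time
#'
#' Iterates: rank the current gene set on its induced subnetwork of the
#' global collection; pool the adjacent non-ranked genes; keep candidates
#' passing both hypergeometric filters; add the single candidate with the
#' highest expansion score (ties: smaller `pe`, then lexicographic) and
#' repeat, until no candidate passes or `max_add` genes have been added.
#' The loop is deterministic: it uses no randomness.
#'
#' @param seeds character vector of seed genes.
#' @param global_net the full interaction collection.
#' @param config a [ranking_config()].
#' @param alpha significance cut for both tests; default 0.05.
#' @param max_add maximum number of genes to add.
#' @return list with `result` (final `winner_ranking` over seeds plus
#'   added genes), `added` (data.frame ledger of the added genes with
#'   their test statistics and `iteration_added`), and `candidates` (the
#'   evaluated candidate table of the final iteration, including failures).
#' @export
expand_network <- function(seeds, global_net, config = ranking_config(),
                           alpha = 0.05, max_add = 10) {
  stopifnot(max_add >= 0)
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) stop("no seeds")
  ranked <- seeds
  ledger <- list()
  iteration <- 0L
  repeat {
    sub <- suppressWarnings(induced_subnetwork(global_net, ranked))
    res <- winner_rank(sub, global_net, config)
    pool <- candidate_pool(ranked, global_net)
    cand <- filter_candidates(pool, ranked, global_net, alpha,
                              keep_all = TRUE)
    passing <- cand[cand$pass, , drop = FALSE]
    if (!nrow(passing) || iteration >= max_add) break
    passing$expansion_score <- vapply(passing$gene, function(g) {
      expansion_score(g, ranked, res$scores, global_net)
    }, 0)
    ord <- order(-passing$expansion_score, passing$pe, passing$gene)
    best <- passing[ord[1], , drop = FALSE]
    iteration <- iteration + 1L
    best$iteration_added <- iteration
    ledger[[iteration]] <- best
    ranked <- c(ranked, best$gene)
  }
  added <- if (length(ledger)) {
    do.call(rbind, ledger)
  } else {
    data.frame(gene = character(), degree_global = integer(),
               seed_links = integer(), matched_seed = character(),
               p1e = numeric(), p2e = numeric(), pe = numeric(),
               pass = logical(), expansion_score = numeric(),
               iteration_added = integer(), stringsAsFactors = FALSE)
  }
  rownames(added) <- NULL
  list(result = res, added = added, candidates = cand)
}
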