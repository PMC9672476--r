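# Null-model network randomization.
#
# All schemes keep the node set fixed and resample edge weights from the
# empirical weight distribution of the original network, since rewiring
# procedures generate unweighted topologies.

local_seed <- function(rng_seed) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  invisible(NULL)
}

edge_indices <- function(net) {
  cbind(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
}

rebuild_network <- function(net, idx, weights) {
  gene_network(data.frame(from = net$nodes[idx[, 1]],
                          to = net$nodes[idx[, 2]],
                          confidence = weights,
                          stringsAsFactors = FALSE),
               nodes = net$nodes, directed = net$directed)
}

#' Resample edge weights from an empirical distribution
#'
#' Draws `k` values with replacement from the multiset of template weights.
#'
#' @param template_weights non-empty numeric vector.
#' @param k number of draws.
#' @param rng_seed optional seed.
#' @return numeric vector of length `k`.
#' @export
resample_weights <- function(template_weights, k, rng_seed = NULL) {
  if (!length(template_weights)) stop("empty weight template")
  stopifnot(k >= 0)
  local_seed(rng_seed)
  if (k == 0) return(numeric())
  template_weights[sample.int(length(template_weights), k, replace = TRUE)]
}

#' Total rewiring (total network permutation)
#'
#' Every edge's two endpoints are redrawn uniformly at random over the node
#' set, rejecting self-loops and duplicate pairs. The edge count is
#' preserved; nothing else about the topology is.
#'
#' @param net an undirected [gene_network] with at least 2 nodes.
#' @param rng_seed optional seed.
#' @return a randomized [gene_network].
#' @export
randomize_total_rewire <- function(net, rng_seed = NULL) {
  if (net$directed) stop("randomization is defined for undirected networks")
  n <- length(net$nodes)
  if (n < 2) stop("need at least 2 nodes")
  m <- n_edges(net)
  local_seed(rng_seed)
  placed <- integer(0)   # canonical pair codes a + n*b, a < b
  idx <- matrix(0L, m, 2)
  budget <- 200L * m
  for (e in seq_len(m)) {
    repeat {
      if (budget <= 0L) {
        stop("could not place all rewired edges; network too dense")
      }
      budget <- budget - 1L
      ab <- sample.int(n, 2)    # distinct, so no self-loop
      a <- min(ab); b <- max(ab)
      code <- a + n * b
      if (!(code %in% placed)) {
        placed <- c(placed, code)
        idx[e, ] <- c(a, b)
        break
      }
    }
  }
  rebuild_network(net, idx, resample_weights(net$edges$confidence, m))
}

# Double-edge-swap engine. `labels` (optional) restricts swaps to edge
# pairs with equal labels, aligning endpoints so each swapped edge keeps
# its label (used for modularity preservation). Preserves every node's
# degree by construction.
double_edge_swaps <- function(idx, n, attempts, labels = NULL,
                              membership = NULL) {
  m <- nrow(idx)
  if (m < 2) return(idx)
  codes <- pmin(idx[, 1], idx[, 2]) + n * pmax(idx[, 1], idx[, 2])
  by_label <- if (!is.null(labels)) split(seq_len(m), labels) else NULL
  for (a in seq_len(attempts)) {
    e1 <- sample.int(m, 1)
    if (is.null(by_label)) {
      e2 <- sample.int(m, 1)
    } else {
      pool <- by_label[[labels[e1]]]
      e2 <- pool[sample.int(length(pool), 1)]
    }
    if (e1 == e2) next
    p <- idx[e1, ]; q <- idx[e2, ]
    if (is.null(membership)) {
      if (stats::runif(1) < 0.5) q <- rev(q)
    } else {
      # align so both new edges keep their community-pair label
      if (membership[p[1]] != membership[q[1]]) q <- rev(q)
    }
    new1 <- c(p[1], q[2]); new2 <- c(q[1], p[2])
    if (new1[1] == new1[2] || new2[1] == new2[2]) next
    c1 <- min(new1) + n * max(new1)
    c2 <- min(new2) + n * max(new2)
    if (c1 == c2) next
    other <- codes[-c(e1, e2)]
    if (c1 %in% other || c2 %in% other) next
    idx[e1, ] <- new1; idx[e2, ] <- new2
    codes[e1] <- c1; codes[e2] <- c2
  }
  idx
}

#' Degree-preserving randomization
#'
#' Randomizes the topology with repeated double-edge swaps (10 x |edges|
#' attempted swaps), so that every gene keeps exactly its original degree,
#' then resamples edge weights from the original weight distribution.
#'
#' @param net an undirected [gene_network] with >= 2 edges.
#' @param rng_seed optional seed.
#' @param attempts number of attempted swaps; default `10 * n_edges(net)`.
#' @return a randomized [gene_network] with the original degree sequence.
#' @export
randomize_preserve_degree <- function(net, rng_seed = NULL, attempts = NULL) {
  if (net$directed) stop("randomization is defined for undirected networks")
  local_seed(rng_seed)
  m <- n_edges(net)
  if (is.null(attempts)) attempts <- 10L * m
  idx <- double_edge_swaps(edge_indices(net), length(net$nodes), attempts)
  out <- rebuild_network(net, idx, resample_weights(net$edges$confidence, m))
  stopifnot(identical(degree_counts(out), degree_counts(net)))
  out
}

degree_counts <- function(net) {
  d <- integer(length(net$nodes))
  idx <- c(match(net$edges$from, net$nodes), match(net$edges$to, net$nodes))
  t <- tabulate(idx, nbins = length(net$nodes))
  t
}

#' Modularity-preserving randomization
#'
#' Detects a community partition once (greedy modularity maximization) and
#' then performs double-edge swaps restricted to edge pairs connecting the
#' same pair of communities. This preserves each node's degree and each
#' community pair's edge count, hence Newman's modularity Q of the fixed
#' partition exactly, while still shuffling partners within those
#' constraints. Weights are resampled.
#'
#' @param net an undirected [gene_network] with >= 2 edges.
#' @param rng_seed optional seed.
#' @param attempts number of attempted swaps; default `10 * n_edges(net)`.
#' @return list with elements `network` (the randomized [gene_network]),
#'   `membership` (named community ids) and `modularity` (Q of the fixed
#'   partition on the randomized network).
#' @export
randomize_preserve_modularity <- function(net, rng_seed = NULL,
                                          attempts = NULL) {
  if (net$directed) stop("randomization is defined for undirected networks")
  local_seed(rng_seed)
  g <- as_igraph(net)
  comm <- igraph::cluster_fast_greedy(g, weights = NULL)
  membership <- igraph::membership(comm)
  mem <- as.integer(membership[net$nodes])
  idx <- edge_indices(net)
  lab <- paste(pmin(mem[idx[, 1]], mem[idx[, 2]]),
               pmax(mem[idx[, 1]], mem[idx[, 2]]))
  m <- n_edges(net)
  if (is.null(attempts)) attempts <- 10L * m
  idx <- double_edge_swaps(idx, length(net$nodes), attempts,
                           labels = lab, membership = mem)
  out <- rebuild_network(net, idx, resample_weights(net$edges$confidence, m))
  q <- igraph::modularity(as_igraph(out), mem[match(out$nodes, net$nodes)])
  list(network = out,
       membership = stats::setNames(mem, net$nodes),
       modularity = q)
}

#' Newman modularity of a network under a given partition
#' @param net an undirected [gene_network].
#' @param membership named (or node-ordered) integer community ids.
#' @return modularity Q (unweighted).
#' @export
network_modularity <- function(net, membership) {
  if (!is.null(names(membership))) membership <- membership[net$nodes]
  igraph::modularity(as_igraph(net), as.integer(membership))
}

#' Randomly add or remove a fraction of interactions
#'
#' Adds `round(fraction * |edges|)` (at least 1) edges between uniformly
#' sampled non-adjacent node pairs, with weights resampled from the
#' original weight distribution, or removes that many uniformly sampled
#' existing edges.
#'
#' @param net a [gene_network].
#' @param fraction fraction of the edge count to change, in (0, 1).
#' @param direction `"add"` or `"remove"`.
#' @param rng_seed optional seed.
#' @return the perturbed [gene_network].
#' @export
perturb_edges <- function(net, fraction, direction = c("add", "remove"),
                          rng_seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(fraction > 0, fraction < 1)
  local_seed(rng_seed)
  m <- n_edges(net)
  k <- max(1L, as.integer(round(fraction * m)))
  n <- length(net$nodes)
  if (direction == "remove") {
    if (k >= m) stop("cannot remove ", k, " of ", m, " edges")
    drop <- sample.int(m, k)
    return(gene_network(net$edges[-drop, , drop = FALSE], nodes = net$nodes,
                        directed = net$directed))
  }
  max_edges <- n * (n - 1) / 2
  if (m + k > max_edges) stop("not enough non-adjacent pairs to add ", k,
                              " edges")
  idx <- edge_indices(net)
  existing <- pmin(idx[, 1], idx[, 2]) + n * pmax(idx[, 1], idx[, 2])
  new_codes <- integer(0)
  budget <- 500L * k
  while (length(new_codes) < k) {
    if (budget <= 0L) stop("could not sample enough non-adjacent pairs")
    budget <- budget - 1L
    ab <- sample.int(n, 2)
    code <- min(ab) + n * max(ab)
    if (!(code %in% existing) && !(code %in% new_codes)) {
      new_codes <- c(new_codes, code)
    }
  }
  a <- new_codes %% n          # a in 1..n-1, so never 0
  b <- new_codes %/% n
  add <- data.frame(from = net$nodes[a], to = net$nodes[b],
                    confidence = resample_weights(net$edges$confidence, k),
                    stringsAsFactors = FALSE)
  gene_network(rbind(net$edges, add), nodes = net$nodes,
               directed = net$directed)
}

#' Dispatch a randomization scheme by name
#'
#' @param net a [gene_network].
#' @param method one of `"preserve_degree"`, `"preserve_modularity"`,
#'   `"total_rewire"`, `"add_fraction"`, `"remove_fraction"`.
#' @param fraction edge fraction for the add/remove schemes; default 0.05.
#' @param rng_seed optional seed.
#' @return a randomized [gene_network].
#' @export
randomize_network <- function(net,
                              method = c("preserve_degree",
                                         "preserve_modularity",
                                         "total_rewire",
                                         "add_fraction", "remove_fraction"),
                              fraction = 0.05, rng_seed = NULL) {
  method <- match.arg(method)
  switch(method,
         preserve_degree = randomize_preserve_degree(net, rng_seed),
         preserve_modularity =
           randomize_preserve_modularity(net, rng_seed)$network,
         total_rewire = randomize_total_rewire(net, rng_seed),
         add_fraction = perturb_edges(net, fraction, "add", rng_seed),
         remove_fraction = perturb_edges(net, fraction, "remove", rng_seed))
}

#' Chi-square goodness-of-fit test against a fitted normal
#'
#' Fits a normal by the sample mean and standard deviation, forms 10
#' equal-probability bins under that normal, pools adjacent bins until every
#' expected count is at least 5, and computes the chi-square statistic with
#' `bins - 3` degrees of freedom (two fitted parameters). Smaller statistics
#' mean the samples look more normally distributed.
#'
#' @param samples numeric vector, at least 30 values.
#' @return list with `chi2`, `df` and `p`. Zero-variance samples return
#'   `chi2 = Inf` with a warning.
#' @export
normality_chi2 <- function(samples) {
  samples <- as.numeric(samples)
  if (length(samples) < 30) stop("need at least 30 samples")
  m <- mean(samples)
  s <- stats::sd(samples)
  if (!is.finite(s) || s == 0) {
    warning("zero variance: chi-square undefined, returning Inf")
    return(list(chi2 = Inf, df = NA_real_, p = 0))
  }
  edges <- stats::qnorm(seq(0, 1, length.out = 11), m, s)
  obs <- as.numeric(table(cut(samples, edges, include.lowest = TRUE)))
  exp_cnt <- rep(length(samples) / 10, 10)
  # pool adjacent bins until all expected counts reach 5
  while (length(exp_cnt) > 1 && min(exp_cnt) < 5) {
    i <- which.min(exp_cnt)
    j <- if (i == length(exp_cnt)) i - 1 else i
    exp_cnt[j] <- exp_cnt[j] + exp_cnt[j + 1]
    obs[j] <- obs[j] + obs[j + 1]
    exp_cnt <- exp_cnt[-(j + 1)]
    obs <- obs[-(j + 1)]
  }
  chi2 <- sum((obs - exp_cnt)^2 / exp_cnt)
  df <- max(1, length(exp_cnt) - 3)
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
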