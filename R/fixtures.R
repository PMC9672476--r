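# Deterministic synthetic-network generators for benchmarking: scale-free
# interactomes with confidence weights, planted expansion modules, layered
# regulatory DAGs and regular graphs. All are pure functions of their seed.

gene_labels <- function(n, prefix = "G") sprintf("%s%04d", prefix, seq_len(n))

#' Draw interaction confidence scores
#'
#' A symmetric beta(2, 2) rescaled onto \[`min_weight`, 1\]; the default
#' floor of 0.75 mimics curated interactomes filtered to high-confidence
#' interactions. `dist = "unit"` gives all-1 confidences.
#'
#' @param k number of draws.
#' @param dist `"beta"` or `"unit"`.
#' @param min_weight lower bound of the support for `"beta"`.
#' @param rng_seed optional seed.
#' @return numeric vector of confidences in \[0, 1\].
#' @export
draw_weights <- function(k, dist = c("beta", "unit"), min_weight = 0.75,
                         rng_seed = NULL) {
  dist <- match.arg(dist)
  stopifnot(min_weight >= 0, min_weight < 1)
  local_seed(rng_seed)
  if (dist == "unit") return(rep(1, k))
  min_weight + (1 - min_weight) * stats::rbeta(k, 2, 2)
}

#' Scale-free weighted network by preferential attachment
#'
#' Starts from `m` unconnected nodes and attaches each subsequent node to
#' `m` distinct existing nodes with probability proportional to their
#' current degree (uniform among the initial targets), yielding exactly
#' `(n - m) * m` edges.
#'
#' @param n number of nodes (> m).
#' @param m edges per attached node.
#' @param weight_dist `"beta"` or `"unit"` (see [draw_weights()]).
#' @param min_weight confidence floor for `"beta"`.
#' @param rng_seed seed; identical seeds give identical networks.
#' @return an undirected [gene_network] with nodes `G0001..`.
#' @export
make_scale_free_weighted <- function(n, m = 2, weight_dist = "beta",
                                     min_weight = 0.75, rng_seed = NULL) {
  stopifnot(n > m, m >= 1)
  local_seed(rng_seed)
  from <- integer(0)
  to <- integer(0)
  targets <- seq_len(m)
  repeated <- integer(0)
  for (v in seq.int(m + 1, n)) {
    from <- c(from, rep(v, m))
    to <- c(to, targets)
    repeated <- c(repeated, targets, rep(v, m))
    # sample m distinct targets proportionally to degree via the repeated list
    nxt <- integer(0)
    while (length(nxt) < m) {
      cand <- repeated[sample.int(length(repeated), 1)]
      if (!(cand %in% nxt)) nxt <- c(nxt, cand)
    }
    targets <- nxt
  }
  labels <- gene_labels(n)
  gene_network(data.frame(from = labels[from], to = labels[to],
                          confidence = draw_weights(length(from), weight_dist,
                                                    min_weight),
                          stringsAsFactors = FALSE),
               nodes = labels, directed = FALSE)
}

#' Plant a dense expansion module in a background network
#'
#' Samples `module_size` background genes, wires each within-module pair
#' with probability `module_density` (weights drawn from the background's
#' weight distribution), and withholds `held_out` random module genes from
#' the seed set. The held-out set is the ground truth for retrieval
#' benchmarks of the expansion loop.
#'
#' @param background an undirected [gene_network].
#' @param module_size module gene count.
#' @param module_density within-module edge probability in (0, 1\].
#' @param held_out number of module genes excluded from the seeds (>= 1).
#' @param rng_seed seed.
#' @return list with `network` (background plus module edges), `seeds`
#'   (character), `held_out` (character) and `module` (character).
#' @export
plant_expansion_module <- function(background, module_size = 20,
                                   module_density = 0.7, held_out = 10,
                                   rng_seed = NULL) {
  stopifnot(module_size > held_out, held_out >= 1,
            module_density > 0, module_density <= 1)
  if (module_size > length(background$nodes)) {
    stop("module larger than background")
  }
  local_seed(rng_seed)
  module <- sort(sample(background$nodes, module_size))
  pairs <- utils::combn(module, 2)
  keep <- stats::runif(ncol(pairs)) <= module_density
  wts <- resample_weights(background$edges$confidence, sum(keep))
  module_edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep],
                             confidence = wts, stringsAsFactors = FALSE)
  net <- gene_network(rbind(background$edges, module_edges),
                      nodes = background$nodes, directed = FALSE)
  held <- sort(sample(module, held_out))
  list(network = net, seeds = setdiff(module, held), held_out = held,
       module = module)
}

#' Layered regulatory DAG
#'
#' `layers` layers of `width` genes; each gene regulates each gene of the
#' next layer with probability `p_forward`, and every gene below the top
#' layer is guaranteed at least one regulator. Layer recovery by
#' [bfs_layers()] returns the construction layers exactly.
#'
#' @param layers number of layers (>= 2).
#' @param width genes per layer.
#' @param p_forward forward edge probability.
#' @param weight_dist,min_weight see [draw_weights()]; default unit
#'   confidences.
#' @param rng_seed seed.
#' @return a directed [gene_network]; node labels encode the layer
#'   (`L01N01`, ...), and the true layer map is attached as attribute
#'   `"true_layers"`.
#' @export
make_layered_dag <- function(layers, width, p_forward = 0.5,
                             weight_dist = "unit", min_weight = 0.75,
                             rng_seed = NULL) {
  stopifnot(layers >= 2, width >= 1, p_forward > 0, p_forward <= 1)
  local_seed(rng_seed)
  lab <- function(l, i) sprintf("L%02dN%02d", l, i)
  from <- character(0)
  to <- character(0)
  for (l in seq_len(layers - 1)) {
    for (b in seq_len(width)) {
      src <- which(stats::runif(width) <= p_forward)
      if (!length(src)) src <- sample.int(width, 1)
      from <- c(from, lab(l, src))
      to <- c(to, rep(lab(l + 1, b), length(src)))
    }
  }
  nodes <- as.vector(vapply(seq_len(layers), function(l) {
    vapply(seq_len(width), function(i) lab(l, i), "")
  }, character(width)))
  net <- gene_network(data.frame(from = from, to = to,
                                 confidence = draw_weights(length(from),
                                                           weight_dist,
                                                           min_weight),
                                 stringsAsFactors = FALSE),
                      nodes = nodes, directed = TRUE)
  truth <- rep(seq_len(layers), each = width)
  names(truth) <- nodes
  attr(net, "true_layers") <- truth[net$nodes]
  net
}

#' Random k-regular graph
#'
#' @param n number of nodes (`n * k` must be even, `k < n`).
#' @param k common degree.
#' @param rng_seed seed.
#' @return an undirected [gene_network] with all confidences 1.
#' @export
make_regular_graph <- function(n, k, rng_seed = NULL) {
  stopifnot(n * k %% 2 == 0, k < n, k >= 1)
  local_seed(rng_seed)
  g <- igraph::sample_k_regular(n, k)
  el <- igraph::as_edgelist(g, names = FALSE)
  labels <- gene_labels(n)
  gene_network(data.frame(from = labels[el[, 1]], to = labels[el[, 2]],
                          confidence = 1, stringsAsFactors = FALSE),
               nodes = labels, directed = FALSE)
}
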