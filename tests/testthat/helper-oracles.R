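# Independent oracles and small fixture builders shared across tests.

# Dense closed-form solve of the propagation fixed point:
# (I - damping * M) S = (1 - damping) * S0, with M built entry by entry
# from the edge list, independently of the package's sparse machinery.
solve_scores_direct <- function(net, config = ranking_config()) {
  nodes <- net$nodes
  n <- length(nodes)
  stats <- node_stats(net, mode = config$mode)
  s0 <- initial_score(stats)
  M <- matrix(0, n, n, dimnames = list(nodes, nodes))
  e <- net$edges
  if (config$mode == "undirected") {
    w <- stats::setNames(stats$w, nodes)
    for (r in seq_len(nrow(e))) {
      a <- e$from[r]; b <- e$to[r]; cc <- e$confidence[r]
      if (w[b] > 0) M[a, b] <- M[a, b] + cc / w[b]
      if (w[a] > 0) M[b, a] <- M[b, a] + cc / w[a]
    }
  } else if (config$mode == "upstream") {
    din <- stats::setNames(numeric(n), nodes)
    for (r in seq_len(nrow(e))) din[e$to[r]] <- din[e$to[r]] + e$confidence[r]
    for (r in seq_len(nrow(e))) {
      a <- e$from[r]; b <- e$to[r]
      if (din[b] > 0) M[a, b] <- M[a, b] + e$confidence[r] / din[b]
    }
  } else {
    dout <- stats::setNames(numeric(n), nodes)
    for (r in seq_len(nrow(e))) {
      dout[e$from[r]] <- dout[e$from[r]] + e$confidence[r]
    }
    for (r in seq_len(nrow(e))) {
      a <- e$from[r]; b <- e$to[r]
      if (dout[a] > 0) M[b, a] <- M[b, a] + e$confidence[r] / dout[a]
    }
  }
  s <- solve(diag(n) - config$damping * M, (1 - config$damping) * s0[nodes])
  stats::setNames(as.numeric(s), nodes)
}

# Brute-force upper-tail hypergeometric probability by enumerating every
# size-n subset of a universe with K marked objects.
enumerate_hyper_tail <- function(N, K, n, k) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(K)   # which objects are marked is arbitrary
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

triangle_net <- function(conf = c(1, 1, 1)) {
  gene_network(data.frame(from = c("A", "A", "B"), to = c("B", "C", "C"),
                          confidence = conf))
}

star_net <- function(leaves = 3) {
  gene_network(data.frame(from = "HUB",
                          to = paste0("L", seq_len(leaves)),
                          confidence = 1))
}

random_weighted_net <- function(n, p = 0.08, seed = 1) {
  set.seed(seed)
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  labels <- sprintf("N%03d", seq_len(n))
  gene_network(data.frame(from = labels[pairs[1, keep]],
                          to = labels[pairs[2, keep]],
                          confidence = stats::runif(sum(keep), 0.1, 1)),
               nodes = labels)
}

write_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
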