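#' Ranking configuration
#'
#' Parameters of the score-propagation model. `damping` is the fraction of
#' score received from neighbours each iteration (the remainder is pinned to
#' the initial score); propagation stops once the largest per-gene change
#' falls below `tol`, or after `max_iter` iterations.
#'
#' @param damping random-walk damping in (0, 1); default 0.85.
#' @param tol convergence tolerance on the maximum absolute per-gene score
#'   change; default 0.001.
#' @param max_iter iteration cap; default 200.
#' @param mode propagation mode: `"undirected"`, or for directed networks
#'   `"upstream"` (rank regulators that drive high-scoring targets) or
#'   `"downstream"` (rank effectors of high-scoring regulators).
#' @return list of class `ranking_config`.
#' @export
ranking_config <- function(damping = 0.85, tol = 0.001, max_iter = 200,
                           mode = c("undirected", "upstream", "downstream")) {
  mode <- match.arg(mode)
  stopifnot(damping > 0, damping < 1, tol > 0, max_iter >= 1)
  structure(list(damping = damping, tol = tol,
                 max_iter = as.integer(max_iter), mode = mode),
            class = "ranking_config")
}

#' Initial gene score
#'
#' The seed score of gene i is exp(2 ln w(i) - ln I(i)) = w(i)^2 / I(i):
#' the squared total interaction confidence over the interaction count.
#' When every confidence is 1 this equals the node degree. Genes with no
#' interaction under the active mode get score 0.
#'
#' @param stats data.frame from [node_stats()] (columns `gene`, `w`, `I`).
#' @return named numeric vector of initial scores.
#' @export
initial_score <- function(stats) {
  if (any(stats$w < 0)) stop("negative interaction weight sum")
  s0 <- ifelse(stats$I > 0, stats$w^2 / stats$I, 0)
  names(s0) <- stats$gene
  s0
}

# Sparse propagation matrix M (n x n): new_score = (1-d)*S0 + d * M %*% S.
# M[i, j] = c(j, i) / d(j) where j passes score to i in the active mode and
# d(j) is the total confidence of the edges along which j distributes score:
# its total incident confidence (undirected), the total confidence of the
# relationships in which j is regulated (upstream mode: j passes score to
# its regulators), or of the relationships j regulates (downstream mode).
propagation_matrix <- function(net, mode) {
  n <- length(net$nodes)
  a <- match(net$edges$from, net$nodes)
  b <- match(net$edges$to, net$nodes)
  conf <- net$edges$confidence
  accum <- function(idx, val) {
    out <- numeric(n)
    if (length(idx)) {
      s <- tapply(val, idx, sum)
      out[as.integer(names(s))] <- as.numeric(s)
    }
    out
  }
  if (mode == "undirected") {
    d <- accum(c(a, b), c(conf, conf))   # w(j)
    i_idx <- c(a, b)
    j_idx <- c(b, a)
    x <- c(conf, conf)
  } else if (mode == "upstream") {
    d <- accum(b, conf)            # total confidence of j's regulations-in
    i_idx <- a                     # regulator receives from its target
    j_idx <- b
    x <- conf
  } else {
    d <- accum(a, conf)            # total confidence of j's regulations-out
    i_idx <- b                     # target receives from its regulator
    j_idx <- a
    x <- conf
  }
  keep <- d[j_idx] > 0
  Matrix::sparseMatrix(i = i_idx[keep], j = j_idx[keep],
                       x = x[keep] / d[j_idx[keep]], dims = c(n, n))
}

#' One propagation step
#'
#' S_t(i) = (1 - damping) * S0(i) + damping * sum_j c(j, i) * S_{t-1}(j) / d(j),
#' where j runs over the genes that pass score to i under the active mode
#' and d(j) is the total confidence along which j distributes (see
#' [ranking_config()] and the package vignette). Genes that distribute no
#' confidence contribute nothing.
#'
#' @param net a [gene_network].
#' @param s_prev named numeric, previous scores over `net$nodes`.
#' @param s0 named numeric, initial scores over `net$nodes`.
#' @param config a [ranking_config()].
#' @return named numeric vector of updated scores.
#' @export
propagate_step <- function(net, s_prev, s0, config = ranking_config()) {
  M <- propagation_matrix(net, config$mode)
  s <- (1 - config$damping) * s0[net$nodes] +
    config$damping * as.numeric(M %*% s_prev[net$nodes])
  names(s) <- net$nodes
  s
}

#' Rank the genes of a network
#'
#' Computes initial scores, iterates the damped propagation update until the
#' maximum per-gene absolute change drops below `config$tol` (or `max_iter`
#' is reached), and derives descending ranks (ties get the average rank) and
#' percentiles (rank 1 maps to 100, the last rank to 0).
#'
#' @param net a [gene_network]; for `mode != "undirected"` it must be
#'   directed.
#' @param global_net optional full interaction collection, used only for the
#'   `W` column of the per-gene statistics carried on the result.
#' @param config a [ranking_config()].
#' @return object of class `winner_ranking`: list with `scores`, `ranks`,
#'   `percentiles` (named numerics), `iterations`, `converged`, `config`,
#'   and `stats` (the [node_stats()] table). `as.data.frame()` gives a tidy
#'   per-gene table.
#' @examples
#' net <- gene_network(data.frame(from = c("A", "A", "B"),
#'                                to = c("B", "C", "C")))
#' winner_rank(net)$scores  # all confidences 1: scores equal node degree
#' @export
winner_rank <- function(net, global_net = NULL, config = ranking_config()) {
  if (!length(net$nodes)) stop("empty network")
  if (config$mode != "undirected" && !net$directed) {
    stop("mode '", config$mode, "' requires a directed network")
  }
  stats <- node_stats(net, global_net, mode = config$mode)
  s0 <- initial_score(stats)
  M <- propagation_matrix(net, config$mode)
  s <- s0
  iterations <- 0L
  converged <- FALSE
  for (t in seq_len(config$max_iter)) {
    s_new <- (1 - config$damping) * s0 +
      config$damping * as.numeric(M %*% s)
    iterations <- t
    delta <- max(abs(s_new - s))
    s <- s_new
    if (delta < config$tol) {
      converged <- TRUE
      break
    }
  }
  names(s) <- net$nodes
  r <- rank(-s, ties.method = "average")
  n <- length(s)
  pct <- if (n > 1) (n - r) / (n - 1) * 100 else rep(100, n)
  names(r) <- names(pct) <- net$nodes
  structure(list(scores = s, ranks = r, percentiles = pct,
                 iterations = iterations, converged = converged,
                 config = config, stats = stats),
            class = "winner_ranking")
}

#' @export
print.winner_ranking <- function(x, ...) {
  cat(sprintf(
    "<winner_ranking> %d genes, mode %s, %d iteration(s), %s\n",
    length(x$scores), x$config$mode, x$iterations,
    if (x$converged) "converged" else "NOT converged"))
  top <- names(sort(x$ranks))[seq_len(min(5, length(x$ranks)))]
  cat("top genes:", paste(top, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.winner_ranking <- function(x, ...) {
  tab <- data.frame(gene = names(x$scores),
                    score = as.numeric(x$scores),
                    rank = as.numeric(x$ranks),
                    percentile = as.numeric(x$percentiles),
                    stringsAsFactors = FALSE)
  for (col in c("p_r", "mu", "sigma")) {
    if (!is.null(x[[col]])) tab[[col]] <- as.numeric(x[[col]])
  }
  tab[order(tab$rank, tab$gene), , drop = FALSE]
}
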