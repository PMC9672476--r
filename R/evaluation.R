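# Assessment procedures: retrieval metrics, layer analysis, baseline
# centralities and pathway-level correlation.

#' Precision, recall and F1 for retrieved gene sets
#'
#' @param E predicted (expansion) gene set.
#' @param U reference (update) gene set.
#' @return list with `precision` (= |E n U| / |E|, 0 for empty E), `recall`
#'   (= |E n U| / |U|, 0 for empty U) and `f1` (harmonic mean, 0 when both
#'   are 0).
#' @export
precision_recall_f1 <- function(E, U) {
  E <- unique(as.character(E))
  U <- unique(as.character(U))
  hit <- length(intersect(E, U))
  precision <- if (length(E)) hit / length(E) else 0
  recall <- if (length(U)) hit / length(U) else 0
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1)
}

#' Breadth-first layer assignment with cycle collapse
#'
#' Strongly connected components with two or more genes are collapsed to a
#' single super-node; the condensed graph is acyclic, its source nodes (no
#' incoming edges) form layer 1, and every other node's layer is 1 plus its
#' shortest condensed-path distance from the nearest source. All genes of a
#' collapsed cycle share its layer.
#'
#' @param net a directed [gene_network].
#' @return list with `layers` (named integer per gene), `groups` (named
#'   integer: condensed component id per gene).
#' @export
bfs_layers <- function(net) {
  if (!net$directed) stop("layer assignment requires a directed network")
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  mem <- comp$membership
  cg <- igraph::simplify(igraph::contract(g, mapping = mem))
  roots <- which(igraph::degree(cg, mode = "in") == 0)
  d <- igraph::distances(cg, v = roots, mode = "out")
  layer_comp <- apply(d, 2, min) + 1
  layers <- as.integer(layer_comp[mem])
  names(layers) <- names(mem)
  list(layers = layers[net$nodes],
       groups = stats::setNames(as.integer(mem), names(mem))[net$nodes])
}

#' Pool ranking percentiles by layer across pathways
#'
#' @param results list of pairs: each element a list with `ranking` (a
#'   `winner_ranking`) and `layers` (from [bfs_layers()]) over the same
#'   genes.
#' @return data.frame with columns `pathway`, `gene`, `layer`,
#'   `percentile`; a `summary` attribute holds per-layer median and
#'   quartiles.
#' @export
percentile_by_layer <- function(results) {
  rows <- lapply(seq_along(results), function(i) {
    r <- results[[i]]
    genes <- names(r$ranking$percentiles)
    data.frame(pathway = i, gene = genes,
               layer = as.integer(r$layers$layers[genes]),
               percentile = as.numeric(r$ranking$percentiles),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  sm <- do.call(rbind, lapply(split(out$percentile, out$layer), function(v) {
    data.frame(n = length(v), q1 = stats::quantile(v, 0.25, names = FALSE),
               median = stats::median(v),
               q3 = stats::quantile(v, 0.75, names = FALSE))
  }))
  sm$layer <- as.integer(rownames(sm))
  attr(out, "summary") <- sm[, c("layer", "n", "q1", "median", "q3")]
  out
}

#' Classical node-ranking baselines
#'
#' PageRank (damping 0.85, uniform teleport, confidence weights), node
#' degree (interaction count), normalized betweenness (unweighted paths),
#' eigenvector centrality (confidence weights) and the local clustering
#' coefficient (isolated/degree-1 nodes get 0).
#'
#' @param net an undirected [gene_network].
#' @return named list of named numeric score vectors, one per method:
#'   `pagerank`, `degree`, `betweenness`, `eigenvector`,
#'   `clustering_coefficient`.
#' @export
baseline_rankers <- function(net) {
  g <- as_igraph(net)
  w <- if (n_edges(net)) igraph::E(g)$weight else NULL
  pr <- igraph::page_rank(g, damping = 0.85, weights = w)$vector
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA, normalized = TRUE)
  ev <- igraph::eigen_centrality(g, weights = w)$vector
  cc <- igraph::transitivity(g, type = "local", isolates = "zero")
  names(cc) <- igraph::V(g)$name
  lapply(list(pagerank = pr, degree = deg, betweenness = btw,
              eigenvector = ev, clustering_coefficient = cc),
         function(v) v[net$nodes])
}

#' Pearson correlation between two gene rankings
#'
#' @param a,b named numeric score vectors; compared over their shared
#'   genes (at least 3 required).
#' @return list with `r` (correlation) and `p` (two-sided p-value).
#' @export
compare_rankings <- function(a, b) {
  shared <- intersect(names(a), names(b))
  if (length(shared) < 3) stop("need at least 3 shared genes")
  x <- as.numeric(a[shared])
  y <- as.numeric(b[shared])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in one ranking")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(shared))
}

#' Assign levels to a directed pathway-to-pathway network
#'
#' Five steps: (1) all-pairs shortest hop distances; (2) the longest
#' shortest path defines a spine numbered 1..n from its upstream to its
#' downstream end (ties broken lexicographically; along the spine the
#' lexicographically smallest shortest path is taken); (3) each unassigned
#' pathway gets candidate levels from every assigned pathway it connects
#' to, offsetting the assigned level by the shortest distance (subtracting
#' when the unassigned pathway lies upstream); (4) multiple candidates are
#' averaged; (5) steps 3-4 repeat until no pathway can be reached, after
#' which any disconnected remainder is levelled recursively on its own.
#'
#' @param net a directed [gene_network] whose nodes are pathway
#'   identifiers.
#' @return named numeric vector of levels (may be fractional after
#'   averaging).
#' @export
pathway_levels <- function(net) {
  if (!net$directed) stop("pathway-level assignment requires directed input")
  if (!length(net$nodes)) stop("empty pathway network")
  assign_component <- function(nodes, D) {
    levels <- stats::setNames(rep(NA_real_, length(nodes)), nodes)
    finite <- is.finite(D) & D > 0
    if (!any(finite)) {
      levels[] <- 1
      return(levels)
    }
    dmax <- max(D[finite])
    ends <- which(D == dmax & finite, arr.ind = TRUE)
    pick <- ends[order(nodes[ends[, 1]], nodes[ends[, 2]]), , drop = FALSE][1, ]
    u <- nodes[pick[1]]; v <- nodes[pick[2]]
    # lexicographically smallest shortest path u -> v
    spine <- u
    cur <- u
    remaining <- dmax
    while (cur != v) {
      succ <- nodes[is.finite(D[cur, ]) & D[cur, ] == 1 &
                      D[, v] == remaining - 1]
      succ <- sort(succ)
      cur <- succ[1]
      spine <- c(spine, cur)
      remaining <- remaining - 1
    }
    levels[spine] <- seq_along(spine)
    repeat {
      todo <- names(levels)[is.na(levels)]
      if (!length(todo)) break
      done <- names(levels)[!is.na(levels)]
      newly <- stats::setNames(rep(NA_real_, length(todo)), todo)
      for (q in todo) {
        down <- is.finite(D[q, done])   # q upstream of an assigned pathway
        up <- is.finite(D[done, q])     # q downstream of an assigned pathway
        cand <- c(levels[done][down] - D[q, done][down],
                  levels[done][up] + D[done, q][up])
        if (length(cand)) newly[q] <- mean(cand)
      }
      hit <- !is.na(newly)
      if (!any(hit)) break
      levels[names(newly)[hit]] <- newly[hit]
    }
    levels
  }
  g <- as_igraph(net)
  D <- igraph::distances(g, mode = "out")
  levels <- stats::setNames(rep(NA_real_, length(net$nodes)), net$nodes)
  remaining <- net$nodes
  while (length(remaining)) {
    Dr <- D[remaining, remaining, drop = FALSE]
    lv <- assign_component(remaining, Dr)
    got <- names(lv)[!is.na(lv)]
    levels[got] <- lv[got]
    remaining <- setdiff(remaining, got)
  }
  levels
}

#' Correlate pathway levels with exponential rank bins
#'
#' The ranked significant genes are cut into nested top-2^x bins
#' (x = 1..`max_exponent`). For each x, the pathways hit by the top 2^x
#' genes minus those already hit by smaller bins are that bin's "add-on"
#' pathways; the pairs (x, add-on pathway level) feed a Pearson
#' correlation.
#'
#' @param ranked_genes character vector of significant genes ordered best
#'   first.
#' @param gene_pathways data.frame with columns `gene` and `pathway`.
#' @param levels named numeric pathway levels (see [pathway_levels()]);
#'   add-on pathways without a level are dropped.
#' @param max_exponent largest exponent x.
#' @return list with `r` (Pearson correlation), `p`, and `table`
#'   (data.frame `bin`, `pathway`, `level`).
#' @export
bin_level_correlation <- function(ranked_genes, gene_pathways, levels,
                                  max_exponent = 4) {
  stopifnot(length(ranked_genes) >= 1, max_exponent >= 1)
  seen <- character(0)
  rows <- list()
  for (x in seq_len(max_exponent)) {
    top <- utils::head(ranked_genes, 2^x)
    paths <- unique(gene_pathways$pathway[gene_pathways$gene %in% top])
    addon <- setdiff(paths, seen)
    seen <- union(seen, paths)
    addon <- addon[addon %in% names(levels)]
    if (length(addon)) {
      rows[[length(rows) + 1]] <- data.frame(
        bin = x, pathway = addon, level = as.numeric(levels[addon]),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) < 3) {
    stop("no (or too few) add-on pathways across bins; correlation undefined")
  }
  if (stats::sd(tab$level) == 0 || stats::sd(tab$bin) == 0) {
    stop("correlation undefined: zero variance in levels or bins")
  }
  ct <- stats::cor.test(tab$bin, tab$level, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, table = tab)
}
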