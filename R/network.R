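#' Construct a weighted gene-gene interaction network
#'
#' `gene_network` is the package's central container: a set of opaque,
#' case-sensitive gene identifiers and a set of confidence-weighted
#' interactions between them. Confidence scores live in \[0, 1\]; when a data
#' source carries no confidences, every interaction gets confidence 1. For a
#' directed network an edge `from -> to` means "`from` regulates `to`".
#'
#' Self-loops are dropped (with a message reporting how many) because the
#' propagation model gives them no meaning, and duplicate node pairs are
#' merged keeping the maximum confidence, i.e. the strongest piece of
#' evidence for the interaction wins.
#'
#' @param edges data.frame with columns `from`, `to` and optionally
#'   `confidence` (numeric in \[0, 1\]).
#' @param nodes character vector of node identifiers; defaults to the nodes
#'   appearing in `edges`. Extra identifiers become isolated nodes.
#' @param directed logical; interpret edges as regulator -> target?
#' @param default_confidence confidence assigned to edges lacking one.
#' @return An object of class `gene_network`: a list with elements `nodes`
#'   (character), `edges` (data.frame `from`, `to`, `confidence`) and
#'   `directed` (logical). Undirected edges are stored with `from < to`.
#' @examples
#' net <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C"),
#'                                confidence = c(0.9, 0.4)))
#' net
#' @export
gene_network <- function(edges = NULL, nodes = NULL, directed = FALSE,
                         default_confidence = 1) {
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        confidence = numeric())
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("`edges` must have columns `from` and `to`")
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(edges$confidence)) {
    edges$confidence <- rep(default_confidence, nrow(edges))
  }
  edges$confidence <- as.numeric(edges$confidence)
  edges$confidence[is.na(edges$confidence)] <- default_confidence
  if (anyNA(edges$from) || anyNA(edges$to)) stop("edge endpoints contain NA")
  bad <- edges$confidence < 0 | edges$confidence > 1
  if (any(bad)) {
    stop(sprintf("confidence outside [0, 1] for %d edge(s), e.g. %s-%s (%g)",
                 sum(bad), edges$from[which(bad)[1]], edges$to[which(bad)[1]],
                 edges$confidence[which(bad)[1]]))
  }
  loops <- edges$from == edges$to
  if (any(loops)) {
    message(sprintf("dropping %d self-loop(s)", sum(loops)))
    edges <- edges[!loops, , drop = FALSE]
  }
  if (!directed && nrow(edges)) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
  }
  if (nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    if (anyDuplicated(key)) {
      conf <- tapply(edges$confidence, key, max)
      keep <- !duplicated(key)
      edges <- edges[keep, , drop = FALSE]
      edges$confidence <- as.numeric(conf[paste(edges$from, edges$to,
                                                sep = "\r")])
    }
    ord <- order(edges$from, edges$to)
    edges <- edges[ord, , drop = FALSE]
  }
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(nodes, edges$from, edges$to)))
  structure(list(nodes = all_nodes,
                 edges = edges[, c("from", "to", "confidence")],
                 directed = isTRUE(directed)),
            class = "gene_network")
}

#' @export
print.gene_network <- function(x, ...) {
  cat(sprintf("<gene_network> %s, %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Number of edges / nodes of a gene network
#' @param net a `gene_network`
#' @return integer count
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_edges
#' @export
n_nodes <- function(net) length(net$nodes)

#' Read a weighted edge table or SIF file into a `gene_network`
#'
#' Accepts tab-separated tables with a header naming at least `source` and
#' `target` columns (a `confidence` column is optional; `from`/`to` are
#' accepted as synonyms), or the simple interaction format (`*.sif`:
#' `nodeA relation nodeB`, no header, confidence 1).
#'
#' @param path file path.
#' @param directed logical; treat the first column as the regulator.
#' @param default_confidence value used where no confidence is given.
#' @return a validated [gene_network].
#' @export
read_edge_table <- function(path, directed = FALSE, default_confidence = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.sif$", path, ignore.case = TRUE)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "[\t ]+")
    nfield <- lengths(parts)
    if (any(nfield < 3)) {
      stop("malformed SIF row at line ", which(nfield < 3)[1])
    }
    edges <- data.frame(from = vapply(parts, `[`, "", 1),
                        to = vapply(parts, `[`, "", 3),
                        confidence = 1, stringsAsFactors = FALSE)
    return(gene_network(edges, directed = directed,
                        default_confidence = default_confidence))
  }
  tab <- tryCatch(
    utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                      comment.char = "#", check.names = FALSE),
    error = function(e) stop("cannot parse edge table ", path, ": ",
                             conditionMessage(e)))
  nm <- tolower(names(tab))
  src <- match(TRUE, nm %in% c("source", "from"))
  tgt <- match(TRUE, nm %in% c("target", "to"))
  if (is.na(src) || is.na(tgt)) {
    stop("edge table needs `source`/`target` (or `from`/`to`) columns")
  }
  conf <- match("confidence", nm)
  edges <- data.frame(from = as.character(tab[[src]]),
                      to = as.character(tab[[tgt]]),
                      stringsAsFactors = FALSE)
  if (!is.na(conf)) {
    cv <- suppressWarnings(as.numeric(tab[[conf]]))
    bad <- is.na(cv) & !is.na(tab[[conf]]) & nzchar(as.character(tab[[conf]]))
    if (any(bad)) {
      stop("malformed confidence at data line ", which(bad)[1])
    }
    edges$confidence <- cv
  }
  gene_network(edges, directed = directed,
               default_confidence = default_confidence)
}

#' Read a seed-gene list
#'
#' One identifier per line; blank lines and lines starting with `#` are
#' ignored; duplicates are removed keeping first occurrence order.
#'
#' @param path file path.
#' @return character vector of unique seed identifiers.
#' @export
read_seed_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  seeds <- unique(lines)
  if (!length(seeds)) stop("no seeds found in ", path)
  seeds
}

#' Induced subnetwork on a set of genes
#'
#' Keeps the edges with both endpoints in `genes`. Genes absent from the
#' network are retained as isolated nodes, with a warning, so that a seed
#' list can be carried through even when some members lack interactions.
#'
#' @param net a [gene_network].
#' @param genes character vector of identifiers.
#' @return a [gene_network] over `genes`.
#' @export
induced_subnetwork <- function(net, genes) {
  genes <- unique(as.character(genes))
  unknown <- setdiff(genes, net$nodes)
  if (length(unknown)) {
    warning(sprintf("%d gene(s) not in network kept as isolated nodes: %s",
                    length(unknown),
                    paste(utils::head(unknown, 5), collapse = ", ")))
  }
  keep <- net$edges$from %in% genes & net$edges$to %in% genes
  gene_network(net$edges[keep, , drop = FALSE], nodes = genes,
               directed = net$directed)
}

#' Per-gene interaction statistics
#'
#' For every gene computes `w`, the sum of confidence scores of its
#' interactions under the requested mode; `I`, the number of those
#' interactions; and `W`, the total confidence of all its interactions in
#' the global collection (always counted over every incident edge,
#' irrespective of mode).
#'
#' Modes for a directed network: `"upstream"` counts the relationships the
#' gene regulates (out-edges), `"downstream"` the relationships in which it
#' is regulated (in-edges).
#'
#' @param net a [gene_network].
#' @param global_net optional [gene_network] holding the full interaction
#'   collection; defaults to `net`.
#' @param mode one of `"undirected"`, `"upstream"`, `"downstream"`.
#' @return data.frame with columns `gene`, `w`, `I`, `W`, one row per node
#'   of `net`, ordered as `net$nodes`.
#' @export
node_stats <- function(net, global_net = NULL,
                       mode = c("undirected", "upstream", "downstream")) {
  mode <- match.arg(mode)
  if (mode != "undirected" && !net$directed) {
    stop("mode '", mode, "' requires a directed network")
  }
  n <- length(net$nodes)
  idx_from <- match(net$edges$from, net$nodes)
  idx_to <- match(net$edges$to, net$nodes)
  conf <- net$edges$confidence
  zero <- numeric(n)
  sum_at <- function(idx, val) {
    out <- zero
    if (length(idx)) {
      s <- tapply(val, idx, sum)
      out[as.integer(names(s))] <- as.numeric(s)
    }
    out
  }
  if (mode == "undirected") {
    w <- sum_at(c(idx_from, idx_to), c(conf, conf))
    I <- sum_at(c(idx_from, idx_to), rep(1, 2 * length(conf)))
  } else if (mode == "upstream") {
    w <- sum_at(idx_from, conf)
    I <- sum_at(idx_from, rep(1, length(conf)))
  } else {
    w <- sum_at(idx_to, conf)
    I <- sum_at(idx_to, rep(1, length(conf)))
  }
  gnet <- if (is.null(global_net)) net else global_net
  gi_from <- match(gnet$edges$from, net$nodes)
  gi_to <- match(gnet$edges$to, net$nodes)
  gconf <- gnet$edges$confidence
  keep_f <- !is.na(gi_from)
  keep_t <- !is.na(gi_to)
  W <- sum_at(c(gi_from[keep_f], gi_to[keep_t]),
              c(gconf[keep_f], gconf[keep_t]))
  data.frame(gene = net$nodes, w = w, I = I, W = W,
             stringsAsFactors = FALSE)
}

#' Write a ranking result to a TSV file
#'
#' Columns: `gene`, `score`, `rank`, `percentile`, `p_r`, `mu`, `sigma`.
#' Significance columns are empty when not computed. Rows are ordered by
#' rank then identifier so output is deterministic.
#'
#' @param result a `winner_ranking` (see [winner_rank()]), optionally
#'   carrying significance columns from [score_significance()].
#' @param path output file path.
#' @param comments optional character vector written as `#`-prefixed header
#'   lines (provenance).
#' @return `path`, invisibly.
#' @export
write_scores <- function(result, path, comments = NULL) {
  tab <- as.data.frame(result)
  ord <- order(tab$rank, tab$gene)
  tab <- tab[ord, , drop = FALSE]
  for (col in c("p_r", "mu", "sigma")) {
    if (is.null(tab[[col]])) tab[[col]] <- NA_real_
  }
  tab <- tab[, c("gene", "score", "rank", "percentile", "p_r", "mu", "sigma")]
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  suppressWarnings(utils::write.table(
    format(tab, digits = 15, trim = TRUE, scientific = NA),
    con, sep = "\t", quote = FALSE, row.names = FALSE, na = ""))
  invisible(path)
}

#' Read a score table written by [write_scores()]
#' @param path file path.
#' @return data.frame with the score columns, numeric where appropriate.
#' @export
read_scores <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  for (col in c("score", "rank", "percentile", "p_r", "mu", "sigma")) {
    if (!is.null(tab[[col]])) tab[[col]] <- as.numeric(tab[[col]])
  }
  tab
}

#' Write a `gene_network` as a TSV edge table
#' @param net a [gene_network].
#' @param path output path.
#' @param comments optional `#` header lines.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(net, path, comments = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  tab <- net$edges
  names(tab) <- c("source", "target", "confidence")
  suppressWarnings(utils::write.table(
    format(tab, digits = 15, trim = TRUE),
    con, sep = "\t", quote = FALSE, row.names = FALSE))
  invisible(path)
}

# igraph view of a gene_network (edge attribute `weight` = confidence)
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(net$edges, directed = net$directed,
                                     vertices = data.frame(name = net$nodes))
  if (nrow(net$edges)) {
    igraph::E(g)$weight <- net$edges$confidence
  }
  g
}
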