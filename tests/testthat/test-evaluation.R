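test_that("precision/recall/F1 follow their definitions", {
  full <- precision_recall_f1(c("a", "b"), c("a", "b"))
  expect_equal(unlist(full), c(precision = 1, recall = 1, f1 = 1))

  part <- precision_recall_f1(c("a", "b", "c", "d"), c("a", "b", "x", "y", "z"))
  expect_equal(part$precision, 0.5)
  expect_equal(part$recall, 0.4)
  expect_equal(part$f1, 2 * 0.5 * 0.4 / 0.9)

  none <- precision_recall_f1(c("a"), c("b"))
  expect_equal(unlist(none), c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(character(), c("a"))$precision, 0)
  # all metrics bounded by [0,1] on random sets
  set.seed(1)
  for (i in 1:10) {
    E <- sample(letters, sample(0:10, 1))
    U <- sample(letters, sample(1:10, 1))
    m <- precision_recall_f1(E, U)
    expect_true(all(unlist(m) >= 0 & unlist(m) <= 1))
    expect_lte(m$f1, 2 * min(m$precision, m$recall) /
                 max(1e-12, 1 + min(m$precision, m$recall)) + 1e-12)
  }
})

test_that("layer assignment collapses cycles and counts from the roots", {
  chain <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                        directed = TRUE)
  la <- bfs_layers(chain)
  expect_equal(la$layers, c(A = 1L, B = 2L, C = 3L))

  cyc <- gene_network(data.frame(from = c("A", "B", "C", "C"),
                                 to = c("B", "C", "B", "D")),
                      directed = TRUE)
  lc <- bfs_layers(cyc)
  expect_equal(lc$layers, c(A = 1L, B = 2L, C = 2L, D = 3L))
  expect_equal(lc$groups[["B"]], lc$groups[["C"]])

  ring <- gene_network(data.frame(from = c("A", "B", "C"),
                                  to = c("B", "C", "A")),
                       directed = TRUE)
  expect_equal(unname(bfs_layers(ring)$layers), c(1L, 1L, 1L))

  # contracting an acyclic graph changes nothing
  dag <- make_layered_dag(4, 3, 0.7, rng_seed = 5)
  ld <- bfs_layers(dag)
  expect_equal(length(unique(ld$groups)), length(dag$nodes))
  expect_equal(as.integer(ld$layers), as.integer(attr(dag, "true_layers")))

  expect_error(bfs_layers(triangle_net()), "directed")
})

test_that("percentiles pool by layer across pathways", {
  chain <- gene_network(data.frame(from = c("A", "B"), to = c("B", "C")),
                        directed = TRUE)
  up <- winner_rank(chain, config = ranking_config(mode = "upstream"))
  pooled <- percentile_by_layer(list(list(ranking = up,
                                          layers = bfs_layers(chain))))
  expect_equal(pooled$percentile[pooled$layer == 1], 100)

  # uniform scores: every gene sits at the 50th percentile after tie-averaging
  ring <- gene_network(data.frame(from = c("A", "B", "C"),
                                  to = c("B", "C", "A")),
                       directed = TRUE)
  upr <- winner_rank(ring, config = ranking_config(mode = "upstream"))
  pooled2 <- percentile_by_layer(list(list(ranking = upr,
                                           layers = bfs_layers(ring))))
  expect_true(all(pooled2$percentile == 50))
})

test_that("baseline centralities follow their standard conventions", {
  reg <- make_regular_graph(10, 4, rng_seed = 3)
  base <- baseline_rankers(reg)
  expect_equal(length(unique(round(base$degree, 12))), 1)
  expect_equal(length(unique(round(base$eigenvector, 6))), 1)

  star <- star_net(4)
  bs <- baseline_rankers(star)
  expect_equal(unname(bs$betweenness[paste0("L", 1:4)]), rep(0, 4))
  expect_gt(bs$betweenness[["HUB"]], 0)

  tri <- triangle_net()
  expect_equal(unname(baseline_rankers(tri)$clustering_coefficient),
               rep(1, 3))
})

test_that("ranking comparisons use Pearson correlation over shared genes", {
  a <- c(A = 1, B = 2, C = 3, D = 4)
  expect_equal(compare_rankings(a, a)$r, 1)
  expect_equal(compare_rankings(a, -a)$r, -1)
  expect_error(compare_rankings(a[1:2], a[1:2]), "at least 3")
  expect_error(compare_rankings(a, c(A = 1, B = 1, C = 1, D = 1)),
               "zero variance")

  # unweighted identity: converged scores equal degree, so r = 1 vs degree
  net <- make_scale_free_weighted(40, 2, weight_dist = "unit", rng_seed = 2)
  res <- winner_rank(net)
  base <- baseline_rankers(net)
  expect_equal(compare_rankings(res$scores, base$degree)$r, 1,
               tolerance = 1e-12)
})

test_that("pathway levels follow the spine-and-offset procedure", {
  chain <- gene_network(data.frame(from = c("P1", "P2"), to = c("P2", "P3")),
                        directed = TRUE)
  expect_equal(pathway_levels(chain), c(P1 = 1, P2 = 2, P3 = 3))

  plus <- gene_network(data.frame(from = c("P1", "P2", "P0"),
                                  to = c("P2", "P3", "P2")),
                       directed = TRUE)
  lv <- pathway_levels(plus)
  expect_equal(lv[["P0"]], 1)   # one step upstream of level-2 P2
  expect_equal(lv[["P3"]], 3)

  # two equal-length spines: deterministic lexicographic choice, offsets
  # reconcile the other branch by averaging
  fork <- gene_network(data.frame(from = c("A1", "A2", "B1", "B2"),
                                  to = c("A2", "C", "B2", "C")),
                       directed = TRUE)
  lf <- pathway_levels(fork)
  expect_equal(lf[["A1"]], 1)
  expect_equal(lf[["C"]], 3)
  expect_equal(lf[["B2"]], 2)
  expect_equal(pathway_levels(fork), pathway_levels(fork))  # deterministic

  # relabelling pathways leaves the multiset of levels unchanged
  relab <- gene_network(data.frame(from = c("Z9", "Z8", "Z0"),
                                   to = c("Z8", "Z7", "Z8")),
                        directed = TRUE)
  expect_equal(sort(unname(pathway_levels(relab))),
               sort(unname(pathway_levels(plus))))
  expect_error(pathway_levels(gene_network(directed = TRUE)), "empty")
})

test_that("bin-level correlation finds monotone add-on structure", {
  # constructed monotone case: each bin's add-on pathways one level deeper
  genes <- paste0("g", 1:16)
  gp <- data.frame(gene = genes,
                   pathway = rep(paste0("pw", 1:4), times = c(2, 2, 4, 8)))
  levels <- c(pw1 = 1, pw2 = 2, pw3 = 3, pw4 = 4)
  out <- bin_level_correlation(genes, gp, levels, max_exponent = 4)
  expect_equal(out$r, 1)
  expect_equal(nrow(out$table), 4)

  # constant levels: undefined correlation
  flat <- c(pw1 = 2, pw2 = 2, pw3 = 2, pw4 = 2)
  expect_error(bin_level_correlation(genes, gp, flat, 4), "zero variance")

  # noisy monotone fixture recovers a clear positive correlation
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    gp2 <- data.frame(gene = paste0("g", 1:16),
                      pathway = paste0("q", 1:16))
    lv <- stats::setNames(rep(1:4, times = c(2, 2, 4, 8)) +
                            stats::rnorm(16, 0, 0.5), paste0("q", 1:16))
    bin_level_correlation(paste0("g", 1:16), gp2, lv, 4)$r > 0.5
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})
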