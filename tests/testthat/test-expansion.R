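test_that("candidate pools are the non-ranked neighbours of ranked genes", {
  star <- star_net(5)
  expect_setequal(candidate_pool("HUB", star), paste0("L", 1:5))
  expect_length(candidate_pool(star$nodes, star), 0)

  two_comp <- gene_network(data.frame(from = c("A", "C"), to = c("B", "D")))
  expect_equal(candidate_pool("A", two_comp), "B")
})

test_that("upper-tail hypergeometric matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(10, 5, 2, 2), 10 / 45, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(20, 5, 4, 2), 1205 / 4845,
               tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(10, 5, 3, 0), 1)
  # spot-check random parameter combinations against brute force
  set.seed(7)
  for (i in 1:25) {
    N <- sample(2:11, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:min(n, K), 1)
    expect_equal(hypergeom_upper_tail(N, K, n, k),
                 enumerate_hyper_tail(N, K, n, k), tolerance = 1e-10)
  }
  expect_error(hypergeom_upper_tail(5, 6, 2, 1), "invalid")
  expect_error(hypergeom_upper_tail(5, 2, 2, 3), "invalid")
})

test_that("expansion test 1 uses the global universe", {
  # candidate X with 3 neighbours, all ranked; universe of 10 genes, 5 ranked
  edges <- data.frame(
    from = c("X", "X", "X", "R4", "R5", "U1", "U2"),
    to = c("R1", "R2", "R3", "R5", "U1", "U2", "U3"))
  extra <- gene_network(edges, nodes = c(edges$from, edges$to, "U4"))
  ranked <- paste0("R", 1:5)
  expect_equal(length(extra$nodes), 10)
  expect_equal(expansion_test1("X", ranked, extra),
               enumerate_hyper_tail(9, 5, 3, 3), tolerance = 1e-10)
  # no ranked neighbours
  expect_equal(expansion_test1("U3", ranked, extra), 1)
})

test_that("expansion test 2 compares against the degree-closest ranked gene", {
  # reference seed S1: degree 4, 2 ranked neighbours; candidate X: degree 3,
  # 2 ranked neighbours
  edges <- data.frame(
    from = c("S1", "S1", "S1", "S1", "X", "X", "X"),
    to = c("S2", "S3", "B1", "B2", "S2", "S3", "B3"))
  net <- gene_network(edges)
  ranked <- c("S1", "S2", "S3")
  t2 <- expansion_test2("X", ranked, net)
  expect_equal(t2$matched_seed, "S1")   # |4-3| ties |2-3|; larger degree wins
  expect_equal(t2$p2e, enumerate_hyper_tail(4, 2, 3, 2), tolerance = 1e-10)

  # monotone in the candidate's seed links at fixed degree
  edges_lo <- data.frame(from = c("S1", "S1", "S1", "S1", "Y", "Y", "Y"),
                         to = c("S2", "S3", "B1", "B2", "S2", "B3", "B4"))
  lo <- expansion_test2("Y", ranked, gene_network(edges_lo))$p2e
  expect_lte(t2$p2e, lo)

  # candidates without seeded links are never significant
  edges0 <- data.frame(from = c("S1", "Z"), to = c("S2", "B1"))
  expect_equal(expansion_test2("Z", c("S1", "S2"),
                               gene_network(edges0))$p2e, 1)
})

test_that("candidate filtering applies the AND rule and records pe = max", {
  pool_tab <- function(p1, p2) {
    data.frame(gene = "X", degree_global = 1L, seed_links = 1L,
               matched_seed = "S", p1e = p1, p2e = p2,
               pe = max(p1, p2), pass = p1 < 0.05 && p2 < 0.05)
  }
  expect_false(pool_tab(0.01, 0.2)$pass)
  ok <- pool_tab(0.01, 0.03)
  expect_true(ok$pass)
  expect_equal(ok$pe, 0.03)
  expect_equal(nrow(filter_candidates(character(), "S",
                                      star_net(2))), 0)

  # end-to-end: a filtered table only contains candidates passing both tests
  set.seed(2)
  bg <- make_scale_free_weighted(80, 2, rng_seed = 21)
  pl <- plant_expansion_module(bg, 12, 0.8, 4, rng_seed = 22)
  tab <- filter_candidates(candidate_pool(pl$seeds, pl$network), pl$seeds,
                           pl$network, keep_all = TRUE)
  kept <- filter_candidates(candidate_pool(pl$seeds, pl$network), pl$seeds,
                            pl$network)
  expect_true(all(kept$p1e < 0.05 & kept$p2e < 0.05))
  expect_equal(kept$pe, pmax(kept$p1e, kept$p2e))
  expect_true(all(tab$gene[tab$pass] %in% kept$gene))
})

test_that("expansion scores weight seed scores by global confidence", {
  # candidate X: edges to j1 (c 0.8, S 2, W 4) and j2 (c 0.5, S 1, W 2)
  edges <- data.frame(
    from = c("X", "X", "j1", "j1", "j1", "j1", "j2", "j2"),
    to = c("j1", "j2", "a", "b", "c", "f", "d", "e"),
    confidence = c(0.8, 0.5, 1, 1, 1, 0.2, 0.75, 0.75))
  net <- gene_network(edges)   # W(j1) = 4.0; W(j2) = 2.0
  scores <- c(j1 = 2, j2 = 1)
  e <- expansion_score("X", c("j1", "j2"), scores, net)
  expect_equal(e, 0.65, tolerance = 1e-12)
  expect_equal(expansion_score("d", "j1", c(j1 = 2), net), 0)
  # linear in the scores
  expect_equal(expansion_score("X", c("j1", "j2"), 2 * scores, net), 2 * e,
               tolerance = 1e-12)
})

test_that("the expansion loop adds one justified gene per iteration", {
  set.seed(5)
  bg <- make_scale_free_weighted(150, 2, rng_seed = 31)
  pl <- plant_expansion_module(bg, 16, 0.8, 6, rng_seed = 32)

  none <- expand_network(pl$seeds, pl$network, max_add = 0)
  expect_equal(nrow(none$added), 0)
  expect_setequal(names(none$result$scores), pl$seeds)

  ex <- expand_network(pl$seeds, pl$network, max_add = 6)
  expect_lte(nrow(ex$added), 6)
  expect_true(all(ex$added$p1e < 0.05 & ex$added$p2e < 0.05))
  expect_equal(ex$added$iteration_added, seq_len(nrow(ex$added)))
  expect_setequal(names(ex$result$scores), c(pl$seeds, ex$added$gene))

  # deterministic: no randomness in the loop
  ex2 <- expand_network(pl$seeds, pl$network, max_add = 6)
  expect_equal(ex$added, ex2$added)
})
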