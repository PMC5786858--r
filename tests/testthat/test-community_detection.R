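test_that("modularity matches closed-form values on toy graphs", {
  g <- two_triangles()
  m <- c(a = 1, b = 1, c = 1, d = 2, e = 2, f = 2)
  expect_equal(modularity_q(g, m), 0.5)                 # 2*(3/6 - (6/12)^2)
  expect_equal(modularity_q(g, c(a = 1, b = 1, c = 1, d = 1, e = 1, f = 1)), 0)

  # two 4-cliques joined by one bridge: W=13, W_c={6,6}, S_c={13,13}
  el <- rbind(t(combn(paste0("x", 1:4), 2)), t(combn(paste0("y", 1:4), 2)),
              c("x1", "y1"))
  g2 <- igraph::graph_from_edgelist(el, directed = FALSE)
  m2 <- stats::setNames(rep(1:2, each = 4), c(paste0("x", 1:4), paste0("y", 1:4)))
  expect_equal(modularity_q(g2, m2), 2 * (6 / 13) - 2 * (13 / 26)^2)

  # agrees with igraph's implementation on a weighted random graph
  set.seed(3)
  g3 <- igraph::sample_gnp(25, 0.2)
  igraph::V(g3)$name <- sprintf("n%02d", 1:25)
  igraph::E(g3)$weight <- sample(1:900, igraph::ecount(g3), TRUE)
  mm <- stats::setNames(sample(1:4, 25, TRUE), igraph::V(g3)$name)
  expect_equal(modularity_q(g3, mm),
               igraph::modularity(g3, mm, weights = igraph::E(g3)$weight))
})

test_that("modularity input validation", {
  g <- two_triangles()
  expect_error(modularity_q(g, c(a = 1, b = 1, c = 1, d = 2, e = 2)), "f")
  expect_error(modularity_q(igraph::make_empty_graph(0), integer()), "empty")
})

test_that("louvain recovers the obvious optimum on toy graphs", {
  p <- louvain_partition(two_triangles(), seed = 1)
  expect_equal(length(unique(p$membership)), 2)
  expect_equal(p$modularity, 0.5)
  expect_equal(unname(p$membership[c("a", "b", "c")]), rep(0L, 3))

  # ring of 4 K5 cliques with single bridges -> one module per clique
  g <- clique_ring(5, 4)
  p <- louvain_partition(g, seed = 2)
  expect_equal(length(unique(p$membership)), 4)
  tags <- substr(names(p$membership), 1, 1)
  expect_true(all(tapply(p$membership, tags, function(x) length(unique(x))) == 1))
  # the clique partition beats any merge of adjacent cliques
  merged <- stats::setNames(match(tags, letters), names(p$membership))
  merged[tags == "b"] <- 1   # merge cliques a and b
  expect_gt(p$modularity, modularity_q(g, merged))
})

test_that("louvain Q never falls below singleton Q and is locally optimal vs brute force", {
  set.seed(21)
  for (rep in 1:4) {
    g <- igraph::sample_gnp(7, 0.5)
    while (igraph::ecount(g) < 3) g <- igraph::sample_gnp(7, 0.5)
    igraph::V(g)$name <- letters[1:7]
    p <- louvain_partition(g, seed = rep)
    singletons <- stats::setNames(1:7, letters[1:7])
    expect_gte(p$modularity, modularity_q(g, singletons))
    expect_lte(p$modularity, brute_best_q(g) + 1e-9)
  }
  # and exact global optimum on the listed toys
  expect_equal(louvain_partition(two_triangles(), seed = 5)$modularity,
               brute_best_q(two_triangles()))
})

test_that("determinism and stability across seeds on separated SBMs", {
  s <- sbm_spec(rep(25, 6), p_in = 0.3, p_out = 0.005, seed = 99)
  sim <- generate_sbm(s)
  p1 <- louvain_partition(sim$graph, seed = 4)
  p2 <- louvain_partition(sim$graph, seed = 4)
  expect_identical(p1$membership, p2$membership)
  expect_identical(p1$modularity, p2$modularity)
  p3 <- louvain_partition(sim$graph, seed = 5)
  expect_gte(adjusted_rand_index(p1$membership, p3$membership), 0.95)
  # stored modularity is recomputable from the assignment
  expect_equal(p1$modularity, modularity_q(sim$graph, p1$membership),
               tolerance = 1e-9)
})

test_that("labels are canonical: 0..M-1, sizes non-increasing", {
  s <- sbm_spec(c(30, 20, 10), p_in = 0.5, p_out = 0.01, seed = 12)
  p <- louvain_partition(generate_sbm(s)$graph, seed = 1)
  summ <- partition_summary(p)
  expect_equal(summ$module, seq_len(nrow(summ)) - 1L)
  expect_true(all(diff(summ$size) <= 0))
  expect_equal(sum(summ$size), 60)
})

test_that("partition_summary and as_partition", {
  p <- louvain_partition(two_triangles(), seed = 1)
  expect_equal(partition_summary(p),
               data.frame(module = 0:1, size = c(3L, 3L)))
  m <- stats::setNames(c(9, 9, 9, 9, 4), paste0("n", 1:5))
  ap <- as_partition(m)
  expect_equal(sort(unique(ap$membership)), 0:1)
  expect_equal(partition_summary(ap)$size, c(4L, 1L))
  expect_equal(vapply(module_members(ap), length, integer(1)),
               c("0" = 4L, "1" = 1L))
})

test_that("adjusted_rand_index agrees with the pair-counting oracle", {
  set.seed(8)
  for (rep in 1:5) {
    a <- sample(1:4, 30, TRUE)
    b <- sample(1:3, 30, TRUE)
    expect_equal(adjusted_rand_index(a, b), ari_pairs_oracle(a, b))
  }
  expect_equal(adjusted_rand_index(c(x = 1, y = 1, z = 2),
                                   c(z = 5, x = 7, y = 7)), 1)
})
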