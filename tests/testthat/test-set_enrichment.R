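test_that("hypergeometric upper tail matches the enumeration oracle", {
  expect_equal(hypergeom_upper_tail(0, 5, 4, 10), 1)
  expect_equal(hypergeom_upper_tail(4, 5, 4, 10), 5 / 210)  # C(5,4)C(5,0)/C(10,4)

  # full enumeration across k for a fixed urn
  for (k in 0:8) {
    expect_equal(hypergeom_upper_tail(k, 10, 8, 30),
                 hyper_tail_oracle(k, 10, 8, 30), tolerance = 1e-12)
  }
  # random urns, N <= 60
  set.seed(13)
  for (rep in 1:200) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    k <- sample(0:min(K, n), 1)
    expect_equal(hypergeom_upper_tail(k, K, n, N),
                 hyper_tail_oracle(k, K, n, N), tolerance = 1e-12)
  }
})

test_that("hypergeometric pmf sums to 1 and tail is monotone in k", {
  set.seed(14)
  for (rep in 1:50) {
    N <- sample(2:60, 1)
    K <- sample(0:N, 1)
    n <- sample(1:N, 1)
    ks <- 0:min(K, n)
    pmf <- vapply(ks, function(k)
      exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)), numeric(1))
    expect_equal(sum(pmf), 1, tolerance = 1e-12)
    tails <- hypergeom_upper_tail(ks, K, n, N)
    expect_true(all(diff(tails) <= 1e-15))
  }
})

test_that("domain violations are rejected", {
  expect_error(hypergeom_upper_tail(5, 4, 10, 20), "k <= min")
  expect_error(hypergeom_upper_tail(1, 25, 10, 20), "K <= N")
  expect_error(hypergeom_upper_tail(1, 5, 30, 20), "n <= N")
  expect_error(hypergeom_upper_tail(-1, 5, 5, 20), "non-negative")
})

make_partition <- function(sizes, prefix = "M") {
  labels <- rep(seq_along(sizes) - 1L, sizes)
  nodes <- sprintf("%s%d_g%d", prefix, labels,
                   unlist(lapply(sizes, seq_len)))
  as_partition(stats::setNames(labels, nodes))
}

test_that("select_potential_modules finds intersecting modules and covered universe", {
  p <- make_partition(c(5, 5, 5))
  mm <- module_members(p)
  genes <- c(mm[["0"]][1], mm[["2"]][3])
  pot <- select_potential_modules(p, genes)
  expect_setequal(pot$modules, c(0L, 2L))
  expect_setequal(pot$universe, c(mm[["0"]], mm[["2"]]))
  expect_warning(pot2 <- select_potential_modules(p, c("zz1", "zz2")),
                 "no module")
  expect_length(pot2$modules, 0)

  # random planted instance equals brute-force per-module intersection
  set.seed(15)
  p2 <- make_partition(sample(3:10, 6, TRUE))
  g2 <- sample(names(p2$membership), 12)
  pot2 <- select_potential_modules(p2, g2)
  brute <- as.integer(names(Filter(function(m) length(intersect(m, g2)) > 0,
                                   module_members(p2))))
  expect_setequal(pot2$modules, sort(brute))
})

test_that("enrich_modules computes the urn counts and sorts by p", {
  # universe of 20, one module of 5 holding 4 of the 8 annotated genes
  p <- make_partition(c(5, 15))
  U <- names(p$membership)
  mm <- module_members(p)
  small <- names(which(lengths(mm) == 5L))     # canonical labels sort by size
  genes <- c(mm[[small]][1:4], mm[[setdiff(names(mm), small)]][1:4])
  bg <- background(U, policy = "custom")
  rec <- enrich_modules(p, genes, bg)
  r0 <- rec[rec$module == as.integer(small), ]
  expect_equal(unlist(r0[c("N", "K", "n", "k")], use.names = FALSE),
               c(20L, 8L, 5L, 4L))
  expect_equal(r0$p_value, hyper_tail_oracle(4, 8, 5, 20))
  expect_equal(rec$background_proportion, rep(8 / 20, nrow(rec)))
  expect_true(!is.unsorted(rec$p_value))

  # genes outside the universe are dropped with a logged count
  expect_message(enrich_modules(p, c(genes, "alien1", "alien2"), bg),
                 "dropped 2")

  # degenerate saturation: genes = universe -> k = n and p = 1
  rec2 <- enrich_modules(p, U, bg)
  expect_equal(rec2$k, rec2$n)
  expect_equal(rec2$p_value, rep(1, nrow(rec2)))
})

test_that("disease-module selection applies the joint criterion", {
  rec <- module_enrichment(module = 1:3,
                           k = c(10, 4, 30), n = c(24, 20, 300),
                           K = 997, N = 11380,
                           p_value = c(2.55e-4, 0.5, 1e-6))
  sel <- select_disease_modules(rec)
  expect_equal(sel$module, 1L)     # 2 fails p, 3 fails rr (0.1 < 0.2628)
  # rr_multiplier = 0 reduces to the p rule; alpha = 1 to the rr rule
  expect_equal(select_disease_modules(rec, rr_multiplier = 0)$module, c(1L, 3L))
  expect_equal(select_disease_modules(rec, alpha = 1)$module, 1L)
  expect_equal(nrow(select_disease_modules(rec, alpha = 1, rr_multiplier = 0)), 3)
  # a proportion of 0.20 fails 3 x 8.76% regardless of p
  rec2 <- module_enrichment(2, k = 20, n = 100, K = 997, N = 11380, p_value = 1e-30)
  expect_equal(nrow(select_disease_modules(rec2)), 0)
})

test_that("syndrome selection requires enrichment AND disease-module membership", {
  sym <- module_enrichment(module = c(5L, 7L, 9L),
                           k = c(10, 12, 3), n = c(24, 31, 59),
                           K = 890, N = 11380,
                           p_value = c(1.08e-4, 0.002, 0.9))
  expect_equal(select_syndrome_modules(sym, c(5L, 9L))$module, 5L)
  expect_equal(nrow(select_syndrome_modules(sym, integer())), 0)
  expect_equal(select_syndrome_modules(sym, c(5L, 7L, 9L))$module, c(5L, 7L))
})

test_that("null calibration: p < 0.01 rate within the binomial band around 0.01", {
  # 10 modules of 100 in a 1000-gene universe; 200 uniform draws of K = 100
  p <- make_partition(rep(100, 10))
  U <- names(p$membership)
  bg <- background(U, policy = "custom")
  hits <- 0L; tests <- 0L
  set.seed(1234)
  for (d in 1:200) {
    genes <- sample(U, 100)
    rec <- enrich_modules(p, genes, bg, modules = 0:9)
    hits <- hits + sum(rec$p_value < 0.01)
    tests <- tests + nrow(rec)
  }
  expect_equal(tests, 2000L)
  band <- 0.01 + c(-1, 1) * 1.96 * sqrt(0.01 * 0.99 / 2000)
  expect_gte(hits / tests, band[1])
  expect_lte(hits / tests, band[2])
})

test_that("power under 5x planted enrichment exceeds 0.9 for modules of size 50", {
  # module of 50 in a universe of 1000; background rate 0.08, planted 0.40
  set.seed(99)
  p <- make_partition(c(50, 950))
  U <- names(p$membership)
  bg <- background(U, policy = "custom")
  m0 <- module_members(p)[["0"]]
  rest <- setdiff(U, m0)
  hits <- 0L
  for (d in 1:200) {
    genes <- c(m0[stats::runif(50) < 0.40], rest[stats::runif(950) < 0.08])
    rec <- enrich_modules(p, genes, bg, modules = 0L)
    hits <- hits + (rec$p_value[1] < 0.01)
  }
  expect_gte(hits / 200, 0.9)
})
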