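test_that("score filter, undirected collapse and self-loop handling", {
  f <- string_links_fixture(c("A\tB\t900", "B\tC\t700", "C\tD\t701",
                              "D\tE\t150", "E\tF\t800"))
  g <- load_string_links(f, min_score = 700, strict = TRUE)
  expect_equal(igraph::ecount(g), 3)              # 900, 701, 800; 700 excluded
  expect_setequal(igraph::E(g)$weight, c(900, 701, 800))
  g2 <- load_string_links(f, min_score = 700, strict = FALSE)
  expect_equal(igraph::ecount(g2), 4)             # >= keeps the 700 edge

  # reciprocal duplicates collapse keeping the max score
  f <- string_links_fixture(c("A\tB\t950", "B\tA\t950", "B\tA\t960"))
  g <- load_string_links(f, min_score = 0)
  expect_equal(igraph::ecount(g), 1)
  expect_equal(igraph::E(g)$weight, 960)

  # header only -> empty graph; isolated nodes dropped
  g <- load_string_links(string_links_fixture(character()), min_score = 0)
  expect_equal(igraph::vcount(g), 0)
  expect_warning(
    g <- load_string_links(string_links_fixture(c("A\tA\t900", "A\tB\t900")),
                           min_score = 0),
    "self-loop")
  expect_equal(igraph::vcount(g), 2)
})

test_that("format errors name the column or line", {
  f <- write_lines_tmp(c("protein1\tprotein2\tscore", "A\tB\t1"))
  expect_error(load_string_links(f), "combined_score")
  f <- string_links_fixture(c("A\tB\t900", "B\tC\t7.5"))
  expect_error(load_string_links(f), "line 3.*not an integer")
  expect_error(load_string_links(string_links_fixture("A\tB"), 0), "line 2")
})

test_that("round-trip and row-permutation invariance", {
  rows <- c("A\tB\t900", "B\tC\t701", "C\tD\t801", "D\tA\t950", "A\tC\t750")
  g <- load_string_links(string_links_fixture(rows), min_score = 0)
  f2 <- tempfile()
  write_string_links(g, f2)
  g2 <- load_string_links(f2, min_score = 0)
  key <- function(g) {
    el <- igraph::as_edgelist(g)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]),
               igraph::E(g)$weight))
  }
  expect_identical(key(g), key(g2))
  g3 <- load_string_links(string_links_fixture(rev(rows)), min_score = 0)
  expect_identical(key(g), key(g3))
})

test_that("filter monotonicity: edge count non-increasing in min_score", {
  set.seed(7)
  rows <- sprintf("P%d\tQ%d\t%d", 1:60, sample(1:60), sample(0:1000, 60, TRUE))
  f <- string_links_fixture(rows)
  counts <- vapply(seq(0, 1000, by = 100), function(th)
    igraph::ecount(load_string_links(f, min_score = th)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("gene-set loading groups, dedupes and trims", {
  f <- write_lines_tmp(c("S1\tg1", "S1\t g2 ", "S1\tg2", "S2\tg3"))
  sets <- load_gene_sets(f)
  expect_length(sets, 2)
  expect_setequal(sets[[1]]$members, c("g1", "g2"))
  expect_equal(sets[[2]]$members, "g3")

  # single-column file is one unnamed set
  sets <- load_gene_sets(write_lines_tmp(c("g1", "g2", "g2", "g3", "g4")))
  expect_length(sets, 1)
  expect_length(sets[[1]]$members, 4)

  # group-and-count oracle on 1,000 random rows over 10 names
  set.seed(11)
  nm <- sprintf("S%02d", sample(10, 1000, TRUE))
  gg <- sprintf("g%03d", sample(200, 1000, TRUE))
  sets <- load_gene_sets(write_lines_tmp(paste(nm, gg, sep = "\t")))
  oracle <- vapply(split(gg, nm), function(x) length(unique(x)), integer(1))
  got <- vapply(sets, length, integer(1))
  names(got) <- vapply(sets, `[[`, character(1), "name")
  expect_equal(got[names(oracle)], oracle)

  expect_warning(load_gene_sets(write_lines_tmp("# only a comment")), "no data")
  expect_error(load_gene_sets(write_lines_tmp(c("S1\tg1", "S1\tg1\tx"))),
               "line 2")
})

test_that("GMT parsing matches an independent line-splitting oracle", {
  expect_equal(load_gmt(write_lines_tmp("TermA\tdesc\tg1\tg2\tg2"))[[1]]$members,
               c("g1", "g2"))
  expect_length(load_gmt(write_lines_tmp(character())), 0)
  expect_error(load_gmt(write_lines_tmp(c("T\td\tg1", "T2\td"))), "line 2")

  set.seed(5)
  lines <- vapply(1:50, function(i) {
    genes <- sprintf("g%03d", sample(300, sample(3:20, 1)))
    paste(c(sprintf("T%02d", i), "desc", genes), collapse = "\t")
  }, character(1))
  sets <- load_gmt(write_lines_tmp(lines))
  oracle <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  expect_equal(vapply(sets, length, integer(1)), lengths(oracle))
  expect_equal(vapply(sets, `[[`, character(1), "name"),
               vapply(strsplit(lines, "\t"), `[[`, character(1), 1))
})

test_that("bipartite map grouping and flattening", {
  rows <- c("s1\tg1", "s1\tg2", "s2\tg2", "s2\tg3", "s3\tg4", "s4\tg5",
            "s5\tg6", "s5\tg7", "s6\tg8", "s6\tg1", "s7\tg9", "s7\tg10")
  m <- load_bipartite(write_lines_tmp(rows))
  expect_length(m, 7)
  expect_length(flatten_genes(m), 10)   # brute-force union of the 12 rows
  expect_setequal(flatten_genes(m),
                  unique(vapply(strsplit(rows, "\t"), `[[`, character(1), 2)))
  one <- load_bipartite(write_lines_tmp("s\tg"))
  expect_length(one, 1)
  expect_equal(flatten_genes(one), "g")
  expect_error(bipartite_map(list(a = character())), "empty")
})
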