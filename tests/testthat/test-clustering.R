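# Similarity clustering: local alignment scores vs an independent DP
# oracle, e-values, graph construction, component labelling and the
# seeded force layout.

b62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})

test_that("self-alignment score is the diagonal sum; mismatch floors at zero", {
  s <- "MKWLQRFNDTA"
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  expect_equal(pairwise_local_score(s, s), sum(diag(b62[ch, ch])))
  expect_equal(pairwise_local_score("A", "G"), max(0, b62["A", "G"]))
})

test_that("alignment scores equal the quadratic DP oracle and are symmetric", {
  set.seed(53)
  for (k in 1:15) {
    a <- random_residues(50)
    b <- random_residues(50)
    s_ab <- pairwise_local_score(a, b)
    expect_equal(s_ab, oracle_sw_score(a, b, b62))
    expect_equal(s_ab, pairwise_local_score(b, a))
  }
})

test_that("e-values follow the Karlin-Altschul closed form and its properties", {
  cfg <- cluster_config()
  expect_equal(evalue_from_score(0, 100, 100, cfg), cfg$K * 1e4)
  e1 <- evalue_from_score(10, 100, 100, cfg)
  e2 <- evalue_from_score(20, 100, 100, cfg)
  expect_lt(e2, e1)  # strictly decreasing in score
  expect_equal(evalue_from_score(10, 200, 100, cfg), 2 * e1)  # linear in m
})

test_that("identical sequences form a complete triangle; unrelated pairs no edge", {
  set.seed(59)
  s <- random_residues(80)
  g <- build_graph(setNames(c(s, s, s), c("a", "b", "c")))
  expect_equal(nrow(g$edges), 3L)
  expect_equal(g$edges$i, c("a", "a", "b"))
  expect_equal(g$edges$j, c("b", "c", "c"))
  g2 <- build_graph(setNames(c(random_residues(60), random_residues(60)),
                             c("x", "y")),
                    cluster_config(e_cutoff = 1e-10))
  expect_equal(nrow(g2$edges), 0L)
})

test_that("lowering the e-value cutoff never adds edges", {
  set.seed(61)
  seqs <- make_two_family_set(4, 50, 0.3)
  cuts <- c(1e-2, 1e-4, 1e-6, 1e-8)
  prev <- Inf
  prev_edges <- NULL
  for (ct in cuts) {
    g <- build_graph(seqs, cluster_config(e_cutoff = ct))
    key <- paste(g$edges$i, g$edges$j)
    if (!is.null(prev_edges)) expect_true(all(key %in% prev_edges))
    prev_edges <- if (is.null(prev_edges)) key else key
  }
})

test_that("connected components are labelled by size then smallest member", {
  g <- structure(list(nodes = c("a", "b", "c", "d", "e"),
                      lengths = rep(10L, 5),
                      edges = data.frame(i = c("a", "b"), j = c("b", "c"),
                                         raw_score = c(50, 50),
                                         e_value = c(1e-9, 1e-9),
                                         stringsAsFactors = FALSE)),
                 class = "neuropep_simgraph")
  lab <- connected_clusters(g)
  expect_equal(lab$cluster_label[lab$id %in% c("a", "b", "c")],
               rep("cluster_1", 3))
  expect_equal(lab$cluster_label[lab$id %in% c("d", "e")],
               rep("singleton", 2))
  # edgeless graph: all singletons
  g0 <- g
  g0$edges <- g$edges[0, ]
  expect_true(all(connected_clusters(g0)$cluster_label == "singleton"))
})

test_that("cluster labels are invariant under node input order", {
  set.seed(67)
  seqs <- make_two_family_set(4, 60, 0.15)
  g1 <- build_graph(seqs)
  g2 <- build_graph(rev(seqs))
  expect_identical(connected_clusters(g1), connected_clusters(g2))
})

test_that("planted two-family benchmark is recovered exactly", {
  set.seed(71)
  seqs <- make_two_family_set(10, 60, 0.15)
  g <- build_graph(seqs)
  lab <- connected_clusters(g)
  famA <- lab$cluster_label[startsWith(lab$id, "famA")]
  famB <- lab$cluster_label[startsWith(lab$id, "famB")]
  expect_equal(length(unique(famA)), 1L)
  expect_equal(length(unique(famB)), 1L)
  expect_false(unique(famA) == unique(famB))
  expect_false("singleton" %in% c(famA, famB))
})

test_that("force layout is bit-reproducible and separates disconnected cliques", {
  set.seed(73)
  s1 <- random_residues(80)
  s2 <- random_residues(80)
  seqs <- setNames(c(s1, s1, s1, s2, s2, s2),
                   c("a1", "a2", "a3", "b1", "b2", "b3"))
  cfg <- cluster_config(layout = list(seed = 99L))
  g <- build_graph(seqs, cfg)
  l1 <- force_layout(g, cfg)
  l2 <- force_layout(g, cfg)
  expect_identical(l1, l2)
  # different seed, different coordinates
  l3 <- force_layout(g, cluster_config(layout = list(seed = 100L)))
  expect_false(identical(l1$x, l3$x))
  coords <- as.matrix(l1[, c("x", "y")])
  rownames(coords) <- l1$id
  a <- coords[c("a1", "a2", "a3"), ]
  b <- coords[c("b1", "b2", "b3"), ]
  intra <- mean(c(dist(a), dist(b)))
  inter <- mean(sqrt(rowSums((a[rep(1:3, each = 3), ] - b[rep(1:3, 3), ])^2)))
  expect_gt(inter, intra)
})

test_that("a single connected node keeps its seeded initial position", {
  g <- structure(list(nodes = "solo", lengths = 10L,
                      edges = data.frame(i = character(), j = character(),
                                         raw_score = numeric(),
                                         e_value = numeric(),
                                         stringsAsFactors = FALSE)),
                 class = "neuropep_simgraph")
  cfg <- cluster_config(layout = list(seed = 5L))
  l <- force_layout(g, cfg)
  set.seed(5L)
  expect_equal(c(l$x, l$y), runif(2))
})

test_that("clustering fewer than two sequences is a usage error", {
  expect_error(build_graph(setNames("MKWL", "only")),
               class = "neuropep_usage_error")
})
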