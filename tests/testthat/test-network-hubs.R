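test_that("edge-list reading normalizes to a simple graph", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb\t0.9", "b\ta\t0.8", "a\ta\t0.5"), f)
  expect_warning(g <- read_edge_list(f), "self-loop")
  expect_equal(nrow(g$edges), 1)
  expect_equal(g$edges$node1, "a")
  expect_equal(g$edges$node2, "b")

  writeLines(c("a\tb\t0.6", "b\tc\t0.9"), f)
  g2 <- read_edge_list(f, min_score = 0.7)
  expect_equal(nrow(g2$edges), 1)
  expect_equal(g2$edges$node2, "c")

  writeLines("a\tb\tc\td", f)
  expect_error(read_edge_list(f), "line 1")
  writeLines("a\tb\tnot_a_number", f)
  expect_error(read_edge_list(f), "unparseable score")

  # round-trip of a generated graph
  ds <- generate_dataset(synth_config(n_proteins = 200, seed = 4))
  pp <- generate_ppi(ds$truth, clique_size = 4, n_nodes = 25,
                     edge_prob = 0.1, seed = 5)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_edge_list(pp$graph, f2)
  # identical edge set (an edge list cannot carry isolated nodes)
  expect_equal(read_edge_list(f2)$edges, pp$graph$edges)
})

test_that("clique enumeration handles canonical small cases", {
  tri <- ppi_graph(edges = data.frame(node1 = c("a", "b", "a"),
                                      node2 = c("b", "c", "c")))
  expect_equal(enumerate_maximal_cliques(tri), list(c("a", "b", "c")))

  path <- ppi_graph(edges = data.frame(node1 = c("a", "b"),
                                       node2 = c("b", "c")))
  expect_equal(enumerate_maximal_cliques(path),
               list(c("a", "b"), c("b", "c")))

  expect_equal(enumerate_maximal_cliques(ppi_graph()), list())
  iso <- ppi_graph(nodes = c("x", "y"),
                   edges = data.frame(node1 = "x", node2 = "y")[0, ])
  expect_equal(enumerate_maximal_cliques(iso), list("x", "y"))
})

test_that("enumeration and MCC equal the exhaustive oracle (all graphs
           up to 5 nodes, random up to 15)", {
  # exhaustive over every labelled graph on 2..5 nodes
  for (n in 2:5) {
    n_pairs <- choose(n, 2)
    for (mask in 0:(2^n_pairs - 1)) {
      bits <- as.integer(intToBits(mask))[seq_len(n_pairs)]
      g <- graph_from_mask(n, bits)
      expect_identical(enumerate_maximal_cliques(g), oracle_max_cliques(g))
    }
  }
  # random graphs on 6..15 nodes across densities
  set.seed(20)
  for (i in 1:120) {
    n <- sample(6:15, 1)
    g <- random_test_graph(n, p = runif(1, 0.1, 0.8))
    expect_identical(enumerate_maximal_cliques(g), oracle_max_cliques(g))
    tab <- mcc_scores(g)
    om <- oracle_mcc(g)
    expect_equal(stats::setNames(tab$mcc, tab$node)[names(om)], om)
  }
})

test_that("MCC matches the factorial formula on canonical graphs", {
  tri <- ppi_graph(edges = data.frame(node1 = c("a", "b", "a"),
                                      node2 = c("b", "c", "c")))
  expect_equal(mcc_scores(tri)$mcc, rep(2, 3))

  star <- ppi_graph(edges = data.frame(node1 = rep("a", 3),
                                       node2 = c("b", "c", "d")))
  tab <- mcc_scores(star)
  expect_equal(tab$mcc[tab$node == "a"], 3)   # = degree
  expect_equal(tab$mcc[tab$node != "a"], rep(1, 3))

  k4 <- ppi_graph(edges = data.frame(
    node1 = c("a", "a", "a", "b", "b", "c"),
    node2 = c("b", "c", "d", "c", "d", "d")))
  expect_equal(mcc_scores(k4)$mcc, rep(6, 4))

  lone <- ppi_graph(nodes = "z")
  expect_equal(mcc_scores(lone)$mcc, 1)
})

test_that("for triangle-free graphs MCC equals degree", {
  set.seed(44)
  for (i in 1:20) {
    # random bipartite graphs are triangle-free
    left <- sprintf("l%d", 1:5); right <- sprintf("r%d", 1:5)
    pairs <- expand.grid(node1 = left, node2 = right,
                         stringsAsFactors = FALSE)
    keep <- runif(nrow(pairs)) < 0.4
    if (!any(keep)) next
    g <- ppi_graph(c(left, right), pairs[keep, ])
    tab <- mcc_scores(g)
    deg <- stats::setNames(tab$degree, tab$node)
    noniso <- tab$node[tab$degree > 0]
    expect_equal(tab$mcc[match(noniso, tab$node)],
                 unname(deg[noniso]))
  }
})

test_that("MCC is invariant under node relabeling", {
  set.seed(3)
  g <- random_test_graph(12, 0.35)
  relab <- stats::setNames(sprintf("Q%02d", sample(12)), g$nodes)
  g2 <- ppi_graph(unname(relab),
                  data.frame(node1 = unname(relab[g$edges$node1]),
                             node2 = unname(relab[g$edges$node2]),
                             stringsAsFactors = FALSE))
  m1 <- mcc_scores(g); m2 <- mcc_scores(g2)
  expect_equal(stats::setNames(m2$mcc, m2$node)[unname(relab[m1$node])],
               stats::setNames(m1$mcc, unname(relab[m1$node])))
})

test_that("top_hubs applies the documented tie-break", {
  t <- data.frame(node = c("a", "b", "c", "d"),
                  mcc = c(6, 2, 2, 1),
                  degree = c(4, 3, 2, 1), stringsAsFactors = FALSE)
  t <- t[order(-t$mcc, -t$degree, t$node), ]
  t$rank <- seq_len(4)
  expect_equal(top_hubs(t, 2), c("a", "b"))
  expect_equal(top_hubs(t, 4), c("a", "b", "c", "d"))
  expect_warning(all_nodes <- top_hubs(t, 10), "exceeds node count")
  expect_length(all_nodes, 4)
  expect_error(top_hubs(t, 0), ">= 1")

  # planted clique dominates factorial scoring
  ds <- generate_dataset(synth_config(n_proteins = 300, seed = 2))
  pp <- generate_ppi(ds$truth, clique_size = 6, n_nodes = 60,
                     edge_prob = 0.02, seed = 6)
  hubs <- top_hubs(mcc_scores(pp$graph), 6)
  expect_setequal(hubs, pp$truth$clique_nodes)
})

test_that("adding an edge never decreases max clique size and leaves
           remote nodes untouched", {
  set.seed(10)
  g <- random_test_graph(10, 0.3)
  non_edges <- setdiff(
    apply(utils::combn(g$nodes, 2), 2, paste, collapse = "\r"),
    paste(g$edges$node1, g$edges$node2, sep = "\r"))
  if (length(non_edges) > 0) {
    add <- strsplit(non_edges[1], "\r", fixed = TRUE)[[1]]
    g2 <- ppi_graph(g$nodes, rbind(g$edges[, 1:2],
                                   data.frame(node1 = add[1], node2 = add[2])))
    size1 <- max(lengths(enumerate_maximal_cliques(g)))
    size2 <- max(lengths(enumerate_maximal_cliques(g2)))
    expect_gte(size2, size1)
    # nodes adjacent to neither endpoint keep their MCC
    adj <- adjacency <- c(add,
      g$edges$node2[g$edges$node1 %in% add],
      g$edges$node1[g$edges$node2 %in% add])
    remote <- setdiff(g$nodes, adj)
    if (length(remote) > 0) {
      m1 <- mcc_scores(g); m2 <- mcc_scores(g2)
      expect_equal(stats::setNames(m1$mcc, m1$node)[remote],
                   stats::setNames(m2$mcc, m2$node)[remote])
    }
  }
})
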