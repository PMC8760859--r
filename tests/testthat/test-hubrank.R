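triangle <- tibble::tibble(from = c("a", "b", "a"), to = c("b", "c", "c"))
path3 <- tibble::tibble(from = c("a", "b"), to = c("b", "c"))

test_that("maximal cliques of canonical small graphs", {
  expect_identical(
    enumerate_maximal_cliques(triangle), list(c("a", "b", "c"))
  )
  cl <- enumerate_maximal_cliques(path3)
  expect_setequal(
    purrr::map_chr(cl, paste, collapse = "-"), c("a-b", "b-c")
  )
  # isolated node is its own maximal clique
  cl_iso <- enumerate_maximal_cliques(path3, nodes = c("a", "b", "c", "z"))
  expect_true(list("z") %in% cl_iso)
  # duplicate edges and self-loops are collapsed
  messy <- tibble::tibble(from = c("a", "a", "a"), to = c("b", "b", "a"))
  expect_identical(enumerate_maximal_cliques(messy), list(c("a", "b")))
  expect_error(
    enumerate_maximal_cliques(triangle, max_nodes = 2), "max_nodes"
  )
})

test_that("MCC scores follow the (|C|-1)! definition on fixtures", {
  sc_tri <- hub_scores(triangle)
  expect_equal(sc_tri$mcc, rep(2, 3)) # (3-1)! per node
  sc_path <- hub_scores(path3)
  expect_equal(
    setNames(sc_path$mcc, sc_path$node_id)[c("a", "b", "c")],
    c(a = 1, b = 2, c = 1)
  )
  sc_iso <- hub_scores(path3, nodes = "lonely")
  expect_equal(sc_iso$mcc[sc_iso$node_id == "lonely"], 1) # 0! = 1
  expect_equal(sc_iso$degree[sc_iso$node_id == "lonely"], 0L)
})

test_that("clique enumeration and MCC match the exhaustive oracle", {
  withr::with_seed(55, seeds <- sample(1e6, 30))
  for (i in seq_along(seeds)) {
    n <- 4 + (i %% 9) # 4..12 nodes
    g <- random_graph(n, p = 0.4, seed = seeds[i])
    ours <- enumerate_maximal_cliques(g$edges, nodes = g$ids)
    ours_sets <- sort(purrr::map_chr(ours, paste, collapse = "-"))
    oracle <- oracle_maximal_cliques(g$adj)
    oracle_sets <- sort(
      purrr::map_chr(oracle, ~ paste(g$ids[.x], collapse = "-"))
    )
    expect_identical(ours_sets, oracle_sets)
    sc <- hub_scores(g$edges, nodes = g$ids)
    expect_equal(
      setNames(sc$mcc, sc$node_id)[g$ids],
      setNames(oracle_mcc(g$adj), g$ids)
    )
  }
})

test_that("for triangle-free graphs MCC equals degree on non-isolated nodes", {
  # random bipartite graphs are triangle-free
  withr::with_seed(77, {
    for (rep in 1:10) {
      left <- sprintf("L%d", 1:5)
      right <- sprintf("R%d", 1:5)
      e <- tidyr::expand_grid(from = left, to = right)
      e <- e[runif(nrow(e)) < 0.35, ]
      if (nrow(e) == 0) next
      sc <- hub_scores(e)
      expect_equal(sc$mcc[sc$degree > 0], sc$degree[sc$degree > 0])
    }
  })
})

test_that("degree scores satisfy the handshake lemma", {
  g <- random_graph(10, 0.5, seed = 99)
  sc <- degree_scores(g$edges, nodes = g$ids)
  expect_equal(sum(sc$degree), 2 * nrow(g$edges))
  star <- tibble::tibble(from = "hub", to = sprintf("leaf%d", 1:5))
  sd <- degree_scores(star)
  expect_equal(sd$degree[sd$node_id == "hub"], 5L)
  expect_true(all(sd$degree[sd$node_id != "hub"] == 1L))
  empty3 <- degree_scores(
    tibble::tibble(from = character(), to = character()),
    nodes = c("a", "b", "c")
  )
  expect_equal(empty3$degree, c(0L, 0L, 0L))
})

test_that("top_k truncates to the graph size and breaks ties by id", {
  # a 45-node network asked for 50 returns all 45
  e45 <- tibble::tibble(
    from = sprintf("v%02d", 1:44), to = sprintf("v%02d", c(2:44, 1))
  )
  sc45 <- hub_scores(e45, nodes = sprintf("v%02d", 45))
  expect_length(top_k(sc45, 50, "degree"), 45)
  # ties: lexicographically smallest ids first, deterministically
  tie <- tibble::tibble(node_id = c("b", "a", "d", "c"), degree = 2L)
  expect_identical(top_k(tie, 2, "degree"), c("a", "b"))
  expect_identical(top_k(tie, 2, "degree"), top_k(tie, 2, "degree"))
  star <- hub_scores(
    tibble::tibble(from = "hub", to = sprintf("leaf%d", 1:5))
  )
  expect_identical(top_k(star, 1, "degree"), "hub")
})
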