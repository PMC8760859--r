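test_that("shared miRNA counting is plain set intersection", {
  expect_identical(
    shared_mirna_count(paste0("m", 1:5), paste0("m", 3:8)), 3L
  )
  expect_identical(shared_mirna_count(c("a", "b"), c("c", "d")), 0L)
  expect_identical(shared_mirna_count(paste0("m", 1:7), paste0("m", 1:7)), 7L)
  # duplicates in the input do not inflate the count
  expect_identical(shared_mirna_count(c("a", "a", "b"), c("a", "b", "b")), 2L)
})

test_that("hypergeometric tail matches enumeration on frozen examples", {
  expect_equal(hypergeom_pvalue(10, 5, 5, 5), 1 / 252)
  expect_equal(hypergeom_pvalue(4, 2, 2, 1), 5 / 6)
  expect_equal(hypergeom_pvalue(50, 10, 10, 0), 1)
  expect_error(hypergeom_pvalue(10, 5, 5, 6), "min")
  expect_error(hypergeom_pvalue(10, 12, 5, 2), "universe")
})

test_that("hypergeometric tail is monotone in k and symmetric in set sizes", {
  for (m in c(8, 12, 20)) {
    p <- vapply(0:5, function(k) hypergeom_pvalue(m, 6, 5, k), numeric(1))
    expect_true(all(diff(p) <= 1e-15))
    expect_equal(hypergeom_pvalue(m, 6, 5, 3), hypergeom_pvalue(m, 5, 6, 3))
  }
})

test_that("pair co-expression recovers exact and null correlations", {
  x <- c(1, 3, 2, 5, 4, 6, 8, 7)
  expect_equal(pair_coexpression(x, 2 * x)$r, 1)
  expect_equal(pair_coexpression(x, -x + 10)$r, -1)
  withr::with_seed(13, {
    a <- rnorm(1000)
    b <- rnorm(1000)
  })
  expect_lt(abs(pair_coexpression(a, b)$r), 0.1)
  # zero variance fails the filter instead of erroring
  z <- pair_coexpression(rep(1, 5), c(1, 2, 3, 4, 5))
  expect_true(is.na(z$r) && z$r_pvalue == 1)
  expect_error(pair_coexpression(1:2, 1:2), ">= 3")
})

test_that("the full pair-calling rule is applied conjunctively", {
  # k=6 with strong hypergeometric evidence but r = 0 must not pass
  mirs <- sprintf("m%02d", 1:40)
  ia <- dplyr::bind_rows(
    tibble::tibble(mirna_id = mirs[1:6], target_id = "lnc1", target_type = "lncRNA"),
    tibble::tibble(mirna_id = mirs[1:6], target_id = "gene1", target_type = "mRNA"),
    # background edges fixing the miRNA universe at 40
    tibble::tibble(mirna_id = mirs[7:40], target_id = "gene_bg", target_type = "mRNA")
  )
  n <- 20
  withr::with_seed(19, {
    expr <- tibble::tibble(
      feature_id = c("lnc1", "gene1"),
      !!!setNames(
        as.data.frame(matrix(rpois(2 * n, 100), nrow = 2)),
        sprintf("s%02d", 1:n)
      )
    )
  })
  res <- tidy(call_cerna_pairs(ia, expr))
  expect_equal(res$k, 6L)
  expect_lt(res$p_hyper, 0.01)
  expect_false(res$passed) # co-expression criterion fails
  # identical expression passes everything
  expr2 <- expr
  expr2[2, -1] <- expr2[1, -1]
  res2 <- tidy(call_cerna_pairs(ia, expr2))
  expect_true(res2$passed)
})

test_that("empty and background-only interaction tables yield no pairs", {
  empty <- tibble::tibble(
    mirna_id = character(), target_id = character(), target_type = character()
  )
  expr <- tibble::tibble(feature_id = "x", s1 = 1, s2 = 2, s3 = 3)
  expect_equal(nrow(tidy(call_cerna_pairs(empty, expr))), 0)
  # sparse background: max shared count 2 -> nothing passes
  cfg <- simulation_config(
    n_genes = 80, n_lncrnas = 40, n_mirnas = 100, n_triplets = 0,
    targets_per_mirna = 2, seed = 23
  )
  ann <- simulate_annotation(cfg)
  ia <- simulate_interactions(ann, cfg)$interactions
  sim <- simulate_counts(ann, cfg)
  res <- call_cerna_pairs(ia, normalize_counts(sim$counts))
  expect_equal(sum(tidy(res)$passed), 0)
})

test_that("planted triplets are recovered with high precision", {
  cfg <- tiny_config(seed = 29, k_shared = 8)
  sim <- simulate_dataset(cfg)
  res <- tidy(call_cerna_pairs(sim$interactions, normalize_counts(sim$counts)))
  truth <- paste(
    sim$truth$cerna_triplets$lncrna_id, sim$truth$cerna_triplets$mrna_id
  )
  called <- paste(res$lncrna_id, res$mrna_id)[res$passed]
  expect_true(all(truth %in% called))
  expect_gte(mean(called %in% truth), 0.9)
})

test_that("differential network keeps only fully differential triplets", {
  pairs <- tibble::tibble(
    lncrna_id = c("l1", "l2"), mrna_id = c("g1", "g2"),
    passed = c(TRUE, TRUE)
  )
  ia <- dplyr::bind_rows(
    tibble::tibble(
      mirna_id = c("m1", "m1", "m2", "m2"),
      target_id = c("l1", "g1", "l2", "g2"),
      target_type = c("lncRNA", "mRNA", "lncRNA", "mRNA")
    )
  )
  st <- tibble::tibble(
    feature_id = c("l1", "g1", "m1", "l2", "g2", "m2"),
    call = c("up", "up", "down", "up", "up", "ns")
  )
  net <- extract_differential_network(pairs, ia, st)
  # triplet 2 dropped: its miRNA is ns
  expect_identical(net$triplets$lncrna_id, "l1")
  expect_setequal(net$nodes$id, c("l1", "m1", "g1"))
  expect_identical(
    net$nodes$regulation[net$nodes$id == "m1"], "down"
  )
  expect_setequal(
    net$edges$edge_type,
    c("lncRNA-miRNA", "miRNA-mRNA", "lncRNA-mRNA_cerna")
  )
  # edges reference existing nodes with consistent endpoint types
  expect_true(all(net$edges$source %in% net$nodes$id))
  expect_true(all(net$edges$target %in% net$nodes$id))
  # empty status -> empty network
  net0 <- extract_differential_network(
    pairs, ia, tibble::tibble(feature_id = character(), call = character())
  )
  expect_equal(nrow(net0$triplets), 0)
  expect_equal(nrow(net0$nodes), 0)
})
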