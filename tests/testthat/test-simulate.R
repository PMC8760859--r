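test_that("largest-remainder apportionment matches hand computation", {
  expect_identical(
    largest_remainder(100, c(0.4, 0.088, 0.488, 0.024)),
    c(40L, 9L, 49L, 2L)
  )
  expect_identical(largest_remainder(4, c(1, 0, 0, 0)), c(4L, 0L, 0L, 0L))
  # counts always sum to n across random fraction vectors
  withr::with_seed(42, {
    for (i in 1:25) {
      f <- runif(4)
      f <- f / sum(f)
      n <- sample(1:500, 1)
      expect_equal(sum(largest_remainder(n, f)), n)
    }
  })
  expect_error(largest_remainder(10, c(0.5, 0.6)), "sum to 1")
})

test_that("configuration validation rejects inconsistent settings", {
  expect_error(
    simulation_config(class_fractions = c(0.5, 0.5, 0.1, 0.1)),
    "sum to 1"
  )
  expect_error(simulation_config(n_genes = 0), "n_genes")
  expect_error(
    simulation_config(k_shared = 20, n_mirnas = 10),
    "cannot exceed"
  )
})

test_that("annotation realizes the requested class counts by construction", {
  cfg <- simulation_config(
    n_lncrnas = 100,
    class_fractions = c(
      lincRNA = 0.4, antisense = 0.088, intronic = 0.488, sense = 0.024
    )
  )
  ann <- simulate_annotation(cfg)
  counts <- table(ann$lncrnas$true_class)
  expect_equal(counts[["lincRNA"]], 40)
  expect_equal(counts[["antisense"]], 9)
  expect_equal(counts[["intronic"]], 49)
  expect_equal(counts[["sense"]], 2)
})

test_that("degenerate all-lincRNA annotation has no gene overlap", {
  cfg <- simulation_config(
    n_genes = 5, n_lncrnas = 4,
    class_fractions = c(lincRNA = 1, antisense = 0, intronic = 0, sense = 0)
  )
  ann <- simulate_annotation(cfg)
  expect_equal(nrow(ann$lncrnas), 4)
  expect_true(all(ann$lncrnas$true_class == "lincRNA"))
  for (i in seq_len(nrow(ann$lncrnas))) {
    gaps <- pmax(
      ann$genes$start - ann$lncrnas$end[i],
      ann$lncrnas$start[i] - ann$genes$end
    )
    expect_true(all(gaps >= 5000)) # lincRNAs at least 5 kb from every gene
  }
})

test_that("generators are pure functions of (config, seed)", {
  cfg <- tiny_config(seed = 99)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1, a2)
  expect_identical(simulate_counts(a1, cfg), simulate_counts(a2, cfg))
  expect_identical(
    simulate_interactions(a1, cfg),
    simulate_interactions(a2, cfg)
  )
  expect_identical(simulate_qpcr(cfg), simulate_qpcr(cfg))
  # different seed changes the draw
  cfg2 <- tiny_config(seed = 100)
  expect_false(identical(
    simulate_counts(a1, cfg)$counts, simulate_counts(a1, cfg2)$counts
  ))
})

test_that("counts approach the Poisson limit as dispersion goes to zero", {
  cfg <- simulation_config(
    n_genes = 2, n_lncrnas = 2, n_mirnas = 2, k_shared = 2, n_triplets = 0,
    n_replicates = 2500, nb_dispersion = 1e-8, prop_de = 0,
    mean_log2_sd = 0, seed = 3
  )
  sim <- simulate_counts(simulate_annotation(cfg), cfg)
  m <- as.matrix(sim$counts[, -(1:3)])
  # undo the known size factors, then check variance/mean ~ 1 per feature
  y <- sweep(m, 2, sim$design$size_factor_true, `/`)
  ratio <- apply(y, 1, var) / rowMeans(y)
  expect_true(all(abs(ratio - 1) < 0.15))
})

test_that("null generator plants no effect and calibration matches the plant", {
  # all-null: empirical group log-ratio shrinks toward 0
  cfg0 <- simulation_config(
    n_genes = 50, n_lncrnas = 10, n_mirnas = 5, k_shared = 2, n_triplets = 0,
    prop_de = 0, n_replicates = 50, seed = 5
  )
  sim0 <- simulate_counts(simulate_annotation(cfg0), cfg0)
  expect_equal(nrow(sim0$truth$de_features), 0)
  m <- as.matrix(sim0$counts[, -(1:3)])
  y <- sweep(m, 2, sim0$design$size_factor_true, `/`)
  acl <- sim0$design$tissue == "ACL"
  inj <- sim0$design$condition == "injured"
  lr <- log2(rowMeans(y[, acl & inj]) / rowMeans(y[, acl & !inj]))
  expect_lt(mean(abs(lr)), 0.15)

  # planted features: empirical log2 ratio within 3 SE of the plant
  cfg1 <- simulation_config(
    n_genes = 300, n_lncrnas = 50, n_mirnas = 5, k_shared = 2,
    n_triplets = 0, prop_de = 0.2, n_replicates = 10,
    planted_log2fc = 2, seed = 6
  )
  sim1 <- simulate_counts(simulate_annotation(cfg1), cfg1)
  m1 <- as.matrix(sim1$counts[, -(1:3)])
  y1 <- sweep(m1, 2, sim1$design$size_factor_true, `/`)
  acl <- sim1$design$tissue == "ACL"
  inj <- sim1$design$condition == "injured"
  planted <- dplyr::filter(
    sim1$truth$de_features, contrast == "ACL_injured_vs_normal"
  )
  i <- match(planted$feature_id, sim1$counts$feature_id)
  lr <- log2(rowMeans(y1[i, acl & inj]) / rowMeans(y1[i, acl & !inj]))
  err <- lr * sign(planted$lfc) - abs(planted$lfc)
  se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * se + 0.05)
})

test_that("planted triplet pairs share exactly k_shared miRNAs", {
  cfg <- tiny_config(k_shared = 8)
  ann <- simulate_annotation(cfg)
  ia <- simulate_interactions(ann, cfg)
  sets <- split(ia$interactions$mirna_id, ia$interactions$target_id)
  trip <- ia$truth$cerna_triplets
  for (t in seq_len(nrow(trip))) {
    expect_identical(
      shared_mirna_count(sets[[trip$lncrna_id[t]]], sets[[trip$mrna_id[t]]]),
      8L
    )
  }
})

test_that("sparse background alone yields no pair above the shared cutoff", {
  cfg <- simulation_config(
    n_genes = 80, n_lncrnas = 40, n_mirnas = 100, n_triplets = 0,
    k_shared = 6, targets_per_mirna = 2, seed = 17
  )
  ia <- simulate_interactions(simulate_annotation(cfg), cfg)$interactions
  sets <- split(ia$mirna_id, ia$target_id)
  lnc <- unique(ia$target_id[ia$target_type == "lncRNA"])
  mrna <- unique(ia$target_id[ia$target_type == "mRNA"])
  max_k <- 0L
  for (a in lnc) {
    for (b in mrna) {
      max_k <- max(max_k, shared_mirna_count(sets[[a]], sets[[b]]))
    }
  }
  expect_lte(max_k, 5)
})

test_that("qPCR generator plants recoverable fold changes", {
  # noise-free: estimated fold equals the plant exactly
  cfg <- simulation_config(ct_noise_sd = 0, n_replicates = 3, seed = 8)
  qp <- simulate_qpcr(cfg, folds = c(gene_x = 4))
  rel <- ddct(qp$ct)
  expect_equal(unique(round(rel$fold[rel$group == "case"], 12)), 4)
  # all-null plant: mean estimated fold ~ 1
  qp0 <- simulate_qpcr(
    simulation_config(n_replicates = 30, ct_noise_sd = 0.25, seed = 9),
    folds = c(a = 1, b = 1)
  )
  rel0 <- ddct(qp0$ct)
  expect_lt(abs(mean(rel0$fold[rel0$group == "case"]) - 1), 0.15)
})
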