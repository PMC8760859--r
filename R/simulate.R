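#' Simulate a genome annotation with labelled lncRNA classes
#'
#' Lays out protein-coding gene models and lncRNA transcripts on a single
#' synthetic chromosome so that every lncRNA realizes one of the four
#' positional classes *by construction*: lincRNAs sit at least 5 kb from any
#' gene, antisense/sense lncRNAs overlap an exon on the opposite/same
#' strand, and intronic lncRNAs lie strictly inside an intron. Class counts
#' follow `config$class_fractions` by largest-remainder rounding. Genes
#' occupy dedicated 20 kb units (two exons of 500 bp around a 2 kb intron),
#' so the class of every transcript is unambiguous.
#'
#' @param config A [simulation_config()].
#' @return A `genome_annotation`: list with tibbles `genes`
#'   (`gene_id, chrom, strand, start, end`), `exons`
#'   (`gene_id, exon_number, start, end`), `lncrnas`
#'   (`transcript_id, chrom, strand, start, end, true_class`), and
#'   `chrom_length`. All coordinates are 1-based inclusive.
#' @examples
#' ann <- simulate_annotation(simulation_config(n_genes = 20, n_lncrnas = 10))
#' dplyr::count(ann$lncrnas, true_class)
#' @export
simulate_annotation <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  class_counts <- largest_remainder(config$n_lncrnas, config$class_fractions)

  unit <- 20000L
  n_g <- config$n_genes
  n_linc <- class_counts[["lincRNA"]]

  withr::with_seed(stage_seed(config$seed, "annotation"), {
    gene_strand <- sample(c("+", "-"), n_g, replace = TRUE)
    gene_start <- (seq_len(n_g) - 1L) * unit + 5001L
    genes <- tibble::tibble(
      gene_id = sprintf("gene_%04d", seq_len(n_g)),
      chrom = "chr1",
      strand = gene_strand,
      start = gene_start,
      end = gene_start + 2999L
    )
    exons <- dplyr::bind_rows(
      dplyr::mutate(genes,
        exon_number = 1L,
        exon_start = .data$start, exon_end = .data$start + 499L
      ),
      dplyr::mutate(genes,
        exon_number = 2L,
        exon_start = .data$start + 2500L, exon_end = .data$start + 2999L
      )
    ) |>
      dplyr::transmute(
        .data$gene_id, .data$exon_number,
        start = .data$exon_start, end = .data$exon_end
      ) |>
      dplyr::arrange(.data$gene_id, .data$exon_number)

    # lincRNAs get their own gene-free units appended after the gene units,
    # guaranteeing > 5 kb clearance from every gene span.
    linc_start <- (n_g + seq_len(n_linc) - 1L) * unit + 9601L
    linc <- tibble::tibble(
      strand = sample(c("+", "-"), n_linc, replace = TRUE),
      start = linc_start,
      end = linc_start + 799L,
      true_class = "lincRNA"
    )

    overlapping <- purrr::imap(
      class_counts[c("antisense", "intronic", "sense")],
      function(k, cls) {
        if (k == 0) {
          return(NULL)
        }
        host <- ((seq_len(k) - 1L) %% n_g) + 1L # cycle hosts if k > n_genes
        g0 <- genes$start[host]
        gs <- genes$strand[host]
        if (cls == "intronic") {
          tibble::tibble(
            strand = sample(c("+", "-"), k, replace = TRUE),
            start = g0 + 700L, end = g0 + 1499L, true_class = cls
          )
        } else {
          tibble::tibble(
            strand = if (cls == "antisense") ifelse(gs == "+", "-", "+") else gs,
            start = g0 + 100L, end = g0 + 799L, true_class = cls
          )
        }
      }
    )

    lncrnas <- dplyr::bind_rows(c(list(linc), unname(overlapping))) |>
      dplyr::mutate(
        transcript_id = sprintf("lnc_%04d", dplyr::row_number()),
        chrom = "chr1", .before = 1
      ) |>
      dplyr::relocate(
        "transcript_id", "chrom", "strand", "start", "end", "true_class"
      )
  })

  structure(
    list(
      genes = genes, exons = exons, lncrnas = lncrnas,
      chrom_length = (n_g + n_linc + 1L) * unit
    ),
    class = "genome_annotation"
  )
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("<genome_annotation>\n")
  cat(sprintf(
    "  %d genes (%d exons), %d lncRNAs on %s (%d bp)\n",
    nrow(x$genes), nrow(x$exons), nrow(x$lncrnas),
    x$genes$chrom[1] %||% "chr1", x$chrom_length
  ))
  print(table(x$lncrnas$true_class))
  invisible(x)
}

# Deterministic ids shared by the count and interaction generators.
mirna_ids <- function(config) sprintf("mir_%03d", seq_len(config$n_mirnas))

# Choose triplet members (lncRNA, mRNA, k_shared miRNAs) from a dedicated
# seed sub-stream so simulate_counts() and simulate_interactions() agree on
# membership without sharing state.
plan_triplets <- function(annotation, config) {
  n_t <- config$n_triplets
  if (n_t == 0) {
    return(tibble::tibble(
      triplet_id = character(), lncrna_id = character(),
      mrna_id = character(), mirnas = list()
    ))
  }
  if (n_t > nrow(annotation$lncrnas) || n_t > nrow(annotation$genes)) {
    abort("`n_triplets` exceeds the number of available lncRNAs or genes")
  }
  mirs <- mirna_ids(config)
  withr::with_seed(stage_seed(config$seed, "triplets"), {
    lnc <- sample(annotation$lncrnas$transcript_id, n_t)
    mrna <- sample(annotation$genes$gene_id, n_t)
    # draw shared sets disjointly across triplets when the universe allows
    sets <- if (n_t * config$k_shared <= length(mirs)) {
      split(
        sample(mirs, n_t * config$k_shared),
        rep(seq_len(n_t), each = config$k_shared)
      )
    } else {
      purrr::map(seq_len(n_t), ~ sample(mirs, config$k_shared))
    }
  })
  tibble::tibble(
    triplet_id = sprintf("triplet_%02d", seq_len(n_t)),
    lncrna_id = lnc, mrna_id = mrna,
    mirnas = purrr::map(unname(sets), sort)
  )
}

# Plant the three disjoint effect sets (ACL injury, MCL injury, tissue) and
# fold the planted ceRNA triplets into the ACL-injury effect with
# coordinated signs (lncRNA and mRNA up together, their miRNAs down).
plan_effects <- function(annotation, config, triplets) {
  feats <- c(annotation$genes$gene_id, annotation$lncrnas$transcript_id)
  lfc <- config$planted_log2fc
  n_de <- round(config$prop_de * length(feats))

  withr::with_seed(stage_seed(config$seed, "de"), {
    reserved <- c(triplets$lncrna_id, triplets$mrna_id)
    pool <- sample(setdiff(feats, reserved))
    take <- function(n) {
      picked <- utils::head(pool, n)
      pool <<- pool[-seq_len(min(n, length(pool)))]
      picked
    }
    effects <- list(
      acl_injury = take(n_de), mcl_injury = take(n_de), tissue = take(n_de)
    )
    eff <- purrr::imap(effects, function(ids, nm) {
      tibble::tibble(
        feature_id = ids, effect = nm,
        lfc = lfc * sample(c(-1, 1), length(ids), replace = TRUE)
      )
    }) |> dplyr::bind_rows()
  })

  if (nrow(triplets) > 0) {
    trip_eff <- dplyr::bind_rows(
      tibble::tibble(
        feature_id = c(triplets$lncrna_id, triplets$mrna_id),
        effect = "acl_injury", lfc = lfc
      ),
      tibble::tibble(
        feature_id = unique(unlist(triplets$mirnas)),
        effect = "acl_injury", lfc = -lfc
      )
    )
    eff <- dplyr::bind_rows(eff, trip_eff)
  }
  eff
}

#' Simulate a count matrix with planted differential expression
#'
#' Draws negative-binomial counts for every mRNA, lncRNA, and miRNA feature
#' across a 2 tissue (ACL, MCL) x 2 condition (normal, injured) x
#' `n_replicates` design. Per-sample size factors are drawn log-uniform in
#' \[0.5, 2\] to exercise normalization. Three disjoint planted effect sets
#' drive the four standard contrasts, and the members of each planted ceRNA
#' triplet additionally share a per-sample latent factor (log2 sd
#' `coexpr_sd`) so they are co-expressed.
#'
#' @param annotation A `genome_annotation` from [simulate_annotation()].
#' @param config A [simulation_config()]; `n_replicates` must be >= 2.
#' @return A list with
#'   * `counts`: tibble `feature_id, feature_type, length` plus one integer
#'     column per sample;
#'   * `design`: tibble `sample_id, tissue, condition, size_factor_true`;
#'   * `truth`: a `truth_set` with `de_features` (per-contrast planted
#'     log2FC), `null_features`, and `cerna_triplets`.
#' @examples
#' cfg <- simulation_config(n_genes = 40, n_lncrnas = 20, n_replicates = 3)
#' sim <- simulate_counts(simulate_annotation(cfg), cfg)
#' dim(sim$counts)
#' @export
simulate_counts <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (config$n_replicates < 2) abort("`n_replicates` must be >= 2")

  features <- dplyr::bind_rows(
    tibble::tibble(
      feature_id = annotation$genes$gene_id, feature_type = "mRNA",
      length = as.integer(
        tapply(
          annotation$exons$end - annotation$exons$start + 1L,
          annotation$exons$gene_id, sum
        )[annotation$genes$gene_id]
      )
    ),
    tibble::tibble(
      feature_id = annotation$lncrnas$transcript_id, feature_type = "lncRNA",
      length = as.integer(
        annotation$lncrnas$end - annotation$lncrnas$start + 1L
      )
    ),
    tibble::tibble(
      feature_id = mirna_ids(config), feature_type = "miRNA", length = 22L
    )
  )

  design <- tidyr::expand_grid(
    tissue = c("ACL", "MCL"),
    condition = c("normal", "injured"),
    replicate = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_%d", .data$tissue, .data$condition, .data$replicate),
      .before = 1
    ) |>
    dplyr::select(-"replicate")

  triplets <- plan_triplets(annotation, config)
  eff <- plan_effects(annotation, config, triplets)
  eff_wide <- eff |>
    tidyr::pivot_wider(
      names_from = "effect", values_from = "lfc", values_fill = 0
    )
  for (nm in c("acl_injury", "mcl_injury", "tissue")) {
    if (!nm %in% names(eff_wide)) eff_wide[[nm]] <- numeric(nrow(eff_wide))
  }

  n_feat <- nrow(features)
  n_samp <- nrow(design)
  lfc_acl <- lfc_mcl <- lfc_tis <- numeric(n_feat)
  idx <- match(eff_wide$feature_id, features$feature_id)
  lfc_acl[idx] <- eff_wide$acl_injury
  lfc_mcl[idx] <- eff_wide$mcl_injury
  lfc_tis[idx] <- eff_wide$tissue

  is_acl <- design$tissue == "ACL"
  is_inj <- design$condition == "injured"

  withr::with_seed(stage_seed(config$seed, "counts"), {
    base_log2 <- rnorm(n_feat, log2(config$mean_count), config$mean_log2_sd)
    sf <- 2^runif(n_samp, -1, 1) # log-uniform in [0.5, 2]

    log2_mu <- outer(base_log2, rep(1, n_samp)) +
      outer(lfc_tis, as.numeric(is_acl)) +
      outer(lfc_acl, as.numeric(is_acl & is_inj)) +
      outer(lfc_mcl, as.numeric(!is_acl & is_inj))

    if (nrow(triplets) > 0 && config$coexpr_sd > 0) {
      latent <- matrix(
        rnorm(nrow(triplets) * n_samp, 0, config$coexpr_sd),
        nrow = nrow(triplets)
      )
      for (t in seq_len(nrow(triplets))) {
        members <- match(
          c(triplets$lncrna_id[t], triplets$mrna_id[t]), features$feature_id
        )
        log2_mu[members, ] <- sweep(
          log2_mu[members, , drop = FALSE], 2, latent[t, ], `+`
        )
      }
    }

    mu <- sweep(2^log2_mu, 2, sf, `*`)
    counts <- if (config$nb_dispersion > 0) {
      matrix(
        rnbinom(n_feat * n_samp, mu = mu, size = 1 / config$nb_dispersion),
        nrow = n_feat
      )
    } else {
      matrix(stats::rpois(n_feat * n_samp, lambda = mu), nrow = n_feat)
    }
  })
  colnames(counts) <- design$sample_id

  contrast_lfc <- dplyr::bind_rows(
    tibble::tibble(
      feature_id = features$feature_id,
      contrast = "ACL_injured_vs_normal", lfc = lfc_acl
    ),
    tibble::tibble(
      feature_id = features$feature_id,
      contrast = "MCL_injured_vs_normal", lfc = lfc_mcl
    ),
    tibble::tibble(
      feature_id = features$feature_id,
      contrast = "normal_ACL_vs_MCL", lfc = lfc_tis
    ),
    tibble::tibble(
      feature_id = features$feature_id,
      contrast = "injured_ACL_vs_MCL", lfc = lfc_tis + lfc_acl - lfc_mcl
    )
  ) |>
    dplyr::filter(.data$lfc != 0)

  planted_ids <- unique(contrast_lfc$feature_id)
  truth <- structure(
    list(
      de_features = contrast_lfc,
      null_features = setdiff(features$feature_id, planted_ids),
      cerna_triplets = triplets
    ),
    class = "truth_set"
  )

  list(
    counts = dplyr::bind_cols(features, tibble::as_tibble(counts)),
    design = dplyr::mutate(design, size_factor_true = sf),
    truth = truth
  )
}

#' Simulate a miRNA-target interaction table
#'
#' Builds miRNA-to-target edges in two layers: each planted ceRNA triplet's
#' lncRNA and mRNA are both targeted by the triplet's `k_shared` miRNAs (and
#' receive no other edges, so every planted pair shares *exactly*
#' `k_shared` miRNAs), and each miRNA additionally targets
#' `targets_per_mirna` background features drawn uniformly from the
#' non-planted mRNAs and lncRNAs.
#'
#' @inheritParams simulate_counts
#' @return A list with `interactions` (tibble
#'   `mirna_id, target_id, target_type`) and `truth` (a `truth_set` carrying
#'   `cerna_triplets`).
#' @export
simulate_interactions <- function(annotation, config) {
  stopifnot(inherits(annotation, "genome_annotation"))
  triplets <- plan_triplets(annotation, config)

  type_of <- c(
    setNames(rep("mRNA", nrow(annotation$genes)), annotation$genes$gene_id),
    setNames(
      rep("lncRNA", nrow(annotation$lncrnas)),
      annotation$lncrnas$transcript_id
    )
  )
  planted_edges <- if (nrow(triplets) > 0) {
    tidyr::unnest(triplets, "mirnas") |>
      dplyr::rename(mirna_id = "mirnas") |>
      tidyr::pivot_longer(
        c("lncrna_id", "mrna_id"),
        names_to = NULL, values_to = "target_id"
      ) |>
      dplyr::transmute(
        .data$mirna_id, .data$target_id,
        target_type = type_of[.data$target_id]
      )
  } else {
    tibble::tibble(
      mirna_id = character(), target_id = character(),
      target_type = character()
    )
  }

  eligible <- setdiff(names(type_of), c(triplets$lncrna_id, triplets$mrna_id))
  withr::with_seed(stage_seed(config$seed, "interactions"), {
    background <- purrr::map(mirna_ids(config), function(m) {
      tibble::tibble(
        mirna_id = m,
        target_id = sample(
          eligible, min(config$targets_per_mirna, length(eligible))
        )
      )
    }) |>
      dplyr::bind_rows() |>
      dplyr::mutate(target_type = type_of[.data$target_id])
  })

  interactions <- dplyr::bind_rows(planted_edges, background) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$mirna_id, .data$target_id)

  truth <- structure(
    list(
      de_features = tibble::tibble(
        feature_id = character(), contrast = character(), lfc = numeric()
      ),
      null_features = character(),
      cerna_triplets = triplets
    ),
    class = "truth_set"
  )
  list(interactions = interactions, truth = truth)
}

#' Simulate a qPCR cycle-threshold table
#'
#' Generates Ct values for a panel of target genes plus the `ACTB`
#' reference across control and case samples, three technical replicates
#' each. The model is `Ct = baseline - log2(relative expression) + offset +
#' noise`, where the per-sample loading offset is shared by every gene in a
#' sample (and therefore cancels in delta-Ct) and the reference gene has
#' relative expression 1 in both groups.
#'
#' @param config A [simulation_config()].
#' @param folds Named numeric vector of planted case-vs-control relative
#'   expression per target gene. Default: `qpcr_n_genes` genes alternating
#'   4-fold up and 4-fold down.
#' @param reference_gene Name of the reference gene (default `"ACTB"`).
#' @return A list with `ct` (tibble
#'   `sample_id, group, gene_id, replicate, ct`) and `folds` (the planted
#'   truth, reference included at 1).
#' @export
simulate_qpcr <- function(config, folds = NULL, reference_gene = "ACTB") {
  if (is.null(folds)) {
    folds <- setNames(
      rep(c(4, 0.25), length.out = config$qpcr_n_genes),
      sprintf("target_%02d", seq_len(config$qpcr_n_genes))
    )
  }
  if (is.null(names(folds)) || any(!nzchar(names(folds)))) {
    abort("`folds` must be a named vector of relative expressions")
  }
  if (any(folds <= 0)) abort("planted relative expression must be positive")

  genes <- c(setNames(1, reference_gene), folds)
  samples <- tidyr::expand_grid(
    group = c("control", "case"), replicate_bio = seq_len(config$n_replicates)
  ) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%d", .data$group, .data$replicate_bio)
    )

  withr::with_seed(stage_seed(config$seed, "qpcr"), {
    baseline <- setNames(runif(length(genes), 18, 28), names(genes))
    offset <- setNames(rnorm(nrow(samples), 0, 0.3), samples$sample_id)
    ct <- tidyr::expand_grid(
      sample_id = samples$sample_id,
      gene_id = names(genes),
      replicate = 1:3
    ) |>
      dplyr::left_join(
        dplyr::select(samples, "sample_id", "group"),
        by = "sample_id"
      ) |>
      dplyr::mutate(
        relexp = ifelse(.data$group == "case", genes[.data$gene_id], 1),
        ct = baseline[.data$gene_id] - log2(.data$relexp) +
          offset[.data$sample_id] +
          rnorm(dplyr::n(), 0, config$ct_noise_sd)
      ) |>
      dplyr::select("sample_id", "group", "gene_id", "replicate", "ct")
  })

  list(ct = ct, folds = genes)
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper running [simulate_annotation()], [simulate_counts()],
#' [simulate_interactions()], and [simulate_qpcr()] with one configuration,
#' plus a term-to-gene map and a protein-protein interaction edge list for
#' the enrichment and hub-ranking stages. Terms are gene blocks of 25;
#' PPI edges connect random gene pairs.
#'
#' @param config A [simulation_config()].
#' @return List with `annotation`, `counts`, `design`, `truth`,
#'   `interactions`, `term_map`, `ppi_edges`, `qpcr` (list `ct`, `folds`),
#'   and `config`.
#' @examples
#' sim <- simulate_dataset(simulation_config(
#'   n_genes = 40, n_lncrnas = 20,
#'   n_mirnas = 60, n_triplets = 2
#' ))
#' names(sim)
#' @export
simulate_dataset <- function(config) {
  annotation <- simulate_annotation(config)
  cs <- simulate_counts(annotation, config)
  ia <- simulate_interactions(annotation, config)
  qp <- simulate_qpcr(config)

  gene_ids <- annotation$genes$gene_id
  term_map <- tibble::tibble(
    term_id = sprintf("TERM:%04d", ((seq_along(gene_ids) - 1) %/% 25) + 1),
    gene_id = gene_ids
  )
  ppi_edges <- simulate_dataset_ppi(annotation, config)

  list(
    annotation = annotation, counts = cs$counts, design = cs$design,
    truth = cs$truth, interactions = ia$interactions,
    term_map = term_map, ppi_edges = ppi_edges, qpcr = qp, config = config
  )
}
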