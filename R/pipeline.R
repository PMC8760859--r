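#' Pipeline thresholds
#'
#' Every numeric cutoff used by the end-to-end run, at the study's values:
#' DE calling at `FC >= 2` with strict `FDR < 0.01`; ceRNA pairs at more
#' than 5 shared miRNAs, hypergeometric `p < 0.01` and `FDR < 0.01`, plus
#' positive co-expression; top 30 PPI hub genes by MCC; top 50 ceRNA
#' network nodes by Degree; top 20 enriched terms.
#'
#' @param fc_min,fdr_max DE calling thresholds ([call_de()]).
#' @param shared_min,p_max,cerna_fdr_max,r_min,r_p_max ceRNA pair thresholds
#'   ([cerna_thresholds()]).
#' @param top_k_ppi,top_k_cerna,top_terms Reporting sizes.
#' @return Named list.
#' @export
pipeline_thresholds <- function(fc_min = 2, fdr_max = 0.01, shared_min = 5,
                                p_max = 0.01, cerna_fdr_max = 0.01,
                                r_min = 0.7, r_p_max = 0.05,
                                top_k_ppi = 30, top_k_cerna = 50,
                                top_terms = 20) {
  list(
    fc_min = fc_min, fdr_max = fdr_max, shared_min = shared_min,
    p_max = p_max, cerna_fdr_max = cerna_fdr_max, r_min = r_min,
    r_p_max = r_p_max, top_k_ppi = top_k_ppi, top_k_cerna = top_k_cerna,
    top_terms = top_terms
  )
}

#' Run the full analysis pipeline
#'
#' Orchestrates every stage over one dataset: (optional) simulation, size
#' factors and normalization, differential expression for the four standard
#' contrasts, lncRNA positional classification, ceRNA pair calling and
#' per-contrast differential triplet networks, hub ranking (Degree top-K on
#' each ceRNA network, MCC top-K on each contrast's DE-gene PPI
#' subnetwork), term enrichment of each contrast's DE mRNAs, and qPCR
#' relative quantification. All outputs are written as plain text under
#' `out_dir` and summarised in `manifest.json` (file MD5 hashes, seed,
#' thresholds, per-stage counts) — two runs with the same configuration and
#' seed produce byte-identical manifests.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()]; ignored for stages whose input
#'   files are supplied through `inputs`.
#' @param inputs Optional named list of input paths (`gtf`, `counts`,
#'   `design`, `interactions`, `term_map`, `ppi_edges`, `ct`); any supplied
#'   path must exist (checked before any stage runs). Missing entries are
#'   simulated from `config`.
#' @param thresholds A [pipeline_thresholds()] list.
#' @param contrasts List of [de_contrast()]s (default [default_contrasts()]).
#' @param quiet Suppress per-stage progress messages.
#' @return The manifest, invisibly (class `pipeline_manifest`).
#' @examples
#' \donttest{
#' out <- file.path(tempdir(), "run1")
#' man <- run_pipeline(
#'   out,
#'   simulation_config(
#'     n_genes = 60, n_lncrnas = 30,
#'     n_mirnas = 60, n_triplets = 3
#'   ),
#'   quiet = TRUE
#' )
#' man$counts$de
#' }
#' @export
run_pipeline <- function(out_dir, config = simulation_config(),
                         inputs = NULL, thresholds = pipeline_thresholds(),
                         contrasts = default_contrasts(), quiet = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(inputs)) {
    bad <- names(inputs)[!purrr::map_lgl(inputs, file.exists)]
    if (length(bad) > 0) {
      abort(sprintf(
        "input file(s) not found: %s",
        paste(sprintf("%s (%s)", bad, unlist(inputs[bad])), collapse = ", ")
      ))
    }
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(fmt, ...) {
    if (!quiet) {
      message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
    }
  }
  outfile <- function(...) file.path(out_dir, paste0(...))
  written <- character()
  emit <- function(writer, x, name) {
    p <- outfile(name)
    writer(x, p)
    written <<- c(written, p)
    p
  }

  # --- inputs: read what was supplied, simulate the rest -------------------
  say("stage simulate/load")
  annotation <- if (!is.null(inputs$gtf)) {
    read_annotation_gtf(inputs$gtf)
  } else {
    simulate_annotation(config)
  }
  truth <- NULL
  if (!is.null(inputs$counts)) {
    counts <- read_counts_tsv(inputs$counts)
    design <- read_design_tsv(inputs$design)
  } else {
    sim <- simulate_counts(annotation, config)
    counts <- sim$counts
    design <- dplyr::select(sim$design, "sample_id", "tissue", "condition")
    truth <- sim$truth
    emit(write_counts_tsv, counts, "counts.tsv")
    emit(write_design_tsv, design, "design.tsv")
    emit(write_truth_json, truth, "truth.json")
  }
  interactions <- if (!is.null(inputs$interactions)) {
    read_interactions_tsv(inputs$interactions)
  } else {
    ia <- simulate_interactions(annotation, config)$interactions
    emit(write_interactions_tsv, ia, "interactions.tsv")
    ia
  }
  term_map <- if (!is.null(inputs$term_map)) {
    read_term_map_tsv(inputs$term_map)
  } else {
    gene_ids <- annotation$genes$gene_id
    tm <- tibble::tibble(
      term_id = sprintf("TERM:%04d", ((seq_along(gene_ids) - 1) %/% 25) + 1),
      gene_id = gene_ids
    )
    emit(write_term_map_tsv, tm, "term_map.tsv")
    tm
  }
  ppi_edges <- if (!is.null(inputs$ppi_edges)) {
    read_edges_tsv(inputs$ppi_edges)
  } else {
    ppi <- simulate_dataset_ppi(annotation, config)
    emit(write_edges_tsv, ppi, "ppi_edges.tsv")
    ppi
  }
  ct <- if (!is.null(inputs$ct)) {
    read_ct_tsv(inputs$ct)
  } else {
    qp <- simulate_qpcr(config)$ct
    emit(write_ct_tsv, qp, "qpcr_ct.tsv")
    qp
  }
  if (is.null(inputs$gtf)) {
    if (requireNamespace("rtracklayer", quietly = TRUE)) {
      p <- outfile("annotation.gtf")
      write_annotation_gtf(annotation, p)
      written <- c(written, p)
    }
  }

  # --- normalize -----------------------------------------------------------
  say("stage normalize")
  sf <- size_factors(counts)
  norm <- normalize_counts(counts, sf)
  emit(write_expression_tsv, norm, "normalized_counts.tsv")
  emit(write_expression_tsv, fpkm(counts), "fpkm.tsv")

  # --- differential expression --------------------------------------------
  say("stage de (%d contrasts)", length(contrasts))
  de <- purrr::map(contrasts, function(ctr) {
    de_analysis(counts, design, ctr,
      factors = sf,
      fc_min = thresholds$fc_min, fdr_max = thresholds$fdr_max
    )
  })
  for (r in de) {
    emit(
      function(x, p) readr::write_tsv(x, p), tidy(r),
      sprintf("de_%s.tsv", r$contrast$name)
    )
  }
  de_counts <- purrr::map(de, ~ as.list(glance(.x)[c("n_tested", "n_up", "n_down")]))

  # --- lncRNA classification ----------------------------------------------
  say("stage classify")
  cls <- classify_lncrna(annotation$lncrnas, annotation$genes, annotation$exons)
  props <- class_proportions(cls)
  emit(function(x, p) readr::write_tsv(x, p), cls, "lncrna_classes.tsv")
  emit(
    function(x, p) {
      jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    },
    setNames(as.list(props$fraction), props$class), "class_proportions.json"
  )

  # --- ceRNA pairs and per-contrast networks -------------------------------
  say("stage cerna")
  cth <- cerna_thresholds(
    shared_min = thresholds$shared_min, p_max = thresholds$p_max,
    fdr_max = thresholds$cerna_fdr_max, r_min = thresholds$r_min,
    r_p_max = thresholds$r_p_max
  )
  pairs <- call_cerna_pairs(interactions, norm, cth)
  emit(function(x, p) readr::write_tsv(x, p), tidy(pairs), "cerna_pairs.tsv")

  status <- de_status(de)
  networks <- purrr::map(de, function(r) {
    extract_differential_network(
      pairs, interactions,
      dplyr::filter(status, .data$contrast == r$contrast$name)
    )
  })
  for (nm in names(networks)) {
    emit(
      function(x, p) readr::write_tsv(x, p), networks[[nm]]$edges,
      sprintf("cerna_network_%s_edges.tsv", nm)
    )
    emit(
      function(x, p) readr::write_tsv(x, p), networks[[nm]]$nodes,
      sprintf("cerna_network_%s_nodes.tsv", nm)
    )
  }

  # --- hub ranking ---------------------------------------------------------
  say("stage hub")
  cerna_hubs <- purrr::imap(networks, function(net, nm) {
    if (nrow(net$edges) == 0) {
      return(character())
    }
    sc <- hub_scores(network_edges(net))
    emit(
      function(x, p) readr::write_tsv(x, p), sc,
      sprintf("hub_cerna_%s.tsv", nm)
    )
    top_k(sc, thresholds$top_k_cerna, "degree")
  })
  ppi_hubs <- purrr::imap(de, function(r, nm) {
    degs <- r$table$feature_id[
      r$table$call != "ns" &
        (r$table$feature_type %||% "mRNA") == "mRNA"
    ]
    sub <- ppi_edges[ppi_edges[[1]] %in% degs & ppi_edges[[2]] %in% degs, ]
    if (nrow(sub) == 0) {
      return(character())
    }
    sc <- hub_scores(sub, nodes = degs)
    emit(
      function(x, p) readr::write_tsv(x, p), sc,
      sprintf("hub_ppi_%s.tsv", nm)
    )
    top_k(sc, thresholds$top_k_ppi, "mcc")
  })

  # --- enrichment ----------------------------------------------------------
  say("stage enrich")
  enrich_counts <- purrr::imap(de, function(r, nm) {
    tab <- r$table[(r$table$feature_type %||% "mRNA") == "mRNA", ]
    query <- tab$feature_id[tab$call != "ns"]
    if (length(query) == 0) {
      return(0L)
    }
    res <- enrichment_test(query, term_map, tab$feature_id)
    emit(
      function(x, p) readr::write_tsv(x, p),
      top_terms(res, thresholds$top_terms),
      sprintf("enrichment_%s.tsv", nm)
    )
    nrow(res)
  })

  # --- qPCR ----------------------------------------------------------------
  say("stage qpcr")
  rel <- ddct(ct)
  qsum <- group_compare(rel)
  emit(function(x, p) readr::write_tsv(x, p), rel, "qpcr_fold.tsv")
  emit(function(x, p) readr::write_tsv(x, p), qsum, "qpcr_summary.tsv")

  # --- manifest ------------------------------------------------------------
  say("writing manifest")
  manifest <- list(
    package = "cernakit",
    version = as.character(utils::packageVersion("cernakit")),
    seed = config$seed,
    thresholds = thresholds,
    counts = list(
      features = nrow(counts),
      samples = nrow(design),
      lncrna_classes = setNames(as.list(props$n), props$class),
      de = de_counts,
      cerna_pairs_scored = nrow(tidy(pairs)),
      cerna_pairs_passed = sum(tidy(pairs)$passed),
      network_triplets = purrr::map(networks, ~ nrow(.x$triplets)),
      cerna_hub_nodes = purrr::map(cerna_hubs, length),
      ppi_hub_nodes = purrr::map(ppi_hubs, length),
      enriched_terms_tested = enrich_counts,
      qpcr_genes = nrow(qsum)
    ),
    files = as.list(setNames(
      unname(tools::md5sum(sort(written))), basename(sort(written))
    ))
  )
  jsonlite::write_json(
    manifest, outfile("manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  say("done: %d files in %s", length(written) + 1, out_dir)
  invisible(structure(manifest, class = "pipeline_manifest"))
}

# PPI background for a simulated run (deterministic in config$seed).
simulate_dataset_ppi <- function(annotation, config) {
  gene_ids <- annotation$genes$gene_id
  withr::with_seed(stage_seed(config$seed, "pipeline"), {
    n_edges <- min(3L * length(gene_ids), choose(length(gene_ids), 2))
    a <- sample(gene_ids, n_edges, replace = TRUE)
    b <- sample(gene_ids, n_edges, replace = TRUE)
  })
  tibble::tibble(from = pmin(a, b), to = pmax(a, b)) |>
    dplyr::filter(.data$from != .data$to) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to)
}
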