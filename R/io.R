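#' Read and write pipeline tables
#'
#' Plain TSV round-trips for every table the pipeline consumes or produces:
#' counts (`feature_id, feature_type, length`, then one column per sample),
#' sample design (`sample_id, tissue, condition`), miRNA-target interactions
#' (`mirna_id, target_id, target_type`), term maps (`term_id, gene_id`, and
#' optionally `term_name`/`namespace`), qPCR Ct tables, and 2-column edge
#' lists. Expression tables carry their unit (`normalized_count` or `FPKM`)
#' in a `# unit:` header comment.
#'
#' @param x Table to write.
#' @param path File path.
#' @return Writers return `path` invisibly; readers return a tibble.
#' @name pipeline_io
NULL

#' @rdname pipeline_io
#' @export
write_counts_tsv <- function(x, path) {
  assert_columns(x, c("feature_id", "feature_type", "length"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_expression_tsv <- function(x, path) {
  unit <- attr(x, "unit") %||% "unknown"
  writeLines(sprintf("# unit: %s", unit), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_expression_tsv <- function(path) {
  unit <- sub("^# unit: ", "", readLines(path, n = 1))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "unit") <- unit
  out
}

#' @rdname pipeline_io
#' @export
write_design_tsv <- function(x, path) {
  assert_columns(x, c("sample_id", "tissue", "condition"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_design_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_interactions_tsv <- function(x, path) {
  assert_columns(x, c("mirna_id", "target_id", "target_type"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_interactions_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_ct_tsv <- function(x, path) {
  assert_columns(x, c("sample_id", "group", "gene_id", "replicate", "ct"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_ct_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_term_map_tsv <- function(x, path) {
  assert_columns(x, c("term_id", "gene_id"), "x")
  readr::write_tsv(x, path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_term_map_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname pipeline_io
#' @export
write_edges_tsv <- function(x, path) {
  readr::write_tsv(as.data.frame(x)[, 1:2], path)
  invisible(path)
}

#' @rdname pipeline_io
#' @export
read_edges_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' Write a genome annotation as GTF
#'
#' Exports gene, exon, and lncRNA transcript records with
#' `gene_id`/`transcript_id`/`feature_type` attributes (1-based inclusive
#' coordinates, via rtracklayer). lncRNA records also carry their generator
#' `true_class` so the classification round-trip can be checked from the
#' file alone.
#'
#' @param annotation A `genome_annotation`.
#' @param path Output `.gtf` path.
#' @return `path`, invisibly.
#' @export
write_annotation_gtf <- function(annotation, path) {
  stopifnot(inherits(annotation, "genome_annotation"))
  if (!requireNamespace("rtracklayer", quietly = TRUE) ||
    !requireNamespace("GenomicRanges", quietly = TRUE)) {
    abort("GTF export needs the rtracklayer and GenomicRanges packages")
  }
  rows <- dplyr::bind_rows(
    dplyr::transmute(
      annotation$genes,
      .data$chrom, .data$start, .data$end, .data$strand,
      type = "gene", gene_id = .data$gene_id,
      transcript_id = NA_character_, feature_type = "mRNA",
      true_class = NA_character_, exon_number = NA_integer_
    ),
    annotation$exons |>
      dplyr::left_join(
        dplyr::select(annotation$genes, "gene_id", "chrom", "strand"),
        by = "gene_id"
      ) |>
      dplyr::transmute(
        .data$chrom, .data$start, .data$end, .data$strand,
        type = "exon", gene_id = .data$gene_id,
        transcript_id = NA_character_, feature_type = "mRNA",
        true_class = NA_character_, exon_number = .data$exon_number
      ),
    dplyr::transmute(
      annotation$lncrnas,
      .data$chrom, .data$start, .data$end, .data$strand,
      type = "transcript", gene_id = NA_character_,
      transcript_id = .data$transcript_id, feature_type = "lncRNA",
      true_class = .data$true_class, exon_number = NA_integer_
    )
  )
  gr <- GenomicRanges::GRanges(
    seqnames = rows$chrom,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr) <- rows[
    c("type", "gene_id", "transcript_id", "feature_type", "true_class", "exon_number")
  ]
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

#' Read a genome annotation from GTF
#'
#' Inverse of [write_annotation_gtf()].
#'
#' @param path A `.gtf` file.
#' @return A `genome_annotation`.
#' @export
read_annotation_gtf <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    abort("GTF import needs the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- tibble::as_tibble(as.data.frame(gr))
  df$chrom <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  genes <- df |>
    dplyr::filter(.data$type == "gene") |>
    dplyr::select("gene_id", "chrom", "strand", "start", "end")
  exons <- df |>
    dplyr::filter(.data$type == "exon") |>
    dplyr::mutate(exon_number = as.integer(.data$exon_number)) |>
    dplyr::select("gene_id", "exon_number", "start", "end") |>
    dplyr::arrange(.data$gene_id, .data$exon_number)
  lncrnas <- df |>
    dplyr::filter(.data$type == "transcript", .data$feature_type == "lncRNA") |>
    dplyr::select(
      "transcript_id", "chrom", "strand", "start", "end", "true_class"
    )
  structure(
    list(
      genes = genes, exons = exons, lncrnas = lncrnas,
      chrom_length = max(df$end) + 20000L
    ),
    class = "genome_annotation"
  )
}

#' Write or read a ground-truth set as JSON
#'
#' @param truth A `truth_set` (from [simulate_counts()]).
#' @param path JSON path.
#' @return Writers return `path` invisibly; the reader returns a
#'   `truth_set`.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_set"))
  jsonlite::write_json(
    list(
      de_features = truth$de_features,
      null_features = truth$null_features,
      cerna_triplets = truth$cerna_triplets
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  trip <- tibble::as_tibble(x$cerna_triplets)
  if (nrow(trip) > 0 && !is.list(trip$mirnas)) trip$mirnas <- as.list(trip$mirnas)
  structure(
    list(
      de_features = tibble::as_tibble(x$de_features),
      null_features = as.character(x$null_features),
      cerna_triplets = trip
    ),
    class = "truth_set"
  )
}
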