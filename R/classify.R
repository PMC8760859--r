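#' Positional classification of lncRNA transcripts
#'
#' Assigns each lncRNA one of the four standard positional classes relative
#' to protein-coding gene models, applying the rules in strict precedence
#' (first match wins):
#'
#' 1. **lincRNA** — no base overlap with any gene span;
#' 2. **intronic** — entirely inside a single intron of a gene (any strand);
#' 3. **antisense** — overlaps at least one exonic base of a gene on the
#'    opposite strand;
#' 4. **sense** — overlaps at least one exonic base on the same strand.
#'
#' A transcript that overlaps a gene span but matches none of the rules
#' (e.g. sits entirely in an intron-flanking region of two genes, or spans
#' an exon-intron junction without touching an exon of an opposite-strand
#' gene) falls through to **sense** and is flagged in the `fallback`
#' column. Intervals are compared on a 0-based half-open scale internally;
#' inputs are 1-based inclusive as in GTF.
#'
#' @param lncrnas Tibble of transcripts:
#'   `transcript_id, chrom, strand, start, end`.
#' @param genes Tibble of gene spans: `gene_id, chrom, strand, start, end`.
#' @param exons Tibble of exon intervals: `gene_id, start, end`.
#' @return Tibble `transcript_id, class, evidence, fallback`; `evidence` is
#'   the supporting gene id, or `"none"` for lincRNAs.
#' @examples
#' genes <- tibble::tibble(
#'   gene_id = "g1", chrom = "chr1", strand = "+", start = 1000, end = 2000
#' )
#' exons <- tibble::tibble(
#'   gene_id = "g1", start = c(1000, 1800), end = c(1200, 2000)
#' )
#' lnc <- tibble::tibble(
#'   transcript_id = c("a", "b", "c"), chrom = "chr1",
#'   strand = c("+", "+", "-"),
#'   start = c(5000, 1300, 1100), end = c(6000, 1700, 1500)
#' )
#' classify_lncrna(lnc, genes, exons)
#' @export
classify_lncrna <- function(lncrnas, genes, exons) {
  assert_columns(
    lncrnas, c("transcript_id", "chrom", "strand", "start", "end"), "lncrnas"
  )
  assert_columns(genes, c("gene_id", "chrom", "strand", "start", "end"), "genes")
  assert_columns(exons, c("gene_id", "start", "end"), "exons")
  if (any(lncrnas$end < lncrnas$start) || any(genes$end < genes$start)) {
    abort("intervals must satisfy start <= end")
  }

  introns <- gene_introns(genes, exons)

  res <- purrr::pmap(
    lncrnas[c("transcript_id", "chrom", "strand", "start", "end")],
    function(transcript_id, chrom, strand, start, end) {
      # 0-based half-open
      t0 <- start - 1L
      t1 <- end
      g <- genes[genes$chrom == chrom, , drop = FALSE]
      hit <- g[g$start - 1L < t1 & t0 < g$end, , drop = FALSE]
      if (nrow(hit) == 0) {
        return(list(
          transcript_id = transcript_id, class = "lincRNA",
          evidence = "none", fallback = FALSE
        ))
      }
      ih <- introns[
        introns$gene_id %in% hit$gene_id &
          introns$start - 1L <= t0 & t1 <= introns$end, ,
        drop = FALSE
      ]
      if (nrow(ih) > 0) {
        return(list(
          transcript_id = transcript_id, class = "intronic",
          evidence = ih$gene_id[1], fallback = FALSE
        ))
      }
      ex <- exons[exons$gene_id %in% hit$gene_id, , drop = FALSE]
      ex <- ex[ex$start - 1L < t1 & t0 < ex$end, , drop = FALSE]
      ex_strand <- genes$strand[match(ex$gene_id, genes$gene_id)]
      anti <- ex$gene_id[ex_strand != strand]
      if (length(anti) > 0) {
        return(list(
          transcript_id = transcript_id, class = "antisense",
          evidence = sort(anti)[1], fallback = FALSE
        ))
      }
      same <- ex$gene_id[ex_strand == strand]
      if (length(same) > 0) {
        return(list(
          transcript_id = transcript_id, class = "sense",
          evidence = sort(same)[1], fallback = FALSE
        ))
      }
      # overlaps a gene span but neither an intron (fully) nor an exon
      list(
        transcript_id = transcript_id, class = "sense",
        evidence = sort(hit$gene_id)[1], fallback = TRUE
      )
    }
  ) |> dplyr::bind_rows()

  if (any(res$fallback)) {
    rlang::inform(sprintf(
      "%d transcript(s) overlapped a gene but matched no rule; classified sense",
      sum(res$fallback)
    ))
  }
  res
}

# Introns as 1-based inclusive gaps between sorted exons of each gene.
gene_introns <- function(genes, exons) {
  exons |>
    dplyr::arrange(.data$gene_id, .data$start) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::reframe(
      intron_start = .data$end[-dplyr::n()] + 1L,
      intron_end = .data$start[-1L] - 1L
    ) |>
    dplyr::filter(.data$intron_end >= .data$intron_start) |>
    dplyr::rename(start = "intron_start", end = "intron_end")
}

#' Class proportions of a classification result
#'
#' @param results Tibble with a `class` column (from [classify_lncrna()]).
#' @return Tibble `class, n, fraction` over all four classes (zero-count
#'   classes included); fractions sum to 1.
#' @export
class_proportions <- function(results) {
  assert_columns(results, "class", "results")
  if (nrow(results) == 0) abort("no classification results")
  tibble::tibble(class = lncrna_classes()) |>
    dplyr::left_join(
      dplyr::count(results, .data$class),
      by = "class"
    ) |>
    dplyr::mutate(
      n = tidyr::replace_na(.data$n, 0L),
      fraction = .data$n / sum(.data$n)
    )
}
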