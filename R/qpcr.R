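#' Relative expression by the 2^-ddCt method
#'
#' For each sample and target gene: technical-replicate Ct values are
#' averaged first, then `dCt = Ct(target) - Ct(reference)`,
#' `ddCt = dCt - mean(dCt over control samples)`, and
#' `fold = 2^-ddCt`. By construction the control group's folds have
#' geometric mean exactly 1, and any constant added to every Ct of a sample
#' (loading differences) cancels in `dCt`.
#'
#' @param ct Tibble `sample_id, group, gene_id, replicate, ct`.
#' @param reference_gene Internal control gene (default `"ACTB"`); must be
#'   measured in every sample.
#' @param control_group Level of `group` used as the ddCt baseline
#'   (default `"control"`).
#' @return Tibble `sample_id, group, gene_id, delta_ct, delta_delta_ct,
#'   fold` for every non-reference gene.
#' @examples
#' ct <- tibble::tibble(
#'   sample_id = rep(c("c1", "c2", "t1", "t2"), each = 2),
#'   group = rep(c("control", "control", "case", "case"), each = 2),
#'   gene_id = rep(c("ACTB", "g"), 4),
#'   replicate = 1L,
#'   ct = c(20, 25, 20, 25, 20, 24, 20, 24)
#' )
#' ddct(ct) # case folds = 2
#' @export
ddct <- function(ct, reference_gene = "ACTB", control_group = "control") {
  assert_columns(
    ct, c("sample_id", "group", "gene_id", "replicate", "ct"), "ct"
  )
  mean_ct <- ct |>
    dplyr::group_by(.data$sample_id, .data$group, .data$gene_id) |>
    dplyr::summarise(ct = mean(.data$ct), .groups = "drop")

  ref <- mean_ct |>
    dplyr::filter(.data$gene_id == reference_gene) |>
    dplyr::select("sample_id", ref_ct = "ct")
  no_ref <- setdiff(unique(ct$sample_id), ref$sample_id)
  if (length(no_ref) > 0) {
    abort(sprintf(
      "reference gene `%s` missing in sample(s): %s",
      reference_gene, paste(no_ref, collapse = ", ")
    ))
  }
  if (!control_group %in% ct$group) {
    abort(sprintf("control group `%s` has no samples", control_group))
  }

  mean_ct |>
    dplyr::filter(.data$gene_id != reference_gene) |>
    dplyr::inner_join(ref, by = "sample_id") |>
    dplyr::mutate(delta_ct = .data$ct - .data$ref_ct) |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      delta_delta_ct = .data$delta_ct -
        mean(.data$delta_ct[.data$group == control_group]),
      fold = 2^-.data$delta_delta_ct
    ) |>
    dplyr::ungroup() |>
    dplyr::select(
      "sample_id", "group", "gene_id", "delta_ct", "delta_delta_ct", "fold"
    ) |>
    dplyr::arrange(.data$gene_id, .data$group, .data$sample_id)
}

#' Compare qPCR fold changes between groups
#'
#' Welch two-sample t-test on the per-sample 2^-ddCt fold values of one
#' gene, with mean and standard error of the mean (`SEM = sd/sqrt(n)`) per
#' group.
#'
#' @param rel Tibble from [ddct()].
#' @param gene_id Gene to compare (default: all genes in `rel`).
#' @return Tibble `gene_id, group1, group2, mean_1, sem_1, n_1, mean_2,
#'   sem_2, n_2, p_value`, one row per gene; `group1` is the non-control
#'   (case) group when present.
#' @export
group_compare <- function(rel, gene_id = NULL) {
  assert_columns(rel, c("sample_id", "group", "gene_id", "fold"), "rel")
  genes <- gene_id %||% unique(rel$gene_id)
  groups <- unique(rel$group)
  if (length(groups) != 2) abort("`rel` must contain exactly two groups")
  g1 <- if ("control" %in% groups) setdiff(groups, "control") else groups[1]
  g2 <- setdiff(groups, g1)

  purrr::map(genes, function(g) {
    x <- rel$fold[rel$gene_id == g & rel$group == g1]
    y <- rel$fold[rel$gene_id == g & rel$group == g2]
    if (length(x) < 2 || length(y) < 2) {
      abort(sprintf("gene `%s`: each group needs >= 2 samples", g))
    }
    p <- if (var(x) == 0 && var(y) == 0) {
      # degenerate inputs: constant folds in both groups
      if (mean(x) == mean(y)) 1 else 0
    } else {
      t.test(x, y)$p.value
    }
    tibble::tibble(
      gene_id = g, group1 = g1, group2 = g2,
      mean_1 = mean(x), sem_1 = sd(x) / sqrt(length(x)), n_1 = length(x),
      mean_2 = mean(y), sem_2 = sd(y) / sqrt(length(y)), n_2 = length(y),
      p_value = p
    )
  }) |> dplyr::bind_rows()
}
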