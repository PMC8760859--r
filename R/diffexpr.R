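#' Define a two-group contrast
#'
#' @param name Label for the contrast (used in outputs and truth tables).
#' @param variable Design column whose levels are compared.
#' @param numerator,denominator Levels of `variable`; fold change is
#'   `mean(numerator) / mean(denominator)`.
#' @param subset Optional named character vector restricting the design
#'   (e.g. `c(tissue = "ACL")`).
#' @return A list of class `de_contrast`.
#' @examples
#' de_contrast(
#'   "ACL_injured_vs_normal", "condition", "injured", "normal",
#'   subset = c(tissue = "ACL")
#' )
#' @export
de_contrast <- function(name, variable, numerator, denominator, subset = NULL) {
  structure(
    list(
      name = name, variable = variable, numerator = numerator,
      denominator = denominator, subset = subset
    ),
    class = "de_contrast"
  )
}

#' The four standard contrasts of the two-tissue injury design
#'
#' Injured-vs-normal within each ligament, and ACL-vs-MCL within each
#' condition.
#'
#' @return Named list of [de_contrast()] objects.
#' @export
default_contrasts <- function() {
  cs <- list(
    de_contrast(
      "ACL_injured_vs_normal", "condition", "injured", "normal",
      subset = c(tissue = "ACL")
    ),
    de_contrast(
      "MCL_injured_vs_normal", "condition", "injured", "normal",
      subset = c(tissue = "MCL")
    ),
    de_contrast(
      "normal_ACL_vs_MCL", "tissue", "ACL", "MCL",
      subset = c(condition = "normal")
    ),
    de_contrast(
      "injured_ACL_vs_MCL", "tissue", "ACL", "MCL",
      subset = c(condition = "injured")
    )
  )
  setNames(cs, purrr::map_chr(cs, "name"))
}

contrast_samples <- function(design, contrast) {
  assert_columns(design, c("sample_id", contrast$variable), "design")
  d <- design
  for (col in names(contrast$subset)) {
    d <- d[d[[col]] == contrast$subset[[col]], , drop = FALSE]
  }
  g1 <- d$sample_id[d[[contrast$variable]] == contrast$numerator]
  g2 <- d$sample_id[d[[contrast$variable]] == contrast$denominator]
  if (length(g1) < 2 || length(g2) < 2) {
    abort(sprintf(
      "contrast `%s` needs >= 2 samples per group (found %d vs %d)",
      contrast$name, length(g1), length(g2)
    ))
  }
  list(group1 = g1, group2 = g2)
}

#' Negative-binomial Wald test for two groups
#'
#' A moment-matched NB test on normalized counts: per-feature dispersion is
#' estimated by the method of moments from the pooled within-group variance,
#' floored at zero and shrunk toward a lowess mean-dispersion trend; the
#' Wald statistic on the difference of group log-means (delta-method
#' standard error `sqrt((1/m + alpha)/n)` per group) is referred to the
#' standard normal, as usual for Wald tests. Features with a
#' zero group mean get a +0.5 continuity correction before the log-ratio,
#' so p-values are never NaN. This is deliberately simpler than a full
#' shrunken-GLM engine; see the methods vignette for the divergence.
#'
#' @param counts Counts tibble or matrix (see [size_factors()]).
#' @param group1,group2 Sample id vectors (numerator and denominator group).
#' @param factors Optional size factors covering both groups; estimated from
#'   the two groups' columns when missing.
#' @param prior_df Prior degrees of freedom pulling the per-feature
#'   dispersion toward the trend (default 8).
#' @return Tibble with `feature_id`, `base_mean_1`, `base_mean_2` (group
#'   means of normalized counts), `fc`, `log2fc`, `dispersion`, `stat`,
#'   `p_value`.
#' @export
nb_test <- function(counts, group1, group2, factors = NULL, prior_df = 8) {
  m <- as_count_matrix(counts)
  missing <- setdiff(c(group1, group2), colnames(m))
  if (length(missing) > 0) {
    abort(sprintf("samples not in counts: %s", paste(missing, collapse = ", ")))
  }
  if (length(group1) < 2 || length(group2) < 2) {
    abort("need >= 2 samples per group")
  }
  cols <- c(group1, group2)
  if (is.null(factors)) {
    factors <- size_factors(m[, cols, drop = FALSE])
  }
  y <- sweep(m[, cols, drop = FALSE], 2, factors[cols], `/`)
  y1 <- y[, group1, drop = FALSE]
  y2 <- y[, group2, drop = FALSE]
  n1 <- length(group1)
  n2 <- length(group2)

  m1 <- rowMeans(y1)
  m2 <- rowMeans(y2)
  v1 <- apply(y1, 1, var)
  v2 <- apply(y2, 1, var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  mbar <- (n1 * m1 + n2 * m2) / (n1 + n2)

  expressed <- mbar > 0
  alpha_mom <- rep(0, nrow(y))
  alpha_mom[expressed] <-
    pmax((s2[expressed] - mbar[expressed]) / mbar[expressed]^2, 0)

  # mean-dispersion trend fitted on expressed features, then moderated
  alpha_trend <- rep(median(alpha_mom[expressed]), nrow(y))
  if (sum(expressed) >= 20) {
    fit <- lowess(log(mbar[expressed]), alpha_mom[expressed], f = 0.5)
    alpha_trend[expressed] <- pmax(
      stats::approx(fit$x, fit$y,
        xout = log(mbar[expressed]), rule = 2, ties = mean
      )$y,
      1e-8
    )
  }
  df_feat <- n1 + n2 - 2
  alpha <- (df_feat * alpha_mom + prior_df * alpha_trend) /
    (df_feat + prior_df)

  zero <- m1 == 0 | m2 == 0
  m1c <- m1 + 0.5 * zero
  m2c <- m2 + 0.5 * zero
  se <- sqrt((1 / m1c + alpha) / n1 + (1 / m2c + alpha) / n2)
  stat <- (log(m1c) - log(m2c)) / se
  p <- 2 * pnorm(-abs(stat))
  p[m1 == m2] <- 1 # includes the all-zero / exactly-equal case

  tibble::tibble(
    feature_id = rownames(y),
    base_mean_1 = unname(m1), base_mean_2 = unname(m2),
    fc = unname(m1c / m2c), log2fc = unname(log2(m1c / m2c)),
    dispersion = unname(alpha), stat = unname(stat), p_value = unname(p)
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * n / j`, capped at 1 and returned in the
#' input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.04)) # 0.03 0.03 0.04
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0 | p > 1)) {
    abort("`p` must be numeric in [0, 1] with no missing values")
  }
  p.adjust(p, method = "BH")
}

#' Call differential expression with fold-change and FDR thresholds
#'
#' A feature is `up` when `FC >= fc_min` and `fdr < fdr_max`, `down` when
#' `FC <= 1/fc_min` and `fdr < fdr_max`, and `ns` otherwise — i.e. the
#' symmetric rule |FC| >= `fc_min` with a strict FDR cutoff.
#'
#' @param results Tibble with columns `fc` and `fdr` (e.g. from
#'   [nb_test()] plus [bh_adjust()]).
#' @param fc_min Minimum fold change (default 2).
#' @param fdr_max Strict FDR cutoff (default 0.01): a feature at
#'   `fdr == fdr_max` is not called.
#' @return `results` with a `call` column (`up`/`down`/`ns`).
#' @export
call_de <- function(results, fc_min = 2, fdr_max = 0.01) {
  assert_columns(results, c("fc", "fdr"), "results")
  dplyr::mutate(
    results,
    call = dplyr::case_when(
      .data$fdr < fdr_max & .data$fc >= fc_min ~ "up",
      .data$fdr < fdr_max & .data$fc <= 1 / fc_min ~ "down",
      TRUE ~ "ns"
    )
  )
}

#' Differential expression analysis for one contrast
#'
#' Runs [nb_test()] on the contrast's two groups, adjusts p-values with
#' [bh_adjust()], and applies the DE calling rule of [call_de()].
#'
#' @param counts Counts tibble (features x samples, with `feature_id` and
#'   optionally `feature_type`).
#' @param design Design tibble with `sample_id` plus the contrast columns.
#' @param contrast A [de_contrast()].
#' @param factors Optional size factors for all samples.
#' @param fc_min,fdr_max Calling thresholds, see [call_de()].
#' @return An object of class `de_result`; use [tidy()] for the per-feature
#'   table and [glance()] for the summary counts.
#' @examples
#' cfg <- simulation_config(n_genes = 60, n_lncrnas = 30, n_replicates = 4)
#' sim <- simulate_counts(simulate_annotation(cfg), cfg)
#' res <- de_analysis(sim$counts, sim$design, default_contrasts()[[1]])
#' glance(res)
#' @export
de_analysis <- function(counts, design, contrast, factors = NULL,
                        fc_min = 2, fdr_max = 0.01) {
  stopifnot(inherits(contrast, "de_contrast"))
  grp <- contrast_samples(design, contrast)
  tab <- nb_test(counts, grp$group1, grp$group2, factors = factors)
  tab$fdr <- bh_adjust(tab$p_value)
  tab <- call_de(tab, fc_min = fc_min, fdr_max = fdr_max)
  if (!is.matrix(counts) && "feature_type" %in% names(counts)) {
    tab <- dplyr::left_join(
      tab, dplyr::select(counts, "feature_id", "feature_type"),
      by = "feature_id"
    ) |>
      dplyr::relocate("feature_type", .after = "feature_id")
  }
  structure(
    list(
      table = tab, contrast = contrast,
      params = list(fc_min = fc_min, fdr_max = fdr_max),
      groups = grp
    ),
    class = "de_result"
  )
}

#' @export
print.de_result <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "<de_result> %s: %d features tested, %d up, %d down (FC >= %g, FDR < %g)\n",
    x$contrast$name, g$n_tested, g$n_up, g$n_down,
    x$params$fc_min, x$params$fdr_max
  ))
  invisible(x)
}

#' @rdname de_analysis
#' @param x A `de_result`.
#' @param ... Unused.
#' @export
tidy.de_result <- function(x, ...) x$table

#' @rdname de_analysis
#' @export
glance.de_result <- function(x, ...) {
  tibble::tibble(
    contrast = x$contrast$name,
    n_tested = nrow(x$table),
    n_up = sum(x$table$call == "up"),
    n_down = sum(x$table$call == "down")
  )
}

#' Per-feature DE status table from one or more results
#'
#' Collapses `de_result` objects into the `feature_id -> up/down/ns` map
#' consumed by [extract_differential_network()].
#'
#' @param de A `de_result` or list of them (one per contrast).
#' @return Tibble `feature_id, contrast, call`.
#' @export
de_status <- function(de) {
  if (inherits(de, "de_result")) de <- list(de)
  purrr::map(de, function(r) {
    tibble::tibble(
      feature_id = r$table$feature_id,
      contrast = r$contrast$name,
      call = r$table$call
    )
  }) |> dplyr::bind_rows()
}
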