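#' Number of miRNAs shared by two target sets
#'
#' @param set_a,set_b Character vectors of miRNA ids.
#' @return Integer `|A intersect B|`.
#' @export
shared_mirna_count <- function(set_a, set_b) {
  length(intersect(unique(set_a), unique(set_b)))
}

#' Upper-tail hypergeometric p-value for shared miRNA targeting
#'
#' Probability of observing at least `k` shared miRNAs between two RNAs
#' whose target-miRNA sets have sizes `n_a` and `n_b`, drawn from a universe
#' of `m` miRNAs: `P(X >= k)` with
#' `X ~ Hypergeometric(m, n_a, n_b)`. Evaluated through the stable
#' distribution-function tail rather than naive summation.
#'
#' @param m Universe size (distinct miRNAs in the interaction table).
#' @param n_a,n_b Sizes of the two miRNA sets.
#' @param k Observed shared count.
#' @return p-value in \[0, 1\].
#' @examples
#' hypergeom_pvalue(10, 5, 5, 5) # 1 / choose(10, 5) = 1/252
#' hypergeom_pvalue(4, 2, 2, 1) # 5/6
#' @export
hypergeom_pvalue <- function(m, n_a, n_b, k) {
  for (v in c("m", "n_a", "n_b", "k")) {
    assert_scalar_number(get(v), v, lower = 0)
  }
  if (n_a > m || n_b > m) abort("set sizes cannot exceed the universe `m`")
  if (k > min(n_a, n_b)) abort("`k` cannot exceed min(n_a, n_b)")
  if (k == 0) {
    return(1)
  }
  phyper(k - 1, n_a, m - n_a, n_b, lower.tail = FALSE)
}

#' Pearson co-expression of a candidate ceRNA pair
#'
#' @param expr_a,expr_b Paired per-sample expression vectors (>= 3 samples).
#' @return List `r` (Pearson correlation) and `r_pvalue` (two-sided t-test
#'   p). Zero variance in either vector yields `r = NA` with `r_pvalue = 1`,
#'   which fails any co-expression filter.
#' @export
pair_coexpression <- function(expr_a, expr_b) {
  if (length(expr_a) != length(expr_b) || length(expr_a) < 3) {
    abort("need >= 3 paired samples")
  }
  if (sd(expr_a) == 0 || sd(expr_b) == 0) {
    return(list(r = NA_real_, r_pvalue = 1))
  }
  ct <- suppressWarnings(cor.test(expr_a, expr_b, method = "pearson"))
  list(r = unname(ct$estimate), r_pvalue = ct$p.value)
}

#' ceRNA pair thresholds
#'
#' The calling rule for candidate lncRNA-mRNA ceRNA pairs: shared miRNA
#' count strictly greater than `shared_min`, hypergeometric `p < p_max` and
#' BH `FDR < fdr_max`, and positive co-expression `r >= r_min` with
#' `r_pvalue < r_p_max`.
#'
#' @param shared_min Strict lower bound on shared miRNAs (default 5, i.e.
#'   at least 6 shared).
#' @param p_max,fdr_max Hypergeometric p and FDR cutoffs (default 0.01).
#' @param r_min Minimum Pearson correlation (default 0.7).
#' @param r_p_max Co-expression p cutoff (default 0.05).
#' @return Named list of thresholds.
#' @export
cerna_thresholds <- function(shared_min = 5, p_max = 0.01, fdr_max = 0.01,
                             r_min = 0.7, r_p_max = 0.05) {
  list(
    shared_min = shared_min, p_max = p_max, fdr_max = fdr_max,
    r_min = r_min, r_p_max = r_p_max
  )
}

# per-target miRNA sets from an interaction table
target_mirna_sets <- function(interactions) {
  assert_columns(
    interactions, c("mirna_id", "target_id", "target_type"), "interactions"
  )
  ia <- dplyr::distinct(interactions)
  split(ia$mirna_id, ia$target_id)
}

#' Score and call candidate ceRNA pairs
#'
#' Scores every lncRNA x mRNA pair sharing at least one miRNA in the
#' interaction table: shared count `k`, upper-tail hypergeometric p against
#' the universe of distinct miRNAs in the table, BH FDR across the scored
#' pairs, and Pearson co-expression on the supplied expression values. The
#' `passed` flag applies the full rule of [cerna_thresholds()].
#'
#' @param interactions Tibble `mirna_id, target_id, target_type`
#'   (`target_type` in `mRNA`, `lncRNA`).
#' @param expression Expression tibble (`feature_id` + one column per
#'   sample, e.g. from [normalize_counts()]); pairs with a member absent
#'   from it get `r = NA` and fail the co-expression filter.
#' @param thresholds A [cerna_thresholds()] list.
#' @param samples Optional sample ids over which co-expression is computed
#'   (default: every sample column of `expression`).
#' @param log_transform Compute co-expression on `log2(x + 1)` (default
#'   `TRUE`), the usual variance-stabilised scale for expression
#'   correlation; set `FALSE` to correlate raw values.
#' @return An object of class `cerna_result`; [tidy()] returns the pair
#'   table (`lncrna_id, mrna_id, k, n_a, n_b, p_hyper, fdr, r, r_pvalue,
#'   passed`), [glance()] the counts.
#' @examples
#' cfg <- simulation_config(
#'   n_genes = 40, n_lncrnas = 20, n_mirnas = 60,
#'   n_triplets = 2, n_replicates = 3
#' )
#' sim <- simulate_dataset(cfg)
#' pairs <- call_cerna_pairs(sim$interactions, normalize_counts(sim$counts))
#' glance(pairs)
#' @export
call_cerna_pairs <- function(interactions, expression,
                             thresholds = cerna_thresholds(),
                             samples = NULL, log_transform = TRUE) {
  sets <- target_mirna_sets(interactions)
  m_universe <- length(unique(interactions$mirna_id))
  type_of <- interactions |>
    dplyr::distinct(.data$target_id, .data$target_type)
  lnc <- type_of$target_id[type_of$target_type == "lncRNA"]
  mrna <- type_of$target_id[type_of$target_type == "mRNA"]

  empty <- tibble::tibble(
    lncrna_id = character(), mrna_id = character(), k = integer(),
    n_a = integer(), n_b = integer(), p_hyper = numeric(), fdr = numeric(),
    r = numeric(), r_pvalue = numeric(), passed = logical()
  )
  if (length(lnc) == 0 || length(mrna) == 0) {
    return(new_cerna_result(empty, thresholds, m_universe))
  }

  # enumerate candidate pairs through shared miRNAs (sparse join), then score
  ia <- dplyr::distinct(interactions)
  cand <- dplyr::inner_join(
    dplyr::filter(ia, .data$target_type == "lncRNA") |>
      dplyr::select(lncrna_id = "target_id", "mirna_id"),
    dplyr::filter(ia, .data$target_type == "mRNA") |>
      dplyr::select(mrna_id = "target_id", "mirna_id"),
    by = "mirna_id", relationship = "many-to-many"
  ) |>
    dplyr::count(.data$lncrna_id, .data$mrna_id, name = "k")

  if (nrow(cand) == 0) {
    return(new_cerna_result(empty, thresholds, m_universe))
  }

  cand$n_a <- lengths(sets[cand$lncrna_id])
  cand$n_b <- lengths(sets[cand$mrna_id])
  cand$p_hyper <- purrr::pmap_dbl(
    cand[c("n_a", "n_b", "k")],
    function(n_a, n_b, k) hypergeom_pvalue(m_universe, n_a, n_b, k)
  )
  cand$fdr <- bh_adjust(cand$p_hyper)

  expr <- as_count_matrix(expression)
  if (!is.null(samples)) expr <- expr[, samples, drop = FALSE]
  if (log_transform) expr <- log2(expr + 1)
  coex <- purrr::map2(cand$lncrna_id, cand$mrna_id, function(a, b) {
    if (!a %in% rownames(expr) || !b %in% rownames(expr)) {
      return(list(r = NA_real_, r_pvalue = 1))
    }
    pair_coexpression(expr[a, ], expr[b, ])
  })
  cand$r <- purrr::map_dbl(coex, "r")
  cand$r_pvalue <- purrr::map_dbl(coex, "r_pvalue")

  th <- thresholds
  cand$passed <- cand$k > th$shared_min &
    cand$p_hyper < th$p_max &
    cand$fdr < th$fdr_max &
    !is.na(cand$r) & cand$r >= th$r_min & cand$r_pvalue < th$r_p_max

  new_cerna_result(
    dplyr::arrange(cand, .data$p_hyper, .data$lncrna_id, .data$mrna_id),
    thresholds, m_universe
  )
}

new_cerna_result <- function(pairs, thresholds, m_universe) {
  structure(
    list(pairs = pairs, thresholds = thresholds, m_universe = m_universe),
    class = "cerna_result"
  )
}

#' @export
print.cerna_result <- function(x, ...) {
  cat(sprintf(
    "<cerna_result> %d candidate pairs scored (miRNA universe %d), %d passed\n",
    nrow(x$pairs), x$m_universe, sum(x$pairs$passed)
  ))
  invisible(x)
}

#' @rdname call_cerna_pairs
#' @param x A `cerna_result`.
#' @param ... Unused.
#' @export
tidy.cerna_result <- function(x, ...) x$pairs

#' @rdname call_cerna_pairs
#' @export
glance.cerna_result <- function(x, ...) {
  tibble::tibble(
    n_candidates = nrow(x$pairs),
    n_passed = sum(x$pairs$passed),
    m_universe = x$m_universe
  )
}

#' Extract the differential lncRNA-miRNA-mRNA network
#'
#' Keeps a triplet (lncRNA, miRNA, mRNA) when the lncRNA-mRNA pair passed
#' the ceRNA filters, the miRNA targets both partners, and all three
#' members are differentially expressed (`up` or `down`); the union of the
#' retained triplets forms the network. Ids missing from `de_status` are
#' treated as `ns`.
#'
#' @param pairs A `cerna_result` (or its [tidy()] pair table).
#' @param interactions The interaction table used to call the pairs.
#' @param de_status Tibble `feature_id, call` (`up`/`down`/`ns`) covering
#'   lncRNAs, miRNAs, and mRNAs, e.g. from [de_status()] filtered to one
#'   contrast.
#' @return A `triplet_network`: list with `nodes`
#'   (`id, node_type, regulation`), `edges` (`source, target, edge_type`),
#'   and `triplets` (`lncrna_id, mirna_id, mrna_id`).
#' @export
extract_differential_network <- function(pairs, interactions, de_status) {
  if (inherits(pairs, "cerna_result")) pairs <- pairs$pairs
  assert_columns(pairs, c("lncrna_id", "mrna_id", "passed"), "pairs")
  assert_columns(de_status, c("feature_id", "call"), "de_status")

  status <- setNames(de_status$call, de_status$feature_id)
  reg_of <- function(ids) {
    s <- unname(status[ids])
    ifelse(is.na(s), "ns", s)
  }

  ia <- dplyr::distinct(interactions)
  trip <- pairs[pairs$passed, c("lncrna_id", "mrna_id")]
  if (nrow(trip) > 0) {
    trip <- dplyr::inner_join(
      trip,
      dplyr::select(ia, lncrna_id = "target_id", "mirna_id"),
      by = "lncrna_id", relationship = "many-to-many"
    ) |>
      dplyr::semi_join(
        dplyr::select(ia, mrna_id = "target_id", "mirna_id"),
        by = c("mrna_id", "mirna_id")
      ) |>
      dplyr::filter(
        reg_of(.data$lncrna_id) != "ns",
        reg_of(.data$mirna_id) != "ns",
        reg_of(.data$mrna_id) != "ns"
      ) |>
      dplyr::select("lncrna_id", "mirna_id", "mrna_id") |>
      dplyr::arrange(.data$lncrna_id, .data$mirna_id, .data$mrna_id)
  } else {
    trip <- tibble::tibble(
      lncrna_id = character(), mirna_id = character(), mrna_id = character()
    )
  }

  nodes <- dplyr::bind_rows(
    tibble::tibble(id = unique(trip$lncrna_id), node_type = "lncRNA"),
    tibble::tibble(id = unique(trip$mirna_id), node_type = "miRNA"),
    tibble::tibble(id = unique(trip$mrna_id), node_type = "mRNA")
  ) |>
    dplyr::mutate(regulation = reg_of(.data$id)) |>
    dplyr::arrange(.data$node_type, .data$id)

  edges <- dplyr::bind_rows(
    dplyr::distinct(trip, source = .data$lncrna_id, target = .data$mirna_id) |>
      dplyr::mutate(edge_type = "lncRNA-miRNA"),
    dplyr::distinct(trip, source = .data$mirna_id, target = .data$mrna_id) |>
      dplyr::mutate(edge_type = "miRNA-mRNA"),
    dplyr::distinct(trip, source = .data$lncrna_id, target = .data$mrna_id) |>
      dplyr::mutate(edge_type = "lncRNA-mRNA_cerna")
  ) |>
    dplyr::arrange(.data$edge_type, .data$source, .data$target)

  structure(
    list(nodes = nodes, edges = edges, triplets = trip),
    class = "triplet_network"
  )
}

#' @export
print.triplet_network <- function(x, ...) {
  cat(sprintf(
    "<triplet_network> %d nodes, %d edges, %d triplets\n",
    nrow(x$nodes), nrow(x$edges), nrow(x$triplets)
  ))
  invisible(x)
}
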