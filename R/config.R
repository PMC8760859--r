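#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator into one validated
#' list. The defaults describe a small two-tissue (ACL, MCL) by
#' two-condition (normal, injured) ligament RNA-seq experiment with planted
#' differential expression and planted ceRNA triplets, sized so that a full
#' pipeline run takes seconds.
#'
#' @param n_genes Number of protein-coding genes on the synthetic chromosome.
#' @param n_lncrnas Number of lncRNA transcripts.
#' @param n_mirnas Number of miRNAs in the interaction universe.
#' @param class_fractions Named fractions of the four lncRNA positional
#'   classes (`lincRNA`, `antisense`, `intronic`, `sense`); must sum to 1.
#'   Defaults follow the class proportions observed in rabbit ligament
#'   tissue (40% / 8.8% / 48.8% / 2.4%).
#' @param n_replicates Biological replicates per tissue-condition group.
#' @param nb_dispersion Negative-binomial dispersion `alpha` in the
#'   `variance = mu + alpha * mu^2` parameterization. `0` gives Poisson counts.
#' @param planted_log2fc Absolute log2 fold change planted in DE features.
#' @param mean_count Median baseline expected count per feature.
#' @param mean_log2_sd Spread (sd of log2 baseline mean) across features.
#' @param prop_de Fraction of mRNA+lncRNA features planted as DE for each
#'   of the three independent effects (ACL injury, MCL injury, tissue).
#' @param n_triplets Number of planted ceRNA (lncRNA, miRNA-set, mRNA)
#'   triplets.
#' @param k_shared Number of miRNAs shared by each planted triplet's lncRNA
#'   and mRNA; must exceed the downstream shared-miRNA cutoff for the
#'   triplet to be recoverable.
#' @param targets_per_mirna Background targets drawn per miRNA (sparse
#'   background; planted features receive no background edges so planted
#'   pairs share exactly `k_shared` miRNAs).
#' @param coexpr_sd Standard deviation (log2 scale) of the shared latent
#'   factor that co-expresses the members of each planted triplet.
#' @param qpcr_n_genes Number of target genes in the simulated qPCR panel.
#' @param ct_noise_sd Gaussian noise sd (cycles) on each technical replicate.
#' @param seed Integer root seed; every generator derives a named sub-seed
#'   from it, so all outputs are pure functions of the configuration.
#'
#' @return A list of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(n_genes = 50, n_lncrnas = 20, seed = 7)
#' cfg$class_fractions
#' @export
simulation_config <- function(n_genes = 400,
                              n_lncrnas = 250,
                              n_mirnas = 150,
                              class_fractions = c(
                                lincRNA = 0.4, antisense = 0.088,
                                intronic = 0.488, sense = 0.024
                              ),
                              n_replicates = 3,
                              nb_dispersion = 0.1,
                              planted_log2fc = 2,
                              mean_count = 200,
                              mean_log2_sd = 1,
                              prop_de = 0.1,
                              n_triplets = 10,
                              k_shared = 8,
                              targets_per_mirna = 2,
                              coexpr_sd = 2,
                              qpcr_n_genes = 6,
                              ct_noise_sd = 0.25,
                              seed = 1L) {
  for (nm in c("n_genes", "n_lncrnas", "n_mirnas", "n_replicates")) {
    v <- get(nm)
    assert_scalar_number(v, nm, lower = 1)
    if (v != round(v)) abort(sprintf("`%s` must be a whole number", nm))
  }
  if (length(class_fractions) != 4 || any(class_fractions < 0)) {
    abort("`class_fractions` must be 4 non-negative fractions")
  }
  if (is.null(names(class_fractions))) {
    names(class_fractions) <- lncrna_classes()
  }
  if (!setequal(names(class_fractions), lncrna_classes())) {
    abort(sprintf(
      "`class_fractions` names must be: %s",
      paste(lncrna_classes(), collapse = ", ")
    ))
  }
  if (abs(sum(class_fractions) - 1) > 1e-9) {
    abort("`class_fractions` must sum to 1 (within 1e-9)")
  }
  assert_scalar_number(nb_dispersion, "nb_dispersion", lower = 0)
  assert_scalar_number(mean_count, "mean_count", lower = 1e-8)
  assert_scalar_number(prop_de, "prop_de", lower = 0, upper = 1)
  assert_scalar_number(k_shared, "k_shared", lower = 1)
  if (k_shared > n_mirnas) {
    abort("`k_shared` cannot exceed `n_mirnas`")
  }
  assert_scalar_number(seed, "seed", lower = 0, upper = 2147483646)

  structure(
    list(
      n_genes = as.integer(n_genes),
      n_lncrnas = as.integer(n_lncrnas),
      n_mirnas = as.integer(n_mirnas),
      class_fractions = class_fractions[lncrna_classes()],
      n_replicates = as.integer(n_replicates),
      nb_dispersion = nb_dispersion,
      planted_log2fc = planted_log2fc,
      mean_count = mean_count,
      mean_log2_sd = mean_log2_sd,
      prop_de = prop_de,
      n_triplets = as.integer(n_triplets),
      k_shared = as.integer(k_shared),
      targets_per_mirna = as.integer(targets_per_mirna),
      coexpr_sd = coexpr_sd,
      qpcr_n_genes = as.integer(qpcr_n_genes),
      ct_noise_sd = ct_noise_sd,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("<simulation_config>\n")
  cat(sprintf(
    "  %d genes, %d lncRNAs, %d miRNAs; %d replicates per group\n",
    x$n_genes, x$n_lncrnas, x$n_mirnas, x$n_replicates
  ))
  cat(sprintf(
    "  NB dispersion %.3g, planted |log2FC| %.3g, seed %d\n",
    x$nb_dispersion, x$planted_log2fc, x$seed
  ))
  invisible(x)
}

#' The four positional lncRNA classes
#'
#' @return Character vector `c("lincRNA", "antisense", "intronic", "sense")`.
#' @export
lncrna_classes <- function() {
  c("lincRNA", "antisense", "intronic", "sense")
}

#' Largest-remainder apportionment
#'
#' Split an integer total into counts proportional to `fractions`, rounding
#' by the largest-remainder (Hamilton) method so the counts sum exactly to
#' `n`. Ties on the remainder are broken by position order.
#'
#' @param n Integer total.
#' @param fractions Non-negative fractions summing to 1.
#' @return Integer vector of counts, same length and names as `fractions`.
#' @examples
#' largest_remainder(100, c(0.4, 0.088, 0.488, 0.024))
#' @export
largest_remainder <- function(n, fractions) {
  if (abs(sum(fractions) - 1) > 1e-9) {
    abort("`fractions` must sum to 1 (within 1e-9)")
  }
  raw <- n * fractions
  counts <- floor(raw)
  short <- as.integer(round(n - sum(counts)))
  if (short > 0) {
    # order(-remainder) is a stable sort: ties go to the earlier class
    bump <- order(-(raw - counts))[seq_len(short)]
    counts[bump] <- counts[bump] + 1
  }
  as.integer(counts) |> setNames(names(fractions))
}
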