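# Independent brute-force oracles used to validate the analytic
# implementations on small instances.

# Upper-tail probability of sharing >= k elements between a fixed set of
# size n_a and a uniformly drawn set of size n_b from universe 1..m,
# by exhaustive enumeration of all C(m, n_b) draws.
oracle_hyper_tail <- function(m, n_a, n_b, k) {
  if (k == 0) {
    return(1)
  }
  if (n_b == 0) {
    return(0)
  }
  draws <- utils::combn(m, n_b)
  mean(colSums(draws <= n_a) >= k)
}

# All inclusion-maximal cliques of an adjacency matrix by scanning every
# vertex subset (bitmask enumeration), n <= 20ish.
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  stopifnot(n >= 1, n <= 20)
  bits <- 2^(0:(n - 1))
  # closed neighbourhood of each vertex as a bitmask
  nb <- vapply(
    seq_len(n),
    function(v) sum(bits[adj[v, ]]) + bits[v],
    numeric(1)
  )
  masks <- seq_len(2^n - 1) # non-empty subsets
  member <- lapply(seq_len(n), function(v) bitwAnd(masks, bits[v]) > 0)
  is_clique <- rep(TRUE, length(masks))
  for (v in seq_len(n)) {
    # every member's closed neighbourhood must cover the whole subset
    bad <- member[[v]] & bitwAnd(masks, nb[v]) != masks
    is_clique[bad] <- FALSE
  }
  cl <- masks[is_clique]
  maximal <- vapply(
    cl,
    function(mk) !any(cl != mk & bitwAnd(cl, mk) == mk),
    logical(1)
  )
  lapply(cl[maximal], function(mk) which(bitwAnd(mk, bits) > 0))
}

# MCC scores from the oracle clique list.
oracle_mcc <- function(adj) {
  cl <- oracle_maximal_cliques(adj)
  scores <- numeric(nrow(adj))
  for (c in cl) scores[c] <- scores[c] + factorial(length(c) - 1)
  scores
}

# Random simple undirected graph as (adjacency matrix, edge tibble) with
# letter node names.
random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    adj <- matrix(FALSE, n, n)
    adj[upper.tri(adj)] <- runif(n * (n - 1) / 2) < p
    adj <- adj | t(adj)
  })
  ids <- sprintf("n%02d", seq_len(n))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  list(
    adj = adj,
    ids = ids,
    edges = tibble::tibble(from = ids[idx[, 1]], to = ids[idx[, 2]])
  )
}

# Small shared simulation used across tests (kept tiny for speed).
tiny_config <- function(seed = 1, ...) {
  simulation_config(
    n_genes = 60, n_lncrnas = 30, n_mirnas = 60, n_triplets = 3,
    n_replicates = 3, seed = seed, ...
  )
}
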