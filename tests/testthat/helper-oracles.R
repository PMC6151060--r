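# Independent brute-force oracles. These deliberately avoid the package's
# own graph machinery (igraph, condensation): reachability is computed by
# boolean matrix closure, seeds by the mutual-reachability definition.

# n x n logical reachability matrix (reach[i, j]: path i -> j, i != j
# unless on a cycle) by repeated boolean squaring
oracle_reachability <- function(nodes, edges) {
  n <- length(nodes)
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(edges) > 0) adj[cbind(edges$from, edges$to)] <- TRUE
  reach <- adj
  repeat {
    nxt <- reach | ((reach %*% reach) > 0)
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  reach
}

# v is a seed iff every u that reaches v is also reached by v; its
# confidence is 1 / |mutual reachability class of v|
oracle_seeds <- function(network) {
  nodes <- network$compounds$base_id
  reach <- oracle_reachability(nodes, network$edges)
  mutual <- reach & t(reach)
  diag(mutual) <- TRUE
  is_seed <- vapply(seq_along(nodes), function(v) {
    reaches_v <- which(reach[, v])
    all(mutual[v, reaches_v])
  }, logical(1))
  class_size <- rowSums(mutual)
  tibble::tibble(
    base_id = nodes[is_seed],
    confidence = unname(1 / class_size[is_seed])
  ) |>
    dplyr::arrange(base_id)
}

# upper-tail hypergeometric by explicit binomial-coefficient enumeration
oracle_hyper <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, numeric(1))) / choose(N, n)
}

# Erdos-Renyi style random digraph as a metabolic_network; node count n,
# each ordered pair an edge with probability p
random_digraph <- function(n, p, organism_id = "rand") {
  pairs <- expand.grid(from = seq_len(n), to = seq_len(n))
  pairs <- pairs[pairs$from != pairs$to, ]
  keep <- stats::runif(nrow(pairs)) < p
  ids <- sprintf("n%03d", seq_len(n))
  edges <- tibble::tibble(from = ids[pairs$from[keep]],
                          to = ids[pairs$to[keep]])
  metabolic_network(edges, compounds = tibble::tibble(base_id = ids),
                    organism_id = organism_id)
}

expect_seed_sets_equal <- function(found, expected_tbl) {
  f <- dplyr::arrange(found$seeds[, c("base_id", "confidence")], base_id)
  e <- dplyr::arrange(tibble::as_tibble(expected_tbl)[, c("base_id",
                                                          "confidence")],
                      base_id)
  expect_equal(f$base_id, e$base_id)
  expect_equal(f$confidence, e$confidence, tolerance = 1e-12)
}
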