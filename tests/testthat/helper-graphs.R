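# graph fixtures for the message-passing module

# apply a vertex permutation to a molecular graph, also shuffling the edge
# list order (the forward pass must be invariant to both)
permute_graph <- function(g, perm) {
  inv <- order(perm)
  reorder <- sample(nrow(g$edges))
  molecular_graph(
    node_features = g$node_features[perm, , drop = FALSE],
    edges = matrix(inv[g$edges], ncol = 2)[reorder, , drop = FALSE],
    edge_features = if (is.null(g$edge_features)) NULL else
      g$edge_features[reorder, , drop = FALSE]
  )
}

random_graph <- function(n = 8, d = 3, de = 2) {
  pairs <- t(utils::combn(n, 2))
  keep <- sample(nrow(pairs), size = 2 * n, replace = FALSE)
  molecular_graph(
    node_features = matrix(rnorm(n * d), n, d),
    edges = pairs[keep, ],
    edge_features = matrix(rnorm(length(keep) * de), ncol = de)
  )
}
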