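#' Molecular graph container
#'
#' Undirected vertex/edge graph with numeric feature vectors, the input of
#' [mpnn_forward()]. Tests and examples use hand-built graphs; converting a
#' SMILES string to this structure is a pluggable adapter for a
#' cheminformatics backend and is deliberately not required by anything in
#' this module.
#'
#' @param node_features Numeric matrix, one row per vertex.
#' @param edges Two-column matrix of vertex indices (undirected, no
#'   self-loops).
#' @param edge_features Optional numeric matrix, one row per edge; features
#'   belong to the undirected edge and are therefore symmetric in (v, w).
#' @param global_features Optional numeric vector of whole-molecule
#'   descriptors.
#' @return A `molecular_graph` object.
#' @export
molecular_graph <- function(node_features, edges,
                            edge_features = NULL, global_features = NULL) {
  node_features <- as.matrix(node_features)
  n <- nrow(node_features)
  edges <- matrix(as.integer(edges), ncol = 2)
  if (nrow(edges) > 0) {
    if (any(edges < 1 | edges > n)) abort("edge endpoint out of range")
    if (any(edges[, 1] == edges[, 2])) abort("self-loops are not allowed")
  }
  if (!is.null(edge_features)) {
    edge_features <- as.matrix(edge_features)
    if (nrow(edge_features) != nrow(edges)) {
      abort("edge_features must have one row per edge")
    }
  }
  structure(list(node_features = node_features, edges = edges,
                 edge_features = edge_features,
                 global_features = global_features),
            class = "molecular_graph")
}

#' Message-passing network specification
#'
#' Defines the three learned maps of a message-passing neural network: the
#' message function `M(h_v, h_w, e_vw)`, the vertex update `U(h, m)` and the
#' permutation-invariant readout `R({h_v})`. Training is out of scope here;
#' weights are either supplied or drawn once from a seeded normal
#' initialisation, and [mpnn_forward()] is a deterministic forward pass.
#'
#' Defaults: edge-conditioned linear message
#' `tanh(W_msg h_w + W_edge e_vw)`, additive update `h + tanh(W_upd m)`, and
#' a linear readout on the vertex-state sum. Any component can be replaced
#' by a custom function taking `(h_v, h_w, e, weights)`, `(h, m, weights)`
#' or `(H, weights)` respectively.
#'
#' @param node_dim,edge_dim Feature dimensions of the input graph.
#' @param hidden_dim Hidden state size (default `node_dim`; if larger, the
#'   input features are zero-padded).
#' @param n_steps Number of message-passing rounds `T >= 0`.
#' @param weights Optional weight list (`W_msg`, `W_edge`, `W_upd`, `w_out`,
#'   `b_out`).
#' @param seed Seed for random initialisation when `weights` is `NULL`.
#' @param message_fn,update_fn,readout_fn Optional replacements for the
#'   default maps.
#' @return An `mpnn_model` object.
#' @export
mpnn_model <- function(node_dim, edge_dim = 0, hidden_dim = node_dim,
                       n_steps = 1, weights = NULL, seed = NULL,
                       message_fn = NULL, update_fn = NULL,
                       readout_fn = NULL) {
  stopifnot(n_steps >= 0, node_dim >= 1, hidden_dim >= node_dim)
  if (is.null(weights)) {
    draw <- function(nr, nc) {
      matrix(rnorm(nr * nc, sd = 1 / sqrt(hidden_dim)), nr, nc)
    }
    weights <- withr::with_seed(seed %||% 1L, list(
      W_msg = draw(hidden_dim, hidden_dim),
      W_edge = if (edge_dim > 0) draw(hidden_dim, edge_dim) else NULL,
      W_upd = draw(hidden_dim, hidden_dim),
      w_out = drop(draw(1, hidden_dim)),
      b_out = 0
    ))
  }
  structure(list(node_dim = node_dim, edge_dim = edge_dim,
                 hidden_dim = hidden_dim, n_steps = n_steps,
                 weights = weights,
                 message_fn = message_fn, update_fn = update_fn,
                 readout_fn = readout_fn),
            class = "mpnn_model")
}

#' Forward pass of the message-passing network
#'
#' Runs `n_steps` rounds of neighbour message aggregation
#' \deqn{m_v^{t+1} = \sum_{w \in N(v)} M(h_v^t, h_w^t, e_{vw})}
#' followed by the vertex update `h_v^{t+1} = U(h_v^t, m_v^{t+1})`, then a
#' readout over the vertex-state multiset. The readout aggregates by
#' summation, so the prediction is invariant to vertex relabelling and
#' edge-list reordering by construction.
#'
#' @param graph A [molecular_graph()].
#' @param model An [mpnn_model()].
#' @return Predicted scalar.
#' @export
mpnn_forward <- function(graph, model) {
  stopifnot(inherits(graph, "molecular_graph"), inherits(model, "mpnn_model"))
  X <- graph$node_features
  if (ncol(X) != model$node_dim) {
    abort(sprintf("graph has node dimension %d; model expects %d",
                  ncol(X), model$node_dim))
  }
  edim <- if (is.null(graph$edge_features)) 0 else ncol(graph$edge_features)
  if (edim != model$edge_dim) {
    abort(sprintf("graph has edge dimension %d; model expects %d",
                  edim, model$edge_dim))
  }
  n <- nrow(X)
  H <- cbind(X, matrix(0, n, model$hidden_dim - model$node_dim))
  W <- model$weights

  message_fn <- model$message_fn %||% function(h_v, h_w, e, w) {
    m <- w$W_msg %*% h_w
    if (!is.null(e) && !is.null(w$W_edge)) m <- m + w$W_edge %*% e
    tanh(m)
  }
  update_fn <- model$update_fn %||% function(h, m, w) {
    h + tanh(drop(w$W_upd %*% m))
  }
  readout_fn <- model$readout_fn %||% function(H, w) {
    drop(w$w_out %*% colSums(H)) + w$b_out
  }

  if (model$n_steps > 0 && nrow(graph$edges) > 0) {
    # expand undirected edges into both directions once
    from <- c(graph$edges[, 1], graph$edges[, 2])
    to <- c(graph$edges[, 2], graph$edges[, 1])
    efeat <- if (edim > 0) {
      rbind(graph$edge_features, graph$edge_features)
    } else NULL
    for (step in seq_len(model$n_steps)) {
      Msg <- matrix(0, n, model$hidden_dim)
      for (k in seq_along(from)) {
        e <- if (is.null(efeat)) NULL else efeat[k, ]
        Msg[to[k], ] <- Msg[to[k], ] +
          drop(message_fn(H[to[k], ], H[from[k], ], e, W))
      }
      Hnew <- matrix(0, n, model$hidden_dim)
      for (v in seq_len(n)) Hnew[v, ] <- drop(update_fn(H[v, ], Msg[v, ], W))
      H <- Hnew
    }
  }
  readout_fn(H, W)
}
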