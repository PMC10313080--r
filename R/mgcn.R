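#' Per-relation sparse adjacency operators
#'
#' For each relation r the message-passing operator is the binary
#' n_dst x n_src adjacency A_r, so that unnormalized sum aggregation of
#' transformed source features is `A_r (X_src W_r)`. A logical `recv` mask
#' marks destination nodes receiving at least one message (the per-relation
#' bias is added once to exactly those rows). With `normalize = "mean"` rows
#' of A_r are divided by the in-degree (mean-aggregation variant).
#'
#' @param graph a `hetero_graph`.
#' @param normalize `"none"` (sum aggregation, the default) or `"mean"`.
#' @return named list of `dgCMatrix` operators with attributes `src`, `dst`,
#'   `recv`.
#' @export
graph_adjacency <- function(graph, normalize = c("none", "mean")) {
  normalize <- match.arg(normalize)
  out <- list()
  for (rel in names(graph$edges)) {
    et <- graph$edge_types[[rel]]
    e <- graph$edges[[rel]]
    nd <- length(graph$nodes[[et[["dst"]]]])
    ns <- length(graph$nodes[[et[["src"]]]])
    A <- Matrix::sparseMatrix(i = e[, 2], j = e[, 1], x = 1, dims = c(nd, ns))
    deg <- Matrix::rowSums(A)
    if (normalize == "mean") {
      d <- ifelse(deg > 0, 1 / deg, 0)
      A <- Matrix::Diagonal(x = d) %*% A
    }
    attr(A, "src") <- unname(et[["src"]])
    attr(A, "dst") <- unname(et[["dst"]])
    attr(A, "recv") <- deg > 0
    out[[rel]] <- A
  }
  out
}

#' Initialize a multi-subgraph convolution layer
#'
#' One (W^r, b^r) per relation; W^r is d_src(r) x d_out with Xavier-uniform
#' entries (limit sqrt(6/(fan_in + fan_out))), b^r starts at 0. All relations
#' share the output dimension; input dimensions may differ per source type.
#'
#' @param edge_types named list relation -> `c(src, dst)` node types.
#' @param in_dims named integer vector: node type -> input feature dim.
#' @param out_dim output embedding dimension.
#' @param seed optional seed (`NULL` = current RNG stream).
#' @param slope LeakyReLU negative slope applied after cross-relation
#'   summation.
#' @return an `mgcn_layer`: list(W, b, edge_types, out_dim, slope).
#' @export
mgcn_layer <- function(edge_types, in_dims, out_dim, seed = NULL, slope = 0.2) {
  with_seed(seed, {
    W <- list(); b <- list()
    for (rel in names(edge_types)) {
      din <- in_dims[[edge_types[[rel]][["src"]]]]
      lim <- sqrt(6 / (din + out_dim))
      W[[rel]] <- matrix(runif(din * out_dim, -lim, lim), din, out_dim)
      b[[rel]] <- numeric(out_dim)
    }
    structure(list(W = W, b = b, edge_types = edge_types,
                   out_dim = out_dim, slope = slope),
              class = "mgcn_layer")
  })
}

# node types of the graph covered by an adjacency list
adj_node_types <- function(adj) {
  unique(unlist(lapply(adj, function(A) c(attr(A, "src"), attr(A, "dst")))))
}

#' Single multi-subgraph convolution layer forward pass
#'
#' For each destination node i:
#' h_i' = sigma( sum_r [ sum_{j in N_i^r} W^r h_j  + b^r ] ),
#' where the per-relation bias is added once per relation delivering at
#' least one message to i, sigma is LeakyReLU applied after the
#' cross-relation summation, and nodes receiving no messages map to
#' sigma(0) = 0 (no implicit self-loops).
#'
#' @param layer an [mgcn_layer()].
#' @param adj adjacency list from [graph_adjacency()].
#' @param feats named list of input feature matrices per node type.
#' @param activation apply the LeakyReLU nonlinearity (set `FALSE` for a
#'   purely linear pass).
#' @return list(H = activated embeddings per node type, Z = pre-activations).
#' @export
mgcn_layer_forward <- function(layer, adj, feats, activation = TRUE) {
  sizes <- vapply(feats, nrow, 0L)
  Z <- lapply(sizes, function(n) matrix(0, n, layer$out_dim))
  for (rel in names(adj)) {
    A <- adj[[rel]]
    s <- attr(A, "src"); d <- attr(A, "dst")
    W <- layer$W[[rel]]
    if (is.null(W)) stop("layer has no weights for relation '", rel, "'")
    if (ncol(feats[[s]]) != nrow(W))
      stop("feature dimension ", ncol(feats[[s]]), " of type '", s,
           "' does not match W input dim ", nrow(W), " for relation '", rel, "'")
    msg <- as.matrix(A %*% (feats[[s]] %*% W))
    recv <- attr(A, "recv")
    if (any(recv))
      msg[recv, ] <- msg[recv, , drop = FALSE] +
        rep(layer$b[[rel]], each = sum(recv))
    Z[[d]] <- Z[[d]] + msg
  }
  H <- if (activation) lapply(Z, leaky_relu, slope = layer$slope) else Z
  list(H = H, Z = Z)
}

#' Forward pass through a stack of convolution layers
#'
#' Composition of [mgcn_layer_forward()] with inverted dropout between
#' layers in training mode; evaluation mode (`training = FALSE`) is
#' deterministic. The cache returned carries everything the backward pass
#' needs (per-layer inputs, pre-activations, dropout masks).
#'
#' @param layers list of [mgcn_layer()]s (>= 1).
#' @param adj adjacency list.
#' @param feats input feature matrices per node type.
#' @param dropout dropout rate between layers (default 0).
#' @param training draw dropout masks (from the current RNG stream).
#' @return list(H = final embeddings per type, cache).
#' @export
mgcn_stack_forward <- function(layers, adj, feats, dropout = 0, training = FALSE) {
  if (!length(layers)) stop("empty layer list")
  cache <- vector("list", length(layers))
  X <- feats
  for (l in seq_along(layers)) {
    mask <- NULL
    if (l > 1 && training && dropout > 0) {
      mask <- lapply(X, function(m)
        matrix(rbinom(length(m), 1, 1 - dropout), nrow(m), ncol(m)) / (1 - dropout))
      X <- tree_map2(`*`, X, mask)
    }
    fw <- mgcn_layer_forward(layers[[l]], adj, X)
    cache[[l]] <- list(X = X, Z = fw$Z, mask = mask)
    X <- fw$H
  }
  list(H = X, cache = cache)
}

#' Backward pass through a convolution stack
#'
#' Given the gradient of a scalar loss with respect to the stack's final
#' embeddings, returns the gradients for every layer's (W^r, b^r) and the
#' gradient with respect to the stack input (used to chain the type-module
#' stack into the link-module stack).
#'
#' @param layers the layer list used in the forward pass.
#' @param adj the adjacency list used in the forward pass.
#' @param cache cache returned by [mgcn_stack_forward()].
#' @param dH named list (per node type) of gradients w.r.t. final embeddings.
#' @return list(grads = per-layer list(W, b), dX = input gradient per type).
#' @export
mgcn_stack_backward <- function(layers, adj, cache, dH) {
  grads <- vector("list", length(layers))
  for (l in rev(seq_along(layers))) {
    layer <- layers[[l]]
    cc <- cache[[l]]
    dZ <- tree_map2(function(g, z) g * leaky_relu_grad(z, layer$slope), dH, cc$Z)
    gW <- list(); gb <- list()
    dX <- lapply(cc$X, function(m) matrix(0, nrow(m), ncol(m)))
    for (rel in names(adj)) {
      A <- adj[[rel]]
      s <- attr(A, "src"); d <- attr(A, "dst")
      M <- as.matrix(Matrix::crossprod(A, dZ[[d]]))      # t(A) %*% dZ_d
      gW[[rel]] <- crossprod(cc$X[[s]], M)
      recv <- attr(A, "recv")
      gb[[rel]] <- colSums(dZ[[d]][recv, , drop = FALSE])
      dX[[s]] <- dX[[s]] + tcrossprod(M, layer$W[[rel]])
    }
    grads[[l]] <- list(W = gW, b = gb)
    if (!is.null(cc$mask)) dX <- tree_map2(`*`, dX, cc$mask)
    dH <- dX
  }
  list(grads = grads, dX = dH)
}
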