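#' Subgraph of regulatory edges with known type
#'
#' The regulation-type module convolves only over the TF-target edges whose
#' activation/repression annotation is known; "unknown"-typed edges never
#' enter its message passing or its loss. Dual-annotated edges (both
#' activation and repression) are retained once with label (1, 1). The node
#' set is preserved.
#'
#' @param graph a `hetero_graph` with regulatory edges.
#' @param reverse_edges add the reverse relation (default `TRUE`).
#' @return a `hetero_graph` with relations `reg_typed` (+`reg_typed_rev`),
#'   carrying a `labels` attribute: (n_edges x 2) 0/1 matrix
#'   (activation, repression).
#' @export
type_subgraph <- function(graph, reverse_edges = TRUE) {
  rel <- graph$reg_relation
  if (is.null(graph$edges[[rel]])) stop("graph has no '", rel, "' edges")
  known <- if (is.null(graph$reg_type)) logical(nrow(graph$edges[[rel]])) else graph$reg_type$known
  e <- graph$edges[[rel]][known, , drop = FALSE]
  if (!nrow(e)) grn_log("type subgraph is empty: no known-type regulatory edges")
  et <- graph$edge_types[[rel]]
  edges <- list(reg_typed = e)
  edge_types <- list(reg_typed = et)
  if (reverse_edges) {
    edges$reg_typed_rev <- e[, c(2L, 1L), drop = FALSE]
    edge_types$reg_typed_rev <- c(src = unname(et[["dst"]]), dst = unname(et[["src"]]))
  }
  g <- hetero_graph(graph$nodes, edge_types, edges, reg_relation = "reg_typed")
  attr(g, "labels") <- cbind(
    activation = as.integer(graph$reg_type$activation[known]),
    repression = as.integer(graph$reg_type$repression[known]))
  g
}

#' Multilabel regulation-type head
#'
#' Per edge (i, j), logits = t(W2) (h_i || h_j) where || concatenates the
#' two endpoint embeddings and W2 is (2 d_embedding) x 2. Scores use the
#' configured head: per-class sigmoid by default (a pair can be both
#' activating and repressing, so the two classes must be independent), or a
#' softmax over the two classes behind the `head` flag.
#'
#' @param W2 weight matrix, (2 * d_embedding) x 2.
#' @param emb_src,emb_dst endpoint embedding matrices.
#' @param edges 2-column index matrix of (src, dst) pairs.
#' @param head `"sigmoid"` (default) or `"softmax"`.
#' @return list(logits (n x 2), scores (n x 2), predicted (n x 2, 0/1 at
#'   score > 0.5)).
#' @export
classify_edges <- function(W2, emb_src, edges, emb_dst = emb_src,
                           head = c("sigmoid", "softmax")) {
  head <- match.arg(head)
  edges <- matrix(as.integer(edges), ncol = 2)
  d <- ncol(emb_src)
  if (nrow(W2) != 2 * d || ncol(W2) != 2)
    stop("W2 must be (2 * d_embedding) x 2; got ", nrow(W2), " x ", ncol(W2),
         " for d_embedding = ", d)
  C <- cbind(emb_src[edges[, 1], , drop = FALSE],
             emb_dst[edges[, 2], , drop = FALSE])
  logits <- C %*% W2
  scores <- if (head == "sigmoid") sigmoid(logits) else {
    ez <- exp(logits - apply(logits, 1, max))
    ez / rowSums(ez)
  }
  list(logits = logits, scores = scores,
       predicted = matrix(as.integer(scores > 0.5), nrow(scores), 2,
                          dimnames = list(NULL, c("activation", "repression"))))
}

#' Multilabel regulation-type loss
#'
#' Per (edge, class) slot k the loss contributes
#' -[ y_k log(sigma(yhat_k)) + (1 - y_k) log(1 - sigma(yhat_k)) ], summed
#' over the two classes with the factor 1/2 and then reduced over edges
#' (`"mean"` by default; `"sum"` gives the un-reduced half-sum over all
#' slots; `"none"` the per-edge values). Computed on logits in
#' log-sum-exp form.
#'
#' @param logits (n x 2) logits.
#' @param Y (n x 2) 0/1 label matrix; label (1, 1) is legal.
#' @param reduction `"mean"`, `"sum"` or `"none"`.
#' @return scalar loss (or per-edge vector for `"none"`).
#' @export
type_loss <- function(logits, Y, reduction = c("mean", "sum", "none")) {
  reduction <- match.arg(reduction)
  logits <- as.matrix(logits); Y <- as.matrix(Y)
  if (!nrow(logits)) stop("empty batch")
  if (!all(dim(logits) == dim(Y))) stop("shape mismatch")
  if (!all(Y %in% c(0, 1))) stop("labels must be 0/1")
  slot <- log1pexp(logits) - Y * logits   # per-slot BCE on logits
  per_edge <- 0.5 * rowSums(slot)
  switch(reduction, mean = mean(per_edge), sum = sum(per_edge), none = per_edge)
}

# gradient of mean-reduced type_loss w.r.t. logits
type_loss_grad <- function(logits, Y) {
  0.5 * (sigmoid(logits) - Y) / nrow(logits)
}

#' Predict regulation types for TF-target pairs
#'
#' @param model trained model from [train_model()].
#' @param graph,features graph and features used in training.
#' @param edges 2-column (TF index, gene index) matrix; defaults to the
#'   unknown-type regulatory edges of the graph.
#' @return data.frame(tf_id, gene_id, score_activation, score_repression,
#'   pred_activation, pred_repression).
#' @export
predict_types <- function(model, graph, features, edges = NULL) {
  if (is.null(edges)) {
    known <- graph$reg_type$known
    edges <- graph$edges[[graph$reg_relation]][!known, , drop = FALSE]
  }
  emb <- model_embeddings(model, graph, features)$type
  cl <- classify_edges(model$params$W2, emb$TF, edges, emb$tg,
                       head = model$config$head)
  data.frame(tf_id = graph$nodes$TF[edges[, 1]],
             gene_id = graph$nodes$tg[edges[, 2]],
             score_activation = cl$scores[, 1],
             score_repression = cl$scores[, 2],
             pred_activation = cl$predicted[, 1],
             pred_repression = cl$predicted[, 2])
}
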