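#' Dot-product link scores
#'
#' Probability of a link between nodes i and j is the logistic dot product
#' of their embeddings, P_ij = 1 / (1 + exp(-h_i . h_j)); a pair is
#' predicted linked iff P > 0.5. The score is symmetric in i and j.
#'
#' @param emb_src embedding matrix of the source-type nodes.
#' @param pairs 2-column index matrix (src_index, dst_index).
#' @param emb_dst embedding matrix of the destination-type nodes (defaults
#'   to `emb_src` for within-type pairs).
#' @return list(logits, scores, predicted) with scores strictly in (0, 1).
#' @export
score_pairs <- function(emb_src, pairs, emb_dst = emb_src) {
  pairs <- matrix(as.integer(pairs), ncol = 2)
  if (nrow(pairs)) {
    if (any(pairs[, 1] < 1 | pairs[, 1] > nrow(emb_src)) ||
        any(pairs[, 2] < 1 | pairs[, 2] > nrow(emb_dst)))
      stop("pair index out of range")
  }
  z <- rowSums(emb_src[pairs[, 1], , drop = FALSE] *
               emb_dst[pairs[, 2], , drop = FALSE])
  list(logits = z, scores = sigmoid(z), predicted = as.integer(z > 0))
}

#' Link-existence loss (mean binary cross-entropy)
#'
#' Cross-entropy between pair scores and 0/1 link labels, computed on the
#' logits in log-sum-exp form for numerical safety and averaged over the
#' scored pairs: mean( log(1 + e^z) - y z ). Identical to
#' -mean( y log P + (1-y) log(1-P) ) with P the sigmoid score.
#'
#' @param logits pair logits (h_i . h_j).
#' @param labels binary labels, same length.
#' @return scalar loss.
#' @export
link_loss <- function(logits, labels) {
  if (!length(logits)) stop("empty batch")
  stopifnot(length(logits) == length(labels), all(labels %in% c(0, 1)))
  mean(log1pexp(logits) - labels * logits)
}

# gradient of link_loss w.r.t. logits
link_loss_grad <- function(logits, labels) {
  (sigmoid(logits) - labels) / length(logits)
}

#' Rank candidate links by score
#'
#' Scores candidate (src, dst) pairs of a relation with a trained model and
#' returns them sorted by score descending (top-k recommendation workflow).
#' Pairs already present as positive edges are excluded by default.
#'
#' @param model a trained model from [train_model()].
#' @param graph,features the graph and feature set used in training.
#' @param relation relation to score (default the regulatory relation).
#' @param pairs candidate pairs, or `NULL` for all non-edge pairs.
#' @return data.frame(src_id, dst_id, relation, score, predicted_link)
#'   sorted by score descending.
#' @export
predict_links <- function(model, graph, features, relation = graph$reg_relation,
                          pairs = NULL) {
  emb <- model_embeddings(model, graph, features)$link
  et <- graph$edge_types[[relation]]
  if (is.null(pairs)) {
    ns <- length(graph$nodes[[et[["src"]]]])
    nd <- length(graph$nodes[[et[["dst"]]]])
    all_p <- cbind(rep(seq_len(ns), each = nd), rep.int(seq_len(nd), ns))
    pos <- paste(graph$edges[[relation]][, 1], graph$edges[[relation]][, 2])
    pairs <- all_p[!(paste(all_p[, 1], all_p[, 2]) %in% pos), , drop = FALSE]
  }
  sc <- score_pairs(emb[[et[["src"]]]], pairs, emb[[et[["dst"]]]])
  out <- data.frame(src_id = graph$nodes[[et[["src"]]]][pairs[, 1]],
                    dst_id = graph$nodes[[et[["dst"]]]][pairs[, 2]],
                    relation = relation, score = sc$scores,
                    predicted_link = sc$predicted)
  out[order(-out$score), , drop = FALSE]
}
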