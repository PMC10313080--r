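#' Run configuration
#'
#' Defaults follow the reference training recipe: 300 epochs, Adam with
#' learning rate 0.001 and weight decay 0.0001, dropout 0.2, LeakyReLU
#' slope 0.2, Xavier initialization, 2 convolution layers, link embedding
#' dimension 256 and type embedding dimension 32, one negative per
#' positive, per-class sigmoid type head, reverse relations on, GradNorm
#' enabled with alpha 1.5 and an independent Adam (lr 0.025) on the task
#' weights.
#'
#' @param strategy graph-construction strategy (see [graph_strategies()]).
#' @param k cross-validation folds.
#' @param epochs,lr,weight_decay,dropout,leaky_slope optimizer and
#'   regularization settings.
#' @param layers,link_dim,type_dim,type_layers convolution depth/widths of
#'   the two modules (the type module consumes the link module's output
#'   embeddings as its input features).
#' @param gradnorm list(enabled, alpha, weight_lr).
#' @param negative_ratio negatives per positive in training batches.
#' @param head type head: `"sigmoid"` (default) or `"softmax"`.
#' @param reverse_edges add reverse relations with their own weights.
#' @param relation the predicted relation (fold splitting and scoring).
#' @param normalize `"none"` (sum aggregation) or `"mean"`.
#' @param self_loops add per-type self-loop relations (off by default).
#' @param verbose log per-epoch losses.
#' @return a `run_config` list.
#' @export
run_config <- function(strategy = "go_disease", k = 5, epochs = 300,
                       lr = 0.001, weight_decay = 1e-4, dropout = 0.2,
                       leaky_slope = 0.2, layers = 2, link_dim = 256,
                       type_dim = 32, type_layers = 2,
                       gradnorm = list(enabled = TRUE, alpha = 1.5, weight_lr = 0.025),
                       negative_ratio = 1, head = c("sigmoid", "softmax"),
                       reverse_edges = TRUE, relation = REG_RELATION,
                       normalize = c("none", "mean"), self_loops = FALSE,
                       verbose = FALSE) {
  head <- match.arg(head)
  normalize <- match.arg(normalize)
  gn <- utils::modifyList(list(enabled = TRUE, alpha = 1.5, weight_lr = 0.025), gradnorm)
  structure(as.list(environment()), class = "run_config")
}

edge_types_of_adj <- function(adj) {
  lapply(adj, function(A) c(src = attr(A, "src"), dst = attr(A, "dst")))
}

add_self_loops <- function(adj, graph) {
  for (t in names(graph$nodes)) {
    n <- length(graph$nodes[[t]])
    A <- Matrix::Diagonal(n)
    attr(A, "src") <- t; attr(A, "dst") <- t
    attr(A, "recv") <- rep(TRUE, n)
    adj[[paste0("self_", t)]] <- A
  }
  adj
}

# layer template (structure/slope) + parameter leaves -> usable layer
layer_with <- function(template, p) {
  template$W <- p$W; template$b <- p$b
  template
}

layer_params <- function(layer) list(W = layer$W, b = layer$b)

accum_rows <- function(n, d, idx, M) {
  out <- matrix(0, n, d)
  if (length(idx)) {
    rs <- rowsum(M, group = idx)
    out[as.integer(rownames(rs)), ] <- out[as.integer(rownames(rs)), ] + rs
  }
  out
}

zeros_like <- function(tree) tree_map(function(x) x * 0, tree)

# rebuild a parameter tree from a flat vector (inverse of unlist)
unflatten_like <- function(tree, vec) {
  pos <- 0L
  rec <- function(t) {
    if (is.list(t)) return(lapply(t, rec))
    n <- length(t)
    out <- vec[pos + seq_len(n)]
    pos <<- pos + n
    dim(out) <- dim(t)
    out
  }
  rec(tree)
}

# one Adam step on flat vectors; returns list(p, m, v)
adam_flat <- function(p, g, m, v, t, lr, weight_decay = 0) {
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  if (weight_decay > 0) g <- g + weight_decay * p
  m <- b1 * m + (1 - b1) * g
  v <- b2 * v + (1 - b2) * g * g
  p <- p - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
  list(p = p, m = m, v = v)
}

# joint forward + per-task backward pass.
# Returns losses, per-task gradient trees and the embeddings.
model_forward_backward <- function(params, meta, feats, pairs, plab,
                                   tedges, Y, training = TRUE) {
  cfg <- meta$config
  link_layers <- Map(layer_with, meta$link_templates, params$link)
  lf <- mgcn_stack_forward(link_layers, meta$adj_link, feats,
                           dropout = cfg$dropout, training = training)
  H2 <- lf$H
  st <- meta$pred_src_type; dt <- meta$pred_dst_type
  z <- rowSums(H2[[st]][pairs[, 1], , drop = FALSE] *
               H2[[dt]][pairs[, 2], , drop = FALSE])
  L1 <- link_loss(z, plab)
  dz <- link_loss_grad(z, plab)
  dH2_link <- lapply(H2, function(m) matrix(0, nrow(m), ncol(m)))
  d <- ncol(H2[[st]])
  dH2_link[[st]] <- dH2_link[[st]] +
    accum_rows(nrow(H2[[st]]), d, pairs[, 1], dz * H2[[dt]][pairs[, 2], , drop = FALSE])
  dH2_link[[dt]] <- dH2_link[[dt]] +
    accum_rows(nrow(H2[[dt]]), d, pairs[, 2], dz * H2[[st]][pairs[, 1], , drop = FALSE])
  g1_link <- mgcn_stack_backward(link_layers, meta$adj_link, lf$cache, dH2_link)$grads

  has_type <- nrow(tedges) > 0
  if (has_type) {
    type_layers <- Map(layer_with, meta$type_templates, params$type)
    tf2 <- mgcn_stack_forward(type_layers, meta$adj_type, H2,
                              dropout = cfg$dropout, training = training)
    Te <- tf2$H
    C <- cbind(Te[[st]][tedges[, 1], , drop = FALSE],
               Te[[dt]][tedges[, 2], , drop = FALSE])
    logits <- C %*% params$W2
    L2 <- type_loss(logits, Y)
    dlog <- type_loss_grad(logits, Y)
    gW2 <- crossprod(C, dlog)
    dC <- dlog %*% t(params$W2)
    td <- cfg$type_dim
    dT <- lapply(Te, function(m) matrix(0, nrow(m), ncol(m)))
    dT[[st]] <- dT[[st]] + accum_rows(nrow(Te[[st]]), td, tedges[, 1], dC[, seq_len(td), drop = FALSE])
    dT[[dt]] <- dT[[dt]] + accum_rows(nrow(Te[[dt]]), td, tedges[, 2], dC[, td + seq_len(td), drop = FALSE])
    tb <- mgcn_stack_backward(type_layers, meta$adj_type, tf2$cache, dT)
    g2_type <- tb$grads
    g2_link <- mgcn_stack_backward(link_layers, meta$adj_link, lf$cache, tb$dX)$grads
  } else {
    Te <- NULL
    L2 <- 0
    gW2 <- zeros_like(params$W2)
    g2_type <- zeros_like(params$type)
    g2_link <- zeros_like(params$link)
  }
  list(L1 = L1, L2 = L2, logits = z,
       g1_link = g1_link, g2_link = g2_link, g2_type = g2_type, gW2 = gW2,
       H2 = H2, Te = Te, has_type = has_type)
}

build_model_meta <- function(graph, features, config, train_idx) {
  rel <- config$relation
  et <- graph$edge_types[[rel]]
  n_pos <- nrow(graph$edges[[rel]])
  test_idx <- setdiff(seq_len(n_pos), train_idx)

  # message graph: held-out predicted edges (and their reverses) are removed
  msg_graph <- graph
  msg_graph$edges[[rel]] <- graph$edges[[rel]][train_idx, , drop = FALSE]
  rrel <- paste0(rel, REV_SUFFIX)
  if (!is.null(graph$edges[[rrel]]))
    msg_graph$edges[[rrel]] <- msg_graph$edges[[rel]][, c(2L, 1L), drop = FALSE]
  if (!is.null(msg_graph$reg_type))
    msg_graph$reg_type <- graph$reg_type[train_idx, , drop = FALSE]
  adj_link <- graph_adjacency(msg_graph, normalize = config$normalize)
  if (config$self_loops) adj_link <- add_self_loops(adj_link, graph)

  # leakage guard: held-out edges must be absent from the message operator
  if (length(test_idx)) {
    te <- graph$edges[[rel]][test_idx, , drop = FALSE]
    A <- adj_link[[rel]]
    if (any(A[cbind(te[, 2], te[, 1])] != 0))
      stop("leakage: held-out edge present in the message-passing graph")
  }

  # type module: train-fold edges with known annotation only
  tg <- type_subgraph(msg_graph, reverse_edges = config$reverse_edges)
  adj_type <- graph_adjacency(tg, normalize = config$normalize)
  if (config$self_loops) adj_type <- add_self_loops(adj_type, graph)

  in_dims <- vapply(features, ncol, 0L)
  link_et <- edge_types_of_adj(adj_link)
  type_et <- edge_types_of_adj(adj_type)
  dims_link <- c(list(in_dims), rep(list(setNames(rep(config$link_dim, length(in_dims)),
                                                  names(in_dims))), config$layers - 1))
  dims_type_in <- setNames(rep(config$link_dim, length(in_dims)), names(in_dims))
  dims_type <- c(list(dims_type_in), rep(list(setNames(rep(config$type_dim, length(in_dims)),
                                                       names(in_dims))), config$type_layers - 1))
  link_templates <- lapply(seq_len(config$layers), function(l)
    mgcn_layer(link_et, dims_link[[l]], config$link_dim, slope = config$leaky_slope))
  type_templates <- lapply(seq_len(config$type_layers), function(l)
    mgcn_layer(type_et, dims_type[[l]], config$type_dim, slope = config$leaky_slope))

  list(config = config, adj_link = adj_link, adj_type = adj_type,
       link_templates = link_templates, type_templates = type_templates,
       pred_src_type = unname(et[["src"]]), pred_dst_type = unname(et[["dst"]]),
       train_idx = train_idx, test_idx = test_idx,
       type_edges = tg$edges$reg_typed, type_labels = attr(tg, "labels"))
}

#' Train the multi-task model
#'
#' End-to-end training of the two-task network on a heterogeneous graph:
#' per epoch, negatives for the link task are re-sampled (never colliding
#' with a positive edge), the link convolution stack runs on the message
#' graph (held-out edges excluded), the link loss is computed on the
#' train-fold positives plus negatives, the type convolution stack runs on
#' the train-fold known-type regulatory subgraph with the link embeddings
#' as input, the multilabel type loss is computed on the labeled train
#' edges, GradNorm updates the task weights, and all parameters take one
#' Adam step on the weighted total loss. Fully deterministic given the
#' seed.
#'
#' @param graph a `hetero_graph`.
#' @param features a [build_features()] feature set for `graph`.
#' @param config a [run_config()].
#' @param seed integer seed controlling initialization, dropout and
#'   negative sampling.
#' @param train_idx indices (into the predicted relation's edges) used for
#'   training; defaults to all edges.
#' @param test_idx held-out edge indices (excluded from message passing and
#'   from every loss); defaults to the complement of `train_idx`.
#' @return a `grn_model`: list(params, meta, config, log, seed). The log
#'   data.frame has one row per epoch (epoch, L1, L2, w1, w2, total).
#' @export
train_model <- function(graph, features, config = run_config(), seed = 1,
                        train_idx = NULL, test_idx = NULL) {
  rel <- config$relation
  n_pos <- nrow(graph$edges[[rel]])
  if (is.null(train_idx))
    train_idx <- if (is.null(test_idx)) seq_len(n_pos) else setdiff(seq_len(n_pos), test_idx)
  with_seed(seed, {
    meta <- build_model_meta(graph, features, config, train_idx)
    # Xavier-initialized parameters (templates already drew W; reuse them)
    params <- list(link = lapply(meta$link_templates, layer_params),
                   type = lapply(meta$type_templates, layer_params),
                   W2 = {
                     lim <- sqrt(6 / (2 * config$type_dim + 2))
                     matrix(runif(2 * config$type_dim * 2, -lim, lim),
                            2 * config$type_dim, 2)
                   })
    n_typed <- nrow(meta$type_edges)
    use_gradnorm <- isTRUE(config$gn$enabled) && n_typed > 0
    gstate <- gradnorm_state(2, alpha = config$gn$alpha, lr = config$gn$weight_lr)
    pvec <- unlist(params, use.names = FALSE)
    m <- numeric(length(pvec)); v <- numeric(length(pvec)); tstep <- 0L
    pos_pairs <- graph$edges[[rel]][train_idx, , drop = FALSE]
    n_neg <- round(config$negative_ratio * nrow(pos_pairs))
    log <- vector("list", config$epochs)
    shared_l <- length(params$link)   # GradNorm shared layer: last link layer
    Y <- meta$type_labels
    for (ep in seq_len(config$epochs)) {
      negs <- sample_negatives(graph, rel, n_neg, seed = NULL)
      pairs <- rbind(pos_pairs, negs)
      plab <- c(rep(1, nrow(pos_pairs)), rep(0, nrow(negs)))
      fb <- model_forward_backward(params, meta, features, pairs, plab,
                                   meta$type_edges, Y, training = TRUE)
      if (!is.finite(fb$L1)) stop("NaN/Inf in link loss at epoch ", ep)
      if (!is.finite(fb$L2)) stop("NaN/Inf in type loss at epoch ", ep)
      if (use_gradnorm) {
        gs <- gradnorm_step(gstate, c(fb$L1, fb$L2),
                            list(fb$g1_link[[shared_l]], fb$g2_link[[shared_l]]))
        gstate <- gs$state
        w <- gs$omega
      } else {
        w <- c(1, 1)
      }
      gvec <- c(w[1] * unlist(fb$g1_link, use.names = FALSE) +
                  w[2] * unlist(fb$g2_link, use.names = FALSE),
                w[2] * unlist(fb$g2_type, use.names = FALSE),
                w[2] * as.vector(fb$gW2))
      tstep <- tstep + 1L
      upd <- adam_flat(pvec, gvec, m, v, tstep, config$lr, config$weight_decay)
      pvec <- upd$p; m <- upd$m; v <- upd$v
      params <- unflatten_like(params, pvec)
      log[[ep]] <- data.frame(epoch = ep, L1 = fb$L1, L2 = fb$L2,
                              w1 = w[1], w2 = w[2],
                              total = w[1] * fb$L1 + w[2] * fb$L2)
      if (config$verbose && (ep %% 25 == 0 || ep == 1))
        grn_log(sprintf("epoch %d  L1=%.4f L2=%.4f w=(%.3f, %.3f)",
                        ep, fb$L1, fb$L2, w[1], w[2]), verbose = TRUE)
    }
    structure(list(params = params, meta = meta, config = config,
                   log = do.call(rbind, log), seed = seed),
              class = "grn_model")
  })
}

#' Embeddings of a trained model (evaluation mode)
#'
#' Deterministic forward pass (no dropout) on the model's own message
#' graph; returns the link-module and type-module embedding tables.
#'
#' @param model a `grn_model`. @param graph,features as in training.
#' @return list(link = per-type matrices, type = per-type matrices).
#' @export
model_embeddings <- function(model, graph, features) {
  meta <- model$meta
  link_layers <- Map(layer_with, meta$link_templates, model$params$link)
  H2 <- mgcn_stack_forward(link_layers, meta$adj_link, features, training = FALSE)$H
  type_layers <- Map(layer_with, meta$type_templates, model$params$type)
  Te <- mgcn_stack_forward(type_layers, meta$adj_type, H2, training = FALSE)$H
  list(link = H2, type = Te)
}

#' Evaluate a trained model on held-out edges
#'
#' Link metrics (AUC, accuracy, precision, recall, F1 at the 0.5 score
#' threshold) on the held-out positives plus the supplied fixed negative
#' pairs; regulation-type metrics (AUC over flattened (edge, class) scores,
#' Hamming loss, example-based CP/CR/CF1 at the 0.5 threshold) on the
#' held-out known-type edges. The forward pass uses the model's training
#' message graph, so held-out edges never leak into convolution.
#'
#' @param model a `grn_model`.
#' @param graph,features graph and features used in training.
#' @param test_idx held-out positive edge indices (default: the model's).
#' @param negatives fixed 2-column matrix of negative pairs for the link
#'   task (seeded once per fold; required).
#' @return named list of metrics plus sample counts.
#' @export
evaluate_model <- function(model, graph, features,
                           test_idx = model$meta$test_idx, negatives) {
  rel <- model$config$relation
  emb <- model_embeddings(model, graph, features)
  st <- model$meta$pred_src_type; dt <- model$meta$pred_dst_type
  pos <- graph$edges[[rel]][test_idx, , drop = FALSE]
  pairs <- rbind(pos, negatives)
  lab <- c(rep(1, nrow(pos)), rep(0, nrow(negatives)))
  sc <- score_pairs(emb$link[[st]], pairs, emb$link[[dt]])
  roc <- roc_auc(lab, sc$logits)
  bm <- binary_metrics(lab, sc$predicted)

  known <- graph$reg_type$known
  t_idx <- intersect(test_idx, which(known))
  out_type <- list(auc2 = NA_real_, hl = NA_real_, cp = NA_real_,
                   cr = NA_real_, cf1 = NA_real_)
  n_typed <- length(t_idx)
  if (n_typed > 0) {
    te <- graph$edges[[rel]][t_idx, , drop = FALSE]
    Yt <- cbind(as.integer(graph$reg_type$activation[t_idx]),
                as.integer(graph$reg_type$repression[t_idx]))
    cl <- classify_edges(model$params$W2, emb$type[[st]], te, emb$type[[dt]],
                         head = model$config$head)
    ml <- multilabel_metrics(Yt, cl$predicted)
    yflat <- as.vector(Yt); sflat <- as.vector(cl$logits)
    auc2 <- if (length(unique(yflat)) == 2) roc_auc(yflat, sflat)$auc else NA_real_
    out_type <- list(auc2 = auc2, hl = ml$hl, cp = ml$cp, cr = ml$cr, cf1 = ml$cf1)
  }
  c(list(auc1 = roc$auc, acc = bm$acc, pre = bm$pre, recall = bm$recall,
         f1 = bm$f1),
    out_type,
    list(n_link_pairs = nrow(pairs), n_typed_edges = n_typed))
}

#' k-fold cross-validation of the full pipeline
#'
#' Splits the predicted relation's positive edges into k folds with seeded
#' per-fold negatives, trains a model on each train split (test edges
#' excluded from message passing) and evaluates on the held-out fold;
#' reports per-fold metrics and their mean.
#'
#' @param graph,features,config as in [train_model()].
#' @param k folds. @param seed seed (fold split, negatives, per-fold
#'   training seeds all derive from it).
#' @return list(k, seed, per_fold, mean, plan).
#' @export
cross_validate <- function(graph, features, config = run_config(), k = 5, seed = 1) {
  plan <- split_kfold(graph, k, seed, relation = config$relation)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- plan$folds[[f]]
    model <- train_model(graph, features, config, seed = seed + f,
                         test_idx = test_idx)
    per_fold[[f]] <- evaluate_model(model, graph, features, test_idx,
                                    plan$negatives[[f]])
  }
  agg <- aggregate_folds(per_fold)
  list(k = k, seed = seed, per_fold = agg$per_fold, mean = agg$mean, plan = plan)
}

#' Serialize a metrics report to JSON
#'
#' @param report result of [cross_validate()].
#' @param path output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(list(k = report$k, seed = report$seed,
                            mean = report$mean, per_fold = report$per_fold),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
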