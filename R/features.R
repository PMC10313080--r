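#' Chemical-profile cosine similarity features
#'
#' Each gene (TF or target) is described by a binary chemical-association
#' profile; the feature vector of gene i is row i of the gene-by-gene cosine
#' similarity matrix of those profiles:
#' \deqn{C_{sim}(i,j) = \langle c_i, c_j \rangle / (\|c_i\| \|c_j\|)}
#'
#' Genes with an all-zero profile have no defined direction; by default their
#' similarity row (including the diagonal) is set to 0 and a warning is
#' logged, or an error is raised with `on_zero_row = "error"`.
#'
#' @param assoc binary gene x chemical matrix (entries in \{0, 1\}), rows
#'   ordered as the TF nodes followed by the target-gene nodes.
#' @param on_zero_row `"zero"` (default) or `"error"`.
#' @return symmetric gene x gene similarity matrix; rows are the features.
#' @export
chemical_similarity_features <- function(assoc, on_zero_row = c("zero", "error")) {
  on_zero_row <- match.arg(on_zero_row)
  assoc <- as.matrix(assoc)
  if (!all(assoc %in% c(0, 1))) stop("association matrix entries must be 0/1")
  nrm <- sqrt(rowSums(assoc^2))
  zero <- nrm == 0
  if (any(zero)) {
    if (on_zero_row == "error")
      stop(sum(zero), " gene(s) have an all-zero chemical profile")
    grn_log(sum(zero), " all-zero chemical profile(s); similarity rows set to 0")
  }
  nrm[zero] <- 1  # avoid 0/0; rows zeroed below
  S <- tcrossprod(assoc / nrm)
  S[zero, ] <- 0
  S[, zero] <- 0
  diag(S)[!zero] <- 1
  if (!is.null(rownames(assoc)))
    dimnames(S) <- list(rownames(assoc), rownames(assoc))
  S
}

#' One-hot node features
#'
#' @param n number of nodes (>= 1).
#' @return the n x n identity matrix (row i is the one-hot code of node i).
#' @export
onehot_features <- function(n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) stop("n must be a positive integer")
  diag(as.integer(n))
}

#' Random-normal node features
#'
#' Standard-normal i.i.d. features for node types with no intrinsic
#' attributes; deterministic given the seed.
#'
#' @param n number of nodes. @param d feature dimension. @param seed seed.
#' @return n x d matrix.
#' @export
random_features <- function(n, d, seed = NULL) {
  if (n < 1 || d < 1) stop("n and d must be >= 1")
  with_seed(seed, matrix(rnorm(n * d), n, d))
}

#' Build the per-node-type feature set
#'
#' TF and target-gene nodes get chemical-similarity rows (dimension
#' n_TF + n_tg), GO-term nodes get one-hot codes, and every remaining node
#' type (diseases by default) gets seeded random-normal features. Feature
#' dimensions may differ across node types; the convolution layer absorbs
#' this with per-relation input dimensions. A `user` matrix supplied in
#' `override` replaces the built feature of that type (hook for, e.g.,
#' expression-derived features).
#'
#' @param graph a `hetero_graph`.
#' @param chem_assoc binary association matrix with rownames covering the TF
#'   and tg node ids, or `NULL` to fall back to random features for genes.
#' @param random_dim dimension of random features (default 64).
#' @param seed seed for the random features.
#' @param override named list of user feature matrices by node type.
#' @return named list of matrices (class `feature_set`) with a `provenance`
#'   attribute per type in \{chemical_sim, onehot, random_normal, user\}.
#' @export
build_features <- function(graph, chem_assoc = NULL, random_dim = 64,
                           seed = 0, override = list()) {
  feats <- list(); prov <- character(0)
  gene_types <- intersect(c("TF", "tg"), names(graph$nodes))
  if (!is.null(chem_assoc) && length(gene_types)) {
    ids <- unlist(lapply(gene_types, function(t) graph$nodes[[t]]), use.names = FALSE)
    miss <- setdiff(ids, rownames(chem_assoc))
    if (length(miss)) stop(length(miss), " gene id(s) missing from chem_assoc rownames")
    S <- chemical_similarity_features(chem_assoc[ids, , drop = FALSE])
    off <- 0L
    for (t in gene_types) {
      nt <- length(graph$nodes[[t]])
      feats[[t]] <- S[off + seq_len(nt), , drop = FALSE]
      prov[t] <- "chemical_sim"
      off <- off + nt
    }
  }
  si <- 0L
  for (t in names(graph$nodes)) {
    if (!is.null(feats[[t]])) next
    if (t == "GO") {
      feats[[t]] <- onehot_features(length(graph$nodes[[t]]))
      prov[t] <- "onehot"
    } else {
      si <- si + 1L
      feats[[t]] <- random_features(length(graph$nodes[[t]]), random_dim,
                                    seed = if (is.null(seed)) NULL else seed + si)
      prov[t] <- "random_normal"
    }
  }
  for (t in names(override)) {
    stopifnot(nrow(override[[t]]) == length(graph$nodes[[t]]))
    feats[[t]] <- override[[t]]
    prov[t] <- "user"
  }
  feats <- feats[names(graph$nodes)]
  structure(feats, provenance = prov[names(feats)], class = c("feature_set", "list"))
}
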