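#' Specification of a planted-block synthetic knowledge graph
#'
#' The generator emulates the shape of a curated transcriptional-regulation
#' knowledge graph (4 node types, 4 relation types, sparse chemical
#' profiles) with a planted block structure that makes both link existence
#' and regulation type learnable: TF and target-gene nodes are assigned to
#' blocks; within-block TF-target pairs are linked with probability `p_in`
#' and cross-block pairs with `p_out`; disease and GO edges respect blocks
#' with probability `aux_informativeness` (else uniform endpoints); genes of
#' the same block share block-characteristic chemical associations so cosine
#' profiles carry the block signal; and the regulation type is set by the
#' parity of the TF's block (even blocks activate, odd repress), flipped
#' with probability `type_noise`, with a fraction `dual_frac` of edges
#' dual-annotated (both activation and repression). After generation a
#' fraction `frac_unknown` of regulatory edges has its type masked to
#' "unknown" (the masked truth is kept for evaluation); the default mirrors
#' the 46\% unknown share of the curated human TF-target catalogue.
#'
#' @param n_tf,n_tg,n_d,n_go,n_chem node / chemical counts.
#' @param n_blocks number of planted blocks.
#' @param p_in,p_out within/cross-block TF-target link probabilities.
#' @param aux_informativeness probability an auxiliary (disease/GO) edge
#'   respects the block structure.
#' @param type_noise probability a regulation-type label is flipped.
#' @param frac_unknown fraction of regulatory edges masked to "unknown".
#' @param dual_frac fraction of typed edges annotated both activation and
#'   repression.
#' @param d_degree_tf,d_degree_tg,go_degree auxiliary edge counts per
#'   disease (to TFs / to genes) and per GO term (to TFs).
#' @param chem_p_in,chem_p_bg probability a gene carries one of its block's
#'   characteristic chemicals / a background chemical.
#' @param seed integer seed; generation is fully deterministic given it.
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_tf = 60, n_tg = 200, n_d = 50, n_go = 50,
                           n_chem = 100, n_blocks = 4,
                           p_in = 0.3, p_out = 0.02,
                           aux_informativeness = 0.8,
                           type_noise = 0.1, frac_unknown = 0.46,
                           dual_frac = 0.05,
                           d_degree_tf = 4, d_degree_tg = 8, go_degree = 5,
                           chem_p_in = 0.6, chem_p_bg = 0.05,
                           seed = 1) {
  spec <- as.list(environment())
  probs <- c(p_in = p_in, p_out = p_out, aux_informativeness = aux_informativeness,
             type_noise = type_noise, frac_unknown = frac_unknown,
             dual_frac = dual_frac, chem_p_in = chem_p_in, chem_p_bg = chem_p_bg)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  counts <- c(n_tf, n_tg, n_d, n_go, n_chem, n_blocks)
  if (any(counts < 1)) stop("counts must be >= 1")
  # expected edge counts must be positive for every required relation
  exp_reg <- n_tf * n_tg * (p_in / n_blocks + p_out * (1 - 1 / n_blocks))
  if (exp_reg <= 0) stop("expected TF-target edge count is 0; raise p_in/p_out")
  if (n_d * (d_degree_tf + d_degree_tg) <= 0 || n_go * go_degree <= 0)
    stop("expected auxiliary edge count is 0")
  structure(spec, class = "synthetic_spec")
}

#' Generate a planted-block synthetic knowledge graph
#'
#' @param spec a [synthetic_spec()].
#' @return list with elements `graph` (a `hetero_graph` over all 4 forward
#'   relations, regulation types already masked), `chem_assoc` (binary
#'   (n_tf+n_tg) x n_chem matrix with gene ids as rownames), `blocks`
#'   (ground-truth block assignment per node type), `truth` (pre-mask
#'   activation/repression flags and the masked-edge indicator for every
#'   regulatory edge), and `fragment` (the edge list as an `edge_fragment`,
#'   convenient for [build_graph()] strategy experiments).
#' @export
generate_synthetic_kg <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    b_tf <- rep_len(seq_len(spec$n_blocks), spec$n_tf)
    b_tg <- rep_len(seq_len(spec$n_blocks), spec$n_tg)
    b_d  <- rep_len(seq_len(spec$n_blocks), spec$n_d)
    b_go <- rep_len(seq_len(spec$n_blocks), spec$n_go)

    tf_ids <- sprintf("TF%03d", seq_len(spec$n_tf))
    tg_ids <- sprintf("G%04d", seq_len(spec$n_tg))
    d_ids  <- sprintf("D%03d", seq_len(spec$n_d))
    go_ids <- sprintf("GO%04d", seq_len(spec$n_go))

    # TF-target edges: Bernoulli(p_in) within block, Bernoulli(p_out) across
    P <- ifelse(outer(b_tf, b_tg, "=="), spec$p_in, spec$p_out)
    A <- matrix(rbinom(length(P), 1, P), nrow(P), ncol(P))
    idx <- which(A == 1, arr.ind = TRUE)
    if (!nrow(idx)) stop("no TF-target edges realized; raise p_in/p_out")
    src <- idx[, 1]; dst <- idx[, 2]

    # regulation type from TF-block parity, flipped with prob type_noise
    act <- (b_tf[src] %% 2) == 0
    flip <- runif(length(act)) < spec$type_noise
    act <- xor(act, flip)
    dual <- runif(length(act)) < spec$dual_frac
    activation <- act | dual
    repression <- (!act) | dual
    masked <- runif(length(act)) < spec$frac_unknown
    reg_lab <- ifelse(masked, "unknown",
               ifelse(activation & repression, "both",
               ifelse(activation, "activation", "repression")))
    rows <- data.frame(src_id = tf_ids[src], dst_id = tg_ids[dst],
                       relation = "regulates", reg_type = reg_lab,
                       stringsAsFactors = FALSE)

    draw_aux <- function(src_blocks, dst_blocks, deg, aux) {
      # per source node, `deg` edges; block-respecting with prob `aux`
      out <- vector("list", length(src_blocks))
      for (i in seq_along(src_blocks)) {
        respect <- runif(deg) < aux
        same <- which(dst_blocks == src_blocks[i])
        tgt <- integer(deg)
        tgt[respect] <- same[sample.int(length(same), sum(respect), replace = TRUE)]
        tgt[!respect] <- sample.int(length(dst_blocks), sum(!respect), replace = TRUE)
        out[[i]] <- unique(tgt)
      }
      cbind(rep(seq_along(src_blocks), lengths(out)), unlist(out))
    }
    e_td <- draw_aux(b_d, b_tf, spec$d_degree_tf, spec$aux_informativeness)  # D -> its TFs
    e_dg <- draw_aux(b_d, b_tg, spec$d_degree_tg, spec$aux_informativeness)
    e_go <- draw_aux(b_go, b_tf, spec$go_degree, spec$aux_informativeness)
    rows <- rbind(rows,
      data.frame(src_id = tf_ids[e_td[, 2]], dst_id = d_ids[e_td[, 1]],
                 relation = "tf_disease", reg_type = "unknown"),
      data.frame(src_id = d_ids[e_dg[, 1]], dst_id = tg_ids[e_dg[, 2]],
                 relation = "disease_gene", reg_type = "unknown"),
      data.frame(src_id = go_ids[e_go[, 1]], dst_id = tf_ids[e_go[, 2]],
                 relation = "go_tf", reg_type = "unknown"))

    # chemical profiles: block-characteristic chemicals + background
    chem_block <- rep_len(seq_len(spec$n_blocks), spec$n_chem)
    gene_blocks <- c(b_tf, b_tg)
    n_gene <- length(gene_blocks)
    Pc <- ifelse(outer(gene_blocks, chem_block, "=="), spec$chem_p_in, spec$chem_p_bg)
    chem <- matrix(rbinom(length(Pc), 1, Pc), n_gene, spec$n_chem,
                   dimnames = list(c(tf_ids, tg_ids),
                                   sprintf("C%03d", seq_len(spec$n_chem))))

    frag <- edge_fragment(rows)
    graph <- build_graph(frag, strategy = "go_disease")
    # node registries are sorted ids; our generated ids sort naturally, but map
    # block vectors through the registry order to stay index-correct
    blocks <- list(TF = b_tf[match(graph$nodes$TF, tf_ids)],
                   tg = b_tg[match(graph$nodes$tg, tg_ids)],
                   D  = b_d[match(graph$nodes$D, d_ids)],
                   GO = b_go[match(graph$nodes$GO, go_ids)])
    # align truth to the graph's (deduplicated, re-ordered) regulatory edges
    ekey <- paste(tf_ids[src], tg_ids[dst])
    ge <- graph$edges$regulates
    gkey <- paste(graph$nodes$TF[ge[, 1]], graph$nodes$tg[ge[, 2]])
    m <- match(gkey, ekey)
    truth <- data.frame(activation = activation[m], repression = repression[m],
                        masked = masked[m])
    list(graph = graph, chem_assoc = chem, blocks = blocks, truth = truth,
         fragment = frag, spec = spec)
  })
}
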