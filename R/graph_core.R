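#' Heterogeneous gene-regulation knowledge graph
#'
#' The knowledge graph is a directed multi-relational graph G = (V, E, T, R)
#' with four node types by default -- transcription factors (`TF`), target
#' genes (`tg`), diseases (`D`) and Gene Ontology terms (`GO`) -- and typed
#' directed edge sets, one per relation. TF-target edges additionally carry a
#' regulation-type annotation: activation, repression, both (dual-annotated
#' pairs are legitimate and occur in curated databases), or unknown.
#'
#' @section Representation:
#' * `nodes`: named list, node type -> character vector of ids (index = the
#'   0-free, 1-based internal index of that node within its type).
#' * `edge_types`: named list, relation -> `c(src = type, dst = type)`.
#' * `edges`: named list, relation -> 2-column integer matrix of
#'   (src_index, dst_index) pairs, unique within the relation.
#' * `reg_type`: for the regulatory relation, a data.frame with logical
#'   columns `activation`, `repression`, `known`, one row per edge.
#'
#' @name hetero_graph
NULL

#' Default relation schema
#'
#' Maps relation labels to their (source type, destination type) pair:
#' `regulates` (TF -> tg, carries the regulation-type annotation),
#' `tf_disease` (TF -> D), `disease_gene` (D -> tg), `go_tf` (GO -> TF) and
#' the derived symmetric `coregulates` (TF -> TF).
#'
#' @return named list of `c(src, dst)` character pairs.
#' @export
default_schema <- function() {
  list(
    regulates    = c(src = "TF", dst = "tg"),
    tf_disease   = c(src = "TF", dst = "D"),
    disease_gene = c(src = "D",  dst = "tg"),
    go_tf        = c(src = "GO", dst = "TF"),
    coregulates  = c(src = "TF", dst = "TF")
  )
}

REG_RELATION <- "regulates"
REV_SUFFIX <- "_rev"

#' Construct a heterogeneous graph
#'
#' Low-level constructor; validates all structural invariants (endpoint
#' indices valid for their node type, no duplicate (src, dst) pairs within a
#' relation, exactly one regulation-type record per regulatory edge).
#'
#' @param nodes named list: node type -> character ids.
#' @param edge_types named list: relation -> `c(src, dst)` node types.
#' @param edges named list: relation -> 2-column integer matrix.
#' @param reg_type `NULL` or data.frame(activation, repression, known) with
#'   one row per edge of `reg_relation`.
#' @param reg_relation relation carrying regulation-type annotations.
#' @return an object of class `hetero_graph`.
#' @export
hetero_graph <- function(nodes, edge_types, edges, reg_type = NULL,
                         reg_relation = REG_RELATION) {
  stopifnot(is.list(nodes), is.list(edge_types), is.list(edges))
  g <- structure(
    list(nodes = nodes, edge_types = edge_types, edges = edges,
         reg_type = reg_type, reg_relation = reg_relation),
    class = "hetero_graph")
  validate_hetero_graph(g)
  g
}

validate_hetero_graph <- function(g) {
  for (rel in names(g$edges)) {
    et <- g$edge_types[[rel]]
    if (is.null(et)) stop("relation '", rel, "' has edges but no declared types")
    e <- g$edges[[rel]]
    if (!is.matrix(e) || ncol(e) != 2) stop("edges of '", rel, "' must be a 2-column matrix")
    if (nrow(e)) {
      ns <- length(g$nodes[[et[["src"]]]]); nd <- length(g$nodes[[et[["dst"]]]])
      if (any(e[, 1] < 1L | e[, 1] > ns) || any(e[, 2] < 1L | e[, 2] > nd))
        stop("edge endpoint index out of range for relation '", rel, "'")
      if (anyDuplicated(paste(e[, 1], e[, 2])))
        stop("duplicate (src, dst) pair within relation '", rel, "'")
    }
  }
  if (!is.null(g$reg_type)) {
    ne <- nrow(g$edges[[g$reg_relation]])
    if (is.null(ne)) ne <- 0L
    if (nrow(g$reg_type) != ne)
      stop("reg_type must have exactly one record per '", g$reg_relation, "' edge")
  }
  invisible(g)
}

#' @export
print.hetero_graph <- function(x, ...) {
  cat("hetero_graph:",
      paste(sprintf("%s=%d", names(x$nodes), lengths(x$nodes)), collapse = ", "), "nodes\n")
  for (rel in names(x$edges))
    cat(sprintf("  %-16s %s -> %s : %d edges\n", rel,
                x$edge_types[[rel]][["src"]], x$edge_types[[rel]][["dst"]],
                nrow(x$edges[[rel]])))
  invisible(x)
}

#' Read a typed edge list
#'
#' Parses a tab-separated edge-list file: `src_id<TAB>dst_id<TAB>relation`
#' with an optional fourth column giving the regulation type (`activation`,
#' `repression`, `both`, `unknown`) for regulatory edges. Lines starting with
#' `#` and blank lines are ignored. Duplicate (src, dst, relation) rows are
#' collapsed to a single edge; regulation annotations of collapsed duplicates
#' are merged (activation + repression rows for the same pair become `both`).
#'
#' @param path file path.
#' @param schema named list mapping relation labels to `c(src, dst)` node
#'   types; unknown relation labels raise an error naming the line.
#' @return an `edge_fragment`: a data.frame of deduplicated rows plus the
#'   schema, with `n_rows` / `n_collapsed` counts recorded as attributes.
#' @export
load_edge_list <- function(path, schema = default_schema()) {
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3L))
    stop("malformed row (need >= 3 tab-separated fields) at line ",
         lineno[which(nf < 3L)[1]])
  src <- vapply(parts, `[[`, "", 1L)
  dst <- vapply(parts, `[[`, "", 2L)
  rel <- vapply(parts, `[[`, "", 3L)
  reg <- ifelse(nf >= 4L, vapply(parts, function(p) if (length(p) >= 4) p[[4]] else "", ""), "")
  bad <- !(rel %in% names(schema))
  if (any(bad))
    stop("unknown relation label '", rel[which(bad)[1]], "' at line ",
         lineno[which(bad)[1]], " (not in schema)")
  badreg <- reg != "" & !(reg %in% c("activation", "repression", "both", "unknown"))
  if (any(badreg))
    stop("invalid regulation type '", reg[which(badreg)[1]], "' at line ",
         lineno[which(badreg)[1]])
  df <- data.frame(src_id = src, dst_id = dst, relation = rel,
                   reg_type = ifelse(reg == "", "unknown", reg),
                   stringsAsFactors = FALSE)
  edge_fragment(df, schema, n_raw = length(lines))
}

#' Build an edge fragment from a data.frame
#'
#' @param df data.frame with columns src_id, dst_id, relation and optionally
#'   reg_type.
#' @param schema relation schema (see [default_schema()]).
#' @param n_raw raw row count before deduplication (for logging).
#' @return deduplicated `edge_fragment`.
#' @export
edge_fragment <- function(df, schema = default_schema(), n_raw = nrow(df)) {
  if (is.null(df$reg_type)) df$reg_type <- "unknown"
  key <- paste(df$src_id, df$dst_id, df$relation, sep = "\r")
  if (anyDuplicated(key)) {
    # merge regulation annotations of duplicate rows
    act <- tapply(df$reg_type %in% c("activation", "both"), key, any)
    rep_ <- tapply(df$reg_type %in% c("repression", "both"), key, any)
    first <- !duplicated(key)
    df <- df[first, , drop = FALSE]
    k <- key[first]
    df$reg_type <- ifelse(act[k] & rep_[k], "both",
                   ifelse(act[k], "activation",
                   ifelse(rep_[k], "repression", "unknown")))
  }
  n_collapsed <- n_raw - nrow(df)
  grn_log("edge fragment: ", n_raw, " rows read, ", n_collapsed, " collapsed")
  structure(list(edges = df, schema = schema,
                 n_rows = n_raw, n_collapsed = n_collapsed),
            class = "edge_fragment")
}

#' Write a graph back to an edge-list file
#'
#' Inverse of [load_edge_list()] for forward relations (reverse relations
#' created by [build_graph()] are skipped); `load_edge_list()` on the output
#' reproduces the same edges up to row order.
#'
#' @param graph a `hetero_graph`.
#' @param path output path.
#' @export
write_edge_list <- function(graph, path) {
  rows <- character(0)
  for (rel in names(graph$edges)) {
    if (endsWith(rel, REV_SUFFIX)) next
    et <- graph$edge_types[[rel]]
    e <- graph$edges[[rel]]
    if (!nrow(e)) next
    src <- graph$nodes[[et[["src"]]]][e[, 1]]
    dst <- graph$nodes[[et[["dst"]]]][e[, 2]]
    if (rel == graph$reg_relation && !is.null(graph$reg_type)) {
      rt <- with(graph$reg_type,
                 ifelse(activation & repression, "both",
                 ifelse(activation, "activation",
                 ifelse(repression, "repression", "unknown"))))
      rows <- c(rows, paste(src, dst, rel, rt, sep = "\t"))
    } else {
      rows <- c(rows, paste(src, dst, rel, sep = "\t"))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' Graph-construction strategies
#'
#' The five strategies select which relations enter the graph:
#' `baseline` only TF-target edges; `coregulate` adds derived TF-TF
#' co-regulation edges (TFs sharing at least `coregulate_min_shared` common
#' targets); `go` adds GO-term-TF edges; `disease` adds TF-disease and
#' disease-gene edges; `go_disease` adds both GO and disease relations.
#'
#' @return character vector of strategy names.
#' @export
graph_strategies <- function() c("baseline", "coregulate", "go", "disease", "go_disease")

strategy_relations <- function(strategy) {
  switch(strategy,
    baseline   = REG_RELATION,
    coregulate = c(REG_RELATION, "coregulates"),
    go         = c(REG_RELATION, "go_tf"),
    disease    = c(REG_RELATION, "tf_disease", "disease_gene"),
    go_disease = c(REG_RELATION, "go_tf", "tf_disease", "disease_gene"),
    stop("unknown strategy '", strategy, "'"))
}

#' Assemble a heterogeneous graph from edge fragments
#'
#' Interns node ids per node type (ids are case-sensitive strings; indices
#' are internal and 1-based), selects the relations of the chosen
#' construction strategy, derives TF-TF co-regulation edges where requested,
#' and optionally adds a distinct reverse relation (`<rel>_rev`, with its own
#' convolution weights downstream) per forward relation so that messages flow
#' in both directions. Node registries are built from *all* fragments, so the
#' same ids map to the same indices under every strategy.
#'
#' @param fragments an `edge_fragment` or list of them.
#' @param strategy one of [graph_strategies()].
#' @param reverse_edges add a reverse relation per forward relation
#'   (default `TRUE`). The symmetric `coregulates` relation gets no reverse.
#' @param coregulate_min_shared minimum number of shared target genes for a
#'   derived TF-TF co-regulation edge (default 1).
#' @return a `hetero_graph`.
#' @export
build_graph <- function(fragments, strategy = "go_disease", reverse_edges = TRUE,
                        coregulate_min_shared = 1L) {
  strategy <- match.arg(strategy, graph_strategies())
  if (inherits(fragments, "edge_fragment")) fragments <- list(fragments)
  stopifnot(length(fragments) >= 1)
  schema <- fragments[[1]]$schema
  df <- do.call(rbind, lapply(fragments, `[[`, "edges"))
  frag <- edge_fragment(df, schema)   # dedup across fragments
  df <- frag$edges

  # intern ids per node type from every fragment row (strategy-stable)
  types <- unique(unlist(lapply(schema, unname)))
  nodes <- setNames(vector("list", length(types)), types)
  for (rel in unique(df$relation)) {
    et <- schema[[rel]]
    i <- df$relation == rel
    nodes[[et[["src"]]]] <- c(nodes[[et[["src"]]]], df$src_id[i])
    nodes[[et[["dst"]]]] <- c(nodes[[et[["dst"]]]], df$dst_id[i])
  }
  nodes <- lapply(nodes, function(v) sort(unique(v)))
  nodes <- nodes[lengths(nodes) > 0]

  rels <- strategy_relations(strategy)
  missing_rel <- setdiff(setdiff(rels, "coregulates"), unique(df$relation))
  if (length(missing_rel))
    stop("strategy '", strategy, "' requires relation(s) ",
         paste(missing_rel, collapse = ", "), " absent from the fragments")

  edges <- list(); edge_types <- list(); reg_type <- NULL
  for (rel in setdiff(rels, "coregulates")) {
    et <- schema[[rel]]
    i <- which(df$relation == rel)
    m <- cbind(match(df$src_id[i], nodes[[et[["src"]]]]),
               match(df$dst_id[i], nodes[[et[["dst"]]]]))
    storage.mode(m) <- "integer"
    edges[[rel]] <- m
    edge_types[[rel]] <- et
    if (rel == REG_RELATION) {
      rt <- df$reg_type[i]
      reg_type <- data.frame(activation = rt %in% c("activation", "both"),
                             repression = rt %in% c("repression", "both"),
                             known = rt != "unknown")
    }
  }
  if ("coregulates" %in% rels) {
    edges[["coregulates"]] <- derive_coregulation(edges[[REG_RELATION]],
                                                  length(nodes[["TF"]]),
                                                  coregulate_min_shared)
    edge_types[["coregulates"]] <- schema[["coregulates"]]
  }
  if (reverse_edges) {
    for (rel in names(edges)) {
      if (rel == "coregulates") next   # already symmetric
      rrel <- paste0(rel, REV_SUFFIX)
      edges[[rrel]] <- edges[[rel]][, c(2L, 1L), drop = FALSE]
      et <- edge_types[[rel]]
      edge_types[[rrel]] <- c(src = unname(et[["dst"]]), dst = unname(et[["src"]]))
    }
  }
  g <- hetero_graph(nodes, edge_types, edges, reg_type)
  attr(g, "strategy") <- strategy
  g
}

# TF pairs sharing >= min_shared common targets, both directions
derive_coregulation <- function(reg_edges, n_tf, min_shared = 1L) {
  if (!nrow(reg_edges)) return(matrix(integer(0), 0, 2))
  targets <- split(reg_edges[, 2], reg_edges[, 1])
  tfs <- as.integer(names(targets))
  out <- matrix(integer(0), 0, 2)
  if (length(tfs) >= 2) {
    pairs <- list()
    for (a in seq_along(tfs)) for (b in seq_along(tfs)) {
      if (a >= b) next
      if (length(intersect(targets[[a]], targets[[b]])) >= min_shared)
        pairs[[length(pairs) + 1L]] <- c(tfs[a], tfs[b])
    }
    if (length(pairs)) {
      m <- do.call(rbind, pairs)
      out <- rbind(m, m[, c(2L, 1L), drop = FALSE])
      storage.mode(out) <- "integer"
    }
  }
  out
}

#' k-fold split of positive edges with seeded negative samples
#'
#' Partitions the positive edges of the predicted relation into k disjoint
#' folds of near-equal size (each fold serves as the test set in turn) and
#' attaches to each fold a seeded set of negative node pairs of the same size,
#' drawn uniformly from unlabeled pairs and disjoint from every positive edge.
#'
#' @param graph a `hetero_graph`.
#' @param k number of folds (2 <= k <= number of positive edges).
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param relation predicted relation (default the TF-target relation).
#' @return a `fold_plan`: list(k, relation, folds, negatives, seed).
#' @export
split_kfold <- function(graph, k, seed, relation = REG_RELATION) {
  e <- graph$edges[[relation]]
  n <- nrow(e)
  if (k < 2 || k > n) stop("k must satisfy 2 <= k <= ", n, " (got ", k, ")")
  with_seed(seed, {
    perm <- sample.int(n)
    sizes <- rep(n %/% k, k) + c(rep(1L, n %% k), rep(0L, k - n %% k))
    folds <- split(perm, rep(seq_len(k), times = sizes))
    names(folds) <- NULL
    negatives <- lapply(folds, function(f)
      sample_negatives(graph, relation, length(f), seed = NULL))
    structure(list(k = k, relation = relation, folds = folds,
                   negatives = negatives, seed = seed),
              class = "fold_plan")
  })
}

#' Serialize / deserialize a fold plan as JSON
#'
#' @param plan a `fold_plan`.
#' @param path output path.
#' @export
write_fold_plan <- function(plan, path) {
  obj <- list(k = plan$k, relation = plan$relation, seed = plan$seed,
              folds = plan$folds,
              negatives = lapply(plan$negatives, function(m)
                list(src = m[, 1], dst = m[, 2])))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_fold_plan
#' @export
read_fold_plan <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  structure(list(
    k = obj$k, relation = obj$relation, seed = obj$seed,
    folds = lapply(obj$folds, function(f) vapply(f, as.integer, 0L)),
    negatives = lapply(obj$negatives, function(x)
      cbind(vapply(x$src, as.integer, 0L), vapply(x$dst, as.integer, 0L)))),
    class = "fold_plan")
}

#' Sample negative node pairs for a relation
#'
#' Draws `count` (src, dst) pairs uniformly without replacement from the
#' unlabeled pairs of the relation's source x destination space, i.e.
#' excluding every pair in `exclude` (defaults to all positive edges of the
#' relation). Deterministic given `seed`.
#'
#' @param graph a `hetero_graph`.
#' @param relation relation name.
#' @param count number of pairs to draw.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @param exclude 2-column matrix of pairs that must not be sampled.
#' @return `count` x 2 integer matrix of (src_index, dst_index).
#' @export
sample_negatives <- function(graph, relation, count, seed = NULL,
                             exclude = graph$edges[[relation]]) {
  et <- graph$edge_types[[relation]]
  ns <- length(graph$nodes[[et[["src"]]]])
  nd <- length(graph$nodes[[et[["dst"]]]])
  if (count == 0) return(matrix(integer(0), 0, 2))
  space <- as.double(ns) * nd
  excl_codes <- if (nrow(exclude)) unique((as.double(exclude[, 1]) - 1) * nd + exclude[, 2]) else numeric(0)
  n_unlab <- space - length(excl_codes)
  if (count > n_unlab)
    stop("requested ", count, " negatives but only ", n_unlab,
         " unlabeled pairs exist for relation '", relation, "'")
  draw <- function() {
    if (space <= 5e6) {
      pool <- setdiff(seq_len(space), excl_codes)
      pool[sample.int(length(pool), count)]
    } else {
      got <- numeric(0)
      while (length(got) < count) {
        cand <- ceiling(runif(2L * (count - length(got))) * space)
        cand <- setdiff(unique(cand), c(excl_codes, got))
        got <- c(got, cand)
      }
      got[seq_len(count)]
    }
  }
  codes <- with_seed(seed, draw())
  cbind(as.integer((codes - 1) %/% nd) + 1L, as.integer((codes - 1) %% nd) + 1L)
}
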