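# small fixture builders used across test files

with_seed_test <- function(seed, code) {
  set.seed(seed)
  force(code)
}

# a 2 TF x 2 tg toy with two positive regulatory edges
tiny_bipartite <- function() {
  hetero_graph(
    nodes = list(TF = c("A", "B"), tg = c("x", "y")),
    edge_types = list(regulates = c(src = "TF", dst = "tg")),
    edges = list(regulates = cbind(c(1L, 2L), c(1L, 2L))),
    reg_type = data.frame(activation = c(TRUE, FALSE),
                          repression = c(FALSE, TRUE),
                          known = c(TRUE, TRUE)))
}

# edge-list text fixture written to a temp file
write_tmp_edges <- function(lines) {
  f <- tempfile(fileext = ".tsv")
  writeLines(lines, f)
  f
}

# a small but non-trivial synthetic KG shared by heavier tests
small_sim <- function(seed = 5) {
  generate_synthetic_kg(synthetic_spec(
    n_tf = 10, n_tg = 30, n_d = 8, n_go = 8, n_chem = 20,
    p_in = 0.5, p_out = 0.05, frac_unknown = 0.3, seed = seed))
}

# brute-force cosine similarity oracle (double loop)
cosine_oracle <- function(A) {
  n <- nrow(A)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ni <- sqrt(sum(A[i, ]^2)); nj <- sqrt(sum(A[j, ]^2))
    S[i, j] <- if (ni == 0 || nj == 0) 0 else sum(A[i, ] * A[j, ]) / (ni * nj)
  }
  S
}

# brute-force per-edge message-passing oracle for one MGCN layer
layer_oracle <- function(layer, graph, feats, slope = 0.2) {
  out <- lapply(graph$nodes, function(ids) matrix(0, length(ids), layer$out_dim))
  got_bias <- lapply(graph$nodes, function(ids)
    matrix(FALSE, length(ids), length(graph$edges)))
  for (ri in seq_along(graph$edges)) {
    rel <- names(graph$edges)[ri]
    et <- graph$edge_types[[rel]]
    e <- graph$edges[[rel]]
    for (k in seq_len(nrow(e))) {
      j <- e[k, 1]; i <- e[k, 2]
      out[[et[["dst"]]]][i, ] <- out[[et[["dst"]]]][i, ] +
        as.vector(feats[[et[["src"]]]][j, ] %*% layer$W[[rel]])
      got_bias[[et[["dst"]]]][i, ri] <- TRUE
    }
  }
  for (ri in seq_along(graph$edges)) {
    rel <- names(graph$edges)[ri]
    d <- graph$edge_types[[rel]][["dst"]]
    rows <- which(got_bias[[d]][, ri])
    for (i in rows) out[[d]][i, ] <- out[[d]][i, ] + layer$b[[rel]]
  }
  lapply(out, function(m) pmax(m, 0) + slope * pmin(m, 0))
}
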