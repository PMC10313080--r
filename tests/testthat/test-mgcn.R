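# two-relation toy graph used by the forward-pass oracles:
# TF -> tg ("regulates") and D -> tg ("disease_gene")
toy_graph <- function() {
  hetero_graph(
    nodes = list(TF = c("A", "B"), tg = c("x", "y", "z"), D = "d1"),
    edge_types = list(regulates = c(src = "TF", dst = "tg"),
                      disease_gene = c(src = "D", dst = "tg")),
    edges = list(regulates = cbind(c(1L, 2L, 1L), c(1L, 1L, 2L)),
                 disease_gene = cbind(1L, 2L)))
}

toy_feats <- function(d = 3, seed = 1) {
  with_seed_test(seed, list(TF = matrix(rnorm(2 * d), 2, d),
                            tg = matrix(rnorm(3 * d), 3, d),
                            D = matrix(rnorm(1 * d), 1, d)))
}

test_that("identity-weight sum aggregation reproduces neighbor sums", {
  g <- toy_graph()
  adj <- graph_adjacency(g)
  layer <- mgcn_layer(g$edge_types, c(TF = 3L, tg = 3L, D = 3L), 3, seed = 1)
  layer$W$regulates <- diag(3); layer$W$disease_gene <- diag(3)
  layer$b$regulates <- rep(0, 3); layer$b$disease_gene <- rep(0, 3)
  X <- toy_feats()
  fw <- mgcn_layer_forward(layer, adj, X, activation = FALSE)
  # tg node 1 receives TF1 + TF2 through "regulates" only
  expect_equal(fw$H$tg[1, ], X$TF[1, ] + X$TF[2, ])
  # tg node 2 receives TF1 + D1 across the two relations
  expect_equal(fw$H$tg[2, ], X$TF[1, ] + X$D[1, ])
  # node with no in-edges gets the zero vector
  expect_equal(fw$H$tg[3, ], rep(0, 3))
  expect_equal(fw$H$TF, matrix(0, 2, 3))
})

test_that("layer forward matches the per-edge accumulation oracle", {
  for (s in 1:4) {
    g <- toy_graph()
    layer <- mgcn_layer(g$edge_types, c(TF = 3L, tg = 3L, D = 3L), 4, seed = s)
    layer$b <- lapply(layer$b, function(b) b + 0.3)  # exercise bias-per-relation
    X <- toy_feats(seed = s + 10)
    got <- mgcn_layer_forward(layer, graph_adjacency(g), X)$H
    want <- layer_oracle(layer, g, X)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("a 6-node toy with two relations into one destination matches the oracle", {
  # both relations write into tg; bias added once per contributing relation
  g <- hetero_graph(
    nodes = list(TF = c("A", "B", "C"), tg = c("x", "y"), D = "d1"),
    edge_types = list(regulates = c(src = "TF", dst = "tg"),
                      disease_gene = c(src = "D", dst = "tg")),
    edges = list(regulates = cbind(c(1L, 2L, 3L), c(1L, 1L, 2L)),
                 disease_gene = cbind(c(1L, 1L), c(1L, 2L))))
  layer <- mgcn_layer(g$edge_types, c(TF = 2L, tg = 2L, D = 2L), 2, seed = 2)
  layer$b$regulates <- c(1, -1); layer$b$disease_gene <- c(0.5, 0.5)
  X <- with_seed_test(3, list(TF = matrix(rnorm(6), 3, 2),
                              tg = matrix(rnorm(4), 2, 2), D = matrix(rnorm(2), 1, 2)))
  got <- mgcn_layer_forward(layer, graph_adjacency(g), X)$H
  expect_equal(got, layer_oracle(layer, g, X), tolerance = 1e-6)
})

test_that("stacks compose layers; eval mode is deterministic; dims checked", {
  g <- toy_graph()
  adj <- graph_adjacency(g)
  dims <- c(TF = 3L, tg = 3L, D = 3L)
  l1 <- mgcn_layer(g$edge_types, dims, 4, seed = 1)
  l2 <- mgcn_layer(g$edge_types, c(TF = 4L, tg = 4L, D = 4L), 2, seed = 2)
  X <- toy_feats()
  one <- mgcn_stack_forward(list(l1), adj, X)
  expect_equal(one$H, mgcn_layer_forward(l1, adj, X)$H)
  two <- mgcn_stack_forward(list(l1, l2), adj, X)
  manual <- mgcn_layer_forward(l2, adj, mgcn_layer_forward(l1, adj, X)$H)$H
  expect_equal(two$H, manual, tolerance = 1e-12)
  expect_identical(mgcn_stack_forward(list(l1, l2), adj, X)$H, two$H)
  expect_error(mgcn_stack_forward(list(), adj, X), "empty layer list")
  Xbad <- X; Xbad$TF <- X$TF[, 1:2]
  expect_error(mgcn_layer_forward(l1, adj, Xbad), "dimension.*TF")
})

test_that("permuting node order permutes outputs identically (equivariance)", {
  g <- toy_graph()
  layer <- mgcn_layer(g$edge_types, c(TF = 3L, tg = 3L, D = 3L), 3, seed = 4)
  X <- toy_feats(seed = 6)
  base <- mgcn_layer_forward(layer, graph_adjacency(g), X)$H
  perm <- c(2L, 3L, 1L)             # permute the tg nodes
  g2 <- g
  g2$nodes$tg <- g$nodes$tg[perm]
  inv <- order(perm)
  g2$edges$regulates[, 2] <- inv[g$edges$regulates[, 2]]
  g2$edges$disease_gene[, 2] <- inv[g$edges$disease_gene[, 2]]
  X2 <- X; X2$tg <- X$tg[perm, ]
  out2 <- mgcn_layer_forward(layer, graph_adjacency(g2), X2)$H
  expect_equal(out2$tg, base$tg[perm, ], tolerance = 1e-12)
})

test_that("single-relation linear layer equals the adjacency-matrix product", {
  g <- hetero_graph(nodes = list(TF = letters[1:3], tg = letters[4:7]),
                    edge_types = list(regulates = c(src = "TF", dst = "tg")),
                    edges = list(regulates = cbind(c(1L, 2L, 3L, 1L), c(1L, 2L, 3L, 4L))))
  adj <- graph_adjacency(g)
  layer <- mgcn_layer(g$edge_types, c(TF = 5L, tg = 5L), 5, seed = 1)
  layer$W$regulates <- diag(5); layer$b$regulates <- rep(0, 5)
  X <- with_seed_test(2, list(TF = matrix(rnorm(15), 3, 5), tg = matrix(0, 4, 5)))
  A <- matrix(0, 4, 3); A[cbind(g$edges$regulates[, 2], g$edges$regulates[, 1])] <- 1
  got <- mgcn_layer_forward(layer, adj, X, activation = FALSE)$H$tg
  expect_equal(got, A %*% X$TF, tolerance = 1e-12)
})

test_that("doubling one relation's weights doubles only that relation's messages", {
  g <- toy_graph()
  adj <- graph_adjacency(g)
  layer <- mgcn_layer(g$edge_types, c(TF = 3L, tg = 3L, D = 3L), 3, seed = 9)
  layer$b <- lapply(layer$b, function(b) b * 0)
  X <- toy_feats(seed = 11)
  z0 <- mgcn_layer_forward(layer, adj, X, activation = FALSE)$Z
  l2 <- layer; l2$W$regulates <- 2 * layer$W$regulates
  z1 <- mgcn_layer_forward(l2, adj, X, activation = FALSE)$Z
  # tg node 3 has no in-edges, tg 1 gets only "regulates" messages: doubled
  expect_equal(z1$tg[1, ], 2 * z0$tg[1, ])
  # tg 2 = regulates-part doubled + disease part unchanged
  zd <- mgcn_layer_forward(layer, adj["disease_gene"], X, activation = FALSE)$Z$tg[2, ]
  expect_equal(z1$tg[2, ], 2 * (z0$tg[2, ] - zd) + zd, tolerance = 1e-12)
})

test_that("stack backward gradients match central finite differences", {
  g <- toy_graph()
  adj <- graph_adjacency(g)
  dims <- c(TF = 3L, tg = 3L, D = 3L)
  layers <- list(mgcn_layer(g$edge_types, dims, 4, seed = 1),
                 mgcn_layer(g$edge_types, c(TF = 4L, tg = 4L, D = 4L), 3, seed = 2))
  X <- toy_feats(seed = 3)
  # scalar loss: sum of squares of all final embeddings
  loss <- function(ls) {
    H <- mgcn_stack_forward(ls, adj, X)$H
    sum(vapply(H, function(m) sum(m^2), 0))
  }
  fw <- mgcn_stack_forward(layers, adj, X)
  dH <- lapply(fw$H, function(m) 2 * m)
  bk <- mgcn_stack_backward(layers, adj, fw$cache, dH)
  eps <- 1e-6
  for (l in 1:2) for (rel in names(g$edges)) {
    W <- layers[[l]]$W[[rel]]
    for (idx in c(1L, length(W))) {
      lp <- layers; lp[[l]]$W[[rel]][idx] <- W[idx] + eps
      lm <- layers; lm[[l]]$W[[rel]][idx] <- W[idx] - eps
      fd <- (loss(lp) - loss(lm)) / (2 * eps)
      expect_equal(bk$grads[[l]]$W[[rel]][idx], fd, tolerance = 1e-4)
    }
    bp <- layers; bp[[l]]$b[[rel]][1] <- layers[[l]]$b[[rel]][1] + eps
    bm <- layers; bm[[l]]$b[[rel]][1] <- layers[[l]]$b[[rel]][1] - eps
    expect_equal(bk$grads[[l]]$b[[rel]][1], (loss(bp) - loss(bm)) / (2 * eps),
                 tolerance = 1e-4)
  }
  # input gradient too (chains the type module into the link module)
  for (idx in c(1L, 4L)) {
    Xp <- X; Xp$TF[idx] <- X$TF[idx] + eps
    Xm <- X; Xm$TF[idx] <- X$TF[idx] - eps
    lossX <- function(Xi) {
      H <- mgcn_stack_forward(layers, adj, Xi)$H
      sum(vapply(H, function(m) sum(m^2), 0))
    }
    expect_equal(bk$dX$TF[idx], (lossX(Xp) - lossX(Xm)) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("mean normalization averages incoming messages", {
  g <- toy_graph()
  adj <- graph_adjacency(g, normalize = "mean")
  layer <- mgcn_layer(g$edge_types, c(TF = 3L, tg = 3L, D = 3L), 3, seed = 1)
  layer$W$regulates <- diag(3); layer$W$disease_gene <- diag(3)
  layer$b <- lapply(layer$b, function(b) b * 0)
  X <- toy_feats()
  fw <- mgcn_layer_forward(layer, adj, X, activation = FALSE)
  expect_equal(fw$H$tg[1, ], (X$TF[1, ] + X$TF[2, ]) / 2)
})
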