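# a small planted graph and features shared across trainer tests
trainer_fixture <- function(seed = 5) {
  sim <- small_sim(seed)
  feats <- build_features(sim$graph, sim$chem_assoc, seed = 1)
  list(sim = sim, feats = feats)
}

fast_cfg <- function(...) {
  args <- utils::modifyList(list(epochs = 15, link_dim = 16, type_dim = 8),
                            list(...))
  do.call(run_config, args)
}

test_that("training reduces the total loss on a planted-structure graph", {
  fx <- trainer_fixture()
  m <- train_model(fx$sim$graph, fx$feats, run_config(epochs = 20, link_dim = 16,
                                                      type_dim = 8), seed = 3)
  expect_lt(tail(m$log$total, 1), m$log$total[1])
  expect_true(all(is.finite(m$log$L1)))
  expect_equal(nrow(m$log), 20)
})

test_that("disabling GradNorm keeps task weights fixed at 1", {
  fx <- trainer_fixture()
  m <- train_model(fx$sim$graph, fx$feats,
                   fast_cfg(gradnorm = list(enabled = FALSE)), seed = 3)
  expect_true(all(m$log$w1 == 1) && all(m$log$w2 == 1))
  # and with GradNorm on, weights move but always sum to 2
  m2 <- train_model(fx$sim$graph, fx$feats, fast_cfg(), seed = 3)
  expect_false(all(m2$log$w1 == 1))
  expect_equal(m2$log$w1 + m2$log$w2, rep(2, nrow(m2$log)), tolerance = 1e-9)
})

test_that("identical config and seed reproduce bitwise-identical runs", {
  fx <- trainer_fixture()
  m1 <- train_model(fx$sim$graph, fx$feats, fast_cfg(), seed = 11, test_idx = 1:10)
  m2 <- train_model(fx$sim$graph, fx$feats, fast_cfg(), seed = 11, test_idx = 1:10)
  expect_identical(m1$log, m2$log)
  expect_identical(m1$params, m2$params)
  ev1 <- evaluate_model(m1, fx$sim$graph, fx$feats, 1:10,
                        sample_negatives(fx$sim$graph, "regulates", 10, seed = 4))
  ev2 <- evaluate_model(m2, fx$sim$graph, fx$feats, 1:10,
                        sample_negatives(fx$sim$graph, "regulates", 10, seed = 4))
  expect_identical(ev1, ev2)
  m3 <- train_model(fx$sim$graph, fx$feats, fast_cfg(), seed = 12, test_idx = 1:10)
  expect_false(identical(m1$params, m3$params))
})

test_that("held-out edges are absent from the message-passing operators", {
  fx <- trainer_fixture()
  g <- fx$sim$graph
  n <- nrow(g$edges$regulates)
  plan <- split_kfold(g, 3, seed = 2)
  for (f in 1:3) {
    test_idx <- plan$folds[[f]]
    m <- train_model(g, fx$feats, fast_cfg(epochs = 2), seed = 1, test_idx = test_idx)
    te <- g$edges$regulates[test_idx, , drop = FALSE]
    A <- m$meta$adj_link$regulates
    expect_true(all(A[cbind(te[, 2], te[, 1])] == 0))
    Ar <- m$meta$adj_link$regulates_rev
    expect_true(all(Ar[cbind(te[, 1], te[, 2])] == 0))
    # typed-subgraph operator also excludes held-out edges
    At <- m$meta$adj_type$reg_typed
    expect_true(all(At[cbind(te[, 2], te[, 1])] == 0))
    # and training positives are exactly the complement
    expect_setequal(m$meta$train_idx, setdiff(seq_len(n), test_idx))
  }
})

test_that("model gradients match finite differences through both tasks", {
  fx <- trainer_fixture(seed = 8)
  g <- fx$sim$graph
  cfg <- run_config(epochs = 1, link_dim = 6, type_dim = 4, dropout = 0)
  n <- nrow(g$edges$regulates)
  set.seed(2)
  meta <- grnlink:::build_model_meta(g, fx$feats, cfg, seq_len(n - 6))
  params <- list(link = lapply(meta$link_templates, grnlink:::layer_params),
                 type = lapply(meta$type_templates, grnlink:::layer_params),
                 W2 = matrix(rnorm(16, 0, 0.3), 8, 2))
  pos <- g$edges$regulates[seq_len(n - 6), , drop = FALSE]
  neg <- sample_negatives(g, "regulates", nrow(pos), seed = 3)
  pairs <- rbind(pos, neg)
  plab <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
  Y <- meta$type_labels
  fb <- grnlink:::model_forward_backward(params, meta, fx$feats, pairs, plab,
                                         meta$type_edges, Y, training = FALSE)
  loss_at <- function(p) {
    r <- grnlink:::model_forward_backward(p, meta, fx$feats, pairs, plab,
                                          meta$type_edges, Y, training = FALSE)
    r$L1 + r$L2
  }
  eps <- 1e-5
  set.seed(4)
  # probe a few coordinates in every parameter group
  probes <- list(
    list(get = function(p) p$link[[1]]$W$regulates,
         set = function(p, v) { p$link[[1]]$W$regulates[] <- v; p },
         an = fb$g1_link[[1]]$W$regulates + fb$g2_link[[1]]$W$regulates),
    list(get = function(p) p$link[[2]]$W$go_tf_rev,
         set = function(p, v) { p$link[[2]]$W$go_tf_rev[] <- v; p },
         an = fb$g1_link[[2]]$W$go_tf_rev + fb$g2_link[[2]]$W$go_tf_rev),
    list(get = function(p) p$type[[1]]$W$reg_typed,
         set = function(p, v) { p$type[[1]]$W$reg_typed[] <- v; p },
         an = fb$g2_type[[1]]$W$reg_typed),
    list(get = function(p) p$W2,
         set = function(p, v) { p$W2[] <- v; p },
         an = fb$gW2))
  for (pr in probes) {
    v <- pr$get(params)
    for (i in sample(length(v), 3)) {
      vp <- v; vp[i] <- vp[i] + eps
      vm <- v; vm[i] <- vm[i] - eps
      fd <- (loss_at(pr$set(params, vp)) - loss_at(pr$set(params, vm))) / (2 * eps)
      expect_equal(pr$an[i], fd, tolerance = 1e-4)
    }
  }
})

test_that("a random-embedding model scores near chance on many pairs", {
  # untrained (0-epoch equivalent): evaluate with freshly initialized params
  sim <- generate_synthetic_kg(synthetic_spec(n_tf = 25, n_tg = 80, n_d = 10,
                                              n_go = 10, seed = 13))
  feats <- build_features(sim$graph, sim$chem_assoc, seed = 1)
  g <- sim$graph
  n <- nrow(g$edges$regulates)
  aucs <- vapply(1:6, function(s) {
    emb <- with_seed_test(s, lapply(g$nodes, function(ids)
      matrix(rnorm(length(ids) * 8), length(ids), 8)))
    k <- min(500, n)
    pos <- g$edges$regulates[seq_len(k), , drop = FALSE]
    neg <- sample_negatives(g, "regulates", 500, seed = s)
    pp <- rbind(pos, neg)
    lab <- c(rep(1, nrow(pos)), rep(0, nrow(neg)))
    roc_auc(lab, score_pairs(emb$TF, pp, emb$tg)$logits)$auc
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("k-fold cross-validation reports per-fold and mean metrics", {
  fx <- trainer_fixture()
  cv <- cross_validate(fx$sim$graph, fx$feats, fast_cfg(epochs = 10), k = 2, seed = 4)
  expect_length(cv$per_fold, 2)
  expect_true(all(c("auc1", "auc2", "acc", "hl") %in% names(cv$mean)))
  a <- vapply(cv$per_fold, `[[`, 0, "auc1")
  expect_true(cv$mean$auc1 >= min(a) && cv$mean$auc1 <= max(a))
  expect_true(cv$mean$auc1 > 0 && cv$mean$auc1 < 1)
  f <- tempfile(fileext = ".json")
  write_metrics_report(cv, f)
  expect_true(jsonlite::validate(readLines(f, warn = FALSE)))
})

test_that("training metrics dominate held-out metrics on average", {
  fx <- trainer_fixture(seed = 21)
  g <- fx$sim$graph
  n <- nrow(g$edges$regulates)
  gaps <- vapply(1:3, function(s) {
    plan <- split_kfold(g, 3, seed = s)
    ti <- plan$folds[[1]]
    m <- train_model(g, fx$feats, fast_cfg(epochs = 25), seed = s, test_idx = ti)
    held <- evaluate_model(m, g, fx$feats, ti, plan$negatives[[1]])
    tr_idx <- setdiff(seq_len(n), ti)
    tr_neg <- sample_negatives(g, "regulates", length(tr_idx), seed = s + 50)
    tr <- evaluate_model(m, g, fx$feats, tr_idx, tr_neg)
    tr$auc1 - held$auc1
  }, 0)
  expect_gt(mean(gaps), -0.02)
})

test_that("type predictions cover unknown edges with scores and calls", {
  fx <- trainer_fixture()
  m <- train_model(fx$sim$graph, fx$feats, fast_cfg(), seed = 2)
  pt <- predict_types(m, fx$sim$graph, fx$feats)
  expect_equal(nrow(pt), sum(!fx$sim$graph$reg_type$known))
  expect_true(all(pt$score_activation > 0 & pt$score_activation < 1))
  expect_true(all(pt$pred_activation %in% 0:1))
})
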