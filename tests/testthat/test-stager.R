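test_that("the network is built to the configured shape", {
  cfg <- stager_config(seed = 1)
  m <- build_stager(cfg)
  expect_equal(cfg$n_bilstm_layers, 3L)
  expect_equal(cfg$hidden_units, 128L)
  expect_equal(dim(m$params[["l1.fwd.W"]]), c(4, 512))
  expect_equal(dim(m$params[["l1.fwd.U"]]), c(128, 512))
  expect_equal(dim(m$params[["l2.fwd.W"]]), c(256, 512))  # biLSTM concat in
  expect_equal(dim(m$params[["l3.bwd.U"]]), c(128, 512))
  expect_equal(dim(m$params[["fc.W"]]), c(256, 6))
  expect_error(stager_config(n_classes = 5), "n_classes = 6")
})

test_that("forward pass produces a probability simplex, deterministically", {
  cfg <- fast_stager_config(seed = 5)
  m <- build_stager(cfg)
  x <- matrix(rnorm(18 * 4), 18, 4)
  pr <- predict_stages(m, x)
  expect_equal(nrow(pr$probs), 18)
  expect_true(all(abs(rowSums(pr$probs) - 1) < 1e-6))
  expect_true(all(pr$probs >= 0))
  expect_length(pr$hypnogram, 18)

  m2 <- build_stager(fast_stager_config(seed = 5))
  expect_identical(predict_stages(m2, x)$probs, pr$probs)

  expect_error(predict_stages(m, matrix(0, 5, 3)), "4 feature")
})

test_that("cross-entropy matches its closed forms and a brute-force sum", {
  lab <- hypnogram(c("N1", "N2", "N3", "REM", "WK"))
  onehot <- matrix(0, 5, 6)
  onehot[cbind(1:5, 1:5)] <- 1
  expect_equal(cross_entropy_loss(onehot, lab), 0, tolerance = 1e-10)

  unif <- matrix(1 / 6, 5, 6)
  expect_equal(cross_entropy_loss(unif, lab), log(6), tolerance = 1e-12)

  set.seed(9)
  p <- matrix(runif(5 * 6), 5, 6)
  p <- p / rowSums(p)
  want <- oracle_cel(p, match(as.character(lab), cardiosleep::CLASS_ORDER))
  expect_equal(cross_entropy_loss(p, lab), want, tolerance = 1e-10)
})

test_that("training learns separable data and is reproducible", {
  toy <- toy_feature_cohort(4, 40, seed = 2)
  cfg <- stager_config(n_bilstm_layers = 1, hidden_units = 16,
                       l2_regularization = 1e-4, max_epochs = 30,
                       early_stop_patience = 30, seed = 3)
  m <- train_stager(toy$features[1:3], toy$labels[1:3], cfg,
                    toy$features[4], toy$labels[4])
  h <- m$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])

  m2 <- train_stager(toy$features[1:3], toy$labels[1:3], cfg,
                     toy$features[4], toy$labels[4])
  expect_identical(m$history, m2$history)
  expect_identical(m$params, m2$params)
})

test_that("learning-rate schedule, gradient clipping and early stopping follow the protocol", {
  toy <- toy_feature_cohort(3, 25, seed = 4)
  cfg <- stager_config(n_bilstm_layers = 1, hidden_units = 8,
                       l2_regularization = 1e-4, max_epochs = 120,
                       early_stop_patience = 500, seed = 6)
  m <- train_stager(toy$features[1:2], toy$labels[1:2], cfg,
                    toy$features[3], toy$labels[3])
  h <- m$history
  expect_equal(nrow(h), 120)
  # lr = 1e-2 * 0.01^floor((epoch-1)/50)
  expect_equal(h$lr, 1e-2 * 0.01^((h$epoch - 1) %/% 50), tolerance = 1e-15)
  expect_equal(h$lr[c(1, 50, 51, 101)],
               c(1e-2, 1e-2, 1e-4, 1e-6), tolerance = 1e-15)
  # post-clip global gradient norm never exceeds the threshold
  expect_true(all(h$grad_norm <= 2 + 1e-6))

  # early stopping halts within patience+1 epochs of the best validation loss
  cfg2 <- stager_config(n_bilstm_layers = 1, hidden_units = 8,
                        l2_regularization = 1e-4, max_epochs = 1000,
                        early_stop_patience = 10, seed = 6)
  m2 <- train_stager(toy$features[1:2], toy$labels[1:2], cfg2,
                     toy$features[3], toy$labels[3])
  h2 <- m2$history
  expect_lte(nrow(h2), which.min(h2$val_loss) + 10)
})

test_that("leave-one-out harness covers every subject independently of order", {
  toy <- toy_feature_cohort(3, 20, seed = 7)
  cfg <- stager_config(n_bilstm_layers = 1, hidden_units = 8,
                       l2_regularization = 1e-4, max_epochs = 15,
                       early_stop_patience = 15, seed = 8)
  res <- loocv(toy$features, toy$labels, cfg)
  expect_length(res, 3)
  for (id in names(toy$features)) {
    expect_equal(length(res[[id]]$pred), nrow(toy$features[[id]]))
    expect_identical(as.character(res[[id]]$true),
                     as.character(toy$labels[[id]]))
  }
  # permuting the subject list leaves per-subject results unchanged
  perm <- c(2, 3, 1)
  res2 <- loocv(toy$features[perm], toy$labels[perm], cfg)
  for (id in names(toy$features))
    expect_identical(as.character(res2[[id]]$pred),
                     as.character(res[[id]]$pred))

  expect_error(loocv(toy$features[1:2], toy$labels[1:2], cfg), "3 subjects")
})

test_that("checkpoints round-trip weights and predictions", {
  cfg <- fast_stager_config(seed = 10)
  m <- build_stager(cfg)
  x <- matrix(rnorm(12 * 4), 12, 4)
  f <- tempfile(fileext = ".json")
  save_stager(m, f)
  m2 <- load_stager(f)
  expect_equal(predict_stages(m2, x)$probs, predict_stages(m, x)$probs,
               tolerance = 1e-12)
  unlink(f)
})
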