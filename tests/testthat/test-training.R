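# Loss contract, optimizer behaviour, gradient correctness, early stopping,
# reproducibility, ensembling and grid search.

test_that("weighted cross-entropy reduces to BCE at w = 1 and scales with w", {
  p <- c(0.9, 0.2, 0.6); y <- c(1, 0, 1)
  bce <- -mean(y * log(p) + (1 - y) * log(1 - p))
  expect_equal(weighted_ce(p, y, w = 1), bce, tolerance = 1e-12)
  expect_equal(weighted_ce(0.5, 1, w = 2), 2 * log(2), tolerance = 1e-12)
  # perfect predictions drive the loss to (clamped) zero
  expect_lt(weighted_ce(c(1, 0), c(1, 0), w = 3), 1e-5)
  # masked residues are excluded
  expect_equal(weighted_ce(c(0.9, 0.0001), c(1, 1), w = 1,
                           mask = c(1L, 0L)),
               -log(0.9), tolerance = 1e-12)
  expect_error(weighted_ce(p, y, w = 0), "positive")
})

test_that("the optimizer descends and Lookahead interpolates slow weights", {
  cfg <- run_config(learning_rate = 0.1, weight_decay = 0)
  theta0 <- list(theta = matrix(1))
  grad_of <- function(p) list(theta = 2 * p$theta)   # f = theta^2
  opt <- make_optimizer(theta0, cfg)
  p <- theta0
  for (i in 1:10) p <- opt$step(p, grad_of(p))
  expect_lt(abs(p$theta), 1)
  # alpha = 1 equals the pure inner optimizer at sync points
  inner <- make_optimizer(theta0, cfg, lookahead_k = 10000L)
  la1 <- make_optimizer(theta0, cfg, lookahead_k = 5L, lookahead_alpha = 1)
  pi_ <- theta0; pl <- theta0
  for (i in 1:5) { pi_ <- inner$step(pi_, grad_of(pi_))
                   pl <- la1$step(pl, grad_of(pl)) }
  expect_equal(pl$theta, pi_$theta, tolerance = 1e-12)
  # alpha = 0.5: after the first sync, slow = (theta0 + fast) / 2
  fast <- make_optimizer(theta0, cfg, lookahead_k = 10000L)
  half <- make_optimizer(theta0, cfg, lookahead_k = 5L, lookahead_alpha = 0.5)
  pf <- theta0; ph <- theta0
  for (i in 1:5) { pf <- fast$step(pf, grad_of(pf))
                   ph <- half$step(ph, grad_of(ph)) }
  expect_equal(ph$theta, 0.5 * (theta0$theta + pf$theta), tolerance = 1e-12)
})

test_that("analytic gradients match finite differences through the model", {
  cfg <- tiny_config()
  d_p <- 8L
  params <- init_model_params(d_p, cfg)
  X <- synthetic_embed(tiny_protein(10, seed = 13), d_p = d_p, seed = 2)
  pos <- 0:9
  y <- c(1, 0, 0, 1, 0, 0, 0, 1, 0, 0)
  w <- 3
  run <- seq2site:::cpp_model_run(X, params, cfg, as.integer(pos), y, w,
                                  TRUE, 0, 1L)
  lossfun <- function(p2) {
    seq2site:::cpp_model_run(X, p2, cfg, as.integer(pos), y, w,
                             FALSE, 0, 1L)$loss
  }
  set.seed(33)
  # classifier parameters exactly (the 1-residue-toy contract) plus a
  # sample across every other parameter group
  check_names <- unique(c("cls_W1", "cls_W2", "cls_W3", "cls_b3",
                          sample(names(params), 12)))
  h <- 1e-5
  for (nm in check_names) {
    for (idx in sample(length(params[[nm]]), min(2, length(params[[nm]])))) {
      hi <- params; hi[[nm]][idx] <- hi[[nm]][idx] + h
      lo <- params; lo[[nm]][idx] <- lo[[nm]][idx] - h
      fd <- (lossfun(hi) - lossfun(lo)) / (2 * h)
      an <- run$grads[[nm]][idx]
      if (max(abs(fd), abs(an)) < 1e-7) {
        expect_lt(abs(fd - an), 1e-6)     # both effectively zero
      } else {
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-4)
      }
    }
  }
})

make_tiny_training_data <- function(n = 6L, len = 20L, d_p = 8L, seed = 40L) {
  bench <- make_benchmark(n_train = n, n_valid = 3L, n_test = 2L, d_p = d_p,
                          length_range = c(len, len + 5L), pi_target = 0.2,
                          rho = 0, seed = seed)
  bench
}

test_that("training stops after patience epochs without improvement", {
  bench <- make_tiny_training_data()
  cfg <- tiny_config(batch_size = 8L, max_epochs = 50L)
  frozen <- function(probabilities, labels) 0.5
  m <- train_model(bench$train$proteins, bench$train$labels,
                   bench$valid$proteins, bench$valid$labels,
                   config = cfg, embeddings = bench$train$embeddings,
                   valid_embeddings = bench$valid$embeddings,
                   metric_fn = frozen)
  expect_identical(m$n_epochs_run, 11L)   # patience 10 + the first epoch
  expect_identical(m$best_epoch, 1L)
})

test_that("training is bitwise reproducible for a fixed seed", {
  bench <- make_tiny_training_data()
  cfg <- tiny_config(batch_size = 8L, max_epochs = 3L, dropout_rate = 0.1)
  fit <- function() {
    train_model(bench$train$proteins, bench$train$labels,
                bench$valid$proteins, bench$valid$labels,
                config = cfg, embeddings = bench$train$embeddings,
                valid_embeddings = bench$valid$embeddings)
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)
})

test_that("training on the planted rule reduces the loss", {
  bench <- make_benchmark(n_train = 20L, n_valid = 5L, n_test = 2L,
                          d_p = 8L, length_range = c(25L, 40L),
                          pi_target = 0.2, rho = 0, seed = 55)
  cfg <- tiny_config(batch_size = 16L, max_epochs = 5L)
  m <- train_model(bench$train$proteins, bench$train$labels,
                   bench$valid$proteins, bench$valid$labels,
                   config = cfg, embeddings = bench$train$embeddings,
                   valid_embeddings = bench$valid$embeddings)
  expect_lt(m$history$train_loss[5], m$history$train_loss[1])
})

test_that("a training split without positives is rejected with a diagnostic", {
  bench <- make_tiny_training_data()
  labs <- lapply(bench$train$labels, function(tr) {
    label_track(tr$protein_id, integer(length(tr$labels)), tr$mask)
  })
  cfg <- tiny_config()
  expect_error(
    train_model(bench$train$proteins, labs,
                bench$valid$proteins, bench$valid$labels,
                config = cfg, embeddings = bench$train$embeddings,
                valid_embeddings = bench$valid$embeddings),
    "no positive")
})

test_that("ensembling averages probabilities and is order-invariant", {
  cfg <- tiny_config()
  d_p <- 8L
  p <- tiny_protein(15, seed = 61)
  mk <- function(seed) {
    c2 <- cfg; c2$seed <- seed
    list(params = init_model_params(d_p, c2), config = cfg, d_p = d_p,
         embedder = "synthetic", embed_seed = cfg$seed)
  }
  m1 <- mk(1L); m2 <- mk(2L)
  t1 <- predict_protein(p, m1); t2 <- predict_protein(p, m2)
  ens <- ensemble_predict(list(m1, m2), p)
  expect_equal(ens$probability, (t1$probability + t2$probability) / 2,
               tolerance = 1e-12)
  ens_rev <- ensemble_predict(list(m2, m1), p)
  expect_identical(ens$probability, ens_rev$probability)
  solo <- ensemble_predict(list(m1), p)
  expect_identical(solo$probability, t1$probability)
  m3 <- mk(3L); m3$config <- tiny_config(d_hid = 8L, n_heads = 2L)
  m3$params <- init_model_params(d_p, m3$config)
  expect_error(ensemble_predict(list(m1, m3), p), "mismatched")
})

test_that("grid search selects the configuration that learns", {
  bench <- make_benchmark(n_train = 24L, n_valid = 4L, n_test = 2L,
                          d_p = 8L, length_range = c(30L, 40L),
                          pi_target = 0.25, rho = 0, seed = 71)
  cfg <- tiny_config(batch_size = 32L, max_epochs = 10L)
  prots <- bench$train$proteins
  labs <- bench$train$labels
  emb <- bench$train$embeddings
  # singleton grid returns that configuration
  g1 <- grid_search(prots, labs, tiny_config(max_epochs = 2L),
                    grid = list(learning_rate = 0.002),
                    scheme = scheme_holdout(0.25), embeddings = emb)
  expect_equal(g1$best_config$learning_rate, 0.002)
  expect_error(grid_search(prots, labs, cfg, grid = list()), "empty")
  expect_error(grid_search(prots, labs, cfg, grid = list(d_hid = 4)),
               "grid keys")
  # a learning rate of ~0 cannot learn; the searcher must prefer the other
  g2 <- grid_search(prots, labs, cfg,
                    grid = list(learning_rate = c(1e-9, 2e-3)),
                    scheme = scheme_holdout(0.25), embeddings = emb)
  expect_equal(g2$best_config$learning_rate, 2e-3)
  expect_gt(diff(sort(g2$results$valid_metric)), 0.05)
  # deterministic given seeds
  g3 <- grid_search(prots, labs, cfg,
                    grid = list(learning_rate = c(1e-9, 2e-3)),
                    scheme = scheme_holdout(0.25), embeddings = emb)
  expect_identical(g2$results, g3$results)
})

test_that("training schemes split, repeat and report as requested", {
  bench <- make_tiny_training_data(n = 10L)
  cfg <- tiny_config(batch_size = 8L, max_epochs = 2L)
  prots <- c(bench$train$proteins)
  labs <- bench$train$labels
  emb <- bench$train$embeddings
  rep3 <- fit_scheme(prots, labs, cfg, scheme_repeated(R = 3L),
                     embeddings = emb, valid_embeddings = emb)
  expect_length(rep3$models, 3L)
  expect_identical(nrow(rep3$report), 3L)
  expect_identical(rep3$summary$n_models, 3L)
  expect_true(is.finite(rep3$summary$sd))
  kf <- fit_scheme(prots, labs, cfg, scheme_kfold(K = 3L),
                   embeddings = emb, valid_embeddings = emb)
  expect_length(kf$fold_models, 3L)
  expect_length(kf$models, 1L)   # the retrained final model
})

test_that("checkpoints round-trip models through disk", {
  cfg <- tiny_config()
  model <- list(params = init_model_params(8L, cfg), config = cfg, d_p = 8L,
                embedder = "synthetic", embed_seed = cfg$seed,
                loss_weight = 2.5, history = data.frame())
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_identical(back$params, model$params)
  expect_identical(unclass(back$config), unclass(cfg))
  p <- tiny_protein(9, seed = 3)
  expect_identical(predict_protein(p, back)$probability,
                   predict_protein(p, model)$probability)
})
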