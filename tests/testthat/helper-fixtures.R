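# Shared fixtures: tiny architectures for fast exact tests, and a cache of
# trained models reused across test files (training is the expensive step,
# and several properties are asserted on the same fitted models).

tiny_config <- function(...) {
  defaults <- list(d_hid = 16L, n_heads = 4L, d_ff = 24L, n_enc_layers = 2L,
                   n_dec_layers = 2L, kernel_size = 3L, window_size = 5L,
                   dropout_rate = 0, batch_size = 16L, seed = 7L)
  overrides <- list(...)
  defaults[names(overrides)] <- overrides
  do.call(run_config, defaults)
}

tiny_protein <- function(len = 12L, seed = 5L, id = NULL) {
  p <- generate_proteins(1L, c(len, len), seed = seed)[[1L]]
  if (!is.null(id)) p$id <- id
  p
}

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache, inherits = FALSE)
}

# The synthetic benchmark at study-condition scale: 200/50/50 proteins,
# lengths 50-150, positive fraction 0.12, flip noise 0.02, d_p = 64.
study_benchmark <- function() {
  cache_get("study_benchmark", function() {
    make_benchmark(n_train = 200L, n_valid = 50L, n_test = 50L, d_p = 64L,
                   length_range = c(50L, 150L), pi_target = 0.12,
                   rho = 0.02, half_width = 2L, seed = 101L)
  })
}

# Default-configuration model (d_hid 64 variant) trained on the study
# benchmark; w = NULL uses the class-ratio loss weight.
study_model <- function(seed, w = NULL) {
  key <- paste0("model_s", seed, "_w", if (is.null(w)) "ratio" else w)
  cache_get(key, function() {
    bench <- study_benchmark()
    cfg <- run_config(d_hid = 64L, seed = as.integer(seed), loss_weight = w)
    train_model(bench$train$proteins, bench$train$labels,
                bench$valid$proteins, bench$valid$labels,
                config = cfg,
                embeddings = bench$train$embeddings,
                valid_embeddings = bench$valid$embeddings)
  })
}

study_test_report <- function(seed) {
  key <- paste0("report_s", seed)
  cache_get(key, function() {
    bench <- study_benchmark()
    m <- study_model(seed)
    preds <- predict_proteins(bench$test$proteins, m,
                              embeddings = bench$test$embeddings)
    pooled_metrics(preds, bench$test$labels)
  })
}

# Full-validation-set probabilities and labels for a fitted model.
study_validation_scores <- function(model) {
  bench <- study_benchmark()
  probs <- numeric(0); ys <- numeric(0)
  for (id in names(bench$valid$labels)) {
    tr <- bench$valid$labels[[id]]
    pos <- which(tr$mask == 1L)
    pt <- predict_protein(bench$valid$proteins[[match(id, names(bench$valid$embeddings))]],
                          model, embedding = bench$valid$embeddings[[id]],
                          positions = pos)
    probs <- c(probs, pt$probability)
    ys <- c(ys, tr$labels[pos])
  }
  list(probabilities = probs, labels = ys)
}
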