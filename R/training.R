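# Training: weighted cross-entropy objective, RAdam + Lookahead optimizer,
# the three training schemes (hold-out, k-fold selection + retrain,
# repeated splits), early stopping on validation MCC, and grid search.

#' Weighted binary cross-entropy
#'
#' `loss = -sum_i [ w * y_i * log(p_i) + (1 - y_i) * log(1 - p_i) ] / N`
#' over masked-in residues, with probabilities clamped to
#' `[1e-7, 1 - 1e-7]`. `w` is the loss weight of the positive (binding)
#' class; with `w = 1` this is the standard binary cross-entropy. The mean
#' reduction keeps the magnitude comparable across batch sizes.
#'
#' @param probabilities Predicted binding probabilities.
#' @param labels 0/1 true labels.
#' @param w Positive-class weight (> 0).
#' @param mask Optional 0/1 vector; 0 positions are excluded.
#' @return Mean loss over the counted residues.
#' @export
weighted_ce <- function(probabilities, labels, w = 1, mask = NULL) {
  if (w <= 0) stop("loss weight w must be positive", call. = FALSE)
  if (length(probabilities) != length(labels)) {
    stop("probabilities and labels must align", call. = FALSE)
  }
  if (!is.null(mask)) {
    probabilities <- probabilities[mask == 1L]
    labels <- labels[mask == 1L]
  }
  if (!length(labels)) stop("no residues to score", call. = FALSE)
  p <- pmin(pmax(probabilities, 1e-7), 1 - 1e-7)
  -mean(w * labels * log(p) + (1 - labels) * log(1 - p))
}

#' Create a RAdam + Lookahead optimizer
#'
#' Rectified Adam inner steps (beta1 0.9, beta2 0.999) wrapped by Lookahead
#' slow-weight interpolation every `k = 5` steps with `alpha = 0.5` (the
#' technique's published defaults). Decoupled-style weight decay
#' (`config$weight_decay`) is added to the gradient of weight matrices;
#' biases and layer-norm vectors are not decayed.
#'
#' @param params Initial parameter list.
#' @param config A `run_config` (uses `learning_rate`, `weight_decay`).
#' @param lookahead_k,lookahead_alpha Lookahead synchronization period and
#'   interpolation factor.
#' @return An optimizer object (environment) with `$step(params, grads)`
#'   returning the updated parameter list, and counter `$t`.
#' @export
make_optimizer <- function(params, config, lookahead_k = 5L,
                           lookahead_alpha = 0.5) {
  opt <- new.env(parent = emptyenv())
  opt$t <- 0L
  # flat-vector state over all parameter arrays; the fused update runs in
  # compiled code and mutates the state buffers in place
  sizes <- vapply(params, length, integer(1L))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  n_tot <- ends[length(ends)]
  order <- names(params)
  opt$p <- unlist(params, use.names = FALSE)
  opt$m <- numeric(n_tot)
  opt$v <- numeric(n_tot)
  opt$slow <- unlist(params, use.names = FALSE)
  # weight decay applies to weight matrices only (not biases / LN vectors)
  decay_mask <- unlist(lapply(params, function(p) {
    rep(as.numeric(is.matrix(p)), length(p))
  }), use.names = FALSE)
  opt$lr <- config$learning_rate
  opt$wd <- config$weight_decay
  opt$k <- as.integer(lookahead_k)
  opt$alpha <- lookahead_alpha
  opt$step <- function(params, grads) {
    opt$t <- opt$t + 1L
    cpp_radam_step(opt$p, grads, order, opt$m, opt$v, opt$slow, decay_mask,
                   opt$t, opt$lr, opt$wd, opt$alpha, opt$k)
    for (i in seq_along(params)) params[[i]][] <- opt$p[starts[i]:ends[i]]
    params
  }
  opt
}

# Embed a list of proteins with a registered embedder; returns a named list.
embed_proteins <- function(proteins, embedder = "synthetic", d_p = 64L,
                           seed = 1L) {
  proteins <- as_protein_list(proteins)
  fn <- get_embedder(embedder)
  out <- lapply(proteins, fn, d_p = d_p, seed = seed)
  names(out) <- protein_ids(proteins)
  out
}

# Default positive-class weight: non-binding / binding residue ratio.
class_ratio_weight <- function(labels) {
  pos <- sum(vapply(labels, function(tr) sum(tr$labels[tr$mask == 1L]),
                    numeric(1L)))
  tot <- sum(vapply(labels, function(tr) tr$n_effective, numeric(1L)))
  if (pos == 0) {
    stop("training split has no positive (binding) residues; cannot set the ",
         "class-ratio loss weight or learn the positive class", call. = FALSE)
  }
  (tot - pos) / pos
}

# Model probabilities for masked-in residues of a set of proteins.
# `positions` optionally restricts each protein to a fixed residue subset.
predict_masked <- function(embeddings, labels, params, config,
                           positions = NULL, use_float = FALSE) {
  probs <- numeric(0); ys <- numeric(0)
  for (id in names(labels)) {
    tr <- labels[[id]]
    pos <- if (is.null(positions)) which(tr$mask == 1L) else positions[[id]]
    if (!length(pos)) next
    run <- cpp_model_run(embeddings[[id]], params, config,
                         as.integer(pos - 1L), numeric(0), 1.0,
                         FALSE, 0.0, 1L, use_float)
    probs <- c(probs, run$probabilities)
    ys <- c(ys, tr$labels[pos])
  }
  list(probabilities = probs, labels = ys)
}

# Fixed per-protein monitoring subsample (seeded once per run): caps the
# per-epoch early-stopping evaluation at `cap` residues per protein.
monitor_positions <- function(labels, cap, seed) {
  out <- lapply(names(labels), function(id) {
    pos <- which(labels[[id]]$mask == 1L)
    if (length(pos) > cap) {
      pos <- with_seed(mix_seed(seed, 903L, hash_string(id)),
                       sort(sample(pos, cap)))
    }
    pos
  })
  names(out) <- names(labels)
  out
}

#' Train one binding-site model
#'
#' Residue-level minibatches are drawn afresh each epoch (one optimizer step
#' per protein visit, up to `batch_size` masked-in residues per step).
#' After every epoch the validation MCC at the decision threshold is
#' computed; training stops when it has not improved for
#' `config$patience` epochs (or at `config$max_epochs`), and the
#' best-epoch parameters are kept. Fully deterministic for a fixed
#' configuration seed.
#'
#' @param train_proteins,train_labels Training proteins and their label
#'   tracks (named list keyed by protein id).
#' @param valid_proteins,valid_labels Validation set used for early
#'   stopping.
#' @param config A `run_config`.
#' @param embedder Registered embedder name.
#' @param d_p Embedding dimension.
#' @param embed_seed Seed passed to the embedder (defaults to
#'   `config$seed`); must match between training and later prediction.
#' @param embeddings,valid_embeddings Optional precomputed embedding lists
#'   (bypass the embedder).
#' @param metric_fn Validation metric: function
#'   `(probabilities, labels) -> scalar` maximized for early stopping.
#'   Defaults to MCC at the decision threshold.
#' @param monitor_cap Per-protein cap on validation residues used for the
#'   per-epoch early-stopping metric (a fixed seeded subsample, so the
#'   monitored set is identical across epochs). `Inf` monitors every
#'   masked-in residue.
#' @param log_file Optional path for progress logging.
#' @return A model list: `params`, `config`, `d_p`, `loss_weight`,
#'   `embedder`, `embed_seed`, `history` (per-epoch loss and validation
#'   metric), `best_epoch`, `n_epochs_run`.
#' @export
train_model <- function(train_proteins, train_labels,
                        valid_proteins, valid_labels,
                        config = run_config(),
                        embedder = "synthetic", d_p = 64L,
                        embed_seed = config$seed,
                        embeddings = NULL, valid_embeddings = NULL,
                        metric_fn = NULL, monitor_cap = 48L,
                        log_file = NULL) {
  train_proteins <- as_protein_list(train_proteins)
  valid_proteins <- as_protein_list(valid_proteins)
  if (is.null(embeddings)) {
    embeddings <- embed_proteins(train_proteins, embedder, d_p, embed_seed)
  } else {
    embeddings <- embeddings[protein_ids(train_proteins)]
  }
  d_p <- ncol(embeddings[[1L]])
  if (is.null(valid_embeddings)) {
    valid_embeddings <- embed_proteins(valid_proteins, embedder, d_p, embed_seed)
  } else {
    valid_embeddings <- valid_embeddings[protein_ids(valid_proteins)]
  }
  w <- if (is.null(config$loss_weight)) class_ratio_weight(train_labels)
       else config$loss_weight
  if (is.null(metric_fn)) {
    metric_fn <- function(probabilities, labels) {
      mcc(confusion(probabilities, labels, config$decision_threshold))
    }
  }
  params <- init_model_params(d_p, config)
  opt <- make_optimizer(params, config)
  ids <- names(embeddings)
  monitor_pos <- if (is.finite(monitor_cap)) {
    monitor_positions(valid_labels, as.integer(monitor_cap), config$seed)
  } else NULL

  best_metric <- -Inf; best_params <- params; best_epoch <- 0L
  stall <- 0L
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        valid_metric = numeric())
  if (!is.null(log_file)) {
    log_line(sprintf("training start: %d train / %d valid proteins, w=%.3f",
                     length(ids), length(valid_proteins), w),
             log_file, seed = config$seed)
  }
  for (epoch in seq_len(config$max_epochs)) {
    order_ids <- with_seed(mix_seed(config$seed, 900L, epoch),
                           sample(ids, length(ids)))
    losses <- numeric(0)
    for (si in seq_along(order_ids)) {
      id <- order_ids[si]
      tr <- train_labels[[id]]
      pos <- which(tr$mask == 1L)
      if (!length(pos)) next
      if (length(pos) > config$batch_size) {
        pos <- with_seed(mix_seed(config$seed, 901L, epoch, si),
                         sort(sample(pos, config$batch_size)))
      }
      run <- cpp_model_run(embeddings[[id]], params, config,
                           as.integer(pos - 1L), as.numeric(tr$labels[pos]),
                           w, TRUE, config$dropout_rate,
                           mix_seed(config$seed, 902L, epoch, si),
                           use_float = TRUE)
      params <- opt$step(params, run$grads)
      losses <- c(losses, run$loss)
    }
    val <- predict_masked(valid_embeddings, valid_labels, params, config,
                          positions = monitor_pos, use_float = TRUE)
    metric <- metric_fn(val$probabilities, val$labels)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = mean(losses),
                                         valid_metric = metric))
    if (!is.null(log_file)) {
      log_line(sprintf("epoch %d: loss=%.4f valid=%.4f", epoch,
                       mean(losses), metric), log_file)
    }
    if (metric > best_metric) {
      best_metric <- metric; best_params <- params
      best_epoch <- epoch; stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }
  structure(list(params = best_params, config = config, d_p = d_p,
                 loss_weight = w, embedder = embedder,
                 embed_seed = embed_seed, history = history,
                 best_epoch = best_epoch, n_epochs_run = nrow(history)),
            class = "binding_model")
}

#' @export
print.binding_model <- function(x, ...) {
  cat(sprintf("<binding_model> d_hid=%d, d_p=%d, w=%.3f, best epoch %d/%d (valid metric %.4f)\n",
              x$config$d_hid, x$d_p, x$loss_weight, x$best_epoch,
              x$n_epochs_run,
              if (nrow(x$history)) max(x$history$valid_metric) else NA))
  invisible(x)
}

#' Training scheme descriptors
#'
#' `scheme_holdout`: a single random train/validation split.
#' `scheme_kfold`: K-fold cross-validation for selection, then a retrain on
#' the full training set (with an internal holdout for early stopping).
#' `scheme_repeated`: R independent ratio splits, producing R models whose
#' metrics are reported as mean +/- SD.
#'
#' @param valid_fraction,ratio Validation fraction / train share.
#' @param K Number of folds.
#' @param R Number of repeats.
#' @return A list of class `training_scheme`.
#' @export
scheme_holdout <- function(valid_fraction = 0.2) {
  structure(list(kind = "holdout", valid_fraction = valid_fraction),
            class = "training_scheme")
}

#' @rdname scheme_holdout
#' @export
scheme_kfold <- function(K = 5L) {
  structure(list(kind = "kfold_then_retrain", K = as.integer(K)),
            class = "training_scheme")
}

#' @rdname scheme_holdout
#' @export
scheme_repeated <- function(R = 10L, ratio = 0.8) {
  structure(list(kind = "repeated_splits", R = as.integer(R), ratio = ratio),
            class = "training_scheme")
}

#' Train under a scheme
#'
#' Runs the requested training scheme over a labelled protein set and
#' returns the fitted model(s) plus a per-model report of validation
#' metrics (with mean +/- SD for repeated splits).
#'
#' @param proteins Protein records.
#' @param labels Named list of label tracks.
#' @param config A `run_config`.
#' @param scheme A `training_scheme` (default holdout 8:2).
#' @param ... Passed to [train_model()] (e.g. `embedder`, `d_p`,
#'   `embeddings`).
#' @return List with `models`, `scheme`, `report` (data.frame of per-model
#'   validation metrics) and, for repeated splits, `summary` (mean/SD).
#' @export
fit_scheme <- function(proteins, labels, config = run_config(),
                       scheme = scheme_holdout(), ...) {
  stopifnot(inherits(scheme, "training_scheme"))
  proteins <- as_protein_list(proteins)
  ids <- protein_ids(proteins)
  by_id <- function(sel) proteins[match(sel, ids)]
  one <- function(train_ids, valid_ids, seed_shift) {
    cfg <- config
    cfg$seed <- mix_seed(config$seed, seed_shift)
    train_model(by_id(train_ids), labels[train_ids],
                by_id(valid_ids), labels[valid_ids],
                config = cfg, embed_seed = config$seed, ...)
  }
  if (scheme$kind == "holdout") {
    sp <- split_dataset(ids, c(train = 1 - scheme$valid_fraction,
                               valid = scheme$valid_fraction),
                        seed = config$seed)
    m <- one(sp$train, sp$valid, 1L)
    report <- data.frame(model = 1L,
                         valid_metric = max(m$history$valid_metric))
    list(models = list(m), scheme = scheme, report = report)
  } else if (scheme$kind == "kfold_then_retrain") {
    folds <- kfold_indices(ids, scheme$K, seed = config$seed)
    models <- lapply(seq_along(folds), function(k) {
      one(folds[[k]]$train, folds[[k]]$valid, 10L + k)
    })
    report <- data.frame(model = seq_along(models),
                         valid_metric = vapply(models, function(m) {
                           max(m$history$valid_metric)
                         }, numeric(1L)))
    sp <- split_dataset(ids, c(train = 0.8, valid = 0.2),
                        seed = mix_seed(config$seed, 99L))
    final <- one(sp$train, sp$valid, 100L)
    list(models = list(final), fold_models = models, scheme = scheme,
         report = report, mean_valid_metric = mean(report$valid_metric))
  } else { # repeated_splits
    models <- lapply(seq_len(scheme$R), function(r) {
      sp <- split_dataset(ids, c(train = scheme$ratio,
                                 valid = 1 - scheme$ratio),
                          seed = mix_seed(config$seed, 200L + r))
      one(sp$train, sp$valid, 200L + r)
    })
    vm <- vapply(models, function(m) max(m$history$valid_metric), numeric(1L))
    report <- data.frame(model = seq_along(models), valid_metric = vm)
    summary <- data.frame(metric = "valid_metric", mean = mean(vm),
                          sd = stats::sd(vm), n_models = length(vm))
    list(models = models, scheme = scheme, report = report, summary = summary)
  }
}

#' Ensemble prediction by probability averaging
#'
#' Per-residue mean probability across models (all models must share the
#' architecture configuration). Metric averaging across models — the
#' repeated-splits reporting protocol — lives in [aggregate_runs()].
#'
#' @param models List of `binding_model`s.
#' @param protein A `protein_record`.
#' @param ... Passed to [predict_protein()].
#' @return A prediction table with averaged probabilities.
#' @export
ensemble_predict <- function(models, protein, ...) {
  if (!length(models)) stop("need at least one model", call. = FALSE)
  keys <- vapply(models, function(m) {
    paste(m$config$d_hid, m$config$n_enc_layers, m$config$n_dec_layers,
          m$config$n_heads, m$config$d_ff, m$config$kernel_size,
          m$config$window_size, m$d_p, sep = "/")
  }, character(1L))
  if (length(unique(keys)) != 1L) {
    stop("models have mismatched architectures: ",
         paste(unique(keys), collapse = " vs "), call. = FALSE)
  }
  tabs <- lapply(models, function(m) predict_protein(protein, m, ...))
  out <- tabs[[1L]]
  probs <- rowMeans(vapply(tabs, `[[`, numeric(nrow(out)), "probability"))
  prediction_table(out$protein_id, out$position, out$residue, probs,
                   threshold = models[[1L]]$config$decision_threshold)
}

#' Grid search over the sensitive hyperparameters
#'
#' Trains one model per grid point (per fold under the k-fold scheme,
#' selecting by mean validation metric). Ties are broken in favour of the
#' smaller learning rate, then the smaller loss weight.
#'
#' @param proteins,labels Training data.
#' @param base_config Configuration whose non-grid entries are held fixed.
#' @param grid Named list over any of `batch_size`, `learning_rate`,
#'   `dropout_rate`, `loss_weight`; the Cartesian product is searched.
#' @param scheme A `training_scheme` (holdout or kfold).
#' @param ... Passed to [fit_scheme()].
#' @return List with `best_config`, `results` (one row per grid point with
#'   mean validation metric), and `best_index`.
#' @export
grid_search <- function(proteins, labels, base_config = run_config(),
                        grid = list(), scheme = scheme_holdout(), ...) {
  allowed <- c("batch_size", "learning_rate", "dropout_rate", "loss_weight")
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  bad <- setdiff(names(grid), allowed)
  if (length(bad)) stop("grid keys must be among ",
                        paste(allowed, collapse = ", "), call. = FALSE)
  pts <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  scores <- numeric(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    cfg <- base_config
    for (nm in names(pts)) cfg[[nm]] <- pts[[nm]][i]
    cfg <- validate_run_config(cfg)
    fit <- fit_scheme(proteins, labels, cfg, scheme, ...)
    scores[i] <- mean(fit$report$valid_metric)
  }
  results <- cbind(pts, valid_metric = scores)
  ord <- order(-scores,
               if ("learning_rate" %in% names(pts)) pts$learning_rate else
                 rep(0, nrow(pts)),
               if ("loss_weight" %in% names(pts)) pts$loss_weight else
                 rep(0, nrow(pts)))
  best <- ord[1L]
  best_config <- base_config
  for (nm in names(pts)) best_config[[nm]] <- pts[[nm]][best]
  list(best_config = validate_run_config(best_config), results = results,
       best_index = best)
}
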