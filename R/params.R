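# Model parameter initialization and checkpoint IO.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), nrow = n_in)
}

#' Initialize model parameters
#'
#' Weight matrices are Glorot-uniform, biases zero, layer-norm gains one,
#' and the within-window position embedding small Gaussian (sd 0.02).
#' Deterministic for fixed `(d_p, config$seed)`.
#'
#' @param d_p Input embedding dimension.
#' @param config A `run_config`.
#' @param seed Seed; defaults to `config$seed`.
#' @return Named list of parameter arrays ("model params"). The layout is
#'   flat: encoder entries `enc_*`, decoder layers `dec<l>_*`, classifier
#'   `cls_*`.
#' @export
init_model_params <- function(d_p, config, seed = config$seed) {
  H <- config$d_hid
  k <- config$kernel_size
  F_ <- config$d_ff
  with_seed(mix_seed(seed, 4242L), {
    p <- list()
    p$enc_in_W <- glorot(d_p, H); p$enc_in_b <- numeric(H)
    for (l in seq_len(config$n_enc_layers)) {
      p[[paste0("enc_conv_W", l)]] <- glorot(k * H, 2L * H)
      p[[paste0("enc_conv_b", l)]] <- numeric(2L * H)
    }
    p$enc_ln_g <- rep(1, H); p$enc_ln_b <- numeric(H)
    p$dec_in_W <- glorot(d_p, H); p$dec_in_b <- numeric(H)
    p$pos_emb <- matrix(stats::rnorm(config$window_size * H, sd = 0.02),
                        nrow = config$window_size)
    for (l in seq_len(config$n_dec_layers)) {
      pre <- paste0("dec", l, "_")
      for (blk in c("sa", "ca")) {
        for (w in c("Wq", "Wk", "Wv", "Wo")) {
          p[[paste0(pre, blk, "_", w)]] <- glorot(H, H)
        }
        for (b in c("bq", "bk", "bv", "bo")) {
          p[[paste0(pre, blk, "_", b)]] <- numeric(H)
        }
      }
      p[[paste0(pre, "ln1_g")]] <- rep(1, H); p[[paste0(pre, "ln1_b")]] <- numeric(H)
      p[[paste0(pre, "ln2_g")]] <- rep(1, H); p[[paste0(pre, "ln2_b")]] <- numeric(H)
      p[[paste0(pre, "ff_W1")]] <- glorot(H, F_); p[[paste0(pre, "ff_b1")]] <- numeric(F_)
      p[[paste0(pre, "ff_W2")]] <- glorot(F_, H); p[[paste0(pre, "ff_b2")]] <- numeric(H)
      p[[paste0(pre, "ln3_g")]] <- rep(1, H); p[[paste0(pre, "ln3_b")]] <- numeric(H)
    }
    p$cls_W1 <- glorot(H, 64L); p$cls_b1 <- numeric(64L)
    p$cls_W2 <- glorot(64L, 32L); p$cls_b2 <- numeric(32L)
    p$cls_W3 <- glorot(32L, 2L); p$cls_b3 <- numeric(2L)
    p
  })
}

CHECKPOINT_FORMAT <- "seq2site-checkpoint-1"

#' Save a model checkpoint
#'
#' A checkpoint bundles the parameters, the full run configuration, the
#' input dimension and a format-version tag into a single file.
#'
#' @param model List with at least `params`, `config`, `d_p` (e.g. from
#'   [train_model()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(is.list(model$params), inherits(model$config, "run_config"))
  obj <- list(format = CHECKPOINT_FORMAT, params = model$params,
              config = model$config, d_p = model$d_p,
              history = model$history, loss_weight = model$loss_weight)
  saveRDS(obj, path)
  invisible(path)
}

#' Load a model checkpoint
#' @param path Checkpoint file written by [save_checkpoint()].
#' @return The model list (`params`, `config`, `d_p`, ...).
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, CHECKPOINT_FORMAT)) {
    stop("unrecognized checkpoint format: ", obj$format, call. = FALSE)
  }
  obj
}
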