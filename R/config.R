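#' Construct a run configuration
#'
#' Holds every architecture and optimization hyperparameter of the model.
#' Defaults follow the published configuration of the method: hidden width
#' 128, three encoder and three decoder layers, eight attention heads,
#' feed-forward width 256, convolution kernel 7, weight decay 1e-4. The four
#' sensitive hyperparameters (batch size, learning rate, dropout rate, loss
#' weight) are tunables; `loss_weight = NULL` means "use the non-binding to
#' binding residue ratio of the training split".
#'
#' @param d_hid Hidden width; must be divisible by `n_heads`.
#' @param n_enc_layers,n_dec_layers Number of encoder / decoder layers.
#' @param n_heads Attention heads.
#' @param d_ff Position-wise feed-forward hidden width.
#' @param kernel_size Conv1D kernel width, odd.
#' @param weight_decay L2 weight decay applied to weight matrices.
#' @param batch_size Residues per optimization step.
#' @param learning_rate RAdam step size.
#' @param dropout_rate Dropout probability (training only).
#' @param loss_weight Positive-class weight `w` of the loss, or `NULL` for the
#'   class-ratio default.
#' @param window_size Local context window length `L_l`, odd.
#' @param decision_threshold Probability threshold for hard calls, in (0,1).
#' @param seed Integer seed governing initialization, splits and sampling.
#' @param max_epochs Epoch cap for training.
#' @param patience Early-stopping patience in epochs.
#' @param norm_squared If `TRUE` the significance-aggregation weights use the
#'   squared feature norm instead of the norm (config switch; see vignette).
#' @return A list of class `run_config`.
#' @export
run_config <- function(d_hid = 128L,
                       n_enc_layers = 3L,
                       n_dec_layers = 3L,
                       n_heads = 8L,
                       d_ff = 256L,
                       kernel_size = 7L,
                       weight_decay = 1e-4,
                       batch_size = 32L,
                       learning_rate = 2e-3,
                       dropout_rate = 0.1,
                       loss_weight = NULL,
                       window_size = 15L,
                       decision_threshold = 0.5,
                       seed = 1L,
                       max_epochs = 15L,
                       patience = 10L,
                       norm_squared = FALSE) {
  cfg <- list(d_hid = as.integer(d_hid),
              n_enc_layers = as.integer(n_enc_layers),
              n_dec_layers = as.integer(n_dec_layers),
              n_heads = as.integer(n_heads),
              d_ff = as.integer(d_ff),
              kernel_size = as.integer(kernel_size),
              weight_decay = as.numeric(weight_decay),
              batch_size = as.integer(batch_size),
              learning_rate = as.numeric(learning_rate),
              dropout_rate = as.numeric(dropout_rate),
              loss_weight = if (is.null(loss_weight)) NULL else as.numeric(loss_weight),
              window_size = as.integer(window_size),
              decision_threshold = as.numeric(decision_threshold),
              seed = as.integer(seed),
              max_epochs = as.integer(max_epochs),
              patience = as.integer(patience),
              norm_squared = isTRUE(norm_squared))
  class(cfg) <- "run_config"
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  with(cfg, {
    if (d_hid < 1L || d_hid %% n_heads != 0L) {
      stop("d_hid (", d_hid, ") must be a positive multiple of n_heads (",
           n_heads, ")", call. = FALSE)
    }
    if (kernel_size %% 2L != 1L) stop("kernel_size must be odd", call. = FALSE)
    if (window_size %% 2L != 1L) stop("window_size must be odd", call. = FALSE)
    if (decision_threshold <= 0 || decision_threshold >= 1) {
      stop("decision_threshold must lie strictly in (0,1)", call. = FALSE)
    }
    if (n_enc_layers < 0L || n_dec_layers < 1L) {
      stop("layer counts out of range", call. = FALSE)
    }
    if (dropout_rate < 0 || dropout_rate >= 1) {
      stop("dropout_rate must lie in [0,1)", call. = FALSE)
    }
    if (!is.null(loss_weight) && loss_weight <= 0) {
      stop("loss_weight must be positive", call. = FALSE)
    }
    if (patience < 1L || max_epochs < 1L) stop("patience/max_epochs must be >= 1",
                                               call. = FALSE)
  })
  cfg
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-18s %s\n", nm,
                if (is.null(x[[nm]])) "NULL (class ratio)" else format(x[[nm]])))
  }
  invisible(x)
}

.numeric_config_keys <- c("d_hid", "n_enc_layers", "n_dec_layers", "n_heads",
                          "d_ff", "kernel_size", "weight_decay", "batch_size",
                          "learning_rate", "dropout_rate", "loss_weight",
                          "window_size", "decision_threshold", "seed",
                          "max_epochs", "patience")

#' Load a run configuration from a YAML file
#'
#' The file is a flat key-value document. Keys that are absent take their
#' defaults (see [run_config()]); unknown keys are rejected so typos cannot
#' silently change a run.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (e.g. parsed CLI
#'   flags); same validation rules.
#' @return A validated `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    vals <- yaml::yaml.load_file(path)
    if (is.null(vals)) vals <- list()
    if (!is.list(vals)) stop("config must be a flat key-value mapping", call. = FALSE)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (key in intersect(names(vals), .numeric_config_keys)) {
    v <- vals[[key]]
    if (!is.null(v) && (!is.numeric(v) || length(v) != 1L || is.na(v))) {
      stop("config key '", key, "' must be a single number, got: ",
           deparse(v), call. = FALSE)
    }
  }
  do.call(run_config, vals)
}

#' Write a run configuration to YAML
#' @param cfg A `run_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  vals <- unclass(cfg)
  vals <- vals[!vapply(vals, is.null, logical(1L))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
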