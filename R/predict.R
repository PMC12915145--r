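#' Predict binding probabilities for a protein
#'
#' Runs the trained model over every residue (or a subset) of a protein and
#' returns a prediction table. Inference is deterministic: dropout is off
#' and repeated calls give identical probabilities. `chunk_size` controls
#' how many residues are decoded per internal batch; results are invariant
#' to it (the encoder always sees the full protein).
#'
#' @param protein A `protein_record`.
#' @param model A `binding_model` (from [train_model()]) or a checkpoint
#'   list from [load_checkpoint()].
#' @param embedding Optional precomputed `L x d_p` embedding matrix;
#'   otherwise the model's embedder and embed seed are used.
#' @param positions Residues to predict (default all).
#' @param chunk_size Residues per decoding batch (default: all at once).
#' @return A prediction table (see [prediction_table()]).
#' @export
predict_protein <- function(protein, model, embedding = NULL,
                            positions = NULL, chunk_size = NULL) {
  stopifnot(inherits(protein, "protein_record"))
  cfg <- model$config
  if (is.null(embedding)) {
    fn <- get_embedder(model$embedder %||% "synthetic")
    embedding <- fn(protein, d_p = model$d_p,
                    seed = model$embed_seed %||% cfg$seed)
  }
  L <- protein_length(protein)
  if (nrow(embedding) != L) {
    stop("embedding has ", nrow(embedding), " rows but protein '",
         protein$id, "' has ", L, " residues", call. = FALSE)
  }
  if (is.null(positions)) positions <- seq_len(L)
  if (is.null(chunk_size)) chunk_size <- length(positions)
  probs <- numeric(length(positions))
  for (start in seq(1L, length(positions), by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, length(positions))
    run <- cpp_model_run(embedding, model$params, cfg,
                         as.integer(positions[idx] - 1L), numeric(0),
                         1.0, FALSE, 0.0, 1L)
    probs[idx] <- run$probabilities
  }
  residues <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]][positions]
  prediction_table(protein$id, positions, residues, probs,
                   threshold = cfg$decision_threshold)
}

#' Predict over a set of proteins
#'
#' @param proteins List of `protein_record`s.
#' @param model A `binding_model`.
#' @param embeddings Optional named list of precomputed embeddings.
#' @param ... Passed to [predict_protein()].
#' @return A single prediction table with one row per residue.
#' @export
predict_proteins <- function(proteins, model, embeddings = NULL, ...) {
  proteins <- as_protein_list(proteins)
  do.call(rbind, lapply(proteins, function(p) {
    predict_protein(p, model,
                    embedding = if (is.null(embeddings)) NULL
                                else embeddings[[p$id]], ...)
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
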