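#' Deterministic synthetic per-residue embeddings
#'
#' A stand-in for protein-language-model features that needs no download and
#' is a pure function of its arguments. Each residue i receives
#' `e_i = u(aa_i) + 0.5 * mean(u(aa_j), j in [i-3, i+3]) + eps_i`, where
#' `u(letter)` is a vector with independent standard-normal entries drawn
#' once per letter from an RNG stream keyed by `(seed, letter)`, and the
#' noise `eps_i` has sd `noise_sd` and comes from a stream keyed by
#' `(seed, protein_id)` (so two proteins with the same sequence share their
#' `u` components but not their noise). The smoothing term makes embeddings
#' context-dependent over a 7-residue window, mimicking the local context
#' sensitivity of real language-model features.
#'
#' @param protein A `protein_record`.
#' @param d_p Embedding dimension, >= 8. The published model consumes
#'   2,560-dimensional language-model features; 64 is a practical default for
#'   CPU-scale experiments.
#' @param seed Integer seed.
#' @param noise_sd Standard deviation of the residue-specific noise
#'   (default 0.1; set 0 for the noiseless deterministic embedding).
#' @return A `d_p`-column embedding matrix with one row per residue, with
#'   attributes `protein_id` and `d_p`.
#' @export
synthetic_embed <- function(protein, d_p = 64L, seed = 1L, noise_sd = 0.1) {
  stopifnot(inherits(protein, "protein_record"))
  d_p <- as.integer(d_p)
  if (d_p < 8L) stop("d_p must be at least 8", call. = FALSE)
  chars <- strsplit(protein$sequence, "", fixed = TRUE)[[1L]]
  L <- length(chars)
  U <- letter_basis(d_p, seed)
  base <- U[chars, , drop = FALSE]
  # window mean of u(aa_j) over j in [i-3, i+3], truncated at the ends
  csum <- rbind(0, apply(base, 2L, cumsum))
  lo <- pmax(seq_len(L) - 3L, 1L)
  hi <- pmin(seq_len(L) + 3L, L)
  win <- (csum[hi + 1L, , drop = FALSE] - csum[lo, , drop = FALSE]) / (hi - lo + 1)
  E <- base + 0.5 * win
  if (noise_sd > 0) {
    eps <- with_seed(mix_seed(seed, hash_string(protein$id)),
                     matrix(stats::rnorm(L * d_p, sd = noise_sd), nrow = L))
    E <- E + eps
  }
  dimnames(E) <- NULL
  attr(E, "protein_id") <- protein$id
  attr(E, "d_p") <- d_p
  E
}

# One unit-variance basis vector per residue letter, keyed by (seed, letter).
letter_basis <- function(d_p, seed) {
  letters21 <- c(AA_LETTERS, "X")
  U <- t(vapply(letters21, function(aa) {
    with_seed(mix_seed(seed, utf8ToInt(aa)), stats::rnorm(d_p))
  }, numeric(d_p)))
  rownames(U) <- letters21
  U
}

#' Pad a list of embedding matrices into a batch
#'
#' @param embeddings Nonempty list of embedding matrices sharing `d_p`.
#' @return A list with `values` (`B x L_max x d_p` array, zero beyond each
#'   protein's length), `pad_mask` (`B x L_max`, 1 = real residue), and
#'   `lengths`.
#' @export
pad_batch <- function(embeddings) {
  if (!is.list(embeddings) || length(embeddings) == 0L) {
    stop("pad_batch needs a nonempty list of matrices", call. = FALSE)
  }
  dps <- vapply(embeddings, ncol, integer(1L))
  if (length(unique(dps)) != 1L) {
    stop("all embeddings must share the same d_p (got ",
         paste(unique(dps), collapse = ", "), ")", call. = FALSE)
  }
  lengths <- vapply(embeddings, nrow, integer(1L))
  L_max <- max(lengths)
  B <- length(embeddings)
  values <- array(0, dim = c(B, L_max, dps[1L]))
  pad_mask <- matrix(0L, nrow = B, ncol = L_max)
  for (b in seq_len(B)) {
    values[b, seq_len(lengths[b]), ] <- embeddings[[b]]
    pad_mask[b, seq_len(lengths[b])] <- 1L
  }
  list(values = values, pad_mask = pad_mask, lengths = lengths)
}

.embedder_registry <- new.env(parent = emptyenv())

#' Register or look up an embedding adapter
#'
#' Embedders are pluggable: any function `(protein, d_p, seed) -> matrix`
#' with one row per residue can back the pipeline (e.g. an adapter that loads
#' cached protein-language-model features). The core never inspects
#' provenance; it only validates the shape contract.
#'
#' @param name Adapter name.
#' @param fn Function with signature `(protein, d_p, seed)`.
#' @return `register_embedder` returns `name` invisibly; `get_embedder`
#'   returns a shape-validated embedding function.
#' @export
register_embedder <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  assign(name, fn, envir = .embedder_registry)
  invisible(name)
}

#' @rdname register_embedder
#' @export
get_embedder <- function(name) {
  if (!exists(name, envir = .embedder_registry, inherits = FALSE)) {
    stop("no embedder registered under name '", name, "'", call. = FALSE)
  }
  fn <- get(name, envir = .embedder_registry, inherits = FALSE)
  function(protein, d_p, seed) {
    E <- fn(protein, d_p, seed)
    if (!is.matrix(E) || nrow(E) != protein_length(protein)) {
      stop("embedder '", name, "' violated its contract: expected ",
           protein_length(protein), " rows for protein '", protein$id, "'",
           call. = FALSE)
    }
    if (any(!is.finite(E))) {
      stop("embedder '", name, "' produced non-finite values", call. = FALSE)
    }
    E
  }
}

# The synthetic embedder ships registered under "synthetic".
register_default_embedders <- function() {
  register_embedder("synthetic", function(protein, d_p, seed) {
    synthetic_embed(protein, d_p = d_p, seed = seed)
  })
}

.onLoad <- function(libname, pkgname) {
  register_default_embedders()
}
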