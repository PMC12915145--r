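#' @useDynLib seq2site, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Create a protein record
#'
#' The unit of all sequence IO: an identifier plus an amino-acid sequence over
#' the 20 canonical letters, with `X` standing for unknown residues. Sequences
#' are uppercased on construction; any letter outside the canonical alphabet
#' is mapped to `X` (with a warning for lowercase or unusual input).
#'
#' @param id Protein identifier; must be non-empty and contain no whitespace.
#' @param sequence Amino-acid sequence, length >= 1.
#' @return An object of class `protein_record` with elements `id` and
#'   `sequence`.
#' @export
protein_record <- function(id, sequence) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id)) {
    stop("protein id must be a non-empty string without whitespace", call. = FALSE)
  }
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop("sequence must be a non-empty string (protein '", id, "')", call. = FALSE)
  }
  seq_norm <- normalize_sequence(sequence, id = id)
  structure(list(id = id, sequence = seq_norm), class = "protein_record")
}

normalize_sequence <- function(sequence, id = "?") {
  if (grepl("[a-z]", sequence)) {
    warning("lowercase letters in sequence of '", id, "' were uppercased",
            call. = FALSE)
    sequence <- toupper(sequence)
  }
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(AA_LETTERS, "X"))
  if (any(bad)) {
    warning(sum(bad), " non-canonical residue letter(s) in '", id,
            "' mapped to 'X'", call. = FALSE)
    chars[bad] <- "X"
  }
  paste(chars, collapse = "")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s (%d aa)\n", x$id, nchar(x$sequence)))
  invisible(x)
}

#' Sequence length of a protein record
#' @param x A `protein_record`.
#' @return Integer sequence length.
#' @export
protein_length <- function(x) nchar(x$sequence)

as_protein_list <- function(proteins) {
  if (inherits(proteins, "protein_record")) return(list(proteins))
  stopifnot(is.list(proteins))
  lapply(proteins, function(p) {
    if (!inherits(p, "protein_record")) stop("expected protein_record objects")
    p
  })
}

protein_ids <- function(proteins) {
  vapply(as_protein_list(proteins), `[[`, character(1L), "id")
}

check_unique_ids <- function(ids) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicate protein id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  invisible(ids)
}

#' Create a per-residue label track
#'
#' Binary binding labels with a validity mask. Positions where the mask is 0
#' carry no experimental annotation and are excluded from training and
#' evaluation; the effective sample size `N` of the loss is the number of
#' masked-in positions.
#'
#' @param protein_id Protein identifier the track belongs to.
#' @param labels Integer vector over \{0,1\}, one per residue.
#' @param mask Integer vector over \{0,1\}, same length; 1 = label defined.
#'   Defaults to all 1.
#' @return An object of class `label_track` with elements `protein_id`,
#'   `labels`, `mask` and `n_effective`.
#' @export
label_track <- function(protein_id, labels, mask = NULL) {
  labels <- as.integer(labels)
  if (is.null(mask)) mask <- rep(1L, length(labels))
  mask <- as.integer(mask)
  if (length(labels) != length(mask)) {
    stop("labels and mask must have equal length", call. = FALSE)
  }
  if (length(labels) < 1L) stop("empty label track", call. = FALSE)
  if (!all(labels[mask == 1L] %in% c(0L, 1L))) {
    stop("labels must be 0/1 where mask == 1", call. = FALSE)
  }
  if (!all(mask %in% c(0L, 1L))) stop("mask must be 0/1", call. = FALSE)
  labels[mask == 0L] <- 0L
  structure(list(protein_id = protein_id, labels = labels, mask = mask,
                 n_effective = sum(mask)),
            class = "label_track")
}

#' @export
print.label_track <- function(x, ...) {
  cat(sprintf("<label_track> %s: %d residues, %d labelled, %d positive\n",
              x$protein_id, length(x$labels), x$n_effective,
              sum(x$labels[x$mask == 1L])))
  invisible(x)
}

#' Build a per-residue prediction table
#'
#' One row per masked-in residue with the predicted binding probability and
#' the hard call at the decision threshold.
#'
#' @param protein_id,position,residue,probability Parallel vectors.
#' @param threshold Decision threshold in (0,1); the hard call is
#'   `probability >= threshold`.
#' @return A `data.frame` with columns `protein_id`, `position` (1-based),
#'   `residue`, `probability`, `call`.
#' @export
prediction_table <- function(protein_id, position, residue, probability,
                             threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  if (any(probability < 0 | probability > 1)) {
    stop("probabilities must lie in [0,1]", call. = FALSE)
  }
  data.frame(protein_id = as.character(protein_id),
             position = as.integer(position),
             residue = as.character(residue),
             probability = as.numeric(probability),
             call = as.integer(probability >= threshold),
             stringsAsFactors = FALSE)
}

# Run the expression with a private RNG stream derived from `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user RNG.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic 31-bit mixing of integer keys (order-sensitive), used to derive
# independent RNG streams from (seed, key...) tuples. Pure double arithmetic
# keeps every intermediate below 2^53 so the result is exact.
mix_seed <- function(...) {
  keys <- c(...)
  h <- 17
  m <- 2147483647 # 2^31 - 1
  for (k in keys) {
    k <- as.numeric(k) %% m
    h <- (h * 31 + k + 1) %% m
    h <- (h * 2654435 + 97) %% m
  }
  as.integer(h)
}

# Stable string -> integer hash (polynomial over code points, mod 2^31-1).
hash_string <- function(s) {
  codes <- utf8ToInt(s)
  h <- 7
  m <- 2147483647
  for (cc in codes) h <- (h * 131 + cc) %% m
  as.integer(h)
}
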