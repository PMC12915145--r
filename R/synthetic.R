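#' Specification of the planted binding rule
#'
#' The synthetic benchmark labels residues by thresholding a linear score of
#' the local mean embedding: `score_i = v . mean(e_{i-h}, ..., e_{i+h})`,
#' with `label = 1` iff `score_i >= b`, after which each label is flipped
#' independently with probability `rho`. The intercept `b` is calibrated so
#' the positive fraction is approximately `pi_target`, emulating the strong
#' class imbalance of experimental binding-site datasets.
#'
#' @param d_p Embedding dimension the rule applies to.
#' @param half_width Window half-width `h` (default 2, i.e. a 5-residue
#'   window — narrower than the model's default 15-residue decoder window so
#'   the signal is locally recoverable).
#' @param rho Label flip probability (default 0.02).
#' @param pi_target Target positive fraction (default 0.12).
#' @param seed Seed for drawing the unit direction vector `v`.
#' @return A list of class `planted_rule` with `v` (unit norm), `half_width`,
#'   `rho`, `pi_target`, `intercept` (NA until calibrated) and `seed`.
#' @export
planted_rule <- function(d_p = 64L, half_width = 2L, rho = 0.02,
                         pi_target = 0.12, seed = 1L) {
  if (pi_target <= 0 || pi_target >= 0.5) {
    stop("pi_target must lie in (0, 0.5)", call. = FALSE)
  }
  if (rho < 0 || rho >= 0.5) stop("rho must lie in [0, 0.5)", call. = FALSE)
  v <- with_seed(mix_seed(seed, 811L), stats::rnorm(as.integer(d_p)))
  v <- v / sqrt(sum(v^2))
  structure(list(v = v, half_width = as.integer(half_width),
                 rho = as.numeric(rho), pi_target = as.numeric(pi_target),
                 intercept = NA_real_, seed = as.integer(seed)),
            class = "planted_rule")
}

#' Generate random protein sequences
#'
#' Residues are i.i.d. uniform over the 20 canonical letters; lengths are
#' uniform over `length_range`. Deterministic per seed.
#'
#' @param n Number of proteins.
#' @param length_range Integer pair `(min, max)` of sequence lengths.
#' @param seed Integer seed.
#' @param prefix Id prefix; ids are `<prefix><i>`.
#' @return List of `protein_record`s.
#' @export
generate_proteins <- function(n, length_range = c(50L, 150L), seed = 1L,
                              prefix = "syn") {
  if (length(length_range) != 2L || length_range[1L] > length_range[2L] ||
      length_range[1L] < 1L) {
    stop("invalid length_range", call. = FALSE)
  }
  with_seed(mix_seed(seed, 101L), {
    len_vals <- length_range[1L]:length_range[2L]
    lens <- len_vals[sample.int(length(len_vals), n, replace = TRUE)]
    lapply(seq_len(n), function(i) {
      protein_record(paste0(prefix, i),
                     paste(sample(AA_LETTERS, lens[i], replace = TRUE),
                           collapse = ""))
    })
  })
}

# Linear rule scores for one embedding matrix: v . mean over [i-h, i+h].
rule_scores <- function(E, rule) {
  if (ncol(E) != length(rule$v)) {
    stop("embedding d_p (", ncol(E), ") does not match rule d_p (",
         length(rule$v), ")", call. = FALSE)
  }
  proj <- as.numeric(E %*% rule$v)
  L <- length(proj)
  h <- rule$half_width
  csum <- c(0, cumsum(proj))
  lo <- pmax(seq_len(L) - h, 1L)
  hi <- pmin(seq_len(L) + h, L)
  (csum[hi + 1L] - csum[lo]) / (hi - lo + 1)
}

#' Calibrate the rule intercept to a target positive fraction
#'
#' Sets `b` to the empirical `(1 - pi)`-quantile of the pooled scores so the
#' expected positive fraction is approximately `pi`.
#'
#' @param scores Pooled numeric scores (>= 100 values).
#' @param pi_target Target positive fraction in (0,1).
#' @return The intercept `b`.
#' @export
calibrate_intercept <- function(scores, pi_target) {
  if (pi_target <= 0 || pi_target >= 1) {
    stop("pi_target must lie in (0,1)", call. = FALSE)
  }
  if (length(scores) < 100L) {
    stop("need at least 100 scores to calibrate the intercept", call. = FALSE)
  }
  as.numeric(stats::quantile(scores, probs = 1 - pi_target, names = FALSE,
                             type = 7))
}

#' Plant labels on synthetic embeddings
#'
#' Applies the rule's threshold to every residue and then flips each label
#' independently with probability `rho`. All residues are masked in.
#'
#' @param embeddings Named list of embedding matrices (names = protein ids),
#'   from the synthetic embedder with the rule's `d_p`.
#' @param rule A calibrated `planted_rule` (finite `intercept`).
#' @param seed Seed for the flip noise.
#' @return Named list of `label_track`s.
#' @export
plant_labels <- function(embeddings, rule, seed = 1L) {
  stopifnot(inherits(rule, "planted_rule"))
  if (is.na(rule$intercept)) {
    stop("rule intercept not calibrated; call calibrate_intercept first",
         call. = FALSE)
  }
  ids <- names(embeddings)
  if (is.null(ids)) stop("embeddings list must be named by protein id",
                         call. = FALSE)
  out <- lapply(ids, function(id) {
    sc <- rule_scores(embeddings[[id]], rule)
    labels <- as.integer(sc >= rule$intercept)
    if (rule$rho > 0) {
      flips <- with_seed(mix_seed(seed, hash_string(id), 577L),
                         stats::runif(length(labels)) < rule$rho)
      labels <- ifelse(flips, 1L - labels, labels)
    }
    label_track(id, labels)
  })
  names(out) <- ids
  out
}

#' Generate a train/validation/test synthetic benchmark
#'
#' Produces disjoint protein sets with embeddings and planted labels under a
#' single shared rule whose intercept is calibrated on the pooled training
#' scores. The returned manifest (spec + seed) regenerates the dataset
#' exactly.
#'
#' @param n_train,n_valid,n_test Number of proteins per split.
#' @param d_p Embedding dimension.
#' @param length_range Sequence length range.
#' @param pi_target Target positive fraction.
#' @param rho Label flip probability.
#' @param half_width Rule window half-width.
#' @param seed Master seed; all internal streams derive from it.
#' @return A list of class `synthetic_benchmark` with elements `train`,
#'   `valid`, `test` (each: `proteins`, `embeddings`, `labels`), the shared
#'   `rule`, `manifest`, and `realized_pi` per split.
#' @export
make_benchmark <- function(n_train = 200L, n_valid = 50L, n_test = 50L,
                           d_p = 64L, length_range = c(50L, 150L),
                           pi_target = 0.12, rho = 0.02, half_width = 2L,
                           seed = 7L) {
  manifest <- list(n_train = as.integer(n_train), n_valid = as.integer(n_valid),
                   n_test = as.integer(n_test), d_p = as.integer(d_p),
                   length_range = as.integer(length_range),
                   pi_target = as.numeric(pi_target), rho = as.numeric(rho),
                   half_width = as.integer(half_width), seed = as.integer(seed))
  splits <- list(train = n_train, valid = n_valid, test = n_test)
  prefixes <- c(train = "tr", valid = "va", test = "te")
  rule <- planted_rule(d_p = d_p, half_width = half_width, rho = rho,
                       pi_target = pi_target, seed = seed)
  parts <- lapply(names(splits), function(part) {
    prot <- generate_proteins(splits[[part]], length_range,
                              seed = mix_seed(seed, hash_string(part)),
                              prefix = prefixes[[part]])
    emb <- lapply(prot, synthetic_embed, d_p = d_p, seed = seed)
    names(emb) <- protein_ids(prot)
    list(proteins = prot, embeddings = emb)
  })
  names(parts) <- names(splits)

  train_scores <- unlist(lapply(parts$train$embeddings, rule_scores, rule = rule),
                         use.names = FALSE)
  rule$intercept <- calibrate_intercept(train_scores, pi_target)

  realized <- numeric(0)
  for (part in names(parts)) {
    parts[[part]]$labels <- plant_labels(parts[[part]]$embeddings, rule,
                                         seed = mix_seed(seed, hash_string(part), 3L))
    pos <- sum(vapply(parts[[part]]$labels, function(tr) sum(tr$labels), numeric(1L)))
    tot <- sum(vapply(parts[[part]]$labels, function(tr) tr$n_effective, numeric(1L)))
    realized[part] <- pos / tot
  }
  structure(c(parts, list(rule = rule, manifest = manifest,
                          realized_pi = realized)),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_benchmark> %d/%d/%d proteins, d_p=%d, pi=%.3g, rho=%.3g, seed=%d\n",
              m$n_train, m$n_valid, m$n_test, m$d_p, m$pi_target, m$rho, m$seed))
  cat("  realized positive fraction:",
      paste(sprintf("%s=%.3f", names(x$realized_pi), x$realized_pi),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write a synthetic benchmark to disk
#'
#' Writes per-split FASTA and label TSV files plus a `manifest.json` from
#' which [make_benchmark()] regenerates the dataset exactly.
#'
#' @param bench A `synthetic_benchmark`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, dir) {
  stopifnot(inherits(bench, "synthetic_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (part in c("train", "valid", "test")) {
    write_fasta(bench[[part]]$proteins, file.path(dir, paste0(part, ".fasta")))
    write_labels(bench[[part]]$labels, file.path(dir, paste0(part, "_labels.tsv")))
  }
  jsonlite::write_json(bench$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Regenerate a benchmark from its manifest
#' @param path Path to a `manifest.json` written by [write_benchmark()].
#' @return A `synthetic_benchmark` identical to the one the manifest records.
#' @export
read_benchmark_manifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  make_benchmark(n_train = m$n_train, n_valid = m$n_valid, n_test = m$n_test,
                 d_p = m$d_p, length_range = m$length_range,
                 pi_target = m$pi_target, rho = m$rho,
                 half_width = m$half_width, seed = m$seed)
}
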