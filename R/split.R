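#' Randomly split protein ids into disjoint subsets
#'
#' Deterministic for a fixed `(ids, seed)` pair. Part sizes are floors of the
#' fractional shares, with the remainder assigned to the part with the
#' largest fraction, so the sizes always sum to `length(ids)`. The canonical
#' use is the 8:2 train/validation split of the repeated-split training
#' scheme.
#'
#' @param ids Character vector of unique protein ids.
#' @param fractions Numeric vector summing to 1 (within 1e-9); one entry per
#'   part. Names, if present, name the parts; otherwise parts are named
#'   `train`, `valid`, `test` (first three) or `part<i>`.
#' @param seed Integer seed.
#' @return A list of class `dataset_split` with one character vector of ids
#'   per part, plus attribute `seed`.
#' @export
split_dataset <- function(ids, fractions = c(train = 0.8, valid = 0.2),
                          seed = 1L) {
  ids <- as.character(ids)
  check_unique_ids(ids)
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1 (got ", sum(fractions), ")", call. = FALSE)
  }
  if (any(fractions < 0)) stop("fractions must be nonnegative", call. = FALSE)
  n_parts <- sum(fractions > 0)
  if (length(ids) < n_parts) {
    stop("need at least ", n_parts, " ids for ", n_parts, " nonempty parts",
         call. = FALSE)
  }
  nm <- names(fractions)
  if (is.null(nm)) {
    defaults <- c("train", "valid", "test")
    nm <- if (length(fractions) <= 3L) defaults[seq_along(fractions)]
          else paste0("part", seq_along(fractions))
  }
  sizes <- floor(fractions * length(ids))
  rem <- length(ids) - sum(sizes)
  if (rem > 0L) sizes[which.max(fractions)] <- sizes[which.max(fractions)] + rem
  perm <- with_seed(seed, sample(ids, length(ids)))
  out <- vector("list", length(fractions))
  names(out) <- nm
  offset <- 0L
  for (i in seq_along(sizes)) {
    out[[i]] <- sort(perm[seq_len(sizes[i]) + offset])
    offset <- offset + sizes[i]
  }
  structure(out, seed = as.integer(seed), class = "dataset_split")
}

#' @export
print.dataset_split <- function(x, ...) {
  cat("<dataset_split> seed =", attr(x, "seed"), "\n")
  for (nm in names(x)) cat(sprintf("  %-8s %d ids\n", nm, length(x[[nm]])))
  invisible(x)
}

#' K-fold cross-validation assignments
#'
#' Every id appears in exactly one validation fold; fold sizes differ by at
#' most one (larger folds first). Deterministic for fixed `(ids, K, seed)`.
#'
#' @param ids Character vector of unique ids.
#' @param K Number of folds, `2 <= K <= length(ids)`.
#' @param seed Integer seed.
#' @return List of `K` `dataset_split`s, each with parts `train` and `valid`.
#' @export
kfold_indices <- function(ids, K = 5L, seed = 1L) {
  ids <- as.character(ids)
  check_unique_ids(ids)
  K <- as.integer(K)
  if (K < 2L) stop("K must be at least 2", call. = FALSE)
  if (K > length(ids)) stop("K (", K, ") exceeds number of ids (",
                            length(ids), ")", call. = FALSE)
  perm <- with_seed(seed, sample(ids, length(ids)))
  base <- length(ids) %/% K
  extra <- length(ids) %% K
  sizes <- rep(base, K) + c(rep(1L, extra), rep(0L, K - extra))
  bounds <- cumsum(c(0L, sizes))
  lapply(seq_len(K), function(k) {
    valid <- sort(perm[(bounds[k] + 1L):bounds[k + 1L]])
    structure(list(train = sort(setdiff(ids, valid)), valid = valid),
              seed = as.integer(seed), fold = k, class = "dataset_split")
  })
}
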