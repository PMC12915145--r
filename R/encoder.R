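# Gated convolutional protein feature encoder: input projection, stacked
# Conv1D + GLU blocks with scaled residual connections, final layer norm.
# These are the reference (pure R) implementations; training and batch
# prediction run through the compiled core, which is tested against them.

LN_EPS <- 1e-5
RESIDUAL_SCALE <- sqrt(0.5)

#' Gated linear unit
#'
#' Maps a vector (or matrix rows) of `2d` values to `d` values:
#' `out_j = a_j * sigmoid(b_j)` where `a` and `b` are the first and second
#' halves of the input.
#'
#' @param x Numeric vector of even length, or a matrix with an even number
#'   of columns (applied rowwise).
#' @return The gated half-size vector/matrix.
#' @export
glu <- function(x) {
  if (is.matrix(x)) {
    d2 <- ncol(x)
    if (d2 %% 2L != 0L) stop("GLU input dimension must be even", call. = FALSE)
    d <- d2 %/% 2L
    a <- x[, seq_len(d), drop = FALSE]
    b <- x[, d + seq_len(d), drop = FALSE]
    a * stats::plogis(b)
  } else {
    d2 <- length(x)
    if (d2 %% 2L != 0L) stop("GLU input dimension must be even", call. = FALSE)
    d <- d2 %/% 2L
    x[seq_len(d)] * stats::plogis(x[d + seq_len(d)])
  }
}

# im2col for a 1-D convolution over the rows of H (L x d): row i of the
# result concatenates H[i - c .. i + c, ] (zero outside), tap-major.
im2col <- function(H, kernel_size) {
  L <- nrow(H); d <- ncol(H)
  c_half <- (kernel_size - 1L) %/% 2L
  out <- matrix(0, nrow = L, ncol = kernel_size * d)
  for (tap in seq_len(kernel_size)) {
    offset <- tap - 1L - c_half
    src <- seq_len(L) + offset
    ok <- src >= 1L & src <= L
    cols <- (tap - 1L) * d + seq_len(d)
    out[ok, cols] <- H[src[ok], , drop = FALSE]
  }
  out
}

#' One convolution + GLU encoder block
#'
#' Computes `H' = (H + GLU(Conv(H))) * s` with `s = sqrt(0.5)`: a width-`k`
#' 1-D convolution producing `2 d_hid` channels, gated down to `d_hid`, and
#' a scaled residual connection. Sequence length is preserved by zero
#' padding of `(k-1)/2` on each side. Masked positions are re-zeroed after
#' the block so padding never leaks into real positions.
#'
#' @param H `L x d_hid` input matrix (one protein).
#' @param layer_params List with `W` (`(k*d_hid) x (2*d_hid)`, tap-major
#'   rows) and `b` (length `2*d_hid`).
#' @param mask Optional 0/1 vector of length `L`; 0 rows are zeroed.
#' @return The transformed `L x d_hid` matrix.
#' @export
conv_glu_block <- function(H, layer_params, mask = NULL) {
  d <- ncol(H)
  k <- nrow(layer_params$W) / d
  if (k != round(k)) {
    stop("conv weight rows (", nrow(layer_params$W),
         ") not a multiple of input channels (", d, ")", call. = FALSE)
  }
  if (ncol(layer_params$W) != 2L * d) {
    stop("conv must produce 2*d_hid channels", call. = FALSE)
  }
  U <- im2col(H, as.integer(k))
  C <- sweep(U %*% layer_params$W, 2L, layer_params$b, "+")
  out <- (H + glu(C)) * RESIDUAL_SCALE
  if (!is.null(mask)) out[mask == 0, ] <- 0
  out
}

#' Rowwise layer normalization
#'
#' Each row is standardized to zero mean and unit (population) variance
#' across features, then scaled and shifted by the learned gain and bias.
#'
#' @param M Numeric matrix (positions x features).
#' @param g,b Gain and bias vectors of length `ncol(M)`.
#' @param eps Variance floor.
#' @return Normalized matrix.
#' @export
layer_norm <- function(M, g, b, eps = LN_EPS) {
  mu <- rowMeans(M)
  centered <- M - mu
  v <- rowMeans(centered^2)
  xhat <- centered / sqrt(v + eps)
  sweep(sweep(xhat, 2L, g, "*"), 2L, b, "+")
}

#' Encode a batch of proteins
#'
#' Reference implementation of the full encoder: input projection (a single
#' affine map), `n_enc_layers` convolution + GLU blocks with scaled
#' residuals, and a final per-position layer normalization. Each protein is
#' processed on its real length (convolution zero-padding applies at true
#' sequence ends only), so batch padding cannot influence real positions;
#' padded rows of the output are exactly zero.
#'
#' @param P_batch A padded batch from [pad_batch()] (or a single `L x d_p`
#'   matrix, treated as a batch of one).
#' @param params Model parameter list from [init_model_params()].
#' @param config A `run_config`.
#' @return For a batch: `B x L_max x d_hid` array; for a single matrix:
#'   `L x d_hid` matrix.
#' @export
encode <- function(P_batch, params, config) {
  single <- is.matrix(P_batch)
  if (single) P_batch <- pad_batch(list(P_batch))
  B <- dim(P_batch$values)[1L]
  L_max <- dim(P_batch$values)[2L]
  out <- array(0, dim = c(B, L_max, config$d_hid))
  for (bi in seq_len(B)) {
    L <- P_batch$lengths[bi]
    X <- matrix(P_batch$values[bi, seq_len(L), ], nrow = L)
    out[bi, seq_len(L), ] <- encode_one(X, params, config)
  }
  if (single) matrix(out[1L, , ], nrow = L_max) else out
}

encode_one <- function(X, params, config) {
  H <- sweep(X %*% params$enc_in_W, 2L, params$enc_in_b, "+")
  for (l in seq_len(config$n_enc_layers)) {
    lp <- list(W = params[[paste0("enc_conv_W", l)]],
               b = params[[paste0("enc_conv_b", l)]])
    H <- conv_glu_block(H, lp)
  }
  layer_norm(H, params$enc_ln_g, params$enc_ln_b)
}
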