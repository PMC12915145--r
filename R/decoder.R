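# Cross-attention decoder over per-residue local windows, plus the
# significance-weighted aggregation and the fully connected classifier.
# Reference (pure R) implementations of the op surface; the compiled core
# used by train/predict implements identical arithmetic.

#' Build local context windows for target residues
#'
#' For each target residue i, gathers the window
#' `[i - (L_l-1)/2, i + (L_l-1)/2]` of projected embeddings. Slots that
#' overhang a sequence end are zero with window mask 0; a learned
#' within-window position embedding is added to valid slots.
#'
#' @param P_projected `L x d_hid` matrix of projected residue embeddings.
#' @param positions 1-based target residue positions.
#' @param L_l Odd window length.
#' @param pos_emb Optional `L_l x d_hid` position embedding matrix.
#' @return List with `L` (`B x L_l x d_hid` array), `M_l` (`B x L_l` 0/1
#'   matrix) and `center_index` (slot of the target residue, `(L_l+1)/2`).
#' @export
build_local_context <- function(P_projected, positions, L_l, pos_emb = NULL) {
  L_l <- as.integer(L_l)
  if (L_l %% 2L != 1L) stop("window length L_l must be odd", call. = FALSE)
  L <- nrow(P_projected)
  if (any(positions < 1L | positions > L)) {
    stop("positions out of range 1..", L, call. = FALSE)
  }
  c_half <- (L_l - 1L) %/% 2L
  B <- length(positions)
  H <- ncol(P_projected)
  win <- array(0, dim = c(B, L_l, H))
  M_l <- matrix(0L, nrow = B, ncol = L_l)
  for (b in seq_len(B)) {
    src <- positions[b] + (seq_len(L_l) - 1L - c_half)
    ok <- src >= 1L & src <= L
    rows <- P_projected[src[ok], , drop = FALSE]
    if (!is.null(pos_emb)) rows <- rows + pos_emb[ok, , drop = FALSE]
    win[b, ok, ] <- rows
    M_l[b, ok] <- 1L
  }
  list(L = win, M_l = M_l, center_index = c_half + 1L)
}

#' Scaled dot-product attention
#'
#' `weights = softmax(Q K' / sqrt(d_k))` with masked keys excluded (they
#' receive exactly zero weight); `output = weights V`.
#'
#' @param Q `n_q x d_k` query matrix.
#' @param K,V `n_k x d_k` / `n_k x d_v` key and value matrices.
#' @param key_mask Optional 0/1 vector over keys; 0 = masked out.
#' @return List with `output` (`n_q x d_v`) and `weights` (`n_q x n_k`).
#' @export
attention <- function(Q, K, V, key_mask = NULL) {
  if (ncol(Q) != ncol(K)) stop("Q and K must share d_k", call. = FALSE)
  if (nrow(K) != nrow(V)) stop("K and V must have equal row counts", call. = FALSE)
  if (is.null(key_mask)) key_mask <- rep(1L, nrow(K))
  if (length(key_mask) != nrow(K)) {
    stop("key_mask must align with K rows", call. = FALSE)
  }
  valid <- key_mask != 0L
  if (!any(valid)) stop("all keys masked", call. = FALSE)
  scores <- Q %*% t(K) / sqrt(ncol(Q))
  W <- masked_softmax_rows(scores, valid)
  list(output = W %*% V, weights = W)
}

# Rowwise softmax over valid columns only; masked columns get exactly 0.
masked_softmax_rows <- function(scores, valid) {
  sub <- scores[, valid, drop = FALSE]
  m <- apply(sub, 1L, max)
  ex <- exp(sub - m)
  W <- matrix(0, nrow = nrow(scores), ncol = ncol(scores))
  W[, valid] <- ex / rowSums(ex)
  W
}

# Multi-head attention: full H x H projections, per-head scaled dot-product,
# concatenation, output projection.
multi_head_attention <- function(Xq, Xkv, p, n_heads, key_mask = NULL) {
  H <- ncol(Xq)
  dk <- H %/% n_heads
  Q <- sweep(Xq %*% p$Wq, 2L, p$bq, "+")
  K <- sweep(Xkv %*% p$Wk, 2L, p$bk, "+")
  V <- sweep(Xkv %*% p$Wv, 2L, p$bv, "+")
  out <- matrix(0, nrow = nrow(Xq), ncol = H)
  for (h in seq_len(n_heads)) {
    cols <- (h - 1L) * dk + seq_len(dk)
    att <- attention(Q[, cols, drop = FALSE], K[, cols, drop = FALSE],
                     V[, cols, drop = FALSE], key_mask)
    out[, cols] <- att$output
  }
  sweep(out %*% p$Wo, 2L, p$bo, "+")
}

#' One decoder layer
#'
#' Self-attention over the local window (keys masked by the window mask),
#' cross-attention with window queries against the encoded protein (keys
#' masked by the padding mask), and a position-wise feed-forward network
#' (two width-1 convolutions `d_hid -> d_ff -> d_hid` with ReLU between).
#' Each sublayer is wrapped in a residual connection and layer
#' normalization; there is no causal mask. Invalid window slots are
#' re-zeroed after every sublayer.
#'
#' @param L_state `B x L_l x d_hid` window array (see
#'   [build_local_context()]).
#' @param H_p `L x d_hid` encoded protein features.
#' @param M_l `B x L_l` window validity mask.
#' @param M_p Optional 0/1 vector over `H_p` rows (padding mask).
#' @param layer_params Named list with self-attention (`sa`),
#'   cross-attention (`ca`), feed-forward (`ff_W1`, `ff_b1`, `ff_W2`,
#'   `ff_b2`) and layer-norm (`ln1_g` ... `ln3_b`) parameters.
#' @param n_heads Number of attention heads.
#' @return Updated `B x L_l x d_hid` array.
#' @export
decoder_layer <- function(L_state, H_p, M_l, M_p = NULL, layer_params,
                          n_heads = 8L) {
  B <- dim(L_state)[1L]
  W <- dim(L_state)[2L]
  Hd <- dim(L_state)[3L]
  if (ncol(H_p) != Hd) stop("channel mismatch between window and encoder",
                            call. = FALSE)
  if (is.null(M_p)) M_p <- rep(1L, nrow(H_p))
  lp <- layer_params
  out <- array(0, dim = dim(L_state))
  for (b in seq_len(B)) {
    Ti <- matrix(L_state[b, , ], nrow = W)
    ml <- M_l[b, ]
    sa <- multi_head_attention(Ti, Ti, lp$sa, n_heads, key_mask = ml)
    T1 <- layer_norm(Ti + sa, lp$ln1_g, lp$ln1_b)
    T1[ml == 0L, ] <- 0
    ca <- multi_head_attention(T1, H_p, lp$ca, n_heads, key_mask = M_p)
    T2 <- layer_norm(T1 + ca, lp$ln2_g, lp$ln2_b)
    T2[ml == 0L, ] <- 0
    ff <- sweep(pmax(sweep(T2 %*% lp$ff_W1, 2L, lp$ff_b1, "+"), 0) %*% lp$ff_W2,
                2L, lp$ff_b2, "+")
    T3 <- layer_norm(T2 + ff, lp$ln3_g, lp$ln3_b)
    T3[ml == 0L, ] <- 0
    out[b, , ] <- T3
  }
  out
}

#' Significance-weighted aggregation of window features
#'
#' Combines the window rows into one vector per residue with softmax
#' weights derived from the feature norms:
#' `weight_j = exp(||H_j||) / sum_k exp(||H_k||)` over valid rows (masked
#' rows are excluded), stabilized by subtracting the maximum norm. The
#' result is a convex combination of the valid rows. With
#' `norm_squared = TRUE` the squared norm is used instead.
#'
#' @param H_window `B x L_l x d_hid` array, or a single `L_l x d_hid`
#'   matrix.
#' @param M_l `B x L_l` validity mask (or a vector for a single window);
#'   each window needs at least one valid row.
#' @param norm_squared Use `||H||^2` in place of `||H||`.
#' @return `B x d_hid` matrix (or a vector for a single window).
#' @export
aggregate_significance <- function(H_window, M_l = NULL, norm_squared = FALSE) {
  single <- is.matrix(H_window)
  if (single) {
    H_window <- array(H_window, dim = c(1L, nrow(H_window), ncol(H_window)))
    if (!is.null(M_l)) M_l <- matrix(M_l, nrow = 1L)
  }
  B <- dim(H_window)[1L]; W <- dim(H_window)[2L]; Hd <- dim(H_window)[3L]
  if (is.null(M_l)) M_l <- matrix(1L, B, W)
  out <- matrix(0, nrow = B, ncol = Hd)
  for (b in seq_len(B)) {
    valid <- which(M_l[b, ] != 0L)
    if (!length(valid)) stop("all window rows masked", call. = FALSE)
    rows <- matrix(H_window[b, valid, ], nrow = length(valid))
    nrm <- sqrt(rowSums(rows^2))
    if (norm_squared) nrm <- nrm^2
    wgt <- exp(nrm - max(nrm))
    wgt <- wgt / sum(wgt)
    out[b, ] <- colSums(rows * wgt)
  }
  if (single) out[1L, ] else out
}

#' Classify aggregated representations
#'
#' Three affine layers `d_hid -> 64 -> 32 -> 2` with ReLU after the first
#' two; the binding probability is the softmax mass of class 1.
#'
#' @param H_agg `B x d_hid` matrix (or a single vector).
#' @param params Model parameter list (uses `cls_W1` ... `cls_b3`).
#' @return List with `z` (`B x 2` logits) and `probability` (length-B
#'   vector).
#' @export
classify <- function(H_agg, params) {
  if (!is.matrix(H_agg)) H_agg <- matrix(H_agg, nrow = 1L)
  Z1 <- pmax(sweep(H_agg %*% params$cls_W1, 2L, params$cls_b1, "+"), 0)
  Z2 <- pmax(sweep(Z1 %*% params$cls_W2, 2L, params$cls_b2, "+"), 0)
  z <- sweep(Z2 %*% params$cls_W3, 2L, params$cls_b3, "+")
  m <- pmax(z[, 1L], z[, 2L])
  e1 <- exp(z[, 1L] - m); e2 <- exp(z[, 2L] - m)
  list(z = z, probability = e2 / (e1 + e2))
}

# Per-layer parameter view for the reference decoder.
dec_layer_params <- function(params, l) {
  g <- function(nm) params[[paste0("dec", l, "_", nm)]]
  list(sa = list(Wq = g("sa_Wq"), bq = g("sa_bq"), Wk = g("sa_Wk"),
                 bk = g("sa_bk"), Wv = g("sa_Wv"), bv = g("sa_bv"),
                 Wo = g("sa_Wo"), bo = g("sa_bo")),
       ln1_g = g("ln1_g"), ln1_b = g("ln1_b"),
       ca = list(Wq = g("ca_Wq"), bq = g("ca_bq"), Wk = g("ca_Wk"),
                 bk = g("ca_bk"), Wv = g("ca_Wv"), bv = g("ca_bv"),
                 Wo = g("ca_Wo"), bo = g("ca_bo")),
       ln2_g = g("ln2_g"), ln2_b = g("ln2_b"),
       ff_W1 = g("ff_W1"), ff_b1 = g("ff_b1"),
       ff_W2 = g("ff_W2"), ff_b2 = g("ff_b2"),
       ln3_g = g("ln3_g"), ln3_b = g("ln3_b"))
}

#' Reference forward pass (pure R)
#'
#' Composes the exported ops — encode, window construction, decoder layers,
#' significance aggregation, classifier — into residue-level binding
#' probabilities. Slow but transparent; the compiled path used by
#' [predict_protein()] must agree with it to numerical precision, which the
#' test suite checks.
#'
#' @param X `L x d_p` embedding matrix of one protein.
#' @param params Model parameters.
#' @param config A `run_config`.
#' @param positions Target residues (default all).
#' @return Numeric vector of binding probabilities.
#' @export
reference_forward <- function(X, params, config, positions = seq_len(nrow(X))) {
  H_p <- encode_one(X, params, config)
  P_proj <- sweep(X %*% params$dec_in_W, 2L, params$dec_in_b, "+")
  ctx <- build_local_context(P_proj, positions, config$window_size,
                             pos_emb = params$pos_emb)
  state <- ctx$L
  for (l in seq_len(config$n_dec_layers)) {
    state <- decoder_layer(state, H_p, ctx$M_l, M_p = NULL,
                           layer_params = dec_layer_params(params, l),
                           n_heads = config$n_heads)
  }
  H_agg <- aggregate_significance(state, ctx$M_l,
                                  norm_squared = config$norm_squared)
  classify(H_agg, params)$probability
}
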