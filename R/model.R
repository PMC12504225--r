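# Transformer auto-encoder: patch embedding, sinusoidal positional encoding,
# learnable mask token, post-norm self-attention blocks, and affine output
# heads (reconstruction or moment regression).  Forward and backward passes
# are written out explicitly; multi-head attention runs through the compiled
# kernels in src/attention.cpp.
#
# Batch layout: a batch of B windows of length W is a (B*W) x d matrix in
# which window b occupies rows (b-1)*W + 1 ... b*W.

#' Architecture hyperparameters of the Transformer auto-encoder
#'
#' Defaults follow the reference configuration: 64-sample windows, patch
#' length 1, model width 24, eight post-norm self-attention blocks with 12
#' heads and a 2048-unit feed-forward layer, ReLU activation, dropout 0.1.
#'
#' @param window Window length W in samples.
#' @param patch_length Patch length (must divide `window`; 1 = one time step
#'   per token).
#' @param n_channels_in Input channels (18 for pre-training; 2 per-joint,
#'   1 per-channel fine-tuning).
#' @param n_channels_out Output channels (defaults to `n_channels_in` for
#'   reconstruction).
#' @param d_model Token embedding width (divisible by `n_heads`).
#' @param n_blocks Number of self-attention blocks.
#' @param n_heads Attention heads per block.
#' @param ffn_dim Feed-forward hidden width.
#' @param dropout Dropout probability in `[0, 1)`.
#' @param layernorm_eps Layer-normalization epsilon.
#' @return Object of class `model_spec`.
#' @export
model_spec <- function(window = 64L, patch_length = 1L, n_channels_in = 18L,
                       n_channels_out = n_channels_in, d_model = 24L,
                       n_blocks = 8L, n_heads = 12L, ffn_dim = 2048L,
                       dropout = 0.1, layernorm_eps = 1e-5) {
  if (window %% patch_length != 0)
    stop_invalid("patch_length must divide window")
  if (d_model %% n_heads != 0)
    stop_invalid("d_model must be divisible by n_heads")
  if (dropout < 0 || dropout >= 1) stop_invalid("dropout must be in [0, 1)")
  structure(list(window = as.integer(window),
                 patch_length = as.integer(patch_length),
                 n_channels_in = as.integer(n_channels_in),
                 n_channels_out = as.integer(n_channels_out),
                 d_model = as.integer(d_model),
                 n_blocks = as.integer(n_blocks),
                 n_heads = as.integer(n_heads),
                 ffn_dim = as.integer(ffn_dim),
                 dropout = dropout, layernorm_eps = layernorm_eps,
                 activation = "relu"),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(
    "<model_spec> W=%d patch=%d in=%d out=%d d=%d blocks=%d heads=%d ffn=%d\n",
    x$window, x$patch_length, x$n_channels_in, x$n_channels_out, x$d_model,
    x$n_blocks, x$n_heads, x$ffn_dim))
  invisible(x)
}

n_patches <- function(spec) spec$window %/% spec$patch_length
patch_width_in <- function(spec) spec$patch_length * spec$n_channels_in
patch_width_out <- function(spec) spec$patch_length * spec$n_channels_out

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize model parameters for a given architecture
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for the weight draw.
#' @return Object of class `gait_model`: `spec`, named parameter list
#'   `params`, character vector `frozen` (empty initially).
#' @export
init_model <- function(spec, seed = 1L) {
  d <- spec$d_model
  params <- with_substream(seed, "init", 0L, {
    p <- list()
    p[["embed.W"]] <- glorot(patch_width_in(spec), d)
    p[["embed.b"]] <- numeric(d)
    p[["mask_token"]] <- rnorm(d, 0, 0.02)
    for (i in seq_len(spec$n_blocks)) {
      pre <- sprintf("block%02d.", i)
      for (nm in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, nm)]] <- glorot(d, d)
      for (nm in c("bq", "bk", "bv", "bo")) p[[paste0(pre, nm)]] <- numeric(d)
      p[[paste0(pre, "ln1.g")]] <- rep(1, d)
      p[[paste0(pre, "ln1.b")]] <- numeric(d)
      p[[paste0(pre, "W1")]] <- glorot(d, spec$ffn_dim)
      p[[paste0(pre, "b1")]] <- numeric(spec$ffn_dim)
      p[[paste0(pre, "W2")]] <- glorot(spec$ffn_dim, d)
      p[[paste0(pre, "b2")]] <- numeric(d)
      p[[paste0(pre, "ln2.g")]] <- rep(1, d)
      p[[paste0(pre, "ln2.b")]] <- numeric(d)
    }
    p[["head.W"]] <- glorot(d, patch_width_out(spec))
    p[["head.b"]] <- numeric(patch_width_out(spec))
    p
  })
  structure(list(spec = spec, params = params, frozen = character(0)),
            class = "gait_model")
}

#' @export
print.gait_model <- function(x, ...) {
  cat("<gait_model>", format(count_params(x)$total, big.mark = ","),
      "parameters;", length(x$frozen), "frozen tensors\n")
  print(x$spec)
  invisible(x)
}

#' Parameter counts of a model
#'
#' @param model A `gait_model` (or [model_spec()], which is initialized
#'   internally with dummy weights).
#' @return List with `total`, `encoder` (embedding + mask token + blocks),
#'   `head`, and per-tensor counts.
#' @export
count_params <- function(model) {
  if (inherits(model, "model_spec")) model <- init_model(model, seed = 0L)
  sizes <- vapply(model$params, length, integer(1))
  head_n <- sum(sizes[grepl("^head\\.", names(sizes))])
  list(total = sum(sizes), encoder = sum(sizes) - head_n, head = head_n,
       by_tensor = sizes)
}

# ---------------------------------------------------------------------------
# building blocks

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i+1] = sin(pos / 10000^(2i/d))`,
#' `PE[pos, 2i+2] = cos(pos / 10000^(2i/d))` with `pos = 0 ... n-1` and
#' `i = 0 ... d/2 - 1`.
#'
#' @param n_positions Number of positions.
#' @param d_model Even embedding width.
#' @return `n_positions` x `d_model` matrix with entries in `[-1, 1]`.
#' @export
positional_encoding <- function(n_positions, d_model) {
  if (d_model %% 2 != 0) stop_invalid("d_model must be even")
  pos <- seq_len(n_positions) - 1
  i <- seq_len(d_model / 2) - 1
  ang <- outer(pos, 1 / 10000^(2 * i / d_model))
  pe <- matrix(0, n_positions, d_model)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

#' Linear patch embedding
#'
#' Maps each patch (one time step across channels for patch length 1) to a
#' `d_model`-vector with a single affine map shared across positions.
#'
#' @param window `window` x `n_channels_in` matrix.
#' @param model A `gait_model`.
#' @return `n_patches` x `d_model` token matrix.
#' @export
embed_patches <- function(window, model) {
  spec <- model$spec
  if (!all(dim(window) == c(spec$window, spec$n_channels_in)))
    stop_schema("window must be ", spec$window, " x ", spec$n_channels_in,
                ", got ", nrow(window), " x ", ncol(window))
  P <- patches_matrix(window, spec)
  sweep(P %*% model$params[["embed.W"]], 2, model$params[["embed.b"]], "+")
}

# reshape (W x C) into (n_patches x patch_length*C), rows = patches
patches_matrix <- function(window, spec) {
  if (spec$patch_length == 1L) return(window)
  np <- n_patches(spec)
  out <- matrix(0, np, patch_width_in(spec))
  for (p in seq_len(np)) {
    rows <- ((p - 1) * spec$patch_length + 1):(p * spec$patch_length)
    out[p, ] <- as.vector(window[rows, , drop = FALSE])
  }
  out
}

#' Masking specification for masked-reconstruction pre-training
#'
#' @param ratio Fraction of patches to mask, in `[0, 1)`; the per-window
#'   masked count is `round(ratio * n_patches)` (a fixed count per window, so
#'   the pretext loss has stable support).
#' @param seed Integer seed.
#' @return Object of class `mask_spec`.
#' @export
mask_spec <- function(ratio = 0.10, seed = 1L) {
  if (ratio < 0 || ratio >= 1) stop_invalid("mask ratio must be in [0, 1)")
  structure(list(ratio = ratio, seed = as.integer(seed)), class = "mask_spec")
}

#' Replace randomly chosen token positions with the learnable mask token
#'
#' @param tokens `n_patches` x `d_model` token matrix.
#' @param mask A [mask_spec()].
#' @param model A `gait_model` supplying the mask token.
#' @return List with `tokens` (masked) and `masked_idx` (sorted positions).
#' @export
apply_mask <- function(tokens, mask, model) {
  np <- nrow(tokens)
  k <- round(mask$ratio * np)
  if (k >= np)
    stop_invalid("mask ratio ", mask$ratio, " leaves no visible patch")
  idx <- sort(with_substream(mask$seed, "mask", 0L, sample(np, k)))
  if (k > 0)
    tokens[idx, ] <- matrix(model$params[["mask_token"]], k,
                            ncol(tokens), byrow = TRUE)
  list(tokens = tokens, masked_idx = idx)
}

# draw per-window mask indices for a batch (uses the current RNG stream)
draw_batch_mask <- function(B, np, ratio) {
  k <- round(ratio * np)
  if (k >= np) stop_invalid("mask ratio leaves no visible patch")
  if (k == 0L) return(integer(0))
  idx <- integer(B * k)
  for (b in seq_len(B))
    idx[((b - 1) * k + 1):(b * k)] <- (b - 1) * np + sample(np, k)
  sort(idx)
}

layernorm_fwd <- function(x, g, b, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + eps)
  xhat <- xc * invstd
  list(y = sweep(xhat, 2, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, invstd = invstd)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2, g, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$invstd
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

addbias <- function(X, b) X + rep(b, each = nrow(X))

# ---------------------------------------------------------------------------
# full forward / backward

# X: (B*W') x pw input patch matrix (W' = n_patches); mask_idx: global row
# indices replaced by the mask token; training: dropout + caches active.
model_forward_pass <- function(model, X, W, mask_idx = integer(0),
                               training = FALSE) {
  spec <- model$spec
  p <- model$params
  d <- spec$d_model
  drop_p <- if (training) spec$dropout else 0
  tok <- addbias(X %*% p[["embed.W"]], p[["embed.b"]])
  if (length(mask_idx))
    tok[mask_idx, ] <- matrix(p[["mask_token"]], length(mask_idx), d,
                              byrow = TRUE)
  B <- nrow(X) %/% W
  tok <- tok + positional_encoding(W, d)[rep(seq_len(W), B), ]
  caches <- if (training) vector("list", spec$n_blocks)
  Xc <- tok
  for (i in seq_len(spec$n_blocks)) {
    pre <- sprintf("block%02d.", i)
    Q <- addbias(Xc %*% p[[paste0(pre, "Wq")]], p[[paste0(pre, "bq")]])
    K <- addbias(Xc %*% p[[paste0(pre, "Wk")]], p[[paste0(pre, "bk")]])
    V <- addbias(Xc %*% p[[paste0(pre, "Wv")]], p[[paste0(pre, "bv")]])
    mh <- .mha_forward_cpp(Q, K, V, W, spec$n_heads, training)
    O <- addbias(mh$out %*% p[[paste0(pre, "Wo")]], p[[paste0(pre, "bo")]])
    if (drop_p > 0) {
      dm1 <- matrix((runif(length(O)) >= drop_p) / (1 - drop_p),
                    nrow(O), ncol(O))
      O <- O * dm1
    } else dm1 <- NULL
    a1 <- Xc + O
    ln1 <- layernorm_fwd(a1, p[[paste0(pre, "ln1.g")]],
                         p[[paste0(pre, "ln1.b")]], spec$layernorm_eps)
    X1 <- ln1$y
    H <- addbias(X1 %*% p[[paste0(pre, "W1")]], p[[paste0(pre, "b1")]])
    Hr <- pmax(H, 0)
    FF <- addbias(Hr %*% p[[paste0(pre, "W2")]], p[[paste0(pre, "b2")]])
    if (drop_p > 0) {
      dm2 <- matrix((runif(length(FF)) >= drop_p) / (1 - drop_p),
                    nrow(FF), ncol(FF))
      FF <- FF * dm2
    } else dm2 <- NULL
    a2 <- X1 + FF
    ln2 <- layernorm_fwd(a2, p[[paste0(pre, "ln2.g")]],
                         p[[paste0(pre, "ln2.b")]], spec$layernorm_eps)
    if (training)
      caches[[i]] <- list(Xin = Xc, Q = Q, K = K, V = V,
                          attn = mh$weights, A = mh$out, dm1 = dm1,
                          ln1 = ln1, X1 = X1, relu = H > 0, Hr = Hr,
                          dm2 = dm2, ln2 = ln2)
    Xc <- ln2$y
  }
  Y <- addbias(Xc %*% p[["head.W"]], p[["head.b"]])
  list(Y = Y, Xlast = Xc, tok = tok, caches = caches, X = X,
       mask_idx = mask_idx, W = W, B = B)
}

# dY: gradient of the loss w.r.t. the head output
model_backward_pass <- function(model, fwd, dY) {
  spec <- model$spec
  p <- model$params
  g <- list()
  g[["head.W"]] <- t(fwd$Xlast) %*% dY
  g[["head.b"]] <- colSums(dY)
  dX <- dY %*% t(p[["head.W"]])
  for (i in rev(seq_len(spec$n_blocks))) {
    pre <- sprintf("block%02d.", i)
    cc <- fwd$caches[[i]]
    l2 <- layernorm_bwd(dX, cc$ln2, p[[paste0(pre, "ln2.g")]])
    g[[paste0(pre, "ln2.g")]] <- l2$dg
    g[[paste0(pre, "ln2.b")]] <- l2$db
    da2 <- l2$dx
    dFF <- if (is.null(cc$dm2)) da2 else da2 * cc$dm2
    g[[paste0(pre, "W2")]] <- t(cc$Hr) %*% dFF
    g[[paste0(pre, "b2")]] <- colSums(dFF)
    dHr <- dFF %*% t(p[[paste0(pre, "W2")]])
    dH <- dHr * cc$relu
    g[[paste0(pre, "W1")]] <- t(cc$X1) %*% dH
    g[[paste0(pre, "b1")]] <- colSums(dH)
    dX1 <- da2 + dH %*% t(p[[paste0(pre, "W1")]])
    l1 <- layernorm_bwd(dX1, cc$ln1, p[[paste0(pre, "ln1.g")]])
    g[[paste0(pre, "ln1.g")]] <- l1$dg
    g[[paste0(pre, "ln1.b")]] <- l1$db
    da1 <- l1$dx
    dO <- if (is.null(cc$dm1)) da1 else da1 * cc$dm1
    g[[paste0(pre, "Wo")]] <- t(cc$A) %*% dO
    g[[paste0(pre, "bo")]] <- colSums(dO)
    dA <- dO %*% t(p[[paste0(pre, "Wo")]])
    mb <- .mha_backward_cpp(dA, cc$Q, cc$K, cc$V, cc$attn, fwd$W,
                            spec$n_heads)
    g[[paste0(pre, "Wq")]] <- t(cc$Xin) %*% mb$dQ
    g[[paste0(pre, "bq")]] <- colSums(mb$dQ)
    g[[paste0(pre, "Wk")]] <- t(cc$Xin) %*% mb$dK
    g[[paste0(pre, "bk")]] <- colSums(mb$dK)
    g[[paste0(pre, "Wv")]] <- t(cc$Xin) %*% mb$dV
    g[[paste0(pre, "bv")]] <- colSums(mb$dV)
    dX <- da1 + mb$dQ %*% t(p[[paste0(pre, "Wq")]]) +
      mb$dK %*% t(p[[paste0(pre, "Wk")]]) +
      mb$dV %*% t(p[[paste0(pre, "Wv")]])
  }
  # token gradient: positional encoding is additive, passes dX through
  if (length(fwd$mask_idx)) {
    g[["mask_token"]] <- colSums(dX[fwd$mask_idx, , drop = FALSE])
    vis <- setdiff(seq_len(nrow(dX)), fwd$mask_idx)
  } else {
    g[["mask_token"]] <- numeric(spec$d_model)
    vis <- seq_len(nrow(dX))
  }
  g[["embed.W"]] <- t(fwd$X[vis, , drop = FALSE]) %*% dX[vis, , drop = FALSE]
  g[["embed.b"]] <- colSums(dX[vis, , drop = FALSE])
  g
}

# ---------------------------------------------------------------------------
# user-facing forward + freezing

# (n, W, C) array -> (n*W) x C matrix with contiguous window row blocks
batch_to_matrix <- function(A) {
  d <- dim(A)
  m <- aperm(A, c(2, 1, 3))
  dim(m) <- c(d[1] * d[2], d[3])
  m
}

matrix_to_batch <- function(M, n, W) {
  A <- array(M, c(W, n, ncol(M)))
  aperm(A, c(2, 1, 3))
}

#' Run the model on one window or a batch of windows (evaluation mode)
#'
#' Dropout is disabled, no masking is applied, and repeated calls with the
#' same weights and input are identical.
#'
#' @param model A `gait_model`.
#' @param x A `window` x `n_channels_in` matrix, or an `n` x `window` x
#'   `n_channels_in` array.
#' @return Output of matching layout with `n_channels_out` channels.
#' @export
model_forward <- function(model, x) {
  spec <- model$spec
  single <- length(dim(x)) == 2L
  A <- if (single) array(x, c(1L, dim(x))) else x
  if (dim(A)[2] != spec$window || dim(A)[3] != spec$n_channels_in)
    stop_schema("input must be windows of ", spec$window, " x ",
                spec$n_channels_in)
  X <- batch_to_matrix(A)
  if (spec$patch_length > 1L) {
    Xw <- lapply(seq_len(dim(A)[1]), function(i)
      patches_matrix(A[i, , ], spec))
    X <- do.call(rbind, Xw)
  }
  fwd <- model_forward_pass(model, X, n_patches(spec), training = FALSE)
  Yb <- unpatch_output(fwd$Y, spec, dim(A)[1])
  if (single) array(Yb[1, , ], dim(Yb)[2:3]) else Yb
}

# (n*n_patches) x pw_out head output -> (n, W, C_out) array
unpatch_output <- function(Y, spec, n) {
  if (spec$patch_length == 1L) return(matrix_to_batch(Y, n, spec$window))
  out <- array(0, c(n, spec$window, spec$n_channels_out))
  np <- n_patches(spec)
  for (b in seq_len(n)) for (pp in seq_len(np)) {
    rows <- ((pp - 1) * spec$patch_length + 1):(pp * spec$patch_length)
    out[b, rows, ] <- matrix(Y[(b - 1) * np + pp, ], spec$patch_length,
                             spec$n_channels_out)
  }
  out
}

#' Freeze the leading encoder blocks (and the input embedding)
#'
#' Marks the patch embedding, mask token and the first `n_frozen_blocks`
#' attention blocks non-trainable; output heads always stay trainable.
#'
#' @param model A `gait_model`.
#' @param n_frozen_blocks Number of leading blocks to freeze
#'   (`0 <= n <= n_blocks`).
#' @param include_embedding Freeze the patch embedding and mask token too
#'   (default `TRUE`).
#' @return The model with `frozen` set; `frozen_fraction` attribute reports
#'   the frozen share of encoder parameters.
#' @export
freeze_prefix <- function(model, n_frozen_blocks,
                          include_embedding = n_frozen_blocks > 0) {
  if (n_frozen_blocks < 0 || n_frozen_blocks > model$spec$n_blocks)
    stop_invalid("n_frozen_blocks must be between 0 and ",
                 model$spec$n_blocks)
  frozen <- character(0)
  if (include_embedding && n_frozen_blocks > 0)
    frozen <- c("embed.W", "embed.b", "mask_token")
  for (i in seq_len(n_frozen_blocks))
    frozen <- c(frozen, grep(sprintf("^block%02d\\.", i),
                             names(model$params), value = TRUE))
  model$frozen <- frozen
  sizes <- vapply(model$params, length, integer(1))
  enc <- !grepl("^head\\.", names(sizes))
  attr(model, "frozen_fraction") <-
    sum(sizes[names(sizes) %in% frozen]) / sum(sizes[enc])
  model
}
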