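# Forward model: modality projection -> zero substitution -> availability-
# masked gating -> weighted fusion -> shared transformer encoder ->
# cancer-type-specific hazard heads. Every stage caches the intermediates
# needed by the hand-written backward pass in model-backward.R.

LN_EPS <- 1e-5

#' Project one modality into the unified embedding space
#'
#' `Z = Dropout(ReLU(x W' + b))`; dropout (inverted, scale 1/(1-p)) is
#' active only in training mode and draws from the current RNG stream.
#'
#' @param x B x D_m input matrix.
#' @param w D x D_m weight matrix.
#' @param b length-D bias.
#' @param dropout dropout rate.
#' @param training logical; dropout applied only when TRUE.
#' @return B x D embedding matrix.
#' @export
project_modality <- function(x, w, b, dropout = 0, training = FALSE) {
  x <- as.matrix(x)
  if (ncol(x) != ncol(w)) {
    stop("dimension mismatch: input has ", ncol(x), " features, projection expects ", ncol(w))
  }
  a <- x %*% t(w)
  a <- sweep(a, 2, b, `+`)
  r <- pmax(a, 0)
  if (training && dropout > 0) {
    keep <- matrix(stats::rbinom(length(r), 1, 1 - dropout), nrow(r), ncol(r))
    r <- r * keep / (1 - dropout)
  }
  r
}

project_fwd <- function(x, pw, dropout, training) {
  x <- as.matrix(x)
  a <- sweep(x %*% t(pw$W), 2, pw$b, `+`)
  relu_mask <- a > 0
  r <- a * relu_mask
  drop_mask <- NULL
  if (training && dropout > 0) {
    drop_mask <- matrix(stats::rbinom(length(r), 1, 1 - dropout),
                        nrow(r), ncol(r)) / (1 - dropout)
    r <- r * drop_mask
  }
  list(z = r, x = x, relu_mask = relu_mask, drop_mask = drop_mask)
}

#' Zero-substitute unavailable modalities
#'
#' Sets the RNA / text embedding rows of samples whose availability-mask
#' entry is 0 to the exact zero vector; the image (anchor) modality may
#' never be marked absent.
#'
#' @param z_img,z_rna,z_txt B x d embedding matrices.
#' @param mask B x 3 binary availability matrix, columns (img, rna, txt).
#' @return list with the three matrices, absent rows zeroed.
#' @export
zero_substitute <- function(z_img, z_rna, z_txt, mask) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("availability mask must be binary")
  if (any(mask[, 1] != 1)) {
    stop("pathological image modality must be available for every patient")
  }
  list(img = z_img, rna = z_rna * mask[, 2], txt = z_txt * mask[, 3])
}

#' Raw gate logits
#'
#' `L = Concat(Z_img, Z_rna, Z_txt) W_gate'` with the fixed concatenation
#' order img, rna, txt; the gate layer has no bias.
#'
#' @param z_img,z_rna,z_txt B x d embedding matrices.
#' @param w_gate 3 x 3d gate weight matrix.
#' @return B x 3 logit matrix.
#' @export
gate_logits <- function(z_img, z_rna, z_txt, w_gate) {
  if (ncol(z_img) != ncol(z_rna) || ncol(z_img) != ncol(z_txt) ||
      ncol(w_gate) != 3 * ncol(z_img)) {
    stop("shape mismatch between modality embeddings and gate weights")
  }
  cbind(z_img, z_rna, z_txt) %*% t(w_gate)
}

#' Mask gate logits by availability
#'
#' Adds `penalty` (default -1e9) to the logit of every unavailable
#' modality: `L + (1 - M) * penalty`. After softmax such a modality's
#' weight underflows to numerical zero while differentiability is
#' preserved. Additive, never an assignment.
#'
#' @param logits B x 3 raw logits.
#' @param mask B x 3 binary availability matrix.
#' @param penalty additive penalty constant.
#' @return B x 3 masked logits.
#' @export
mask_logits <- function(logits, mask, penalty = -1e9) {
  mask <- as.matrix(mask)
  if (!all(mask %in% c(0, 1))) stop("availability mask must be binary")
  if (any(mask[, 1] != 1)) stop("image mask column must be all ones")
  logits + (1 - mask) * penalty
}

#' Gate weights by softmax
#'
#' Row-wise softmax of the masked logits; each row is a convex combination
#' weight vector over (img, rna, txt).
#'
#' @param masked_logits B x 3 matrix.
#' @return B x 3 matrix with rows summing to 1.
#' @export
gate_weights <- function(masked_logits) {
  g <- softmax_rows(masked_logits)
  dimnames(g) <- NULL
  g
}

#' Fuse modality embeddings with gate weights
#'
#' `Z_fused = sum_m G[, m] * Z_m`: each per-sample scalar weight is
#' broadcast over the embedding dimensions. Rows of `g` must sum to 1
#' within 1e-6 (a violation indicates a broken gate upstream).
#'
#' @param g B x 3 gate weights.
#' @param z_img,z_rna,z_txt B x d embeddings.
#' @return B x d fused embedding.
#' @export
fuse_modalities <- function(g, z_img, z_rna, z_txt) {
  if (any(abs(rowSums(g) - 1) > 1e-6)) {
    stop("gate weight rows must sum to 1 (contract violation upstream)")
  }
  g[, 1] * z_img + g[, 2] * z_rna + g[, 3] * z_txt
}

# ---- layer norm ----

layernorm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  y <- sweep(xhat * rep(1, nrow(x)) %o% g, 2, b, `+`)
  list(y = y, xhat = xhat, inv = inv)
}

layernorm_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- sweep(dy, 2, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- (dxhat - m1 - xhat * m2) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

# ---- transformer encoder (list of L token matrices, each B x d) ----

encoder_layer_fwd <- function(tokens, lp, n_heads) {
  d <- ncol(tokens[[1]]); dh <- d / n_heads; L <- length(tokens)
  ln1 <- lapply(tokens, layernorm_fwd, g = lp$ln1$g, b = lp$ln1$b)
  U <- lapply(ln1, `[[`, "y")
  lin <- function(x, W, b) sweep(x %*% t(W), 2, b, `+`)
  Q <- lapply(U, lin, W = lp$attn$Wq, b = lp$attn$bq)
  K <- lapply(U, lin, W = lp$attn$Wk, b = lp$attn$bk)
  V <- lapply(U, lin, W = lp$attn$Wv, b = lp$attn$bv)
  B <- nrow(tokens[[1]])
  O <- lapply(seq_len(L), function(i) matrix(0, B, d))
  P_all <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    S <- array(0, c(B, L, L))
    for (i in seq_len(L)) for (j in seq_len(L)) {
      S[, i, j] <- rowSums(Q[[i]][, cols, drop = FALSE] *
                           K[[j]][, cols, drop = FALSE]) / sqrt(dh)
    }
    P <- array(0, c(B, L, L))
    for (i in seq_len(L)) {
      sm <- S[, i, , drop = FALSE]
      dim(sm) <- c(B, L)
      P[, i, ] <- softmax_rows(sm)
    }
    for (i in seq_len(L)) {
      acc <- matrix(0, B, dh)
      for (j in seq_len(L)) acc <- acc + P[, i, j] * V[[j]][, cols, drop = FALSE]
      O[[i]][, cols] <- acc
    }
    P_all[[h]] <- P
  }
  attn <- lapply(O, lin, W = lp$attn$Wo, b = lp$attn$bo)
  x1 <- Map(`+`, tokens, attn)
  ln2 <- lapply(x1, layernorm_fwd, g = lp$ln2$g, b = lp$ln2$b)
  V2 <- lapply(ln2, `[[`, "y")
  A1 <- lapply(V2, lin, W = lp$ffn$W1, b = lp$ffn$b1)
  Rm <- lapply(A1, function(a) a > 0)
  R1 <- Map(function(a, m) a * m, A1, Rm)
  Fo <- lapply(R1, lin, W = lp$ffn$W2, b = lp$ffn$b2)
  out <- Map(`+`, x1, Fo)
  list(out = out,
       cache = list(ln1 = ln1, U = U, Q = Q, K = K, V = V, P = P_all, O = O,
                    x1 = x1, ln2 = ln2, V2 = V2, Rm = Rm, R1 = R1))
}

encoder_layer_bwd <- function(dout, cache, lp, n_heads) {
  d <- ncol(dout[[1]]); dh <- d / n_heads; L <- length(dout)
  B <- nrow(dout[[1]])
  g <- list(ln1 = list(g = numeric(d), b = numeric(d)),
            attn = list(Wq = matrix(0, d, d), bq = numeric(d),
                        Wk = matrix(0, d, d), bk = numeric(d),
                        Wv = matrix(0, d, d), bv = numeric(d),
                        Wo = matrix(0, d, d), bo = numeric(d)),
            ln2 = list(g = numeric(d), b = numeric(d)),
            ffn = list(W1 = matrix(0, nrow(lp$ffn$W1), d),
                       b1 = numeric(nrow(lp$ffn$W1)),
                       W2 = matrix(0, d, nrow(lp$ffn$W1)),
                       b2 = numeric(d)))
  # FFN sublayer
  dx1 <- dout
  for (l in seq_len(L)) {
    dF <- dout[[l]]
    g$ffn$W2 <- g$ffn$W2 + t(dF) %*% cache$R1[[l]]
    g$ffn$b2 <- g$ffn$b2 + colSums(dF)
    dR1 <- (dF %*% lp$ffn$W2) * cache$Rm[[l]]
    g$ffn$W1 <- g$ffn$W1 + t(dR1) %*% cache$V2[[l]]
    g$ffn$b1 <- g$ffn$b1 + colSums(dR1)
    dV2 <- dR1 %*% lp$ffn$W1
    lb <- layernorm_bwd(dV2, cache$ln2[[l]], lp$ln2$g)
    g$ln2$g <- g$ln2$g + lb$dg
    g$ln2$b <- g$ln2$b + lb$db
    dx1[[l]] <- dx1[[l]] + lb$dx
  }
  # attention sublayer
  dO <- vector("list", L)
  for (l in seq_len(L)) {
    dattn <- dx1[[l]]
    g$attn$Wo <- g$attn$Wo + t(dattn) %*% cache$O[[l]]
    g$attn$bo <- g$attn$bo + colSums(dattn)
    dO[[l]] <- dattn %*% lp$attn$Wo
  }
  dQ <- lapply(seq_len(L), function(i) matrix(0, B, d))
  dK <- lapply(seq_len(L), function(i) matrix(0, B, d))
  dV <- lapply(seq_len(L), function(i) matrix(0, B, d))
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1) * dh + 1):(h * dh)
    P <- cache$P[[h]]
    dP <- array(0, c(B, L, L))
    for (i in seq_len(L)) for (j in seq_len(L)) {
      dP[, i, j] <- rowSums(dO[[i]][, cols, drop = FALSE] *
                            cache$V[[j]][, cols, drop = FALSE])
      dV[[j]][, cols] <- dV[[j]][, cols] + P[, i, j] * dO[[i]][, cols, drop = FALSE]
    }
    for (i in seq_len(L)) {
      dot <- numeric(B)
      for (j in seq_len(L)) dot <- dot + dP[, i, j] * P[, i, j]
      for (j in seq_len(L)) {
        dS <- P[, i, j] * (dP[, i, j] - dot)
        dQ[[i]][, cols] <- dQ[[i]][, cols] + dS * cache$K[[j]][, cols, drop = FALSE] / sqrt(dh)
        dK[[j]][, cols] <- dK[[j]][, cols] + dS * cache$Q[[i]][, cols, drop = FALSE] / sqrt(dh)
      }
    }
  }
  dtok <- dx1
  for (l in seq_len(L)) {
    g$attn$Wq <- g$attn$Wq + t(dQ[[l]]) %*% cache$U[[l]]
    g$attn$bq <- g$attn$bq + colSums(dQ[[l]])
    g$attn$Wk <- g$attn$Wk + t(dK[[l]]) %*% cache$U[[l]]
    g$attn$bk <- g$attn$bk + colSums(dK[[l]])
    g$attn$Wv <- g$attn$Wv + t(dV[[l]]) %*% cache$U[[l]]
    g$attn$bv <- g$attn$bv + colSums(dV[[l]])
    dU <- dQ[[l]] %*% lp$attn$Wq + dK[[l]] %*% lp$attn$Wk + dV[[l]] %*% lp$attn$Wv
    lb <- layernorm_bwd(dU, cache$ln1[[l]], lp$ln1$g)
    g$ln1$g <- g$ln1$g + lb$dg
    g$ln1$b <- g$ln1$b + lb$db
    dtok[[l]] <- dtok[[l]] + lb$dx
  }
  list(dtokens = dtok, grads = g)
}

encoder_fwd <- function(tokens, enc, n_heads) {
  caches <- vector("list", length(enc$layers))
  for (l in seq_along(enc$layers)) {
    r <- encoder_layer_fwd(tokens, enc$layers[[l]], n_heads)
    tokens <- r$out
    caches[[l]] <- r$cache
  }
  list(tokens = tokens, caches = caches)
}

encoder_bwd <- function(dtokens, caches, enc, n_heads) {
  grads <- list(layers = vector("list", length(enc$layers)))
  for (l in rev(seq_along(enc$layers))) {
    r <- encoder_layer_bwd(dtokens, caches[[l]], enc$layers[[l]], n_heads)
    dtokens <- r$dtokens
    grads$layers[[l]] <- r$grads
  }
  list(dtokens = dtokens, grads = grads)
}

#' Shared transformer encoding of fused embeddings
#'
#' Treats each fused vector as a length-1 token sequence, applies the
#' pre-norm transformer encoder and average-pools over tokens (for one
#' token, the pooled output is the encoder output itself). With zero
#' attention/feed-forward weights the residual path makes this the
#' identity.
#'
#' @param z_fused B x d matrix.
#' @param params model parameters (uses `params$enc`).
#' @param config an `sg_config`.
#' @return B x d encoded matrix.
#' @export
shared_encode <- function(z_fused, params, config) {
  r <- encoder_fwd(list(as.matrix(z_fused)), params$enc, config$n_heads)
  Reduce(`+`, r$tokens) / length(r$tokens)
}

#' Cancer-type-specific hazard heads
#'
#' Row i of the output uses the head of cancer `cancer_ids[i]`:
#' `sigmoid(W_c h_i + b_c)`, one sigmoid per time bin.
#'
#' @param h B x d encoded matrix.
#' @param cancer_ids integer cancer types in 1..C.
#' @param heads list of C head parameter lists (`W` T x d, `b` length T).
#' @return B x T hazard matrix with entries in (0, 1).
#' @export
cancer_hazards <- function(h, cancer_ids, heads) {
  cancer_ids <- as.integer(cancer_ids)
  if (any(cancer_ids < 1 | cancer_ids > length(heads)) || anyNA(cancer_ids)) {
    stop("unknown cancer id: head indices must lie in 1..", length(heads))
  }
  Tb <- length(heads[[1]]$b)
  out <- matrix(0, nrow(h), Tb)
  for (cc in unique(cancer_ids)) {
    idx <- which(cancer_ids == cc)
    z <- h[idx, , drop = FALSE] %*% t(heads[[cc]]$W)
    out[idx, ] <- 1 / (1 + exp(-sweep(z, 2, heads[[cc]]$b, `+`)))
  }
  out
}

#' Full forward pass
#'
#' Runs projection, zero substitution, (masked gated or early) fusion, the
#' shared encoder and the per-cancer hazard heads, and derives survival
#' curves and scalar risks. Deterministic in eval mode given the
#' parameters; in training mode projection dropout draws from the current
#' RNG stream.
#'
#' @param params `sg_params`.
#' @param batch `sg_batch` (see [make_batch()]).
#' @param config `sg_config`.
#' @param training logical.
#' @return list with `hazards` (B x T), `surv` (B x T), `risk` (B),
#'   `gates` (B x 3; uniform NA for early fusion), and `cache` for the
#'   backward pass.
#' @export
model_forward <- function(params, batch, config, training = FALSE) {
  pr <- list(
    img = project_fwd(batch$x$img, params$proj$img, config$dropout, training),
    rna = project_fwd(batch$x$rna, params$proj$rna, config$dropout, training),
    txt = project_fwd(batch$x$txt, params$proj$txt, config$dropout, training)
  )
  Z <- zero_substitute(pr$img$z, pr$rna$z, pr$txt$z, batch$mask)
  B <- nrow(Z$img)
  cache <- list(pr = pr, Z = Z, mask = batch$mask)
  if (config$fusion == "gated") {
    L <- gate_logits(Z$img, Z$rna, Z$txt, params$gate$W)
    Lm <- mask_logits(L, batch$mask, config$penalty)
    G <- gate_weights(Lm)
    cache$G <- G
    if (config$encoder_tokens == "fused") {
      tokens <- list(fuse_modalities(G, Z$img, Z$rna, Z$txt))
    } else {
      tokens <- list(G[, 1] * Z$img, G[, 2] * Z$rna, G[, 3] * Z$txt)
    }
  } else {
    G <- matrix(NA_real_, B, 3)
    zc <- cbind(Z$img, Z$rna, Z$txt)
    zf <- sweep(zc %*% t(params$fuse_early$W), 2, params$fuse_early$b, `+`)
    cache$zc <- zc
    tokens <- list(zf)
  }
  enc <- encoder_fwd(tokens, params$enc, config$n_heads)
  Ltok <- length(enc$tokens)
  H <- Reduce(`+`, enc$tokens) / Ltok
  cache$enc <- enc
  cache$H <- H
  hz <- cancer_hazards(H, batch$cancer, params$heads)
  surv <- survival_curve(hz)
  list(hazards = hz, surv = surv, risk = risk_score(hz), gates = G,
       cache = cache)
}
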