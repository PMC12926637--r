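# Multi-scale fusion: the three per-drug vectors (a_i, l_i, g_i) are stacked
# as tokens and passed through a transformer encoder block — multi-head
# self-attention and a position-wise feedforward, each wrapped in a pre-norm
# residual — then flattened and linearly projected back to width d. No
# positional encoding is used over the scale tokens: scale identity is
# carried by the learned projections, and the token stream is permutation
# equivariant by construction. Concatenation, Hadamard-product and averaging
# fusions are retained as baselines; all strategies project to width d.
#
# The batched forms below carry one n_drugs x d matrix per token so the
# whole drug set moves through the encoder in a handful of BLAS calls; the
# exported single-instance operations wrap them with n = token rows.

#' Initialise fusion parameters
#'
#' @param d common embedding width.
#' @param n_tokens number of scale tokens (3 for a/l/g; ablations use fewer).
#' @param heads attention head count m (must divide d; d_k = d / m).
#' @param strategy fusion strategy the readout is sized for.
#' @param seed integer seed.
#' @param eps layer-norm stabiliser.
#' @return list of class `fusion_params`.
#' @export
init_fusion_params <- function(d = 128L, n_tokens = 3L, heads = 4L,
                               strategy = c("transformer", "concat",
                                            "hadamard", "average"),
                               seed = 1L, eps = 1e-5) {
  strategy <- match.arg(strategy)
  if (d %% heads != 0L) stop("d (", d, ") must be divisible by heads (", heads, ")")
  dk <- d %/% heads
  with_seed(seed, {
    p <- list(
      heads = lapply(seq_len(heads), function(h) {
        list(WQ = init_mat(d, dk, 1 / sqrt(d)),
             WK = init_mat(d, dk, 1 / sqrt(d)),
             WV = init_mat(d, dk, 1 / sqrt(d)))
      }),
      WO = init_mat(d, d, 1 / sqrt(d)), bO = rep(0, d),
      ln1 = list(gamma = rep(1, d), beta = rep(0, d)),
      ln2 = list(gamma = rep(1, d), beta = rep(0, d)),
      ffn = list(W1 = init_mat(4L * d, d), b1 = rep(0, 4L * d),
                 W2 = init_mat(d, 4L * d), b2 = rep(0, d)),
      readout = switch(strategy,
        transformer = list(W = init_mat(d, n_tokens * d, 1 / sqrt(n_tokens * d)),
                           b = rep(0, d)),
        concat = list(W = init_mat(d, n_tokens * d, 1 / sqrt(n_tokens * d)),
                      b = rep(0, d)),
        hadamard = list(W = init_mat(d, d, 1 / sqrt(d)), b = rep(0, d)),
        average = list(W = init_mat(d, d, 1 / sqrt(d)), b = rep(0, d)))
    )
    p$d <- as.integer(d); p$dk <- as.integer(dk)
    p$n_heads <- as.integer(heads); p$n_tokens <- as.integer(n_tokens)
    p$eps <- eps; p$strategy <- strategy
    class(p) <- "fusion_params"
    p
  })
}

#' Layer normalisation across the feature dimension
#'
#' @param x numeric vector or matrix (rows normalised independently).
#' @param gamma,beta scale and shift vectors.
#' @param eps stabiliser added to the variance.
#' @return normalised object of the same shape.
#' @export
layer_norm <- function(x, gamma, beta, eps = 1e-5) {
  if (is.vector(x)) {
    return(as.numeric(ln_forward(matrix(x, 1L), gamma, beta, eps)$out))
  }
  ln_forward(x, gamma, beta, eps)$out
}

ln_forward <- function(x, gamma, beta, eps) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(xhat * rep(gamma, each = nrow(x)), 2L, beta, "+")
  list(out = out, xhat = xhat, inv = inv, xc = xc)
}

ln_backward <- function(cache, gamma, dout) {
  d <- ncol(cache$xhat)
  dgamma <- colSums(dout * cache$xhat)
  dbeta <- colSums(dout)
  dxhat <- dout * rep(gamma, each = nrow(dout))
  # dx for population-variance layer norm
  s1 <- rowSums(dxhat)
  s2 <- rowSums(dxhat * cache$xhat)
  dx <- cache$inv * (dxhat - s1 / d - cache$xhat * s2 / d)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# ---- batched multi-head attention ------------------------------------------

# toks: list of S matrices (n x d). Returns list(out = list of S matrices,
# cache) for backprop.
mha_forward <- function(toks, params) {
  S <- length(toks)
  n <- nrow(toks[[1L]])
  d <- params$d; dk <- params$dk
  scale <- 1 / sqrt(dk)
  head_caches <- vector("list", params$n_heads)
  concat <- lapply(seq_len(S), function(i) matrix(0, n, 0L))
  for (h in seq_len(params$n_heads)) {
    ph <- params$heads[[h]]
    Q <- lapply(toks, function(tk) tk %*% ph$WQ)
    K <- lapply(toks, function(tk) tk %*% ph$WK)
    V <- lapply(toks, function(tk) tk %*% ph$WV)
    P <- vector("list", S)   # P[[i]]: n x S attention weights of token i
    O <- vector("list", S)
    for (i in seq_len(S)) {
      sc <- vapply(seq_len(S), function(j) rowSums(Q[[i]] * K[[j]]) * scale,
                   numeric(n))
      sc <- matrix(sc, n, S)
      P[[i]] <- softmax_rows(sc)
      Oi <- matrix(0, n, dk)
      for (j in seq_len(S)) Oi <- Oi + P[[i]][, j] * V[[j]]
      O[[i]] <- Oi
    }
    head_caches[[h]] <- list(Q = Q, K = K, V = V, P = P)
    concat <- lapply(seq_len(S), function(i) cbind(concat[[i]], O[[i]]))
  }
  out <- lapply(seq_len(S), function(i) {
    sweep(concat[[i]] %*% params$WO, 2L, params$bO, "+")
  })
  list(out = out, cache = list(heads = head_caches, concat = concat,
                               toks = toks))
}

mha_backward <- function(cache, dout, params) {
  S <- length(dout)
  n <- nrow(dout[[1L]])
  d <- params$d; dk <- params$dk
  scale <- 1 / sqrt(dk)
  gWO <- matrix(0, d, d); gbO <- rep(0, d)
  dconcat <- vector("list", S)
  for (i in seq_len(S)) {
    gWO <- gWO + t(cache$concat[[i]]) %*% dout[[i]]
    gbO <- gbO + colSums(dout[[i]])
    dconcat[[i]] <- dout[[i]] %*% t(params$WO)
  }
  dtoks <- lapply(seq_len(S), function(i) matrix(0, n, d))
  ghead <- vector("list", params$n_heads)
  for (h in seq_len(params$n_heads)) {
    hc <- cache$heads[[h]]
    ph <- params$heads[[h]]
    cols <- (h - 1L) * dk + seq_len(dk)
    dO <- lapply(dconcat, function(m) m[, cols, drop = FALSE])
    dQ <- lapply(seq_len(S), function(i) matrix(0, n, dk))
    dK <- lapply(seq_len(S), function(i) matrix(0, n, dk))
    dV <- lapply(seq_len(S), function(i) matrix(0, n, dk))
    for (i in seq_len(S)) {
      dP <- vapply(seq_len(S), function(j) rowSums(dO[[i]] * hc$V[[j]]),
                   numeric(n))
      dP <- matrix(dP, n, S)
      Pi <- hc$P[[i]]
      dS <- Pi * (dP - rowSums(dP * Pi))
      for (j in seq_len(S)) {
        dV[[j]] <- dV[[j]] + Pi[, j] * dO[[i]]
        dQ[[i]] <- dQ[[i]] + dS[, j] * hc$K[[j]] * scale
        dK[[j]] <- dK[[j]] + dS[, j] * hc$Q[[i]] * scale
      }
    }
    gWQ <- matrix(0, d, dk); gWK <- gWQ; gWV <- gWQ
    for (i in seq_len(S)) {
      gWQ <- gWQ + t(cache$toks[[i]]) %*% dQ[[i]]
      gWK <- gWK + t(cache$toks[[i]]) %*% dK[[i]]
      gWV <- gWV + t(cache$toks[[i]]) %*% dV[[i]]
      dtoks[[i]] <- dtoks[[i]] + dQ[[i]] %*% t(ph$WQ) +
        dK[[i]] %*% t(ph$WK) + dV[[i]] %*% t(ph$WV)
    }
    ghead[[h]] <- list(WQ = gWQ, WK = gWK, WV = gWV)
  }
  list(dtoks = dtoks, grads = list(heads = ghead, WO = gWO, bO = gbO))
}

#' Multi-head self-attention over scale tokens
#'
#' @param tokens S x d matrix (one row per scale token).
#' @param params a `fusion_params`.
#' @return S x d matrix after attention, head concatenation and the output
#'   projection; each underlying attention row sums to one.
#' @export
multi_head_attention <- function(tokens, params) {
  if (ncol(tokens) != params$d) {
    stop("token width ", ncol(tokens), " does not match d = ", params$d)
  }
  toks <- lapply(seq_len(nrow(tokens)),
                 function(i) tokens[i, , drop = FALSE])
  out <- mha_forward(toks, params)$out
  do.call(rbind, out)
}

# ---- encoder block ----------------------------------------------------------

block_forward <- function(toks, params) {
  S <- length(toks)
  ln1 <- lapply(toks, function(tk) {
    ln_forward(tk, params$ln1$gamma, params$ln1$beta, params$eps)
  })
  mha <- mha_forward(lapply(ln1, `[[`, "out"), params)
  y <- Map(`+`, toks, mha$out)
  ln2 <- lapply(y, function(tk) {
    ln_forward(tk, params$ln2$gamma, params$ln2$beta, params$eps)
  })
  ffn <- lapply(ln2, function(l) {
    Z1 <- sweep(l$out %*% t(params$ffn$W1), 2L, params$ffn$b1, "+")
    H1 <- relu(Z1)
    Z2 <- sweep(H1 %*% t(params$ffn$W2), 2L, params$ffn$b2, "+")
    list(Z1 = Z1, H1 = H1, Z2 = Z2)
  })
  out <- Map(function(yi, f) yi + f$Z2, y, ffn)
  list(out = out, cache = list(ln1 = ln1, mha = mha, y = y, ln2 = ln2,
                               ffn = ffn))
}

block_backward <- function(cache, dout, params) {
  S <- length(dout)
  d <- params$d
  gW1 <- matrix(0, 4L * d, d); gb1 <- rep(0, 4L * d)
  gW2 <- matrix(0, d, 4L * d); gb2 <- rep(0, d)
  gln2 <- list(gamma = rep(0, d), beta = rep(0, d))
  dy <- vector("list", S)
  for (i in seq_len(S)) {
    f <- cache$ffn[[i]]
    dZ2 <- dout[[i]]
    gW2 <- gW2 + t(dZ2) %*% f$H1
    gb2 <- gb2 + colSums(dZ2)
    dH1 <- dZ2 %*% params$ffn$W2
    dZ1 <- dH1 * (f$Z1 > 0)
    gW1 <- gW1 + t(dZ1) %*% cache$ln2[[i]]$out
    gb1 <- gb1 + colSums(dZ1)
    dln2out <- dZ1 %*% params$ffn$W1
    lb <- ln_backward(cache$ln2[[i]], params$ln2$gamma, dln2out)
    gln2$gamma <- gln2$gamma + lb$dgamma
    gln2$beta <- gln2$beta + lb$dbeta
    dy[[i]] <- dout[[i]] + lb$dx   # residual + FFN path
  }
  mb <- mha_backward(cache$mha$cache, dy, params)
  gln1 <- list(gamma = rep(0, d), beta = rep(0, d))
  dtoks <- vector("list", S)
  for (i in seq_len(S)) {
    lb <- ln_backward(cache$ln1[[i]], params$ln1$gamma, mb$dtoks[[i]])
    gln1$gamma <- gln1$gamma + lb$dgamma
    gln1$beta <- gln1$beta + lb$dbeta
    dtoks[[i]] <- dy[[i]] + lb$dx  # residual + attention path
  }
  list(dtoks = dtoks,
       grads = list(heads = mb$grads$heads, WO = mb$grads$WO,
                    bO = mb$grads$bO, ln1 = gln1, ln2 = gln2,
                    ffn = list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)))
}

#' Transformer encoder block over scale tokens
#'
#' Pre-norm arrangement: `tokens + MHA(LN(tokens))` then `y + FFN(LN(y))`.
#' With all sub-layer weights zero the block is the identity map.
#'
#' @param tokens S x d matrix.
#' @param params a `fusion_params`.
#' @return S x d matrix.
#' @export
transformer_encoder_block <- function(tokens, params) {
  toks <- lapply(seq_len(nrow(tokens)),
                 function(i) tokens[i, , drop = FALSE])
  do.call(rbind, block_forward(toks, params)$out)
}

# ---- fuse -------------------------------------------------------------------

# Batched fusion: scales = list of n x d matrices. Returns list(X, cache).
fuse_forward <- function(scales, params) {
  strategy <- params$strategy
  n <- nrow(scales[[1L]])
  d <- ncol(scales[[1L]])
  if (strategy == "transformer") {
    blk <- block_forward(scales, params)
    C <- do.call(cbind, blk$out)
    X <- sweep(C %*% t(params$readout$W), 2L, params$readout$b, "+")
    list(X = X, cache = list(blk = blk, C = C))
  } else if (strategy == "concat") {
    C <- do.call(cbind, scales)
    X <- sweep(C %*% t(params$readout$W), 2L, params$readout$b, "+")
    list(X = X, cache = list(C = C))
  } else if (strategy == "hadamard") {
    H <- Reduce(`*`, scales)
    X <- sweep(H %*% t(params$readout$W), 2L, params$readout$b, "+")
    list(X = X, cache = list(H = H, scales = scales))
  } else if (strategy == "average") {
    A <- Reduce(`+`, scales) / length(scales)
    X <- sweep(A %*% t(params$readout$W), 2L, params$readout$b, "+")
    list(X = X, cache = list(A = A))
  } else stop("unknown fusion strategy '", strategy, "'")
}

fuse_backward <- function(cache, dX, params) {
  strategy <- params$strategy
  S <- params$n_tokens
  d <- params$d
  if (strategy == "transformer") {
    gR <- list(W = t(dX) %*% cache$C, b = colSums(dX))
    dC <- dX %*% params$readout$W
    dtoks <- lapply(seq_len(S), function(i) {
      dC[, (i - 1L) * d + seq_len(d), drop = FALSE]
    })
    bb <- block_backward(cache$blk$cache, dtoks, params)
    list(dscales = bb$dtoks, grads = c(bb$grads, list(readout = gR)))
  } else if (strategy == "concat") {
    gR <- list(W = t(dX) %*% cache$C, b = colSums(dX))
    dC <- dX %*% params$readout$W
    dscales <- lapply(seq_len(S), function(i) {
      dC[, (i - 1L) * d + seq_len(d), drop = FALSE]
    })
    list(dscales = dscales, grads = list(readout = gR))
  } else if (strategy == "hadamard") {
    gR <- list(W = t(dX) %*% cache$H, b = colSums(dX))
    dH <- dX %*% params$readout$W
    sc <- cache$scales
    dscales <- lapply(seq_len(S), function(i) {
      others <- Reduce(`*`, sc[-i])
      dH * others
    })
    list(dscales = dscales, grads = list(readout = gR))
  } else {
    gR <- list(W = t(dX) %*% cache$A, b = colSums(dX))
    dA <- dX %*% params$readout$W
    dscales <- lapply(seq_len(S), function(i) dA / S)
    list(dscales = dscales, grads = list(readout = gR))
  }
}

#' Fuse per-drug scale embeddings into one vector
#'
#' @param scales list of equal-width numeric vectors (or 1-row matrices),
#'   typically `list(a = a_i, l = l_i, g = g_i)`.
#' @param strategy one of "transformer", "concat", "hadamard", "average".
#' @param params a `fusion_params` sized for the strategy, or `NULL` for the
#'   identity readout (no projection; concat then returns a 3d-length
#'   vector).
#' @return fused numeric vector x_i.
#' @export
fuse <- function(scales, strategy = c("transformer", "concat", "hadamard",
                                      "average"), params = NULL) {
  strategy <- match.arg(strategy)
  mats <- lapply(scales, function(s) matrix(as.numeric(s), nrow = 1L))
  d <- ncol(mats[[1L]])
  if (!all(vapply(mats, ncol, integer(1)) == d)) {
    stop("all scale vectors must have equal width")
  }
  if (is.null(params)) {
    out <- switch(strategy,
      transformer = stop("transformer fusion requires params"),
      concat = do.call(cbind, mats),
      hadamard = Reduce(`*`, mats),
      average = Reduce(`+`, mats) / length(mats))
    return(as.numeric(out))
  }
  if (params$strategy != strategy) {
    stop("params were initialised for strategy '", params$strategy, "'")
  }
  as.numeric(fuse_forward(mats, params)$X)
}
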