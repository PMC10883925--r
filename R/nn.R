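# Minimal transformer-encoder engine in base R.
#
# This is the numerical core behind both the ELECTRA-style pre-training
# (generator + discriminator) and the fine-tuned stability classifier.  It
# implements a pre-LayerNorm transformer encoder with learned token and
# position embeddings, multi-head self-attention, a GELU feed-forward block,
# exact hand-written backpropagation, and Adam.  Parameters live in a flat
# named list of arrays ("l1.Wq", "lnf.g", ...), which keeps the optimizer a
# simple loop and makes gradient checking straightforward (see the tests,
# which verify every parameter group against central finite differences).
#
# Batches are dense: `ids` is a B x L matrix of 1-based vocabulary indices
# (PAD-filled), `mask` the parallel 0/1 matrix of real positions.  Row
# (b - 1) * L + t of every activation matrix is position t of sequence b.
# Attention masks padded *columns*; padded rows are kept inert by only ever
# injecting loss gradients at real positions.

nn_eps <- 1e-5

nn_gelu <- function(x) x * stats::pnorm(x)
nn_gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)

nn_softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

# ---- layer primitives ------------------------------------------------------

ln_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  inv <- 1 / sqrt(rowMeans(xc * xc) + nn_eps)
  xhat <- xc * inv
  list(y = sweep(xhat, 2L, g, "*") + rep(b, each = nrow(x)),
       xhat = xhat, inv = inv)
}

ln_bwd <- function(dy, cache, g) {
  xhat <- cache$xhat
  dxhat <- sweep(dy, 2L, g, "*")
  dx <- cache$inv * (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dx = dx, dg = colSums(dy * xhat), db = colSums(dy))
}

lin_fwd <- function(x, W, b) x %*% W + rep(b, each = nrow(x))

# ---- parameter initialization ---------------------------------------------

# cfg: list(V, d, H, ffn, n_layers, max_pos, init_std)
encoder_init <- function(cfg) {
  rn <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, cfg$init_std), nr, nc)
  p <- list(Etok = rn(cfg$V, cfg$d), Epos = rn(cfg$max_pos, cfg$d),
            lnf.g = rep(1, cfg$d), lnf.b = rep(0, cfg$d))
  for (i in seq_len(cfg$n_layers)) {
    nm <- function(s) sprintf("l%d.%s", i, s)
    p[[nm("ln1.g")]] <- rep(1, cfg$d); p[[nm("ln1.b")]] <- rep(0, cfg$d)
    p[[nm("Wq")]] <- rn(cfg$d, cfg$d); p[[nm("bq")]] <- rep(0, cfg$d)
    p[[nm("Wk")]] <- rn(cfg$d, cfg$d); p[[nm("bk")]] <- rep(0, cfg$d)
    p[[nm("Wv")]] <- rn(cfg$d, cfg$d); p[[nm("bv")]] <- rep(0, cfg$d)
    p[[nm("Wo")]] <- rn(cfg$d, cfg$d); p[[nm("bo")]] <- rep(0, cfg$d)
    p[[nm("ln2.g")]] <- rep(1, cfg$d); p[[nm("ln2.b")]] <- rep(0, cfg$d)
    p[[nm("W1")]] <- rn(cfg$d, cfg$ffn); p[[nm("b1")]] <- rep(0, cfg$ffn)
    p[[nm("W2")]] <- rn(cfg$ffn, cfg$d); p[[nm("b2")]] <- rep(0, cfg$d)
  }
  p
}

# ---- encoder forward / backward -------------------------------------------

encoder_forward <- function(p, cfg, ids, mask) {
  B <- nrow(ids); L <- ncol(ids)
  if (L > cfg$max_pos)
    stop_ns("sequence length %d exceeds positional table %d", L, cfg$max_pos)
  ids_vec <- as.vector(t(ids))           # (b, t) with t fastest
  pos_vec <- rep(seq_len(L), B)
  x <- p$Etok[ids_vec, , drop = FALSE] + p$Epos[pos_vec, , drop = FALSE]
  H <- cfg$H; dh <- cfg$d / H
  scale <- 1 / sqrt(dh)
  layers <- vector("list", cfg$n_layers)
  for (i in seq_len(cfg$n_layers)) {
    nm <- function(s) sprintf("l%d.%s", i, s)
    c1 <- ln_fwd(x, p[[nm("ln1.g")]], p[[nm("ln1.b")]])
    Q <- lin_fwd(c1$y, p[[nm("Wq")]], p[[nm("bq")]])
    K <- lin_fwd(c1$y, p[[nm("Wk")]], p[[nm("bk")]])
    V <- lin_fwd(c1$y, p[[nm("Wv")]], p[[nm("bv")]])
    O <- matrix(0, B * L, cfg$d)
    A_list <- vector("list", B * H)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * L + 1L):(b * L)
      dead <- which(mask[b, ] == 0L)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        S <- tcrossprod(Q[rb, hc, drop = FALSE], K[rb, hc, drop = FALSE]) * scale
        if (length(dead)) S[, dead] <- -1e30
        A <- nn_softmax_rows(S)
        O[rb, hc] <- A %*% V[rb, hc, drop = FALSE]
        A_list[[(b - 1L) * H + h]] <- A
      }
    }
    attn_out <- lin_fwd(O, p[[nm("Wo")]], p[[nm("bo")]])
    x2 <- x + attn_out
    c2 <- ln_fwd(x2, p[[nm("ln2.g")]], p[[nm("ln2.b")]])
    Z1 <- lin_fwd(c2$y, p[[nm("W1")]], p[[nm("b1")]])
    G <- nn_gelu(Z1)
    x3 <- x2 + lin_fwd(G, p[[nm("W2")]], p[[nm("b2")]])
    layers[[i]] <- list(c1 = c1, Q = Q, K = K, V = V, A = A_list, O = O,
                        x_in = x, x2 = x2, c2 = c2, Z1 = Z1, G = G)
    x <- x3
  }
  cf <- ln_fwd(x, p$lnf.g, p$lnf.b)
  list(out = cf$y,
       cache = list(layers = layers, cf = cf, x_last = x,
                    ids_vec = ids_vec, pos_vec = pos_vec, B = B, L = L))
}

encoder_backward <- function(p, cfg, cache, dY) {
  B <- cache$B; L <- cache$L
  H <- cfg$H; dh <- cfg$d / H
  scale <- 1 / sqrt(dh)
  g <- list()
  bf <- ln_bwd(dY, cache$cf, p$lnf.g)
  g[["lnf.g"]] <- bf$dg; g[["lnf.b"]] <- bf$db
  dx <- bf$dx
  for (i in rev(seq_len(cfg$n_layers))) {
    nm <- function(s) sprintf("l%d.%s", i, s)
    lc <- cache$layers[[i]]
    # FFN branch
    dZ2 <- dx                                   # grad wrt W2 output (residual passthrough below)
    g[[nm("W2")]] <- crossprod(lc$G, dZ2)
    g[[nm("b2")]] <- colSums(dZ2)
    dG <- dZ2 %*% t(p[[nm("W2")]])
    dZ1 <- dG * nn_gelu_grad(lc$Z1)
    g[[nm("W1")]] <- crossprod(lc$c2$y, dZ1)
    g[[nm("b1")]] <- colSums(dZ1)
    dh2 <- dZ1 %*% t(p[[nm("W1")]])
    b2l <- ln_bwd(dh2, lc$c2, p[[nm("ln2.g")]])
    g[[nm("ln2.g")]] <- b2l$dg; g[[nm("ln2.b")]] <- b2l$db
    dx2 <- dx + b2l$dx                          # residual + LN path
    # attention branch
    dattn <- dx2
    g[[nm("Wo")]] <- crossprod(lc$O, dattn)
    g[[nm("bo")]] <- colSums(dattn)
    dO <- dattn %*% t(p[[nm("Wo")]])
    dQ <- matrix(0, B * L, cfg$d)
    dK <- matrix(0, B * L, cfg$d)
    dV <- matrix(0, B * L, cfg$d)
    for (b in seq_len(B)) {
      rb <- ((b - 1L) * L + 1L):(b * L)
      for (h in seq_len(H)) {
        hc <- ((h - 1L) * dh + 1L):(h * dh)
        A <- lc$A[[(b - 1L) * H + h]]
        dOb <- dO[rb, hc, drop = FALSE]
        dA <- tcrossprod(dOb, lc$V[rb, hc, drop = FALSE])
        dV[rb, hc] <- dV[rb, hc] + crossprod(A, dOb)
        dS <- A * (dA - rowSums(dA * A))
        dQ[rb, hc] <- dQ[rb, hc] + dS %*% lc$K[rb, hc, drop = FALSE] * scale
        dK[rb, hc] <- dK[rb, hc] + crossprod(dS, lc$Q[rb, hc, drop = FALSE]) * scale
      }
    }
    g[[nm("Wq")]] <- crossprod(lc$c1$y, dQ); g[[nm("bq")]] <- colSums(dQ)
    g[[nm("Wk")]] <- crossprod(lc$c1$y, dK); g[[nm("bk")]] <- colSums(dK)
    g[[nm("Wv")]] <- crossprod(lc$c1$y, dV); g[[nm("bv")]] <- colSums(dV)
    dh1 <- dQ %*% t(p[[nm("Wq")]]) + dK %*% t(p[[nm("Wk")]]) + dV %*% t(p[[nm("Wv")]])
    b1l <- ln_bwd(dh1, lc$c1, p[[nm("ln1.g")]])
    g[[nm("ln1.g")]] <- b1l$dg; g[[nm("ln1.b")]] <- b1l$db
    dx <- dx2 + b1l$dx
  }
  # embeddings
  dE <- rowsum(dx, group = cache$ids_vec)
  dEtok <- matrix(0, cfg$V, cfg$d)
  dEtok[as.integer(rownames(dE)), ] <- dE
  dP <- rowsum(dx, group = cache$pos_vec)
  dEpos <- matrix(0, cfg$max_pos, cfg$d)
  dEpos[as.integer(rownames(dP)), ] <- dP
  g[["Etok"]] <- dEtok; g[["Epos"]] <- dEpos
  g
}

# ---- losses ----------------------------------------------------------------

# mean cross-entropy of rows of `logits` against 1-based class indices.
softmax_ce <- function(logits, target) {
  n <- nrow(logits)
  m <- apply(logits, 1L, max)
  z <- logits - m
  lse <- log(rowSums(exp(z)))
  picked <- z[cbind(seq_len(n), target)]
  loss <- mean(lse - picked)
  probs <- exp(z - lse)
  dlogits <- probs
  dlogits[cbind(seq_len(n), target)] <- dlogits[cbind(seq_len(n), target)] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

# mean sigmoid binary cross-entropy of a logit vector against 0/1 targets
sigmoid_bce <- function(logits, target) {
  n <- length(logits)
  loss <- mean(pmax(logits, 0) - logits * target + log1p(exp(-abs(logits))))
  sig <- 1 / (1 + exp(-logits))
  list(loss = loss, dlogits = (sig - target) / n, probs = sig)
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  zl <- lapply(params, function(x) x * 0)
  list(t = 0L, m = zl, v = zl)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat * gmat
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- batching --------------------------------------------------------------

# token-id lists (1-based, already truncated) -> dense ids/mask matrices
pad_batch <- function(id_lists, pad_idx) {
  B <- length(id_lists)
  L <- max(vapply(id_lists, length, integer(1L)))
  ids <- matrix(pad_idx, B, L)
  mask <- matrix(0L, B, L)
  for (b in seq_len(B)) {
    n <- length(id_lists[[b]])
    ids[b, seq_len(n)] <- id_lists[[b]]
    mask[b, seq_len(n)] <- 1L
  }
  list(ids = ids, mask = mask)
}

# mean+max pooling over real positions of each sequence.
# Returns pooled (B x 2d) and a cache for the backward pass.
pool_fwd <- function(Y, mask, B, L) {
  d <- ncol(Y)
  pooled <- matrix(0, B, 2L * d)
  argmax <- matrix(0L, B, d)
  nreal <- integer(B)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * L + 1L):(b * L)
    real <- rb[mask[b, ] == 1L]
    sub <- Y[real, , drop = FALSE]
    nreal[b] <- length(real)
    pooled[b, seq_len(d)] <- colMeans(sub)
    wm <- max.col(t(sub), ties.method = "first")
    argmax[b, ] <- real[wm]
    pooled[b, d + seq_len(d)] <- sub[cbind(wm, seq_len(d))]
  }
  list(pooled = pooled, argmax = argmax, nreal = nreal)
}

pool_bwd <- function(dpooled, cache, mask, B, L, n_rows) {
  d <- ncol(dpooled) / 2L
  dY <- matrix(0, n_rows, d)
  for (b in seq_len(B)) {
    rb <- ((b - 1L) * L + 1L):(b * L)
    real <- rb[mask[b, ] == 1L]
    dY[real, ] <- dY[real, ] + matrix(dpooled[b, seq_len(d)] / cache$nreal[b],
                                      length(real), d, byrow = TRUE)
    idx <- cbind(cache$argmax[b, ], seq_len(d))
    dY[idx] <- dY[idx] + dpooled[b, d + seq_len(d)]
  }
  dY
}
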