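# Numeric primitives of the network: gated recurrent encoder, word
# attention, dense layers, activations, and the Adam update.  All forward
# functions return the caches their matching backward functions need; the
# analytic gradients are verified against finite differences in the test
# suite.

sigmoid <- function(x) 1 / (1 + exp(-x))

# add a bias row-wise without sweep()'s overhead
add_bias <- function(x, b) x + rep(b, each = nrow(x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# Glorot-uniform initializer
glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

new_gru_params <- function(input_dim, units) {
  # gate order in the stacked blocks: update (z), reset (r), candidate (h)
  list(Wx = glorot(input_dim, 3L * units),
       Uzr = glorot(units, 2L * units),
       Uh = glorot(units, units),
       b = numeric(3L * units))
}

new_attention_params <- function(state_dim, attn_dim) {
  list(W = glorot(state_dim, attn_dim),
       b = numeric(attn_dim),
       u = stats::runif(attn_dim, -sqrt(6 / attn_dim), sqrt(6 / attn_dim)))
}

new_dense_params <- function(input_dim, units) {
  list(W = glorot(input_dim, units), b = numeric(units))
}

zeros_like <- function(p) lapply(p, function(x) {
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
})

# ---- GRU (one direction) ----------------------------------------------

# X: list over time of (batch x input_dim); mask: batch x T (1 real, 0 pad)
# masked positions carry the previous hidden state through unchanged
gru_forward <- function(X, mask, p, units, reverse = FALSE) {
  T_ <- length(X)
  B <- nrow(mask)
  h <- matrix(0, B, units)
  H <- vector("list", T_)
  cache <- vector("list", T_)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  iz <- seq_len(units)
  ir <- units + iz
  ih <- 2L * units + iz
  for (t in ord) {
    pre <- add_bias(X[[t]] %*% p$Wx, p$b)
    zr <- pre[, c(iz, ir), drop = FALSE] + h %*% p$Uzr
    z <- sigmoid(zr[, iz, drop = FALSE])
    r <- sigmoid(zr[, units + iz, drop = FALSE])
    cpre <- pre[, ih, drop = FALSE] + (r * h) %*% p$Uh
    cc <- tanh(cpre)
    hraw <- (1 - z) * h + z * cc
    m <- mask[, t]
    hnew <- m * hraw + (1 - m) * h
    cache[[t]] <- list(z = z, r = r, cc = cc, h_prev = h)
    h <- hnew
    H[[t]] <- h
  }
  list(H = H, cache = cache)
}

gru_backward <- function(dH, X, mask, p, cache, units, reverse = FALSE) {
  T_ <- length(X)
  B <- nrow(mask)
  g <- zeros_like(p)
  dh <- matrix(0, B, units)
  tUh <- t(p$Uh)
  tUzr <- t(p$Uzr)
  ord <- if (reverse) seq_len(T_) else rev(seq_len(T_))
  for (t in ord) {
    ca <- cache[[t]]
    dht <- dH[[t]] + dh
    m <- mask[, t]
    dhraw <- m * dht
    dhp <- (1 - m) * dht
    dz <- dhraw * (ca$cc - ca$h_prev)
    dcc <- dhraw * ca$z
    dhp <- dhp + dhraw * (1 - ca$z)
    dcpre <- dcc * (1 - ca$cc^2)
    g$Uh <- g$Uh + crossprod(ca$r * ca$h_prev, dcpre)
    drh <- dcpre %*% tUh
    dr <- drh * ca$h_prev
    dhp <- dhp + drh * ca$r
    dzpre <- dz * ca$z * (1 - ca$z)
    drpre <- dr * ca$r * (1 - ca$r)
    dzr <- cbind(dzpre, drpre)
    g$Uzr <- g$Uzr + crossprod(ca$h_prev, dzr)
    dhp <- dhp + dzr %*% tUzr
    dall <- cbind(dzr, dcpre)
    g$Wx <- g$Wx + crossprod(X[[t]], dall)
    g$b <- g$b + colSums(dall)
    dh <- dhp
  }
  g
}

# ---- bidirectional wrapper --------------------------------------------

bigru_forward <- function(X, mask, pf, pb, units) {
  fw <- gru_forward(X, mask, pf, units, reverse = FALSE)
  bw <- gru_forward(X, mask, pb, units, reverse = TRUE)
  H <- mapply(cbind, fw$H, bw$H, SIMPLIFY = FALSE)
  list(H = H, fw = fw, bw = bw)
}

bigru_backward <- function(dH, X, mask, pf, pb, fwd, units) {
  iu <- seq_len(units)
  dHf <- lapply(dH, function(m) m[, iu, drop = FALSE])
  dHb <- lapply(dH, function(m) m[, units + iu, drop = FALSE])
  list(f = gru_backward(dHf, X, mask, pf, fwd$fw$cache, units, FALSE),
       b = gru_backward(dHb, X, mask, pb, fwd$bw$cache, units, TRUE))
}

# ---- word attention ----------------------------------------------------

#' Word attention over encoder states
#'
#' Computes per-token scores `u_t = tanh(W h_t + b) . u_w`, a masked
#' softmax over them, and the attention-weighted context vector
#' `c = sum_t alpha_t h_t`.  Masked positions receive weight exactly 0 and
#' the unmasked weights sum to 1 per sentence.
#'
#' @param states list over time of `batch x state_dim` hidden-state
#'   matrices.
#' @param mask `batch x T` matrix of 1 (real token) / 0 (padding); every
#'   row needs at least one unmasked position.
#' @param params list with projection `W` (`state_dim x attn_dim`), bias
#'   `b` and context vector `u` (`attn_dim`).
#' @return List with `context` (`batch x state_dim`), `weights`
#'   (`batch x T`), and an internal cache used by the backward pass.
#' @export
attend <- function(states, mask, params) {
  T_ <- length(states)
  B <- nrow(mask)
  if (any(rowSums(mask) == 0))
    stop("attention over a fully masked sequence", call. = FALSE)
  S <- vector("list", T_)
  E <- matrix(-Inf, B, T_)
  for (t in seq_len(T_)) {
    st <- tanh(add_bias(states[[t]] %*% params$W, params$b))
    S[[t]] <- st
    E[, t] <- as.vector(st %*% params$u)
  }
  E[mask == 0] <- -Inf
  alpha <- softmax_rows(E)
  ctx <- matrix(0, B, ncol(states[[1L]]))
  for (t in seq_len(T_)) ctx <- ctx + alpha[, t] * states[[t]]
  list(context = ctx, weights = alpha, cache = list(S = S))
}

attend_backward <- function(dctx, states, mask, params, fwd) {
  T_ <- length(states)
  B <- nrow(mask)
  alpha <- fwd$weights
  S <- fwd$cache$S
  g <- zeros_like(params)
  dH <- vector("list", T_)
  dalpha <- matrix(0, B, T_)
  for (t in seq_len(T_)) {
    dalpha[, t] <- rowSums(dctx * states[[t]])
    dH[[t]] <- alpha[, t] * dctx
  }
  de <- alpha * (dalpha - rowSums(alpha * dalpha))
  de[mask == 0] <- 0
  tW <- t(params$W)
  for (t in seq_len(T_)) {
    st <- S[[t]]
    g$u <- g$u + colSums(st * de[, t])
    ds <- tcrossprod(de[, t], params$u)
    dpre <- ds * (1 - st^2)
    g$W <- g$W + crossprod(states[[t]], dpre)
    g$b <- g$b + colSums(dpre)
    dH[[t]] <- dH[[t]] + dpre %*% tW
  }
  list(grads = g, dstates = dH)
}

# ---- dense / dropout ---------------------------------------------------

dense_forward <- function(x, p, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  pre <- add_bias(x %*% p$W, p$b)
  out <- if (activation == "relu") relu(pre) else pre
  list(out = out, pre = pre, x = x)
}

dense_backward <- function(dout, p, cache, activation = c("relu", "linear")) {
  activation <- match.arg(activation)
  dpre <- if (activation == "relu") dout * (cache$pre > 0) else dout
  list(grads = list(W = crossprod(cache$x, dpre), b = colSums(dpre)),
       dx = dpre %*% t(p$W))
}

# inverted dropout; in eval mode the identity
dropout_mask <- function(dim_r, dim_c, rate, train) {
  if (!train || rate <= 0) return(NULL)
  matrix(stats::rbinom(dim_r * dim_c, 1L, 1 - rate) / (1 - rate),
         dim_r, dim_c)
}

apply_dropout <- function(x, msk) if (is.null(msk)) x else x * msk

# ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  z <- rapply(params, function(x)
    if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x)),
    how = "replace")
  list(m = z, v = z, t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t_ <- state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t_)
    vhat <- v / (1 - beta2^t_)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      list(p = out_p, m = out_m, v = out_v)
    } else upd(p, g, m, v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = t_))
}
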