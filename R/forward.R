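# Full network forward and backward passes.  The forward pass caches all
# intermediates; the backward pass consumes the cache and returns a
# gradient structure mirroring the parameter structure.  Dropout masks are
# drawn in the forward pass (training mode only) and reused in backward.

# softmax jacobian-vector product: dlogits given dP and probabilities P
softmax_vjp <- function(P, dP) P * (dP - rowSums(P * dP))

network_forward <- function(params, desc, emb, idx, mask, train = FALSE) {
  U <- desc$config$encoder_units
  rate <- desc$config$dropout_rate
  B <- nrow(idx)
  T_ <- ncol(idx)
  X <- lapply(seq_len(T_), function(t) emb[idx[, t], , drop = FALSE])
  enc <- bigru_forward(X, mask, params$enc_f, params$enc_b, U)
  H <- enc$H
  cache <- list(X = X, enc = enc, mask = mask)
  drop <- function(x) {
    msk <- dropout_mask(nrow(x), ncol(x), rate, train)
    list(out = apply_dropout(x, msk), msk = msk)
  }
  if (desc$single) {
    task <- desc$tasks
    att <- attend(H, mask, params$att)
    cd <- drop(att$context)
    dn <- dense_forward(cd$out, params$dense$task)
    phid <- drop(dn$out)
    logits <- add_bias(phid$out %*% params$head[[task]]$W,
                       params$head[[task]]$b)
    prob <- if (task == "emotion") sigmoid(logits) else softmax_rows(logits)
    cache <- c(cache, list(att = att, cd = cd, dn = dn, phid = phid,
                           logits = logits))
    probs <- stats::setNames(list(prob), task)
    return(list(probs = probs, cache = cache))
  }
  tks <- c("temporal", "sentiment", "emotion")
  satt <- attend(H, mask, params$att_shared)
  sattd <- drop(satt$context)
  priv <- NULL
  privd <- NULL
  if (desc$has_private) {
    priv <- lapply(tks, function(tk) attend(H, mask, params$att_private[[tk]]))
    names(priv) <- tks
    privd <- lapply(priv, function(a) drop(a$context))
  }
  dense_in <- if (desc$has_private)
    lapply(privd, `[[`, "out") else
      stats::setNames(rep(list(sattd$out), 3L), tks)
  dn <- lapply(tks, function(tk) dense_forward(dense_in[[tk]],
                                               params$dense[[tk]]))
  names(dn) <- tks
  phid <- lapply(dn, function(d) drop(d$out))
  head_out <- function(tk, x) {
    logits <- add_bias(x %*% params$head[[tk]]$W, params$head[[tk]]$b)
    prob <- if (tk == "emotion") sigmoid(logits) else softmax_rows(logits)
    list(logits = logits, prob = prob)
  }
  IR <- list()
  heads <- list()
  if (desc$arch == "mtl1") {
    for (tk in tks) heads[[tk]] <- head_out(tk, phid[[tk]]$out)
  } else if (desc$arch == "mtl4") {
    for (tk in tks) {
      IR[[tk]] <- cbind(phid[[tk]]$out, sattd$out)
      heads[[tk]] <- head_out(tk, IR[[tk]])
    }
  } else if (desc$arch == "mtl2") {
    IR$temporal <- cbind(phid$temporal$out, sattd$out)
    heads$temporal <- head_out("temporal", IR$temporal)
    IR$sentiment <- cbind(phid$sentiment$out, sattd$out, heads$temporal$prob)
    heads$sentiment <- head_out("sentiment", IR$sentiment)
    IR$emotion <- cbind(phid$emotion$out, sattd$out, heads$sentiment$prob)
    heads$emotion <- head_out("emotion", IR$emotion)
  } else {  # spanmlc, mtl3: cascaded intermediate representations
    IR$temporal <- cbind(phid$temporal$out, sattd$out)
    heads$temporal <- head_out("temporal", IR$temporal)
    IR$sentiment <- cbind(phid$sentiment$out, sattd$out, IR$temporal)
    heads$sentiment <- head_out("sentiment", IR$sentiment)
    IR$emotion <- cbind(phid$emotion$out, sattd$out, IR$sentiment)
    heads$emotion <- head_out("emotion", IR$emotion)
  }
  cache <- c(cache, list(satt = satt, sattd = sattd, priv = priv,
                         privd = privd, dn = dn, phid = phid, IR = IR,
                         heads = heads))
  list(probs = lapply(heads, `[[`, "prob"), cache = cache)
}

drop_bwd <- function(d, wrap) if (is.null(wrap$msk)) d else d * wrap$msk

network_backward <- function(params, desc, fwd, truth, weights) {
  cache <- fwd$cache
  mask <- cache$mask
  H <- cache$enc$H
  B <- nrow(mask)
  U <- desc$config$encoder_units
  g <- list()
  dH <- lapply(H, function(m) matrix(0, nrow(m), ncol(m)))
  add_dH <- function(dh_list) for (t in seq_along(dH))
    dH[[t]] <<- dH[[t]] + dh_list[[t]]

  if (desc$single) {
    task <- desc$tasks
    P <- fwd$probs[[task]]
    Y <- truth[[task]]
    dlogits <- if (task == "emotion")
      (P - Y) / (B * ncol(P)) else (P - Y) / B
    g$head <- stats::setNames(list(list(
      W = crossprod(cache$phid$out, dlogits),
      b = colSums(dlogits))), task)
    dphid <- dlogits %*% t(params$head[[task]]$W)
    dphi <- drop_bwd(dphid, cache$phid)
    db <- dense_backward(dphi, params$dense$task, cache$dn)
    g$dense <- list(task = db$grads)
    dcd <- drop_bwd(db$dx, cache$cd)
    ab <- attend_backward(dcd, H, mask, params$att, cache$att)
    g$att <- ab$grads
    add_dH(ab$dstates)
  } else {
    tks <- c("temporal", "sentiment", "emotion")
    w <- stats::setNames(weights, tks)
    heads <- cache$heads
    # loss-derivative part of each head's logit gradient
    dlog_loss <- lapply(tks, function(tk) {
      P <- heads[[tk]]$prob
      Y <- truth[[tk]]
      if (is.null(Y)) return(matrix(0, nrow(P), ncol(P)))
      if (tk == "emotion") w[[tk]] * (P - Y) / (B * ncol(P))
      else w[[tk]] * (P - Y) / B
    })
    names(dlog_loss) <- tks
    M <- desc$mlp_dim
    Hd <- desc$state_dim
    iphi <- seq_len(M)
    isat <- M + seq_len(Hd)
    dsattd <- matrix(0, B, Hd)
    dphid <- stats::setNames(lapply(tks, function(tk)
      matrix(0, B, M)), tks)
    head_grad <- function(tk, x, dlogits)
      list(W = crossprod(x, dlogits), b = colSums(dlogits))
    g$head <- list()
    if (desc$arch == "mtl1") {
      for (tk in tks) {
        g$head[[tk]] <- head_grad(tk, cache$phid[[tk]]$out, dlog_loss[[tk]])
        dphid[[tk]] <- dlog_loss[[tk]] %*% t(params$head[[tk]]$W)
      }
    } else if (desc$arch == "mtl4") {
      for (tk in tks) {
        g$head[[tk]] <- head_grad(tk, cache$IR[[tk]], dlog_loss[[tk]])
        dIR <- dlog_loss[[tk]] %*% t(params$head[[tk]]$W)
        dphid[[tk]] <- dIR[, iphi, drop = FALSE]
        dsattd <- dsattd + dIR[, isat, drop = FALSE]
      }
    } else if (desc$arch == "mtl2") {
      # emotion head
      g$head$emotion <- head_grad("emotion", cache$IR$emotion,
                                  dlog_loss$emotion)
      dIR3 <- dlog_loss$emotion %*% t(params$head$emotion$W)
      dphid$emotion <- dIR3[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR3[, isat, drop = FALSE]
      dOS <- dIR3[, M + Hd + 1:3, drop = FALSE]
      dlog_s <- dlog_loss$sentiment +
        softmax_vjp(heads$sentiment$prob, dOS)
      g$head$sentiment <- head_grad("sentiment", cache$IR$sentiment, dlog_s)
      dIR2 <- dlog_s %*% t(params$head$sentiment$W)
      dphid$sentiment <- dIR2[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR2[, isat, drop = FALSE]
      dOT <- dIR2[, M + Hd + 1:3, drop = FALSE]
      dlog_t <- dlog_loss$temporal +
        softmax_vjp(heads$temporal$prob, dOT)
      g$head$temporal <- head_grad("temporal", cache$IR$temporal, dlog_t)
      dIR1 <- dlog_t %*% t(params$head$temporal$W)
      dphid$temporal <- dIR1[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR1[, isat, drop = FALSE]
    } else {  # spanmlc / mtl3: cascaded IRs
      g$head$emotion <- head_grad("emotion", cache$IR$emotion,
                                  dlog_loss$emotion)
      dIR3 <- dlog_loss$emotion %*% t(params$head$emotion$W)
      dphid$emotion <- dIR3[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR3[, isat, drop = FALSE]
      dIR2 <- dIR3[, (M + Hd) + seq_len(2L * (M + Hd)), drop = FALSE]
      g$head$sentiment <- head_grad("sentiment", cache$IR$sentiment,
                                    dlog_loss$sentiment)
      dIR2 <- dIR2 + dlog_loss$sentiment %*% t(params$head$sentiment$W)
      dphid$sentiment <- dIR2[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR2[, isat, drop = FALSE]
      dIR1 <- dIR2[, (M + Hd) + seq_len(M + Hd), drop = FALSE]
      g$head$temporal <- head_grad("temporal", cache$IR$temporal,
                                   dlog_loss$temporal)
      dIR1 <- dIR1 + dlog_loss$temporal %*% t(params$head$temporal$W)
      dphid$temporal <- dIR1[, iphi, drop = FALSE]
      dsattd <- dsattd + dIR1[, isat, drop = FALSE]
    }
    # dense layers
    g$dense <- list()
    ddense_in <- list()
    for (tk in tks) {
      dphi <- drop_bwd(dphid[[tk]], cache$phid[[tk]])
      db <- dense_backward(dphi, params$dense[[tk]], cache$dn[[tk]])
      g$dense[[tk]] <- db$grads
      ddense_in[[tk]] <- db$dx
    }
    # attentions
    if (desc$has_private) {
      g$att_private <- list()
      for (tk in tks) {
        dctx <- drop_bwd(ddense_in[[tk]], cache$privd[[tk]])
        ab <- attend_backward(dctx, H, mask, params$att_private[[tk]],
                              cache$priv[[tk]])
        g$att_private[[tk]] <- ab$grads
        add_dH(ab$dstates)
      }
    } else {
      for (tk in tks) dsattd <- dsattd + ddense_in[[tk]]
    }
    dsatt <- drop_bwd(dsattd, cache$sattd)
    ab <- attend_backward(dsatt, H, mask, params$att_shared, cache$satt)
    g$att_shared <- ab$grads
    add_dH(ab$dstates)
  }
  eb <- bigru_backward(dH, cache$X, mask, params$enc_f, params$enc_b,
                       cache$enc, U)
  g$enc_f <- eb$f
  g$enc_b <- eb$b
  # order fields like params so the optimizer can walk them in parallel
  g[names(params)]
}

#' Export attention weights for a sentence
#'
#' Runs the model in evaluation mode on one sentence and returns the
#' per-token attention weight vector of the shared layer and, where the
#' architecture has them, each task's private layer.  Each vector sums to
#' one over the real tokens.  Architectures without private attentions
#' return the shared layer only, with a warning.
#'
#' @param model a fitted [mtcascade] model.
#' @param tokens character vector of tokens (one sentence).
#' @param file optional path; when given, a `token  layer  weight` TSV is
#'   written there.
#' @return Named list of numeric weight vectors aligned to `tokens`.
#' @export
export_attention <- function(model, tokens, file = NULL) {
  stopifnot(inherits(model, "mtcascade"))
  desc <- model$desc
  vec <- vectorize_tokens(list(tokens), model$vocab,
                          max(length(tokens), 1L))
  fwd <- network_forward(model$params, desc, model$emb, vec$idx, vec$mask,
                         train = FALSE)
  keep <- seq_along(tokens)
  out <- list()
  if (desc$single) {
    out$shared <- as.vector(fwd$cache$att$weights[1L, keep])
    warning("architecture has no private attention layers; ",
            "returning the shared layer only")
  } else {
    out$shared <- as.vector(fwd$cache$satt$weights[1L, keep])
    if (desc$has_private) {
      for (tk in c("temporal", "sentiment", "emotion"))
        out[[tk]] <- as.vector(fwd$cache$priv[[tk]]$weights[1L, keep])
    } else {
      warning("architecture has no private attention layers; ",
              "returning the shared layer only")
    }
  }
  if (!is.null(file)) {
    df <- do.call(rbind, lapply(names(out), function(ly)
      data.frame(token = tokens, layer = ly, weight = out[[ly]])))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
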