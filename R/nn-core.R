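# Vectorised LSTM / CNN / attention primitives with hand-written
# backpropagation. All batched operations keep instances in rows; the
# sentence encoder flattens (batch, sentence) to one row dimension of size
# B * n1 so every LSTM time step is a single matrix product.

# ---- LSTM cell ------------------------------------------------------------

# gate order in the fused weight matrices: input, forget, cell, output
init_lstm <- function(in_dim, h, seed_offset = 0L) {
  list(
    Wx = matrix(runif(in_dim * 4L * h, -0.05, 0.05), in_dim, 4L * h),
    Wh = matrix(runif(h * 4L * h, -0.05, 0.05), h, 4L * h),
    b = rep(0, 4L * h)
  )
}

# xs: list of T matrices (M x in); mask: M x T in {0,1}. Masked steps carry
# the previous state through, so right-padded sequences end with the state
# of their last real token and all-pad rows stay at zero.
lstm_run <- function(xs, mask, p, reverse = FALSE) {
  T_ <- length(xs)
  M <- nrow(xs[[1]])
  h <- nrow(p$Wh)
  ord <- if (reverse) rev(seq_len(T_)) else seq_len(T_)
  H <- matrix(0, M, h)
  C <- matrix(0, M, h)
  cache <- vector("list", T_)
  for (t in ord) {
    a <- xs[[t]] %*% p$Wx + H %*% p$Wh
    a <- a + rep(p$b, each = M)
    i <- sigmoid(a[, seq_len(h), drop = FALSE])
    f <- sigmoid(a[, h + seq_len(h), drop = FALSE])
    g <- tanh(a[, 2L * h + seq_len(h), drop = FALSE])
    o <- sigmoid(a[, 3L * h + seq_len(h), drop = FALSE])
    c_new <- f * C + i * g
    tanh_c <- tanh(c_new)
    h_new <- o * tanh_c
    m <- mask[, t]
    cache[[t]] <- list(i = i, f = f, g = g, o = o, tanh_c = tanh_c,
                       Hprev = H, Cprev = C, m = m)
    H <- m * h_new + (1 - m) * H
    C <- m * c_new + (1 - m) * C
  }
  list(h = H, cache = cache, ord = ord)
}

lstm_backward <- function(dHf, xs, p, run) {
  M <- nrow(dHf)
  h <- ncol(dHf)
  dWx <- p$Wx * 0
  dWh <- p$Wh * 0
  db <- p$b * 0
  dxs <- vector("list", length(xs))
  dH <- dHf
  dC <- matrix(0, M, h)
  for (t in rev(run$ord)) {
    cc <- run$cache[[t]]
    m <- cc$m
    dh_new <- m * dH
    dc_new <- m * dC + dh_new * cc$o * (1 - cc$tanh_c^2)
    do_ <- dh_new * cc$tanh_c
    di <- dc_new * cc$g
    df <- dc_new * cc$Cprev
    dg <- dc_new * cc$i
    da <- cbind(di * cc$i * (1 - cc$i),
                df * cc$f * (1 - cc$f),
                dg * (1 - cc$g^2),
                do_ * cc$o * (1 - cc$o))
    dWx <- dWx + crossprod(xs[[t]], da)
    dWh <- dWh + crossprod(cc$Hprev, da)
    db <- db + colSums(da)
    dxs[[t]] <- da %*% t(p$Wx)
    dH <- (1 - m) * dH + da %*% t(p$Wh)
    dC <- (1 - m) * dC + dc_new * cc$f
  }
  list(dxs = dxs, grads = list(Wx = dWx, Wh = dWh, b = db))
}

# ---- parameter container --------------------------------------------------

init_params <- function(config, word_vocab_n, pos_vocab_n,
                        word_pretrained = NULL, pos_pretrained = NULL,
                        rel_pretrained = NULL, word_vocab = NULL,
                        pos_vocab = NULL) {
  cf <- config
  l <- cf$l1 + cf$l2
  set.seed(cf$seed)
  p <- list(
    word_emb = matrix(runif(word_vocab_n * cf$l1, -0.05, 0.05), word_vocab_n, cf$l1),
    pos_emb = matrix(runif(pos_vocab_n * cf$l2, -0.05, 0.05), pos_vocab_n, cf$l2),
    rel_emb = matrix(runif(4L * cf$m, -0.05, 0.05), 4L, cf$m),
    sent_f = init_lstm(l, cf$h1),
    sent_b = init_lstm(l, cf$h1),
    title_f = init_lstm(l, cf$h1),
    title_b = init_lstm(l, cf$h1),
    doc_f = init_lstm(2L * cf$h1, cf$h2),
    doc_b = init_lstm(2L * cf$h1, cf$h2),
    Wc = matrix(runif(cf$w * 2L * cf$h1 * cf$f, -0.05, 0.05), cf$w * 2L * cf$h1, cf$f),
    bc = rep(0, cf$f),
    W_att = matrix(runif(a_prime_dim(cf) * cf$m, -0.05, 0.05), a_prime_dim(cf), cf$m),
    Ws = matrix(runif(ds_dim(cf) * 2L, -0.05, 0.05), ds_dim(cf), 2L),
    bs = rep(0, 2L)
  )
  if (!is.null(word_pretrained) && !is.null(word_vocab)) {
    hit <- match(word_vocab, word_pretrained$vocab)
    p$word_emb[!is.na(hit), ] <- word_pretrained$matrix[hit[!is.na(hit)], , drop = FALSE]
  }
  if (!is.null(pos_pretrained) && !is.null(pos_vocab)) {
    hit <- match(pos_vocab, pos_pretrained$vocab)
    p$pos_emb[!is.na(hit), ] <- pos_pretrained$matrix[hit[!is.na(hit)], , drop = FALSE]
  }
  if (!is.null(rel_pretrained)) {
    p$rel_emb <- rel_pretrained$matrix
  }
  p$word_emb[1, ] <- 0
  p$pos_emb[1, ] <- 0
  p
}

# document representation width: 2*h2 (document BLSTM) + f (CNN) + 2*h1 (title)
a_prime_dim <- function(cf) 2L * cf$h2 + cf$f + 2L * cf$h1

# knowledge representation width by aggregation mode
k_dim <- function(cf) if (cf$mode == "con") 4L * cf$m else cf$m

ds_dim <- function(cf) a_prime_dim(cf) + k_dim(cf)

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

# ---- forward pass ----------------------------------------------------------

# batch: list(word B x n1 x n2, pos idem, title_word B x n2, title_pos idem,
#             rel B x 4, label integer 0/1)
cid_forward <- function(params, batch, config, train = FALSE) {
  cf <- config
  B <- dim(batch$word)[1]
  n1 <- cf$n1; n2 <- cf$n2
  M <- B * n1
  keep <- 1 - (if (train) cf$dropout else 0)

  # --- sentence encoder over all (instance, sentence) rows
  xs <- vector("list", n2)
  mask <- matrix(0, M, n2)
  wid_t <- vector("list", n2)
  pid_t <- vector("list", n2)
  for (t in seq_len(n2)) {
    wt <- as.vector(batch$word[, , t])
    pt <- as.vector(batch$pos[, , t])
    wid_t[[t]] <- wt
    pid_t[[t]] <- pt
    xs[[t]] <- cbind(params$word_emb[wt, , drop = FALSE],
                     params$pos_emb[pt, , drop = FALSE])
    mask[, t] <- as.numeric(wt != 1L)
  }
  run_sf <- lstm_run(xs, mask, params$sent_f, reverse = FALSE)
  run_sb <- lstm_run(xs, mask, params$sent_b, reverse = TRUE)
  De <- cbind(run_sf$h, run_sb$h)                     # M x 2h1
  drop_de <- if (keep < 1) matrix((runif(length(De)) < keep) / keep,
                                  nrow(De), ncol(De)) else NULL
  De_d <- if (is.null(drop_de)) De else De * drop_de

  sent_real <- matrix(as.numeric(rowSums(mask) > 0), B, n1)   # B x n1

  # --- document BLSTM over sentence vectors
  ds_list <- vector("list", n1)
  for (s in seq_len(n1)) {
    ds_list[[s]] <- De_d[(s - 1L) * B + seq_len(B), , drop = FALSE]
  }
  run_df <- lstm_run(ds_list, sent_real, params$doc_f, reverse = FALSE)
  run_db <- lstm_run(ds_list, sent_real, params$doc_b, reverse = TRUE)
  At <- cbind(run_df$h, run_db$h)                     # B x 2h2

  # --- CNN over adjacent sentence vectors, max-pooled
  P <- n1 - cf$w + 1L
  Zs <- vector("list", P)
  Xp_list <- vector("list", P)
  Ac <- matrix(-Inf, B, cf$f)
  amax <- matrix(0L, B, cf$f)
  for (pp in seq_len(P)) {
    Xp <- do.call(cbind, ds_list[pp:(pp + cf$w - 1L)])
    Z <- Xp %*% params$Wc + rep(params$bc, each = B)
    Z <- pmax(Z, 0)
    valid <- rowSums(sent_real[, pp:(pp + cf$w - 1L), drop = FALSE]) > 0
    Zm <- Z
    Zm[!valid, ] <- -Inf
    upd <- Zm > Ac
    Ac[upd] <- Zm[upd]
    amax[upd] <- pp
    Zs[[pp]] <- Z
    Xp_list[[pp]] <- Xp
  }
  Ac[!is.finite(Ac)] <- 0

  # --- title encoder (theme of the article)
  xt <- vector("list", n2)
  tmask <- matrix(0, B, n2)
  twid_t <- vector("list", n2)
  tpid_t <- vector("list", n2)
  for (t in seq_len(n2)) {
    wt <- batch$title_word[, t]
    pt <- batch$title_pos[, t]
    twid_t[[t]] <- wt
    tpid_t[[t]] <- pt
    xt[[t]] <- cbind(params$word_emb[wt, , drop = FALSE],
                     params$pos_emb[pt, , drop = FALSE])
    tmask[, t] <- as.numeric(wt != 1L)
  }
  run_tf <- lstm_run(xt, tmask, params$title_f, reverse = FALSE)
  run_tb <- lstm_run(xt, tmask, params$title_b, reverse = TRUE)
  Tt <- cbind(run_tf$h, run_tb$h)                     # B x 2h1
  drop_t <- if (keep < 1) matrix((runif(length(Tt)) < keep) / keep,
                                 nrow(Tt), ncol(Tt)) else NULL
  Tt_d <- if (is.null(drop_t)) Tt else Tt * drop_t

  Aprime <- cbind(At, Ac, Tt_d)                       # B x dim(A')

  # --- knowledge attention: s_k = (A' W r_k) / m, alpha = softmax(s)
  Rk <- vector("list", 4L)
  for (k in 1:4) {
    Rk[[k]] <- params$rel_emb[batch$rel[, k], , drop = FALSE]  # B x m
  }
  U <- Aprime %*% params$W_att                       # B x m
  S <- matrix(0, B, 4L)
  for (k in 1:4) S[, k] <- rowSums(U * Rk[[k]]) / cf$m
  alpha <- softmax_rows(S)

  # --- aggregation of weighted knowledge
  if (cf$mode == "sum") {
    K <- matrix(0, B, cf$m)
    for (k in 1:4) K <- K + alpha[, k] * Rk[[k]]
  } else if (cf$mode == "max") {
    kmax <- max.col(alpha, ties.method = "first")
    K <- matrix(0, B, cf$m)
    for (k in 1:4) {
      sel <- kmax == k
      if (any(sel)) K[sel, ] <- Rk[[k]][sel, , drop = FALSE]
    }
  } else if (cf$mode == "con") {
    K <- do.call(cbind, lapply(1:4, function(k) alpha[, k] * Rk[[k]]))
  } else {
    abort(sprintf("unknown aggregation mode '%s'", cf$mode))
  }
  if (!cf$use_kb) K[] <- 0

  # --- softmax classifier over [beta1 A'; beta2 K']
  Ds <- cbind(cf$beta1 * Aprime, cf$beta2 * K)
  drop_ds <- if (keep < 1) matrix((runif(length(Ds)) < keep) / keep,
                                  nrow(Ds), ncol(Ds)) else NULL
  Ds_d <- if (is.null(drop_ds)) Ds else Ds * drop_ds
  logits <- Ds_d %*% params$Ws + rep(params$bs, each = B)
  probs <- softmax_rows(logits)

  loss <- NA_real_
  if (!is.null(batch$label)) {
    loss <- -mean(log(pmax(probs[cbind(seq_len(B), batch$label + 1L)], 1e-12)))
  }

  list(
    probs = probs, alpha = alpha, loss = loss, Aprime = Aprime,
    cache = list(
      xs = xs, mask = mask, wid_t = wid_t, pid_t = pid_t,
      run_sf = run_sf, run_sb = run_sb, De = De, drop_de = drop_de,
      ds_list = ds_list, sent_real = sent_real, run_df = run_df,
      run_db = run_db, Zs = Zs, Xp_list = Xp_list, Ac = Ac, amax = amax,
      xt = xt, tmask = tmask, twid_t = twid_t, tpid_t = tpid_t,
      run_tf = run_tf, run_tb = run_tb, drop_t = drop_t,
      Rk = Rk, U = U, alpha = alpha, Ds_d = Ds_d, drop_ds = drop_ds,
      kmax = if (cf$mode == "max") kmax else NULL
    )
  )
}

# ---- backward pass ---------------------------------------------------------

cid_backward <- function(params, batch, config, fwd) {
  cf <- config
  cc <- fwd$cache
  B <- dim(batch$word)[1]
  n1 <- cf$n1; n2 <- cf$n2
  M <- B * n1
  h1 <- cf$h1; h2 <- cf$h2
  dA <- a_prime_dim(cf)

  g <- zero_like(params)

  Y <- matrix(0, B, 2L)
  Y[cbind(seq_len(B), batch$label + 1L)] <- 1
  dlogits <- (fwd$probs - Y) / B
  g$Ws <- crossprod(cc$Ds_d, dlogits)
  g$bs <- colSums(dlogits)
  dDs <- dlogits %*% t(params$Ws)
  if (!is.null(cc$drop_ds)) dDs <- dDs * cc$drop_ds

  dAprime <- cf$beta1 * dDs[, seq_len(dA), drop = FALSE]
  dK <- cf$beta2 * dDs[, dA + seq_len(k_dim(cf)), drop = FALSE]

  # knowledge aggregation + attention
  dalpha <- matrix(0, B, 4L)
  dRk <- lapply(1:4, function(k) matrix(0, B, cf$m))
  if (cf$use_kb) {
    if (cf$mode == "sum") {
      for (k in 1:4) {
        dalpha[, k] <- rowSums(dK * cc$Rk[[k]])
        dRk[[k]] <- dRk[[k]] + cc$alpha[, k] * dK
      }
    } else if (cf$mode == "max") {
      for (k in 1:4) {
        sel <- cc$kmax == k
        if (any(sel)) dRk[[k]][sel, ] <- dRk[[k]][sel, , drop = FALSE] +
            dK[sel, , drop = FALSE]
      }
    } else {
      for (k in 1:4) {
        dKk <- dK[, (k - 1L) * cf$m + seq_len(cf$m), drop = FALSE]
        dalpha[, k] <- rowSums(dKk * cc$Rk[[k]])
        dRk[[k]] <- dRk[[k]] + cc$alpha[, k] * dKk
      }
    }
    dS <- cc$alpha * (dalpha - rowSums(dalpha * cc$alpha))
    dU <- matrix(0, B, cf$m)
    for (k in 1:4) {
      dU <- dU + dS[, k] * cc$Rk[[k]] / cf$m
      dRk[[k]] <- dRk[[k]] + dS[, k] * cc$U / cf$m
    }
    g$W_att <- crossprod(fwd$Aprime, dU)
    dAprime <- dAprime + dU %*% t(params$W_att)
    for (k in 1:4) {
      rs <- rowsum(dRk[[k]], batch$rel[, k])
      u <- as.integer(rownames(rs))
      g$rel_emb[u, ] <- g$rel_emb[u, , drop = FALSE] + rs
    }
  }

  dAt <- dAprime[, seq_len(2L * h2), drop = FALSE]
  dAc <- dAprime[, 2L * h2 + seq_len(cf$f), drop = FALSE]
  dTt <- dAprime[, 2L * h2 + cf$f + seq_len(2L * h1), drop = FALSE]

  # title encoder
  if (!is.null(cc$drop_t)) dTt <- dTt * cc$drop_t
  bt_f <- lstm_backward(dTt[, seq_len(h1), drop = FALSE], cc$xt, params$title_f, cc$run_tf)
  bt_b <- lstm_backward(dTt[, h1 + seq_len(h1), drop = FALSE], cc$xt, params$title_b, cc$run_tb)
  g$title_f <- bt_f$grads
  g$title_b <- bt_b$grads
  for (t in seq_len(n2)) {
    dx <- bt_f$dxs[[t]] + bt_b$dxs[[t]]
    g$word_emb <- acc_emb(g$word_emb, cc$twid_t[[t]], dx[, seq_len(cf$l1), drop = FALSE])
    g$pos_emb <- acc_emb(g$pos_emb, cc$tpid_t[[t]], dx[, cf$l1 + seq_len(cf$l2), drop = FALSE])
  }

  # CNN max-pool: route each (instance, filter) gradient to its argmax window
  P <- n1 - cf$w + 1L
  dDe_d <- matrix(0, M, 2L * h1)
  for (pp in seq_len(P)) {
    sel <- (cc$amax == pp) * 1
    if (!any(sel > 0)) next
    dZ <- dAc * sel * (cc$Zs[[pp]] > 0)
    g$Wc <- g$Wc + crossprod(cc$Xp_list[[pp]], dZ)
    g$bc <- g$bc + colSums(dZ)
    dXp <- dZ %*% t(params$Wc)
    for (j in seq_len(cf$w)) {
      s <- pp + j - 1L
      rows <- (s - 1L) * B + seq_len(B)
      dDe_d[rows, ] <- dDe_d[rows, , drop = FALSE] +
        dXp[, (j - 1L) * 2L * h1 + seq_len(2L * h1), drop = FALSE]
    }
  }

  # document BLSTM
  bd_f <- lstm_backward(dAt[, seq_len(h2), drop = FALSE], cc$ds_list, params$doc_f, cc$run_df)
  bd_b <- lstm_backward(dAt[, h2 + seq_len(h2), drop = FALSE], cc$ds_list, params$doc_b, cc$run_db)
  g$doc_f <- bd_f$grads
  g$doc_b <- bd_b$grads
  for (s in seq_len(n1)) {
    rows <- (s - 1L) * B + seq_len(B)
    dDe_d[rows, ] <- dDe_d[rows, , drop = FALSE] + bd_f$dxs[[s]] + bd_b$dxs[[s]]
  }

  dDe <- if (is.null(cc$drop_de)) dDe_d else dDe_d * cc$drop_de

  # sentence BLSTM back to the embedding tables
  bs_f <- lstm_backward(dDe[, seq_len(h1), drop = FALSE], cc$xs, params$sent_f, cc$run_sf)
  bs_b <- lstm_backward(dDe[, h1 + seq_len(h1), drop = FALSE], cc$xs, params$sent_b, cc$run_sb)
  g$sent_f <- bs_f$grads
  g$sent_b <- bs_b$grads
  for (t in seq_len(n2)) {
    dx <- bs_f$dxs[[t]] + bs_b$dxs[[t]]
    g$word_emb <- acc_emb(g$word_emb, cc$wid_t[[t]], dx[, seq_len(cf$l1), drop = FALSE])
    g$pos_emb <- acc_emb(g$pos_emb, cc$pid_t[[t]], dx[, cf$l1 + seq_len(cf$l2), drop = FALSE])
  }

  # padding rows are pinned at zero
  g$word_emb[1, ] <- 0
  g$pos_emb[1, ] <- 0
  g
}

acc_emb <- function(demb, idx, grad_rows) {
  rs <- rowsum(grad_rows, idx)
  u <- as.integer(rownames(rs))
  demb[u, ] <- demb[u, , drop = FALSE] + rs
  demb
}

# ---- RMSprop ---------------------------------------------------------------

rmsprop_step <- function(params, grads, cache, lr, rho = 0.9, eps = 1e-6) {
  upd <- function(p, g, c) {
    if (is.list(p)) {
      out_p <- p; out_c <- c
      for (nm in names(p)) {
        r <- upd(p[[nm]], g[[nm]], c[[nm]])
        out_p[[nm]] <- r$p
        out_c[[nm]] <- r$c
      }
      list(p = out_p, c = out_c)
    } else {
      c_new <- rho * c + (1 - rho) * g * g
      list(p = p - lr * g / (sqrt(c_new) + eps), c = c_new)
    }
  }
  upd(params, grads, cache)
}
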