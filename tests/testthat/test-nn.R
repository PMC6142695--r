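# independent brute-force oracles, written against the formulas only
oracle_attention <- function(a, Re, W) {
  m <- ncol(Re)
  s <- numeric(4)
  for (k in 1:4) {
    acc <- 0
    for (i in seq_along(a)) for (j in seq_len(m)) {
      acc <- acc + a[i] * W[i, j] * Re[k, j]
    }
    s[k] <- acc / m
  }
  exp(s) / sum(exp(s))
}

oracle_softmax2 <- function(ds, Ws, bs) {
  z <- c(sum(ds * Ws[, 1]) + bs[1], sum(ds * Ws[, 2]) + bs[2])
  exp(z) / sum(exp(z))
}

oracle_conv_maxpool <- function(S, Wc, bc, w) {
  n1 <- nrow(S); d <- ncol(S); f <- ncol(Wc)
  best <- rep(0, f)
  first <- TRUE
  for (p in 1:(n1 - w + 1)) {
    x <- c()
    for (j in p:(p + w - 1)) x <- c(x, S[j, ])
    for (q in 1:f) {
      z <- max(sum(x * Wc[, q]) + bc[q], 0)
      if (first || z > best[q]) best[q] <- z
    }
    first <- FALSE
  }
  best
}

test_that("attention weights match a brute-force oracle and normalise", {
  set.seed(7)
  for (rep in 1:30) {
    dA <- sample(2:6, 1); m <- sample(2:5, 1)
    a <- rnorm(dA); W <- matrix(rnorm(dA * m), dA, m); Re <- matrix(rnorm(4 * m), 4, m)
    alpha <- attention_weights(a, Re, W)
    expect_lt(max(abs(alpha - oracle_attention(a, Re, W))), 1e-6)
    expect_equal(sum(alpha), 1, tolerance = 1e-12)
    expect_true(all(alpha >= 0))
  }
  # symmetric scores give uniform weights
  expect_equal(attention_weights(rep(0, 3), matrix(rnorm(12), 4, 3),
                                 matrix(rnorm(9), 3, 3)),
               rep(0.25, 4))
  expect_error(attention_weights(rnorm(3), matrix(0, 4, 2), matrix(0, 5, 2)),
               "shape mismatch")
})

test_that("softmax over scores (ln 2, 0, 0, 0) is (0.4, 0.2, 0.2, 0.2)", {
  # engineered so that A' W r_k / m produces exactly these scores
  m <- 2L
  Re <- rbind(c(1, 1), c(0, 0), c(0, 0), c(0, 0))
  W <- matrix(c(log(2), 0, 0, log(2)), 2, 2)
  a <- c(1, 1)  # u = (ln2, ln2); s_1 = (ln2 + ln2)/2 = ln2, s_2..4 = 0
  expect_equal(attention_weights(a, Re, W), c(0.4, 0.2, 0.2, 0.2),
               tolerance = 1e-12)
})

test_that("knowledge aggregation variants follow their definitions", {
  Re <- rbind(c(3, 4), c(1, 2), c(5, 6), c(7, 8))
  # sum with a one-hot weight vector returns the selected weighted row
  expect_equal(aggregate_knowledge(c(1, 0, 0, 0), Re, "sum"), c(3, 4))
  # max returns the original, unweighted row at the argmax
  expect_equal(aggregate_knowledge(c(0.1, 0.7, 0.1, 0.1), Re, "max"), c(1, 2))
  # con concatenates the weighted vectors segment by segment
  alpha <- c(0.1, 0.2, 0.3, 0.4)
  con <- aggregate_knowledge(alpha, Re, "con")
  expect_length(con, 8L)
  for (k in 1:4) expect_equal(con[(k - 1) * 2 + 1:2], alpha[k] * Re[k, ])
  # max ties break toward the lower index
  expect_equal(aggregate_knowledge(c(0.3, 0.3, 0.2, 0.2), Re, "max"), Re[1, ])
  expect_error(aggregate_knowledge(alpha, Re, "mean"))
})

test_that("random aggregation inputs match a direct oracle", {
  set.seed(8)
  for (rep in 1:30) {
    m <- sample(2:5, 1)
    Re <- matrix(rnorm(4 * m), 4, m)
    s <- rnorm(4)
    alpha <- exp(s) / sum(exp(s))
    o_sum <- rep(0, m)
    for (k in 1:4) o_sum <- o_sum + alpha[k] * Re[k, ]
    expect_lt(max(abs(aggregate_knowledge(alpha, Re, "sum") - o_sum)), 1e-6)
    expect_lt(max(abs(aggregate_knowledge(alpha, Re, "max") -
                        Re[which.max(alpha), ])), 1e-6)
  }
})

test_that("the softmax classifier matches closed forms and an oracle", {
  # zero weights: exact tie, resolved to null
  z <- classify(rnorm(3), rnorm(2), matrix(0, 5, 2), c(0, 0))
  expect_equal(z$probs, c(0.5, 0.5))
  expect_equal(z$label, "null")
  # logits (ln 3, 0) give probabilities (0.75, 0.25)
  a <- 1; k <- numeric(0)
  z <- classify(a, k, matrix(c(log(3), 0), 1, 2), c(0, 0))
  expect_equal(z$probs, c(0.75, 0.25), tolerance = 1e-12)
  set.seed(9)
  for (rep in 1:30) {
    dA <- sample(2:5, 1); dK <- sample(1:4, 1)
    a <- rnorm(dA); kk <- rnorm(dK)
    Ws <- matrix(rnorm((dA + dK) * 2), dA + dK, 2); bs <- rnorm(2)
    b1 <- runif(1, 0.5, 2); b2 <- runif(1, 0.5, 2)
    got <- classify(a, kk, Ws, bs, b1, b2)
    want <- oracle_softmax2(c(b1 * a, b2 * kk), Ws, bs)
    expect_lt(max(abs(got$probs - want)), 1e-6)
    expect_equal(sum(got$probs), 1, tolerance = 1e-12)
  }
})

test_that("convolution + max-pooling matches the enumerated windows", {
  # one all-ones filter, window 2, sentence vectors [[1,0],[0,2],[3,0]]:
  # window sums are 3 and 5, so the pooled value is 5
  S <- rbind(c(1, 0), c(0, 2), c(3, 0))
  Wc <- matrix(1, 4, 1)
  expect_equal(conv_maxpool(S, Wc, 0, w = 2L), 5)
  # all-zero inputs with zero bias pool to zero
  expect_equal(conv_maxpool(matrix(0, 3, 2), matrix(rnorm(8), 4, 2),
                            c(0, 0), w = 2L), c(0, 0))
  set.seed(10)
  for (rep in 1:30) {
    n1 <- sample(3:6, 1); d <- sample(2:4, 1); w <- sample(2:3, 1)
    f <- sample(1:4, 1)
    S <- matrix(rnorm(n1 * d), n1, d)
    Wc <- matrix(rnorm(w * d * f), w * d, f)
    bc <- rnorm(f)
    expect_lt(max(abs(conv_maxpool(S, Wc, bc, w) -
                        oracle_conv_maxpool(S, Wc, bc, w))), 1e-6)
  }
})

test_that("a one-unit LSTM step reproduces the gate recurrences by hand", {
  # single time step, scalar input x = 1, hand-set fused weights
  p <- list(Wx = matrix(c(0.5, -0.3, 0.8, 0.1), 1, 4),
            Wh = matrix(c(0.2, 0.2, -0.1, 0.4), 1, 4),
            b = c(0.1, -0.2, 0, 0.3))
  run <- cidkat:::lstm_run(list(matrix(1, 1, 1)), matrix(1, 1, 1), p)
  sig <- function(x) 1 / (1 + exp(-x))
  i <- sig(0.5 + 0.1); f <- sig(-0.3 - 0.2); g <- tanh(0.8); o <- sig(0.1 + 0.3)
  c1 <- f * 0 + i * g
  expect_equal(as.vector(run$h), o * tanh(c1), tolerance = 1e-12)
})

test_that("an all-pad sentence encodes to the zero vector", {
  cf <- fixture_small_config()
  batch <- random_batch(cf, B = 3L)
  batch$word[2, 4, ] <- 1L   # sentence 4 of instance 2 entirely padding
  batch$pos[2, 4, ] <- 1L
  set.seed(1)
  p <- cidkat:::init_params(cf, 20L, 6L)
  fwd <- cidkat:::cid_forward(p, batch, cf)
  De <- fwd$cache$De
  row <- (4L - 1L) * 3L + 2L  # (sentence 4, instance 2) in the flat layout
  expect_equal(as.vector(De[row, ]), rep(0, 2 * cf$h1))
})

test_that("the document representation has width 2*h2 + f + 2*h1", {
  # at the full-scale defaults the concatenation is 440 + 300 + 220 = 960
  expect_equal(cidkat:::a_prime_dim(cid_config()), 960L)
  set.seed(2)
  for (rep in 1:5) {
    cf <- cid_config(l1 = sample(3:6, 1), l2 = 2, m = sample(2:5, 1),
                     n1 = 5, n2 = 8, w = sample(2:4, 1), f = sample(2:6, 1),
                     h1 = sample(2:5, 1), h2 = sample(2:5, 1), dropout = 0)
    p <- cidkat:::init_params(cf, 15L, 5L)
    batch <- random_batch(cf, B = 2L, word_n = 15L, pos_n = 5L, seed = rep)
    fwd <- cidkat:::cid_forward(p, batch, cf)
    expect_equal(ncol(fwd$Aprime), 2 * cf$h2 + cf$f + 2 * cf$h1)
    expect_equal(dim(fwd$probs), c(2L, 2L))
  }
})

test_that("the batched forward agrees with the single-instance operations", {
  cf <- fixture_small_config(mode = "con")
  set.seed(3)
  p <- cidkat:::init_params(cf, 20L, 6L)
  batch <- random_batch(cf, B = 4L, seed = 5)
  fwd <- cidkat:::cid_forward(p, batch, cf)
  for (b in 1:4) {
    Re <- p$rel_emb[batch$rel[b, ], , drop = FALSE]
    a <- fwd$Aprime[b, ]
    alpha <- attention_weights(a, Re, p$W_att)
    expect_lt(max(abs(alpha - fwd$alpha[b, ])), 1e-10)
    kp <- aggregate_knowledge(alpha, Re, cf$mode)
    got <- classify(a, kp, p$Ws, p$bs, cf$beta1, cf$beta2)
    expect_lt(max(abs(got$probs - fwd$probs[b, ])), 1e-10)
  }
})

test_that("analytic gradients match finite differences", {
  cf <- fixture_small_config()
  gen <- generate_corpus(synth_config(n_docs = 4, seed = 17))
  ds <- cid_prepare(gen$corpus, gen$kb, cf)
  for (mode in c("sum", "con")) {
    cfm <- fixture_small_config(mode = mode)
    set.seed(6)
    p <- cidkat:::init_params(cfm, length(ds$vocab$word), length(ds$vocab$pos))
    batch <- cidkat:::dataset_batch(ds, seq_len(min(4L, length(ds$label))))
    fwd <- cidkat:::cid_forward(p, batch, cfm, train = TRUE)
    g <- cidkat:::cid_backward(p, batch, cfm, fwd)
    loss_at <- function(pp) cidkat:::cid_forward(pp, batch, cfm, train = TRUE)$loss
    eps <- 1e-5
    check <- function(path, idx) {
      getp <- function(pp) { x <- pp; for (k in path) x <- x[[k]]; x }
      setp <- function(pp, v) {
        cur <- getp(pp); cur[idx] <- v
        if (length(path) == 1) pp[[path]] <- cur else pp[[path[1]]][[path[2]]] <- cur
        pp
      }
      v0 <- getp(p)[idx]
      num <- (loss_at(setp(p, v0 + eps)) - loss_at(setp(p, v0 - eps))) / (2 * eps)
      ana <- getp(g)[idx]
      expect_lt(abs(num - ana), 1e-6 + 1e-3 * (abs(num) + abs(ana)))
    }
    check("Ws", 3L); check("bs", 2L); check("W_att", 4L); check("rel_emb", 5L)
    check("Wc", 6L); check("bc", 1L)
    check(c("sent_f", "Wx"), 8L); check(c("sent_b", "Wh"), 2L)
    check(c("doc_f", "Wx"), 3L); check(c("doc_b", "b"), 4L)
    check(c("title_f", "Wx"), 5L); check(c("title_b", "Wh"), 1L)
    check("word_emb", 200L); check("pos_emb", 15L)
  }
})
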