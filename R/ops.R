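# Single-instance views of the network's core operations. The training
# loop uses the batched implementations in nn-core.R; tests pin the two
# paths together and against independent oracles.

#' Knowledge attention weights
#'
#' Scores each knowledge relation vector against the document
#' representation, `s_k = (a' W r_k) / m`, and softmax-normalises the four
#' scores. `m` is the knowledge embedding width, used as a scaling factor.
#'
#' @param a_prime Numeric vector: the document representation.
#' @param rel_vectors `4 x m` matrix of relation embedding vectors (rows in
#'   the instance's relation-sequence order).
#' @param W `length(a_prime) x m` attention weight matrix.
#' @return Numeric vector of 4 nonnegative weights summing to 1.
#' @export
attention_weights <- function(a_prime, rel_vectors, W) {
  if (length(a_prime) != nrow(W) || ncol(W) != ncol(rel_vectors)) {
    abort("attention shape mismatch: a', W and relation vectors disagree")
  }
  m <- ncol(rel_vectors)
  u <- as.vector(a_prime %*% W)
  s <- as.vector(rel_vectors %*% u) / m
  e <- exp(s - max(s))
  e / sum(e)
}

#' Aggregate weighted knowledge vectors
#'
#' The three aggregation variants of the attention-weighted relation
#' vectors `r'_k = alpha_k * r_k`: `"sum"` adds them; `"max"` selects the
#' original (unweighted) row with the largest weight, ties to the lower
#' index; `"con"` concatenates all four weighted vectors.
#'
#' @param alpha Length-4 attention weights.
#' @param rel_vectors `4 x m` matrix of relation vectors.
#' @param mode `"sum"`, `"max"` or `"con"`.
#' @return Numeric vector of length `m` (`sum`, `max`) or `4m` (`con`).
#' @export
aggregate_knowledge <- function(alpha, rel_vectors, mode = c("sum", "max", "con")) {
  mode <- match.arg(mode)
  switch(mode,
    sum = as.vector(crossprod(rel_vectors, alpha)),
    max = rel_vectors[which.max(alpha), ],
    con = as.vector(t(alpha * rel_vectors))
  )
}

#' Softmax classification of a candidate pair
#'
#' Concatenates the weighted document and knowledge representations,
#' `D_s = [beta1 a'; beta2 k']`, applies the affine softmax layer and picks
#' the larger class probability; an exact tie resolves to `"null"`.
#'
#' @param a_prime Document representation vector.
#' @param k_prime Knowledge representation vector.
#' @param Ws,bs Classifier weights (`(len(a')+len(k')) x 2`) and bias (2).
#' @param beta1,beta2 Representation weights (default 1).
#' @return A list: `probs` (length-2, `null` then `CID`, sums to 1) and
#'   `label` (`"null"` or `"CID"`).
#' @export
classify <- function(a_prime, k_prime, Ws, bs, beta1 = 1, beta2 = 1) {
  ds <- c(beta1 * a_prime, beta2 * k_prime)
  z <- as.vector(ds %*% Ws) + bs
  e <- exp(z - max(z))
  p <- e / sum(e)
  list(probs = p, label = if (p[2] > p[1]) "CID" else "null")
}

#' Convolution and max-pooling over sentence vectors
#'
#' Valid windows of `w` consecutive sentence vectors are concatenated,
#' passed through the ReLU convolution `ReLU(Wc x + bc)` and max-pooled
#' per filter over window positions. Windows made entirely of padding
#' sentences are excluded from the max; if no window survives the result
#' is zero.
#'
#' @param sent_vectors `n1 x d` matrix of sentence vectors.
#' @param Wc `(w*d) x f` convolution weights.
#' @param bc Length-`f` bias.
#' @param w Window width in sentences.
#' @param real Logical length-`n1`: which rows are real sentences.
#' @return Length-`f` vector of pooled filter activations.
#' @export
conv_maxpool <- function(sent_vectors, Wc, bc, w,
                         real = rep(TRUE, nrow(sent_vectors))) {
  n1 <- nrow(sent_vectors)
  stopifnot(w >= 1L, n1 >= w, nrow(Wc) == w * ncol(sent_vectors))
  f <- ncol(Wc)
  out <- rep(-Inf, f)
  for (p in seq_len(n1 - w + 1L)) {
    if (!any(real[p:(p + w - 1L)])) next
    x <- unlist(lapply(p:(p + w - 1L), function(j) sent_vectors[j, ]))
    z <- pmax(as.vector(x %*% Wc) + bc, 0)
    out <- pmax(out, z)
  }
  out[!is.finite(out)] <- 0
  out
}
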