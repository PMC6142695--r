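#' Model configuration
#'
#' All hyperparameters of the document-level network with knowledge
#' attention. The defaults are the full-scale settings: 100-dimensional
#' word and 10-dimensional part-of-speech embeddings (so each token is a
#' 110-vector), 200-dimensional knowledge embeddings, up to 30 sentences of
#' 120 words, a width-5 convolution with 300 filters, bidirectional LSTMs
#' of 220 (sentence/title) and 440 (document) concatenated units (110 and
#' 220 per direction, matching their input widths), weighted-sum knowledge
#' aggregation, mini-batches of 8, RMSprop at learning rate 0.001 and
#' dropout 0.5 on the LSTM outputs and the softmax input. The article and
#' knowledge representations are weighted by `beta1` and `beta2`, both 1.
#'
#' @param l1,l2 Word / PoS embedding widths.
#' @param m Knowledge (relation) embedding width.
#' @param n1,n2 Maximum sentences per article, tokens per sentence.
#' @param w,f CNN window (in sentences) and filter count.
#' @param h1,h2 Per-direction hidden units of the sentence/title and
#'   document LSTMs (concatenated widths are `2*h1`, `2*h2`).
#' @param mode Knowledge aggregation: `"sum"`, `"max"` or `"con"`.
#' @param beta1,beta2 Weights of the text and knowledge representations.
#' @param dropout Dropout rate.
#' @param lr RMSprop learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param use_kb `FALSE` zeroes the knowledge representation (the
#'   "without knowledge base" ablation).
#' @param seed Integer seed controlling initialization, shuffling, dropout.
#' @return A list of class `cid_config`.
#' @export
cid_config <- function(l1 = 100L, l2 = 10L, m = 200L, n1 = 30L, n2 = 120L,
                       w = 5L, f = 300L, h1 = 110L, h2 = 220L,
                       mode = c("sum", "max", "con"),
                       beta1 = 1, beta2 = 1, dropout = 0.5, lr = 0.001,
                       batch_size = 8L, epochs = 30L, use_kb = TRUE,
                       seed = 1L) {
  mode <- match.arg(mode)
  cf <- list(l1 = as.integer(l1), l2 = as.integer(l2), m = as.integer(m),
             n1 = as.integer(n1), n2 = as.integer(n2), n3 = 4L,
             w = as.integer(w), f = as.integer(f),
             h1 = as.integer(h1), h2 = as.integer(h2), mode = mode,
             beta1 = beta1, beta2 = beta2, dropout = dropout, lr = lr,
             batch_size = as.integer(batch_size), epochs = as.integer(epochs),
             use_kb = isTRUE(use_kb), seed = as.integer(seed))
  stopifnot(cf$l1 > 0, cf$l2 > 0, cf$m > 0, cf$n1 >= cf$w, cf$n2 > 0,
            cf$w > 0, cf$f > 0, cf$h1 > 0, cf$h2 > 0,
            cf$dropout >= 0, cf$dropout < 1, cf$lr > 0,
            cf$batch_size > 0, cf$epochs >= 0)
  class(cf) <- "cid_config"
  cf
}

#' Fit the document-level model with knowledge attention
#'
#' Trains by mini-batch RMSprop on the cross-entropy loss, with dropout on
#' the LSTM outputs and the softmax input. When a development set is given,
#' the parameters with the best development F-score are kept (training
#' still runs all epochs); otherwise the final parameters are returned.
#' Two runs with the same configuration and data are identical.
#'
#' @param train A `cid_dataset` from [cid_prepare()].
#' @param config A [cid_config()].
#' @param dev Optional `cid_dataset` for best-F checkpointing.
#' @param pretrained Optional list of pretrained vectors: `word`, `pos`
#'   ([read_word_vectors()] shape), `rel` ([read_relation_vectors()]).
#' @param verbose Print per-epoch loss.
#' @return An object of class `cid_model`: `params`, `config`, `vocab`,
#'   `history` (per-epoch tibble).
#' @export
cid_fit <- function(train, config = cid_config(), dev = NULL,
                    pretrained = NULL, verbose = FALSE) {
  cf <- config
  n <- length(train$label)
  if (n == 0L) abort("empty training set")
  set.seed(cf$seed)
  params <- init_params(cf, length(train$vocab$word), length(train$vocab$pos),
                        word_pretrained = pretrained$word,
                        pos_pretrained = pretrained$pos,
                        rel_pretrained = pretrained$rel,
                        word_vocab = train$vocab$word,
                        pos_vocab = train$vocab$pos)
  cache <- zero_like(params)
  history <- vector("list", cf$epochs)
  best <- list(f = -Inf, params = params)
  for (epoch in seq_len(cf$epochs)) {
    ord <- sample.int(n)
    losses <- numeric(0)
    for (b0 in seq(1L, n, by = cf$batch_size)) {
      idx <- ord[b0:min(b0 + cf$batch_size - 1L, n)]
      batch <- dataset_batch(train, idx)
      fwd <- cid_forward(params, batch, cf, train = TRUE)
      grads <- cid_backward(params, batch, cf, fwd)
      stepped <- rmsprop_step(params, grads, cache, cf$lr)
      params <- stepped$p
      cache <- stepped$c
      params$word_emb[1, ] <- 0
      params$pos_emb[1, ] <- 0
      losses <- c(losses, fwd$loss)
    }
    dev_f <- NA_real_
    if (!is.null(dev)) {
      model_now <- structure(list(params = params, config = cf,
                                  vocab = train$vocab), class = "cid_model")
      pred <- predict(model_now, dev)
      ev <- evaluate_relations(pred, dev$candidates)
      dev_f <- ev$f[ev$stratum == "overall"]
      if (dev_f > best$f) best <- list(f = dev_f, params = params)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       loss = mean(losses), dev_f = dev_f)
    if (verbose) {
      message(sprintf("epoch %d  loss %.4f%s", epoch, mean(losses),
                      if (is.na(dev_f)) "" else sprintf("  dev F %.1f", dev_f)))
    }
  }
  if (!is.null(dev) && is.finite(best$f)) params <- best$params
  structure(
    list(params = params, config = cf, vocab = train$vocab,
         history = dplyr::bind_rows(history)),
    class = "cid_model"
  )
}

#' Predict CID relations for a dataset
#'
#' Stateless inference: per candidate instance, the predicted label, the
#' probability of the positive class and the four attention weights over
#' the knowledge relation types. Ties in the class probabilities resolve to
#' `"null"`.
#'
#' @param object A `cid_model` from [cid_fit()].
#' @param dataset A `cid_dataset` prepared with the model's vocabulary.
#' @param ... Unused.
#' @return A tibble: `doc_id`, `chemical_id`, `disease_id`, `label`
#'   (predicted), `prob_cid`, and `alpha_marker_mechanism`,
#'   `alpha_therapeutic`, `alpha_inferred`, `alpha_null`.
#' @export
predict.cid_model <- function(object, dataset, ...) {
  cf <- object$config
  n <- length(dataset$label)
  inst <- dataset$instances
  if (n == 0L) {
    return(tibble::tibble(
      doc_id = character(), chemical_id = character(), disease_id = character(),
      label = character(), prob_cid = numeric(),
      alpha_marker_mechanism = numeric(), alpha_therapeutic = numeric(),
      alpha_inferred = numeric(), alpha_null = numeric()
    ))
  }
  probs <- matrix(0, n, 2L)
  alpha <- matrix(0, n, 4L)
  for (b0 in seq(1L, n, by = cf$batch_size)) {
    idx <- b0:min(b0 + cf$batch_size - 1L, n)
    batch <- dataset_batch(dataset, idx)
    fwd <- cid_forward(object$params, batch, cf, train = FALSE)
    probs[idx, ] <- fwd$probs
    alpha[idx, ] <- fwd$alpha
  }
  # the attention weights are reported per canonical type regardless of the
  # position a type occupied in the padded relation sequence; "null" may
  # fill several padding slots, whose weights are averaged
  alpha_sum <- matrix(0, n, 4L)
  alpha_cnt <- matrix(0L, n, 4L)
  for (k in 1:4) {
    for (ktype in 1:4) {
      sel <- dataset$rel[, k] == ktype
      if (any(sel)) {
        alpha_sum[sel, ktype] <- alpha_sum[sel, ktype] + alpha[sel, k]
        alpha_cnt[sel, ktype] <- alpha_cnt[sel, ktype] + 1L
      }
    }
  }
  alpha_by_type <- alpha_sum / alpha_cnt
  alpha_by_type[alpha_cnt == 0L] <- NA_real_
  tibble::tibble(
    doc_id = inst$doc_id, chemical_id = inst$chemical_id,
    disease_id = inst$disease_id,
    label = ifelse(probs[, 2] > probs[, 1], "CID", "null"),
    prob_cid = probs[, 2],
    alpha_marker_mechanism = alpha_by_type[, 1],
    alpha_therapeutic = alpha_by_type[, 2],
    alpha_inferred = alpha_by_type[, 3],
    alpha_null = alpha_by_type[, 4]
  )
}

#' @export
print.cid_model <- function(x, ...) {
  cf <- x$config
  cat(sprintf(
    "<cid_model> mode=%s%s  dim(A')=%d  epochs=%d  final loss %.4f\n",
    cf$mode, if (cf$use_kb) "" else " (no KB)", a_prime_dim(cf), cf$epochs,
    tail(x$history$loss, 1)
  ))
  invisible(x)
}

#' @describeIn cid_fit Per-epoch training history (epoch, loss, dev F).
#' @param x A `cid_model`.
#' @exportS3Method generics::tidy
tidy.cid_model <- function(x, ...) {
  x$history
}

#' @describeIn cid_fit One-row model summary: aggregation mode, epochs,
#'   final loss, best development F, parameter count.
#' @exportS3Method generics::glance
glance.cid_model <- function(x, ...) {
  count <- function(p) if (is.list(p)) sum(vapply(p, count, 0)) else length(p)
  tibble::tibble(
    mode = x$config$mode,
    use_kb = x$config$use_kb,
    epochs = nrow(x$history),
    final_loss = tail(x$history$loss, 1),
    best_dev_f = if (all(is.na(x$history$dev_f))) NA_real_ else
      max(x$history$dev_f, na.rm = TRUE),
    n_parameters = count(x$params)
  )
}

#' Save / load a fitted model
#'
#' Single-file parameter archive (RDS) holding parameters, configuration,
#' vocabulary and training history.
#'
#' @param model A `cid_model`.
#' @param path File path.
#' @return `cid_save` the path invisibly; `cid_load` the model.
#' @export
cid_save <- function(model, path) {
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname cid_save
#' @export
cid_load <- function(path) {
  structure(readRDS(path), class = "cid_model")
}
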