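#' Build a token vocabulary
#'
#' Deterministic vocabulary construction: tokens are ordered by decreasing
#' frequency, ties broken lexicographically, and the reserved entries
#' `"<PAD>"` (index 1) and `"<UNK>"` (index 2) are prepended. Tokens below
#' `min_count` are excluded and map to `"<UNK>"` at lookup time.
#'
#' @param tokens Character vector (all tokens of the corpus, with repeats).
#' @param min_count Minimum frequency for inclusion (default 1).
#' @return Character vector: the vocabulary, reserved entries first.
#' @export
build_vocab <- function(tokens, min_count = 1L) {
  if (length(tokens) == 0L) return(c("<PAD>", "<UNK>"))
  tab <- table(tokens)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  c("<PAD>", "<UNK>", names(tab)[ord])
}

# token -> index with UNK fallback (PAD = 1, UNK = 2)
vocab_index <- function(tokens, vocab) {
  i <- match(tokens, vocab)
  i[is.na(i)] <- 2L
  i
}

#' Initialize an embedding table
#'
#' Rows are drawn uniform(-0.05, 0.05) under the given seed; where a token
#' is found in the pretrained vectors its row is copied instead. The
#' `"<PAD>"` row is always zero, so padded positions contribute nothing.
#'
#' @param vocab Character vector from [build_vocab()] (or the 4 relation
#'   types from [cid_relation_types()]).
#' @param dim Embedding width.
#' @param pretrained Optional list with `vocab` and `matrix`
#'   ([read_word_vectors()] / [read_relation_vectors()] shape).
#' @param seed Integer seed for the random rows.
#' @return A `|vocab| x dim` numeric matrix with `rownames(vocab)`.
#' @export
init_embedding <- function(vocab, dim, pretrained = NULL, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mat <- matrix(runif(length(vocab) * dim, -0.05, 0.05), length(vocab), dim)
  if (!is.null(pretrained)) {
    pv <- pretrained$vocab %||% pretrained$relations
    if (ncol(pretrained$matrix) != dim) {
      abort(sprintf("pretrained vectors have dim %d, table wants %d",
                    ncol(pretrained$matrix), dim))
    }
    hit <- match(vocab, pv)
    mat[!is.na(hit), ] <- pretrained$matrix[hit[!is.na(hit)], , drop = FALSE]
  }
  if (vocab[1] == "<PAD>") mat[1, ] <- 0
  rownames(mat) <- vocab
  mat
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Tensorize a tokenized document and relation sequence
#'
#' Maps tokens to vocabulary indices and lays them out on the fixed
#' `n1 x n2` grid the encoder consumes: sentences beyond `n1` and tokens
#' beyond `n2` are head-kept (clipped at the tail), missing positions are
#' `"<PAD>"` (index 1), out-of-vocabulary tokens are `"<UNK>"` (index 2).
#'
#' @param tokdoc A `cid_tokdoc` from [tokenize_candidate()].
#' @param relseq Character vector of 4 relation types
#'   ([lookup_relations()] row).
#' @param word_vocab,pos_vocab Vocabularies from [build_vocab()].
#' @param n1 Maximum sentences per article (default 30).
#' @param n2 Maximum tokens per sentence (default 120).
#' @return A list: `word_ids`, `pos_ids` (`n1 x n2` integer matrices),
#'   `title_word_ids`, `title_pos_ids` (length `n2`), `relation_ids`
#'   (length 4, indices into [cid_relation_types()]).
#' @export
tensorize <- function(tokdoc, relseq, word_vocab, pos_vocab,
                      n1 = 30L, n2 = 120L) {
  sent <- head(tokdoc$sentences, n1)
  pos <- head(tokdoc$pos_tags, n1)
  word_ids <- matrix(1L, n1, n2)
  pos_ids <- matrix(1L, n1, n2)
  for (i in seq_along(sent)) {
    toks <- head(sent[[i]], n2)
    if (length(toks)) {
      word_ids[i, seq_along(toks)] <- vocab_index(toks, word_vocab)
      pos_ids[i, seq_along(toks)] <- vocab_index(head(pos[[i]], n2), pos_vocab)
    }
  }
  ttl <- head(tokdoc$title_tokens, n2)
  tpl <- head(tokdoc$title_pos, n2)
  title_word_ids <- rep(1L, n2)
  title_pos_ids <- rep(1L, n2)
  if (length(ttl)) {
    title_word_ids[seq_along(ttl)] <- vocab_index(ttl, word_vocab)
    title_pos_ids[seq_along(tpl)] <- vocab_index(tpl, pos_vocab)
  }
  relation_ids <- match(relseq, cid_relation_types())
  stopifnot(length(relation_ids) == 4L, !anyNA(relation_ids))
  list(word_ids = word_ids, pos_ids = pos_ids,
       title_word_ids = title_word_ids, title_pos_ids = title_pos_ids,
       relation_ids = relation_ids)
}
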