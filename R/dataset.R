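#' Prepare model-ready instances from a corpus
#'
#' Runs the full preprocessing chain for every candidate pair: mention
#' substitution with candidate boundary markers, sentence splitting, number
#' masking, part-of-speech tagging, knowledge-base lookup, and
#' tensorization onto the fixed `n1 x n2` grid. Candidates flagged
#' `filtered` by the span filter are excluded from the model input but kept
#' in the candidate table for false-negative accounting.
#'
#' @param corpus Corpus tibble from [read_pubtator()] or
#'   [generate_corpus()].
#' @param kb Knowledge base from [read_knowledge_table()].
#' @param config A [cid_config()].
#' @param K,apply_span_filter Passed to [build_candidates()].
#' @param vocab Optional list with `word` and `pos` vocabularies (reuse the
#'   training vocabulary for development/test data); built from this corpus
#'   when `NULL`.
#' @param tagger Tagging plugin.
#' @return A list of class `cid_dataset`: `candidates` (tibble),
#'   `instances` (the non-filtered candidate rows), arrays `word`, `pos`
#'   (N x n1 x n2), `title_word`, `title_pos` (N x n2), `rel` (N x 4),
#'   `label` (integer 0/1), and `vocab`.
#' @export
cid_prepare <- function(corpus, kb, config = cid_config(), K = 4L,
                        apply_span_filter = FALSE, vocab = NULL,
                        tagger = rule_pos_tagger) {
  cf <- config
  candidates <- build_candidates(corpus, K = K,
                                 apply_span_filter = apply_span_filter,
                                 tagger = tagger)
  inst <- candidates[!candidates$filtered, , drop = FALSE]
  n <- nrow(inst)
  tokdocs <- vector("list", n)
  doc_rows <- match(inst$doc_id, corpus$doc_id)
  for (i in seq_len(n)) {
    tokdocs[[i]] <- tokenize_candidate(corpus[doc_rows[i], , drop = FALSE],
                                       inst$chemical_id[i], inst$disease_id[i],
                                       tagger = tagger)
  }
  if (is.null(vocab)) {
    wtok <- unlist(purrr::map(tokdocs, ~ unlist(.x$sentences)), use.names = FALSE)
    ptok <- unlist(purrr::map(tokdocs, ~ unlist(.x$pos_tags)), use.names = FALSE)
    vocab <- list(word = build_vocab(wtok), pos = build_vocab(ptok))
  }
  relseq <- lookup_relations(inst$chemical_id, inst$disease_id, kb)
  word <- array(1L, c(n, cf$n1, cf$n2))
  pos <- array(1L, c(n, cf$n1, cf$n2))
  title_word <- matrix(1L, n, cf$n2)
  title_pos <- matrix(1L, n, cf$n2)
  rel <- matrix(1L, n, 4L)
  for (i in seq_len(n)) {
    tz <- tensorize(tokdocs[[i]], relseq[i, ], vocab$word, vocab$pos,
                    n1 = cf$n1, n2 = cf$n2)
    word[i, , ] <- tz$word_ids
    pos[i, , ] <- tz$pos_ids
    title_word[i, ] <- tz$title_word_ids
    title_pos[i, ] <- tz$title_pos_ids
    rel[i, ] <- tz$relation_ids
  }
  structure(
    list(
      candidates = candidates, instances = inst,
      word = word, pos = pos, title_word = title_word,
      title_pos = title_pos, rel = rel,
      label = as.integer(inst$label == "CID"),
      vocab = vocab
    ),
    class = "cid_dataset"
  )
}

#' @export
print.cid_dataset <- function(x, ...) {
  cat(sprintf(
    "<cid_dataset> %d instances (%d positive), %d filtered gold positives, |V|=%d words / %d tags\n",
    nrow(x$instances), sum(x$label), sum(x$candidates$filtered),
    length(x$vocab$word), length(x$vocab$pos)
  ))
  invisible(x)
}

# slice a dataset into a model batch
dataset_batch <- function(ds, idx) {
  list(
    word = ds$word[idx, , , drop = FALSE],
    pos = ds$pos[idx, , , drop = FALSE],
    title_word = ds$title_word[idx, , drop = FALSE],
    title_pos = ds$title_pos[idx, , drop = FALSE],
    rel = ds$rel[idx, , drop = FALSE],
    label = ds$label[idx]
  )
}
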