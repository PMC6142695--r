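#' Mask bare numbers in a token sequence
#'
#' Integers and decimals that contain no alphabetic character become the
#' reserved token `"NUM"`; tokens with any letter (e.g. `"IL-2"`) are left
#' unchanged.
#'
#' @param tokens Character vector.
#' @return Character vector of the same length.
#' @examples
#' mask_numbers(c("12.5", "IL-2", "7", "dose"))
#' @export
mask_numbers <- function(tokens) {
  num <- grepl("^[+-]?([0-9]+|[0-9]*\\.[0-9]+|[0-9]+\\.[0-9]*)$", tokens)
  tokens[num] <- "NUM"
  tokens
}

# replacement token for one mention: type-prefixed lower-cased id
mention_token <- function(type, concept_id) {
  prefix <- ifelse(type == "Chemical", "ch_", "ds_")
  paste0(prefix, tolower(concept_id))
}

#' Substitute entity mentions into id tokens
#'
#' Replaces every mention's surface text by a single type-prefixed id token
#' (`ch_<id>` for chemicals, `ds_<id>` for diseases, lower-cased). Mentions
#' of the two candidate entities are additionally bracketed by boundary
#' markers: `ch_start ch_<id> ch_end` and `ds_start ds_<id> ds_end`.
#' Replacement proceeds right-to-left so earlier offsets stay valid.
#' Mentions sharing an identical span (split composite ids) each contribute
#' their token; of two properly overlapping mentions the longer is kept and
#' the shorter dropped with a warning.
#'
#' @param doc One-row slice of a corpus tibble ([read_pubtator()]).
#' @param chemical_id,disease_id The candidate pair's MeSH ids; `NULL`
#'   substitutes all mentions without brackets (used for sentence indexing).
#' @return A list with `title` and `abstract`, the substituted texts.
#' @export
substitute_mentions <- function(doc, chemical_id = NULL, disease_id = NULL) {
  mentions <- doc$mentions[[1]]
  title <- doc$title
  abstract <- doc$abstract
  if (!is.null(chemical_id) || !is.null(disease_id)) {
    want <- c(chemical_id, disease_id)
    if (!any(normalize_mesh_id(want) %in% mentions$concept_id)) {
      abort(sprintf("candidate entity absent from document %s", doc$doc_id))
    }
  }
  if (nrow(mentions) == 0L) return(list(title = title, abstract = abstract))

  # resolve proper overlaps: keep the longer span
  spans <- dplyr::distinct(mentions[, c("start", "end")])
  spans <- spans[order(spans$start, -spans$end), , drop = FALSE]
  keep <- rep(TRUE, nrow(spans))
  last_end <- -1L
  for (i in seq_len(nrow(spans))) {
    if (spans$start[i] < last_end) {
      keep[i] <- FALSE  # nested or partially overlapping shorter span
      warn(sprintf("document %s: overlapping mention span [%d,%d) dropped",
                   doc$doc_id, spans$start[i], spans$end[i]))
    } else {
      last_end <- spans$end[i]
    }
  }
  dropped <- spans[!keep, , drop = FALSE]
  if (nrow(dropped)) {
    mentions <- dplyr::anti_join(mentions, dropped, by = c("start", "end"))
  }
  spans <- spans[keep, , drop = FALSE]

  title_len <- nchar(title)
  repl_for_span <- function(s, e) {
    ms <- mentions[mentions$start == s & mentions$end == e, , drop = FALSE]
    toks <- purrr::pmap_chr(ms, function(start, end, text, type, concept_id) {
      tok <- mention_token(type, concept_id)
      bracket <- (type == "Chemical" && !is.null(chemical_id) &&
                    concept_id %in% normalize_mesh_id(chemical_id)) ||
                 (type == "Disease" && !is.null(disease_id) &&
                    concept_id %in% normalize_mesh_id(disease_id))
      if (bracket) {
        pre <- if (type == "Chemical") "ch_" else "ds_"
        paste(paste0(pre, "start"), tok, paste0(pre, "end"))
      } else tok
    })
    paste(toks, collapse = " ")
  }
  # right-to-left so earlier offsets stay valid
  spans <- spans[order(-spans$start), , drop = FALSE]
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]; e <- spans$end[i]
    rep_txt <- repl_for_span(s, e)
    if (e <= title_len) {
      title <- paste0(substr(title, 1L, s), rep_txt,
                      substr(title, e + 1L, title_len))
    } else if (s >= title_len + 1L) {
      a_s <- s - title_len - 1L
      a_e <- e - title_len - 1L
      abstract <- paste0(substr(abstract, 1L, a_s), rep_txt,
                         substr(abstract, a_e + 1L, nchar(abstract)))
    } else {
      warn(sprintf("document %s: mention span [%d,%d) crosses the title/abstract boundary; skipped",
                   doc$doc_id, s, e))
    }
  }
  list(title = title, abstract = abstract)
}

#' Split text into sentences
#'
#' Deterministic rule-based splitting: a sentence ends at `.`, `!` or `?`
#' followed by whitespace and an upper-case letter, digit or opening
#' quote/parenthesis. Decimal numbers never match (no internal whitespace).
#'
#' @param text Character scalar.
#' @return Character vector of sentences (empty input gives length 0).
#' @export
split_sentences <- function(text) {
  if (!nzchar(trimws(text))) return(character())
  parts <- strsplit(text, "(?<=[.!?])[\"')\\]]*\\s+(?=[A-Z0-9\"'(\\[])", perl = TRUE)[[1]]
  parts[nzchar(trimws(parts))]
}

#' Tokenize a sentence
#'
#' Whitespace-and-punctuation tokenization that keeps the reserved
#' preprocessing tokens (`ch_*`, `ds_*`, boundary markers) intact, keeps
#' decimal numbers and hyphenated alphanumeric words as single tokens, and
#' splits remaining punctuation into single-character tokens.
#'
#' @param sentence Character scalar.
#' @return Character vector of tokens.
#' @export
tokenize <- function(sentence) {
  pattern <- paste(
    "(?:ch|ds)_[A-Za-z0-9-]+",
    "[0-9]+\\.[0-9]+",
    "[A-Za-z0-9]+(?:[-'/][A-Za-z0-9]+)*",
    "[^\\sA-Za-z0-9]",
    sep = "|"
  )
  m <- gregexpr(pattern, sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character())
  regmatches(sentence, list(m))[[1]]
}

#' Split, tokenize, number-mask and tag a text
#'
#' Applies [split_sentences()], [tokenize()], [mask_numbers()] and the
#' part-of-speech tagger to a (substituted) text. Reserved id/marker tokens
#' always receive the tag `"ENT"` regardless of the tagger plugin.
#'
#' @param text Character scalar.
#' @param tagger A function tokens -> tags; default [rule_pos_tagger()].
#' @return A list with `sentences` and `pos_tags`, two parallel lists of
#'   character vectors.
#' @export
split_and_tag <- function(text, tagger = rule_pos_tagger) {
  sentences <- purrr::map(split_sentences(text), ~ mask_numbers(tokenize(.x)))
  pos_tags <- purrr::map(sentences, function(toks) {
    tags <- tagger(toks)
    tags[grepl("^(ch|ds)_", toks)] <- "ENT"
    tags
  })
  list(sentences = sentences, pos_tags = pos_tags)
}

#' Tokenize a document for one candidate pair
#'
#' Produces the model-ready token view of an article for a given candidate
#' pair: mentions substituted (candidate mentions bracketed), the article
#' split into sentences (the title is sentence 1, the theme of the article,
#' and is also returned separately), tokens number-masked and tagged.
#'
#' @inheritParams substitute_mentions
#' @param tagger Tagging plugin, see [split_and_tag()].
#' @return A list of class `cid_tokdoc`: `sentences`, `pos_tags` (parallel
#'   lists over the whole article, title first), `title_tokens`,
#'   `title_pos`.
#' @export
tokenize_candidate <- function(doc, chemical_id, disease_id,
                               tagger = rule_pos_tagger) {
  sub <- substitute_mentions(doc, chemical_id, disease_id)
  ttl <- split_and_tag(sub$title, tagger)
  body <- split_and_tag(sub$abstract, tagger)
  title_tokens <- unlist(ttl$sentences, use.names = FALSE) %||% character()
  title_pos <- unlist(ttl$pos_tags, use.names = FALSE) %||% character()
  structure(
    list(
      sentences = c(list(title_tokens), body$sentences),
      pos_tags = c(list(title_pos), body$pos_tags),
      title_tokens = title_tokens,
      title_pos = title_pos
    ),
    class = "cid_tokdoc"
  )
}

# sentence indices (1-based; title is sentence 1) containing each concept id
entity_sentence_index <- function(doc, tagger = rule_pos_tagger) {
  sub <- substitute_mentions(doc)
  ttl_tokens <- mask_numbers(tokenize(sub$title))
  body <- purrr::map(split_sentences(sub$abstract), ~ mask_numbers(tokenize(.x)))
  sentences <- c(list(ttl_tokens), body)
  mentions <- doc$mentions[[1]]
  if (nrow(mentions) == 0L) return(list())
  ids <- unique(mentions$concept_id)
  toks <- purrr::map(ids, function(id) {
    tok_ch <- paste0("ch_", tolower(id))
    tok_ds <- paste0("ds_", tolower(id))
    which(purrr::map_lgl(sentences, ~ any(.x %in% c(tok_ch, tok_ds))))
  })
  setNames(toks, ids)
}

#' Build entity-level candidate pairs for a corpus
#'
#' Generates one candidate instance per distinct (chemical MeSH id, disease
#' MeSH id) pair co-occurring in an article. A pair is labeled `"CID"` iff
#' it is among the article's gold relations, `"null"` otherwise. `min_span`
#' is the smallest sentence-index distance over all (chemical mention,
#' disease mention) pairs; `stratum` is `"intra"` iff `min_span == 0`.
#'
#' With `apply_span_filter = TRUE`, pairs whose entities only co-occur
#' within at least `K` sentence boundaries (`min_span >= K`; the default
#' `K = 4` admits distances 0..3) are removed as unlikely candidates:
#' negative instances are dropped outright, while gold-positive instances
#' are kept with `filtered = TRUE` so that evaluation can count them as
#' false negatives. Mentions with the unmapped concept id `"-1"` never
#' enter candidate generation.
#'
#' @param corpus Corpus tibble from [read_pubtator()].
#' @param K Span filter width in sentences (default 4).
#' @param apply_span_filter Apply the K-sentence filter (default `FALSE`;
#'   conventionally enabled for development/test splits only).
#' @param tagger Tagging plugin (used only for deterministic tokenization
#'   of sentence boundaries).
#' @return A tibble with columns `doc_id`, `chemical_id`, `disease_id`,
#'   `label`, `min_span`, `stratum`, `filtered`.
#' @export
build_candidates <- function(corpus, K = 4L, apply_span_filter = FALSE,
                             tagger = rule_pos_tagger) {
  stopifnot(K >= 1L)
  per_doc <- purrr::pmap(corpus, function(doc_id, title, abstract, mentions, relations, ...) {
    doc <- tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                          mentions = list(mentions), relations = list(relations))
    m <- mentions[mentions$concept_id != "-1", , drop = FALSE]
    chems <- unique(m$concept_id[m$type == "Chemical"])
    dises <- unique(m$concept_id[m$type == "Disease"])
    if (length(chems) == 0L || length(dises) == 0L) return(NULL)
    sidx <- entity_sentence_index(doc, tagger)
    pairs <- tidyr::expand_grid(chemical_id = chems, disease_id = dises)
    gold <- relations
    pairs$label <- ifelse(
      paste(pairs$chemical_id, pairs$disease_id) %in%
        paste(gold$chemical_id, gold$disease_id),
      "CID", "null"
    )
    pairs$min_span <- purrr::map2_int(pairs$chemical_id, pairs$disease_id, function(c_id, d_id) {
      si <- sidx[[c_id]]; sj <- sidx[[d_id]]
      if (length(si) == 0L || length(sj) == 0L) return(NA_integer_)
      min(abs(outer(si, sj, "-")))
    })
    pairs$doc_id <- doc_id
    pairs
  })
  out <- dplyr::bind_rows(purrr::compact(per_doc))
  if (nrow(out) == 0L) {
    return(tibble::tibble(doc_id = character(), chemical_id = character(),
                          disease_id = character(), label = character(),
                          min_span = integer(), stratum = character(),
                          filtered = logical()))
  }
  out$stratum <- ifelse(!is.na(out$min_span) & out$min_span == 0L, "intra", "inter")
  out$filtered <- FALSE
  if (apply_span_filter) {
    far <- is.na(out$min_span) | out$min_span >= K
    out <- out[!(far & out$label == "null"), , drop = FALSE]
    out$filtered <- (is.na(out$min_span) | out$min_span >= K) & out$label == "CID"
  }
  dplyr::select(out, "doc_id", "chemical_id", "disease_id", "label",
                "min_span", "stratum", "filtered")
}
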