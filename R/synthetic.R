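#' Synthetic corpus configuration
#'
#' Controls the generator of PubTator-format articles with a knowledge
#' table and MeSH tree numbers whose label-generating structure is known.
#' Each document carries a few candidate chemical-disease pairs with
#' disjoint, globally unique synthetic MeSH-like ids (`D91xxxx` chemicals,
#' `D92xxxx` diseases), so no real MeSH content is shipped and every pair
#' has its own knowledge-base entry.
#'
#' `knowledge_signal` is the probability that a pair's knowledge entry is
#' label-informative: a positive pair then carries `marker/mechanism`
#' (possibly alongside uninformative `therapeutic`/`inferred` types), a
#' negative pair carries `therapeutic` or nothing. With probability
#' `1 - knowledge_signal` the entry is drawn independently of the label.
#' `text_signal` is the probability that the lexical trigger `"induced"`
#' appears in the chemical's sentence given a positive label (and
#' `1 - text_signal` given a negative one), so at 1 the trigger determines
#' the label and at 0.5 it is uninformative. `inter_fraction` is the share
#' of pairs whose entities never co-occur in one sentence (about a third of
#' gold relations cross sentence boundaries in the reference corpus).
#' `label_noise` flips the gold label after the signals are placed.
#'
#' @param n_docs Number of documents.
#' @param sentences_per_doc,entities_per_doc Inclusive integer ranges:
#'   abstract sentences, and candidate pairs (one chemical + one disease
#'   each) per document.
#' @param vocab_size Size of the filler-token vocabulary.
#' @param knowledge_signal,text_signal,inter_fraction,label_noise
#'   Probabilities in `[0, 1]`, see above.
#' @param p_positive Prior probability that a pair is a gold relation.
#' @param seed Integer seed; the whole corpus is a deterministic function
#'   of the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_docs = 300L, sentences_per_doc = c(4L, 8L),
                         entities_per_doc = c(1L, 3L), vocab_size = 100L,
                         knowledge_signal = 1, text_signal = 0.5,
                         inter_fraction = 1 / 3, label_noise = 0,
                         p_positive = 0.4, seed = 42L) {
  cf <- list(n_docs = as.integer(n_docs),
             sentences_per_doc = as.integer(sentences_per_doc),
             entities_per_doc = as.integer(entities_per_doc),
             vocab_size = as.integer(vocab_size),
             knowledge_signal = knowledge_signal, text_signal = text_signal,
             inter_fraction = inter_fraction, label_noise = label_noise,
             p_positive = p_positive, seed = as.integer(seed))
  stopifnot(cf$n_docs >= 1L,
            all(c(knowledge_signal, text_signal, inter_fraction,
                  label_noise, p_positive) >= 0),
            all(c(knowledge_signal, text_signal, inter_fraction,
                  label_noise, p_positive) <= 1),
            length(cf$sentences_per_doc) == 2L,
            length(cf$entities_per_doc) == 2L)
  class(cf) <- "synth_config"
  cf
}

#' Generate a synthetic corpus, knowledge base and MeSH tree
#'
#' Deterministic under the configuration seed. The emitted structures are
#' the same tibbles the readers in this package produce, and
#' [write_corpus_files()] serialises them to files that parse back
#' identically through [read_pubtator()], [read_knowledge_table()] and
#' [read_mesh_tree()].
#'
#' @param config A [synth_config()].
#' @return A list: `corpus` (tibble as [read_pubtator()]), `kb`
#'   (as [read_knowledge_table()]), `mesh_tree`, and `pairs` — the
#'   generation ledger with one row per candidate pair (`doc_id`,
#'   `chemical_id`, `disease_id`, `label`, `placement` intra/inter,
#'   `relations` list-column, `trigger` flag).
#' @export
generate_corpus <- function(config = synth_config()) {
  cf <- config
  set.seed(cf$seed)
  vocab <- sprintf("w%03d", seq_len(cf$vocab_size))
  ent_counter <- 0L
  docs <- vector("list", cf$n_docs)
  pair_rows <- list()
  kb_rows <- list()
  tree_rows <- list()

  for (d in seq_len(cf$n_docs)) {
    doc_id <- as.character(10000L + d)
    ns <- sample(cf$sentences_per_doc[1]:cf$sentences_per_doc[2], 1L)
    np <- sample(cf$entities_per_doc[1]:cf$entities_per_doc[2], 1L)
    if (2L * np > 5L * ns) {
      abort(sprintf("infeasible geometry: %d entities for %d sentences", 2L * np, ns))
    }
    sent_toks <- purrr::map(seq_len(ns), function(s) {
      c("The", sample(vocab, sample(5:8, 1L), replace = TRUE))
    })
    inserts <- purrr::map(seq_len(ns), ~ list())

    for (q in seq_len(np)) {
      ent_counter <- ent_counter + 1L
      chem_id <- sprintf("D91%04d", ent_counter)
      dis_id <- sprintf("D92%04d", ent_counter)
      label_pre <- runif(1) < cf$p_positive
      inter <- runif(1) < cf$inter_fraction && ns >= 2L
      if (inter) {
        s1 <- sample(seq_len(ns - 1L), 1L)
        dist <- sample(seq_len(min(3L, ns - s1)), 1L)
        s2 <- s1 + dist
      } else {
        s1 <- s2 <- sample(seq_len(ns), 1L)
      }
      chem_surface <- sprintf("Chem%d", ent_counter)
      dis_surface <- sprintf("Dis%d", ent_counter)
      inserts[[s1]] <- c(inserts[[s1]],
                         list(list(type = "Chemical", id = chem_id, surface = chem_surface)))
      inserts[[s2]] <- c(inserts[[s2]],
                         list(list(type = "Disease", id = dis_id, surface = dis_surface)))

      trigger <- runif(1) < (if (label_pre) cf$text_signal else 1 - cf$text_signal)
      if (trigger) {
        inserts[[s1]] <- c(inserts[[s1]],
                           list(list(type = "token", id = NA, surface = "induced")))
      }

      informative <- runif(1) < cf$knowledge_signal
      if (informative) {
        rels <- if (label_pre) {
          c("marker/mechanism",
            if (runif(1) < 0.3) "therapeutic",
            if (runif(1) < 0.3) "inferred")
        } else {
          c(if (runif(1) < 0.5) "therapeutic",
            if (runif(1) < 0.3) "inferred")
        }
      } else {
        rels <- cid_relation_types()[1:3][runif(3) < 0.3]
      }
      for (r in rels) {
        kb_rows[[length(kb_rows) + 1L]] <- tibble::tibble(
          chemical_id = chem_id, disease_id = dis_id, relation = r)
      }
      tree_rows[[length(tree_rows) + 1L]] <- tibble::tibble(
        mesh_id = dis_id,
        tree_number = sprintf("C%02d.%03d", sample(1:23, 1L), sample(100:999, 1L)))

      label <- if (runif(1) < cf$label_noise) !label_pre else label_pre
      pair_rows[[length(pair_rows) + 1L]] <- tibble::tibble(
        doc_id = doc_id, chemical_id = chem_id, disease_id = dis_id,
        label = ifelse(label, "CID", "null"),
        placement = ifelse(inter, "inter", "intra"),
        relations = list(sort(rels)), trigger = trigger)
    }

    # insert entity/trigger tokens at random interior positions
    mention_meta <- list()
    for (s in seq_len(ns)) {
      toks <- sent_toks[[s]]
      for (ins in inserts[[s]]) {
        pos <- sample(2:(length(toks) + 1L), 1L)
        toks <- append(toks, ins$surface, after = pos - 1L)
        mention_meta <- purrr::map(mention_meta, function(mm) {
          if (mm$s == s && mm$pos >= pos) mm$pos <- mm$pos + 1L
          mm
        })
        if (ins$type != "token") {
          mention_meta[[length(mention_meta) + 1L]] <-
            list(s = s, pos = pos, type = ins$type, id = ins$id, surface = ins$surface)
        }
      }
      sent_toks[[s]] <- toks
    }

    title <- paste0(paste(c("The", "study", "of", sample(vocab, 3L)), collapse = " "), ".")
    sent_strings <- purrr::map_chr(sent_toks, ~ paste0(paste(.x, collapse = " "), "."))
    abstract <- paste(sent_strings, collapse = " ")
    # char offset of each sentence within the abstract
    sent_off <- cumsum(c(0L, head(nchar(sent_strings) + 1L, -1L)))
    title_len <- nchar(title)
    mention_tbl <- purrr::map(mention_meta, function(mm) {
      toks <- sent_toks[[mm$s]]
      within <- if (mm$pos > 1L) sum(nchar(toks[seq_len(mm$pos - 1L)]) + 1L) else 0L
      start <- title_len + 1L + sent_off[mm$s] + within
      tibble::tibble(start = start, end = start + nchar(mm$surface),
                     text = mm$surface, type = mm$type, concept_id = mm$id)
    })
    mentions <- if (length(mention_tbl)) dplyr::arrange(dplyr::bind_rows(mention_tbl), start) else
      tibble::tibble(start = integer(), end = integer(), text = character(),
                     type = character(), concept_id = character())
    pr <- dplyr::bind_rows(pair_rows)
    gold <- dplyr::filter(pr, .data$doc_id == !!doc_id, .data$label == "CID")
    docs[[d]] <- tibble::tibble(
      doc_id = doc_id, title = title, abstract = abstract,
      mentions = list(mentions),
      relations = list(dplyr::select(gold, "chemical_id", "disease_id")))
  }

  kb <- if (length(kb_rows)) dplyr::arrange(dplyr::bind_rows(kb_rows),
                                            .data$chemical_id, .data$disease_id,
                                            .data$relation) else
    tibble::tibble(chemical_id = character(), disease_id = character(),
                   relation = character())
  class(kb) <- c("cid_kb", class(kb))
  list(corpus = dplyr::bind_rows(docs), kb = kb,
       mesh_tree = dplyr::bind_rows(tree_rows),
       pairs = dplyr::bind_rows(pair_rows))
}

#' Write generated corpus, knowledge table and MeSH tree to files
#'
#' @param gen Output of [generate_corpus()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths (`corpus.pubtator`,
#'   `knowledge.tsv`, `mesh_tree.tsv`).
#' @export
write_corpus_files <- function(gen, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  corpus_path <- file.path(dir, "corpus.pubtator")
  kb_path <- file.path(dir, "knowledge.tsv")
  tree_path <- file.path(dir, "mesh_tree.tsv")
  write_pubtator(gen$corpus, corpus_path)
  kb_lines <- c("chemical_id\tdisease_id\tdirect_evidence",
                purrr::pmap_chr(gen$kb, function(chemical_id, disease_id, relation) {
                  ev <- if (relation == "inferred") "" else relation
                  paste(chemical_id, disease_id, ev, sep = "\t")
                }))
  writeLines(kb_lines, kb_path)
  writeLines(paste(gen$mesh_tree$mesh_id, gen$mesh_tree$tree_number, sep = "\t"),
             tree_path)
  invisible(c(corpus = corpus_path, kb = kb_path, mesh_tree = tree_path))
}

#' Generate a hypernymy test case with a closed-form expected outcome
#'
#' Builds articles each containing one chemical, a general disease and a
#' strictly more specific disease (tree number extended at a dot boundary).
#' In half the articles the general disease is mentioned in the title.
#' With every (chemical, general disease) pair predicted positive, the
#' expected demotion set of [hypernym_filter()] is exactly the articles
#' whose title lacks the general disease.
#'
#' @param seed Integer seed.
#' @param n_docs Number of articles (default 8).
#' @return A list: `corpus`, `mesh_tree`, `predictions` (all positive
#'   (chemical, general) pairs), `expected_demoted` (logical per
#'   prediction row).
#' @export
generate_hypernym_case <- function(seed = 1L, n_docs = 8L) {
  set.seed(seed)
  docs <- vector("list", n_docs)
  tree_rows <- list()
  pred_rows <- list()
  for (d in seq_len(n_docs)) {
    doc_id <- as.character(20000L + d)
    chem_id <- sprintf("D93%04d", d)
    gen_id <- sprintf("D94%04d", d)
    spec_id <- sprintf("D95%04d", d)
    chem_s <- sprintf("Chem%d", d)
    gen_s <- sprintf("GenDis%d", d)
    spec_s <- sprintf("SpecDis%d", d)
    in_title <- d %% 2L == 0L
    title <- if (in_title) sprintf("A report of %s toxicity.", gen_s) else
      "A case report of drug toxicity."
    abstract <- sprintf("Treatment with %s caused %s. The patient also developed %s.",
                        chem_s, gen_s, spec_s)
    full <- paste(title, abstract)
    find1 <- function(surface) {
      m <- regexpr(surface, full, fixed = TRUE)
      c(as.integer(m) - 1L, as.integer(m) - 1L + attr(m, "match.length"))
    }
    mrows <- list(
      c(find1(chem_s), "Chemical", chem_id, chem_s),
      c(find1(spec_s), "Disease", spec_id, spec_s)
    )
    # the general disease: every occurrence
    g <- gregexpr(gen_s, full, fixed = TRUE)[[1]]
    for (k in seq_along(g)) {
      mrows[[length(mrows) + 1L]] <-
        c(g[k] - 1L, g[k] - 1L + attr(g, "match.length")[k], "Disease", gen_id, gen_s)
    }
    mentions <- dplyr::arrange(dplyr::bind_rows(purrr::map(mrows, function(r) {
      tibble::tibble(start = as.integer(r[1]), end = as.integer(r[2]),
                     text = r[5], type = r[3], concept_id = r[4])
    })), start)
    docs[[d]] <- tibble::tibble(
      doc_id = doc_id, title = title, abstract = abstract,
      mentions = list(mentions),
      relations = list(tibble::tibble(chemical_id = chem_id, disease_id = spec_id)))
    base <- sprintf("C%02d.%03d", sample(1:23, 1L), sample(100:999, 1L))
    tree_rows[[length(tree_rows) + 1L]] <- tibble::tibble(
      mesh_id = c(gen_id, spec_id),
      tree_number = c(base, paste0(base, sprintf(".%03d", sample(100:999, 1L)))))
    pred_rows[[length(pred_rows) + 1L]] <- tibble::tibble(
      doc_id = doc_id, chemical_id = chem_id, disease_id = gen_id,
      label = "CID", expected_demoted = !in_title)
  }
  preds <- dplyr::bind_rows(pred_rows)
  list(corpus = dplyr::bind_rows(docs),
       mesh_tree = dplyr::bind_rows(tree_rows),
       predictions = dplyr::select(preds, -"expected_demoted"),
       expected_demoted = preds$expected_demoted)
}
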