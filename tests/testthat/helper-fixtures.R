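# small fixtures built in code, shared across test files

# a two-document PubTator corpus with known offsets
fixture_pubtator_lines <- function() {
  c(
    "9|t|A induces B.",
    "9|a|Text.",
    "9\t0\t1\tA\tChemical\tD000001",
    "9\t10\t11\tB\tDisease\tD000002",
    "9\tCID\tD000001\tD000002",
    "",
    "10|t|Nothing here.",
    "10|a|Still nothing.",
    ""
  )
}

# title = "The precipitating cause ..." example article: one sentence holding
# a non-candidate disease, a candidate disease and a candidate chemical
fixture_substitution_doc <- function() {
  abstract <- "The precipitating cause of shock was believed to be a relapse of fever."
  title <- "T."
  off <- nchar(title) + 1L
  mentions <- tibble::tibble(
    start = off + c(27L, 54L, 65L),
    end = off + c(32L, 61L, 70L),
    text = c("shock", "relapse", "fever"),
    type = c("Disease", "Disease", "Chemical"),
    concept_id = c("D012640", "D062787", "D014148")
  )
  tibble::tibble(
    doc_id = "x", title = title, abstract = abstract,
    mentions = list(mentions),
    relations = list(tibble::tibble(chemical_id = "D014148", disease_id = "D062787"))
  )
}

# knowledge table lines in the dump layout the reader expects
fixture_kb_lines <- function() {
  c(
    "chemical_id\tdisease_id\tdirect_evidence",
    "D014148\tD062787\tmarker/mechanism",
    "C1\tD1\ttherapeutic",
    "C1\tD1\t",
    "MESH:c2\td2\ttherapeutic"
  )
}

# a document whose entity sentence layout is fully controlled:
# chemical in abstract sentences `chem_s`, disease in `dis_s` (1-based over
# the abstract; the title becomes sentence 1 of the article)
fixture_span_doc <- function(chem_s, dis_s, n_sent = 7L, gold = TRUE,
                             doc_id = "s1") {
  sent <- rep("The filler words here.", n_sent)
  for (s in chem_s) sent[s] <- "The drug ChemX was given."
  for (s in dis_s) sent[s] <- sub("filler", "DisY", sent[s])
  if (any(chem_s %in% dis_s)) {
    for (s in intersect(chem_s, dis_s)) sent[s] <- "The drug ChemX caused DisY."
  }
  abstract <- paste(sent, collapse = " ")
  title <- "A title."
  full <- paste(title, abstract)
  find_all <- function(surface) {
    g <- gregexpr(surface, full, fixed = TRUE)[[1]]
    if (g[1] == -1L) return(NULL)
    tibble::tibble(start = as.integer(g) - 1L,
                   end = as.integer(g) - 1L + attr(g, "match.length"))
  }
  ch <- find_all("ChemX")
  ds <- find_all("DisY")
  mentions <- dplyr::bind_rows(
    if (!is.null(ch)) dplyr::mutate(ch, text = "ChemX", type = "Chemical", concept_id = "D900001"),
    if (!is.null(ds)) dplyr::mutate(ds, text = "DisY", type = "Disease", concept_id = "D900002")
  )
  rel <- if (gold) tibble::tibble(chemical_id = "D900001", disease_id = "D900002") else
    tibble::tibble(chemical_id = character(), disease_id = character())
  tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                 mentions = list(mentions), relations = list(rel))
}

# a tiny ready-to-train dataset: `n_docs` synthetic documents split
# train/test, reduced-width config
fixture_small_config <- function(...) {
  args <- utils::modifyList(
    list(l1 = 8, l2 = 4, m = 6, n1 = 6, n2 = 14, w = 2, f = 4,
         h1 = 5, h2 = 4, dropout = 0, epochs = 3, seed = 3),
    list(...)
  )
  do.call(cid_config, args)
}

# random tensorized batch for exercising the network without a corpus
random_batch <- function(cf, B, word_n = 20L, pos_n = 6L, seed = 1L) {
  set.seed(seed)
  word <- array(sample(c(1:word_n), B * cf$n1 * cf$n2, replace = TRUE,
                       prob = c(3, rep(1, word_n - 1))), c(B, cf$n1, cf$n2))
  pos <- array(sample.int(pos_n, B * cf$n1 * cf$n2, replace = TRUE), c(B, cf$n1, cf$n2))
  pos[word == 1L] <- 1L
  title_word <- matrix(sample.int(word_n, B * cf$n2, replace = TRUE), B, cf$n2)
  title_pos <- matrix(sample.int(pos_n, B * cf$n2, replace = TRUE), B, cf$n2)
  rel <- t(replicate(B, sort(sample.int(4L, 4L, replace = TRUE))))
  rel[, 4] <- 4L
  list(word = word, pos = pos, title_word = title_word, title_pos = title_pos,
       rel = rel, label = sample(0:1, B, replace = TRUE))
}
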