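# build a candidate/prediction pair realising exact TP/FP/POS counts in a
# given stratum
counts_case <- function(tp, fp, pos, stratum = "intra") {
  gold <- tibble::tibble(
    doc_id = sprintf("g%d", seq_len(pos)),
    chemical_id = "C1", disease_id = "D1", label = "CID",
    min_span = ifelse(stratum == "intra", 0L, 1L),
    stratum = stratum, filtered = FALSE
  )
  neg <- tibble::tibble(
    doc_id = sprintf("n%d", seq_len(fp)),
    chemical_id = "C1", disease_id = "D1", label = "null",
    min_span = ifelse(stratum == "intra", 0L, 1L),
    stratum = stratum, filtered = FALSE
  )
  cand <- dplyr::bind_rows(gold, neg)
  pred <- dplyr::bind_rows(
    dplyr::mutate(gold[seq_len(tp), c("doc_id", "chemical_id", "disease_id")],
                  label = "CID"),
    dplyr::mutate(neg[, c("doc_id", "chemical_id", "disease_id")], label = "CID")
  )
  list(pred = pred, cand = cand)
}

test_that("evaluation reproduces printed metrics from their counts", {
  cases <- list(
    list(tp = 182, fp = 163, pos = 303, p = 52.8, r = 60.1, f = 56.2),
    list(tp = 636, fp = 289, pos = 763, p = 68.8, r = 83.4, f = 75.4),
    list(tp = 130, fp = 159, pos = 303, p = 45.0, r = 42.9, f = 43.9)
  )
  for (cs in cases) {
    direct <- prf_from_counts(cs$tp, cs$fp, cs$pos)
    expect_equal(direct$precision, cs$p)
    expect_equal(direct$recall, cs$r)
    expect_equal(direct$f, cs$f)
    # and through the full pair-matching route
    cc <- counts_case(cs$tp, cs$fp, cs$pos, stratum = "inter")
    ev <- evaluate_relations(cc$pred, cc$cand)
    row <- ev[ev$stratum == "inter", ]
    expect_equal(c(row$tp, row$fp, row$pos), c(cs$tp, cs$fp, cs$pos))
    expect_equal(c(row$precision, row$recall, row$f), c(cs$p, cs$r, cs$f))
  }
})

test_that("perfect predictions score 100 and zero predictions score 0", {
  cc <- counts_case(tp = 5, fp = 0, pos = 5)
  ev <- evaluate_relations(cc$pred, cc$cand)
  expect_equal(ev$precision[ev$stratum == "overall"], 100)
  expect_equal(ev$recall[ev$stratum == "overall"], 100)
  expect_equal(ev$f[ev$stratum == "overall"], 100)
  none <- tibble::tibble(doc_id = character(), chemical_id = character(),
                         disease_id = character(), label = character())
  ev0 <- evaluate_relations(none, cc$cand)
  expect_equal(ev0$precision[1], 0)
  expect_equal(ev0$recall[1], 0)
  expect_equal(ev0$f[1], 0)
})

test_that("strata partition the counts and duplicates are rejected", {
  intra <- counts_case(3, 1, 4, "intra")
  inter <- counts_case(2, 2, 3, "inter")
  inter$cand$doc_id <- paste0("i", inter$cand$doc_id)
  inter$pred$doc_id <- paste0("i", inter$pred$doc_id)
  cand <- dplyr::bind_rows(intra$cand, inter$cand)
  pred <- dplyr::bind_rows(intra$pred, inter$pred)
  ev <- evaluate_relations(pred, cand)
  expect_equal(ev$tp[ev$stratum == "overall"],
               ev$tp[ev$stratum == "inter"] + ev$tp[ev$stratum == "intra"])
  expect_equal(ev$pos[ev$stratum == "overall"], 7)
  dup <- dplyr::bind_rows(pred, pred[1, ])
  expect_error(evaluate_relations(dup, cand), "duplicate")
})

test_that("span-filtered gold positives count in POS but never as TP", {
  cand <- tibble::tibble(
    doc_id = c("a", "b"), chemical_id = "C1", disease_id = "D1",
    label = "CID", min_span = c(0L, 5L), stratum = c("intra", "inter"),
    filtered = c(FALSE, TRUE)
  )
  pred <- tibble::tibble(doc_id = "a", chemical_id = "C1", disease_id = "D1",
                         label = "CID")
  ev <- evaluate_relations(pred, cand)
  ov <- ev[ev$stratum == "overall", ]
  expect_equal(ov$pos, 2L)
  expect_equal(ov$tp, 1L)
  expect_equal(ov$recall, 50)
  # predicting the filtered pair cannot turn it into a true positive
  pred2 <- dplyr::bind_rows(pred, tibble::tibble(
    doc_id = "b", chemical_id = "C1", disease_id = "D1", label = "CID"))
  ev2 <- evaluate_relations(pred2, cand)
  expect_equal(ev2$tp[ev2$stratum == "overall"], 1L)
  expect_equal(ev2$fp[ev2$stratum == "overall"], 1L)
})

test_that("hypernym filter demotes general diseases absent from the title", {
  # general disease C01.100, specific C01.100.200 present in the abstract
  title <- "A study."
  abstract <- "ChemA caused GeneralDis. Later SpecificDis developed."
  full <- paste(title, abstract)
  loc <- function(s) {
    m <- regexpr(s, full, fixed = TRUE)
    c(as.integer(m) - 1L, as.integer(m) - 1L + attr(m, "match.length"))
  }
  mk_doc <- function(doc_id, title, abstract, extra_title_mention = FALSE) {
    full <- paste(title, abstract)
    find <- function(s, type, id) {
      g <- gregexpr(s, full, fixed = TRUE)[[1]]
      tibble::tibble(start = as.integer(g) - 1L,
                     end = as.integer(g) - 1L + attr(g, "match.length"),
                     text = s, type = type, concept_id = id)
    }
    mentions <- dplyr::bind_rows(
      find("ChemA", "Chemical", "D800001"),
      find("GeneralDis", "Disease", "D800002"),
      find("SpecificDis", "Disease", "D800003")
    )
    tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                   mentions = list(mentions),
                   relations = list(tibble::tibble(chemical_id = character(),
                                                   disease_id = character())))
  }
  corpus <- dplyr::bind_rows(
    mk_doc("t1", "A study.", abstract),
    mk_doc("t2", "GeneralDis after ChemA.", abstract)
  )
  tree <- read_mesh_tree(c("D800002\tC01.100", "D800003\tC01.100.200"))
  pred <- tibble::tibble(
    doc_id = c("t1", "t2"), chemical_id = "D800001",
    disease_id = "D800002", label = "CID"
  )
  out <- hypernym_filter(pred, corpus, tree)
  expect_equal(out$label, c("null", "CID"))
  expect_equal(out$demoted, c(TRUE, FALSE))
})

test_that("the filter leaves predictions alone without a more specific disease", {
  doc <- fixture_span_doc(1L, 2L)
  tree <- read_mesh_tree("D900002\tC05.200")
  pred <- tibble::tibble(doc_id = "s1", chemical_id = "D900001",
                         disease_id = "D900002", label = "CID")
  out <- hypernym_filter(pred, doc, tree)
  expect_equal(out$label, "CID")
  # a second disease with a sibling code (C05.2001 does not extend C05.200
  # at a dot boundary) does not trigger demotion either
  doc2 <- doc
  m <- doc2$mentions[[1]]
  m <- dplyr::bind_rows(m, tibble::tibble(
    start = m$start[1], end = m$end[1], text = "other",
    type = "Disease", concept_id = "D900099"))
  doc2$mentions[[1]] <- m
  tree2 <- read_mesh_tree(c("D900002\tC05.200", "D900099\tC05.2001"))
  expect_equal(hypernym_filter(pred, doc2, tree2)$label, "CID")
  # whereas a true descendant code does demote
  tree3 <- read_mesh_tree(c("D900002\tC05.200", "D900099\tC05.200.150"))
  expect_equal(hypernym_filter(pred, doc2, tree3)$label, "null")
})

test_that("hypernym filtering is monotone: positives never increase", {
  hc <- generate_hypernym_case(seed = 3, n_docs = 10L)
  out <- hypernym_filter(hc$predictions, hc$corpus, hc$mesh_tree)
  expect_lte(sum(out$label == "CID"), sum(hc$predictions$label == "CID"))
  # applying the filter twice changes nothing further
  again <- hypernym_filter(dplyr::select(out, -"demoted"), hc$corpus, hc$mesh_tree)
  expect_equal(again$label, out$label)
})

test_that("the closed-form expected demotion set is realised exactly", {
  for (seed in c(1L, 9L)) {
    hc <- generate_hypernym_case(seed = seed)
    out <- hypernym_filter(hc$predictions, hc$corpus, hc$mesh_tree)
    expect_equal(out$demoted, hc$expected_demoted)
  }
})
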