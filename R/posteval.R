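# strict dot-boundary tree-number extension: "C12.777" -> "C12.777.419"
# at any depth, but never "C12.7779"
tree_extends <- function(specific, general) {
  startsWith(specific, paste0(general, "."))
}

#' Hypernymy post-filter on predictions
#'
#' Demotes a positive prediction (chemical, disease d_i) to negative when
#' the article also mentions a strictly more specific disease d_j (some
#' tree number of d_j extends a tree number of d_i at a dot boundary, at
#' any depth) and d_i is never mentioned within the title span. Gold
#' annotation targets the most specific disease discussed, so a general
#' disease that the title does not promote is an unlikely relation
#' argument. The filter only ever demotes: the number of positive
#' predictions never increases.
#'
#' @param predictions Tibble with `doc_id`, `chemical_id`, `disease_id`,
#'   `label` (from [predict.cid_model()] or [read_pubtator()] output).
#' @param corpus Corpus tibble (for mentions and title spans).
#' @param mesh_tree Tibble from [read_mesh_tree()]. Diseases without tree
#'   numbers are left untouched.
#' @return `predictions` with demoted rows set to label `"null"` and a
#'   logical column `demoted`.
#' @export
hypernym_filter <- function(predictions, corpus, mesh_tree) {
  tn <- split(mesh_tree$tree_number, mesh_tree$mesh_id)
  out <- predictions
  out$demoted <- FALSE
  for (i in which(predictions$label == "CID")) {
    d_i <- predictions$disease_id[i]
    row <- match(predictions$doc_id[i], corpus$doc_id)
    if (is.na(row)) next
    mentions <- corpus$mentions[[row]]
    title_len <- nchar(corpus$title[row])
    in_title <- any(mentions$concept_id == d_i & mentions$type == "Disease" &
                      mentions$end <= title_len)
    if (in_title) next
    ti <- tn[[d_i]]
    if (is.null(ti)) next
    others <- setdiff(unique(mentions$concept_id[mentions$type == "Disease"]), d_i)
    more_specific <- FALSE
    for (d_j in others) {
      tj <- tn[[d_j]]
      if (is.null(tj)) next
      if (any(outer(tj, ti, Vectorize(tree_extends)))) {
        more_specific <- TRUE
        break
      }
    }
    if (more_specific) {
      out$label[i] <- "null"
      out$demoted[i] <- TRUE
    }
  }
  out
}

#' Entity-level evaluation with inter/intra stratification
#'
#' Scores predicted (chemical id, disease id) pairs per document against
#' the gold candidate table: precision `100*TP/(TP+FP)`, recall
#' `100*TP/POS` and F `2PR/(P+R)`, overall and per stratum, percentages
#' rounded to one decimal. Gold positives removed by the span filter
#' (`filtered = TRUE`) count in POS but can never be true positives; a
#' positive prediction on such a pair counts as a false positive.
#'
#' @param predictions Tibble keyed by `doc_id`, `chemical_id`,
#'   `disease_id` with a `label` column; duplicate keys are an error.
#' @param candidates Gold candidate tibble from [build_candidates()]
#'   (provides labels, strata and filtered flags).
#' @return A tibble of class `cid_eval`: one row per stratum
#'   (`overall`, `inter`, `intra`) with `tp`, `fp`, `pos`, `precision`,
#'   `recall`, `f`.
#' @examples
#' # pred == gold gives P = R = F = 100
#' @export
evaluate_relations <- function(predictions, candidates) {
  pk <- paste(predictions$doc_id, predictions$chemical_id, predictions$disease_id)
  if (anyDuplicated(pk)) {
    abort(sprintf("duplicate prediction key(s): %s", pk[duplicated(pk)][1]))
  }
  ck <- paste(candidates$doc_id, candidates$chemical_id, candidates$disease_id)
  unknown <- !pk %in% ck
  if (any(unknown)) {
    abort(sprintf("prediction for unknown candidate pair: %s", pk[unknown][1]))
  }
  cand <- candidates
  cand$pred_label <- predictions$label[match(ck, pk)]
  cand$pred_label[is.na(cand$pred_label)] <- "null"
  cand$is_tp <- cand$pred_label == "CID" & cand$label == "CID" & !cand$filtered
  cand$is_fp <- cand$pred_label == "CID" & !cand$is_tp
  strata <- list(overall = rep(TRUE, nrow(cand)),
                 inter = cand$stratum == "inter",
                 intra = cand$stratum == "intra")
  rows <- purrr::imap(strata, function(sel, nm) {
    tp <- sum(cand$is_tp[sel])
    fp <- sum(cand$is_fp[sel])
    pos <- sum(cand$label[sel] == "CID")
    metric_row(nm, tp, fp, pos)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("cid_eval", class(out))
  out
}

metric_row <- function(stratum, tp, fp, pos) {
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (pos > 0) 100 * tp / pos else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  tibble::tibble(stratum = stratum, tp = tp, fp = fp, pos = pos,
                 precision = round(p, 1), recall = round(r, 1), f = round(f, 1))
}

#' Compute precision/recall/F from raw counts
#'
#' The evaluation formulas on bare counts: handy for recomputing a printed
#' results row from its TP/FP/POS columns.
#'
#' @param tp,fp,pos True positives, false positives, gold positives.
#' @return A one-row tibble with `tp`, `fp`, `pos`, `precision`, `recall`,
#'   `f` (percent, one decimal).
#' @examples
#' prf_from_counts(182, 163, 303)
#' @export
prf_from_counts <- function(tp, fp, pos) {
  metric_row("overall", tp, fp, pos)[, -1]
}

#' @export
print.cid_eval <- function(x, ...) {
  cat("Entity-level CID evaluation\n")
  df <- as.data.frame(x)
  names(df) <- c("CIDs", "TP", "FP", "POS", "P(%)", "R(%)", "F(%)")
  print(df[, c("CIDs", "P(%)", "R(%)", "F(%)", "TP", "FP", "POS")],
        row.names = FALSE)
  invisible(x)
}
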