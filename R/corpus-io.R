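#' Read a PubTator-format corpus
#'
#' Parses the plain-text PubTator format: blank-line separated document
#' blocks, each with `id|t|title` and `id|a|abstract` lines followed by
#' tab-separated mention lines (6 columns: doc id, start, end, surface text,
#' entity type, concept id) and relation lines (4 columns: doc id, `"CID"`,
#' chemical MeSH id, disease MeSH id). Character offsets are 0-based,
#' half-open, over the concatenation `title + " " + abstract`.
#'
#' Composite concept ids (`"D001|D002"`) are split into one mention per id
#' sharing the span; the unmapped id `"-1"` is kept but later excluded from
#' candidate generation. All ids are normalized with [normalize_mesh_id()].
#' A mention whose offsets fall outside the document text is kept with a
#' warning; malformed lines are an error naming the line number.
#'
#' @param path Path to a PubTator file, or a character vector of lines.
#' @return A tibble with one row per document and columns `doc_id`, `title`,
#'   `abstract`, `mentions` (list of tibbles with `start`, `end`, `text`,
#'   `type`, `concept_id`) and `relations` (list of tibbles with
#'   `chemical_id`, `disease_id`).
#' @seealso [write_pubtator()], [build_candidates()]
#' @export
read_pubtator <- function(path) {
  lines <- as_lines(path)
  docs <- list()
  block <- character()
  block_start <- 1L
  flush <- function(block, start_line) {
    if (length(block) == 0L) return(NULL)
    parse_pubtator_block(block, start_line)
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(trimws(ln))) {
      d <- flush(block, block_start)
      if (!is.null(d)) docs[[length(docs) + 1L]] <- d
      block <- character()
      block_start <- i + 1L
    } else {
      block <- c(block, ln)
    }
  }
  d <- flush(block, block_start)
  if (!is.null(d)) docs[[length(docs) + 1L]] <- d
  if (length(docs) == 0L) {
    return(tibble::tibble(
      doc_id = character(), title = character(), abstract = character(),
      mentions = list(), relations = list()
    ))
  }
  dplyr::bind_rows(docs)
}

parse_pubtator_block <- function(block, start_line) {
  doc_id <- NA_character_
  title <- ""
  abstract <- ""
  mention_rows <- list()
  relation_rows <- list()
  for (k in seq_along(block)) {
    ln <- block[[k]]
    line_no <- start_line + k - 1L
    tm <- regmatches(ln, regexec("^([^|\t]+)\\|t\\|(.*)$", ln))[[1]]
    am <- regmatches(ln, regexec("^([^|\t]+)\\|a\\|(.*)$", ln))[[1]]
    if (length(tm) == 3L) {
      doc_id <- tm[2]
      title <- tm[3]
      next
    }
    if (length(am) == 3L) {
      if (is.na(doc_id)) doc_id <- am[2]
      abstract <- am[3]
      next
    }
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) == 6L) {
      start <- suppressWarnings(as.integer(f[2]))
      end <- suppressWarnings(as.integer(f[3]))
      if (is.na(start) || is.na(end)) {
        stop_parse(line_no, sprintf("non-integer mention offsets '%s', '%s'", f[2], f[3]))
      }
      if (!f[5] %in% c("Chemical", "Disease")) {
        stop_parse(line_no, sprintf("unknown entity type '%s'", f[5]))
      }
      # composite ids share the span, one mention each
      ids <- normalize_mesh_id(strsplit(f[6], "|", fixed = TRUE)[[1]])
      for (id in ids) {
        mention_rows[[length(mention_rows) + 1L]] <- tibble::tibble(
          start = start, end = end, text = f[4], type = f[5], concept_id = id
        )
      }
    } else if (length(f) == 4L) {
      if (f[2] != "CID") {
        stop_parse(line_no, sprintf("unknown relation label '%s'", f[2]))
      }
      relation_rows[[length(relation_rows) + 1L]] <- tibble::tibble(
        chemical_id = normalize_mesh_id(f[3]),
        disease_id = normalize_mesh_id(f[4])
      )
    } else {
      stop_parse(line_no, sprintf("expected 6 or 4 tab-separated columns, got %d", length(f)))
    }
  }
  if (is.na(doc_id)) stop_parse(start_line, "document block without id|t| line")
  mentions <- if (length(mention_rows)) dplyr::bind_rows(mention_rows) else
    tibble::tibble(start = integer(), end = integer(), text = character(),
                   type = character(), concept_id = character())
  full_len <- nchar(title) + 1L + nchar(abstract)
  bad <- mentions$end > full_len | mentions$start < 0L | mentions$start >= mentions$end
  if (any(bad)) {
    warn(sprintf("document %s: %d mention(s) with offsets outside the text; kept",
                 doc_id, sum(bad)))
  }
  ok_len <- mentions$end - mentions$start == nchar(mentions$text)
  if (any(!ok_len & !bad)) {
    warn(sprintf("document %s: %d mention(s) whose span length differs from the surface text",
                 doc_id, sum(!ok_len & !bad)))
  }
  relations <- if (length(relation_rows)) dplyr::distinct(dplyr::bind_rows(relation_rows)) else
    tibble::tibble(chemical_id = character(), disease_id = character())
  tibble::tibble(doc_id = doc_id, title = title, abstract = abstract,
                 mentions = list(mentions), relations = list(relations))
}

#' Write a corpus in PubTator format
#'
#' Inverse of [read_pubtator()]: emits `id|t|`, `id|a|`, mention and relation
#' lines per document, blocks separated by blank lines. Reading the result
#' back reproduces doc ids, mention tuples and relation sets exactly.
#'
#' @param corpus A corpus tibble as returned by [read_pubtator()].
#' @param path Output file path; when `NULL` the lines are returned invisibly.
#' @return Invisibly, the character vector of lines written.
#' @export
write_pubtator <- function(corpus, path = NULL) {
  blocks <- purrr::pmap(corpus, function(doc_id, title, abstract, mentions, relations, ...) {
    c(
      paste0(doc_id, "|t|", title),
      paste0(doc_id, "|a|", abstract),
      if (nrow(mentions)) {
        purrr::pmap_chr(mentions, function(start, end, text, type, concept_id) {
          paste(doc_id, start, end, text, type, concept_id, sep = "\t")
        })
      },
      if (nrow(relations)) {
        purrr::pmap_chr(relations, function(chemical_id, disease_id) {
          paste(doc_id, "CID", chemical_id, disease_id, sep = "\t")
        })
      }
    )
  })
  lines <- unlist(purrr::map(blocks, ~ c(.x, "")), use.names = FALSE)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write predictions as PubTator relation lines
#'
#' Emits one PubTator block per document (title, abstract, mentions) with a
#' `doc_id<TAB>CID<TAB>chemical<TAB>disease` line for every positive
#' prediction, so the output round-trips through [read_pubtator()].
#'
#' @param corpus A corpus tibble ([read_pubtator()]).
#' @param predictions A tibble with columns `doc_id`, `chemical_id`,
#'   `disease_id` and `label` (`"CID"` rows are emitted).
#' @param path Output file path, or `NULL` to just return the lines.
#' @return Invisibly, the lines written.
#' @export
write_predictions <- function(corpus, predictions, path = NULL) {
  pos <- dplyr::filter(predictions, .data$label == "CID")
  out <- corpus
  out$relations <- purrr::map(corpus$doc_id, function(id) {
    dplyr::select(
      dplyr::filter(pos, .data$doc_id == id),
      "chemical_id", "disease_id"
    )
  })
  write_pubtator(out, path)
}

#' Read a chemical-disease knowledge table
#'
#' Reads a tab- or comma-separated dump of curated chemical-disease
#' associations into a knowledge base keyed by (chemical MeSH id, disease
#' MeSH id). The direct-evidence column maps to the relation types
#' `"marker/mechanism"` and `"therapeutic"`; rows with an empty
#' direct-evidence field are curated by inference and map to `"inferred"`.
#' `"null"` is a padding value, never stored. Duplicate rows are idempotent;
#' a pair accumulates the set of its relation types.
#'
#' @param path Path to the table, or a character vector of lines.
#' @param chemical_col,disease_col,evidence_col Column names in the header.
#' @param sep Field separator; `"\t"` (default) or `","`.
#' @return A tibble of class `cid_kb` with columns `chemical_id`,
#'   `disease_id`, `relation`, one row per distinct (pair, type).
#' @export
read_knowledge_table <- function(path, chemical_col = "chemical_id",
                                 disease_col = "disease_id",
                                 evidence_col = "direct_evidence",
                                 sep = "\t") {
  lines <- as_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    out <- tibble::tibble(chemical_id = character(), disease_id = character(),
                          relation = character())
    class(out) <- c("cid_kb", class(out))
    return(out)
  }
  header <- strsplit(lines[[1]], sep, fixed = TRUE)[[1]]
  needed <- c(chemical_col, disease_col, evidence_col)
  if (!all(needed %in% header)) {
    abort(sprintf("knowledge table header lacks column(s): %s",
                  paste(setdiff(needed, header), collapse = ", ")))
  }
  idx <- match(needed, header)
  rows <- strsplit(lines[-1], sep, fixed = TRUE)
  rel <- purrr::map_chr(rows, function(f) if (length(f) >= idx[3]) trimws(f[idx[3]]) else "")
  known <- c("marker/mechanism", "therapeutic", "inferred", "")
  bad <- setdiff(unique(rel), known)
  if (length(bad)) {
    abort(sprintf("unknown relation label(s) in knowledge table: %s",
                  paste(sprintf("'%s'", bad), collapse = ", ")))
  }
  out <- tibble::tibble(
    chemical_id = normalize_mesh_id(purrr::map_chr(rows, ~ .x[idx[1]])),
    disease_id = normalize_mesh_id(purrr::map_chr(rows, ~ .x[idx[2]])),
    relation = ifelse(rel == "", "inferred", rel)
  )
  out <- dplyr::arrange(dplyr::distinct(out), .data$chemical_id,
                        .data$disease_id, .data$relation)
  class(out) <- c("cid_kb", class(out))
  out
}

#' Read a MeSH tree-number table
#'
#' Two tab-separated columns: MeSH id and dot-delimited tree number
#' (e.g. `C12.777.419`). One id may carry several tree numbers.
#'
#' @param path Path or character vector of lines.
#' @return A tibble with columns `mesh_id`, `tree_number`.
#' @export
read_mesh_tree <- function(path) {
  lines <- as_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(tibble::tibble(mesh_id = character(), tree_number = character()))
  }
  rows <- strsplit(lines, "\t", fixed = TRUE)
  nc <- lengths(rows)
  if (any(nc != 2L)) {
    stop_parse(which(nc != 2L)[1], sprintf("expected 2 columns, got %d", nc[nc != 2L][1]))
  }
  tn <- purrr::map_chr(rows, 2L)
  bad <- !grepl("^[A-Z][0-9]+(\\.[0-9]+)*$", tn)
  if (any(bad)) {
    stop_parse(which(bad)[1], sprintf("malformed tree number '%s'", tn[bad][1]))
  }
  dplyr::distinct(tibble::tibble(
    mesh_id = normalize_mesh_id(purrr::map_chr(rows, 1L)),
    tree_number = tn
  ))
}

#' Read word vectors in word2vec text format
#'
#' First line `"<count> <dim>"`, then one token and `dim` floats per line.
#'
#' @param path Path or character vector of lines.
#' @return A list with `vocab` (character) and `matrix` (`count` x `dim`),
#'   row i holding the vector of `vocab[i]`.
#' @export
read_word_vectors <- function(path) {
  lines <- as_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) abort("empty embedding file")
  hdr <- as.integer(strsplit(trimws(lines[[1]]), "\\s+")[[1]])
  if (length(hdr) != 2L || any(is.na(hdr))) abort("malformed word2vec header")
  count <- hdr[1]; dim <- hdr[2]
  if (length(lines) - 1L != count) {
    abort(sprintf("header promises %d vectors, file has %d rows", count, length(lines) - 1L))
  }
  vocab <- character(count)
  mat <- matrix(0, count, dim)
  for (i in seq_len(count)) {
    f <- strsplit(trimws(lines[[i + 1L]]), "\\s+")[[1]]
    if (length(f) != dim + 1L) {
      abort(sprintf("row %d has dimension %d, header says %d", i, length(f) - 1L, dim))
    }
    vocab[i] <- f[1]
    mat[i, ] <- as.numeric(f[-1])
  }
  list(vocab = vocab, matrix = mat)
}

#' Read knowledge-relation vectors
#'
#' A labeled text file with exactly one row per relation type
#' (`marker/mechanism`, `therapeutic`, `inferred`, `null`): the label then
#' the vector components, whitespace separated.
#'
#' @param path Path or character vector of lines.
#' @return A list with `relations` (the canonical order, see
#'   [cid_relation_types()]) and `matrix` (4 x m) in that order.
#' @export
read_relation_vectors <- function(path) {
  lines <- as_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  rows <- strsplit(trimws(lines), "\\s+")
  labels <- purrr::map_chr(rows, 1L)
  missing <- setdiff(cid_relation_types(), labels)
  if (length(missing)) {
    abort(sprintf("relation vector file is missing type(s): %s",
                  paste(missing, collapse = ", ")))
  }
  dims <- lengths(rows) - 1L
  if (length(unique(dims)) != 1L) abort("inconsistent relation vector dimensionality")
  mat <- do.call(rbind, purrr::map(rows, ~ as.numeric(.x[-1])))
  mat <- mat[match(cid_relation_types(), labels), , drop = FALSE]
  list(relations = cid_relation_types(), matrix = mat)
}
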