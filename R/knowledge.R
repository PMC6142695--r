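#' Canonical knowledge relation types
#'
#' The four relation types a chemical-disease pair can carry: the three
#' curated types plus `"null"`, which is used only to pad a pair's relation
#' set to fixed length 4. The order is canonical throughout the package
#' (it fixes the segment order of the concatenating aggregation).
#'
#' @return Character vector of length 4.
#' @export
cid_relation_types <- function() {
  c("marker/mechanism", "therapeutic", "inferred", "null")
}

#' Resolve a candidate pair against the knowledge base
#'
#' Looks up the relation types stored for each (chemical id, disease id)
#' pair, orders them canonically and right-pads with `"null"` to length 4.
#' A pair absent from the knowledge base yields four `"null"` entries: the
#' padding type is a modelled relation like any other, so "no knowledge" is
#' itself a valid input to the attention layer.
#'
#' @param chemical_id,disease_id Character vectors (recycled to a common
#'   length) of MeSH ids.
#' @param kb A knowledge base from [read_knowledge_table()].
#' @return A character matrix with one row per pair and 4 columns; real
#'   relations precede padding, in canonical order.
#' @examples
#' kb <- read_knowledge_table(c(
#'   "chemical_id\tdisease_id\tdirect_evidence",
#'   "D014148\tD062787\tmarker/mechanism"
#' ))
#' lookup_relations("D014148", "D062787", kb)
#' @export
lookup_relations <- function(chemical_id, disease_id, kb) {
  n <- max(length(chemical_id), length(disease_id))
  chemical_id <- rep_len(normalize_mesh_id(chemical_id), n)
  disease_id <- rep_len(normalize_mesh_id(disease_id), n)
  types <- cid_relation_types()
  key <- paste(chemical_id, disease_id, sep = "\r")
  kb_key <- paste(kb$chemical_id, kb$disease_id, sep = "\r")
  out <- matrix("null", n, 4L)
  # presence matrix over the three storable types, canonical order
  for (i in seq_len(n)) {
    rels <- kb$relation[kb_key == key[i]]
    rels <- types[types %in% rels]
    out[i, ] <- pad_clip(rels, 4L, "null")
  }
  colnames(out) <- paste0("r", 1:4)
  out
}
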