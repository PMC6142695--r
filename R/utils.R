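# internal helpers shared across modules

#' Normalize a MeSH identifier
#'
#' Strips a leading `"MESH:"` prefix and upper-cases the identifier. Applied
#' uniformly at read time to the corpus, the knowledge table and the MeSH
#' tree table so that pair keys agree on all sides.
#'
#' @param id Character vector of raw identifiers.
#' @return Character vector of normalized identifiers.
#' @examples
#' normalize_mesh_id(c("MESH:d014148", "D062787"))
#' @export
normalize_mesh_id <- function(id) {
  toupper(sub("^MESH:", "", id, ignore.case = TRUE))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# row-wise softmax, numerically stabilised
softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

# pad or clip a vector to length n with `pad`
pad_clip <- function(x, n, pad) {
  if (length(x) >= n) x[seq_len(n)] else c(x, rep(pad, n - length(x)))
}

# accept a file path or a character vector of lines (possibly with
# embedded newlines); blank lines are preserved
as_lines <- function(path) {
  if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(paste(path, collapse = "\n"), "\n", fixed = TRUE),
           use.names = FALSE)
  }
}

stop_parse <- function(line_no, msg) {
  abort(sprintf("parse error at line %d: %s", line_no, msg))
}
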