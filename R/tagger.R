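#' Rule-based part-of-speech tagger
#'
#' A deterministic suffix-rule tagger used as the default tagging plugin.
#' Reserved tokens produced by preprocessing (entity id tokens `ch_*`/`ds_*`
#' and the boundary markers) receive the reserved tag `"ENT"`; the number
#' mask receives `"CD"`. Everything else is tagged from a small closed-class
#' word list and common English suffixes. Any function mapping a character
#' vector of tokens to an equal-length character vector of tags can be used
#' in its place.
#'
#' @param tokens Character vector of tokens.
#' @return Character vector of tags, same length as `tokens`.
#' @export
rule_pos_tagger <- function(tokens) {
  tags <- rep("NN", length(tokens))
  lower <- tolower(tokens)
  closed <- c(
    "the" = "DT", "a" = "DT", "an" = "DT", "this" = "DT", "these" = "DT",
    "of" = "IN", "in" = "IN", "on" = "IN", "by" = "IN", "with" = "IN",
    "to" = "TO", "for" = "IN", "from" = "IN", "at" = "IN", "after" = "IN",
    "and" = "CC", "or" = "CC", "but" = "CC",
    "is" = "VBZ", "was" = "VBD", "were" = "VBD", "are" = "VBP", "be" = "VB",
    "been" = "VBN", "not" = "RB", "it" = "PRP", "we" = "PRP", "he" = "PRP",
    "she" = "PRP", "they" = "PRP", "that" = "IN", "which" = "WDT"
  )
  hit <- match(lower, names(closed))
  tags[!is.na(hit)] <- closed[hit[!is.na(hit)]]
  left <- is.na(hit)
  tags[left & grepl("ly$", lower)] <- "RB"
  tags[left & grepl("(ing)$", lower)] <- "VBG"
  tags[left & grepl("(ed)$", lower)] <- "VBD"
  tags[left & grepl("(ous|al|ive|ic|able|ible)$", lower)] <- "JJ"
  tags[left & grepl("(tion|sion|ment|ness|ity|ism)$", lower)] <- "NN"
  tags[left & grepl("s$", lower) & !grepl("(ss|us|is)$", lower)] <- "NNS"
  tags[grepl("^[^A-Za-z0-9]+$", tokens)] <- "PUNCT"
  tags[tokens == "NUM"] <- "CD"
  tags[grepl("^(ch|ds)_", tokens)] <- "ENT"
  tags
}
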