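# Human-readable text codec: each word of a sentence becomes one oligomer
# whose flags are the characters of the word, prefixed by the word's position
# in the sentence so that an unordered collection reconstructs the sentence.

.position_prefixed <- function(words, multi_digit = FALSE) {
  words <- as.character(words)
  if (length(words) > 9L && !multi_digit)
    stop_data("more than 9 words needs multi-digit position prefixes ",
              "(set multi_digit = TRUE)")
  paste0(seq_along(words), words)
}

#' Symbols needed to write a position-encoded sentence
#'
#' The distinct characters across all position-prefixed words: the building
#' blocks a chemical alphabet must provide, one per letter, digit prefix or
#' punctuation mark.
#'
#' @param words Character vector of words, in sentence order.
#' @param multi_digit Allow more than 9 words (multi-digit prefixes).
#' @return Character vector of distinct symbols, in order of first use.
#' @examples
#' length(required_alphabet(c("TO", "WRITE", "OR", "NOT", "TO", "WRITE",
#'                            "ON", "OLIGOS?")))  # 19
#' @export
required_alphabet <- function(words, multi_digit = FALSE) {
  if (length(words) == 0L) return(character(0))
  unique(unlist(strsplit(.position_prefixed(words, multi_digit), "", fixed = TRUE)))
}

#' Encode a sentence as position-prefixed oligomers
#'
#' Word `k` (1-based) becomes one variable-length oligomer whose flags are the
#' characters of `paste0(k, word)`, mapped to building blocks of
#' `char_alphabet` by label. Position prefixes are single decimal symbols, so
#' at most 9 words are supported unless `multi_digit = TRUE` (a documented
#' extension; decoding then assumes words do not begin with digit characters).
#'
#' @param words Character vector of words, in order.
#' @param char_alphabet An [alphabet()] whose labels are the text characters
#'   (see [char_alphabet()], [required_alphabet()]).
#' @param multi_digit Allow more than 9 words.
#' @return A `fragment_manifest` with one sequence per word.
#' @examples
#' words <- c("TO", "WRITE", "OR", "NOT", "TO", "WRITE", "ON", "OLIGOS?")
#' ab <- char_alphabet(required_alphabet(words))
#' encode_text(words, ab)
#' @export
encode_text <- function(words, char_alphabet, multi_digit = FALSE) {
  if (length(words) == 0L) return(new_manifest(character(0)))
  pref <- .position_prefixed(words, multi_digit)
  for (k in seq_along(pref)) {
    chars <- strsplit(pref[k], "", fixed = TRUE)[[1L]]
    bad <- setdiff(chars, char_alphabet$label)
    if (length(bad))
      stop_data("no building block for character(s) ",
                paste0("\"", bad, "\"", collapse = ", "),
                " in word \"", words[k], "\"")
  }
  new_manifest(pref)
}

#' Decode position-prefixed oligomers back to the sentence
#'
#' Inverse of [encode_text()]: exact duplicates are dereplicated, the leading
#' position prefix of each sequence is parsed, and the words are returned in
#' position order. Duplicate positions with different words, missing
#' positions, or sequences not starting with a digit are errors.
#'
#' @param manifest A `fragment_manifest` or character vector of sequences.
#' @param char_alphabet The [alphabet()] the text was written with.
#' @param multi_digit Parse multi-digit prefixes (maximal leading digit run).
#' @return Character vector of words in sentence order.
#' @export
decode_text <- function(manifest, char_alphabet, multi_digit = FALSE) {
  seqs <- unique(as.character(manifest))
  if (length(seqs) == 0L) return(character(0))
  unknown <- setdiff(unlist(strsplit(seqs, "", fixed = TRUE)), char_alphabet$label)
  if (length(unknown))
    stop_data("sequence contains label(s) absent from the alphabet: ",
              paste0("\"", unknown, "\"", collapse = ", "))
  pat <- if (multi_digit) "^([0-9]+)(.*)$" else "^([0-9])(.*)$"
  m <- regmatches(seqs, regexec(pat, seqs))
  bad <- lengths(m) != 3L
  if (any(bad))
    stop_data("sequence does not start with a position prefix: ",
              seqs[bad][1L])
  pos <- as.integer(vapply(m, `[[`, "", 2L))
  word <- vapply(m, `[[`, "", 3L)
  dup <- unique(pos[duplicated(pos)])
  if (length(dup))
    stop_data("conflicting words for position(s): ",
              paste(sort(dup), collapse = ", "))
  missing <- setdiff(seq_len(max(pos)), pos)
  if (length(missing))
    stop_data("missing word position(s): ", paste(missing, collapse = ", "))
  word[order(pos)]
}
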