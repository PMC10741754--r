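#' Clause splitter configuration
#'
#' Long report sentences are divided into clauses at delimiter characters and
#' each clause is tokenized separately; triples never span a clause boundary.
#' The default delimiters cover both ASCII and full-width Chinese punctuation
#' so that reports in either script split identically.
#'
#' @param delimiters Characters that end a clause. Default: period, comma,
#'   semicolon and their full-width forms.
#' @param tokenizer Tokenizer backend name or function. `"whitespace"` (the
#'   default) splits on runs of spaces and suits the English-like synthetic
#'   corpus; a custom function `function(clause) character()` may be
#'   registered for languages without spaces.
#' @return A `clause_splitter` configuration list.
#' @export
clause_splitter <- function(delimiters = c(".", ",", ";", "。", "，", "；"),
                            tokenizer = "whitespace") {
  tok_fun <-
    if (is.function(tokenizer)) {
      tokenizer
    } else if (identical(tokenizer, "whitespace")) {
      function(clause) {
        out <- strsplit(trimws(clause), "\\s+")[[1]]
        out[nzchar(out)]
      }
    } else {
      abort(sprintf("Unknown tokenizer backend: %s", format(tokenizer)),
        class = "sonokg_config_error"
      )
    }
  structure(list(delimiters = delimiters, tokenize = tok_fun),
    class = "clause_splitter"
  )
}

#' Segment report text into clause-indexed tokens
#'
#' Splits a report at clause delimiters, tokenizes each clause, and returns
#' one row per token. Delimiters themselves do not become tokens; empty
#' clauses are dropped. `sentence_index` is 0-based and monotone.
#'
#' @param text A single report as a UTF-8 string.
#' @param splitter A [clause_splitter()].
#' @return A tibble with columns `sentence_index` (integer) and `token`
#'   (character). Empty or whitespace-only text yields zero rows.
#' @export
#' @examples
#' segment_report("The liver is abnormal, surface uneven.")
segment_report <- function(text, splitter = clause_splitter()) {
  stopifnot(is.character(text), length(text) == 1)
  empty <- tibble(sentence_index = integer(), token = character())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  delim_re <- paste0("[", paste(vapply(splitter$delimiters, function(d) {
    if (grepl("[][^\\\\-]", d)) paste0("\\", d) else d
  }, character(1)), collapse = ""), "]")
  clauses <- strsplit(text, delim_re)[[1]]
  toks <- lapply(clauses, splitter$tokenize)
  keep <- lengths(toks) > 0
  toks <- toks[keep]
  if (!length(toks)) return(empty)
  tibble(
    sentence_index = rep(seq_along(toks) - 1L, lengths(toks)),
    token = unlist(toks, use.names = FALSE)
  )
}

# Merge multi-word lexicon terms ("right liver", "substantial echo") into
# single tokens by greedy longest match on normalized forms, within a clause.
merge_lexicon_terms <- function(segments, lexicon) {
  maxw <- lexicon_max_words(lexicon)
  if (maxw < 2 || nrow(segments) == 0) return(segments)
  out_sent <- integer()
  out_tok <- character()
  for (s in unique(segments$sentence_index)) {
    toks <- segments$token[segments$sentence_index == s]
    i <- 1L
    while (i <= length(toks)) {
      matched <- 1L
      for (k in rev(seq_len(min(maxw, length(toks) - i + 1L)))) {
        if (k == 1L) break
        cand <- paste(toks[i:(i + k - 1L)], collapse = " ")
        if (normalize_term(cand, lexicon) %in% lexicon$term) {
          matched <- k
          break
        }
      }
      out_sent <- c(out_sent, s)
      out_tok <- c(out_tok, paste(toks[i:(i + matched - 1L)], collapse = " "))
      i <- i + matched
    }
  }
  tibble(sentence_index = out_sent, token = out_tok)
}
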