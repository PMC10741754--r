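#' Tag lexicons: domain terms mapped to custom tags
#'
#' A tag lexicon maps domain terms (possibly multi-word, e.g. `"right liver"`)
#' to custom tags such as `"organ"`. During annotation a term found in the
#' lexicon receives its custom tag; everything else falls back to the
#' part-of-speech backend. Lookup is case-insensitive on normalized forms.
#'
#' @param terms A data frame with columns `term` and `tag`, or a character
#'   vector of terms (then `tag` must be supplied).
#' @param tag Tags, recycled along `terms` when `terms` is a character vector.
#' @param lemmas Optional named character vector mapping surface variants to a
#'   normalized form (e.g. `c(intrahepatic = "liver")`), applied before lookup.
#' @return A `tag_lexicon` object: a tibble with columns `term` (normalized)
#'   and `tag`, plus a `lemmas` attribute.
#' @export
#' @examples
#' lex <- tag_lexicon(c("liver", "right liver"), "organ")
#' lexicon_tag("LIVER", lex)
tag_lexicon <- function(terms, tag = NULL, lemmas = character()) {
  if (is.data.frame(terms)) {
    stopifnot(all(c("term", "tag") %in% names(terms)))
    tbl <- tibble(term = as.character(terms$term), tag = as.character(terms$tag))
  } else {
    if (is.null(tag)) abort("`tag` is required when `terms` is a character vector.")
    tbl <- tibble(term = as.character(terms), tag = rep_len(as.character(tag), length(terms)))
  }
  if (any(!nzchar(tbl$term))) abort("Lexicon terms must be non-empty.")
  tbl$term <- tolower(tbl$term)
  tbl <- distinct(tbl, .data$term, .keep_all = TRUE)
  structure(tbl,
    lemmas = setNames(tolower(as.character(lemmas)), tolower(names(lemmas))),
    class = c("tag_lexicon", class(tbl))
  )
}

#' @rdname tag_lexicon
#' @param path Path to a two-column TSV (`term TAB tag`, no header, `#`
#'   comments allowed).
#' @export
read_tag_lexicon <- function(path, lemmas = character()) {
  raw <- read.delim(path,
    header = FALSE, sep = "\t", comment.char = "#",
    col.names = c("term", "tag"), colClasses = "character", quote = ""
  )
  tag_lexicon(raw, lemmas = lemmas)
}

#' @rdname tag_lexicon
#' @param lexicon A `tag_lexicon`.
#' @export
write_tag_lexicon <- function(lexicon, path) {
  write.table(as.data.frame(lexicon[, c("term", "tag")]), path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname tag_lexicon
#' @param term A single term (any case).
#' @return `lexicon_tag()` returns the custom tag or `NA_character_` when the
#'   term is unknown.
#' @export
lexicon_tag <- function(term, lexicon) {
  key <- normalize_term(term, lexicon)
  hit <- match(key, lexicon$term)
  if (is.na(hit)) NA_character_ else lexicon$tag[[hit]]
}

# Normalized form: lowercase, then lemma-table mapped (whole-term lookup).
normalize_term <- function(term, lexicon = NULL) {
  x <- tolower(trimws(term))
  lem <- if (is.null(lexicon)) character() else attr(lexicon, "lemmas")
  if (length(lem)) {
    hit <- match(x, names(lem))
    x[!is.na(hit)] <- lem[hit[!is.na(hit)]]
  }
  x
}

# Longest lexicon entry, in words; bound for the multi-word merge scan.
lexicon_max_words <- function(lexicon) {
  if (nrow(lexicon) == 0) return(1L)
  max(lengths(strsplit(lexicon$term, " ", fixed = TRUE)))
}

#' Part-of-speech tagger backends
#'
#' Tagging is pluggable: a backend is any function mapping one token to one
#' tag. `pos_tagger_lookup()` wraps a named table; `pos_tagger_english()` is a
#' small closed-class + suffix heuristic adequate for the English-like
#' synthetic corpora this package tests on (real deployments should register a
#' trained tagger). Backend failures are caught by [annotate_token()], which
#' falls back to tag `"unk"`.
#'
#' @param table Named character vector, token (lowercase) -> tag.
#' @param default Tag returned for unknown tokens.
#' @return A function `function(token) tag`.
#' @export
#' @examples
#' tg <- pos_tagger_lookup(c(uneven = "adj"))
#' tg("uneven")
pos_tagger_lookup <- function(table, default = "n") {
  names(table) <- tolower(names(table))
  force(default)
  function(token) {
    hit <- table[[tolower(token)]]
    if (is.null(hit)) default else hit
  }
}

#' @rdname pos_tagger_lookup
#' @export
pos_tagger_english <- function(default = "n") {
  closed <- c(
    the = "det", a = "det", an = "det", this = "det", that = "det",
    is = "cop", are = "cop", was = "cop", be = "cop",
    and = "conj", or = "conj", but = "conj",
    with = "prep", of = "prep", in_ = "prep", on = "prep", at = "prep",
    to = "prep", by = "prep", from = "prep",
    not = "neg", no = "neg"
  )
  names(closed)[names(closed) == "in_"] <- "in"
  function(token) {
    t <- tolower(token)
    if (!is.na(hit <- closed[t]) && !is.null(hit)) return(unname(closed[[t]]))
    if (grepl("(ous|ful|less|ish|ive|al|ic|able|ible|ar|ed|en)$", t) && nchar(t) > 4) return("adj")
    if (grepl("(ly)$", t)) return("adv")
    if (grepl("(s|es)$", t) && nchar(t) > 3) return("verb")
    default
  }
}
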