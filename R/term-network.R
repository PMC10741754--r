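#' Annotate one token as a concept
#'
#' A concept is a token together with its normalized form and tag. The tag is
#' the lexicon's custom tag when the normalized token is a lexicon entry,
#' otherwise the part-of-speech backend's tag; a backend failure yields tag
#' `"unk"` (logged via a warning, never an error).
#'
#' @param token Non-empty token text.
#' @param lexicon A [tag_lexicon()].
#' @param tagger A tagger backend, e.g. [pos_tagger_english()].
#' @return A one-row tibble: `surface`, `normalized`, `tag`.
#' @export
#' @examples
#' annotate_token("LIVER", tag_lexicon("liver", "organ"))
annotate_token <- function(token, lexicon, tagger = pos_tagger_english()) {
  stopifnot(is.character(token), length(token) == 1, nzchar(token))
  norm <- normalize_term(token, lexicon)
  tag <- lexicon_tag(token, lexicon)
  if (is.na(tag)) {
    tag <- tryCatch(as.character(tagger(token))[1], error = function(e) {
      warn(sprintf("Tagger failed on %s: %s", sQuote(token), conditionMessage(e)))
      "unk"
    })
    if (is.na(tag) || !nzchar(tag)) tag <- "unk"
  }
  tibble(surface = token, normalized = norm, tag = tag)
}

#' Build the term network of one report
#'
#' Segments the report into clauses, merges multi-word lexicon terms, annotates
#' every token, and links consecutive concepts within each clause (token-index
#' distance 1). Edges never cross clause boundaries, so the edge count equals
#' the sum over clauses of `max(0, length - 1)`.
#'
#' @inheritParams annotate_token
#' @param text Report text.
#' @param splitter A [clause_splitter()].
#' @return A `term_network`: list with `concepts` (tibble `surface`,
#'   `normalized`, `tag`, `token_index`, `sentence_index`; 0-based indices) and
#'   `edges` (tibble `from`, `to` of token indices).
#' @export
#' @examples
#' lex <- tag_lexicon(c("liver", "uneven"), c("organ", "adj"))
#' build_term_network("The liver is abnormal, surface uneven.", lex)
build_term_network <- function(text, lexicon, tagger = pos_tagger_english(),
                               splitter = clause_splitter()) {
  segs <- merge_lexicon_terms(segment_report(text, splitter), lexicon)
  if (nrow(segs) == 0) {
    concepts <- tibble(
      surface = character(), normalized = character(), tag = character(),
      token_index = integer(), sentence_index = integer()
    )
    return(new_term_network(concepts, tibble(from = integer(), to = integer())))
  }
  ann <- bind_rows(lapply(segs$token, annotate_token, lexicon = lexicon, tagger = tagger))
  concepts <- mutate(ann,
    token_index = seq_len(nrow(ann)) - 1L,
    sentence_index = segs$sentence_index
  )
  adjacent <- concepts$sentence_index[-1] == concepts$sentence_index[-nrow(concepts)]
  edges <- tibble(
    from = concepts$token_index[-nrow(concepts)][adjacent],
    to = concepts$token_index[-1][adjacent]
  )
  new_term_network(concepts, edges)
}

new_term_network <- function(concepts, edges) {
  structure(list(concepts = concepts, edges = edges), class = "term_network")
}

#' @export
print.term_network <- function(x, ...) {
  cat(sprintf(
    "<term_network: %d concepts, %d edges, %d clauses>\n",
    nrow(x$concepts), nrow(x$edges),
    length(unique(x$concepts$sentence_index))
  ))
  print(x$concepts, ...)
  invisible(x)
}

#' @method tidy term_network
#' @export
tidy.term_network <- function(x, ...) x$concepts

#' @method glance term_network
#' @export
glance.term_network <- function(x, ...) {
  tibble(
    n_concepts = nrow(x$concepts),
    n_edges = nrow(x$edges),
    n_clauses = length(unique(x$concepts$sentence_index))
  )
}

#' Term network serialization
#'
#' `term_network_json()` renders a term network as JSON (concepts array plus
#' edges array); `write_term_network()` writes it to a file, as JSON or as
#' GraphML (via igraph) for graph viewers.
#'
#' @param tn A `term_network`.
#' @param path Output file.
#' @param format `"json"` or `"graphml"`.
#' @export
term_network_json <- function(tn) {
  jsonlite::toJSON(list(concepts = tn$concepts, edges = tn$edges),
    dataframe = "rows", auto_unbox = TRUE, pretty = TRUE
  )
}

#' @rdname term_network_json
#' @export
write_term_network <- function(tn, path, format = c("json", "graphml")) {
  format <- match.arg(format)
  if (format == "json") {
    writeLines(term_network_json(tn), path, useBytes = TRUE)
  } else {
    g <- term_network_igraph(tn)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

term_network_igraph <- function(tn) {
  vs <- tn$concepts
  igraph::graph_from_data_frame(
    d = data.frame(
      from = as.character(tn$edges$from),
      to = as.character(tn$edges$to)
    ),
    vertices = data.frame(
      name = as.character(vs$token_index),
      label = vs$surface, tag = vs$tag, clause = vs$sentence_index
    ),
    directed = TRUE
  )
}
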