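#' Simple knowledge graphs (SKG)
#'
#' An SKG is an ordered multiset of `(head, relation, tail)` triples extracted
#' from one or more reports, carried as a tibble with provenance columns.
#' Heads equal to `"@"` mark triples whose subject entity the report writer
#' omitted (see [complete_entity()]).
#'
#' @param head,relation,tail Character vectors (recycled to common length).
#' @param report_id,sentence_index Optional provenance.
#' @return An `skg`: a tibble with columns `head`, `relation`, `tail`,
#'   `placeholder`, `report_id`, `sentence_index`.
#' @export
#' @examples
#' skg(c("liver", "@"), c("has", "surface"), c("blood vessel", "uneven"))
skg <- function(head = character(), relation = character(), tail = character(),
                report_id = NA_character_, sentence_index = NA_integer_) {
  n <- max(length(head), length(relation), length(tail), 0L)
  tbl <- tibble(
    head = rep_len(as.character(head), n),
    relation = rep_len(as.character(relation), n),
    tail = rep_len(as.character(tail), n),
    report_id = rep_len(as.character(report_id), n),
    sentence_index = rep_len(as.integer(sentence_index), n)
  )
  validate_skg(tbl)
}

validate_skg <- function(tbl) {
  tbl <- as_tibble(tbl)
  for (col in c("head", "relation", "tail")) {
    if (!col %in% names(tbl)) abort(sprintf("SKG is missing column `%s`.", col))
  }
  if (!"report_id" %in% names(tbl)) tbl$report_id <- NA_character_
  if (!"sentence_index" %in% names(tbl)) tbl$sentence_index <- NA_integer_
  if (any(!nzchar(tbl$relation)) || any(!nzchar(tbl$tail))) {
    abort("SKG relations and tails must be non-empty.")
  }
  if (any(!nzchar(tbl$head))) abort("SKG heads must be non-empty or '@'.")
  tbl$placeholder <- tbl$head == PLACEHOLDER
  tbl <- tbl[, c("head", "relation", "tail", "placeholder", "report_id", "sentence_index")]
  class(tbl) <- c("skg", class(tibble()))
  tbl
}

#' @rdname skg
#' @param x A data frame with at least `head`, `relation`, `tail` columns.
#' @export
as_skg <- function(x) validate_skg(x)

#' @rdname skg
#' @export
skg_entities <- function(x) {
  sort(unique(c(x$head[x$head != PLACEHOLDER], x$tail)))
}

#' @rdname skg
#' @export
skg_relations <- function(x) sort(unique(x$relation))

#' SKG input and output
#'
#' TSV layout is `head TAB relation TAB tail` plus optional provenance columns
#' (written when present); JSON carries all columns.
#'
#' @param x An `skg`.
#' @param path File path.
#' @export
write_skg <- function(x, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    writeLines(jsonlite::toJSON(as_tibble(x), dataframe = "rows", pretty = TRUE, na = "null"),
      path,
      useBytes = TRUE
    )
  } else {
    cols <- c("head", "relation", "tail")
    if (any(!is.na(x$report_id))) cols <- c(cols, "report_id", "sentence_index")
    write.table(as.data.frame(x)[, cols, drop = FALSE], path,
      sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' @rdname write_skg
#' @export
read_skg <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
    return(validate_skg(as_tibble(raw)))
  }
  raw <- read.delim(path, sep = "\t", header = FALSE, colClasses = "character", quote = "")
  names(raw)[1:3] <- c("head", "relation", "tail")
  if (ncol(raw) >= 5) {
    names(raw)[4:5] <- c("report_id", "sentence_index")
    raw$sentence_index <- as.integer(raw$sentence_index)
  }
  validate_skg(as_tibble(raw))
}

#' Restrict a term network to rule-relevant concepts
#'
#' Keeps, in order, the concepts whose tag occurs in any rule pattern (or is
#' an entity-capable noun); clause boundaries survive in `sentence_index`.
#'
#' @param tn A `term_network`.
#' @param rules A `tag_rules` set.
#' @return A tibble of concepts (same columns as `tn$concepts`).
#' @export
filter_to_ruleset <- function(tn, rules = default_rules()) {
  concepts <- if (inherits(tn, "term_network")) tn$concepts else as_tibble(tn)
  concepts[concepts$tag %in% rule_tags(rules), , drop = FALSE]
}

#' Extraction behaviour switches
#'
#' @param surface_relation When a clause opens with a headless
#'   `(noun, adjective)` attribute group, `TRUE` (default) emits
#'   `(@, <noun>, <adj>)` — the attribute noun becomes the relation, matching
#'   how omitted-head findings are conventionally tabulated — while `FALSE`
#'   emits the rule-4 pair `(@, has, <noun>)` and `(<noun>, show, <adj>)`.
#' @return An `skg_config` list.
#' @export
skg_config <- function(surface_relation = TRUE) {
  structure(list(surface_relation = isTRUE(surface_relation)), class = "skg_config")
}

#' Match tag-sequence rules over filtered concepts
#'
#' Scans each clause left to right, trying length-3 patterns before length-2
#' ones. After a match the scanner re-anchors on the last entity of the
#' matched span, so a matched tail can head the next triple (tail chaining:
#' `{liver, has, blood vessel}` then `{blood vessel, has, structure}`). The
#' anchor entity persists to the end of its clause but never crosses clause
#' boundaries; when a verb/attribute group appears before any entity-capable
#' concept in its clause, the triple is emitted with placeholder head `"@"`.
#'
#' Entity-capable tags are `organ` and `n`; rules whose pattern contains a
#' verb (rule 1) or a noun slot (rule 4) accept either as head, while the
#' two-concept rules 2 and 3 require an `organ` head, which is what forces
#' clause-initial `(n, adj)` groups into placeholder triples.
#'
#' @param m Filtered concepts from [filter_to_ruleset()].
#' @param rules A `tag_rules` set.
#' @param config An [skg_config()].
#' @return An `skg` (no `report_id` provenance; see [extract_skg()]).
#' @export
match_rules <- function(m, rules = default_rules(), config = skg_config()) {
  m <- as_tibble(m)
  out <- list()
  lit <- rule_literals(rules)
  for (s in unique(m$sentence_index)) {
    cl <- m[m$sentence_index == s, , drop = FALSE]
    out[[length(out) + 1L]] <- match_clause(cl, lit, config)
  }
  trips <- bind_rows(out)
  if (nrow(trips) == 0) {
    return(skg())
  }
  validate_skg(trips)
}

# Literal relations / enabled kinds, as configured by the rule set.
rule_literals <- function(rules) {
  pick <- function(kind) {
    i <- which(rules$kind == kind)
    if (length(i)) rules$relation[[i[1]]] else NA_character_
  }
  list(
    evx = pick("entity_verb_x"),          # "$verb" or literal
    ea = pick("entity_adj"),              # e.g. "show"
    ev = pick("entity_verb"),             # e.g. "status"
    ena = pick("entity_noun_adj"),        # e.g. "has"
    ena2 = {
      i <- which(rules$kind == "entity_noun_adj")
      if (length(i)) rules$relation2[[i[1]]] else NA_character_
    }
  )
}

match_clause <- function(cl, lit, config) {
  n <- nrow(cl)
  word <- cl$normalized
  tag <- cl$tag
  heads <- character()
  rels <- character()
  tails <- character()
  sent <- cl$sentence_index[1] %||% NA_integer_
  emit <- function(h, r, t) {
    heads <<- c(heads, h)
    rels <<- c(rels, r)
    tails <<- c(tails, t)
  }
  evx_rel <- function(verb_word) {
    if (identical(lit$evx, "$verb")) verb_word else lit$evx
  }
  anchor <- NA_integer_
  i <- 1L
  while (i <= n) {
    t <- tag[i]
    if (t == "organ") {
      anchor <- i
      i <- i + 1L
    } else if (t == "n") {
      if (!is.na(anchor) && !is.na(lit$ena)) {
        emit(word[anchor], lit$ena, word[i])
        if (i + 1L <= n && tag[i + 1L] == "adj" && !is.na(lit$ena2)) {
          emit(word[i], lit$ena2, word[i + 1L])
          anchor <- i
          i <- i + 2L
        } else {
          anchor <- i
          i <- i + 1L
        }
      } else if (is.na(anchor) && i + 1L <= n && tag[i + 1L] == "adj" && !is.na(lit$ena)) {
        if (isTRUE(config$surface_relation)) {
          emit(PLACEHOLDER, word[i], word[i + 1L])
        } else {
          emit(PLACEHOLDER, lit$ena, word[i])
          if (!is.na(lit$ena2)) emit(word[i], lit$ena2, word[i + 1L])
        }
        anchor <- i
        i <- i + 2L
      } else {
        anchor <- i
        i <- i + 1L
      }
    } else if (t == "verb") {
      if (!is.na(lit$evx) && i + 1L <= n && tag[i + 1L] %in% c("adj", "n")) {
        h <- if (!is.na(anchor)) word[anchor] else PLACEHOLDER
        emit(h, evx_rel(word[i]), word[i + 1L])
        if (tag[i + 1L] == "n") anchor <- i + 1L
        i <- i + 2L
      } else {
        if (!is.na(anchor) && tag[anchor] == "organ" && !is.na(lit$ev)) {
          emit(word[anchor], lit$ev, word[i])
        }
        i <- i + 1L
      }
    } else if (t == "adj") {
      if (!is.na(anchor) && tag[anchor] == "organ" && !is.na(lit$ea)) {
        emit(word[anchor], lit$ea, word[i])
      }
      i <- i + 1L
    } else {
      i <- i + 1L
    }
  }
  tibble(
    head = heads, relation = rels, tail = tails,
    report_id = NA_character_, sentence_index = rep(as.integer(sent), length(heads))
  )
}

#' Extract a simple knowledge graph from report text
#'
#' Runs the full extraction stage: term-network structuring, rule filtering
#' and rule matching, aggregated over all clauses with provenance.
#'
#' @param reports A data frame with columns `report_id` and `text`, or a
#'   character vector of report texts (names become report ids; unnamed
#'   reports are numbered `r1`, `r2`, ...).
#' @param lexicon A [tag_lexicon()].
#' @param rules A `tag_rules` set, default [default_rules()].
#' @param tagger,splitter Backends, as in [build_term_network()].
#' @param config An [skg_config()].
#' @return An `skg` with `report_id` and `sentence_index` provenance.
#' @export
#' @examples
#' lex <- tag_lexicon(
#'   c("liver", "surface", "uneven"),
#'   c("organ", "n", "adj")
#' )
#' extract_skg("The liver surface uneven.", lex)
extract_skg <- function(reports, lexicon, rules = default_rules(),
                        tagger = pos_tagger_english(),
                        splitter = clause_splitter(),
                        config = skg_config()) {
  reports <- as_report_frame(reports)
  parts <- vector("list", nrow(reports))
  for (k in seq_len(nrow(reports))) {
    tn <- build_term_network(reports$text[k], lexicon, tagger, splitter)
    m <- filter_to_ruleset(tn, rules)
    trips <- match_rules(m, rules, config)
    if (nrow(trips)) trips$report_id <- reports$report_id[k]
    parts[[k]] <- trips
  }
  res <- bind_rows(parts)
  if (nrow(res) == 0) {
    return(skg())
  }
  validate_skg(res)
}

as_report_frame <- function(reports) {
  if (is.data.frame(reports)) {
    stopifnot(all(c("report_id", "text") %in% names(reports)))
    return(tibble(
      report_id = as.character(reports$report_id),
      text = as.character(reports$text)
    ))
  }
  ids <- names(reports) %||% rep(NA_character_, length(reports))
  missing <- is.na(ids) | !nzchar(ids)
  ids[missing] <- paste0("r", seq_along(reports))[missing]
  tibble(report_id = ids, text = as.character(reports))
}

#' @export
print.skg <- function(x, ...) {
  # column subsets of an skg may drop the placeholder column; stay printable
  if (all(c("head", "relation", "tail", "placeholder") %in% names(x))) {
    cat(sprintf(
      "<skg: %d triples (%d placeholder heads), %d entities, %d relations>\n",
      nrow(x), sum(x$placeholder), length(skg_entities(x)), length(skg_relations(x))
    ))
  }
  NextMethod()
}

#' Relation-frequency plot of an SKG
#'
#' Bar chart of the most frequent `(head-tag-free)` relation patterns, a
#' quick view of what a corpus of reports talks about.
#'
#' @param object An `skg`.
#' @param top_n Number of relations shown.
#' @param ... Unused.
#' @method autoplot skg
#' @export
autoplot.skg <- function(object, top_n = 15, ...) {
  freq <- count(as_tibble(object), .data$relation, sort = TRUE)
  freq <- head(freq, top_n)
  ggplot2::ggplot(freq, ggplot2::aes(
    x = stats::reorder(.data$relation, .data$n),
    y = .data$n
  )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = "relation", y = "triple count")
}
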