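#' Build a synonym table from a word-vector space
#'
#' Groups candidate terms by cosine similarity: candidates are visited in
#' decreasing corpus frequency (ties broken lexicographically); each still
#' unassigned candidate anchors a new group that absorbs every unassigned
#' candidate whose similarity to the anchor reaches `threshold`. The group's
#' canonical term is its most frequent member — in reports the habitual
#' spelling dominates, so it is the natural category name — and is recorded
#' with similarity 1 by convention. Groups are disjoint.
#'
#' @param space A `word_vector_space` from [train_embeddings()].
#' @param seeds Candidate terms (must be in the vocabulary).
#' @param threshold Similarity threshold in (0, 1). Default 0.55.
#' @return A `synonym_table`: tibble with columns `canonical`, `member`,
#'   `similarity` (to the group anchor).
#' @export
#' @examples
#' corp <- rep(list(c("liver", "surface", "uneven"), c("liver", "surface", "rough")), 10)
#' sp <- train_embeddings(corp, dim = 4, seed = 1)
#' build_synonym_table(sp, c("uneven", "rough"), threshold = 0.5)
build_synonym_table <- function(space, seeds, threshold = 0.55) {
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1).")
  seeds <- unique(as.character(seeds))
  if (!length(seeds)) {
    return(new_synonym_table(tibble(
      canonical = character(), member = character(), similarity = numeric()
    )))
  }
  missing <- setdiff(seeds, rownames(space$vectors))
  if (length(missing)) {
    abort(sprintf("Seed terms not in vocabulary: %s", paste(missing, collapse = ", ")))
  }
  freq <- as.numeric(space$frequencies[seeds])
  ord <- order(-freq, seeds)
  seeds <- seeds[ord]
  assigned <- setNames(rep(FALSE, length(seeds)), seeds)
  rows <- list()
  for (anchor in seeds) {
    if (assigned[[anchor]]) next
    members <- anchor
    sims <- 1
    for (other in seeds) {
      if (other == anchor || assigned[[other]]) next
      s <- cosine_similarity(space$vectors[anchor, ], space$vectors[other, ])
      if (s >= threshold) {
        members <- c(members, other)
        sims <- c(sims, s)
      }
    }
    assigned[members] <- TRUE
    canon <- members[order(-as.numeric(space$frequencies[members]), members)][1]
    sims[members == canon] <- 1
    rows[[length(rows) + 1L]] <- tibble(
      canonical = canon, member = members, similarity = sims
    )
  }
  new_synonym_table(arrange(bind_rows(rows), .data$canonical, dplyr::desc(.data$similarity), .data$member))
}

new_synonym_table <- function(tbl) {
  structure(tbl, class = c("synonym_table", class(tibble())))
}

#' @export
print.synonym_table <- function(x, ...) {
  cat(sprintf(
    "<synonym_table: %d groups, %d members>\n",
    length(unique(x$canonical)), nrow(x)
  ))
  NextMethod()
}

#' Synonym table JSON serialization
#'
#' @param table A `synonym_table`.
#' @param path File path.
#' @export
write_synonym_table <- function(table, path) {
  groups <- split(
    map2(table$member, table$similarity, function(m, s) list(member = m, similarity = s)),
    table$canonical
  )
  writeLines(jsonlite::toJSON(groups, auto_unbox = TRUE, pretty = TRUE, digits = NA),
    path,
    useBytes = TRUE
  )
  invisible(path)
}

#' @rdname write_synonym_table
#' @export
read_synonym_table <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  rows <- imap(raw, function(df, canon) {
    tibble(canonical = canon, member = df$member, similarity = df$similarity)
  })
  new_synonym_table(bind_rows(rows))
}

#' Rewrite an SKG with canonical synonyms
#'
#' Every head, relation or tail token that is a member of a synonym group is
#' replaced by the group's canonical term. Placeholder heads are untouched;
#' triple count and provenance are preserved; the operation is idempotent.
#'
#' @param x An `skg`.
#' @param table A `synonym_table`.
#' @return The rewritten `skg`.
#' @export
normalize_skg <- function(x, table) {
  if (nrow(table) == 0 || nrow(x) == 0) return(x)
  map <- setNames(table$canonical, table$member)
  sub <- function(v) {
    hit <- match(v, names(map))
    v[!is.na(hit)] <- unname(map[hit[!is.na(hit)]])
    v
  }
  x$head[!x$placeholder] <- sub(x$head[!x$placeholder])
  x$relation <- sub(x$relation)
  x$tail <- sub(x$tail)
  x
}
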