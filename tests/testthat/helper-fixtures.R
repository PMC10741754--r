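# Shared fixtures: the worked-example liver passage with its gold lexicon and
# expected SKG, random-instance generators, and independent oracles used to
# cross-check the extraction matcher and the embedding scores.

table3_lexicon <- function() {
  tag_lexicon(
    c(
      "liver", "right liver", "has no normalcy", "shows", "shrink",
      "surface", "uneven", "substantial echo", "thickens", "nonuniform",
      "show", "nodule shape", "blood vessel", "structure", "clear"
    ),
    c(
      "organ", "organ", "verb", "verb", "adj",
      "n", "adj", "n", "verb", "adj",
      "verb", "n", "n", "n", "adj"
    ),
    lemmas = c(intrahepatic = "liver")
  )
}

table3_text <- function() {
  paste(
    "The liver has no normalcy, the right liver shows shrink, surface uneven,",
    "the substantial echo thickens nonuniform, show nodule shape,",
    "intrahepatic blood vessel structure show clear."
  )
}

# The SKG-stage gold triples of the worked example (two omitted heads).
table3_gold_skg <- function() {
  skg(
    head = c(
      "liver", "right liver", "@", "substantial echo", "@",
      "liver", "blood vessel", "structure"
    ),
    relation = c(
      "status", "shows", "surface", "thickens", "show",
      "has", "has", "show"
    ),
    tail = c(
      "has no normalcy", "shrink", "uneven", "nonuniform", "nodule shape",
      "blood vessel", "structure", "clear"
    )
  )
}

# After completion the omitted heads resolve to the liver and the echo.
table3_gold_completed_heads <- function() c("liver", "substantial echo")

# Random tag sequences for matcher property tests.
random_tag_clauses <- function(n_clauses, max_len = 8) {
  tags <- c("organ", "verb", "adj", "n")
  out <- list()
  for (s in seq_len(n_clauses)) {
    len <- sample.int(max_len, 1)
    tg <- sample(tags, len, replace = TRUE)
    out[[s]] <- tibble::tibble(
      surface = paste0("w", s, "_", seq_len(len)),
      normalized = paste0("w", s, "_", seq_len(len)),
      tag = tg,
      token_index = seq_len(len) - 1L,
      sentence_index = s - 1L
    )
  }
  dplyr::bind_rows(out)
}

# Independent matcher oracle: enumerates, at every position of every clause,
# every rule window in priority order (explicit per-rule window predicates,
# no shared code with match_rules) and applies the documented advance /
# anchoring policy.
oracle_match <- function(m, surface_relation = TRUE, verb_fact_relation = "status") {
  res <- data.frame(head = character(), relation = character(), tail = character())
  add <- function(h, r, t) res <<- rbind(res, data.frame(head = h, relation = r, tail = t))
  for (s in unique(m$sentence_index)) {
    cl <- m[m$sentence_index == s, , drop = FALSE]
    w <- cl$normalized
    tg <- cl$tag
    n <- length(w)
    anchor <- 0L # 0 = none
    pos <- 1L
    while (pos <= n) {
      # window predicates, tried longest-first
      win_evx <- pos + 1L <= n && tg[pos] == "verb" && tg[pos + 1L] %in% c("adj", "n")
      win_ena3 <- pos + 1L <= n && tg[pos] == "n" && tg[pos + 1L] == "adj"
      if (tg[pos] %in% c("organ")) {
        anchor <- pos
        pos <- pos + 1L
      } else if (win_evx) {
        h <- if (anchor > 0L) w[anchor] else "@"
        add(h, w[pos], w[pos + 1L])
        if (tg[pos + 1L] == "n") anchor <- pos + 1L
        pos <- pos + 2L
      } else if (tg[pos] == "n" && anchor > 0L) {
        add(w[anchor], "has", w[pos])
        if (win_ena3) {
          add(w[pos], "show", w[pos + 1L])
          anchor <- pos
          pos <- pos + 2L
        } else {
          anchor <- pos
          pos <- pos + 1L
        }
      } else if (win_ena3 && anchor == 0L) {
        if (surface_relation) {
          add("@", w[pos], w[pos + 1L])
        } else {
          add("@", "has", w[pos])
          add(w[pos], "show", w[pos + 1L])
        }
        anchor <- pos
        pos <- pos + 2L
      } else if (tg[pos] == "n") {
        anchor <- pos
        pos <- pos + 1L
      } else if (tg[pos] == "verb" && anchor > 0L && tg[anchor] == "organ") {
        add(w[anchor], verb_fact_relation, w[pos])
        pos <- pos + 1L
      } else if (tg[pos] == "adj" && anchor > 0L && tg[anchor] == "organ") {
        add(w[anchor], "show", w[pos])
        pos <- pos + 1L
      } else {
        pos <- pos + 1L
      }
    }
  }
  res
}

# Independent TransH arithmetic: explicit componentwise recomputation.
oracle_transh <- function(h, d, t, w) {
  ph <- numeric(length(h))
  pt <- numeric(length(t))
  wh <- 0
  wt <- 0
  for (j in seq_along(h)) wh <- wh + w[j] * h[j]
  for (j in seq_along(t)) wt <- wt + w[j] * t[j]
  for (j in seq_along(h)) ph[j] <- h[j] - wh * w[j]
  for (j in seq_along(t)) pt[j] <- t[j] - wt * w[j]
  acc <- 0
  for (j in seq_along(h)) acc <- acc + (ph[j] + d[j] - pt[j])^2
  acc
}

oracle_kernel <- function(a, b, sigma) {
  acc <- 0
  for (j in seq_along(a)) acc <- acc + (a[j] - b[j])^2
  exp(-acc / (2 * sigma^2))
}

# A tiny hand-buildable embedding model.
toy_model <- function(entities, relations, normals, sigma = 1) {
  sonokg:::new_kg_embedding(entities, relations, normals, sigma = sigma)
}

# Tokenized corpus of a generated report set, as the pipeline tokenizes it.
corpus_tokens <- function(reports, lexicon) {
  lapply(reports$text, function(txt) {
    segs <- sonokg:::merge_lexicon_terms(segment_report(txt, clause_splitter()), lexicon)
    sonokg:::normalize_term(segs$token, lexicon)
  })
}

# Bind the per-report gold SKGs of generate_reports() output into one skg.
bind_gold <- function(gold_list) {
  sonokg:::validate_skg(dplyr::bind_rows(lapply(gold_list, tibble::as_tibble)))
}
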