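concepts_from <- function(words, tags) {
  tibble::tibble(
    surface = words, normalized = words, tag = tags,
    token_index = seq_along(words) - 1L,
    sentence_index = 0L
  )
}

test_that("the default rule set encodes the four extraction rules", {
  rules <- default_rules()
  expect_equal(nrow(rules), 4L)
  expect_equal(
    rules$pattern,
    list(
      c("organ", "verb", "adj"), c("organ", "adj"),
      c("organ", "verb"), c("organ", "n", "adj")
    )
  )
  # rule 1: relation comes from the matched verb slot
  out <- match_rules(concepts_from(c("liver", "shows", "shrink"), c("organ", "verb", "adj")))
  expect_equal(as.character(out[1, c("head", "relation", "tail")]), c("liver", "shows", "shrink"))
  # rule 2: literal relation
  out <- match_rules(concepts_from(c("liver", "uneven"), c("organ", "adj")))
  expect_equal(out$relation, "show")
  # rule 4: two emitted triples
  out <- match_rules(concepts_from(c("liver", "surface", "uneven"), c("organ", "n", "adj")))
  expect_equal(nrow(out), 2L)
  expect_equal(out$relation, c("has", "show"))
  expect_equal(out$head, c("liver", "surface"))
})

test_that("rule files round-trip through TSV and JSON", {
  rules <- default_rules()
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_rules(rules, tsv)
  back <- read_rules(tsv)
  expect_equal(back$pattern, rules$pattern)
  expect_equal(back$relation, rules$relation)
  expect_equal(back$kind, rules$kind)
  expect_error(
    sonokg:::new_tag_rules(tibble::tibble(
      id = 1L, pattern = list("organ"), relation = "x"
    )),
    "length 2 or 3"
  )
})

test_that("rule filtering keeps rule-relevant tags in order and is idempotent", {
  m <- concepts_from(
    c("the", "liver", "is", "uneven"),
    c("det", "organ", "cop", "adj")
  )
  kept <- filter_to_ruleset(m)
  expect_equal(kept$normalized, c("liver", "uneven"))
  expect_equal(filter_to_ruleset(kept), kept)
  none <- concepts_from(c("the", "is"), c("det", "cop"))
  expect_equal(nrow(filter_to_ruleset(none)), 0L)
})

test_that("tail chaining follows attribute chains through a clause", {
  out <- match_rules(concepts_from(
    c("liver", "has", "blood vessel", "structure", "show", "clear"),
    c("organ", "verb", "n", "n", "verb", "adj")
  ))
  expect_equal(
    as.data.frame(out[, c("head", "relation", "tail")]),
    data.frame(
      head = c("liver", "blood vessel", "structure"),
      relation = c("has", "has", "show"),
      tail = c("blood vessel", "structure", "clear")
    )
  )
})

test_that("headless clause-initial groups emit placeholder triples", {
  m <- concepts_from(c("surface", "uneven"), c("n", "adj"))
  out <- match_rules(m)
  expect_equal(as.character(out[1, c("head", "relation", "tail")]), c("@", "surface", "uneven"))
  expect_true(out$placeholder)
  # rule-4 reading of the same clause, behind the toggle
  out2 <- match_rules(m, config = skg_config(surface_relation = FALSE))
  expect_equal(out2$head, c("@", "surface"))
  expect_equal(out2$relation, c("has", "show"))
  # a lone organ matches no rule
  expect_equal(nrow(match_rules(concepts_from("liver", "organ"))), 0L)
  # an organ earlier in the same clause heads later groups instead of "@"
  out3 <- match_rules(concepts_from(
    c("liver", "uneven", "thick"), c("organ", "adj", "adj")
  ))
  expect_equal(out3$head, c("liver", "liver"))
})

test_that("matching equals the exhaustive window oracle on random tag sequences", {
  set.seed(402)
  for (rep in 1:300) {
    m <- random_tag_clauses(n_clauses = sample.int(3, 1), max_len = 8)
    got <- match_rules(m)
    want <- oracle_match(m)
    expect_equal(
      as.data.frame(got[, c("head", "relation", "tail")]),
      want,
      info = paste(m$tag, collapse = " ")
    )
  }
})

test_that("emitted slots only reference input concepts, literals, or '@'", {
  set.seed(403)
  literals <- c("has", "show", "status")
  for (rep in 1:50) {
    m <- random_tag_clauses(2, 8)
    out <- match_rules(m)
    expect_true(all(out$head %in% c(m$normalized, "@")))
    expect_true(all(out$tail %in% m$normalized))
    expect_true(all(out$relation %in% c(m$normalized, literals)))
  }
})

test_that("appending a clause never removes triples", {
  set.seed(404)
  for (rep in 1:25) {
    m1 <- random_tag_clauses(2, 6)
    extra <- random_tag_clauses(1, 6)
    extra$sentence_index <- max(m1$sentence_index) + 1L
    m2 <- dplyr::bind_rows(m1, extra)
    expect_gte(nrow(match_rules(m2)), nrow(match_rules(m1)))
  }
})

test_that("the worked-example passage extracts its gold SKG", {
  x <- extract_skg(table3_text(), table3_lexicon())
  gold <- table3_gold_skg()
  expect_equal(nrow(x), 8L)
  expect_equal(sum(x$placeholder), 2L)
  expect_equal(x$head, gold$head)
  expect_equal(x$relation, gold$relation)
  expect_equal(x$tail, gold$tail)
  # vocabularies are projections of the triples
  expect_equal(
    skg_entities(x),
    sort(unique(c(x$head[x$head != "@"], x$tail)))
  )
  expect_equal(skg_relations(x), sort(unique(x$relation)))
})

test_that("empty reports yield empty SKGs", {
  x <- extract_skg("", table3_lexicon())
  expect_s3_class(x, "skg")
  expect_equal(nrow(x), 0L)
})

test_that("extraction reproduces generator gold exactly at zero omission", {
  reports <- generate_reports(report_grammar(omission = 0), n = 12, seed = 5)
  lex <- grammar_lexicon(report_grammar())
  x <- extract_skg(reports[, c("report_id", "text")], lex)
  gold <- bind_gold(reports$gold_skg)
  expect_equal(x$head, gold$head)
  expect_equal(x$relation, gold$relation)
  expect_equal(x$tail, gold$tail)
  expect_equal(x$report_id, gold$report_id)
  expect_false(any(x$placeholder))
})

test_that("SKGs round-trip through TSV and JSON with provenance", {
  x <- extract_skg(table3_text(), table3_lexicon())
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_skg(x, tsv)
  write_skg(x, js)
  expect_equal(as.data.frame(read_skg(tsv)), as.data.frame(x))
  expect_equal(as.data.frame(read_skg(js)), as.data.frame(x))
  expect_error(skg("liver", "", "x"), "non-empty")
})
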