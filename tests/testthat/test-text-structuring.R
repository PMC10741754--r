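test_that("segmentation splits clauses at delimiters and keeps tokens clean", {
  segs <- segment_report("The liver is abnormal, and the right liver is reduced")
  expect_equal(unique(segs$sentence_index), c(0L, 1L))
  expect_true(all(nzchar(segs$token)))
  expect_false(any(grepl("[,.;]", segs$token)))
  expect_equal(segs$token[segs$sentence_index == 0][1:2], c("The", "liver"))
  expect_equal(segs$token[segs$sentence_index == 1][1], "and")

  # full-width punctuation splits the same way
  zh <- segment_report("a b，c d。e")
  expect_equal(unique(zh$sentence_index), 0:2)
})

test_that("segmentation of empty and delimiter-free text", {
  expect_equal(nrow(segment_report("")), 0L)
  expect_equal(nrow(segment_report("   \t ")), 0L)
  txt <- "alpha beta gamma delta epsilon"
  segs <- segment_report(txt)
  # whitespace-count oracle
  expect_equal(nrow(segs), length(strsplit(txt, " ")[[1]]))
  expect_true(all(segs$sentence_index == 0L))
})

test_that("segmentation round-trips the text modulo whitespace and delimiters", {
  txt <- "The liver is abnormal, surface uneven; echo clear."
  segs <- segment_report(txt)
  rebuilt <- paste(
    vapply(
      split(segs$token, segs$sentence_index),
      paste,
      character(1),
      collapse = " "
    ),
    collapse = " "
  )
  expect_equal(rebuilt, gsub("\\s+", " ", trimws(gsub("[,.;]", " ", txt))))
})

test_that("unknown tokenizer backends are a configuration error", {
  expect_error(clause_splitter(tokenizer = "morpheme"), class = "sonokg_config_error")
  # custom function backends are accepted
  sp <- clause_splitter(tokenizer = function(cl) strsplit(cl, "")[[1]])
  expect_equal(segment_report("ab", sp)$token, c("a", "b"))
})

test_that("annotation prefers the lexicon tag and falls back to the tagger", {
  lex <- tag_lexicon("liver", "organ")
  expect_equal(annotate_token("liver", lex)$tag, "organ")
  expect_equal(annotate_token("LIVER", lex)$normalized, "liver")
  # empty lexicon + a tagger that calls it an adjective
  empty <- tag_lexicon(character(0), character(0))
  tagger <- pos_tagger_lookup(c(uneven = "adj"))
  expect_equal(annotate_token("uneven", empty, tagger)$tag, "adj")
  expect_equal(annotate_token("uneven", empty, tagger)$tag, tagger("uneven"))
})

test_that("tagger failures degrade to tag 'unk' with a warning, never an error", {
  empty <- tag_lexicon(character(0), character(0))
  broken <- function(token) stop("backend crashed")
  expect_warning(out <- annotate_token("liver", empty, broken), "backend crashed")
  expect_equal(out$tag, "unk")
})

test_that("term-network edges link consecutive concepts within clauses only", {
  lex <- tag_lexicon(character(0), character(0))
  single <- build_term_network("liver.", lex)
  expect_equal(nrow(single$concepts), 1L)
  expect_equal(nrow(single$edges), 0L)

  tn <- build_term_network("a b c d, e f g, h i.", lex)
  # per-sentence (len - 1) sum: 3 + 2 + 1
  expect_equal(nrow(tn$edges), 6L)
  sent_of <- stats::setNames(tn$concepts$sentence_index, tn$concepts$token_index)
  expect_true(all(
    sent_of[as.character(tn$edges$from)] == sent_of[as.character(tn$edges$to)]
  ))
  expect_true(all(tn$edges$to - tn$edges$from == 1L))
})

test_that("edge counts match a brute-force pair enumeration on random reports", {
  lex <- tag_lexicon(character(0), character(0))
  set.seed(401)
  for (rep in 1:20) {
    lens <- sample.int(6, sample.int(5, 1), replace = TRUE)
    text <- paste(
      vapply(seq_along(lens), function(s) {
        paste(paste0("t", s, "x", seq_len(lens[s])), collapse = " ")
      }, character(1)),
      collapse = ", "
    )
    tn <- build_term_network(text, lex)
    # oracle: enumerate all concept pairs, count same-sentence distance-1 pairs
    cc <- tn$concepts
    cnt <- 0L
    for (i in seq_len(nrow(cc))) {
      for (j in seq_len(nrow(cc))) {
        if (cc$sentence_index[i] == cc$sentence_index[j] &&
          cc$token_index[j] - cc$token_index[i] == 1L) {
          cnt <- cnt + 1L
        }
      }
    }
    expect_equal(nrow(tn$edges), cnt)
    expect_equal(nrow(tn$edges), sum(pmax(0L, lens - 1L)))
  }
})

test_that("structuring the detokenized term network reproduces the concepts", {
  lex <- table3_lexicon()
  tn <- build_term_network(table3_text(), lex)
  rebuilt_text <- paste(
    vapply(
      split(tn$concepts$surface, tn$concepts$sentence_index),
      paste,
      character(1),
      collapse = " "
    ),
    collapse = ", "
  )
  tn2 <- build_term_network(rebuilt_text, lex)
  expect_equal(tn2$concepts$normalized, tn$concepts$normalized)
  expect_equal(tn2$concepts$tag, tn$concepts$tag)
  expect_equal(nrow(tn2$edges), nrow(tn$edges))
})

test_that("multi-word lexicon terms merge into single concepts by longest match", {
  lex <- table3_lexicon()
  tn <- build_term_network("the right liver shows shrink.", lex)
  expect_true("right liver" %in% tn$concepts$normalized)
  expect_false("right" %in% tn$concepts$normalized)
  # lemma table folds variants onto the lexicon entry before lookup
  tn2 <- build_term_network("intrahepatic blood vessel.", lex)
  expect_equal(tn2$concepts$normalized[1], "liver")
  expect_equal(tn2$concepts$tag[1], "organ")
})

test_that("term networks serialize to JSON and GraphML", {
  lex <- table3_lexicon()
  tn <- build_term_network("the liver surface uneven.", lex)
  js <- jsonlite::fromJSON(term_network_json(tn))
  expect_equal(nrow(js$concepts), nrow(tn$concepts))
  path <- withr::local_tempfile(fileext = ".graphml")
  write_term_network(tn, path, format = "graphml")
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), nrow(tn$concepts))
  expect_equal(igraph::ecount(g), nrow(tn$edges))
})
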