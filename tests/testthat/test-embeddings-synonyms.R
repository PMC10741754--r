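# A small corpus where two planted terms occur in identical contexts and an
# unrelated term does not.
equivalence_corpus <- function(n = 120, seed = 9) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    adj <- sample(c("rough", "unsmooth"), 1)
    filler <- sample(c("clear", "dilated", "normal"), 1)
    c("liver", "surface", adj, "duct", filler)
  })
}

test_that("cosine similarity matches hand arithmetic and its contracts", {
  expect_equal(cosine_similarity(c(2, 1), c(2, 1)), 1)
  expect_equal(cosine_similarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosine_similarity(c(1, 0), c(1, 1)), 0.70710678, tolerance = 1e-8)
  expect_error(cosine_similarity(c(0, 0), c(1, 1)), "zero vector")
  expect_error(cosine_similarity(c(1, 0), c(1, 0, 0)), "dimension")
  set.seed(101)
  for (i in 1:50) {
    u <- rnorm(5)
    v <- rnorm(5)
    expect_equal(cosine_similarity(u, v), cosine_similarity(v, u))
    expect_lte(abs(cosine_similarity(u, v)), 1 + 1e-12)
  }
})

test_that("training is deterministic per seed and honours min_count", {
  corp <- equivalence_corpus(30)
  a <- train_embeddings(corp, dim = 8, window = 2, seed = 3, epochs = 3)
  b <- train_embeddings(corp, dim = 8, window = 2, seed = 3, epochs = 3)
  expect_identical(a$vectors, b$vectors)
  # a hapax disappears under min_count = 2
  corp2 <- c(corp, list(c("liver", "hapaxterm")))
  sp <- train_embeddings(corp2, dim = 4, min_count = 2, seed = 1, epochs = 1)
  expect_false("hapaxterm" %in% rownames(sp$vectors))
  expect_error(train_embeddings(list(), dim = 4), "non-empty")
  expect_error(train_embeddings(corp, dim = 1), "dim")
})

test_that("distributionally equivalent terms rank closer than unrelated ones", {
  sp <- train_embeddings(equivalence_corpus(), dim = 12, window = 2, seed = 2, epochs = 10)
  planted <- cosine_similarity(sp$vectors["rough", ], sp$vectors["unsmooth", ])
  unrelated <- cosine_similarity(sp$vectors["rough", ], sp$vectors["duct", ])
  expect_gt(planted, unrelated)
})

test_that("synonym grouping filters by threshold and picks the frequent canonical", {
  # vectors constructed so cosines to the anchor equal the printed example
  sims <- c(0.851965, 0.816471, 0.74689, 0.588166)
  vecs <- rbind(
    unsmooth = c(1, 0),
    rough = c(sims[1], sqrt(1 - sims[1]^2)),
    `less smooth` = c(sims[2], sqrt(1 - sims[2]^2)),
    uneven = c(sims[3], sqrt(1 - sims[3]^2)),
    `generally flat` = c(sims[4], sqrt(1 - sims[4]^2))
  )
  space <- structure(
    list(
      vectors = vecs,
      frequencies = c(
        unsmooth = 50L, rough = 20L, `less smooth` = 10L,
        uneven = 8L, `generally flat` = 5L
      ),
      dim = 2L, method = "manual"
    ),
    class = "word_vector_space"
  )
  tab <- build_synonym_table(space, rownames(vecs), threshold = 0.55)
  expect_equal(unique(tab$canonical), "unsmooth")
  expect_equal(tab$similarity[tab$member == "unsmooth"], 1)
  expect_equal(
    sort(tab$similarity[tab$member != "unsmooth"]),
    sort(sims),
    tolerance = 1e-6
  )
  # at 0.80 only the two most similar members survive with the anchor
  tab80 <- build_synonym_table(space, rownames(vecs), threshold = 0.80)
  expect_equal(sum(tab80$canonical == "unsmooth"), 3L)
  # empty candidate set
  empty <- build_synonym_table(space, character(0))
  expect_equal(nrow(empty), 0L)
  expect_error(build_synonym_table(space, "absent"), "not in vocabulary")
  expect_error(build_synonym_table(space, "rough", threshold = 1.2), "threshold")
})

test_that("synonym groups are disjoint and above threshold", {
  sp <- train_embeddings(equivalence_corpus(), dim = 12, window = 2, seed = 4, epochs = 8)
  tab <- build_synonym_table(sp, rownames(sp$vectors), threshold = 0.5)
  expect_equal(anyDuplicated(tab$member), 0L)
  expect_true(all(tab$similarity >= 0.5 | tab$similarity == 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_synonym_table(tab, path)
  back <- read_synonym_table(path)
  expect_equal(
    dplyr::arrange(tibble::as_tibble(back), member),
    dplyr::arrange(tibble::as_tibble(tab), member),
    tolerance = 1e-9
  )
})

test_that("SKG synonym rewriting is canonical, idempotent, count-preserving", {
  x <- skg(
    c("liver", "@", "liver"),
    c("surface", "surface", "has"),
    c("rough", "uneven", "blood vessel"),
    report_id = "r1", sentence_index = 0:2
  )
  tab <- sonokg:::new_synonym_table(tibble::tibble(
    canonical = "unsmooth", member = c("unsmooth", "rough", "uneven"),
    similarity = c(1, 0.85, 0.75)
  ))
  y <- normalize_skg(x, tab)
  expect_equal(y$tail, c("unsmooth", "unsmooth", "blood vessel"))
  expect_equal(nrow(y), nrow(x))
  expect_equal(y$report_id, x$report_id)
  expect_equal(y$sentence_index, x$sentence_index)
  expect_true(all(y$head[y$placeholder] == "@"))
  expect_equal(normalize_skg(y, tab), y)
  # empty table is the identity
  empty <- sonokg:::new_synonym_table(tibble::tibble(
    canonical = character(), member = character(), similarity = numeric()
  ))
  expect_equal(normalize_skg(x, empty), x)
})

test_that("planted synonym sets are recovered across seeds", {
  g <- report_grammar(omission = 0)
  reports <- generate_reports(g, n = 20, seed = 11)
  lex <- grammar_lexicon(g)
  corp <- corpus_tokens(reports, lex)
  sets <- grammar_synonym_sets(g)
  rates <- vapply(1:10, function(s) {
    sp <- train_embeddings(corp, dim = 12, window = 2, seed = s, epochs = 10)
    res <- unlist(lapply(sets, function(set) {
      set <- intersect(set, rownames(sp$vectors))
      if (length(set) < 2) return(NULL)
      tab <- build_synonym_table(sp, set, threshold = 0.5)
      utils::combn(set, 2, function(pr) {
        tab$canonical[match(pr[1], tab$member)] ==
          tab$canonical[match(pr[2], tab$member)]
      })
    }))
    mean(res)
  }, numeric(1))
  expect_gte(mean(rates), 0.9)
})

test_that("word vectors round-trip through the text format", {
  sp <- train_embeddings(equivalence_corpus(20), dim = 6, seed = 1, epochs = 2)
  path <- withr::local_tempfile(fileext = ".txt")
  write_word_vectors(sp, path)
  back <- read_word_vectors(path)
  expect_equal(
    unname(back$vectors),
    unname(sp$vectors[gsub("_", " ", rownames(back$vectors)), , drop = FALSE]),
    tolerance = 1e-12
  )
})
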