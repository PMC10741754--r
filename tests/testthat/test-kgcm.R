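test_that("hyperplane projection is analytic, idempotent and orthogonal", {
  expect_equal(project_onto_hyperplane(c(1, 1), c(1, 0)), c(0, 1))
  # orthogonal input is unchanged; parallel input collapses to zero
  expect_equal(project_onto_hyperplane(c(0, 2), c(1, 0)), c(0, 2))
  expect_equal(project_onto_hyperplane(c(1, 0), c(1, 0)), c(0, 0))
  expect_error(project_onto_hyperplane(c(1, 1), c(1, 1)), "unit")
  set.seed(71)
  for (i in 1:100) {
    d <- sample(2:6, 1)
    e <- rnorm(d)
    w <- rnorm(d)
    w <- w / sqrt(sum(w^2))
    p <- project_onto_hyperplane(e, w)
    expect_lt(abs(sum(p * w)), 1e-9)
    expect_lt(max(abs(project_onto_hyperplane(p, w) - p)), 1e-9)
  }
})

test_that("the translation score is zero iff the translation is exact", {
  w <- c(0, 1)
  m <- toy_model(
    entities = rbind(a = c(1, 0.3), b = c(1.4, -0.2)),
    relations = rbind(r = c(0.4, 0)),
    normals = rbind(r = w)
  )
  # b_perp = a_perp + d by construction
  expect_equal(transh_score(c("a", "r", "b"), m), 0)
  m2 <- toy_model(
    entities = rbind(a = c(1, 0), b = c(0, 1)),
    relations = rbind(r = c(0, 0)),
    normals = rbind(r = c(0, 1))
  )
  expect_equal(transh_score(c("a", "r", "b"), m2), 1)
})

test_that("scores equal an independent arithmetic recomputation", {
  set.seed(72)
  for (i in 1:200) {
    d <- sample(2:8, 1)
    w <- rnorm(d)
    w <- w / sqrt(sum(w^2))
    m <- toy_model(
      entities = rbind(h = rnorm(d), t = rnorm(d)),
      relations = rbind(r = rnorm(d)),
      normals = rbind(r = w),
      sigma = runif(1, 0.5, 2)
    )
    f <- transh_score(c("h", "r", "t"), m)
    expect_equal(f, oracle_transh(m$entities["h", ], m$relations["r", ], m$entities["t", ], w),
      tolerance = 1e-9
    )
    k <- oracle_kernel(m$entities["h", ], m$entities["t", ], m$sigma)
    expect_equal(kgcm_score(c("h", "r", "t"), m), f * k, tolerance = 1e-9)
    expect_equal(kgcm_score(c("h", "r", "t"), m, combine = "divide"), f / k, tolerance = 1e-9)
    expect_gte(kgcm_score(c("h", "r", "t"), m), 0)
  }
})

test_that("the proximity kernel has Gaussian shape and bounds", {
  expect_equal(gaussian_proximity(c(1, 2), c(1, 2)), 1)
  sig <- 0.7
  x <- c(0, 0)
  y <- c(sqrt(2) * sig, 0) # squared distance = 2 sigma^2
  expect_equal(gaussian_proximity(x, y, sig), exp(-1))
  expect_error(gaussian_proximity(x, y, 0), "positive")
  set.seed(73)
  for (i in 1:50) {
    a <- rnorm(4)
    b <- rnorm(4)
    cc <- rnorm(4)
    k_ab <- gaussian_proximity(a, b)
    expect_equal(k_ab, gaussian_proximity(b, a))
    expect_true(k_ab > 0 && k_ab <= 1)
    # strictly decreasing in distance
    d1 <- sqrt(sum((a - b)^2))
    d2 <- sqrt(sum((a - cc)^2))
    if (d1 < d2) expect_gt(k_ab, gaussian_proximity(a, cc))
  }
})

test_that("kgcm annihilates with the translation factor and matches it at zero distance", {
  w <- c(0, 1)
  m <- toy_model(
    entities = rbind(a = c(1, 0.3), b = c(1.4, -0.2), c = c(1, 0.3)),
    relations = rbind(r = c(0.4, 0), s = c(0.2, 0)),
    normals = rbind(r = w, s = w)
  )
  expect_equal(kgcm_score(c("a", "r", "b"), m), 0)
  # identical head and tail: kernel is 1, scores coincide
  expect_equal(
    kgcm_score(c("a", "s", "c"), m),
    transh_score(c("a", "s", "c"), m)
  )
})

test_that("out-of-vocabulary elements are reported by name", {
  m <- toy_model(
    entities = rbind(a = c(1, 0)), relations = rbind(r = c(0, 0)),
    normals = rbind(r = c(0, 1))
  )
  expect_error(transh_score(c("nope", "r", "a"), m), "nope")
  expect_error(transh_score(c("a", "missing_rel", "a"), m), "missing_rel")
})

test_that("training is reproducible, constraint-preserving, and separates scores", {
  pk <- generate_planted_kg(
    n_entities = 20, n_relations = 2, dim = 8,
    noise = 0.05, n_triples = 120, seed = 14
  )
  m1 <- kg_train(pk$triples, dim = 8, epochs = 30, lr = 0.02, seed = 5)
  m2 <- kg_train(pk$triples, dim = 8, epochs = 30, lr = 0.02, seed = 5)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$entities, m2$entities)
  # unit-norm hyperplanes and unit-ball entities after every update
  expect_true(all(abs(sqrt(rowSums(m1$normals^2)) - 1) < 1e-6))
  expect_true(all(sqrt(rowSums(m1$entities^2)) <= 1 + 1e-9))
  # positives score below corrupted triples on average
  ents <- rownames(m1$entities)
  set.seed(6)
  pos <- vapply(seq_len(nrow(pk$facts)), function(i) {
    transh_score(pk$facts[i, ], m1)
  }, numeric(1))
  neg <- vapply(seq_len(nrow(pk$facts)), function(i) {
    tr <- pk$facts[i, ]
    tr$head <- sample(ents, 1)
    transh_score(tr, m1)
  }, numeric(1))
  expect_lt(mean(pos), mean(neg))
})

test_that("zero-epoch training returns the seeded initialization", {
  tr <- skg(c("a", "b"), "r", c("b", "c"))
  m0a <- kg_train(tr, dim = 4, epochs = 0, seed = 9)
  m0b <- kg_train(tr, dim = 4, epochs = 0, seed = 9)
  expect_identical(m0a$entities, m0b$entities)
  expect_length(m0a$loss_trace, 0)
  expect_error(kg_train(tr[0, ], dim = 4), "empty")
  expect_error(kg_train(skg("@", "r", "x"), dim = 4), "Placeholder")
})

test_that("checkpoints round-trip through TSV + JSON", {
  tr <- skg(c("a", "b", "c"), c("r", "r", "s"), c("b", "c", "a"))
  m <- kg_train(tr, dim = 4, epochs = 10, seed = 2, sigma = 0.8)
  dir <- withr::local_tempdir()
  write_kg_embedding(m, dir)
  back <- read_kg_embedding(dir)
  expect_equal(back$entities, m$entities, tolerance = 1e-12)
  expect_equal(back$sigma, m$sigma)
  expect_equal(
    kgcm_score(c("a", "r", "b"), back),
    kgcm_score(c("a", "r", "b"), m),
    tolerance = 1e-9
  )
})
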