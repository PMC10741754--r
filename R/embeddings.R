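#' Train word vectors on a report corpus
#'
#' Learns distributional word vectors with a sliding-window skip-gram model
#' and negative sampling (logistic SGD), the word2vec family. Training is
#' single-threaded and fully driven by R's RNG, so a fixed seed reproduces
#' vectors exactly. A deterministic count-based alternative
#' (`method = "ppmi_svd"`: positive PMI co-occurrence followed by truncated
#' SVD) is provided for contexts where stochastic training is unwanted.
#'
#' @param corpus A list of character vectors, one tokenized sentence/report
#'   each (tokens should already be normalized; multi-word terms as single
#'   tokens).
#' @param dim Vector dimension, >= 2.
#' @param window Sliding-window half-width, >= 1.
#' @param min_count Minimum corpus frequency; rarer terms are dropped.
#' @param seed RNG seed.
#' @param epochs Passes over the corpus.
#' @param negative Negative samples per positive pair.
#' @param lr Initial learning rate (linearly decayed).
#' @param method `"skipgram"` (default) or `"ppmi_svd"`.
#' @return A `word_vector_space`: list with `vectors` (term x dim matrix,
#'   rownames = vocabulary), `frequencies`, `dim`, and training metadata.
#' @export
#' @examples
#' corp <- list(c("liver", "surface", "uneven"), c("liver", "surface", "rough"))
#' sp <- train_embeddings(corp, dim = 4, window = 2, seed = 1, epochs = 2)
#' rownames(sp$vectors)
train_embeddings <- function(corpus, dim = 16, window = 2, min_count = 1,
                             seed = 1, epochs = 15, negative = 5, lr = 0.05,
                             method = c("skipgram", "ppmi_svd")) {
  method <- match.arg(method)
  if (!length(corpus)) abort("Corpus must be non-empty.")
  if (dim < 2) abort("`dim` must be >= 2.")
  if (window < 1) abort("`window` must be >= 1.")
  corpus <- lapply(corpus, as.character)
  counts <- table(unlist(corpus, use.names = FALSE))
  counts <- counts[counts >= min_count]
  vocab <- sort(names(counts))
  if (!length(vocab)) abort("No term reaches `min_count`.")
  freq <- as.integer(counts[vocab])
  names(freq) <- vocab
  sents <- lapply(corpus, function(s) match(s, vocab))
  sents <- lapply(sents, function(s) s[!is.na(s)])
  sents <- sents[lengths(sents) > 1]
  pairs <- skipgram_pairs(sents, window)
  vecs <- if (method == "skipgram") {
    sgns_train(pairs, length(vocab), freq, dim, seed, epochs, negative, lr)
  } else {
    ppmi_svd_train(pairs, length(vocab), dim)
  }
  rownames(vecs) <- vocab
  structure(
    list(
      vectors = vecs, frequencies = freq, dim = dim,
      window = window, min_count = min_count, method = method, seed = seed
    ),
    class = "word_vector_space"
  )
}

# (center, context) index pairs for every position/offset within the window.
skipgram_pairs <- function(sents, window) {
  centers <- integer()
  contexts <- integer()
  for (s in sents) {
    n <- length(s)
    for (off in seq_len(window)) {
      if (n <= off) break
      i <- seq_len(n - off)
      centers <- c(centers, s[i], s[i + off])
      contexts <- c(contexts, s[i + off], s[i])
    }
  }
  cbind(center = centers, context = contexts)
}

sgns_train <- function(pairs, V, freq, dim, seed, epochs, negative, lr) {
  set.seed(seed)
  W <- matrix(runif(V * dim, -0.5, 0.5) / dim, nrow = V)
  C <- matrix(0, nrow = V, ncol = dim)
  if (nrow(pairs) == 0) return(W)
  noise <- freq^0.75
  noise <- noise / sum(noise)
  np <- nrow(pairs)
  total <- epochs * np
  step <- 0L
  for (ep in seq_len(epochs)) {
    negs <- matrix(
      sample.int(V, np * negative, replace = TRUE, prob = noise),
      nrow = np
    )
    for (p in seq_len(np)) {
      step <- step + 1L
      eta <- lr * max(1e-4, 1 - step / total)
      cw <- pairs[p, 1L]
      targets <- c(pairs[p, 2L], negs[p, ])
      label <- c(1, numeric(negative))
      z <- W[cw, ]
      sc <- C[targets, , drop = FALSE] %*% z
      g <- (1 / (1 + exp(-sc)) - label) * eta
      W[cw, ] <- z - crossprod(C[targets, , drop = FALSE], g)
      C[targets, ] <- C[targets, , drop = FALSE] - tcrossprod(g, z)
    }
  }
  W
}

ppmi_svd_train <- function(pairs, V, dim) {
  M <- matrix(0, V, V)
  if (nrow(pairs)) {
    for (p in seq_len(nrow(pairs))) {
      M[pairs[p, 1L], pairs[p, 2L]] <- M[pairs[p, 1L], pairs[p, 2L]] + 1
    }
  }
  tot <- sum(M)
  if (tot == 0) return(matrix(0, V, dim))
  rs <- rowSums(M)
  cs <- colSums(M)
  expd <- outer(rs, cs) / tot
  P <- suppressWarnings(log(M * tot / (rs %o% cs)))
  P[!is.finite(P) | P < 0] <- 0
  sv <- svd(P, nu = min(dim, V), nv = 0)
  k <- min(dim, length(sv$d))
  out <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sqrt(sv$d[seq_len(k)]), k)
  if (k < dim) out <- cbind(out, matrix(0, V, dim - k))
  out
}

#' @export
print.word_vector_space <- function(x, ...) {
  cat(sprintf(
    "<word_vector_space: %d terms, dim %d, %s>\n",
    nrow(x$vectors), x$dim, x$method
  ))
  invisible(x)
}

#' @method tidy word_vector_space
#' @export
tidy.word_vector_space <- function(x, ...) {
  tibble(
    term = rownames(x$vectors),
    frequency = as.integer(x$frequencies[rownames(x$vectors)]),
    vector = lapply(seq_len(nrow(x$vectors)), function(i) unname(x$vectors[i, ]))
  )
}

#' Cosine similarity between two vectors
#'
#' @param u,v Numeric vectors of equal dimension, both nonzero.
#' @return `u . v / (|u| |v|)`, in `[-1, 1]`.
#' @export
#' @examples
#' cosine_similarity(c(1, 0), c(1, 1))
cosine_similarity <- function(u, v) {
  if (length(u) != length(v)) abort("Vectors must share one dimension.")
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) abort("Cosine similarity is undefined for a zero vector.")
  sum(u * v) / (nu * nv)
}

#' Word-vector text format (word2vec convention)
#'
#' First line `vocab_size dim`, then one `term v1 v2 ...` line per term.
#' Terms containing spaces are written with underscores and read back with
#' underscores intact.
#'
#' @param space A `word_vector_space`.
#' @param path File path.
#' @export
write_word_vectors <- function(space, path) {
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(space$vectors), ncol(space$vectors)), con)
  terms <- gsub(" ", "_", rownames(space$vectors), fixed = TRUE)
  for (i in seq_len(nrow(space$vectors))) {
    writeLines(paste(c(terms[i], format(space$vectors[i, ], digits = 17, scientific = TRUE, trim = TRUE)),
      collapse = " "
    ), con)
  }
  invisible(path)
}

#' @rdname write_word_vectors
#' @export
read_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  parts <- strsplit(lines[-1], " ")
  terms <- vapply(parts, `[[`, character(1), 1)
  vecs <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(hdr[2])))
  rownames(vecs) <- terms
  structure(
    list(
      vectors = vecs, frequencies = setNames(rep(1L, length(terms)), terms),
      dim = hdr[2], window = NA_integer_, min_count = NA_integer_,
      method = "file", seed = NA_integer_
    ),
    class = "word_vector_space"
  )
}
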