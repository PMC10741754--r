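#' Hyperplane projection
#'
#' Projects an entity vector onto the hyperplane of a relation:
#' `e - (w . e) w` for a unit normal `w`. The result is orthogonal to `w` and
#' the operation is idempotent.
#'
#' @param e Entity vector.
#' @param w_r Unit normal of the relation hyperplane (checked to 1e-6).
#' @return The projected vector.
#' @export
#' @examples
#' project_onto_hyperplane(c(1, 1), c(1, 0))
project_onto_hyperplane <- function(e, w_r) {
  if (length(e) != length(w_r)) abort("`e` and `w_r` must share one dimension.")
  if (abs(sqrt(sum(w_r^2)) - 1) > 1e-6) {
    abort("`w_r` must be a unit vector (|w_r| = 1 within 1e-6).")
  }
  e - sum(w_r * e) * w_r
}

#' Translation-on-hyperplane score (TransH)
#'
#' Each relation owns a hyperplane (unit normal `w_r`) and a translation
#' vector `d_r`. Head and tail entities are projected onto the hyperplane and
#' the score is the squared Euclidean residual of the translation,
#' `|h_perp + d_r - t_perp|^2`. A correct fact scores near zero; lower is
#' better throughout.
#'
#' @param triple A one-row data frame (or list) with `head`, `relation`,
#'   `tail`, or a character vector of length 3.
#' @param model A `kg_embedding` (see [kg_train()]).
#' @return Non-negative scalar.
#' @export
transh_score <- function(triple, model) {
  trip <- as_triple(triple)
  h <- model_entity(model, trip[1])
  d <- model_relation(model, trip[2])
  t_ <- model_entity(model, trip[3])
  w <- model_normal(model, trip[2])
  res <- project_onto_hyperplane(h, w) + d - project_onto_hyperplane(t_, w)
  sum(res^2)
}

#' Gaussian proximity kernel
#'
#' `k(e_i, e_j) = exp(-|e_i - e_j|^2 / (2 sigma^2))`: 1 at zero distance,
#' symmetric, strictly decreasing in distance, with the classic slow-fast-slow
#' decay profile. The bandwidth `sigma` sets the radial range over which an
#' entity still counts as "near".
#'
#' @param e_i,e_j Vectors of equal dimension.
#' @param sigma Bandwidth, > 0.
#' @return A value in (0, 1].
#' @export
#' @examples
#' gaussian_proximity(c(0, 0), c(1, 1), sigma = 1) # exp(-1)
gaussian_proximity <- function(e_i, e_j, sigma = 1) {
  if (sigma <= 0) abort("`sigma` must be positive.")
  if (length(e_i) != length(e_j)) abort("Vectors must share one dimension.")
  exp(-sum((e_i - e_j)^2) / (2 * sigma^2))
}

#' KGCM score
#'
#' The completion-model score combines the translation residual with the
#' head-tail proximity kernel. `combine = "multiply"` is the product form
#' `transh * k(e_f, e_t)`; `combine = "divide"` uses `transh / k(e_f, e_t)`,
#' which under the lower-is-better convention penalises candidates far from
#' the tail entity and is what [complete_entity()] uses by default (see the
#' package vignette for the reading of the kernel's direction).
#'
#' @inheritParams transh_score
#' @param combine `"multiply"` or `"divide"`.
#' @return Non-negative scalar; 0 exactly when the translation residual is 0.
#' @export
kgcm_score <- function(triple, model, combine = c("multiply", "divide")) {
  combine <- match.arg(combine)
  trip <- as_triple(triple)
  f <- transh_score(trip, model)
  k <- gaussian_proximity(
    model_entity(model, trip[1]), model_entity(model, trip[3]),
    model$sigma
  )
  if (combine == "multiply") f * k else f / k
}

as_triple <- function(triple) {
  if (is.character(triple) && length(triple) == 3) {
    return(unname(triple))
  }
  if (is.data.frame(triple)) {
    stopifnot(nrow(triple) == 1)
    return(c(triple$head[[1]], triple$relation[[1]], triple$tail[[1]]))
  }
  if (is.list(triple)) {
    return(c(triple$head, triple$relation, triple$tail))
  }
  abort("A triple is (head, relation, tail): a character(3), list, or one-row data frame.")
}

model_entity <- function(model, e) {
  i <- match(e, rownames(model$entities))
  if (is.na(i)) abort(sprintf("Entity %s is not in the model vocabulary.", sQuote(e)))
  model$entities[i, ]
}
model_relation <- function(model, r) {
  i <- match(r, rownames(model$relations))
  if (is.na(i)) abort(sprintf("Relation %s is not in the model vocabulary.", sQuote(r)))
  model$relations[i, ]
}
model_normal <- function(model, r) {
  i <- match(r, rownames(model$normals))
  if (is.na(i)) abort(sprintf("Relation %s is not in the model vocabulary.", sQuote(r)))
  model$normals[i, ]
}

new_kg_embedding <- function(entities, relations, normals, sigma, loss_trace = numeric(),
                             config = list()) {
  structure(
    list(
      entities = entities, relations = relations, normals = normals,
      dim = ncol(entities), sigma = sigma, loss_trace = loss_trace,
      config = config
    ),
    class = "kg_embedding"
  )
}

#' Train a hyperplane-translation embedding on SKG triples
#'
#' Margin-ranking training: each positive triple is contrasted with corrupted
#' triples (head or tail replaced uniformly at random) and the loss
#' `max(0, margin + f(pos) - f(neg))` is minimised by SGD. After every update
#' hyperplane normals are renormalised to unit length and entity vectors are
#' projected back into the unit ball. Placeholder-headed triples are
#' inference targets, not training data, and are rejected.
#'
#' @param triples An `skg` or data frame with `head`, `relation`, `tail`.
#' @param dim Embedding dimension.
#' @param sigma Proximity-kernel bandwidth stored with the model.
#' @param margin Ranking margin gamma, > 0.
#' @param lr SGD learning rate.
#' @param epochs Training epochs.
#' @param negative Corrupted samples per positive per epoch.
#' @param seed RNG seed; fixed seed gives an identical model and loss trace.
#' @return A `kg_embedding`: entity/relation/normal matrices (rownames are
#'   the vocabularies), `sigma`, and the per-epoch `loss_trace`.
#' @export
#' @examples
#' tr <- skg(c("liver", "liver"), c("has", "has"), c("surface", "envelope"))
#' m <- kg_train(tr, dim = 4, epochs = 5, seed = 1)
#' transh_score(c("liver", "has", "surface"), m)
kg_train <- function(triples, dim = 16, sigma = 1, margin = 1, lr = 0.01,
                     epochs = 100, negative = 1, seed = 1) {
  triples <- as_tibble(triples)
  stopifnot(all(c("head", "relation", "tail") %in% names(triples)))
  if (nrow(triples) == 0) abort("Cannot train on an empty triple set.")
  if (any(triples$head == PLACEHOLDER)) {
    abort("Placeholder-headed triples must be excluded from training.")
  }
  stopifnot(margin > 0, lr > 0, epochs >= 0, negative >= 1)
  ents <- sort(unique(c(triples$head, triples$tail)))
  rels <- sort(unique(triples$relation))
  hi <- match(triples$head, ents)
  ri <- match(triples$relation, rels)
  ti <- match(triples$tail, ents)
  ne <- length(ents)
  nr <- length(rels)
  set.seed(seed)
  b <- 6 / sqrt(dim)
  E <- matrix(runif(ne * dim, -b, b), ne)
  E <- E / pmax(1, sqrt(rowSums(E^2)))
  D <- matrix(runif(nr * dim, -b, b), nr)
  Wn <- matrix(rnorm(nr * dim), nr)
  Wn <- Wn / sqrt(rowSums(Wn^2))
  np <- nrow(triples)
  score_idx <- function(h, r, t) {
    w <- Wn[r, ]
    eh <- E[h, ]
    et <- E[t, ]
    res <- (eh - sum(w * eh) * w) + D[r, ] - (et - sum(w * et) * w)
    sum(res^2)
  }
  loss_trace <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(np)
    corrupt_head <- matrix(runif(np * negative) < 0.5, np)
    corrupt_with <- matrix(sample.int(ne, np * negative, replace = TRUE), np)
    ep_loss <- 0
    for (p in ord) {
      for (k in seq_len(negative)) {
        h <- hi[p]; r <- ri[p]; t_ <- ti[p]
        if (corrupt_head[p, k]) {
          hn <- corrupt_with[p, k]; tn <- t_
        } else {
          hn <- h; tn <- corrupt_with[p, k]
        }
        if (hn == h && tn == t_) next
        w <- Wn[r, ]
        d <- D[r, ]
        # residuals for positive and corrupted triple
        eh <- E[h, ]; et <- E[t_, ]
        rp <- (eh - sum(w * eh) * w) + d - (et - sum(w * et) * w)
        ehn <- E[hn, ]; etn <- E[tn, ]
        rn <- (ehn - sum(w * ehn) * w) + d - (etn - sum(w * etn) * w)
        loss <- margin + sum(rp^2) - sum(rn^2)
        if (loss <= 0) next
        ep_loss <- ep_loss + loss
        # gradients: with P = I - w w^T (symmetric), d|r|^2/d eh = 2 P r;
        # for the normal, with u = eh - et: d|r|^2/dw = -2((r.w) u + (w.u) r)
        Pp <- 2 * (rp - sum(w * rp) * w)
        Pn <- 2 * (rn - sum(w * rn) * w)
        up <- eh - et
        un <- ehn - etn
        gw_p <- -2 * (sum(rp * w) * up + sum(w * up) * rp)
        gw_n <- -2 * (sum(rn * w) * un + sum(w * un) * rn)
        E[h, ] <- E[h, ] - lr * Pp
        E[t_, ] <- E[t_, ] + lr * Pp
        E[hn, ] <- E[hn, ] + lr * Pn
        E[tn, ] <- E[tn, ] - lr * Pn
        D[r, ] <- D[r, ] - lr * 2 * (rp - rn)
        Wn[r, ] <- Wn[r, ] - lr * (gw_p - gw_n)
        # constraints: unit normals, entities inside the unit ball
        Wn[r, ] <- Wn[r, ] / sqrt(sum(Wn[r, ]^2))
        for (idx in unique(c(h, t_, hn, tn))) {
          nrm <- sqrt(sum(E[idx, ]^2))
          if (nrm > 1) E[idx, ] <- E[idx, ] / nrm
        }
      }
    }
    loss_trace[ep] <- ep_loss / np
  }
  rownames(E) <- ents
  rownames(D) <- rels
  rownames(Wn) <- rels
  new_kg_embedding(E, D, Wn, sigma, loss_trace,
    config = list(
      margin = margin, lr = lr, epochs = epochs,
      negative = negative, seed = seed
    )
  )
}

#' @export
print.kg_embedding <- function(x, ...) {
  cat(sprintf(
    "<kg_embedding: %d entities, %d relations, dim %d, sigma %.3g>\n",
    nrow(x$entities), nrow(x$relations), x$dim, x$sigma
  ))
  if (length(x$loss_trace)) {
    cat(sprintf("  final mean margin loss: %.4g\n", tail(x$loss_trace, 1)))
  }
  invisible(x)
}

#' @method tidy kg_embedding
#' @export
tidy.kg_embedding <- function(x, ...) {
  bind_rows(
    tibble(
      type = "entity", term = rownames(x$entities),
      vector = lapply(seq_len(nrow(x$entities)), function(i) unname(x$entities[i, ]))
    ),
    tibble(
      type = "relation", term = rownames(x$relations),
      vector = lapply(seq_len(nrow(x$relations)), function(i) unname(x$relations[i, ]))
    ),
    tibble(
      type = "hyperplane", term = rownames(x$normals),
      vector = lapply(seq_len(nrow(x$normals)), function(i) unname(x$normals[i, ]))
    )
  )
}

#' @method glance kg_embedding
#' @export
glance.kg_embedding <- function(x, ...) {
  tibble(
    n_entities = nrow(x$entities), n_relations = nrow(x$relations),
    dim = x$dim, sigma = x$sigma,
    epochs = length(x$loss_trace),
    final_loss = if (length(x$loss_trace)) tail(x$loss_trace, 1) else NA_real_
  )
}

#' Training-loss curve
#'
#' @param object A `kg_embedding`.
#' @param ... Unused.
#' @method autoplot kg_embedding
#' @export
autoplot.kg_embedding <- function(object, ...) {
  df <- tibble(epoch = seq_along(object$loss_trace), loss = object$loss_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "mean margin loss")
}

#' Model checkpoints
#'
#' A checkpoint is a directory of TSV vector tables (`entities.tsv`,
#' `relations.tsv`, `hyperplanes.tsv`) plus `meta.json`.
#'
#' @param model A `kg_embedding`.
#' @param dir Checkpoint directory (created if needed).
#' @export
write_kg_embedding <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dump_mat <- function(m, f) {
    df <- data.frame(term = rownames(m), format(m, digits = 17, scientific = TRUE, trim = TRUE))
    write.table(df, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE
    )
  }
  dump_mat(model$entities, "entities.tsv")
  dump_mat(model$relations, "relations.tsv")
  dump_mat(model$normals, "hyperplanes.tsv")
  meta <- list(
    dim = model$dim, sigma = model$sigma,
    loss_trace = model$loss_trace, config = model$config
  )
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE),
    file.path(dir, "meta.json"),
    useBytes = TRUE
  )
  invisible(dir)
}

#' @rdname write_kg_embedding
#' @export
read_kg_embedding <- function(dir) {
  slurp <- function(f) {
    raw <- read.delim(file.path(dir, f), header = FALSE, colClasses = "character", quote = "")
    m <- as.matrix(raw[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- raw[[1]]
    colnames(m) <- NULL
    m
  }
  meta <- jsonlite::fromJSON(file.path(dir, "meta.json"))
  new_kg_embedding(
    slurp("entities.tsv"), slurp("relations.tsv"), slurp("hyperplanes.tsv"),
    sigma = meta$sigma, loss_trace = as.numeric(meta$loss_trace),
    config = as.list(meta$config)
  )
}

#' Restore omitted head entities in an SKG
#'
#' For every placeholder-headed triple `(@, r, t)`, candidate entities are
#' ranked by the completion score with the placeholder replaced, and the
#' lowest-scoring candidate is written into the head slot. The default
#' candidate policy mirrors how writers omit entities: only entities already
#' mentioned earlier in the same report are considered, falling back to the
#' whole entity vocabulary when the report offers none. Ties break by earlier
#' first mention, then lexicographically. Candidates missing from the model
#' vocabulary are skipped; when no candidate can be scored the triple is left
#' as `"@"` and reported via a warning.
#'
#' @param x An `skg`.
#' @param model A `kg_embedding` trained on the non-placeholder triples (or a
#'   superset of them).
#' @param candidate_policy `"report"` (default) or `"global"`.
#' @param scoring `"kgcm"` (default) or `"transh"` (ignores the proximity
#'   kernel).
#' @param combine Kernel combination for the KGCM score; the default
#'   `"divide"` prefers candidates near the tail entity.
#' @return The completed `skg`; a logical column `completed` marks rewritten
#'   rows.
#' @export
complete_entity <- function(x, model, candidate_policy = c("report", "global"),
                            scoring = c("kgcm", "transh"),
                            combine = c("divide", "multiply")) {
  candidate_policy <- match.arg(candidate_policy)
  scoring <- match.arg(scoring)
  combine <- match.arg(combine)
  x$completed <- FALSE
  ph <- which(x$placeholder)
  if (!length(ph)) return(x)
  vocab <- rownames(model$entities)
  score_fun <- function(h, r, t) {
    if (scoring == "transh") {
      transh_score(c(h, r, t), model)
    } else {
      kgcm_score(c(h, r, t), model, combine = combine)
    }
  }
  unresolved <- character()
  for (i in ph) {
    cands <- completion_candidates(x, i, candidate_policy, vocab)
    cands <- cands[cands$entity %in% vocab, , drop = FALSE]
    if (nrow(cands) == 0 ||
      !(x$relation[i] %in% rownames(model$relations)) ||
      !(x$tail[i] %in% vocab)) {
      unresolved <- c(unresolved, sprintf("(@, %s, %s)", x$relation[i], x$tail[i]))
      next
    }
    sc <- vapply(
      cands$entity, function(e) score_fun(e, x$relation[i], x$tail[i]),
      numeric(1)
    )
    best <- cands$entity[order(sc, cands$first_seen, cands$entity)][1]
    x$head[i] <- best
    x$placeholder[i] <- FALSE
    x$completed[i] <- TRUE
  }
  if (length(unresolved)) {
    warn(sprintf(
      "%d placeholder triple(s) left uncompleted: %s",
      length(unresolved), paste(unresolved, collapse = "; ")
    ))
  }
  x
}

# Candidates for row i: entities first mentioned in earlier rows of the same
# report (by row order = text order), else every entity the model knows.
completion_candidates <- function(x, i, policy, vocab) {
  same_report <- !is.na(x$report_id) & !is.na(x$report_id[i]) &
    x$report_id == x$report_id[i]
  if (all(is.na(x$report_id))) same_report <- rep(TRUE, nrow(x))
  earlier <- which(same_report & seq_len(nrow(x)) < i)
  ents <- character()
  first_seen <- integer()
  note_entity <- function(e, at) {
    if (e != PLACEHOLDER && !(e %in% ents)) {
      ents <<- c(ents, e)
      first_seen <<- c(first_seen, at)
    }
  }
  if (policy == "report") {
    for (j in earlier) {
      note_entity(x$head[j], j)
      note_entity(x$tail[j], j)
    }
  }
  if (!length(ents)) {
    ents <- sort(vocab)
    first_seen <- rep(0L, length(ents))
  }
  tibble(entity = ents, first_seen = first_seen)
}
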