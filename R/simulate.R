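#' Synthetic report grammar
#'
#' Defines an English-like clause grammar that emulates the structure of
#' abdominal ultrasound "observations of imaging" passages: per-organ clause
#' groups, attribute-value phrasing, planted synonym sets for attribute
#' adjectives, and deliberate head-entity omission in follow-on clauses.
#' Every template instantiation carries a derivable gold annotation, so the
#' generated corpus doubles as a gold standard for extraction and completion.
#'
#' Each organ has: an intro verb phrase (`(organ, status, vp)` fact), an
#' optional verb-adjective observation (`(organ, verb, adj)`), attribute
#' parts with adjective sets (full form `(organ, has, part)` +
#' `(part, show, adj)`; omitted form `(@, part, adj)` with the organ as the
#' dropped head), and a feature chain (`(part, verb, adj)` followed by a
#' `show <shape>` clause whose head — the feature part — may be omitted).
#'
#' @param omission Probability that an omittable follow-on clause drops its
#'   head entity, in `[0, 1]`. Default 0.3.
#' @param organs Optional replacement organ inventory (same structure as the
#'   default; see the source).
#' @return A `report_grammar` list; `grammar_lexicon()` derives its
#'   [tag_lexicon()].
#' @export
report_grammar <- function(omission = 0.3, organs = NULL) {
  stopifnot(omission >= 0, omission <= 1)
  if (is.null(organs)) {
    organs <- list(
      liver = list(
        vp = "has no normalcy", verb = "shows", verb_adj = "shrink",
        parts = list(
          "surface" = c("uneven", "rough", "unsmooth"),
          "envelope" = c("irregular", "wavy")
        ),
        feature = list(
          part = "substantial echo", verb = "thickens",
          adjs = c("nonuniform", "heterogeneous"), shape = "nodule shape"
        )
      ),
      "right liver" = list(
        vp = "keeps reduced volume", verb = "shows", verb_adj = "shrink",
        parts = list(), feature = NULL
      ),
      gallbladder = list(
        vp = "keeps regular outline", verb = "shows", verb_adj = "distension",
        parts = list(
          "wall" = c("coarse", "granular"),
          "intracavity" = c("anechoic", "transparent")
        ),
        feature = list(
          part = "wall echo", verb = "brightens",
          adjs = c("speckled", "dotted"), shape = "sludge layer"
        )
      ),
      pancreas = list(
        vp = "retains usual form", verb = "shows", verb_adj = "swelling",
        parts = list(
          "pancreatic duct" = c("undilated", "slender"),
          "gland margin" = c("smooth", "even")
        ),
        feature = list(
          part = "gland echo", verb = "dims",
          adjs = c("fine", "soft"), shape = "fat band"
        )
      ),
      spleen = list(
        vp = "has mild prominence", verb = "shows", verb_adj = "enlargement",
        parts = list(
          "parenchymal" = c("homogeneous", "uniform"),
          "hilum" = c("ordinary", "plain")
        ),
        feature = list(
          part = "pulp echo", verb = "steadies",
          adjs = c("steady", "settled"), shape = "dense dots"
        )
      ),
      kidney = list(
        vp = "preserves outline", verb = "shows", verb_adj = "descent",
        parts = list(
          "renal pelvis" = c("separated", "widened"),
          "calyx" = c("dilated", "expanded")
        ),
        feature = list(
          part = "cortex echo", verb = "fades",
          adjs = c("thin", "faint"), shape = "sinus band"
        )
      )
    )
  }
  structure(list(omission = omission, organs = organs), class = "report_grammar")
}

#' @rdname report_grammar
#' @param grammar A `report_grammar`.
#' @export
grammar_lexicon <- function(grammar) {
  terms <- character()
  tags <- character()
  add <- function(t, tag) {
    terms <<- c(terms, t)
    tags <<- c(tags, rep(tag, length(t)))
  }
  for (name in names(grammar$organs)) {
    o <- grammar$organs[[name]]
    add(name, "organ")
    add(o$vp, "verb")
    add(o$verb, "verb")
    add(o$verb_adj, "adj")
    for (p in names(o$parts)) {
      add(p, "n")
      add(o$parts[[p]], "adj")
    }
    if (!is.null(o$feature)) {
      add(o$feature$part, "n")
      add(o$feature$verb, "verb")
      add(o$feature$adjs, "adj")
      add(o$feature$shape, "n")
      add("show", "verb")
    }
  }
  tag_lexicon(tibble(term = terms, tag = tags))
}

#' Planted synonym sets of a grammar
#'
#' The adjective alternatives of each attribute part form a planted synonym
#' set (they are sampled interchangeably in identical contexts). Useful as
#' the gold standard for synonym-recovery checks.
#'
#' @param grammar A `report_grammar`.
#' @return A list of character vectors, one synonym set per attribute.
#' @export
grammar_synonym_sets <- function(grammar) {
  sets <- list()
  for (o in grammar$organs) {
    for (p in names(o$parts)) {
      if (length(o$parts[[p]]) > 1) sets[[length(sets) + 1L]] <- o$parts[[p]]
    }
    if (!is.null(o$feature) && length(o$feature$adjs) > 1) {
      sets[[length(sets) + 1L]] <- o$feature$adjs
    }
  }
  sets
}

#' Generate synthetic reports with gold annotations
#'
#' Deterministic for a fixed seed. Each report samples a subset of organ
#' domains (the liver always present, mirroring an abdominal routine) and
#' realises their clause templates; each omittable follow-on clause drops its
#' head entity with the grammar's omission probability. Gold annotations are
#' derived template-by-template, independently of the extraction code.
#'
#' @param grammar A [report_grammar()].
#' @param n Number of reports, >= 1.
#' @param seed RNG seed.
#' @return A tibble with one row per report: `report_id`, `text`, `gold_tn`
#'   (tibble of rule-relevant concepts: `token`, `tag`, `sentence_index`),
#'   `gold_skg` (`skg` with `"@"` where heads were omitted), `gold_completed`
#'   (`skg` with the true heads restored), `omissions` (tibble
#'   `sentence_index`, `entity`).
#' @export
#' @examples
#' reports <- generate_reports(report_grammar(omission = 0), n = 2, seed = 1)
#' reports$gold_skg[[1]]
generate_reports <- function(grammar = report_grammar(), n = 50, seed = 1) {
  stopifnot(n >= 1)
  if (!length(grammar$organs)) abort("Grammar has no organs.")
  if (!any(vapply(grammar$organs, function(o) length(o$parts) > 0 || !is.null(o$feature), logical(1)))) {
    abort("Degenerate grammar: no organ has parts or features to describe.")
  }
  set.seed(seed)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    out[[k]] <- generate_one_report(grammar, sprintf("r%03d", k))
  }
  res <- bind_rows(out)
  res
}

generate_one_report <- function(grammar, report_id) {
  clauses <- character()
  tn_tok <- character()
  tn_tag <- character()
  tn_sent <- integer()
  heads <- character()
  rels <- character()
  tails <- character()
  trip_sent <- integer()
  omit_sent <- integer()
  omit_entity <- character()
  gold_heads <- character() # like heads but with the omitted entity restored
  sent <- -1L

  push_clause <- function(text, tokens, tags) {
    sent <<- sent + 1L
    clauses <<- c(clauses, text)
    tn_tok <<- c(tn_tok, tokens)
    tn_tag <<- c(tn_tag, tags)
    tn_sent <<- c(tn_sent, rep(sent, length(tokens)))
    sent
  }
  push_triple <- function(h, r, t, s, gold_h = h) {
    heads <<- c(heads, h)
    rels <<- c(rels, r)
    tails <<- c(tails, t)
    trip_sent <<- c(trip_sent, s)
    gold_heads <<- c(gold_heads, gold_h)
  }

  organ_names <- names(grammar$organs)
  present <- c(TRUE, runif(length(organ_names) - 1) < 0.7)
  for (oi in seq_along(organ_names)) {
    if (!present[oi]) next
    oname <- organ_names[oi]
    o <- grammar$organs[[oi]]
    s <- push_clause(
      paste("The", oname, o$vp), c(oname, o$vp), c("organ", "verb")
    )
    push_triple(oname, "status", o$vp, s)
    if (runif(1) < 0.6) {
      s <- push_clause(
        paste("the", oname, o$verb, o$verb_adj),
        c(oname, o$verb, o$verb_adj), c("organ", "verb", "adj")
      )
      push_triple(oname, o$verb, o$verb_adj, s)
    }
    for (p in names(o$parts)) {
      if (runif(1) >= 0.8) next
      adj <- sample(o$parts[[p]], 1)
      if (runif(1) < grammar$omission) {
        s <- push_clause(paste(p, adj), c(p, adj), c("n", "adj"))
        push_triple(PLACEHOLDER, p, adj, s, gold_h = oname)
        omit_sent <- c(omit_sent, s)
        omit_entity <- c(omit_entity, oname)
      } else {
        s <- push_clause(
          paste("the", oname, p, adj), c(oname, p, adj), c("organ", "n", "adj")
        )
        push_triple(oname, "has", p, s)
        push_triple(p, "show", adj, s)
      }
    }
    if (!is.null(o$feature) && runif(1) < 0.8) {
      f <- o$feature
      fadj <- sample(f$adjs, 1)
      s <- push_clause(
        paste("the", f$part, f$verb, fadj),
        c(f$part, f$verb, fadj), c("n", "verb", "adj")
      )
      push_triple(f$part, f$verb, fadj, s)
      if (runif(1) < grammar$omission) {
        s <- push_clause(paste("show", f$shape), c("show", f$shape), c("verb", "n"))
        push_triple(PLACEHOLDER, "show", f$shape, s, gold_h = f$part)
        omit_sent <- c(omit_sent, s)
        omit_entity <- c(omit_entity, f$part)
      } else {
        s <- push_clause(
          paste(f$part, "show", f$shape),
          c(f$part, "show", f$shape), c("n", "verb", "n")
        )
        push_triple(f$part, "show", f$shape, s)
      }
    }
  }
  text <- paste0(paste(clauses, collapse = ", "), ".")
  gold_skg <- skg(heads, rels, tails,
    report_id = report_id, sentence_index = trip_sent
  )
  gold_completed <- skg(gold_heads, rels, tails,
    report_id = report_id, sentence_index = trip_sent
  )
  tibble(
    report_id = report_id,
    text = text,
    gold_tn = list(tibble(token = tn_tok, tag = tn_tag, sentence_index = tn_sent)),
    gold_skg = list(gold_skg),
    gold_completed = list(gold_completed),
    omissions = list(tibble(sentence_index = omit_sent, entity = omit_entity))
  )
}

#' Generate a knowledge graph with planted hyperplane-translation geometry
#'
#' Plants ground-truth relation hyperplanes and translations, then derives
#' entities so that every generated fact satisfies the translation identity
#' up to a noise term: tails are built as
#' `proj(head) + d_r + alpha * w_r + eps` with `|proj(eps)| <= noise`, so
#' every fact's translation score is at most `noise^2`. With
#' `confusable > 0`, extra distractor entities are added that share a true
#' head's hyperplane projection (identical translation score) but sit farther
#' from the tail — the configuration that separates proximity-aware
#' completion from the plain translation score.
#'
#' @param n_entities Total entities (roots + derived), >= 4.
#' @param n_relations Number of relations.
#' @param dim Embedding dimension, >= 2.
#' @param noise On-hyperplane noise bound per fact (Euclidean norm).
#' @param n_triples Size of the generated fact multiset (facts are repeated
#'   observations, as in a report corpus).
#' @param n_roots Entities drawn freely before derivation starts.
#' @param confusable Number of distractor head entities to plant.
#' @param seed RNG seed.
#' @return A `planted_kg` list: `model` (a `kg_embedding` holding the true
#'   vectors), `facts` (distinct gold facts as an `skg`), `triples` (the
#'   sampled multiset `skg`), `queries` (facts with hidden heads:
#'   `head`, `relation`, `tail`, `confusable`), `noise_bound` (`noise^2`).
#' @export
#' @examples
#' pk <- generate_planted_kg(n_entities = 10, n_relations = 2, dim = 4, seed = 1)
#' max(vapply(seq_len(nrow(pk$facts)), function(i) {
#'   transh_score(pk$facts[i, ], pk$model)
#' }, numeric(1))) <= pk$noise_bound
generate_planted_kg <- function(n_entities = 50, n_relations = 4, dim = 16,
                                noise = 0.05, n_triples = 400, n_roots = 10,
                                confusable = 0, seed = 1) {
  stopifnot(n_entities >= 4, dim >= 2, noise >= 0, n_roots >= 1, n_roots < n_entities)
  set.seed(seed)
  rand_unit <- function() {
    v <- rnorm(dim)
    v / sqrt(sum(v^2))
  }
  W <- t(replicate(n_relations, rand_unit()))
  D <- matrix(0, n_relations, dim)
  for (r in seq_len(n_relations)) {
    d <- rnorm(dim)
    d <- d - sum(d * W[r, ]) * W[r, ] # translation lies on the hyperplane
    D[r, ] <- 0.3 * d / sqrt(sum(d^2))
  }
  E <- matrix(0, n_entities, dim)
  for (i in seq_len(n_roots)) {
    v <- rnorm(dim)
    E[i, ] <- 0.4 * runif(1) * v / sqrt(sum(v^2))
  }
  facts_h <- integer()
  facts_r <- integer()
  facts_t <- integer()
  for (i in seq(n_roots + 1, n_entities)) {
    h <- sample.int(n_roots, 1)
    r <- sample.int(n_relations, 1)
    w <- W[r, ]
    eps <- rnorm(dim)
    eps <- eps - sum(eps * w) * w
    nrm <- sqrt(sum(eps^2))
    if (nrm > 0) eps <- eps * (runif(1) * noise) / nrm
    alpha <- runif(1, -0.15, 0.15)
    E[i, ] <- (E[h, ] - sum(w * E[h, ]) * w) + D[r, ] + alpha * w + eps
    facts_h <- c(facts_h, h)
    facts_r <- c(facts_r, r)
    facts_t <- c(facts_t, i)
  }
  ent_names <- sprintf("e%02d", seq_len(n_entities))
  rel_names <- sprintf("rel%d", seq_len(n_relations))
  conf_of <- rep(NA_character_, length(facts_h))
  if (confusable > 0) {
    picks <- sample(seq_along(facts_h), min(confusable, length(facts_h)))
    for (j in seq_along(picks)) {
      f <- picks[j]
      h <- facts_h[f]
      r <- facts_r[f]
      t_ <- facts_t[f]
      w <- W[r, ]
      # same projection as the true head, but pushed away from the tail
      # along the normal
      dir <- sign(sum(w * (E[h, ] - E[t_, ])))
      if (dir == 0) dir <- 1
      dvec <- E[h, ] + dir * 0.45 * w
      E <- rbind(E, dvec)
      ent_names <- c(ent_names, sprintf("e%02d_distractor", h))
      conf_of[f] <- sprintf("e%02d_distractor", h)
    }
  }
  rownames(E) <- ent_names
  rownames(D) <- rel_names
  rownames(W) <- rel_names
  model <- new_kg_embedding(E, D, W, sigma = 1)
  facts <- skg(
    ent_names[facts_h], rel_names[facts_r], ent_names[facts_t],
    report_id = "planted"
  )
  idx <- sample.int(nrow(facts), n_triples, replace = TRUE)
  triples <- validate_skg(as_tibble(facts)[idx, , drop = FALSE])
  queries <- tibble(
    head = facts$head, relation = facts$relation, tail = facts$tail,
    confusable = conf_of
  )
  structure(
    list(
      model = model, facts = facts, triples = triples, queries = queries,
      noise_bound = noise^2, dim = dim
    ),
    class = "planted_kg"
  )
}

#' Head-entity link-prediction accuracy
#'
#' For each query `(?, r, t)` ranks candidate entities by completion score
#' and reports hits@1 against the gold head. Ties break lexicographically.
#'
#' @param model A `kg_embedding`.
#' @param queries Tibble with `head` (gold), `relation`, `tail`.
#' @param scoring `"kgcm"` or `"transh"`.
#' @param combine Kernel combination for KGCM scoring.
#' @param candidates Candidate entity set; default the model vocabulary.
#' @return Fraction of queries whose top-ranked candidate is the gold head.
#' @export
link_prediction_hits <- function(model, queries, scoring = c("kgcm", "transh"),
                                 combine = c("divide", "multiply"),
                                 candidates = NULL) {
  scoring <- match.arg(scoring)
  combine <- match.arg(combine)
  candidates <- candidates %||% rownames(model$entities)
  hit <- logical(nrow(queries))
  for (i in seq_len(nrow(queries))) {
    sc <- vapply(candidates, function(e) {
      trip <- c(e, queries$relation[i], queries$tail[i])
      if (scoring == "transh") {
        transh_score(trip, model)
      } else {
        kgcm_score(trip, model, combine = combine)
      }
    }, numeric(1))
    best <- candidates[order(sc, candidates)][1]
    hit[i] <- identical(best, queries$head[i])
  }
  mean(hit)
}
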