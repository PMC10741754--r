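#' Pipeline configuration
#'
#' Bundles paths, backends and hyperparameters for the batch pipeline stages
#' ([run_extract()], [run_complete()], [run_export()], [run_eval()]). The
#' configuration is fully serializable; runs are stamped with its hash so an
#' output directory records exactly what produced it.
#'
#' @param corpus Directory of `*.txt` report files, or a TSV with columns
#'   `report_id`, `text`.
#' @param lexicon Path to a tag-lexicon TSV (see [read_tag_lexicon()]).
#' @param rules Optional path to a rule file; default rules otherwise.
#' @param out_dir Output directory.
#' @param tokenizer Tokenizer backend name ("whitespace").
#' @param surface_relation Extraction toggle, see [skg_config()].
#' @param synonyms Run synonym normalization during extraction?
#' @param synonym_threshold Similarity threshold for [build_synonym_table()].
#' @param embed_dim,embed_window,embed_epochs Word-vector hyperparameters.
#' @param kg_dim,sigma,margin,lr,epochs,negative Embedding-model
#'   hyperparameters for completion (see [kg_train()]).
#' @param combine Completion kernel direction, see [complete_entity()].
#' @param seed Seed for every stochastic stage.
#' @return A `pipeline_config` list with a `hash` field.
#' @export
pipeline_config <- function(corpus = NULL, lexicon = NULL, rules = NULL,
                            out_dir = "sonokg-out", tokenizer = "whitespace",
                            surface_relation = TRUE, synonyms = TRUE,
                            synonym_threshold = 0.55, embed_dim = 16,
                            embed_window = 2, embed_epochs = 15,
                            kg_dim = 16, sigma = 1, margin = 1, lr = 0.01,
                            epochs = 150, negative = 1,
                            combine = "divide", seed = 1) {
  cfg <- list(
    corpus = corpus, lexicon = lexicon, rules = rules, out_dir = out_dir,
    tokenizer = tokenizer, surface_relation = surface_relation,
    synonyms = synonyms, synonym_threshold = synonym_threshold,
    embed_dim = embed_dim, embed_window = embed_window,
    embed_epochs = embed_epochs, kg_dim = kg_dim, sigma = sigma,
    margin = margin, lr = lr, epochs = epochs, negative = negative,
    combine = combine, seed = seed
  )
  # numeric scalars are canonicalised so a JSON round trip hashes identically
  cfg <- lapply(cfg, function(v) if (is.numeric(v)) as.numeric(v) else v)
  cfg$hash <- rlang::hash(cfg)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML-free key-value JSON file.
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::fromJSON(path)
  raw$hash <- NULL
  do.call(pipeline_config, raw)
}

#' @rdname pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  writeLines(
    jsonlite::toJSON(unclass(config), auto_unbox = TRUE, pretty = TRUE, null = "null"),
    path,
    useBytes = TRUE
  )
  invisible(path)
}

pipeline_log <- function(fmt, ...) {
  message(sprintf(paste0("[sonokg] ", fmt), ...))
}

load_corpus <- function(corpus) {
  if (is.null(corpus)) abort("Pipeline config has no corpus path.", class = "sonokg_data_error")
  if (dir.exists(corpus)) {
    files <- sort(list.files(corpus, pattern = "\\.txt$", full.names = TRUE))
    return(tibble(
      report_id = sub("\\.txt$", "", basename(files)),
      text = vapply(files, function(f) paste(readLines(f, warn = FALSE), collapse = " "), character(1))
    ))
  }
  if (file.exists(corpus)) {
    raw <- read.delim(corpus, sep = "\t", colClasses = "character", quote = "")
    stopifnot(all(c("report_id", "text") %in% names(raw)))
    return(as_tibble(raw))
  }
  abort(sprintf("Corpus not found: %s", corpus), class = "sonokg_data_error")
}

#' Run the extraction stage
#'
#' Structures every report, extracts its SKG, optionally trains word vectors
#' on the corpus and rewrites synonym variants to canonical terms. Writes
#' `skg.tsv`, `skg.json`, `synonyms.json` (when enabled) and `config.json`
#' into the output directory. Deterministic for a fixed config.
#'
#' @param config A [pipeline_config()].
#' @return The (normalized) `skg`, invisibly.
#' @export
run_extract <- function(config) {
  reports <- load_corpus(config$corpus)
  if (is.null(config$lexicon) || !file.exists(config$lexicon)) {
    abort(sprintf("Lexicon file not found: %s", config$lexicon %||% "<missing>"),
      class = "sonokg_data_error"
    )
  }
  lex <- read_tag_lexicon(config$lexicon)
  rules <- if (!is.null(config$rules)) read_rules(config$rules) else default_rules()
  splitter <- clause_splitter(tokenizer = config$tokenizer)
  pipeline_log("extracting %d report(s)", nrow(reports))
  res <- extract_skg(reports, lex,
    rules = rules, splitter = splitter,
    config = skg_config(surface_relation = config$surface_relation)
  )
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (isTRUE(config$synonyms) && nrow(reports) > 0) {
    corpus_tokens <- lapply(reports$text, function(txt) {
      segs <- merge_lexicon_terms(segment_report(txt, splitter), lex)
      normalize_term(segs$token, lex)
    })
    space <- train_embeddings(corpus_tokens,
      dim = config$embed_dim,
      window = config$embed_window, epochs = config$embed_epochs,
      seed = config$seed
    )
    adjs <- intersect(lex$term[lex$tag == "adj"], rownames(space$vectors))
    if (length(adjs) > 1) {
      table <- build_synonym_table(space, adjs, threshold = config$synonym_threshold)
      res <- normalize_skg(res, table)
      write_synonym_table(table, file.path(config$out_dir, "synonyms.json"))
      write_word_vectors(space, file.path(config$out_dir, "vectors.txt"))
      pipeline_log("synonym table: %d group(s)", length(unique(table$canonical)))
    }
  }
  write_skg(res, file.path(config$out_dir, "skg.tsv"))
  write_skg(res, file.path(config$out_dir, "skg.json"))
  write_pipeline_config(config, file.path(config$out_dir, "config.json"))
  pipeline_log(
    "extracted %d triple(s), %d with omitted heads [config %s]",
    nrow(res), sum(res$placeholder), config$hash
  )
  invisible(res)
}

#' Run the completion stage
#'
#' Trains the embedding model on the SKG's non-placeholder triples and
#' restores omitted head entities. Writes `skg_completed.tsv` and a model
#' checkpoint directory. Deterministic per seed.
#'
#' @param config A [pipeline_config()].
#' @param skg_path SKG TSV; default `out_dir/skg.tsv`.
#' @param training Optional additional training triples (an `skg` or TSV
#'   path), e.g. a gold corpus; placeholder rows are dropped.
#' @return The completed `skg`, invisibly.
#' @export
run_complete <- function(config, skg_path = NULL, training = NULL) {
  skg_path <- skg_path %||% file.path(config$out_dir, "skg.tsv")
  if (!file.exists(skg_path)) {
    abort(sprintf("SKG file not found: %s", skg_path), class = "sonokg_data_error")
  }
  x <- read_skg(skg_path)
  train_set <- x[!x$placeholder, , drop = FALSE]
  if (!is.null(training)) {
    extra <- if (is.character(training)) read_skg(training) else validate_skg(training)
    extra <- extra[!extra$placeholder, , drop = FALSE]
    train_set <- validate_skg(bind_rows(as_tibble(train_set), as_tibble(extra)))
  }
  pipeline_log("training embedding on %d triple(s)", nrow(train_set))
  model <- kg_train(train_set,
    dim = config$kg_dim, sigma = config$sigma,
    margin = config$margin, lr = config$lr, epochs = config$epochs,
    negative = config$negative, seed = config$seed
  )
  done <- complete_entity(x, model, combine = config$combine)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  write_skg(done, file.path(config$out_dir, "skg_completed.tsv"))
  write_kg_embedding(model, file.path(config$out_dir, "model"))
  pipeline_log("completed %d head(s) [config %s]", sum(done$completed), config$hash)
  invisible(done)
}

#' Run the export stage
#'
#' Serialises an SKG as RDF/XML, Turtle and GraphML.
#'
#' @param config A [pipeline_config()].
#' @param skg_path SKG TSV; defaults to the completed SKG when present, else
#'   the extracted one.
#' @return Paths of the written documents, invisibly.
#' @export
run_export <- function(config, skg_path = NULL) {
  skg_path <- skg_path %||% {
    cand <- file.path(config$out_dir, "skg_completed.tsv")
    if (file.exists(cand)) cand else file.path(config$out_dir, "skg.tsv")
  }
  if (!file.exists(skg_path)) {
    abort(sprintf("SKG file not found: %s", skg_path), class = "sonokg_data_error")
  }
  x <- read_skg(skg_path)
  g <- to_ontology(x, drop_placeholders = TRUE)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    rdfxml = file.path(config$out_dir, "graph.rdf"),
    turtle = file.path(config$out_dir, "graph.ttl"),
    graphml = file.path(config$out_dir, "graph.graphml")
  )
  writeLines(serialize_ontology(g, "rdfxml"), paths[["rdfxml"]], useBytes = TRUE)
  writeLines(serialize_ontology(g, "turtle"), paths[["turtle"]], useBytes = TRUE)
  export_graphml(x, paths[["graphml"]])
  pipeline_log("exported %s", paste(basename(paths), collapse = ", "))
  invisible(paths)
}

#' Run the evaluation stage
#'
#' Scores predicted triples against gold ones in all match modes and, when a
#' lexicon is configured, computes domain counts and the extraction index.
#' Writes `metrics.csv` and `metrics.json`.
#'
#' @param config A [pipeline_config()].
#' @param pred,gold SKG TSV paths (or `skg` objects).
#' @param baseline Valid-domain count of the text-matching reference (its
#'   fixed organ inventory size), used for the extraction index.
#' @return A list with `metrics` (tibble) and `eta` (number or NA),
#'   invisibly.
#' @export
run_eval <- function(config, pred, gold, baseline = 5) {
  as_skg_arg <- function(p) if (is.character(p)) read_skg(p) else validate_skg(p)
  p <- as_skg_arg(pred)
  g <- as_skg_arg(gold)
  metrics <- bind_rows(
    score_triples(p, g, "triple"),
    score_triples(p, g, "head"),
    score_triples(p, g, "tail")
  )
  eta <- NA_real_
  if (!is.null(config$lexicon) && file.exists(config$lexicon)) {
    lex <- read_tag_lexicon(config$lexicon)
    organs <- lex$term[lex$tag == "organ"]
    doms <- summarize_domains(p, organs)$domains
    n <- sum(doms$n_domains)
    v <- sum(doms$v_domains)
    eta <- if (n > 0) extraction_index(n, v, baseline * max(1, nrow(doms))) else NA_real_
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(as.data.frame(metrics),
    file.path(config$out_dir, "metrics.csv"),
    row.names = FALSE
  )
  writeLines(
    jsonlite::toJSON(list(metrics = metrics, eta = eta),
      dataframe = "rows", auto_unbox = TRUE, pretty = TRUE, digits = NA, na = "null"
    ),
    file.path(config$out_dir, "metrics.json"),
    useBytes = TRUE
  )
  pipeline_log("metrics written [config %s]", config$hash)
  invisible(list(metrics = metrics, eta = eta))
}
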