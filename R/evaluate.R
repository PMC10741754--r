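#' Precision, recall and F1 against gold triples
#'
#' Set-based matching of predicted against gold triples (apply
#' [normalize_skg()] to both sides first if synonym variation should not
#' count as error). `match_mode` selects what is compared: whole triples, or
#' only the head (subject-entity recognition) or tail (value recognition)
#' projections. Zero denominators yield 0, not errors.
#'
#' @param predicted,gold `skg` objects or data frames with `head`,
#'   `relation`, `tail`.
#' @param match_mode `"triple"` (default), `"head"`, or `"tail"`.
#' @return A one-row tibble: `match_mode`, `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`.
#' @export
#' @examples
#' p <- skg(c("liver", "liver"), c("has", "show"), c("surface", "uneven"))
#' score_triples(p, p)
score_triples <- function(predicted, gold, match_mode = c("triple", "head", "tail")) {
  match_mode <- match.arg(match_mode)
  keyset <- function(x) {
    x <- as_tibble(x)
    unique(switch(match_mode,
      triple = paste(x$head, x$relation, x$tail, sep = "\r"),
      head = x$head,
      tail = x$tail
    ))
  }
  p <- keyset(predicted)
  g <- keyset(gold)
  tp <- length(intersect(p, g))
  fp <- length(setdiff(p, g))
  fn <- length(setdiff(g, p))
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  tibble(
    match_mode = match_mode, tp = tp, fp = fp, fn = fn,
    precision = precision, recall = recall, f1 = f1
  )
}

#' Domain-extraction index
#'
#' `eta = (v / baseline) * (v / n)`: the yield of valid extracted domains
#' relative to a fixed-domain text-matching reference, discounted by the
#' fraction of extracted domains that are valid. A method that extracts
#' exactly the reference's domains, all valid, scores 1; extracting more
#' valid domains than the reference pushes eta above 1.
#'
#' @param n Number of extracted domains (>= v).
#' @param v Number of valid extracted domains.
#' @param baseline Valid-domain count of the reference method, > 0.
#' @return The index as a plain number; `n = 0` returns 0 with a warning.
#' @export
#' @examples
#' extraction_index(n = 5, v = 5, baseline = 5)
extraction_index <- function(n, v, baseline) {
  stopifnot(baseline > 0, v >= 0)
  if (v > n) abort("`v` cannot exceed `n`.")
  if (n == 0) {
    warn("No domains extracted; extraction index is 0.")
    return(0)
  }
  (v / baseline) * (v / n)
}

#' Domain and relation summaries over a report collection
#'
#' A domain is a connected component of a report's entity graph; it is valid
#' when it contains an organ from the supplied inventory (the root of the
#' organ's finding subgraph). Returns the distribution of domain counts across
#' reports
#' (the basis of the extraction index) and the relative frequency of the
#' extracted relation patterns.
#'
#' @param x An `skg` with `report_id` provenance (or a list of per-report
#'   `skg`s).
#' @param organs Character vector of organ entities (e.g.
#'   `lexicon$term[lexicon$tag == "organ"]`).
#' @return A list of tibbles: `domains` (`report_id`, `n_domains`,
#'   `v_domains`), `domain_distribution` (`n_domains`, `n_reports`),
#'   `relation_frequencies` (`head`, `relation`, `tail`, `n`, `pct`, sorted
#'   by frequency).
#' @export
summarize_domains <- function(x, organs) {
  if (is.list(x) && !is.data.frame(x)) {
    x <- bind_rows(imap(x, function(s, i) {
      s$report_id <- as.character(i)
      as_tibble(s)
    }))
    x <- validate_skg(x)
  }
  x <- validate_skg(x)
  if (nrow(x) == 0) {
    return(list(
      domains = tibble(report_id = character(), n_domains = integer(), v_domains = integer()),
      domain_distribution = tibble(n_domains = integer(), n_reports = integer()),
      relation_frequencies = tibble(
        head = character(), relation = character(), tail = character(),
        n = integer(), pct = numeric()
      )
    ))
  }
  organs <- tolower(organs)
  per_report <- lapply(split(as_tibble(x), x$report_id), function(df) {
    df <- df[!df$placeholder | df$tail != "", , drop = FALSE]
    ents <- unique(c(df$head[df$head != PLACEHOLDER], df$tail))
    if (!length(ents)) {
      return(tibble(n_domains = 0L, v_domains = 0L))
    }
    edges <- df[df$head != PLACEHOLDER, c("head", "tail"), drop = FALSE]
    g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = ents)
    comp <- igraph::components(g)
    rooted <- vapply(seq_len(comp$no), function(k) {
      members <- names(comp$membership)[comp$membership == k]
      any(tolower(members) %in% organs)
    }, logical(1))
    tibble(n_domains = comp$no, v_domains = sum(rooted))
  })
  domains <- bind_rows(per_report, .id = "report_id")
  dist <- count(domains, .data$n_domains, name = "n_reports")
  freq <- count(as_tibble(x), .data$head, .data$relation, .data$tail, sort = TRUE)
  freq <- mutate(freq, pct = 100 * .data$n / sum(.data$n))
  freq <- arrange(freq, dplyr::desc(.data$n), .data$head, .data$relation, .data$tail)
  list(
    domains = domains,
    domain_distribution = dist,
    relation_frequencies = freq
  )
}
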