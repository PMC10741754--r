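#' Tag-sequence rules for entity-relation extraction
#'
#' Extraction is driven by short rules over concept tags. Each rule is a
#' pattern of length 2 or 3 whose first slot is the head entity; it emits one
#' or two triples, with the relation either copied from the matched verb slot
#' (written `"$verb"`) or a literal (`"show"`, `"has"`, ...). The default set
#' contains the four rules used for ultrasound findings:
#'
#' 1. `(organ, verb, adj)` -> `(organ, <verb>, adj)`
#' 2. `(organ, adj)` -> `(organ, show, adj)`
#' 3. `(organ, verb)` -> `(organ, <verb_fact_relation>, verb)`
#' 4. `(organ, n, adj)` -> `(organ, has, n)` and `(n, show, adj)`
#'
#' During matching the head slot of rules 1 and 4 also accepts plain-noun
#' entities so that attribute chains (`liver -> blood vessel -> structure`)
#' can be followed; see [match_rules()].
#'
#' @param verb_fact_relation Relation used to render two-element
#'   organ-predicate facts (`{liver, has no normalcy}`) as triples. The
#'   default `"status"` keeps such facts distinguishable from attribute
#'   display; set `"show"` for the literal rule-table reading.
#' @return A `tag_rules` tibble: `id`, `pattern` (list of tag vectors),
#'   `kind`, `relation`, `relation2`.
#' @export
#' @examples
#' default_rules()
default_rules <- function(verb_fact_relation = "status") {
  new_tag_rules(tibble(
    id = 1:4,
    pattern = list(
      c("organ", "verb", "adj"),
      c("organ", "adj"),
      c("organ", "verb"),
      c("organ", "n", "adj")
    ),
    relation = c("$verb", "show", verb_fact_relation, "has"),
    relation2 = c(NA, NA, NA, "show")
  ))
}

new_tag_rules <- function(tbl) {
  stopifnot(all(c("id", "pattern", "relation") %in% names(tbl)))
  if (!"relation2" %in% names(tbl)) tbl$relation2 <- NA_character_
  lens <- lengths(tbl$pattern)
  if (any(!lens %in% 2:3)) abort("Rule patterns must have length 2 or 3.")
  tbl$kind <- map_chr(tbl$pattern, rule_kind)
  structure(tbl, class = c("tag_rules", class(tibble())))
}

rule_kind <- function(pattern) {
  n <- length(pattern)
  if (n == 3 && pattern[2] == "verb") return("entity_verb_x")
  if (n == 3 && pattern[2] == "n") return("entity_noun_adj")
  if (n == 2 && pattern[2] == "adj") return("entity_adj")
  if (n == 2 && pattern[2] == "verb") return("entity_verb")
  abort(sprintf(
    "Unsupported rule pattern: (%s). Supported shapes: (*,verb,adj), (*,n,adj), (*,adj), (*,verb).",
    paste(pattern, collapse = ", ")
  ))
}

#' Read or write a rule file
#'
#' Rules are stored as TSV with columns `id`, `pattern` (space-separated
#' tags), `relation` (`$verb` or a literal) and optional `relation2` for the
#' second emission, or as JSON with the same fields.
#'
#' @param path Rule file (`.tsv` or `.json`).
#' @export
read_rules <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    raw <- jsonlite::fromJSON(path)
  } else {
    raw <- read.delim(path, sep = "\t", colClasses = "character", quote = "")
    raw$id <- as.integer(raw$id)
  }
  tbl <- tibble(
    id = as.integer(raw$id),
    pattern = strsplit(as.character(raw$pattern), " +"),
    relation = as.character(raw$relation),
    relation2 = if ("relation2" %in% names(raw)) {
      r2 <- as.character(raw$relation2)
      ifelse(is.na(r2) | r2 == "", NA_character_, r2)
    } else {
      NA_character_
    }
  )
  new_tag_rules(tbl)
}

#' @rdname read_rules
#' @param rules A `tag_rules` tibble.
#' @export
write_rules <- function(rules, path) {
  out <- data.frame(
    id = rules$id,
    pattern = vapply(rules$pattern, paste, character(1), collapse = " "),
    relation = rules$relation,
    relation2 = ifelse(is.na(rules$relation2), "", rules$relation2)
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# All tags mentioned by any rule pattern (plus "n", which may head or tail
# extended matches of rules 1 and 4).
rule_tags <- function(rules) {
  union(unique(unlist(rules$pattern)), "n")
}
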