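#' Relation-to-ontology mapping policy
#'
#' Controls how SKG relations become OWL constructs: `subclass` relations
#' (part-of style, default `"has"`) become `rdfs:subClassOf` axioms with the
#' tail as child class; `type` relations (attribute display, default `"show"`
#' and `"status"`) type the tail as a named individual of the head class;
#' every other relation becomes an object-property fact triple.
#'
#' @param subclass,type Character vectors of relation names.
#' @param base Base IRI prefix; identifiers are written as `<base><name>`.
#' @return An `ontology_mapping` list.
#' @export
ontology_mapping <- function(subclass = "has", type = c("show", "status"),
                             base = "#") {
  structure(list(subclass = subclass, type = type, base = base),
    class = "ontology_mapping"
  )
}

#' Convert an SKG into an ontology graph
#'
#' Every triple maps to exactly one ontology element (a subclass axiom, an
#' individual typing, or a fact), so element count equals triple count after
#' de-duplication. Identifiers are sanitized into IRI-safe form (spaces and
#' other unsafe characters become `_`); sanitized names are reported once via
#' a message. Placeholder heads must be resolved first (see
#' [complete_entity()]) or dropped explicitly.
#'
#' @param x An `skg` without placeholder heads.
#' @param mapping An [ontology_mapping()].
#' @param drop_placeholders Drop `"@"`-headed triples instead of erroring.
#' @return An `ontology_graph`: list with `classes`, `object_properties`
#'   (character), `subclass_axioms` (tibble `child`, `parent`), `individuals`
#'   (tibble `individual`, `class`), `facts` (tibble `subject`, `predicate`,
#'   `object`), and the `base` IRI.
#' @export
#' @examples
#' g <- to_ontology(skg("liver", "has", "portal vein"))
#' g$subclass_axioms
to_ontology <- function(x, mapping = ontology_mapping(), drop_placeholders = FALSE) {
  x <- validate_skg(x)
  if (any(x$placeholder)) {
    if (drop_placeholders) {
      x <- x[!x$placeholder, , drop = FALSE]
    } else {
      abort(paste(
        "SKG still contains placeholder heads;",
        "run complete_entity() first or set drop_placeholders = TRUE."
      ))
    }
  }
  dirty <- character()
  iri <- function(v) {
    out <- gsub("[^A-Za-z0-9_.-]+", "_", v)
    changed <- out != v
    dirty <<- union(dirty, v[changed])
    out
  }
  head_ <- iri(x$head)
  rel <- iri(x$relation)
  tail_ <- iri(x$tail)
  if (length(dirty)) {
    rlang::inform(sprintf(
      "Sanitized %d identifier(s) for IRI use: %s",
      length(dirty), paste(sQuote(dirty), collapse = ", ")
    ))
  }
  sub <- iri(mapping$subclass)
  typ <- iri(mapping$type)
  is_sub <- rel %in% sub
  is_typ <- rel %in% typ
  is_fact <- !is_sub & !is_typ
  subclass_axioms <- distinct(tibble(child = tail_[is_sub], parent = head_[is_sub]))
  individuals <- distinct(tibble(individual = tail_[is_typ], class = head_[is_typ]))
  facts <- distinct(tibble(
    subject = head_[is_fact], predicate = rel[is_fact], object = tail_[is_fact]
  ))
  classes <- sort(unique(c(
    subclass_axioms$child, subclass_axioms$parent, individuals$class
  )))
  check_subclass_acyclic(subclass_axioms)
  g <- structure(
    list(
      classes = classes,
      object_properties = sort(unique(facts$predicate)),
      subclass_axioms = arrange(subclass_axioms, .data$child, .data$parent),
      individuals = arrange(individuals, .data$individual, .data$class),
      facts = arrange(facts, .data$subject, .data$predicate, .data$object),
      base = mapping$base
    ),
    class = "ontology_graph"
  )
  g
}

check_subclass_acyclic <- function(axioms) {
  if (nrow(axioms) == 0) return(invisible(TRUE))
  g <- igraph::graph_from_data_frame(axioms[, c("child", "parent")], directed = TRUE)
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- which(comp$csize > 1)[1]
    path <- names(comp$membership)[comp$membership == bad]
    abort(sprintf(
      "Subclass ('has') chain is cyclic through: %s",
      paste(c(path, path[1]), collapse = " -> ")
    ), class = "sonokg_cycle_error")
  }
  invisible(TRUE)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat(sprintf(
    "<ontology_graph: %d classes, %d subclass axioms, %d individuals, %d facts>\n",
    length(x$classes), nrow(x$subclass_axioms), nrow(x$individuals), nrow(x$facts)
  ))
  invisible(x)
}

# number of elements derived from triples (conservation check)
ontology_size <- function(g) {
  nrow(g$subclass_axioms) + nrow(g$individuals) + nrow(g$facts)
}

#' Serialize an ontology graph
#'
#' Emits RDF/XML (default) or Turtle. Output ordering is canonical (sorted),
#' so serialize -> parse -> serialize is byte-stable.
#'
#' @param g An `ontology_graph`.
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return A single document string.
#' @export
serialize_ontology <- function(g, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  if (dialect == "rdfxml") serialize_rdfxml(g) else serialize_turtle(g)
}

RDF_NS <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS <- "http://www.w3.org/2002/07/owl#"

serialize_rdfxml <- function(g) {
  ref <- function(name) paste0(g$base, name)
  lines <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(
      "<rdf:RDF xmlns:rdf=\"%s\" xmlns:rdfs=\"%s\" xmlns:owl=\"%s\" xmlns:kg=\"%s\">",
      RDF_NS, RDFS_NS, OWL_NS, paste0(g$base, if (!endsWith(g$base, "#")) "#" else "")
    ),
    "  <owl:Ontology rdf:about=\"\"/>"
  )
  for (p in g$object_properties) {
    lines <- c(lines, sprintf("  <owl:ObjectProperty rdf:about=\"%s\"/>", ref(p)))
  }
  for (cl in g$classes) {
    parents <- g$subclass_axioms$parent[g$subclass_axioms$child == cl]
    if (length(parents) == 0) {
      lines <- c(lines, sprintf("  <owl:Class rdf:about=\"%s\"/>", ref(cl)))
    } else {
      lines <- c(
        lines,
        sprintf("  <owl:Class rdf:about=\"%s\">", ref(cl)),
        sprintf("    <rdfs:subClassOf rdf:resource=\"%s\"/>", ref(sort(parents))),
        "  </owl:Class>"
      )
    }
  }
  for (i in seq_len(nrow(g$individuals))) {
    lines <- c(
      lines,
      sprintf("  <owl:NamedIndividual rdf:about=\"%s\">", ref(g$individuals$individual[i])),
      sprintf("    <rdf:type rdf:resource=\"%s\"/>", ref(g$individuals$class[i])),
      "  </owl:NamedIndividual>"
    )
  }
  subjects <- unique(g$facts$subject)
  for (s in subjects) {
    rows <- g$facts[g$facts$subject == s, , drop = FALSE]
    lines <- c(
      lines,
      sprintf("  <rdf:Description rdf:about=\"%s\">", ref(s)),
      sprintf("    <kg:%s rdf:resource=\"%s\"/>", rows$predicate, ref(rows$object)),
      "  </rdf:Description>"
    )
  }
  paste(c(lines, "</rdf:RDF>", ""), collapse = "\n")
}

serialize_turtle <- function(g) {
  ref <- function(name) paste0(":", name)
  lines <- c(
    sprintf("@prefix rdf: <%s> .", RDF_NS),
    sprintf("@prefix rdfs: <%s> .", RDFS_NS),
    sprintf("@prefix owl: <%s> .", OWL_NS),
    sprintf("@prefix : <%s> .", g$base),
    "",
    "<> a owl:Ontology ."
  )
  for (p in g$object_properties) {
    lines <- c(lines, sprintf("%s a owl:ObjectProperty .", ref(p)))
  }
  for (cl in g$classes) {
    parents <- sort(g$subclass_axioms$parent[g$subclass_axioms$child == cl])
    decl <- sprintf("%s a owl:Class", ref(cl))
    if (length(parents)) {
      decl <- paste0(
        decl, " ;\n",
        paste(sprintf("    rdfs:subClassOf %s", ref(parents)), collapse = " ;\n")
      )
    }
    lines <- c(lines, paste0(decl, " ."))
  }
  for (i in seq_len(nrow(g$individuals))) {
    lines <- c(lines, sprintf(
      "%s a owl:NamedIndividual , %s .",
      ref(g$individuals$individual[i]), ref(g$individuals$class[i])
    ))
  }
  for (i in seq_len(nrow(g$facts))) {
    lines <- c(lines, sprintf(
      "%s %s %s .",
      ref(g$facts$subject[i]), ref(g$facts$predicate[i]), ref(g$facts$object[i])
    ))
  }
  paste(c(lines, ""), collapse = "\n")
}

#' Parse a serialized ontology back into a graph
#'
#' Supports the documents this package emits (RDF/XML via xml2; the Turtle
#' subset used by [serialize_ontology()]). Round trip contract:
#' `parse_ontology(serialize_ontology(g))` is isomorphic to `g`.
#'
#' @param text Document text (or a file path for RDF/XML).
#' @param dialect `"rdfxml"` or `"turtle"`.
#' @return An `ontology_graph`.
#' @export
parse_ontology <- function(text, dialect = c("rdfxml", "turtle")) {
  dialect <- match.arg(dialect)
  if (dialect == "rdfxml") parse_rdfxml(text) else parse_turtle(text)
}

parse_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS)
  strip <- function(v) sub("^#", "", v)
  base <- "#"
  about <- function(node) strip(xml2::xml_attr(node, "about"))
  res <- function(node) strip(xml2::xml_attr(node, "resource"))
  classes <- character()
  subclass <- list()
  cls_nodes <- xml2::xml_find_all(doc, ".//owl:Class", ns)
  for (nd in cls_nodes) {
    cl <- about(nd)
    classes <- c(classes, cl)
    for (p in xml2::xml_find_all(nd, "./rdfs:subClassOf", ns)) {
      subclass[[length(subclass) + 1L]] <- tibble(child = cl, parent = res(p))
    }
  }
  props <- vapply(
    xml2::xml_find_all(doc, ".//owl:ObjectProperty", ns), about, character(1)
  )
  indiv <- list()
  for (nd in xml2::xml_find_all(doc, ".//owl:NamedIndividual", ns)) {
    for (p in xml2::xml_find_all(nd, "./rdf:type", ns)) {
      indiv[[length(indiv) + 1L]] <- tibble(individual = about(nd), class = res(p))
    }
  }
  facts <- list()
  for (nd in xml2::xml_find_all(doc, ".//rdf:Description", ns)) {
    for (p in xml2::xml_children(nd)) {
      facts[[length(facts) + 1L]] <- tibble(
        subject = about(nd),
        predicate = xml2::xml_name(p),
        object = res(p)
      )
    }
  }
  empty_sub <- tibble(child = character(), parent = character())
  empty_ind <- tibble(individual = character(), class = character())
  empty_fact <- tibble(subject = character(), predicate = character(), object = character())
  structure(
    list(
      classes = sort(unique(classes)),
      object_properties = sort(unique(props)),
      subclass_axioms = arrange(bind_rows(empty_sub, subclass), .data$child, .data$parent),
      individuals = arrange(bind_rows(empty_ind, indiv), .data$individual, .data$class),
      facts = arrange(bind_rows(empty_fact, facts), .data$subject, .data$predicate, .data$object),
      base = base
    ),
    class = "ontology_graph"
  )
}

parse_turtle <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  base <- "#"
  m <- grep("^@prefix : <", lines, value = TRUE)
  if (length(m)) base <- sub("^@prefix : <([^>]*)> \\.$", "\\1", m[1])
  classes <- character()
  props <- character()
  subclass <- list()
  indiv <- list()
  facts <- list()
  strip <- function(v) sub("^:", "", v)
  stmts <- grep("^:", lines, value = TRUE)
  for (st in stmts) {
    st <- sub(" \\.$", "", st)
    if (grepl(" a owl:ObjectProperty$", st)) {
      props <- c(props, strip(sub(" a owl:ObjectProperty$", "", st)))
    } else if (grepl(" a owl:Class", st)) {
      subj <- strip(sub(" a owl:Class.*$", "", st))
      classes <- c(classes, subj)
    } else if (grepl(" a owl:NamedIndividual , ", st)) {
      parts <- strsplit(st, " a owl:NamedIndividual , ", fixed = TRUE)[[1]]
      indiv[[length(indiv) + 1L]] <- tibble(
        individual = strip(parts[1]), class = strip(parts[2])
      )
    } else {
      parts <- strsplit(st, " ", fixed = TRUE)[[1]]
      if (length(parts) == 3) {
        facts[[length(facts) + 1L]] <- tibble(
          subject = strip(parts[1]), predicate = strip(parts[2]), object = strip(parts[3])
        )
      }
    }
  }
  # subclass continuation lines attach to the preceding class statement
  cur <- NA_character_
  for (ln in lines) {
    if (grepl("^:.* a owl:Class", ln)) cur <- strip(sub(" a owl:Class.*$", "", ln))
    if (grepl("rdfs:subClassOf", ln) && !is.na(cur)) {
      parent <- strip(sub(".*rdfs:subClassOf (:[^ ;.]+).*", "\\1", ln))
      subclass[[length(subclass) + 1L]] <- tibble(child = cur, parent = parent)
    }
  }
  empty_sub <- tibble(child = character(), parent = character())
  empty_ind <- tibble(individual = character(), class = character())
  empty_fact <- tibble(subject = character(), predicate = character(), object = character())
  structure(
    list(
      classes = sort(unique(classes)),
      object_properties = sort(unique(props)),
      subclass_axioms = arrange(bind_rows(empty_sub, subclass), .data$child, .data$parent),
      individuals = arrange(bind_rows(empty_ind, indiv), .data$individual, .data$class),
      facts = arrange(bind_rows(empty_fact, facts), .data$subject, .data$predicate, .data$object),
      base = base
    ),
    class = "ontology_graph"
  )
}

#' Are two ontology graphs isomorphic?
#'
#' Component-wise set equality of classes, properties, axioms, typings and
#' facts (identifier-preserving isomorphism).
#'
#' @param a,b `ontology_graph` objects.
#' @export
ontology_isomorphic <- function(a, b) {
  same_set <- function(x, y) setequal(x, y)
  same_tbl <- function(x, y) {
    key <- function(df) sort(do.call(paste, c(as.list(df), sep = "\r")))
    identical(key(as.data.frame(x)), key(as.data.frame(y)))
  }
  same_set(a$classes, b$classes) &&
    same_set(a$object_properties, b$object_properties) &&
    same_tbl(a$subclass_axioms, b$subclass_axioms) &&
    same_tbl(a$individuals, b$individuals) &&
    same_tbl(a$facts, b$facts)
}

#' Export an SKG as a labeled graph for viewers
#'
#' Nodes are entities (sorted, deterministic order), edges carry the relation
#' as a label; duplicate triples collapse into a single edge with a
#' `multiplicity` attribute. Placeholder-headed triples are dropped (complete
#' them first to keep their facts).
#'
#' @param x An `skg`.
#' @param path Optional file; written as GraphML when supplied.
#' @return The igraph object, invisibly when `path` is given.
#' @export
export_graphml <- function(x, path = NULL) {
  x <- x[!x$placeholder, , drop = FALSE]
  agg <- count(as_tibble(x), .data$head, .data$relation, .data$tail, name = "multiplicity")
  agg <- arrange(agg, .data$head, .data$relation, .data$tail)
  nodes <- sort(unique(c(agg$head, agg$tail)))
  g <- igraph::graph_from_data_frame(
    d = data.frame(
      from = agg$head, to = agg$tail,
      label = agg$relation, multiplicity = agg$multiplicity
    ),
    vertices = data.frame(name = nodes),
    directed = TRUE
  )
  if (!is.null(path)) {
    igraph::write_graph(g, path, format = "graphml")
    return(invisible(g))
  }
  g
}
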