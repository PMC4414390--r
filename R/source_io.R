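## Readers/writers: source classification JSON, alignment TSV, Turtle dialect,
## fact sheets.

RBDO_NS <- "http://purl.org/skeletome/rbdo#"

ttl_prefixes <- function(namespace = RBDO_NS) c(
  rbdo = namespace,
  skos = "http://www.w3.org/2004/02/skos/core#",
  prov = "http://www.w3.org/ns/prov#",
  owl  = "http://www.w3.org/2002/07/owl#",
  rdf  = "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
  rdfs = "http://www.w3.org/2000/01/rdf-schema#",
  hp   = "http://purl.obolibrary.org/obo/HP_")

# SKOS/OWL property used for each internal predicate. BROADER_T(a, b) states
# that a is broader than b, so the emitted property on subject a is
# skos:narrowerTransitive ("a has narrower b"), matching W3C SKOS direction;
# NARROWER_T is the symmetric case.
predicate_property <- c(
  MEMBER               = "skos:member",
  BROADER_T            = "skos:narrowerTransitive",
  NARROWER_T           = "skos:broaderTransitive",
  ASSOCIATED_GENE      = "rbdo:associated_gene",
  ASSOCIATED_PHENOTYPE = "rbdo:associated_phenotype",
  MODE_OF_INHERITANCE  = "rbdo:mode_of_inheritance")

kind_marker <- c(GROUP = "BoneDisorderGroup", DISORDER = "BoneDisorder",
                 GENE = "Gene", PHENOTYPE = "Phenotype",
                 INHERITANCE_MODE = "ModeOfInheritance")

# extra rdf:type triples per kind; GROUP is a SKOS Collection, the concept
# kinds get OWL-2 punning (class + SKOS Concept instance) where they denote
# ontology classes
kind_types <- list(
  GROUP            = c("skos:Collection"),
  DISORDER         = c("owl:Class", "skos:Concept"),
  GENE             = c("owl:Class", "skos:Concept"),
  PHENOTYPE        = c("skos:Concept"),
  INHERITANCE_MODE = c("skos:Concept"))

reserved_rbdo_terms <- c("frequency", "associated_gene", "associated_phenotype",
                         "mode_of_inheritance", unname(kind_marker))

## term encoding --------------------------------------------------------------

token_safe <- function(x) grepl("^[A-Za-z0-9_][A-Za-z0-9_.-]*$", x) &
  !grepl("\\.$", x)

encode_id <- function(id, namespace = RBDO_NS) {
  if (grepl("^HP:[0-9]+$", id)) return(paste0("hp:", sub("^HP:", "", id)))
  if (token_safe(id)) return(paste0("rbdo:", id))
  paste0("<", namespace, utils::URLencode(id, reserved = TRUE), ">")
}

esc_lit <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  gsub("\t", "\\t", x, fixed = TRUE)
}

lit <- function(x) paste0("\"", esc_lit(x), "\"")

## write_turtle ---------------------------------------------------------------

#' Serialize a knowledge graph to RDF Turtle
#'
#' Emits the package's Turtle dialect: disorder/gene identifiers are punned
#' (typed both `owl:Class` and `skos:Concept` instance), groups are SKOS
#' Collections, every statement yields one plain triple in the SKOS/RBDO
#' vocabulary plus an `owl:Axiom` node carrying `owl:annotatedSource` /
#' `owl:annotatedProperty` / `owl:annotatedTarget` and one
#' `prov:wasAttributedTo` triple per asserting agent. Frequency qualifiers are
#' annotations (`rbdo:frequency`) on the phenotype-association axiom node, so
#' the plain triple is identical to the unqualified case. Output is
#' canonicalized — agents, then entities, then statements, each sorted
#' lexicographically — so equal graphs serialize to byte-identical text.
#'
#' @param graph A valid `kg` object.
#' @param file Optional path or connection; if `NULL` the text is returned.
#' @param namespace Base namespace for minted identifiers.
#' @return The Turtle text as a single string (invisibly when `file` given).
#' @export
write_turtle <- function(graph, file = NULL, namespace = RBDO_NS) {
  stop_if_invalid(graph)
  px <- ttl_prefixes(namespace)
  enc <- function(id) encode_id(id, namespace)
  lines <- sprintf("@prefix %s: <%s> .", names(px), unname(px))
  lines <- c(lines, "")
  onto <- paste0("<", sub("#$", "", namespace), ">")
  lines <- c(lines,
             paste(onto, "rdf:type owl:Ontology ."),
             paste(onto, "rdfs:label", lit(graph$graph_id), "."))

  for (a in sort(names(graph$agents))) {
    s <- enc(a)
    lines <- c(lines,
               paste(s, "rdf:type prov:Agent ."),
               paste(s, "rdfs:label", lit(graph$agents[[a]]), "."))
  }

  for (id in sort(names(graph$entities))) {
    e <- graph$entities[[id]]
    s <- enc(id)
    types <- c(kind_types[[e$kind]], paste0("rbdo:", kind_marker[[e$kind]]))
    lines <- c(lines, paste(s, "rdf:type", types, "."))
    lines <- c(lines, paste(s, "rdfs:label", lit(e$label), "."))
    for (al in sort(e$alt_labels))
      lines <- c(lines, paste(s, "skos:altLabel", lit(al), "."))
    for (ns in sort(names(e$xrefs))) {
      if (ns %in% reserved_rbdo_terms || !token_safe(ns))
        kg_error("BadEntity", sprintf("xref namespace '%s' clashes with the dialect", ns))
      for (val in sort(e$xrefs[[ns]]))
        lines <- c(lines, paste(s, paste0("rbdo:", ns), lit(val), "."))
    }
    for (ag in sort(e$attributed_to))
      lines <- c(lines, paste(s, "prov:wasAttributedTo", enc(ag), "."))
  }

  keys <- sort(names(graph$statements))
  plain_seen <- character()
  axn <- 0L
  for (k in keys) {
    st <- graph$statements[[k]]
    prop <- predicate_property[[st$predicate]]
    plain <- paste(enc(st$subject), prop, enc(st$object), ".")
    if (!plain %in% plain_seen) {
      lines <- c(lines, plain)
      plain_seen <- c(plain_seen, plain)
    }
    axn <- axn + 1L
    ax <- sprintf("_:ax%07d", axn)
    lines <- c(lines,
               paste(ax, "rdf:type owl:Axiom ."),
               paste(ax, "owl:annotatedSource", enc(st$subject), "."),
               paste(ax, "owl:annotatedProperty", prop, "."),
               paste(ax, "owl:annotatedTarget", enc(st$object), "."))
    if (st$qualifier != "UNSPECIFIED")
      lines <- c(lines, paste(ax, "rbdo:frequency", lit(st$qualifier), "."))
    for (ag in sort(st$attributed_to))
      lines <- c(lines, paste(ax, "prov:wasAttributedTo", enc(ag), "."))
  }

  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(text, file, sep = "")
    return(invisible(text))
  }
  text
}

## read_turtle ----------------------------------------------------------------

dialect_error <- function(subject, msg)
  kg_error("DialectError", sprintf("%s (subject: %s)", msg, subject))

# tokenize one N-triples-like line into its three terms
parse_triple_line <- function(line, lineno) {
  terms <- list()
  i <- 1L
  n <- nchar(line)
  while (i <= n && length(terms) < 3) {
    while (i <= n && substr(line, i, i) %in% c(" ", "\t")) i <- i + 1L
    if (i > n) break
    ch <- substr(line, i, i)
    if (ch == "<") {
      j <- regexpr(">", substr(line, i, n), fixed = TRUE)
      if (j < 0) kg_error("DialectError", sprintf("line %d: unterminated IRI", lineno))
      terms[[length(terms) + 1]] <- list(type = "iri_full",
                                         value = substr(line, i + 1, i + j - 2))
      i <- i + j
    } else if (ch == "\"") {
      j <- i + 1L
      buf <- character()
      repeat {
        if (j > n) kg_error("DialectError", sprintf("line %d: unterminated literal", lineno))
        cj <- substr(line, j, j)
        if (cj == "\\") {
          nxt <- substr(line, j + 1, j + 1)
          buf <- c(buf, switch(nxt, n = "\n", t = "\t", r = "\r",
                               "\"" = "\"", "\\" = "\\",
                               kg_error("DialectError",
                                        sprintf("line %d: bad escape \\%s", lineno, nxt))))
          j <- j + 2L
        } else if (cj == "\"") { j <- j + 1L; break } else {
          buf <- c(buf, cj); j <- j + 1L
        }
      }
      terms[[length(terms) + 1]] <- list(type = "lit", value = paste(buf, collapse = ""))
      i <- j
    } else {
      j <- i
      while (j <= n && !substr(line, j, j) %in% c(" ", "\t")) j <- j + 1L
      tok <- substr(line, i, j - 1)
      if (startsWith(tok, "_:")) {
        terms[[length(terms) + 1]] <- list(type = "bnode", value = tok)
      } else if (grepl("^[A-Za-z][A-Za-z0-9]*:", tok)) {
        terms[[length(terms) + 1]] <- list(type = "iri_pfx", value = tok)
      } else {
        kg_error("DialectError", sprintf("line %d: unrecognised term '%s'", lineno, tok))
      }
      i <- j
    }
  }
  rest <- trimws(substr(line, i, n))
  if (length(terms) != 3 || rest != ".")
    kg_error("DialectError", sprintf("line %d: expected 'S P O .'", lineno))
  terms
}

expand_term <- function(term, prefixes) {
  if (term$type == "iri_pfx") {
    p <- sub(":.*$", "", term$value)
    local <- sub("^[^:]*:", "", term$value)
    if (!p %in% names(prefixes))
      kg_error("DialectError", sprintf("undeclared prefix '%s:'", p))
    return(list(type = "iri", value = paste0(prefixes[[p]], local)))
  }
  if (term$type == "iri_full") return(list(type = "iri", value = term$value))
  term
}

# full IRI back to the model's id space
iri_to_id <- function(iri, prefixes) {
  hp <- prefixes[["hp"]]
  ns <- prefixes[["rbdo"]]
  if (startsWith(iri, hp)) return(paste0("HP:", substring(iri, nchar(hp) + 1)))
  if (startsWith(iri, ns)) return(utils::URLdecode(substring(iri, nchar(ns) + 1)))
  iri
}

#' Read a knowledge graph from the package's Turtle dialect
#'
#' Inverse of [write_turtle()]: `read_turtle(write_turtle(g))` reproduces `g`
#' exactly (same entities, statements, qualifiers, attribution sets and agent
#' registry). Triples outside the dialect, axiom nodes missing one of their
#' three annotated-triple links, or plain relation triples without a matching
#' axiom node raise a `DialectError` naming the offending subject.
#'
#' @param input Path to a `.ttl` file, or the Turtle text itself (any string
#'   containing a newline is treated as text).
#' @return A validated `kg` object.
#' @export
read_turtle <- function(input) {
  lines <- if (length(input) == 1 && !grepl("\n", input) && file.exists(input))
    readLines(input, warn = FALSE) else unlist(strsplit(paste(input, collapse = "\n"), "\n"))
  prefixes <- character()
  triples <- list()
  for (k in seq_along(lines)) {
    line <- trimws(lines[[k]])
    if (!nzchar(line) || startsWith(line, "#")) next
    if (startsWith(line, "@prefix")) {
      m <- regmatches(line, regexec("^@prefix\\s+([A-Za-z][A-Za-z0-9]*):\\s+<([^>]*)>\\s+\\.$", line))[[1]]
      if (length(m) != 3)
        kg_error("DialectError", sprintf("line %d: malformed @prefix", k))
      prefixes[[m[2]]] <- m[3]
      next
    }
    terms <- lapply(parse_triple_line(line, k), expand_term, prefixes = prefixes)
    triples[[length(triples) + 1]] <- terms
  }
  for (need in c("rbdo", "hp", "skos", "prov", "owl", "rdf", "rdfs"))
    if (!need %in% names(prefixes))
      kg_error("DialectError", sprintf("missing @prefix for '%s:'", need))

  x <- function(nm, local) paste0(prefixes[[nm]], local)
  RDF_TYPE <- x("rdf", "type")
  prop_iri <- vapply(predicate_property, function(p) {
    x(sub(":.*", "", p), sub("^[^:]*:", "", p))
  }, character(1))

  subj_of <- vapply(triples, function(t) t[[1]]$value, character(1))
  pred_of <- vapply(triples, function(t) {
    if (t[[2]]$type != "iri") kg_error("DialectError", "predicate must be an IRI")
    t[[2]]$value
  }, character(1))
  obj_type <- vapply(triples, function(t) t[[3]]$type, character(1))
  obj_of <- vapply(triples, function(t) t[[3]]$value, character(1))
  subj_type <- vapply(triples, function(t) t[[1]]$type, character(1))

  types_of <- function(s) obj_of[subj_of == s & pred_of == RDF_TYPE]
  lit_of <- function(s, p) obj_of[subj_of == s & pred_of == p & obj_type == "lit"]

  is_type <- pred_of == RDF_TYPE
  onto_subj <- unique(subj_of[is_type & obj_of == x("owl", "Ontology")])
  agent_subj <- unique(subj_of[is_type & obj_of == x("prov", "Agent")])
  axiom_subj <- unique(subj_of[is_type & obj_of == x("owl", "Axiom")])
  marker_iris <- vapply(kind_marker, function(m) x("rbdo", m), character(1))
  entity_subj <- unique(subj_of[is_type & obj_of %in% marker_iris])

  graph_id <- if (length(onto_subj)) {
    gl <- lit_of(onto_subj[1], x("rdfs", "label"))
    if (length(gl)) gl[1] else "kg"
  } else "kg"

  g <- kg_new(graph_id)
  for (a in sort(agent_subj)) {
    id <- iri_to_id(a, prefixes)
    lab <- lit_of(a, x("rdfs", "label"))
    g <- kg_add_agent(g, id, if (length(lab)) lab[1] else id)
  }

  for (s in sort(entity_subj)) {
    id <- iri_to_id(s, prefixes)
    tys <- types_of(s)
    kinds <- names(marker_iris)[marker_iris %in% tys]
    if (length(kinds) != 1) dialect_error(s, "entity must carry exactly one kind marker")
    labels <- lit_of(s, x("rdfs", "label"))
    if (!length(labels)) dialect_error(s, "entity lacks rdfs:label")
    alt <- lit_of(s, x("skos", "altLabel"))
    attr_iri <- obj_of[subj_of == s & pred_of == x("prov", "wasAttributedTo")]
    xr <- list()
    sel <- which(subj_of == s & obj_type == "lit" &
                   startsWith(pred_of, prefixes[["rbdo"]]))
    for (i in sel) {
      ns <- substring(pred_of[i], nchar(prefixes[["rbdo"]]) + 1)
      if (ns %in% c("frequency")) dialect_error(s, "rbdo:frequency on an entity")
      xr[[ns]] <- c(xr[[ns]], obj_of[i])
    }
    g <- kg_add_entity(g, entity_record(
      id, kinds, labels[1], alt_labels = alt, xrefs = xr,
      attributed_to = vapply(attr_iri, iri_to_id, character(1), prefixes = prefixes)))
  }

  # statements from axiom nodes
  stmts <- list()
  for (ax in axiom_subj) {
    one <- function(p, what) {
      v <- obj_of[subj_of == ax & pred_of == x("owl", p) & obj_type == "iri"]
      if (length(v) != 1) dialect_error(ax, sprintf("axiom node missing %s", what))
      v
    }
    src <- one("annotatedSource", "owl:annotatedSource")
    prp <- one("annotatedProperty", "owl:annotatedProperty")
    tgt <- one("annotatedTarget", "owl:annotatedTarget")
    if (!prp %in% prop_iri) dialect_error(ax, sprintf("unknown annotatedProperty <%s>", prp))
    pred <- names(prop_iri)[prop_iri == prp]
    q <- lit_of(ax, x("rbdo", "frequency"))
    attr_iri <- obj_of[subj_of == ax & pred_of == x("prov", "wasAttributedTo")]
    if (!length(attr_iri)) dialect_error(ax, "axiom node lacks attribution")
    stmts[[length(stmts) + 1]] <- statement(
      iri_to_id(src, prefixes), pred, iri_to_id(tgt, prefixes),
      qualifier = if (length(q)) q[1] else NULL,
      attributed_to = vapply(attr_iri, iri_to_id, character(1), prefixes = prefixes))
  }
  for (st in stmts) g <- kg_add_statement(g, st)

  # dialect conformance checks: plain relation triples must pair with axioms,
  # and every non-blank subject triple must be accounted for
  known_plain <- vapply(stmts, function(s)
    paste(s$subject, s$predicate, s$object, sep = ""), character(1))
  for (i in seq_along(triples)) {
    if (subj_type[i] == "bnode") {
      if (!subj_of[i] %in% axiom_subj)
        dialect_error(subj_of[i], "blank node is not an owl:Axiom")
      next
    }
    s <- subj_of[i]; p <- pred_of[i]
    if (s %in% onto_subj || p == x("prov", "wasAttributedTo")) next
    if (p == RDF_TYPE) {
      ok_types <- c(x("owl", "Ontology"), x("prov", "Agent"), x("owl", "Axiom"),
                    x("owl", "Class"), x("skos", "Concept"), x("skos", "Collection"),
                    marker_iris)
      if (!obj_of[i] %in% ok_types) dialect_error(s, "unknown rdf:type")
      next
    }
    if (p %in% c(x("rdfs", "label"), x("skos", "altLabel"))) next
    if (obj_type[i] == "lit" && startsWith(p, prefixes[["rbdo"]]) &&
        s %in% entity_subj) next
    if (p %in% prop_iri) {
      pred <- names(prop_iri)[prop_iri == p]
      key <- paste(iri_to_id(s, prefixes), pred, iri_to_id(obj_of[i], prefixes),
                   sep = "")
      if (!key %in% known_plain)
        dialect_error(s, "relation triple has no annotating axiom node")
      next
    }
    dialect_error(s, sprintf("triple with predicate <%s> not in the dialect", p))
  }

  stop_if_invalid(g)
  g
}

## Source documents (JSON) ----------------------------------------------------

#' Read a source classification document
#'
#' Parses the JSON dialect for one source's classification:
#' `{"source": {"id", "label", "version"}, "entities": [...], "statements":
#' [...]}`. Each entity has `id`, `kind`, `label` and optional `alt_labels`,
#' `xrefs`, `attributed_to`; each statement has `subject`, `predicate`,
#' `object` and optional `qualifier`, `attributed_to`. Predicate and
#' qualifier tokens are accepted case-insensitively. An omitted
#' `attributed_to` defaults to the document's source agent (a record may
#' override it, e.g. OMIM-derived phenotype associations inside an ISDS/BDO
#' document).
#'
#' @param input Path to a `.json` file or the JSON text itself.
#' @param config Optional list with `agent_labels` (named) and
#'   `frequency_synonyms` (named map of source tokens to
#'   [FREQUENCY_QUALIFIERS]).
#' @return A `source_document` object.
#' @export
read_source <- function(input, config = NULL) {
  txt <- if (length(input) == 1 && !grepl("[{\n]", input) && file.exists(input))
    paste(readLines(input, warn = FALSE), collapse = "\n") else paste(input, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e) kg_error("SchemaError",
                                               paste("$: not valid JSON:", conditionMessage(e))))
  need <- function(obj, field, path) {
    if (is.null(obj[[field]]))
      kg_error("SchemaError", sprintf("%s.%s: required field missing", path, field))
    obj[[field]]
  }
  src <- need(doc, "source", "$")
  agent <- as.character(need(src, "id", "$.source"))
  label <- if (!is.null(src$label)) as.character(src$label) else agent
  version <- if (!is.null(src$version)) as.character(src$version) else ""
  name <- if (!is.null(src$name)) as.character(src$name) else label
  syn <- toupper(unlist(config$frequency_synonyms %||% list()))

  entities <- lapply(seq_along(doc$entities %||% list()), function(i) {
    e <- doc$entities[[i]]
    path <- sprintf("$.entities[%d]", i - 1)
    rec <- tryCatch(
      entity_record(
        id = as.character(need(e, "id", path)),
        kind = as.character(need(e, "kind", path)),
        label = if (!is.null(e$label)) as.character(e$label) else as.character(e$id),
        alt_labels = as.character(unlist(e$alt_labels %||% list())),
        xrefs = lapply(e$xrefs %||% list(), function(v) as.character(unlist(v))),
        attributed_to = if (length(e$attributed_to))
          as.character(unlist(e$attributed_to)) else agent),
      skosmerge_error = function(c) {
        kg_error(class(c)[1], sprintf("%s: %s", path, conditionMessage(c)))
      })
    rec
  })
  ids <- vapply(entities, `[[`, character(1), "id")
  statements <- lapply(seq_along(doc$statements %||% list()), function(i) {
    s <- doc$statements[[i]]
    path <- sprintf("$.statements[%d]", i - 1)
    q <- s$qualifier
    if (!is.null(q) && length(syn) && toupper(q) %in% names(syn))
      q <- syn[[toupper(q)]]
    tryCatch(
      statement(
        subject = as.character(need(s, "subject", path)),
        predicate = as.character(need(s, "predicate", path)),
        object = as.character(need(s, "object", path)),
        qualifier = if (!is.null(q)) as.character(q) else NULL,
        attributed_to = if (length(s$attributed_to))
          as.character(unlist(s$attributed_to)) else agent),
      skosmerge_error = function(c) {
        kg_error(class(c)[1], sprintf("%s: %s", path, conditionMessage(c)))
      })
  })
  for (i in seq_along(statements)) {
    s <- statements[[i]]
    for (end in c("subject", "object"))
      if (!s[[end]] %in% ids)
        kg_error("DanglingEndpoint",
                 sprintf("$.statements[%d]: %s '%s' not declared in entities",
                         i - 1, end, s[[end]]))
  }

  agent_labels <- lapply(doc$agents %||% list(), function(v) as.character(v)[1])
  for (a in names(config$agent_labels %||% list()))
    agent_labels[[a]] <- config$agent_labels[[a]]
  out <- structure(
    list(source_agent = agent, source_label = label, name = name,
         version = version, entities = entities, statements = statements,
         agent_labels = agent_labels),
    class = "source_document")
  # document-level structural validation (incl. sub-typing cycles)
  tryCatch(source_to_graph(out),
           CycleIntroduced = function(c) kg_error("CycleDetected", conditionMessage(c)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build the per-source knowledge graph of a document
#'
#' Registers the source agent plus any agents named in per-record attribution
#' overrides, then replays all entities and statements through
#' [kg_add_entity()]/[kg_add_statement()] (materialising sub-typing inverses).
#'
#' @param doc A `source_document`.
#' @return A validated `kg` object whose `graph_id` is the source agent id.
#' @export
source_to_graph <- function(doc) {
  stopifnot(inherits(doc, "source_document"))
  used <- unique(c(doc$source_agent,
                   unlist(lapply(doc$entities, `[[`, "attributed_to")),
                   unlist(lapply(doc$statements, `[[`, "attributed_to"))))
  g <- kg_new(doc$source_agent)
  for (a in sort(used)) {
    lab <- if (a == doc$source_agent) doc$source_label
    else doc$agent_labels[[a]] %||% a
    g <- kg_add_agent(g, a, lab)
  }
  for (e in doc$entities) g <- kg_add_entity(g, e)
  for (s in doc$statements) g <- kg_add_statement(g, s)
  stop_if_invalid(g)
  g
}

#' Serialize a source document to its JSON dialect
#'
#' @param doc A `source_document`.
#' @param file Optional output path.
#' @return JSON text (invisibly when `file` given).
#' @export
write_source <- function(doc, file = NULL) {
  stopifnot(inherits(doc, "source_document"))
  ent <- lapply(doc$entities, function(e) {
    out <- list(id = e$id, kind = e$kind, label = e$label)
    if (length(e$alt_labels)) out$alt_labels <- as.list(e$alt_labels)
    if (length(e$xrefs)) out$xrefs <- lapply(e$xrefs, as.list)
    if (!identical(e$attributed_to, doc$source_agent))
      out$attributed_to <- as.list(e$attributed_to)
    out
  })
  stm <- lapply(doc$statements, function(s) {
    out <- list(subject = s$subject, predicate = s$predicate, object = s$object)
    if (s$qualifier != "UNSPECIFIED") out$qualifier <- s$qualifier
    if (!identical(s$attributed_to, doc$source_agent))
      out$attributed_to <- as.list(s$attributed_to)
    out
  })
  obj <- list(source = list(id = doc$source_agent, label = doc$source_label,
                            name = doc$name, version = doc$version),
              entities = ent, statements = stm)
  if (length(doc$agent_labels)) obj$agents <- doc$agent_labels
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(file)) { writeLines(txt, file); return(invisible(txt)) }
  txt
}

#' @export
print.source_document <- function(x, ...) {
  cat(sprintf("<source_document '%s' (%s): %d entities, %d statements>\n",
              x$source_agent, x$version, length(x$entities), length(x$statements)))
  invisible(x)
}

## Alignment tables (TSV) -----------------------------------------------------

alignment_header <- c("left_source", "left_id", "right_source", "right_id",
                      "decision", "note")

#' Read an expert alignment table
#'
#' Tab-separated, UTF-8, no quoting; lines starting with `#` are comments.
#' The fixed header is `left_source left_id right_source right_id decision
#' note` and `decision` is one of `GROUP`, `DISORDER` (an explicit expert
#' verdict on the merged node's kind) or `AUTO` (defer to declared kinds and
#' the advisory heuristic, see [resolve_kind()]). Duplicate identical rows
#' are collapsed; an id mapped to two different counterparts in the same
#' other source is rejected (alignment must be functional per source pair).
#'
#' @param input Path to a `.tsv` file or the TSV text itself.
#' @return An `alignment_table` (a data frame of the six columns).
#' @export
read_alignment <- function(input) {
  lines <- if (length(input) == 1 && !grepl("[\t\n]", input) && file.exists(input))
    readLines(input, warn = FALSE) else unlist(strsplit(paste(input, collapse = "\n"), "\n"))
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  if (!length(lines)) kg_error("HeaderMismatch", "empty alignment file")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, alignment_header))
    kg_error("HeaderMismatch",
             sprintf("expected header '%s', got '%s'",
                     paste(alignment_header, collapse = "\\t"),
                     paste(hdr, collapse = "\\t")))
  rows <- lapply(lines[-1], function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    length(f) <- 6L
    f[is.na(f)] <- ""
    f
  })
  tab <- if (length(rows)) {
    m <- do.call(rbind, rows)
    data.frame(left_source = m[, 1], left_id = m[, 2], right_source = m[, 3],
               right_id = m[, 4], decision = toupper(m[, 5]), note = m[, 6],
               stringsAsFactors = FALSE)
  } else {
    data.frame(left_source = character(), left_id = character(),
               right_source = character(), right_id = character(),
               decision = character(), note = character(), stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(tab$decision), c("GROUP", "DISORDER", "AUTO"))
  if (length(bad))
    kg_error("UnknownDecision", sprintf("unknown decision token(s): %s",
                                        paste(bad, collapse = ", ")))
  tab <- unique(tab)
  check_functional_alignment(tab)
  rownames(tab) <- NULL
  class(tab) <- c("alignment_table", "data.frame")
  tab
}

check_functional_alignment <- function(tab) {
  for (dir in list(c("left_source", "left_id", "right_source", "right_id"),
                   c("right_source", "right_id", "left_source", "left_id"))) {
    key <- paste(tab[[dir[1]]], tab[[dir[2]]], tab[[dir[3]]], sep = "\t")
    split_to <- split(tab[[dir[4]]], key)
    clash <- names(split_to)[vapply(split_to, function(v) length(unique(v)) > 1, logical(1))]
    if (length(clash))
      kg_error("NonFunctionalAlignment",
               sprintf("id(s) aligned to multiple counterparts in one source: %s",
                       paste(gsub("\t", "/", clash), collapse = "; ")))
  }
  invisible(tab)
}

#' Write an alignment table as TSV
#'
#' @param table An `alignment_table`.
#' @param file Optional output path.
#' @return The TSV text (invisibly when `file` given).
#' @export
write_alignment <- function(table, file = NULL) {
  lines <- c(paste(alignment_header, collapse = "\t"),
             if (nrow(table)) apply(table[, alignment_header, drop = FALSE], 1,
                                    paste, collapse = "\t"))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) { writeLines(txt, file, sep = ""); return(invisible(txt)) }
  txt
}

## Fact sheets ----------------------------------------------------------------

#' Tally a fact sheet for a knowledge graph
#'
#' Counts disorders, disorder groups, genes and inheritance modes (the class
#' total is their sum), plus the number of distinct phenotype identifiers
#' reused as objects of phenotype associations, the registered provenance
#' agents, the relationship vocabulary and the namespace.
#'
#' @param graph A valid `kg` object.
#' @param namespace Namespace string reported on the sheet.
#' @return A `fact_sheet` object.
#' @export
fact_sheet <- function(graph, namespace = RBDO_NS) {
  stop_if_invalid(graph)
  kinds <- vapply(graph$entities, `[[`, character(1), "kind")
  n <- function(k) sum(kinds == k)
  pheno_used <- unique(vapply(
    Filter(function(s) s$predicate == "ASSOCIATED_PHENOTYPE", graph$statements),
    `[[`, character(1), "object"))
  counts <- list(disorders = n("DISORDER"), disorder_groups = n("GROUP"),
                 genes = n("GENE"), inheritance_modes = n("INHERITANCE_MODE"),
                 total_classes = n("DISORDER") + n("GROUP") + n("GENE") +
                   n("INHERITANCE_MODE"),
                 phenotypes_reused = length(pheno_used))
  structure(list(counts = counts,
                 agents = sort(names(graph$agents)),
                 relationships = c("associated_gene", "associated_phenotype",
                                   "mode_of_inheritance"),
                 namespace = namespace),
            class = "fact_sheet")
}

#' @export
print.fact_sheet <- function(x, ...) {
  cat("Fact sheet\n")
  cat(sprintf("  %-22s %s\n", "Namespace", x$namespace))
  cat(sprintf("  %-22s %s\n", "Provenance agents", paste(x$agents, collapse = ", ")))
  cat(sprintf("  %-22s %s\n", "Relationships", paste(x$relationships, collapse = ", ")))
  for (nm in names(x$counts))
    cat(sprintf("  %-22s %d\n", gsub("_", " ", nm), x$counts[[nm]]))
  invisible(x)
}

#' @export
format.fact_sheet <- function(x, ...) {
  paste(utils::capture.output(print(x)), collapse = "\n")
}
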