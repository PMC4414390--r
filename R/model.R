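#' @keywords internal
"_PACKAGE"

## Closed vocabularies of the model ------------------------------------------

#' Entity kinds recognised by the knowledge graph
#'
#' `GROUP` nodes carry SKOS Collection semantics (disorder groups); all other
#' kinds are SKOS Concepts (disorders, genes, HPO phenotypes, HPO modes of
#' inheritance).
#'
#' @format Character vector of the five kind tokens.
#' @export
ENTITY_KINDS <- c("GROUP", "DISORDER", "GENE", "PHENOTYPE", "INHERITANCE_MODE")

#' Statement predicates
#'
#' The six relations of the model. `MEMBER` is SKOS group membership
#' (Collection to member). `BROADER_T(a, b)` asserts that disorder `a` is
#' conceptually broader than disorder `b` (its sub-type); `NARROWER_T` is its
#' materialised inverse. The remaining predicates attach genes, phenotypes and
#' modes of inheritance to disorders.
#'
#' @format Character vector of the six predicate tokens.
#' @export
PREDICATES <- c("MEMBER", "BROADER_T", "NARROWER_T",
                "ASSOCIATED_GENE", "ASSOCIATED_PHENOTYPE", "MODE_OF_INHERITANCE")

#' Frequency qualifiers on disorder-phenotype associations
#'
#' Orphanet-style degree-of-occurrence vocabulary; an absent qualifier is
#' normalised to `UNSPECIFIED`. Only `ASSOCIATED_PHENOTYPE` statements may
#' carry a qualifier other than `UNSPECIFIED`.
#'
#' @format Character vector of the six qualifier tokens.
#' @export
FREQUENCY_QUALIFIERS <- c("OBLIGATE", "VERY_FREQUENT", "FREQUENT",
                          "OCCASIONAL", "VERY_RARE", "UNSPECIFIED")

# subject / object kind constraints per predicate
predicate_constraints <- list(
  MEMBER               = list(subject = "GROUP",    object = c("GROUP", "DISORDER")),
  BROADER_T            = list(subject = "DISORDER", object = "DISORDER"),
  NARROWER_T           = list(subject = "DISORDER", object = "DISORDER"),
  ASSOCIATED_GENE      = list(subject = "DISORDER", object = "GENE"),
  ASSOCIATED_PHENOTYPE = list(subject = "DISORDER", object = "PHENOTYPE"),
  MODE_OF_INHERITANCE  = list(subject = "DISORDER", object = "INHERITANCE_MODE")
)

## Conditions -----------------------------------------------------------------

kg_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(class, "skosmerge_error")))
}

## Constructors ---------------------------------------------------------------

#' Create an empty knowledge graph
#'
#' A knowledge graph holds an agent registry (the provenance agents such as
#' ISDS, OMIM, Orphanet that statements can be attributed to), a map of
#' entities and a set of provenance-annotated statements.
#'
#' @param graph_id Identifier string for the graph.
#' @param agents Named character vector `c(id = label, ...)` of provenance
#'   agents to pre-register; may be empty.
#' @return An object of class `kg`.
#' @seealso [kg_add_agent()], [kg_add_entity()], [kg_add_statement()]
#' @export
kg_new <- function(graph_id = "kg", agents = character()) {
  if (length(agents) && (is.null(names(agents)) || any(!nzchar(names(agents)))))
    kg_error("BadAgent", "agents must be a named character vector (id = label)")
  g <- structure(
    list(graph_id = as.character(graph_id)[1],
         agents = character(),
         entities = list(),
         statements = list(),
         edge_index = empty_edge_index()),
    class = "kg")
  for (id in names(agents)) g <- kg_add_agent(g, id, agents[[id]])
  g
}

#' Register a provenance agent
#'
#' @param graph A `kg` object.
#' @param id Short case-sensitive agent token (e.g. `"ISDS"`).
#' @param label Display label; defaults to the id.
#' @return The updated graph. Re-registering an agent updates its label.
#' @export
kg_add_agent <- function(graph, id, label = id) {
  stopifnot(inherits(graph, "kg"))
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    kg_error("BadAgent", "agent id must be a non-empty string")
  graph$agents[[id]] <- as.character(label)[1]
  graph
}

#' Construct an entity record
#'
#' @param id Canonical identifier token (CURIE-like, e.g. `"BD0000189"` or
#'   `"HP:0002857"`).
#' @param kind One of [ENTITY_KINDS].
#' @param label Preferred label.
#' @param alt_labels Character vector of alternative labels.
#' @param xrefs Named list of external identifiers, namespace to one or more
#'   values (e.g. `list(omim_id = "100800")`).
#' @param attributed_to Non-empty character vector of agent ids.
#' @return A list of class `kg_entity`.
#' @export
entity_record <- function(id, kind, label = id, alt_labels = character(),
                          xrefs = list(), attributed_to) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id))
    kg_error("BadEntity", "entity id must be a non-empty string")
  kind <- match_token(kind, ENTITY_KINDS, "entity kind")
  if (missing(attributed_to) || length(attributed_to) == 0)
    kg_error("EmptyAttribution", sprintf("entity '%s' has an empty attribution set", id))
  if (length(xrefs)) {
    if (is.null(names(xrefs)) || any(!nzchar(names(xrefs))))
      kg_error("BadEntity", sprintf("xrefs of '%s' must be a named list", id))
    bad <- vapply(xrefs, function(v) length(v) == 0 || any(!nzchar(v)), logical(1))
    if (any(bad))
      kg_error("BadEntity", sprintf("xref '%s' of '%s' has an empty value",
                                    names(xrefs)[bad][1], id))
  }
  structure(list(id = id, kind = kind, label = as.character(label)[1],
                 alt_labels = sort(unique(as.character(alt_labels))),
                 xrefs = if (length(xrefs)) xrefs[order(names(xrefs))]
                 else stats::setNames(list(), character()),
                 attributed_to = sort(unique(as.character(attributed_to)))),
            class = "kg_entity")
}

#' Construct a statement
#'
#' A statement is one provenance-annotated edge. Its identity is the tuple
#' (subject, predicate, object, qualifier): re-adding an identical statement
#' merges attribution sets, while the same disorder-phenotype pair under two
#' different frequency qualifiers is two distinct statements (each source's
#' assertion is preserved verbatim).
#'
#' @param subject,object Entity ids.
#' @param predicate One of [PREDICATES].
#' @param qualifier One of [FREQUENCY_QUALIFIERS]; `NULL` means `UNSPECIFIED`.
#' @param attributed_to Non-empty character vector of agent ids.
#' @return A list of class `kg_statement`.
#' @export
statement <- function(subject, predicate, object, qualifier = NULL, attributed_to) {
  predicate <- match_token(predicate, PREDICATES, "predicate")
  if (is.null(qualifier) || !length(qualifier)) qualifier <- "UNSPECIFIED"
  qualifier <- match_token(qualifier, FREQUENCY_QUALIFIERS, "frequency qualifier")
  if (missing(attributed_to) || length(attributed_to) == 0)
    kg_error("EmptyAttribution",
             sprintf("statement (%s %s %s) has an empty attribution set",
                     subject, predicate, object))
  structure(list(subject = as.character(subject)[1],
                 predicate = predicate,
                 object = as.character(object)[1],
                 qualifier = qualifier,
                 attributed_to = sort(unique(as.character(attributed_to)))),
            class = "kg_statement")
}

match_token <- function(x, vocabulary, what) {
  x <- toupper(as.character(x)[1])
  if (!x %in% vocabulary)
    kg_error("UnknownToken",
             sprintf("unknown %s '%s' (expected one of: %s)",
                     what, x, paste(vocabulary, collapse = ", ")))
  x
}

stmt_key <- function(s) paste(s$subject, s$predicate, s$object, s$qualifier, sep = "")

inverse_predicate <- c(BROADER_T = "NARROWER_T", NARROWER_T = "BROADER_T")

invert_statement <- function(s) {
  statement(s$object, inverse_predicate[[s$predicate]], s$subject,
            s$qualifier, s$attributed_to)
}

## Mutators -------------------------------------------------------------------

check_agents_registered <- function(graph, agents, context) {
  unknown <- setdiff(agents, names(graph$agents))
  if (length(unknown))
    kg_error("UnknownAgent",
             sprintf("%s attributed to unregistered agent(s): %s",
                     context, paste(unknown, collapse = ", ")))
}

#' Add (or merge) an entity
#'
#' Adding an id that already exists with the same kind unions labels (the new
#' preferred label becomes an alternative label if it differs), alternative
#' labels, xref values and attribution sets; attribution is therefore
#' monotone. Adding an id bound to a different kind is an error.
#'
#' @param graph A `kg` object.
#' @param record A [entity_record()].
#' @return The updated graph.
#' @export
kg_add_entity <- function(graph, record) {
  stopifnot(inherits(graph, "kg"), inherits(record, "kg_entity"))
  check_agents_registered(graph, record$attributed_to,
                          sprintf("entity '%s'", record$id))
  existing <- graph$entities[[record$id]]
  if (is.null(existing)) {
    graph$entities[[record$id]] <- record
    return(graph)
  }
  if (existing$kind != record$kind)
    kg_error("KindClash",
             sprintf("entity '%s' already present with kind %s (got %s)",
                     record$id, existing$kind, record$kind))
  merged <- existing
  extra <- setdiff(c(record$label, record$alt_labels), existing$label)
  merged$alt_labels <- sort(unique(c(existing$alt_labels, extra)))
  for (ns in names(record$xrefs))
    merged$xrefs[[ns]] <- sort(unique(c(merged$xrefs[[ns]], record$xrefs[[ns]])))
  merged$xrefs <- merged$xrefs[order(names(merged$xrefs))]
  merged$attributed_to <- sort(unique(c(existing$attributed_to, record$attributed_to)))
  graph$entities[[record$id]] <- merged
  graph
}

empty_edge_index <- function()
  list(MEMBER = matrix(character(), ncol = 2),
       BROADER_T = matrix(character(), ncol = 2), n = 0L)

# directed edges of one predicate as a 2-column matrix of ids; the MEMBER and
# BROADER_T relations are kept in an incremental index (hot path for cycle
# checks during bulk insertion) that falls back to a full scan whenever the
# statement set was modified without going through kg_add_statement
predicate_edges <- function(graph, predicate) {
  idx <- graph$edge_index
  if (predicate %in% c("MEMBER", "BROADER_T") && !is.null(idx) &&
      identical(idx$n, length(graph$statements)))
    return(idx[[predicate]])
  keep <- vapply(graph$statements, function(s) s$predicate == predicate, logical(1))
  if (!any(keep)) return(matrix(character(), ncol = 2))
  cbind(vapply(graph$statements[keep], `[[`, character(1), "subject"),
        vapply(graph$statements[keep], `[[`, character(1), "object"))
}

# would adding edge from -> to close a directed cycle in `edges` (+ that edge)?
edge_closes_cycle <- function(edges, from, to) {
  if (from == to) return(TRUE)
  if (nrow(edges) == 0) return(FALSE)
  # cycle iff `from` is reachable from `to`
  ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (!to %in% igraph::V(ig)$name || !from %in% igraph::V(ig)$name) return(FALSE)
  from %in% igraph::V(ig)$name[igraph::subcomponent(ig, to, mode = "out")]
}

#' Add (or merge) a statement
#'
#' Endpoints must exist and satisfy the predicate's kind constraints. Adding a
#' `BROADER_T` statement materialises the inverse `NARROWER_T` statement with
#' identical attribution (and symmetrically), so serialized graphs carry both
#' SKOS properties explicitly. A sub-typing or membership edge that would
#' close a directed cycle is rejected: transitivity over a cycle would make
#' every member broader than itself.
#'
#' @param graph A `kg` object.
#' @param stmt A [statement()].
#' @return The updated graph.
#' @export
kg_add_statement <- function(graph, stmt) {
  stopifnot(inherits(graph, "kg"), inherits(stmt, "kg_statement"))
  check_agents_registered(graph, stmt$attributed_to,
                          sprintf("statement (%s %s %s)",
                                  stmt$subject, stmt$predicate, stmt$object))
  for (end in c("subject", "object"))
    if (is.null(graph$entities[[stmt[[end]]]]))
      kg_error("DanglingEndpoint",
               sprintf("statement %s '%s' is not an entity of the graph",
                       end, stmt[[end]]))
  cons <- predicate_constraints[[stmt$predicate]]
  skind <- graph$entities[[stmt$subject]]$kind
  okind <- graph$entities[[stmt$object]]$kind
  if (!skind %in% cons$subject || !okind %in% cons$object)
    kg_error("KindConstraint",
             sprintf("%s requires %s -> %s, got %s -> %s",
                     stmt$predicate, paste(cons$subject, collapse = "|"),
                     paste(cons$object, collapse = "|"), skind, okind))
  if (stmt$qualifier != "UNSPECIFIED" && stmt$predicate != "ASSOCIATED_PHENOTYPE")
    kg_error("KindConstraint",
             sprintf("frequency qualifier %s is only valid on ASSOCIATED_PHENOTYPE",
                     stmt$qualifier))

  # cycle guards on the hierarchical relations (checked on the broader->narrower
  # orientation so BROADER_T and NARROWER_T share one edge set)
  if (stmt$predicate %in% c("BROADER_T", "NARROWER_T")) {
    b <- if (stmt$predicate == "BROADER_T") stmt$subject else stmt$object
    n <- if (stmt$predicate == "BROADER_T") stmt$object else stmt$subject
    if (edge_closes_cycle(predicate_edges(graph, "BROADER_T"), b, n))
      kg_error("CycleIntroduced",
               sprintf("sub-typing edge %s -> %s closes a cycle", b, n))
  } else if (stmt$predicate == "MEMBER") {
    if (edge_closes_cycle(predicate_edges(graph, "MEMBER"), stmt$subject, stmt$object))
      kg_error("CycleIntroduced",
               sprintf("membership edge %s -> %s closes a cycle",
                       stmt$subject, stmt$object))
  }

  graph <- upsert_statement(graph, stmt)
  if (stmt$predicate %in% names(inverse_predicate))
    graph <- upsert_statement(graph, invert_statement(stmt))
  graph
}

upsert_statement <- function(graph, stmt) {
  key <- stmt_key(stmt)
  existing <- graph$statements[[key]]
  if (!is.null(existing))
    stmt$attributed_to <- sort(unique(c(existing$attributed_to, stmt$attributed_to)))
  index_live <- !is.null(graph$edge_index) &&
    identical(graph$edge_index$n, length(graph$statements))
  graph$statements[[key]] <- stmt
  if (index_live) {
    if (is.null(existing) && stmt$predicate %in% c("MEMBER", "BROADER_T"))
      graph$edge_index[[stmt$predicate]] <-
        rbind(graph$edge_index[[stmt$predicate]], c(stmt$subject, stmt$object))
    graph$edge_index$n <- length(graph$statements)
  }
  graph
}

## Queries on the model -------------------------------------------------------

#' Transitive closure of the sub-typing relation
#'
#' Returns every ordered pair `(broader, narrower)` of disorder ids such that
#' the narrower disorder is reachable from the broader one over asserted
#' `BROADER_T` edges (e.g. Polydactyly is broader than Polydactyly of a
#' triphalangeal thumb through Preaxial polydactyly of fingers). The closure
#' is transitive and irreflexive and contains every asserted pair.
#'
#' @param graph A valid `kg` object.
#' @return A data frame with character columns `broader` and `narrower`,
#'   sorted lexicographically.
#' @export
broader_closure <- function(graph) {
  stop_if_invalid(graph)
  edges <- predicate_edges(graph, "BROADER_T")
  empty <- data.frame(broader = character(), narrower = character(),
                      stringsAsFactors = FALSE)
  if (nrow(edges) == 0) return(empty)
  ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
  nm <- igraph::V(ig)$name
  pairs <- do.call(rbind, lapply(nm, function(v) {
    reach <- setdiff(nm[igraph::subcomponent(ig, v, mode = "out")], v)
    if (!length(reach)) return(NULL)
    data.frame(broader = v, narrower = reach, stringsAsFactors = FALSE)
  }))
  if (is.null(pairs)) return(empty)
  pairs <- pairs[order(pairs$broader, pairs$narrower), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

stop_if_invalid <- function(graph) {
  rep <- kg_validate(graph)
  if (!rep$ok)
    kg_error("InvalidGraph",
             paste0("graph fails validation: ",
                    paste(utils::head(rep$violations$message, 3), collapse = "; ")))
  invisible(graph)
}

#' Advisory group-vs-disorder heuristic
#'
#' Reproduces the decision rule used when classifying borderline taxonomy
#' nodes: look at the node's children (objects of its `MEMBER` statements plus
#' objects of its `BROADER_T` statements). If every child is a disorder
#' sub-type — linked only via `BROADER_T`, and for each asserting agent the
#' node is the child's sole broader parent — the node behaves as a disorder
#' with sub-types (the Mesomelic dysplasia pattern). If any child is a group,
#' or the children mix groups and disorders, it behaves as a group (the
#' Dysostosis pattern). A node with no children keeps its declared kind. The
#' verdict is advisory and never mutates the graph; authoritative kinds come
#' from source documents and the alignment table.
#'
#' @param graph A `kg` object.
#' @param node_id Id of a GROUP or DISORDER entity.
#' @return `"GROUP"` or `"DISORDER"`.
#' @export
classify_node_kind <- function(graph, node_id) {
  ent <- graph$entities[[node_id]]
  if (is.null(ent))
    kg_error("UnknownEntity", sprintf("no entity '%s'", node_id))
  if (!ent$kind %in% c("GROUP", "DISORDER"))
    kg_error("NotClassifiable",
             sprintf("'%s' has kind %s; only GROUP/DISORDER nodes are classifiable",
                     node_id, ent$kind))
  out <- Filter(function(s) s$subject == node_id &&
                  s$predicate %in% c("MEMBER", "BROADER_T"), graph$statements)
  if (!length(out)) return(ent$kind)
  children <- vapply(out, `[[`, character(1), "object")
  child_kinds <- vapply(children, function(id) graph$entities[[id]]$kind, character(1))
  via_member <- vapply(out, function(s) s$predicate == "MEMBER", logical(1))
  if (any(child_kinds == "GROUP")) return("GROUP")
  all_subtypes <- !any(via_member) && all(child_kinds == "DISORDER") &&
    all(mapply(function(s, child) {
      sole_broader_parent(graph, child, node_id, s$attributed_to)
    }, out, children))
  if (all_subtypes) return("DISORDER")
  if (any(via_member) && all(child_kinds == "DISORDER") && any(!via_member))
    return("GROUP")  # mixed linkage over disorder children
  if (all(via_member)) return("GROUP")
  ent$kind
}

# is `parent` the only BROADER_T parent of `child` as asserted by each of the
# given agents?
sole_broader_parent <- function(graph, child, parent, agents) {
  parents <- Filter(function(s) s$predicate == "BROADER_T" && s$object == child,
                    graph$statements)
  for (a in agents) {
    by_a <- Filter(function(s) a %in% s$attributed_to, parents)
    ids <- vapply(by_a, `[[`, character(1), "subject")
    if (length(setdiff(ids, parent))) return(FALSE)
  }
  TRUE
}

## Validation -----------------------------------------------------------------

#' Validate a knowledge graph
#'
#' Checks referential integrity (every statement endpoint exists), agent
#' registration, non-empty attribution on entities and statements, predicate
#' kind constraints, qualifier placement, acyclicity of the sub-typing and
#' membership relations, and exact pairing of `BROADER_T`/`NARROWER_T`
#' inverses with identical attribution sets.
#'
#' @param graph A `kg` object.
#' @return A list of class `kg_validation` with elements `ok` (logical) and
#'   `violations` (data frame with columns `code`, `subject`, `message`).
#' @export
kg_validate <- function(graph) {
  stopifnot(inherits(graph, "kg"))
  v <- list()
  bad <- function(code, subject, message)
    list(code = code, subject = subject, message = message)

  for (e in graph$entities) {
    if (length(e$attributed_to) == 0)
      v <- c(v, list(bad("EmptyAttribution", e$id,
                         sprintf("entity '%s' has empty attribution", e$id))))
    unk <- setdiff(e$attributed_to, names(graph$agents))
    if (length(unk))
      v <- c(v, list(bad("UnregisteredAgent", e$id,
                         sprintf("entity '%s' attributed to unregistered %s",
                                 e$id, paste(unk, collapse = ",")))))
  }

  for (s in graph$statements) {
    lab <- sprintf("(%s %s %s)", s$subject, s$predicate, s$object)
    missing_end <- FALSE
    for (end in c("subject", "object"))
      if (is.null(graph$entities[[s[[end]]]])) {
        missing_end <- TRUE
        v <- c(v, list(bad("DanglingEndpoint", s[[end]],
                           sprintf("statement %s: %s '%s' missing",
                                   lab, end, s[[end]]))))
      }
    if (length(s$attributed_to) == 0)
      v <- c(v, list(bad("EmptyAttribution", s$subject,
                         sprintf("statement %s has empty attribution", lab))))
    unk <- setdiff(s$attributed_to, names(graph$agents))
    if (length(unk))
      v <- c(v, list(bad("UnregisteredAgent", s$subject,
                         sprintf("statement %s attributed to unregistered %s",
                                 lab, paste(unk, collapse = ",")))))
    if (!missing_end) {
      cons <- predicate_constraints[[s$predicate]]
      skind <- graph$entities[[s$subject]]$kind
      okind <- graph$entities[[s$object]]$kind
      if (!skind %in% cons$subject || !okind %in% cons$object)
        v <- c(v, list(bad("KindConstraint", s$subject,
                           sprintf("statement %s violates %s -> %s (got %s -> %s)",
                                   lab, paste(cons$subject, collapse = "|"),
                                   paste(cons$object, collapse = "|"),
                                   skind, okind))))
    }
    if (s$qualifier != "UNSPECIFIED" && s$predicate != "ASSOCIATED_PHENOTYPE")
      v <- c(v, list(bad("KindConstraint", s$subject,
                         sprintf("statement %s carries a qualifier on %s",
                                 lab, s$predicate))))
    if (s$predicate %in% names(inverse_predicate)) {
      inv <- graph$statements[[stmt_key(invert_statement(s))]]
      if (is.null(inv))
        v <- c(v, list(bad("MissingInverse", s$subject,
                           sprintf("statement %s lacks its %s inverse",
                                   lab, inverse_predicate[[s$predicate]]))))
      else if (!identical(inv$attributed_to, s$attributed_to))
        v <- c(v, list(bad("InverseAttributionMismatch", s$subject,
                           sprintf("statement %s and its inverse differ in attribution",
                                   lab))))
    }
  }

  for (pred in c("BROADER_T", "MEMBER")) {
    edges <- predicate_edges(graph, pred)
    if (nrow(edges) > 0) {
      ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
      if (!igraph::is_dag(ig))
        v <- c(v, list(bad("Cycle", pred,
                           sprintf("%s edge set contains a directed cycle", pred))))
    }
  }

  violations <- if (length(v)) {
    data.frame(code = vapply(v, `[[`, character(1), "code"),
               subject = vapply(v, `[[`, character(1), "subject"),
               message = vapply(v, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(code = character(), subject = character(), message = character(),
               stringsAsFactors = FALSE)
  }
  structure(list(ok = nrow(violations) == 0, violations = violations),
            class = "kg_validation")
}

## Equality and printing ------------------------------------------------------

normalize_kg <- function(g) {
  g$edge_index <- NULL
  sort_by_name <- function(x) if (length(x)) x[order(names(x))] else x
  g$agents <- sort_by_name(g$agents)
  g$entities <- sort_by_name(g$entities)
  g$statements <- sort_by_name(g$statements)
  g$entities <- lapply(g$entities, function(e) {
    e$alt_labels <- sort(unique(e$alt_labels))
    e$xrefs <- lapply(e$xrefs, function(v) sort(unique(v)))[order(names(e$xrefs))]
    if (!length(e$xrefs)) e$xrefs <- list()
    names(e$xrefs) <- as.character(names(e$xrefs))
    e$attributed_to <- sort(unique(e$attributed_to))
    e
  })
  g$statements <- lapply(g$statements, function(s) {
    s$attributed_to <- sort(unique(s$attributed_to))
    s
  })
  g
}

#' Compare two knowledge graphs for equality
#'
#' Equality means equal graph ids, agent registries, entity maps (labels,
#' alternative labels, xrefs, attribution) and statement sets with identical
#' attribution sets; ordering is irrelevant.
#'
#' @param a,b `kg` objects.
#' @return `TRUE` or `FALSE`.
#' @export
kg_equal <- function(a, b) {
  isTRUE(all.equal(unclass(normalize_kg(a)), unclass(normalize_kg(b)),
                   check.attributes = FALSE))
}

#' @export
print.kg <- function(x, ...) {
  kinds <- table(factor(vapply(x$entities, `[[`, character(1), "kind"),
                        levels = ENTITY_KINDS))
  cat(sprintf("<kg '%s': %d entities, %d statements, agents: %s>\n",
              x$graph_id, length(x$entities), length(x$statements),
              paste(names(x$agents), collapse = ", ")))
  cat("  ", paste(sprintf("%s=%d", names(kinds), kinds), collapse = " "), "\n")
  invisible(x)
}

#' @export
print.kg_validation <- function(x, ...) {
  if (x$ok) cat("valid knowledge graph (0 violations)\n")
  else {
    cat(sprintf("INVALID knowledge graph: %d violation(s)\n", nrow(x$violations)))
    print(utils::head(x$violations, 10))
  }
  invisible(x)
}
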