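## Provenance views, comparative association analytics, coverage, divergence,
## taxonomy depth, and the endpoint-style association queries.

#' Extract the provenance view of a set of agents
#'
#' Restricts the graph to the entities and statements attributed to at least
#' one of the chosen agents, with attribution sets cut down to those agents.
#' Statements losing an endpoint are dropped. This is the
#' backwards-compatibility operation: viewing a merged graph by the agents of
#' one contributing classification recreates that classification.
#'
#' @param graph A valid `kg` object.
#' @param agents Non-empty character vector of registered agent ids.
#' @return A valid `kg` restricted to the chosen agents.
#' @export
provenance_view <- function(graph, agents) {
  stopifnot(inherits(graph, "kg"))
  if (!length(agents)) kg_error("EmptyAgentSet", "agents must be non-empty")
  unknown <- setdiff(agents, names(graph$agents))
  if (length(unknown))
    kg_error("UnknownAgent", sprintf("unregistered agent(s): %s",
                                     paste(unknown, collapse = ", ")))
  agents <- sort(unique(agents))
  out <- kg_new(graph$graph_id)
  for (a in agents) out <- kg_add_agent(out, a, graph$agents[[a]])
  for (e in graph$entities) {
    keep <- intersect(e$attributed_to, agents)
    if (length(keep)) {
      e$attributed_to <- keep
      out$entities[[e$id]] <- e
    }
  }
  for (s in graph$statements) {
    keep <- intersect(s$attributed_to, agents)
    if (length(keep) &&
        !is.null(out$entities[[s$subject]]) && !is.null(out$entities[[s$object]])) {
      s$attributed_to <- keep
      out$statements[[stmt_key(s)]] <- s
    }
  }
  stop_if_invalid(out)
  out
}

assoc_predicates <- c("ASSOCIATED_GENE", "ASSOCIATED_PHENOTYPE", "MODE_OF_INHERITANCE")

#' Compare a disorder's associations across sources
#'
#' For one disorder, collects the phenotype and gene association sets of each
#' agent (a statement counts for every agent in its attribution; frequency
#' qualifiers are ignored for set membership), the common set — the
#' intersection over all agents that annotate the disorder in that category —
#' and each agent's unique contributions (ids asserted by no other agent).
#'
#' @param graph A valid `kg` object.
#' @param disorder_id Id of a DISORDER entity.
#' @return An `association_comparison` with components `phenotypes` and
#'   `genes`, each a list of `per_agent` (named list of id vectors), `common`
#'   and `unique` (named list).
#' @export
association_comparison <- function(graph, disorder_id) {
  ent <- graph$entities[[disorder_id]]
  if (is.null(ent)) kg_error("UnknownEntity", sprintf("no entity '%s'", disorder_id))
  if (ent$kind != "DISORDER")
    kg_error("WrongKind", sprintf("'%s' has kind %s, expected DISORDER",
                                  disorder_id, ent$kind))
  sets_for <- function(predicate) {
    st <- Filter(function(s) s$subject == disorder_id && s$predicate == predicate,
                 graph$statements)
    per_agent <- list()
    for (s in st)
      for (a in s$attributed_to)
        per_agent[[a]] <- sort(unique(c(per_agent[[a]], s$object)))
    if (length(per_agent)) per_agent <- per_agent[order(names(per_agent))]
    common <- if (length(per_agent)) sort(Reduce(intersect, per_agent)) else character()
    uniq <- lapply(names(per_agent), function(a) {
      others <- unlist(per_agent[setdiff(names(per_agent), a)])
      sort(setdiff(per_agent[[a]], others))
    })
    names(uniq) <- names(per_agent)
    list(per_agent = per_agent, common = common, unique = uniq)
  }
  structure(list(disorder = disorder_id,
                 phenotypes = sets_for("ASSOCIATED_PHENOTYPE"),
                 genes = sets_for("ASSOCIATED_GENE")),
            class = "association_comparison")
}

#' @export
print.association_comparison <- function(x, ...) {
  cat(sprintf("Association comparison for %s\n", x$disorder))
  for (cat_nm in c("phenotypes", "genes")) {
    s <- x[[cat_nm]]
    cat(sprintf("  %s: common {%s}\n", cat_nm, paste(s$common, collapse = ", ")))
    for (a in names(s$per_agent))
      cat(sprintf("    %s: %d (%d unique)\n", a, length(s$per_agent[[a]]),
                  length(s$unique[[a]])))
  }
  invisible(x)
}

#' Query disorders associated with a gene or phenotype
#'
#' The endpoint-style query ("bone disorders associated with a given gene"):
#' one row per association statement pointing at the target, with the
#' provenance column reporting the asserting agents.
#'
#' @param graph A valid `kg` object.
#' @param target_id Id of a GENE, PHENOTYPE or INHERITANCE_MODE entity.
#' @return Data frame with columns `disorder`, `predicate`, `qualifier`,
#'   `attributed_to` (comma-joined agent ids), sorted by disorder id.
#' @export
query_associations <- function(graph, target_id) {
  ent <- graph$entities[[target_id]]
  if (is.null(ent)) kg_error("UnknownEntity", sprintf("no entity '%s'", target_id))
  if (ent$kind %in% c("DISORDER", "GROUP"))
    kg_error("WrongKind",
             sprintf("'%s' has kind %s; query targets are genes/phenotypes",
                     target_id, ent$kind))
  st <- Filter(function(s) s$object == target_id && s$predicate %in% assoc_predicates,
               graph$statements)
  out <- data.frame(
    disorder = vapply(st, `[[`, character(1), "subject"),
    predicate = vapply(st, `[[`, character(1), "predicate"),
    qualifier = vapply(st, `[[`, character(1), "qualifier"),
    attributed_to = vapply(st, function(s) paste(s$attributed_to, collapse = ","),
                           character(1)),
    stringsAsFactors = FALSE)
  out <- out[order(out$disorder, out$predicate, out$qualifier), , drop = FALSE]
  rownames(out) <- NULL
  out
}

round_half_up <- function(x, digits = 1) floor(x * 10^digits + 0.5) / 10^digits

#' Coverage comparison between two sources
#'
#' Entity-level coverage uses entity attribution: a disorder counts for an
#' agent iff that agent is in its attribution set. Reports only-in-left /
#' only-in-right / shared disorder counts, the only-in-left percentage of the
#' left total (rounded half-up to one decimal, the convention under which 202
#' of 524 disorders prints as 38.5), the distinct phenotype vocabulary size
#' used by each agent's associations, and per-disorder phenotype overlap
#' triples (left count, right count, common count) for disorders attributed
#' to both.
#'
#' @param graph A valid `kg` object.
#' @param left,right Registered agent ids.
#' @return A `coverage_report` object.
#' @export
coverage_report <- function(graph, left, right) {
  unknown <- setdiff(c(left, right), names(graph$agents))
  if (length(unknown))
    kg_error("UnknownAgent", sprintf("unregistered agent(s): %s",
                                     paste(unknown, collapse = ", ")))
  disorders <- Filter(function(e) e$kind == "DISORDER", graph$entities)
  in_l <- vapply(disorders, function(e) left %in% e$attributed_to, logical(1))
  in_r <- vapply(disorders, function(e) right %in% e$attributed_to, logical(1))
  only_l <- sum(in_l & !in_r); only_r <- sum(in_r & !in_l); shared <- sum(in_l & in_r)
  left_total <- sum(in_l); right_total <- sum(in_r)
  pct <- if (left_total > 0) round_half_up(100 * only_l / left_total, 1) else 0

  pheno_stmts <- Filter(function(s) s$predicate == "ASSOCIATED_PHENOTYPE",
                        graph$statements)
  vocab <- function(agent) length(unique(vapply(
    Filter(function(s) agent %in% s$attributed_to, pheno_stmts),
    `[[`, character(1), "object")))
  both_ids <- sort(names(disorders)[in_l & in_r])
  per_disorder <- do.call(rbind, lapply(both_ids, function(d) {
    st <- Filter(function(s) s$subject == d, pheno_stmts)
    set_of <- function(agent) unique(vapply(
      Filter(function(s) agent %in% s$attributed_to, st),
      `[[`, character(1), "object"))
    sl <- set_of(left); sr <- set_of(right)
    data.frame(disorder = d, left_count = length(sl), right_count = length(sr),
               common = length(intersect(sl, sr)), stringsAsFactors = FALSE)
  }))
  if (is.null(per_disorder))
    per_disorder <- data.frame(disorder = character(), left_count = integer(),
                               right_count = integer(), common = integer(),
                               stringsAsFactors = FALSE)
  structure(list(left = left, right = right,
                 left_total = left_total, right_total = right_total,
                 only_in_left = only_l, only_in_right = only_r, shared = shared,
                 only_in_left_pct = pct,
                 phenotype_vocab = stats::setNames(c(vocab(left), vocab(right)),
                                                   c(left, right)),
                 per_disorder = per_disorder),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage: %s vs %s\n", x$left, x$right))
  cat(sprintf("  disorders: %d vs %d (shared %d)\n", x$left_total, x$right_total,
              x$shared))
  cat(sprintf("  only in %s: %d (%.1f%% of %d)\n", x$left, x$only_in_left,
              x$only_in_left_pct, x$left_total))
  cat(sprintf("  only in %s: %d\n", x$right, x$only_in_right))
  cat(sprintf("  phenotype vocabulary: %s=%d, %s=%d\n",
              x$left, x$phenotype_vocab[[x$left]],
              x$right, x$phenotype_vocab[[x$right]]))
  if (nrow(x$per_disorder)) {
    cat(sprintf("  per-disorder phenotype overlap (%d shared disorders):\n",
                nrow(x$per_disorder)))
    print(utils::head(x$per_disorder, 10), row.names = FALSE)
  }
  invisible(x)
}

#' Divergent groupings across sources
#'
#' For every disorder attributed to at least two agents, collects the parent
#' containers per agent — `MEMBER` parents (groups it belongs to) and
#' `BROADER_T` parents (disorders it is a sub-type of), each tagged by the
#' relation — from statements whose attribution contains that agent. The
#' disorder is flagged divergent when at least two agents disagree on the
#' parent set (the Holt-Oram pattern: member of a group in one source,
#' sub-type of a disorder in the other).
#'
#' @param graph A valid `kg` object.
#' @return A data frame with columns `disorder`, `divergent` and a list
#'   column `parents` (per-agent named lists of `"RELATION:parent_id"` tags).
#' @export
grouping_divergence <- function(graph) {
  disorders <- Filter(function(e) e$kind == "DISORDER" &&
                        length(e$attributed_to) >= 2, graph$entities)
  parent_stmts <- Filter(function(s) s$predicate %in% c("MEMBER", "BROADER_T"),
                         graph$statements)
  recs <- lapply(disorders[order(names(disorders))], function(e) {
    st <- Filter(function(s) s$object == e$id, parent_stmts)
    per_agent <- lapply(e$attributed_to, function(a) {
      tags <- vapply(Filter(function(s) a %in% s$attributed_to, st),
                     function(s) paste0(s$predicate, ":", s$subject), character(1))
      sort(unique(tags))
    })
    names(per_agent) <- e$attributed_to
    divergent <- FALSE
    if (length(per_agent) >= 2)
      for (i in seq_along(per_agent))
        for (j in seq_len(i - 1))
          if (!identical(per_agent[[i]], per_agent[[j]])) divergent <- TRUE
    list(disorder = e$id, divergent = divergent, parents = per_agent)
  })
  out <- data.frame(
    disorder = vapply(recs, `[[`, character(1), "disorder"),
    divergent = vapply(recs, `[[`, logical(1), "divergent"),
    stringsAsFactors = FALSE)
  out$parents <- I(lapply(recs, `[[`, "parents"))
  rownames(out) <- NULL
  out
}

#' Depth of the containment hierarchy
#'
#' Length in edges of the longest downward path over group membership
#' (`MEMBER`, group to child) and sub-typing (`BROADER_T`, disorder to
#' narrower disorder) edges, starting from any root (a node without incoming
#' containment edge). A graph with no containment edges has depth 0. With an
#' agent given, the depth of that agent's provenance view is returned —
#' e.g. nosology-style classifications are shallow (about 3 levels) while
#' Orphanet-style taxonomies nest up to 7.
#'
#' @param graph A valid `kg` object.
#' @param agent Optional registered agent id.
#' @return Integer depth in edges.
#' @export
taxonomy_depth <- function(graph, agent = NULL) {
  if (!is.null(agent)) graph <- provenance_view(graph, agent)
  stop_if_invalid(graph)
  edges <- rbind(predicate_edges(graph, "MEMBER"),
                 predicate_edges(graph, "BROADER_T"))
  edges <- unique(edges)
  if (nrow(edges) == 0) return(0L)
  ig <- igraph::graph_from_edgelist(edges, directed = TRUE)
  ord <- igraph::topo_sort(ig, mode = "out")
  depth <- stats::setNames(integer(length(igraph::V(ig))), igraph::V(ig)$name)
  for (v in ord$name) {
    for (w in igraph::neighbors(ig, v, mode = "out")$name)
      depth[[w]] <- max(depth[[w]], depth[[v]] + 1L)
  }
  max(depth)
}
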