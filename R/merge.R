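## Integration of multiple source documents under an expert alignment table.

KEY_SEP <- "\t"
src_key <- function(agent, id) paste(agent, id, sep = KEY_SEP)

canonical_prefix <- c(DISORDER = "BD", GROUP = "BDG", GENE = "GENE")

#' Resolve the kind of an aligned node pair
#'
#' Precedence: an explicit expert decision (`GROUP`/`DISORDER` in the
#' alignment row) wins; otherwise agreement of the declared kinds; otherwise
#' the advisory heuristic verdict (see [classify_node_kind()]: children that
#' are all sub-types of one disorder mean `DISORDER`, a mixture of groups and
#' disorders means `GROUP`).
#'
#' @param row One alignment row (list or single-row data frame with a
#'   `decision` field).
#' @param left_kind,right_kind Declared kinds (`GROUP` or `DISORDER`).
#' @param heuristic_verdict `"GROUP"`, `"DISORDER"` or `NULL`/`"none"`.
#' @return The resolved kind token.
#' @export
resolve_kind <- function(row, left_kind, right_kind, heuristic_verdict = NULL) {
  decision <- toupper(as.character(row$decision %||% "AUTO"))
  if (decision %in% c("GROUP", "DISORDER")) return(decision)
  if (!decision %in% "AUTO")
    kg_error("UnknownDecision", sprintf("unknown decision '%s'", decision))
  if (identical(left_kind, right_kind)) return(left_kind)
  if (!is.null(heuristic_verdict) && !identical(heuristic_verdict, "none"))
    return(match_token(heuristic_verdict, c("GROUP", "DISORDER"), "heuristic verdict"))
  kg_error("Unresolvable",
           sprintf("kinds disagree (%s vs %s), decision is AUTO and no heuristic verdict",
                   left_kind, right_kind))
}

# union-find over (agent, id) keys
uf_new <- function(keys) stats::setNames(keys, keys)
uf_find <- function(uf, k) { while (uf[[k]] != k) k <- uf[[k]]; k }
uf_union <- function(uf, a, b) {
  ra <- uf_find(uf, a); rb <- uf_find(uf, b)
  if (ra != rb) uf[[max(ra, rb)]] <- min(ra, rb)
  uf
}

#' Build the canonical identifier map
#'
#' Assigns one canonical id to every entity of every source. Expert-aligned
#' entities (closed transitively across source pairs) share one id; canonical
#' ids for disorders, groups and genes are minted deterministically as
#' `BD`/`BDG`/`GENE` plus a 7-digit number — aligned clusters first, then
#' unaligned entities, each ordered by (source agent id, local id) — so the
#' map is independent of source order. Phenotype and inheritance-mode ids
#' (HP CURIEs) pass through unchanged.
#'
#' @param sources List of `source_document`s.
#' @param alignment An `alignment_table`.
#' @return A `canonical_id_map` with a `table` data frame (`agent`,
#'   `local_id`, `kind`, `canonical_id`) and a `kind_conflicts` data frame.
#' @export
build_canonical_map <- function(sources, alignment) {
  stopifnot(length(sources) >= 1, inherits(alignment, "alignment_table"))
  recs <- do.call(rbind, lapply(sources, function(doc) {
    data.frame(agent = doc$source_agent,
               local_id = vapply(doc$entities, `[[`, character(1), "id"),
               kind = vapply(doc$entities, `[[`, character(1), "kind"),
               stringsAsFactors = FALSE)
  }))
  recs <- unique(recs)  # an exact self-copy of a source collapses
  if (any(duplicated(src_key(recs$agent, recs$local_id))))
    kg_error("SchemaError", "entity id bound to two kinds within one source")
  recs$key <- src_key(recs$agent, recs$local_id)
  graphs <- lapply(sources, source_to_graph)
  names(graphs) <- vapply(sources, `[[`, character(1), "source_agent")

  uf <- uf_new(recs$key)
  row_of_cluster <- list()  # root key -> alignment rows touching the cluster
  if (nrow(alignment)) {
    for (i in seq_len(nrow(alignment))) {
      lk <- src_key(alignment$left_source[i], alignment$left_id[i])
      rk <- src_key(alignment$right_source[i], alignment$right_id[i])
      if (!lk %in% recs$key)
        kg_error("UnknownAlignedId",
                 sprintf("alignment row %d: %s/%s not declared", i,
                         alignment$left_source[i], alignment$left_id[i]))
      if (!rk %in% recs$key)
        kg_error("UnknownAlignedId",
                 sprintf("alignment row %d: %s/%s not declared", i,
                         alignment$right_source[i], alignment$right_id[i]))
      uf <- uf_union(uf, lk, rk)
    }
  }
  root <- vapply(recs$key, function(k) uf_find(uf, k), character(1))
  recs$root <- root
  if (nrow(alignment)) {
    arow_root <- vapply(seq_len(nrow(alignment)), function(i)
      uf_find(uf, src_key(alignment$left_source[i], alignment$left_id[i])),
      character(1))
    row_of_cluster <- split(seq_len(nrow(alignment)), arow_root)
  }

  clusters <- split(seq_len(nrow(recs)), recs$root)
  aligned_roots <- names(clusters)[vapply(clusters, length, integer(1)) > 1 |
                                     names(clusters) %in% names(row_of_cluster)]
  # deterministic order: aligned clusters first by their smallest member key,
  # then singletons by key
  ord_key <- vapply(clusters, function(ix) min(recs$key[ix]), character(1))
  aligned_order <- aligned_roots[order(ord_key[aligned_roots])]
  single_roots <- setdiff(names(clusters), aligned_roots)
  single_order <- single_roots[order(ord_key[single_roots])]

  counters <- c(BD = 0L, BDG = 0L, GENE = 0L)
  canon <- character(nrow(recs))
  conflicts <- list()
  assign_cluster <- function(rootk) {
    ix <- clusters[[rootk]]
    kinds <- unique(recs$kind[ix])
    if (all(kinds %in% c("PHENOTYPE", "INHERITANCE_MODE"))) {
      if (length(unique(recs$local_id[ix])) > 1)
        canon[ix] <<- min(recs$local_id[ix])
      else canon[ix] <<- recs$local_id[ix]
      return(invisible())
    }
    if (any(kinds %in% c("PHENOTYPE", "INHERITANCE_MODE")))
      kg_error("KindClashAcrossSources",
               sprintf("cluster of %s mixes phenotype/inheritance with other kinds",
                       paste(recs$key[ix], collapse = ", ")))
    kind <- if (length(kinds) == 1) kinds else {
      if (!all(kinds %in% c("GROUP", "DISORDER")))
        kg_error("KindClashAcrossSources",
                 sprintf("irreconcilable kinds (%s) for cluster %s",
                         paste(kinds, collapse = ", "),
                         paste(recs$key[ix], collapse = ", ")))
      rows_ix <- row_of_cluster[[rootk]]
      decision <- "AUTO"
      if (length(rows_ix)) {
        expl <- setdiff(unique(alignment$decision[rows_ix]), "AUTO")
        if (length(expl)) decision <- expl[1]
      }
      verdicts <- unlist(lapply(ix, function(j) {
        gg <- graphs[[recs$agent[j]]]
        node <- recs$local_id[j]
        has_children <- any(vapply(gg$statements, function(s)
          s$subject == node && s$predicate %in% c("MEMBER", "BROADER_T"),
          logical(1)))
        if (has_children) classify_node_kind(gg, node) else NULL
      }))
      verdict <- if (is.null(verdicts)) NULL
      else if ("GROUP" %in% verdicts) "GROUP" else "DISORDER"
      resolved <- tryCatch(
        resolve_kind(list(decision = decision), kinds[1], kinds[2], verdict),
        Unresolvable = function(c)
          kg_error("KindClashAcrossSources", conditionMessage(c)))
      conflicts[[length(conflicts) + 1]] <<-
        data.frame(cluster = paste(gsub(KEY_SEP, "/", recs$key[ix]), collapse = ";"),
                   kinds = paste(recs$kind[ix], collapse = ";"),
                   resolved = resolved, stringsAsFactors = FALSE)
      resolved
    }
    pre <- canonical_prefix[[kind]]
    counters[[pre]] <<- counters[[pre]] + 1L
    canon[ix] <<- sprintf("%s%07d", pre, counters[[pre]])
    recs$kind[ix] <<- kind
  }
  for (rootk in aligned_order) assign_cluster(rootk)
  for (rootk in single_order) assign_cluster(rootk)

  recs$canonical_id <- canon
  structure(list(table = recs[, c("agent", "local_id", "kind", "canonical_id")],
                 kind_conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                 else data.frame(cluster = character(), kinds = character(),
                                 resolved = character(), stringsAsFactors = FALSE),
                 aligned_clusters = length(aligned_order)),
            class = "canonical_id_map")
}

#' Look up a canonical id
#'
#' @param map A `canonical_id_map`.
#' @param agent Source agent id.
#' @param local_id Source-local entity id.
#' @return The canonical id string.
#' @export
canonical_id <- function(map, agent, local_id) {
  hit <- map$table$canonical_id[map$table$agent == agent &
                                  map$table$local_id == local_id]
  if (!length(hit))
    kg_error("UnknownEntity", sprintf("no canonical id for %s/%s", agent, local_id))
  hit[1]
}

#' Merge source classifications into one provenance-annotated graph
#'
#' Produces the loose integration of all sources: the union of entities
#' (rewritten to canonical ids; attribution is the union of the asserting
#' agents) and the union of statements (identical statements from several
#' sources collapse into one with a unioned attribution set; conflicting
#' assertions — e.g. the same disorder placed in different groups, or
#' sub-typed in one source and group-assigned in another — coexist, each with
#' its own provenance). The preferred label of the lexicographically first
#' asserting source wins; other labels become alternative labels. The result
#' is independent of the order in which sources are given.
#'
#' @param sources List of `source_document`s (at least one).
#' @param alignment An `alignment_table` (may have zero rows).
#' @return A list with elements `graph` (the merged `kg`), `report`
#'   (a `merge_report`) and `map` (the `canonical_id_map`).
#' @export
kg_merge <- function(sources, alignment = empty_alignment()) {
  stopifnot(length(sources) >= 1)
  agents_order <- order(vapply(sources, `[[`, character(1), "source_agent"))
  sources <- sources[agents_order]
  map <- build_canonical_map(sources, alignment)
  lut <- stats::setNames(map$table$canonical_id,
                         src_key(map$table$agent, map$table$local_id))
  kindlut <- stats::setNames(map$table$kind,
                             src_key(map$table$agent, map$table$local_id))

  g <- kg_new("merged")
  for (doc in sources) {
    used <- sort(unique(c(doc$source_agent,
                          unlist(lapply(doc$entities, `[[`, "attributed_to")),
                          unlist(lapply(doc$statements, `[[`, "attributed_to")))))
    for (a in used)
      if (!a %in% names(g$agents))
        g <- kg_add_agent(g, a, if (a == doc$source_agent) doc$source_label
                          else doc$agent_labels[[a]] %||% a)
  }

  xref_clashes <- list()
  for (doc in sources) {
    ag <- doc$source_agent
    for (e in doc$entities) {
      cid <- lut[[src_key(ag, e$id)]]
      rec <- e
      rec$id <- cid
      rec$kind <- kindlut[[src_key(ag, e$id)]]
      before <- g$entities[[cid]]
      g <- kg_add_entity(g, rec)
      after <- g$entities[[cid]]
      if (!is.null(before))
        for (ns in names(after$xrefs))
          if (length(after$xrefs[[ns]]) > 1 &&
              length(before$xrefs[[ns]] %||% character()) >= 1 &&
              length(setdiff(after$xrefs[[ns]], before$xrefs[[ns]])))
            xref_clashes[[length(xref_clashes) + 1]] <-
              data.frame(canonical_id = cid, namespace = ns,
                         values = paste(after$xrefs[[ns]], collapse = ";"),
                         stringsAsFactors = FALSE)
    }
  }
  for (doc in sources) {
    ag <- doc$source_agent
    for (s in doc$statements) {
      s$subject <- lut[[src_key(ag, s$subject)]]
      s$object <- lut[[src_key(ag, s$object)]]
      g <- tryCatch(kg_add_statement(g, s),
                    CycleIntroduced = function(c) kg_error(
                      "CycleIntroduced",
                      sprintf("merged sub-typing/membership union is cyclic: %s",
                              conditionMessage(c))))
    }
  }
  stop_if_invalid(g)

  report <- build_merge_report(sources, map, g, xref_clashes)
  list(graph = g, report = report, map = map)
}

#' An empty alignment table
#' @return An `alignment_table` with zero rows.
#' @export
empty_alignment <- function() {
  tab <- data.frame(left_source = character(), left_id = character(),
                    right_source = character(), right_id = character(),
                    decision = character(), note = character(),
                    stringsAsFactors = FALSE)
  class(tab) <- c("alignment_table", "data.frame")
  tab
}

build_merge_report <- function(sources, map, graph, xref_clashes) {
  tab <- map$table
  agents <- vapply(sources, `[[`, character(1), "source_agent")
  per_source <- lapply(agents, function(a) {
    sub <- tab[tab$agent == a, ]
    cnt <- table(factor(sub$kind, levels = ENTITY_KINDS))
    shared <- vapply(sub$canonical_id, function(cid)
      sum(tab$canonical_id == cid) > 1, logical(1))
    list(entities = length(sub$local_id),
         by_kind = as.list(cnt),
         aligned = sum(shared),
         unaligned = sum(!shared))
  })
  names(per_source) <- agents
  preds <- vapply(graph$statements, `[[`, character(1), "predicate")
  nagents <- vapply(graph$statements, function(s) length(s$attributed_to), integer(1))
  stmt_tab <- do.call(rbind, lapply(PREDICATES, function(p) {
    data.frame(predicate = p, total = sum(preds == p),
               single_source = sum(preds == p & nagents == 1),
               multi_source = sum(preds == p & nagents > 1),
               stringsAsFactors = FALSE)
  }))
  structure(list(per_source = per_source,
                 aligned_clusters = map$aligned_clusters,
                 kind_conflicts = map$kind_conflicts,
                 statements = stmt_tab,
                 xref_clashes = if (length(xref_clashes))
                   unique(do.call(rbind, xref_clashes))
                 else data.frame(canonical_id = character(), namespace = character(),
                                 values = character(), stringsAsFactors = FALSE)),
            class = "merge_report")
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Merge report\n")
  for (a in names(x$per_source)) {
    ps <- x$per_source[[a]]
    cat(sprintf("  %s: %d entities (%d aligned, %d unaligned)\n",
                a, ps$entities, ps$aligned, ps$unaligned))
  }
  cat(sprintf("  aligned clusters: %d\n", x$aligned_clusters))
  if (nrow(x$kind_conflicts))
    cat(sprintf("  kind conflicts resolved: %d\n", nrow(x$kind_conflicts)))
  if (nrow(x$xref_clashes))
    cat(sprintf("  xref value clashes: %d\n", nrow(x$xref_clashes)))
  print(x$statements, row.names = FALSE)
  invisible(x)
}

merge_report_to_list <- function(x) {
  list(per_source = x$per_source,
       aligned_clusters = x$aligned_clusters,
       kind_conflicts = x$kind_conflicts,
       statements = x$statements,
       xref_clashes = x$xref_clashes)
}
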