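# Independent brute-force oracles and small graph builders used across the
# suite. The oracles deliberately avoid the package's graph machinery: they
# enumerate paths recursively over plain edge lists.

# exhaustive reachability: all ordered pairs (a, b) with a directed path a->b,
# found by depth-first path enumeration
oracle_reachability <- function(from, to) {
  nodes <- unique(c(from, to))
  reach_from <- function(v, seen) {
    outs <- setdiff(to[from == v], seen)
    res <- outs
    for (w in outs) res <- union(res, reach_from(w, c(seen, outs)))
    res
  }
  pairs <- list()
  for (v in nodes)
    for (w in reach_from(v, v))
      pairs[[length(pairs) + 1]] <- c(v, w)
  if (!length(pairs))
    return(data.frame(broader = character(), narrower = character(),
                      stringsAsFactors = FALSE))
  m <- do.call(rbind, pairs)
  out <- unique(data.frame(broader = m[, 1], narrower = m[, 2],
                           stringsAsFactors = FALSE))
  out <- out[order(out$broader, out$narrower), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# exhaustive longest path (in edges) by enumerating every path
oracle_longest_path <- function(from, to) {
  if (!length(from)) return(0L)
  walk <- function(v) {
    outs <- to[from == v]
    if (!length(outs)) return(0L)
    1L + max(vapply(outs, walk, integer(1)))
  }
  max(vapply(unique(from), walk, integer(1)))
}

# a random disorder DAG (edges only from lower to higher index, so acyclic),
# wrapped in a valid kg
random_disorder_dag <- function(n, p_edge, seed, agent = "SRC") {
  set.seed(seed)
  g <- kg_new("dag", agents = stats::setNames(agent, agent))
  ids <- sprintf("D%02d", seq_len(n))
  for (id in ids)
    g <- kg_add_entity(g, entity_record(id, "DISORDER", id, attributed_to = agent))
  edges <- list()
  for (i in seq_len(n)) for (j in seq_len(n)) if (i < j && stats::runif(1) < p_edge) {
    g <- kg_add_statement(g, statement(ids[i], "BROADER_T", ids[j],
                                       attributed_to = agent))
    edges[[length(edges) + 1]] <- c(ids[i], ids[j])
  }
  list(graph = g,
       from = vapply(edges, `[`, character(1), 1),
       to = vapply(edges, `[`, character(1), 2))
}

# minimal two-entity graph for statement-level tests
tiny_graph <- function() {
  g <- kg_new("tiny", agents = c(ISDS = "ISDS", Orphanet = "Orphanet",
                                 OMIM = "OMIM"))
  g <- kg_add_entity(g, entity_record("grp", "GROUP", "A group",
                                      attributed_to = "ISDS"))
  g <- kg_add_entity(g, entity_record("ach", "DISORDER", "Achondroplasia",
                                      attributed_to = "ISDS"))
  g <- kg_add_entity(g, entity_record("fgfr3", "GENE", "FGFR3",
                                      attributed_to = "ISDS"))
  g <- kg_add_entity(g, entity_record("HP:0000256", "PHENOTYPE", "Macrocephaly",
                                      attributed_to = "ISDS"))
  g
}

# structural isomorphism of a provenance view against an ingested source
# document, under the canonical id map of a merge
view_matches_source <- function(view, source_graph, map, agent) {
  mid <- function(id) canonical_id(map, agent, id)
  ents_src <- sort(unname(vapply(names(source_graph$entities), mid, character(1))))
  if (!identical(ents_src, sort(unname(names(view$entities))))) return(FALSE)
  key <- function(s, f) paste(f(s$subject), s$predicate, f(s$object), s$qualifier)
  k_src <- sort(unname(vapply(source_graph$statements, key, character(1), f = mid)))
  k_view <- sort(unname(vapply(view$statements, key, character(1), f = identity)))
  identical(k_src, k_view)
}

expect_kg_error <- function(expr, class) {
  testthat::expect_error(expr, class = class)
}
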