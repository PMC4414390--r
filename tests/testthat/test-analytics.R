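# Provenance views, association comparison, endpoint queries, coverage,
# divergence and hierarchy depth.

merged_wx <- local({
  fx <- worked_examples_fixture()
  kg_merge(fx$sources, fx$alignment)
})

test_that("provenance views recreate each ingested source (backwards compatibility)", {
  for (seed in 0:9) {
    fx <- generate_fixture(fixture_params(seed = seed))
    res <- kg_merge(fx$sources, fx$alignment)
    for (i in 1:2) {
      agent <- fx$sources[[i]]$source_agent
      v <- provenance_view(res$graph, agent)
      expect_true(view_matches_source(v, source_to_graph(fx$sources[[i]]),
                                      res$map, agent),
                  info = sprintf("seed %d, %s", seed, agent))
    }
  }
})

test_that("provenance_view is the identity for the full agent set, idempotent and monotone", {
  g <- merged_wx$graph
  all_agents <- names(g$agents)
  expect_true(kg_equal(provenance_view(g, all_agents), g))
  v <- provenance_view(g, "Orphanet")
  expect_true(kg_equal(provenance_view(v, "Orphanet"), v))
  # monotone: the single-agent view is a subgraph of the two-agent view
  v2 <- provenance_view(g, c("Orphanet", "OMIM"))
  expect_true(all(names(v$entities) %in% names(v2$entities)))
  expect_true(all(names(v$statements) %in% names(v2$statements)))
  expect_kg_error(provenance_view(g, character()), "EmptyAgentSet")
  expect_kg_error(provenance_view(g, "nobody"), "UnknownAgent")
})

test_that("the Orphanet view keeps only the Orphanet group placement of Maroteaux-type", {
  res <- merged_wx
  mid <- canonical_id(res$map, "ISDS", "sed_maroteaux")
  sed <- canonical_id(res$map, "ISDS", "sed_group")
  trp <- canonical_id(res$map, "ISDS", "trpv4_group")
  v <- provenance_view(res$graph, "Orphanet")
  mem <- Filter(function(s) s$predicate == "MEMBER" && s$object == mid, v$statements)
  expect_length(mem, 1)
  expect_identical(mem[[1]]$subject, sed)
  expect_false(trp %in% names(v$entities))  # the ISDS-only group disappears
})

test_that("association comparison computes common and unique sets", {
  g <- kg_new("cmp", agents = c(A = "A", B = "B"))
  g <- kg_add_entity(g, entity_record("d", "DISORDER", "d", attributed_to = c("A", "B")))
  for (p in sprintf("HP:%07d", 1:4))
    g <- kg_add_entity(g, entity_record(p, "PHENOTYPE", p, attributed_to = "A"))
  sets <- list(A = sprintf("HP:%07d", 1:3), B = sprintf("HP:%07d", 2:4))
  for (a in names(sets)) for (p in sets[[a]])
    g <- kg_add_statement(g, statement("d", "ASSOCIATED_PHENOTYPE", p,
                                       attributed_to = a))
  ac <- association_comparison(g, "d")
  expect_identical(ac$phenotypes$common, sprintf("HP:%07d", 2:3))
  expect_identical(ac$phenotypes$unique$A, "HP:0000001")
  expect_identical(ac$phenotypes$unique$B, "HP:0000004")
  # qualifier differences do not split set membership
  g2 <- kg_add_statement(g, statement("d", "ASSOCIATED_PHENOTYPE", "HP:0000001",
                                      "VERY_FREQUENT", attributed_to = "B"))
  expect_identical(association_comparison(g2, "d")$phenotypes$common,
                   sprintf("HP:%07d", 1:3))
  expect_kg_error(association_comparison(g, "HP:0000001"), "WrongKind")
  expect_kg_error(association_comparison(g, "missing"), "UnknownEntity")
})

test_that("a disorder annotated by one agent has that agent's whole set in common", {
  res <- merged_wx
  # Maroteaux-type: Genu valgum is unique to OMIM
  mid <- canonical_id(res$map, "ISDS", "sed_maroteaux")
  ac <- association_comparison(res$graph, mid)
  expect_identical(ac$phenotypes$per_agent$OMIM, "HP:0002857")
  expect_identical(ac$phenotypes$unique$OMIM, "HP:0002857")
  expect_identical(ac$phenotypes$common, "HP:0002857")  # OMIM is the sole annotator
  # FGFR3 is common to ISDS and Orphanet for Achondroplasia
  ach <- canonical_id(res$map, "ISDS", "achondroplasia")
  acg <- association_comparison(res$graph, ach)
  fg <- canonical_id(res$map, "ISDS", "fgfr3")
  expect_true(fg %in% acg$genes$per_agent$ISDS)
  expect_true(fg %in% acg$genes$per_agent$Orphanet)
  expect_identical(acg$genes$common, fg)
})

test_that("gene queries list one row per association statement with provenance", {
  res <- merged_wx
  fg <- canonical_id(res$map, "ISDS", "fgfr3")
  rows <- query_associations(res$graph, fg)
  expect_identical(nrow(rows), 2L)  # Achondroplasia and LADD
  ach <- canonical_id(res$map, "ISDS", "achondroplasia")
  expect_identical(rows$attributed_to[rows$disorder == ach], "ISDS,Orphanet")
  # no associations -> empty table; wrong kinds rejected
  g <- tiny_graph()
  expect_identical(nrow(query_associations(g, "fgfr3")), 0L)
  expect_kg_error(query_associations(res$graph, ach), "WrongKind")
})

test_that("query results equal a brute-force scan on random fixtures", {
  for (seed in 0:4) {
    fx <- generate_fixture(fixture_params(seed = seed))
    g <- kg_merge(fx$sources, fx$alignment)$graph
    genes <- names(Filter(function(e) e$kind == "GENE", g$entities))
    for (target in genes[1:3]) {
      rows <- query_associations(g, target)
      manual <- Filter(function(s) s$object == target &&
                         s$predicate == "ASSOCIATED_GENE", g$statements)
      expect_identical(nrow(rows), length(manual))
      expect_setequal(rows$disorder,
                      unique(vapply(manual, `[[`, character(1), "subject")))
    }
  }
})

test_that("coverage percentages follow half-up rounding and the totals identity", {
  # identical coverage
  g <- kg_new("cov", agents = c(L = "L", R = "R"))
  for (i in 1:5)
    g <- kg_add_entity(g, entity_record(sprintf("d%d", i), "DISORDER",
                                        sprintf("d%d", i),
                                        attributed_to = c("L", "R")))
  cov <- coverage_report(g, "L", "R")
  expect_identical(cov$only_in_left, 0L)
  expect_identical(cov$only_in_left_pct, 0)
  expect_identical(cov$only_in_left + cov$shared, cov$left_total)
  # 202 of 524 -> 38.5 (38.549... rounds half-up to one decimal)
  g2 <- kg_new("cov2", agents = c(L = "L", R = "R"))
  for (i in 1:524)
    g2 <- kg_add_entity(g2, entity_record(
      sprintf("d%04d", i), "DISORDER", sprintf("d%04d", i),
      attributed_to = if (i <= 202) "L" else c("L", "R")))
  cov2 <- coverage_report(g2, "L", "R")
  expect_identical(cov2$left_total, 524L)
  expect_identical(cov2$only_in_left, 202L)
  expect_identical(cov2$only_in_left_pct, 38.5)
  expect_kg_error(coverage_report(g2, "L", "nope"), "UnknownAgent")
})

test_that("per-disorder overlap triples reproduce a prescribed 40/66/14 construction", {
  g <- kg_new("adams", agents = c(BDO = "BDO", Orphanet = "Orphanet"))
  g <- kg_add_entity(g, entity_record("adams_oliver", "DISORDER",
                                      "Adams-Oliver syndrome",
                                      attributed_to = c("BDO", "Orphanet")))
  hp <- sprintf("HP:%07d", 1:92)  # 14 common + 26 left-only + 52 right-only
  for (p in hp) g <- kg_add_entity(g, entity_record(p, "PHENOTYPE", p,
                                                    attributed_to = "BDO"))
  left <- hp[1:40]; right <- c(hp[1:14], hp[41:92])
  for (p in left)
    g <- kg_add_statement(g, statement("adams_oliver", "ASSOCIATED_PHENOTYPE", p,
                                       attributed_to = "BDO"))
  for (p in right)
    g <- kg_add_statement(g, statement("adams_oliver", "ASSOCIATED_PHENOTYPE", p,
                                       attributed_to = "Orphanet"))
  cov <- coverage_report(g, "BDO", "Orphanet")
  expect_identical(cov$per_disorder$left_count, 40L)
  expect_identical(cov$per_disorder$right_count, 66L)
  expect_identical(cov$per_disorder$common, 14L)
  expect_identical(unname(cov$phenotype_vocab), c(40L, 66L))
})

test_that("Holt-Oram is flagged divergent; agreeing placements are not", {
  res <- merged_wx
  div <- grouping_divergence(res$graph)
  ho <- canonical_id(res$map, "ISDS", "holt_oram_syndrome")
  rec <- div[div$disorder == ho, ]
  expect_true(rec$divergent)
  parents <- rec$parents[[1]]
  lim <- canonical_id(res$map, "ISDS", "limb_hypoplasia_reduction_defects_group")
  hh <- canonical_id(res$map, "Orphanet", "Orphanet:392")
  expect_identical(parents$ISDS, paste0("MEMBER:", lim))
  expect_identical(parents$Orphanet, paste0("BROADER_T:", hh))

  # identical parent sets under both agents -> not divergent
  g <- kg_new("agree", agents = c(A = "A", B = "B"))
  g <- kg_add_entity(g, entity_record("grp", "GROUP", "grp", attributed_to = c("A", "B")))
  g <- kg_add_entity(g, entity_record("d", "DISORDER", "d", attributed_to = c("A", "B")))
  g <- kg_add_statement(g, statement("grp", "MEMBER", "d", attributed_to = c("A", "B")))
  expect_false(grouping_divergence(g)$divergent)
})

test_that("divergence flags equal a brute-force per-agent parent comparison", {
  for (seed in 0:4) {
    fx <- generate_fixture(fixture_params(seed = seed))
    g <- kg_merge(fx$sources, fx$alignment)$graph
    div <- grouping_divergence(g)
    for (i in seq_len(nrow(div))) {
      d <- div$disorder[i]
      agents <- g$entities[[d]]$attributed_to
      sets <- lapply(agents, function(a) {
        tags <- character()
        for (s in g$statements)
          if (s$object == d && s$predicate %in% c("MEMBER", "BROADER_T") &&
              a %in% s$attributed_to)
            tags <- c(tags, paste0(s$predicate, ":", s$subject))
        sort(unique(tags))
      })
      want <- length(unique(sets)) > 1
      expect_identical(div$divergent[i], want, info = sprintf("seed %d %s", seed, d))
    }
  }
})

test_that("taxonomy depth counts edges over membership and sub-typing", {
  res <- merged_wx
  # the three-disorder Polydactyly chain alone gives depth 2 in its view
  g <- kg_new("chain", agents = c(Orphanet = "Orphanet"))
  for (x in c("p1", "p2", "p3"))
    g <- kg_add_entity(g, entity_record(x, "DISORDER", x, attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("p1", "BROADER_T", "p2", attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("p2", "BROADER_T", "p3", attributed_to = "Orphanet"))
  expect_identical(taxonomy_depth(g), 2L)
  expect_identical(taxonomy_depth(tiny_graph()), 0L)
  # mixed member+subtype path in the merged worked examples:
  # dysostosis-limb group -> Heart-hand -> Holt-Oram
  expect_gte(taxonomy_depth(res$graph, "Orphanet"), 2L)
})

test_that("taxonomy depth equals exhaustive longest-path enumeration on DAGs", {
  for (seed in 10:19) {
    dag <- random_disorder_dag(10, 0.25, seed)
    expect_identical(taxonomy_depth(dag$graph),
                     oracle_longest_path(dag$from, dag$to),
                     info = sprintf("seed %d", seed))
  }
})

test_that("adding statements never decreases taxonomy depth", {
  dag <- random_disorder_dag(8, 0.2, 99)
  g <- dag$graph
  d0 <- taxonomy_depth(g)
  set.seed(123)
  for (k in 1:5) {
    i <- sample(1:7, 1); j <- sample((i + 1):8, 1)
    g2 <- tryCatch(kg_add_statement(g, statement(sprintf("D%02d", i), "BROADER_T",
                                                 sprintf("D%02d", j),
                                                 attributed_to = "SRC")),
                   skosmerge_error = function(e) g)
    expect_gte(taxonomy_depth(g2), taxonomy_depth(g))
    g <- g2
  }
  expect_gte(taxonomy_depth(g), d0)
})
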