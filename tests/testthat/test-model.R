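# Core model semantics: entity/statement union, attribution monotonicity,
# inverse materialisation, cycle rejection, closure, the kind heuristic and
# validation.

test_that("re-adding an entity unions labels, xrefs and attribution", {
  g <- tiny_graph()
  g <- kg_add_entity(g, entity_record("ach", "DISORDER", "Achondroplasia",
                                      alt_labels = "ACH",
                                      xrefs = list(omim_id = "100800"),
                                      attributed_to = "Orphanet"))
  e <- g$entities[["ach"]]
  expect_identical(e$attributed_to, c("ISDS", "Orphanet"))
  expect_identical(e$alt_labels, "ACH")
  expect_identical(e$xrefs$omim_id, "100800")
  # idempotence: adding the identical record again changes nothing
  g2 <- kg_add_entity(g, g$entities[["ach"]])
  expect_true(kg_equal(g, g2))
  # a different preferred label is preserved as an alternative label
  g3 <- kg_add_entity(g, entity_record("ach", "DISORDER", "Achondroplasie",
                                       attributed_to = "Orphanet"))
  expect_identical(g3$entities[["ach"]]$label, "Achondroplasia")
  expect_true("Achondroplasie" %in% g3$entities[["ach"]]$alt_labels)
})

test_that("entity errors: kind clash and empty attribution", {
  g <- tiny_graph()
  expect_kg_error(kg_add_entity(g, entity_record("ach", "GROUP", "x",
                                                 attributed_to = "ISDS")),
                  "KindClash")
  expect_kg_error(entity_record("x", "DISORDER", "x",
                                attributed_to = character()),
                  "EmptyAttribution")
  expect_kg_error(kg_add_entity(g, entity_record("y", "DISORDER", "y",
                                                 attributed_to = "NotRegistered")),
                  "UnknownAgent")
})

test_that("random add sequences replay to the brute-force union fold", {
  set.seed(42)
  agents <- c(A = "A", B = "B", C = "C")
  ids <- sprintf("e%02d", 1:10)
  kind_of <- stats::setNames(rep(c("DISORDER", "GROUP"), 5), ids)
  g <- kg_new("replay", agents = agents)
  expected <- list()  # independent fold of the union semantics
  for (step in 1:50) {
    id <- sample(ids, 1)
    who <- sample(names(agents), sample(1:2, 1))
    lab <- sprintf("label-%d", sample(1:3, 1))
    rec <- entity_record(id, kind_of[[id]], lab, attributed_to = who)
    g <- kg_add_entity(g, rec)
    prev <- expected[[id]]
    if (is.null(prev)) {
      expected[[id]] <- list(label = lab, alts = character(),
                             agents = sort(unique(who)))
    } else {
      expected[[id]]$alts <- sort(unique(c(prev$alts, setdiff(lab, prev$label))))
      expected[[id]]$agents <- sort(unique(c(prev$agents, who)))
    }
  }
  expect_setequal(names(g$entities), names(expected))
  for (id in names(expected)) {
    expect_identical(g$entities[[id]]$label, expected[[id]]$label)
    expect_identical(g$entities[[id]]$alt_labels, expected[[id]]$alts)
    expect_identical(g$entities[[id]]$attributed_to, expected[[id]]$agents)
  }
})

test_that("re-adding a statement unions attribution; qualifier is part of identity", {
  g <- tiny_graph()
  g <- kg_add_statement(g, statement("ach", "ASSOCIATED_GENE", "fgfr3",
                                     attributed_to = "ISDS"))
  g <- kg_add_statement(g, statement("ach", "ASSOCIATED_GENE", "fgfr3",
                                     attributed_to = "Orphanet"))
  st <- Filter(function(s) s$predicate == "ASSOCIATED_GENE", g$statements)
  expect_length(st, 1)
  expect_identical(st[[1]]$attributed_to, c("ISDS", "Orphanet"))
  # same pair, different frequency qualifiers: two coexisting statements
  g <- kg_add_statement(g, statement("ach", "ASSOCIATED_PHENOTYPE", "HP:0000256",
                                     "VERY_FREQUENT", attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("ach", "ASSOCIATED_PHENOTYPE", "HP:0000256",
                                     attributed_to = "ISDS"))
  ph <- Filter(function(s) s$predicate == "ASSOCIATED_PHENOTYPE", g$statements)
  expect_length(ph, 2)
  expect_setequal(vapply(ph, `[[`, character(1), "qualifier"),
                  c("VERY_FREQUENT", "UNSPECIFIED"))
})

test_that("sub-typing statements materialise their inverse with identical attribution", {
  g <- tiny_graph()
  g <- kg_add_entity(g, entity_record("rt", "DISORDER", "Rubinstein-Taybi syndrome",
                                      attributed_to = "Orphanet"))
  g <- kg_add_entity(g, entity_record("rt16p", "DISORDER",
                                      "Rubinstein-Taybi due to 16p13.3 microdeletion",
                                      attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("rt", "BROADER_T", "rt16p",
                                     attributed_to = "Orphanet"))
  inv <- Filter(function(s) s$predicate == "NARROWER_T", g$statements)
  expect_length(inv, 1)
  expect_identical(inv[[1]]$subject, "rt16p")
  expect_identical(inv[[1]]$object, "rt")
  expect_identical(inv[[1]]$attributed_to, "Orphanet")
  # the inverse pairing holds with element-wise identical attribution
  expect_true(kg_validate(g)$ok)
})

test_that("statement errors: dangling endpoints, kind constraints, cycles", {
  g <- tiny_graph()
  expect_kg_error(kg_add_statement(g, statement("ach", "ASSOCIATED_GENE", "nope",
                                                attributed_to = "ISDS")),
                  "DanglingEndpoint")
  expect_kg_error(kg_add_statement(g, statement("fgfr3", "ASSOCIATED_GENE", "ach",
                                                attributed_to = "ISDS")),
                  "KindConstraint")
  # qualifier on a non-phenotype association
  expect_kg_error(kg_add_statement(g, statement("ach", "ASSOCIATED_GENE", "fgfr3",
                                                "FREQUENT", attributed_to = "ISDS")),
                  "KindConstraint")
  g <- kg_add_entity(g, entity_record("d2", "DISORDER", "d2", attributed_to = "ISDS"))
  g <- kg_add_statement(g, statement("ach", "BROADER_T", "d2", attributed_to = "ISDS"))
  expect_kg_error(kg_add_statement(g, statement("d2", "BROADER_T", "ach",
                                                attributed_to = "ISDS")),
                  "CycleIntroduced")
  # membership cycles among groups are rejected too
  g <- kg_add_entity(g, entity_record("grp2", "GROUP", "grp2", attributed_to = "ISDS"))
  g <- kg_add_statement(g, statement("grp", "MEMBER", "grp2", attributed_to = "ISDS"))
  expect_kg_error(kg_add_statement(g, statement("grp2", "MEMBER", "grp",
                                                attributed_to = "ISDS")),
                  "CycleIntroduced")
})

test_that("broader_closure covers the three-disorder chain and stays irreflexive", {
  g <- kg_new("chain", agents = c(Orphanet = "Orphanet"))
  for (x in c("polydactyly", "preaxial", "triphalangeal"))
    g <- kg_add_entity(g, entity_record(x, "DISORDER", x, attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("polydactyly", "BROADER_T", "preaxial",
                                     attributed_to = "Orphanet"))
  g <- kg_add_statement(g, statement("preaxial", "BROADER_T", "triphalangeal",
                                     attributed_to = "Orphanet"))
  cl <- broader_closure(g)
  expect_identical(nrow(cl), 3L)
  expect_true(any(cl$broader == "polydactyly" & cl$narrower == "triphalangeal"))
  expect_false(any(cl$broader == cl$narrower))
  # empty relation
  expect_identical(nrow(broader_closure(tiny_graph())), 0L)
})

test_that("broader_closure equals exhaustive reachability on random DAGs", {
  for (seed in 0:9) {
    dag <- random_disorder_dag(12, 0.2, seed)
    got <- broader_closure(dag$graph)
    want <- oracle_reachability(dag$from, dag$to)
    expect_identical(got, want, info = sprintf("seed %d", seed))
  }
})

test_that("the kind heuristic separates sub-typed disorders from mixed groups", {
  g <- kg_new("h", agents = c(Orphanet = "Orphanet"))
  add <- function(g, id, kind) kg_add_entity(g, entity_record(id, kind, id,
                                                              attributed_to = "Orphanet"))
  g <- add(g, "mesomelic", "DISORDER")
  for (x in c("korean", "kantaputra", "savarirayan")) {
    g <- add(g, x, "DISORDER")
    g <- kg_add_statement(g, statement("mesomelic", "BROADER_T", x,
                                       attributed_to = "Orphanet"))
  }
  expect_identical(classify_node_kind(g, "mesomelic"), "DISORDER")

  g <- add(g, "dysostosis", "GROUP")
  g <- add(g, "craniofacial", "GROUP")
  g <- add(g, "patellar", "GROUP")
  g <- add(g, "pseudoarthrosis", "DISORDER")
  for (x in c("craniofacial", "patellar", "pseudoarthrosis"))
    g <- kg_add_statement(g, statement("dysostosis", "MEMBER", x,
                                       attributed_to = "Orphanet"))
  expect_identical(classify_node_kind(g, "dysostosis"), "GROUP")

  # leaf keeps its declared kind; non-classifiable kinds error
  g <- add(g, "leaf", "DISORDER")
  expect_identical(classify_node_kind(g, "leaf"), "DISORDER")
  g <- add(g, "gene1", "GENE")
  expect_kg_error(classify_node_kind(g, "gene1"), "NotClassifiable")
  # never GROUP when all children are sub-typed disorders (shared-parent case
  # falls back to the declared kind)
  g <- add(g, "other_parent", "DISORDER")
  g <- kg_add_statement(g, statement("other_parent", "BROADER_T", "korean",
                                     attributed_to = "Orphanet"))
  expect_identical(classify_node_kind(g, "mesomelic"), "DISORDER")
})

test_that("validation reports forced violations from bypass-constructed graphs", {
  fx <- worked_examples_fixture()
  g <- kg_merge(fx$sources, fx$alignment)$graph
  expect_true(kg_validate(g)$ok)

  # statement with empty attribution, inserted behind the API's back
  bad <- g
  k <- names(bad$statements)[1]
  bad$statements[[k]]$attributed_to <- character()
  rep <- kg_validate(bad)
  expect_false(rep$ok)
  expect_true("EmptyAttribution" %in% rep$violations$code)

  # BROADER_T without its NARROWER_T inverse
  bad2 <- g
  keys <- names(bad2$statements)
  nkey <- keys[vapply(bad2$statements, function(s) s$predicate == "NARROWER_T",
                      logical(1))][1]
  bad2$statements[[nkey]] <- NULL
  rep2 <- kg_validate(bad2)
  expect_false(rep2$ok)
  expect_true("MissingInverse" %in% rep2$violations$code)

  # dangling endpoint
  bad3 <- g
  bad3$entities[["BD0000001"]] <- NULL
  expect_true("DanglingEndpoint" %in% kg_validate(bad3)$violations$code)
  expect_kg_error(broader_closure(bad3), "InvalidGraph")
})
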