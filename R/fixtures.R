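## Deterministic synthetic two-source fixtures and the bundled worked
## examples (real disorder/gene/phenotype names from the rare bone disorder
## domain; all numeric structure synthetic).

#' Parameters for the synthetic two-source fixture generator
#'
#' The generator emulates the structure of two expert classifications of the
#' same domain maintained in parallel: a nosology-style source (agent ISDS)
#' and an Orphanet-style source, with partially overlapping disorder sets, an
#' expert alignment covering the shared disorders, group hierarchies,
#' sub-typing chains, a shared phenotype vocabulary with a prescribed
#' per-disorder overlap, and Orphanet-side frequency qualifiers.
#'
#' @param n_disorders Integer pair: disorders per source.
#' @param n_groups Integer pair: groups per source.
#' @param frac_aligned Fraction (0-1) of the smaller disorder set covered by
#'   the expert alignment.
#' @param n_phenotype_vocab Size of the shared phenotype vocabulary.
#' @param n_genes Size of the shared gene symbol pool (aligned via AUTO rows).
#' @param assoc_range Integer pair: min/max phenotype associations per
#'   disorder.
#' @param overlap_frac Fraction of the smaller of an aligned pair's two
#'   association sets that both sources assert in common.
#' @param max_depth Maximum group-nesting depth per source.
#' @param seed Integer seed; identical parameters and seed give
#'   byte-identical bundles.
#' @return A validated `fixture_params` list.
#' @export
fixture_params <- function(n_disorders = c(24, 20), n_groups = c(6, 5),
                           frac_aligned = 0.6, n_phenotype_vocab = 60,
                           n_genes = 12, assoc_range = c(2, 6),
                           overlap_frac = 0.35, max_depth = 4, seed = 1) {
  p <- list(n_disorders = as.integer(rep_len(n_disorders, 2)),
            n_groups = as.integer(rep_len(n_groups, 2)),
            frac_aligned = as.numeric(frac_aligned),
            n_phenotype_vocab = as.integer(n_phenotype_vocab),
            n_genes = as.integer(n_genes),
            assoc_range = as.integer(rep_len(assoc_range, 2)),
            overlap_frac = as.numeric(overlap_frac),
            max_depth = as.integer(max_depth),
            seed = as.integer(seed))
  if (any(c(p$n_disorders, p$n_groups, p$n_phenotype_vocab, p$n_genes,
            p$assoc_range) < 0) ||
      p$frac_aligned < 0 || p$frac_aligned > 1 ||
      p$overlap_frac < 0 || p$overlap_frac > 1 || p$max_depth < 1 ||
      p$assoc_range[1] > p$assoc_range[2])
    kg_error("InfeasibleParams", "fixture parameters out of range")
  if (p$assoc_range[2] * 2 > p$n_phenotype_vocab)
    kg_error("InfeasibleParams",
             "phenotype vocabulary too small for the requested association counts")
  structure(p, class = "fixture_params")
}

with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(code)
}

#' Generate a deterministic synthetic two-source fixture
#'
#' Produces two source documents, the expert alignment table that links them,
#' and a manifest of ground-truth tallies (aligned pair count, per-disorder
#' phenotype overlap triples, entity counts, per-source hierarchy depth)
#' written at generation time by direct counting over the generated material,
#' independently of the analytics operations.
#'
#' @param params A [fixture_params()] object.
#' @return A `fixture_bundle`: list with `sources` (two `source_document`s),
#'   `alignment` and `manifest`.
#' @export
generate_fixture <- function(params = fixture_params()) {
  stopifnot(inherits(params, "fixture_params"))
  with_seed(params$seed, build_fixture(params))
}

build_fixture <- function(p) {
  agents <- c("ISDS", "Orphanet")
  n_al <- as.integer(round(p$frac_aligned * min(p$n_disorders)))
  # synthetic phenotype ids, offset away from the real inheritance-mode CURIEs
  hp_ids <- sprintf("HP:%07d", 100000L + seq_len(p$n_phenotype_vocab))
  gene_syms <- sprintf("GN%02d", seq_len(p$n_genes))

  # phenotype association sets with prescribed overlap, drawn once per
  # aligned concept; unaligned disorders draw freely
  draw_counts <- function() {
    if (p$assoc_range[1] == p$assoc_range[2]) return(p$assoc_range[1])
    sample(seq(p$assoc_range[1], p$assoc_range[2]), 1)
  }
  aligned_sets <- lapply(seq_len(n_al), function(k) {
    ka <- draw_counts(); kb <- draw_counts()
    cc <- as.integer(round(p$overlap_frac * min(ka, kb)))
    if (ka + kb - cc > p$n_phenotype_vocab)
      kg_error("InfeasibleParams", "overlap demands more terms than the vocabulary")
    pool <- sample(hp_ids, ka + kb - cc)
    list(common = pool[seq_len(cc)],
         a = pool[seq_len(ka)],                      # common first, then unique
         b = c(pool[seq_len(cc)], pool[ka + seq_len(kb - cc)]))
  })
  aligned_genes <- lapply(seq_len(n_al), function(k)
    sample(gene_syms, sample(1:2, 1)))

  make_source <- function(side) {
    ag <- agents[side]
    tag <- c("ISDS", "ORPHA")[side]
    nd <- p$n_disorders[side]
    ng <- p$n_groups[side]
    ents <- list()
    stmts <- list()
    add_ent <- function(id, kind, label) {
      ents[[length(ents) + 1]] <<- entity_record(id, kind, label,
                                                 attributed_to = ag)
    }
    add_stmt <- function(s, pr, o, q = NULL) {
      stmts[[length(stmts) + 1]] <<- statement(s, pr, o, q, attributed_to = ag)
    }
    gid <- function(i) sprintf("%s_G%02d", tag, i)
    did <- function(i) sprintf("%s_D%04d", tag, i)

    group_depth <- integer(ng)
    for (i in seq_len(ng)) {
      add_ent(gid(i), "GROUP", sprintf("Group-%s-%02d", tag, i))
      if (i > 1) {
        cand <- which(group_depth[seq_len(i - 1)] < p$max_depth - 1)
        if (length(cand) && stats::runif(1) < 0.7) {
          parent <- cand[sample.int(length(cand), 1)]
          add_stmt(gid(parent), "MEMBER", gid(i))
          group_depth[i] <- group_depth[parent] + 1L
        }
      }
    }
    used_hp <- character()
    used_gn <- character()
    for (i in seq_len(nd)) {
      add_ent(did(i), "DISORDER", sprintf("Disorder-%s-%04d", tag, i))
      subtype_of <- 0L
      if (i > n_al && i > 1 && stats::runif(1) < 0.25)
        subtype_of <- sample.int(i - 1, 1)  # later index under earlier: acyclic
      if (subtype_of > 0) add_stmt(did(subtype_of), "BROADER_T", did(i))
      else if (ng > 0) add_stmt(gid(sample.int(ng, 1)), "MEMBER", did(i))

      if (i <= n_al) {
        phenos <- aligned_sets[[i]][[c("a", "b")[side]]]
        genes <- aligned_genes[[i]]
      } else {
        phenos <- sample(hp_ids, draw_counts())
        genes <- sample(gene_syms, sample(1:2, 1))
      }
      for (hp in phenos) {
        q <- if (side == 2)
          sample(c("VERY_FREQUENT", "FREQUENT", "OCCASIONAL", "VERY_RARE", NA), 1)
        else NA
        add_stmt(did(i), "ASSOCIATED_PHENOTYPE", hp,
                 if (is.na(q)) NULL else q)
        used_hp <- unique(c(used_hp, hp))
      }
      for (gn in genes) {
        add_stmt(did(i), "ASSOCIATED_GENE", sprintf("%s_%s", tag, gn))
        used_gn <- unique(c(used_gn, gn))
      }
      if (stats::runif(1) < 0.3) {
        moi <- sample(c("HP:0000006", "HP:0000007"), 1)
        add_stmt(did(i), "MODE_OF_INHERITANCE", moi)
      }
    }
    for (hp in sort(unique(c(used_hp)))) add_ent(hp, "PHENOTYPE", hp)
    moi_used <- unique(vapply(Filter(function(s)
      s$predicate == "MODE_OF_INHERITANCE", stmts), `[[`, character(1), "object"))
    for (m in sort(moi_used))
      add_ent(m, "INHERITANCE_MODE",
              if (m == "HP:0000006") "Autosomal dominant inheritance"
              else "Autosomal recessive inheritance")
    for (gn in gene_syms)  # full pool in both sources so gene rows align
      add_ent(sprintf("%s_%s", tag, gn), "GENE", sprintf("Gene-%s", gn))
    structure(list(source_agent = ag, source_label = ag,
                   name = sprintf("synthetic-%s", tolower(ag)),
                   version = sprintf("seed-%d", p$seed),
                   entities = ents, statements = stmts, agent_labels = list()),
              class = "source_document")
  }

  src_a <- make_source(1)
  src_b <- make_source(2)

  rows <- list()
  for (k in seq_len(n_al))
    rows[[length(rows) + 1]] <- c("ISDS", sprintf("ISDS_D%04d", k),
                                  "Orphanet", sprintf("ORPHA_D%04d", k),
                                  "DISORDER", sprintf("aligned concept %d", k))
  if (all(p$n_groups >= 1))
    rows[[length(rows) + 1]] <- c("ISDS", "ISDS_G01", "Orphanet", "ORPHA_G01",
                                  "GROUP", "top-level group alignment")
  for (gn in gene_syms)
    rows[[length(rows) + 1]] <- c("ISDS", sprintf("ISDS_%s", gn),
                                  "Orphanet", sprintf("ORPHA_%s", gn),
                                  "AUTO", "gene symbol match")
  aln <- if (length(rows)) {
    m <- do.call(rbind, rows)
    tab <- data.frame(left_source = m[, 1], left_id = m[, 2],
                      right_source = m[, 3], right_id = m[, 4],
                      decision = m[, 5], note = m[, 6], stringsAsFactors = FALSE)
    class(tab) <- c("alignment_table", "data.frame")
    tab
  } else empty_alignment()

  manifest <- list(
    seed = p$seed,
    params = unclass(p),
    aligned_disorders = n_al,
    entity_counts = lapply(list(ISDS = src_a, Orphanet = src_b), function(doc)
      as.list(table(factor(vapply(doc$entities, `[[`, character(1), "kind"),
                           levels = ENTITY_KINDS)))),
    per_disorder_overlap = if (n_al) data.frame(
      left_id = sprintf("ISDS_D%04d", seq_len(n_al)),
      right_id = sprintf("ORPHA_D%04d", seq_len(n_al)),
      left_count = vapply(aligned_sets, function(s) length(s$a), integer(1)),
      right_count = vapply(aligned_sets, function(s) length(s$b), integer(1)),
      common = vapply(aligned_sets, function(s) length(s$common), integer(1)),
      stringsAsFactors = FALSE)
    else data.frame(left_id = character(), right_id = character(),
                    left_count = integer(), right_count = integer(),
                    common = integer(), stringsAsFactors = FALSE),
    max_depth = list(ISDS = doc_hierarchy_depth(src_a),
                     Orphanet = doc_hierarchy_depth(src_b)))

  structure(list(sources = list(src_a, src_b), alignment = aln,
                 manifest = manifest),
            class = "fixture_bundle")
}

# independent longest-path count over a document's containment statements,
# by plain recursive enumeration (ground truth for the manifest)
doc_hierarchy_depth <- function(doc) {
  edges <- Filter(function(s) s$predicate %in% c("MEMBER", "BROADER_T"),
                  doc$statements)
  if (!length(edges)) return(0L)
  from <- vapply(edges, `[[`, character(1), "subject")
  to <- vapply(edges, `[[`, character(1), "object")
  longest_from <- function(v) {
    outs <- to[from == v]
    if (!length(outs)) return(0L)
    1L + max(vapply(outs, longest_from, integer(1)))
  }
  max(vapply(unique(from), longest_from, integer(1)))
}

#' Write a fixture bundle to a directory
#'
#' Writes `source_a.json`, `source_b.json`, `alignment.tsv` and
#' `manifest.json`.
#'
#' @param bundle A `fixture_bundle`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "fixture_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_source(bundle$sources[[1]], file.path(dir, "source_a.json"))
  write_source(bundle$sources[[2]], file.path(dir, "source_b.json"))
  write_alignment(bundle$alignment, file.path(dir, "alignment.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}

#' The bundled worked-examples fixture
#'
#' A hand-written two-source bundle encoding the canonical worked examples of
#' the rare bone disorder domain: Spondyloepimetaphyseal dysplasia Maroteaux
#' type placed in the Spondylo-epi(-meta)physeal dysplasias group by Orphanet
#' and in the TRPV4 group by ISDS, with its TRPV4 gene association asserted
#' by both sources and its Genu valgum phenotype attributed to OMIM;
#' Achondroplasia with its FGFR3 association asserted by both sources;
#' the FGFR3 chondrodysplasia group with LADD syndrome placed instead in the
#' Polydactyly-Syndactyly-Triphalangism group; the Holt-Oram divergence
#' (group member on the ISDS side, sub-type of Heart-hand syndrome on the
#' Orphanet side); the three-disorder Polydactyly sub-typing chain; the
#' Rubinstein-Taybi narrower pair; the mixed Dysostosis group; and the
#' Mesomelic dysplasia sub-typing family.
#'
#' @return A `fixture_bundle`.
#' @export
worked_examples_fixture <- function() {
  ent <- function(id, kind, label, attributed_to, xrefs = list())
    entity_record(id, kind, label, xrefs = xrefs, attributed_to = attributed_to)
  stm <- function(s, p, o, attributed_to, q = NULL)
    statement(s, p, o, q, attributed_to = attributed_to)

  ## --- ISDS / BDO side (phenotype detail drawn from OMIM clinical synopses)
  A <- "ISDS"
  isds_entities <- list(
    ent("fgfr3_chondrodysplasia_group", "GROUP", "FGFR3 Chondrodysplasia Group", A),
    ent("polydactyly_syndactyly_triphalangism_group", "GROUP",
        "Polydactyly-Syndactyly-Triphalangism Group", A),
    ent("limb_hypoplasia_reduction_defects_group", "GROUP",
        "Limb hypoplasia - reduction defects Group", A),
    ent("trpv4_group", "GROUP", "TRPV4 Group", A),
    ent("sed_group", "GROUP", "Spondylo-epi(-meta)physeal dysplasias", A),
    ent("achondroplasia", "DISORDER", "Achondroplasia", A,
        xrefs = list(omim_id = "100800")),
    ent("ladd_syndrome", "DISORDER", "Lacrimo-Auriculo-Dento-Digital syndrome", A),
    ent("holt_oram_syndrome", "DISORDER", "Holt-Oram syndrome", A,
        xrefs = list(omim_id = "142900")),
    ent("sed_maroteaux", "DISORDER",
        "Spondyloepimetaphyseal dysplasia Maroteaux type", A,
        xrefs = list(omim_id = "184095")),
    ent("fgfr3", "GENE", "FGFR3", A, xrefs = list(uniprot_id = "P22607")),
    ent("trpv4", "GENE", "TRPV4", A, xrefs = list(uniprot_id = "Q9HBA0")),
    ent("HP:0000256", "PHENOTYPE", "Macrocephaly", A),
    ent("HP:0002857", "PHENOTYPE", "Genu valgum", A),
    ent("HP:0000238", "PHENOTYPE", "Hydrocephalus", A),
    ent("HP:0002938", "PHENOTYPE", "Lumbar hyperlordosis", A),
    ent("HP:0000006", "INHERITANCE_MODE", "Autosomal dominant inheritance", A))
  isds_statements <- list(
    stm("fgfr3_chondrodysplasia_group", "MEMBER", "achondroplasia", A),
    stm("polydactyly_syndactyly_triphalangism_group", "MEMBER", "ladd_syndrome", A),
    stm("limb_hypoplasia_reduction_defects_group", "MEMBER", "holt_oram_syndrome", A),
    stm("trpv4_group", "MEMBER", "sed_maroteaux", A),
    stm("achondroplasia", "ASSOCIATED_GENE", "fgfr3", A),
    stm("ladd_syndrome", "ASSOCIATED_GENE", "fgfr3", A),
    stm("sed_maroteaux", "ASSOCIATED_GENE", "trpv4", A),
    stm("achondroplasia", "ASSOCIATED_PHENOTYPE", "HP:0000256", A),
    stm("achondroplasia", "ASSOCIATED_PHENOTYPE", "HP:0000238", "OMIM"),
    stm("achondroplasia", "ASSOCIATED_PHENOTYPE", "HP:0002938", "OMIM"),
    stm("sed_maroteaux", "ASSOCIATED_PHENOTYPE", "HP:0002857", "OMIM"),
    stm("achondroplasia", "MODE_OF_INHERITANCE", "HP:0000006", A))
  src_isds <- structure(
    list(source_agent = A, source_label = "International Skeletal Dysplasia Society",
         name = "BDO/ISDS nosology excerpt", version = "2010",
         entities = isds_entities, statements = isds_statements,
         agent_labels = list(OMIM = "Online Mendelian Inheritance in Man")),
    class = "source_document")

  ## --- Orphanet side
  B <- "Orphanet"
  orpha_entities <- list(
    ent("Orphanet:93352", "GROUP", "Spondylo-epi(-meta)physeal dysplasias", B),
    ent("Orphanet:364559", "GROUP", "Dysostosis", B),
    ent("Orphanet:93453", "GROUP",
        "Dysostosis with predominant craniofacial involvement", B),
    ent("Orphanet:93455", "GROUP", "Patellar dysostosis", B),
    ent("Orphanet:dysostosis_limb", "GROUP",
        "Dysostosis with limb anomaly as a major feature", B),
    ent("Orphanet:66630", "DISORDER", "Congenital pseudoarthrosis of clavicle", B),
    ent("Orphanet:15", "DISORDER", "Achondroplasia", B),
    ent("Orphanet:392", "DISORDER", "Heart-hand syndrome", B),
    ent("Orphanet:holt_oram", "DISORDER", "Holt-Oram syndrome", B),
    ent("Orphanet:93351", "DISORDER",
        "Spondyloepimetaphyseal dysplasia, Maroteaux type", B),
    ent("Orphanet:2913", "DISORDER", "Polydactyly", B),
    ent("Orphanet:294939", "DISORDER", "Preaxial polydactyly of fingers", B),
    ent("Orphanet:93336", "DISORDER", "Polydactyly of a triphalangeal thumb", B),
    ent("Orphanet:783", "DISORDER", "Rubinstein-Taybi syndrome", B),
    ent("Orphanet:353281", "DISORDER",
        "Rubinstein-Taybi syndrome due to 16p13.3 microdeletion", B),
    ent("Orphanet:2496", "DISORDER", "Mesomelic dysplasia", B),
    ent("Orphanet:2496_korean", "DISORDER", "Mesomelic dysplasia, Korean type", B),
    ent("Orphanet:2496_kantaputra", "DISORDER",
        "Mesomelic dysplasia, Kantaputra type", B),
    ent("Orphanet:2496_savarirayan", "DISORDER",
        "Mesomelic dysplasia, Savarirayan type", B),
    ent("ORPHA_FGFR3", "GENE", "FGFR3", B),
    ent("ORPHA_TRPV4", "GENE", "TRPV4", B),
    ent("HP:0000256", "PHENOTYPE", "Macrocephaly", B))
  orpha_statements <- list(
    stm("Orphanet:93352", "MEMBER", "Orphanet:93351", B),
    stm("Orphanet:364559", "MEMBER", "Orphanet:93453", B),
    stm("Orphanet:364559", "MEMBER", "Orphanet:93455", B),
    stm("Orphanet:364559", "MEMBER", "Orphanet:66630", B),
    stm("Orphanet:dysostosis_limb", "MEMBER", "Orphanet:392", B),
    stm("Orphanet:392", "BROADER_T", "Orphanet:holt_oram", B),
    stm("Orphanet:2913", "BROADER_T", "Orphanet:294939", B),
    stm("Orphanet:294939", "BROADER_T", "Orphanet:93336", B),
    stm("Orphanet:783", "BROADER_T", "Orphanet:353281", B),
    stm("Orphanet:2496", "BROADER_T", "Orphanet:2496_korean", B),
    stm("Orphanet:2496", "BROADER_T", "Orphanet:2496_kantaputra", B),
    stm("Orphanet:2496", "BROADER_T", "Orphanet:2496_savarirayan", B),
    stm("Orphanet:15", "ASSOCIATED_GENE", "ORPHA_FGFR3", B),
    stm("Orphanet:93351", "ASSOCIATED_GENE", "ORPHA_TRPV4", B),
    stm("Orphanet:15", "ASSOCIATED_PHENOTYPE", "HP:0000256", B,
        q = "VERY_FREQUENT"))
  src_orpha <- structure(
    list(source_agent = B, source_label = "Orphanet",
         name = "Orphanet rare bone disorder classification excerpt",
         version = "2014-05",
         entities = orpha_entities, statements = orpha_statements,
         agent_labels = list()),
    class = "source_document")

  rows <- rbind(
    c("ISDS", "achondroplasia", "Orphanet", "Orphanet:15", "DISORDER", ""),
    c("ISDS", "holt_oram_syndrome", "Orphanet", "Orphanet:holt_oram", "DISORDER", ""),
    c("ISDS", "sed_maroteaux", "Orphanet", "Orphanet:93351", "DISORDER", ""),
    c("ISDS", "sed_group", "Orphanet", "Orphanet:93352", "GROUP", ""),
    c("ISDS", "fgfr3", "Orphanet", "ORPHA_FGFR3", "AUTO", "gene symbol match"),
    c("ISDS", "trpv4", "Orphanet", "ORPHA_TRPV4", "AUTO", "gene symbol match"))
  aln <- data.frame(left_source = rows[, 1], left_id = rows[, 2],
                    right_source = rows[, 3], right_id = rows[, 4],
                    decision = rows[, 5], note = rows[, 6],
                    stringsAsFactors = FALSE)
  class(aln) <- c("alignment_table", "data.frame")

  manifest <- list(
    aligned_disorders = 3L,
    aligned_groups = 1L,
    aligned_genes = 2L,
    entity_counts = lapply(list(ISDS = src_isds, Orphanet = src_orpha),
                           function(doc)
                             as.list(table(factor(
                               vapply(doc$entities, `[[`, character(1), "kind"),
                               levels = ENTITY_KINDS)))),
    max_depth = list(ISDS = doc_hierarchy_depth(src_isds),
                     Orphanet = doc_hierarchy_depth(src_orpha)))

  structure(list(sources = list(src_isds, src_orpha), alignment = aln,
                 manifest = manifest),
            class = "fixture_bundle")
}

#' @export
print.fixture_bundle <- function(x, ...) {
  cat(sprintf("<fixture_bundle: sources %s; %d alignment rows>\n",
              paste(vapply(x$sources, `[[`, character(1), "source_agent"),
                    collapse = " + "),
              nrow(x$alignment)))
  invisible(x)
}
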