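# Minimal hand fixture: one enriched miRNA, two associated genes, one
# significant pathway containing both genes.
network_fixture <- function() {
  mirna_de <- apply_de_filter(
    make_de_table("mir-01", 2.0, p_raw = 0.001), 1.5, 0.05, "raw")
  mrna_de <- apply_de_filter(
    make_de_table(c("G1", "G2", "G3"), c(-1.8, -1.6, 1.7),
                  p_raw = rep(0.001, 3)), 1.5, 0.05, "adjusted")
  ir <- structure(list(
    associations = data.frame(
      set_feature = "mir-01", partner = c("G1", "G2"),
      set_stream = "up", p_nominal = 0.01, fdr_q = 0.1,
      set_feature_fc = 2.0, partner_fc = c(-1.8, -1.6),
      stringsAsFactors = FALSE),
    direction = "mrna_ranked"), class = "integration_result")
  sets <- gene_set_collection(list(PW_apoptosis = c("G1", "G2", "G3")))
  pathway_results <- data.frame(set_name = "PW_apoptosis", size = 3,
                                es = 0.9, nes = 2, p_nominal = 0.001,
                                fdr_q = 0.01, significant = TRUE,
                                stringsAsFactors = FALSE)
  list(ir = ir, sets = sets, pathway_results = pathway_results,
       mirna_de = mirna_de, mrna_de = mrna_de)
}

test_that("annotation records the overlap of enriched targets with
           significant-pathway DE genes", {
  fx <- network_fixture()
  ann <- annotate_mirnas(fx$ir, fx$pathway_results, fx$mrna_de, fx$sets)
  expect_equal(nrow(ann), 1)
  expect_identical(ann$mirna_id, "mir-01")
  expect_identical(ann$overlap_genes, "G1,G2")
  expect_identical(ann$category, "Apoptosis")
  # no significant pathway -> no records
  none <- fx$pathway_results; none$significant <- FALSE
  expect_equal(nrow(annotate_mirnas(fx$ir, none, fx$mrna_de, fx$sets)),
               0)
})

test_that("annotation equals a brute-force triple loop on random
           instances", {
  set.seed(81)
  for (rep in 1:5) {
    mir_ids <- sprintf("m%d", 1:4)
    gene_ids <- sprintf("G%02d", 1:30)
    fc_g <- 2^runif(30, 0.7, 2) * sample(c(1, -1), 30, TRUE)
    mrna_de <- apply_de_filter(
      make_de_table(gene_ids, fc_g,
                    p_raw = ifelse(runif(30) < 0.7, 0.001, 0.5)),
      1.5, 0.05, "adjusted")
    assoc <- data.frame(
      set_feature = sample(mir_ids, 25, TRUE),
      partner = sample(gene_ids, 25, TRUE), set_stream = "up",
      p_nominal = 0.01, fdr_q = 0.1, set_feature_fc = 2,
      partner_fc = 1.5, stringsAsFactors = FALSE)
    assoc <- assoc[!duplicated(paste(assoc$set_feature,
                                     assoc$partner)), ]
    ir <- structure(list(associations = assoc,
                         direction = "mrna_ranked"),
                    class = "integration_result")
    sets <- gene_set_collection(stats::setNames(
      lapply(1:5, function(i) sample(gene_ids, 8)),
      sprintf("PW%d", 1:5)))
    pres <- data.frame(set_name = names(sets),
                       significant = runif(5) < 0.6,
                       stringsAsFactors = FALSE)
    ann <- annotate_mirnas(ir, pres, mrna_de, sets)
    de_genes <- mrna_de$feature_id[mrna_de$direction != "ns"]
    for (mir in mir_ids) for (pw in pres$set_name[pres$significant]) {
      tg <- assoc$partner[assoc$set_feature == mir]
      ov <- intersect(tg, intersect(sets[[pw]], de_genes))
      row <- ann[ann$mirna_id == mir & ann$pathway_name == pw, ]
      if (length(ov)) {
        expect_equal(nrow(row), 1)
        expect_identical(row$overlap_genes,
                         paste(sort(ov), collapse = ","))
      } else {
        expect_equal(nrow(row), 0)
      }
    }
  }
})

test_that("the fixture network has the expected nodes, edges and
           fold-change weights", {
  fx <- network_fixture()
  ann <- annotate_mirnas(fx$ir, fx$pathway_results, fx$mrna_de, fx$sets)
  g <- build_network(fx$ir, ann, fx$mirna_de, fx$mrna_de)
  expect_equal(igraph::vcount(g), 4)  # 1 miRNA + 2 genes + 1 pathway
  expect_equal(igraph::ecount(g), 4)  # 2 targets + 2 member_of
  ef <- mimir:::edge_frame(g)
  tg <- ef[ef$type == "targets", ]
  expect_identical(sort(tg$target), c("G1", "G2"))
  expect_equal(tg$weight, c(2, 2))    # miRNA's signed FC on both edges
  mo <- ef[ef$type == "member_of", ]
  expect_equal(sort(mo$weight), c(-1.8, -1.6))  # each gene's own FC
  # bipartite discipline and no orphan nodes
  vtype <- igraph::V(g)$type
  names(vtype) <- igraph::V(g)$name
  expect_true(all(vtype[tg$source] == "mirna" &
                    vtype[tg$target] == "gene"))
  expect_true(all(vtype[mo$source] == "gene" &
                    vtype[mo$target] == "pathway"))
  expect_equal(sum(igraph::degree(g) == 0), 0)
  # every annotation is reachable as a miRNA -> gene -> pathway path
  d <- igraph::distances(g, v = "mir-01", to = "PW_apoptosis",
                         mode = "out")
  expect_true(is.finite(d[1, 1]))
})

test_that("missing fold changes for referenced nodes are an error", {
  fx <- network_fixture()
  ann <- annotate_mirnas(fx$ir, fx$pathway_results, fx$mrna_de, fx$sets)
  short_de <- fx$mrna_de[fx$mrna_de$feature_id != "G2", ]
  expect_error(build_network(fx$ir, ann, fx$mirna_de, short_de), "G2")
})

test_that("SIF export writes one relation line per edge plus a weight
           table", {
  fx <- network_fixture()
  g <- build_network(fx$ir,
                     annotate_mirnas(fx$ir, fx$pathway_results,
                                     fx$mrna_de, fx$sets),
                     fx$mirna_de, fx$mrna_de)
  p <- withr::local_tempfile(fileext = ".sif")
  export_network(g, p, "sif")
  lines <- readLines(p)
  expect_length(lines, 4)
  expect_true("mir-01\ttargets\tG1" %in% lines)
  attrs <- readLines(paste0(p, ".attrs.tsv"))
  expect_identical(attrs[1], "edge\tweight")
  expect_length(attrs, 5)
  expect_error(export_network(g, p, "dot"), "unknown network format")
})

test_that("GraphML export is well-formed XML that igraph reads back", {
  fx <- network_fixture()
  g <- build_network(fx$ir,
                     annotate_mirnas(fx$ir, fx$pathway_results,
                                     fx$mrna_de, fx$sets),
                     fx$mirna_de, fx$mrna_de)
  p <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, p, "graphml")
  doc <- xml2::read_xml(p)   # parse failure would error
  expect_identical(xml2::xml_name(doc), "graphml")
  back <- igraph::read_graph(p, format = "graphml")
  expect_equal(igraph::vcount(back), igraph::vcount(g))
  expect_equal(igraph::ecount(back), igraph::ecount(g))
  expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
})

test_that("edge_tsv exports round-trip to an isomorphic network", {
  set.seed(91)
  for (rep in 1:5) {
    mir_ids <- sprintf("m%d", 1:3)
    gene_ids <- sprintf("G%02d", 1:12)
    assoc <- unique(data.frame(
      set_feature = sample(mir_ids, 15, TRUE),
      partner = sample(gene_ids, 15, TRUE), set_stream = "up",
      p_nominal = 0.01, fdr_q = 0.1, set_feature_fc = 2,
      partner_fc = 1.5, stringsAsFactors = FALSE))
    ir <- structure(list(associations = assoc,
                         direction = "mrna_ranked"),
                    class = "integration_result")
    mirna_de <- make_de_table(mir_ids, c(2, -1.7, 1.6),
                              p_raw = rep(0.001, 3))
    mrna_de <- make_de_table(gene_ids,
                             2^runif(12, 0.7, 2) *
                               sample(c(1, -1), 12, TRUE),
                             p_raw = rep(0.001, 12))
    g <- build_network(ir, annotate_mirnas(
      ir, data.frame(set_name = character(0),
                     significant = logical(0)),
      apply_de_filter(mrna_de, 1.5, 0.05, "adjusted"),
      gene_set_collection(list(PW = gene_ids))),
      mirna_de, mrna_de)
    p <- withr::local_tempfile(fileext = ".tsv")
    export_network(g, p, "edge_tsv")
    back <- import_network_tsv(p)
    expect_true(igraph::isomorphic(g, back))
    expect_setequal(igraph::V(back)$name, igraph::V(g)$name)
    expect_equal(sort(igraph::E(back)$weight),
                 sort(igraph::E(g)$weight))
  }
})
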