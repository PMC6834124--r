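test_that("event tables load with merged nodes and temporal edges", {
  f <- withr::local_tempfile(lines = c(
    "gene\tstage\tvariant_type\tantecedent_of",
    "APC\tearly\tmutation\tTP53",
    "APC\tearly\tLOH\t",
    "KRAS\tearly;late\tmutation\t"))
  net <- load_event_table(f)
  expect_equal(nrow(net$nodes), 3L)  # APC, KRAS + linked TP53
  apc <- net$nodes[net$nodes$gene == "APC", ]
  expect_setequal(strsplit(apc$variant_types, ";")[[1]], c("mutation", "LOH"))
  expect_true(apc$is_target)
  expect_equal(net$edges$antecedent, "APC")
  expect_equal(net$edges$subsequent, "TP53")
  tp53 <- net$nodes[net$nodes$gene == "TP53", ]
  expect_equal(tp53$stages, "")     # link-only gene, empty stage set
  expect_false(tp53$is_target)
})

test_that("unknown vocabulary tokens are rejected with the valid list", {
  f <- withr::local_tempfile(lines = c(
    "gene\tstage\tvariant_type\tantecedent_of",
    "APC\tbanana\tmutation\t"))
  expect_error(load_event_table(f), "banana.*valid stages.*metastatic")
  f2 <- withr::local_tempfile(lines = c(
    "gene\tstage\tvariant_type\tantecedent_of",
    "APC\tearly\tfrobnication\t"))
  expect_error(load_event_table(f2), "frobnication.*valid variant")
})

test_that("stage queries reproduce the staging facts", {
  f <- write_event_fixture(withr::local_tempfile())
  net <- load_event_table(f)
  expect_setequal(stage_of("APC", net$nodes), "early")
  expect_setequal(stage_of("GNAS", net$nodes), "metastatic")
  expect_setequal(stage_of("KRAS", net$nodes),
                  c("early", "late", "drug-resistance"))
  expect_setequal(stage_of("EGFR", net$nodes),
                  c("drug-induced", "drug-resistance"))
  expect_error(stage_of("NOPE", net$nodes), "unknown gene")
})

test_that("temporal paths follow the antecedent chains", {
  f <- write_event_fixture(withr::local_tempfile())
  net <- load_event_table(f)
  expect_equal(temporal_path("APC", "TCF7L2", net$edges),
               c("APC", "TP53", "TCF7L2"))
  expect_equal(temporal_path("CASP8", "PIK3CA", net$edges),
               c("CASP8", "KRAS", "PIK3CA"))
  expect_equal(temporal_path("APC", "APC", net$edges), "APC")
  expect_null(temporal_path("GNAS", "APC", net$edges))
  # every consecutive pair on a returned path is a real edge
  p <- temporal_path("APC", "TCF7L2", net$edges)
  for (i in seq_len(length(p) - 1)) {
    expect_true(any(net$edges$antecedent == p[i] &
                      net$edges$subsequent == p[i + 1]))
  }
})

test_that("edge composition percentages are exact and sum to 100", {
  e <- data.frame(gene_a = c("a", "b", "c", "d"),
                  gene_b = c("b", "c", "d", "a"),
                  kind = c("genetic", "genetic", "physical", "co-expression"),
                  weight = 1)
  comp <- edge_composition(e)
  expect_equal(unname(comp["genetic"]), 50)
  expect_equal(unname(comp["physical"]), 25)
  expect_equal(unname(comp["co-expression"]), 25)
  single <- edge_composition(data.frame(gene_a = "x", gene_b = "y",
                                        kind = "pathway", weight = 7))
  expect_equal(unname(single), 100)
  # weighted fixture with the published composition shape
  w <- data.frame(
    gene_a = letters[1:6], gene_b = letters[7:12],
    kind = c("genetic", "shared-domain", "physical", "co-expression",
             "pathway", "predicted"),
    weight = c(4383, 2628, 1423, 1014, 389, 163))
  cw <- edge_composition(w)
  expect_equal(unname(cw[c("genetic", "shared-domain", "physical",
                           "co-expression", "pathway", "predicted")]),
               c(43.83, 26.28, 14.23, 10.14, 3.89, 1.63))
  # random edge lists always sum to 100
  set.seed(10)
  for (i in 1:20) {
    re <- data.frame(gene_a = "x", gene_b = "y",
                     kind = sample(c("genetic", "physical", "pathway"),
                                   sample(2:20, 1), TRUE),
                     weight = runif(1))
    re$weight <- runif(nrow(re), 0.1, 10)
    expect_equal(sum(edge_composition(re)), 100, tolerance = 1e-9)
  }
  expect_error(edge_composition(e[0, ]), "empty")
})

test_that("edge lists validate their interaction vocabulary", {
  f <- withr::local_tempfile(lines = c(
    "gene_a\tgene_b\tkind\tweight",
    "APC\tKRAS\ttelepathy\t1"))
  expect_error(load_edge_list(f), "telepathy.*valid kinds")
  f2 <- withr::local_tempfile(lines = c(
    "gene_a\tgene_b\tkind",
    "APC\tKRAS\tgenetic"))
  e <- load_edge_list(f2)
  expect_equal(e$weight, 1)  # default weight
})

test_that("networks export to SIF and round-trip through GraphML", {
  f <- write_event_fixture(withr::local_tempfile())
  net <- load_event_table(f)
  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "SIF")
  lines <- readLines(sif)
  expect_true("APC\tantecedent_of\tTP53" %in% lines)
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "GraphML")
  back <- import_network(gml)
  expect_setequal(back$nodes$gene, net$nodes$gene)
  for (g in net$nodes$gene) {
    expect_identical(back$nodes$stages[back$nodes$gene == g],
                     net$nodes$stages[net$nodes$gene == g])
  }
  key <- function(e) sort(paste(e$antecedent, e$subsequent))
  expect_identical(key(back$edges), key(net$edges))
  expect_error(export_network(list(nodes = net$nodes[0, ],
                                   edges = net$edges), sif, "SIF"),
               "empty node set")
})
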