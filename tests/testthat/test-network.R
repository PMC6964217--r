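mk_records <- function(ids, diseases, biomarker = FALSE, class = "miRNA") {
  data.frame(ncrna_id = ids, ncrna_class = class, disease = diseases,
             biomarker = biomarker, direction = "up", pmid = "",
             sample_note = "", stringsAsFactors = FALSE)
}

test_that("bipartite construction counts nodes and edges by unique pairs", {
  rec <- mk_records(c("m1", "m2", "m3", "m4", "m1"),
                    c("Stroke", "Stroke", "Heart failure", "Heart failure", "Heart failure"))
  net <- build_bipartite(rec)
  s <- network_summary(net)
  expect_equal(s$n_phenotypes, 2L)
  expect_equal(s$n_ncrnas, 4L)
  expect_equal(s$n_edges, 5L)
  # a miRNA listed with 12 diseases has degree 12
  hub <- mk_records(rep("miR-146a-5p", 12), default_disease_catalog()$labels[1:12])
  dd <- degree_distribution(build_bipartite(hub), "genotype")
  expect_equal(unname(dd$degrees["miR-146a-5p"]), 12L)
  # a triplicated association still yields one edge
  tri <- mk_records(rep("m1", 3), rep("Stroke", 3))
  expect_equal(network_summary(build_bipartite(tri))$n_edges, 1L)
  expect_warning(build_bipartite(rec[0, ]), "empty")
})

test_that("degree distributions normalize correctly on both sides", {
  rec <- mk_records(c("a", "b", "c", "d", "d", "d"),
                    c("Stroke", "Stroke", "Stroke",
                      "Stroke", "Heart failure", "Cardiomyopathy"))
  dd <- degree_distribution(build_bipartite(rec), "genotype")
  expect_equal(dd$pk, c("1" = 0.75, "3" = 0.25))
  expect_equal(sum(dd$pk), 1, tolerance = 1e-12)
  # star network: 1 disease, n miRNAs
  star <- mk_records(paste0("m", 1:7), rep("Stroke", 7))
  net <- build_bipartite(star)
  expect_true(all(degree_distribution(net, "genotype")$degrees == 1L))
  expect_equal(unname(degree_distribution(net, "phenotype")$degrees), 7L)
})

test_that("handshake property and record-order invariance hold on random networks", {
  for (seed in 1:5) {
    sim <- generate_study_data(synthetic_config(seed = seed, n_mirna = 60,
                                                n_lncrna = 10, n_circrna = 3,
                                                gene_pool_size = 50))
    net <- build_bipartite(sim$associations, "miRNA")
    dg <- degree_distribution(net, "genotype")$degrees
    dp <- degree_distribution(net, "phenotype")$degrees
    expect_equal(sum(dg), network_summary(net)$n_edges)
    expect_equal(sum(dp), sum(dg))
    shuf <- sim$associations[sample(nrow(sim$associations)), ]
    net2 <- build_bipartite(shuf, "miRNA")
    expect_true(igraph::identical_graphs(
      igraph::permute(net$graph, match(igraph::V(net$graph)$name,
                                       igraph::V(net2$graph)$name)),
      net2$graph) ||
      setequal(apply(igraph::as_edgelist(net$graph), 1, paste, collapse = "|"),
               apply(igraph::as_edgelist(net2$graph), 1, paste, collapse = "|")))
  }
})

test_that("ternary networks carry typed edges and split multi-mRNA cells", {
  tn <- build_ternary(read_ternary_table())
  expect_equal(unname(tn$pair_counts), c(14L, 3L))
  deg_nov <- igraph::degree(tn$graph, "novlnc6")
  expect_equal(unname(deg_nov), 3L)
  # edge count = |triples| + per-split mRNA edges
  tt <- read_ternary_table()
  n_mrna_edges <- length(unique(unlist(lapply(
    which(!is.na(tt$mrna)),
    function(i) paste(tt$mirna_id[i], strsplit(tt$mrna[i], "/")[[1]])))))
  expect_equal(igraph::ecount(tn$graph), nrow(tt) + n_mrna_edges)
  # no miRNA-mRNA edge for an NA sentinel
  one <- tt[tt$sponge_id == "APPAT", ]
  g1 <- build_ternary(one)$graph
  expect_equal(igraph::ecount(g1), 1L)
  expect_setequal(igraph::V(g1)$kind, c("sponge", "miRNA"))
})

test_that("network exports round-trip through edge_tsv, graphml and sif", {
  rec <- mk_records(c("m1", "m1", "m2", "m3", "m3"),
                    c("Stroke", "Heart failure", "Stroke",
                      "Cardiomyopathy", "Stroke"), biomarker = TRUE)
  net <- build_bipartite(rec)
  sif <- tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), 5L)

  etsv <- tempfile(fileext = ".tsv")
  export_network(net, etsv, "edge_tsv")
  back <- import_edge_tsv(etsv)
  orig <- igraph::as_data_frame(net$graph, "edges")
  expect_setequal(paste(back$from, back$to), paste(orig$from, orig$to))

  gml <- tempfile(fileext = ".graphml")
  tn <- build_ternary(read_ternary_table())
  export_network(tn, gml, "graphml")
  g2 <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(unique(igraph::V(g2)$kind), c("sponge", "miRNA", "mRNA"))
  expect_equal(igraph::ecount(g2), igraph::ecount(tn$graph))
  expect_setequal(igraph::V(g2)$name, igraph::V(tn$graph)$name)
  expect_error(export_network(net, tempfile(), "dot"))
})

test_that("generated 400-node networks have power-law-like heavy tails", {
  maxk <- vapply(1:50, function(seed) {
    sim <- generate_study_data(synthetic_config(
      seed = seed, n_mirna = 400, n_lncrna = 1, n_circrna = 1,
      gamma_target = 2.5, gene_pool_size = 20,
      mean_targets_universal = 2, mean_targets_specific = 1, n_gmt_sets = 1))
    dd <- degree_distribution(build_bipartite(sim$associations, "miRNA"))
    c(max(dd$degrees), as.integer(names(which.max(dd$histogram))))
  }, integer(2))
  expect_true(all(maxk[1, ] > 5L))          # heavy tail present in every draw
  expect_true(all(maxk[2, ] == 1L))         # mass concentrated at k = 1
})
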