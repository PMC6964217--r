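mk_net <- function(degrees, biomarker = NULL) {
  ids <- names(degrees)
  if (is.null(biomarker)) biomarker <- rep(FALSE, length(ids))
  dis <- default_disease_catalog()$labels
  rec <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(ncrna_id = ids[i], ncrna_class = "miRNA",
               disease = dis[seq_len(degrees[i])], biomarker = biomarker[i],
               direction = "up", pmid = "", sample_note = "",
               stringsAsFactors = FALSE)
  }))
  build_bipartite(rec)
}

test_that("the degree-2 threshold partitions universal from specific miRNAs", {
  net <- mk_net(c("miR-146a-5p" = 12L, "let-7b-3p" = 1L, "m3" = 2L, "m4" = 3L, "m5" = 1L))
  p <- partition_by_degree(net)
  expect_setequal(p$universal, c("miR-146a-5p", "m3", "m4"))
  expect_setequal(p$specific, c("let-7b-3p", "m5"))
  expect_equal(length(p$universal) + length(p$specific),
               network_summary(net)$n_ncrnas)
  expect_true(all(p$degree_map[p$universal] >= 2L))
  expect_true(all(p$degree_map[p$specific] == 1L))
})

test_that("fisher_exact matches the enumeration oracle and reference values", {
  expect_equal(fisher_exact(matrix(c(5, 0, 0, 5), 2, 2, byrow = TRUE))$p_value,
               2 / 252, tolerance = 1e-12)
  expect_equal(fisher_exact(matrix(c(1, 1, 1, 1), 2, 2))$p_value, 1)
  set.seed(9)
  for (i in 1:200) {
    m <- matrix(rpois(4, 6) + c(1, 0, 0, 1), 2, 2)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    ours <- fisher_exact(m)$p_value
    expect_equal(ours, fisher_oracle(m[1, 1], m[1, 2], m[2, 1], m[2, 2]),
                 tolerance = 1e-12)
    expect_equal(ours, stats::fisher.test(m)$p.value, tolerance = 1e-9)
  }
  expect_error(fisher_exact(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)), "margin")
})

test_that("one-sided Fisher tails and the Haldane odds-ratio correction behave", {
  m <- matrix(c(8, 2, 3, 7), 2, 2, byrow = TRUE)
  g <- fisher_exact(m, "greater")$p_value
  l <- fisher_exact(m, "less")$p_value
  expect_equal(g, sum(dhyper(8:10, 10, 10, 11)), tolerance = 1e-12)
  expect_gt(l, g)
  orz <- fisher_exact(matrix(c(5, 0, 2, 5), 2, 2, byrow = TRUE))$odds_ratio
  expect_equal(orz, (5.5 * 5.5) / (0.5 * 2.5), tolerance = 1e-12)
})

test_that("the reconstructed published contingency table is strongly significant", {
  # 175 universal at 90.3% and 251 specific at 59.4% biomarkers
  tab <- matrix(c(158, 17, 149, 102), 2, 2, byrow = TRUE)
  p <- fisher_exact(tab)$p_value
  expect_equal(p, fisher_oracle(158, 17, 149, 102), tolerance = 1e-12)
  expect_lt(p, 1e-10)  # regression fixture: far below 0.05
})

test_that("the permutation class test is valid, extreme-case tight and reproducible", {
  set.seed(101)
  deg <- setNames(c(rep(2L, 12), rep(1L, 12)), sprintf("m%02d", 1:24))
  net <- mk_net(deg)
  part <- partition_by_degree(net)
  flags <- setNames(c(rep(TRUE, 12), rep(FALSE, 12)), names(deg))
  r <- permutation_class_test(flags, part, n_perm = 999, seed = 1)
  expect_lte(r$p_value, 0.01)
  expect_equal(r$observed, 1)
  r2 <- permutation_class_test(flags, part, n_perm = 999, seed = 1)
  expect_identical(r$p_value, r2$p_value)
  expect_error(permutation_class_test(flags, part, n_perm = 0), "n_perm")
  empty <- structure(list(universal = character(), specific = names(deg),
                          degree_map = deg), class = "pg_partition")
  expect_error(permutation_class_test(flags, empty, 99), "non-empty")
})

test_that("target coverage is exact set arithmetic and monotone", {
  tg <- data.frame(mirna_id = c("m1", "m1", "m2"), gene = c("G1", "G2", "G1"),
                   source = "x", stringsAsFactors = FALSE)
  class(tg) <- c("pg_targets", "data.frame")
  cov <- target_coverage(c("m1", "m2"), tg)
  expect_equal(cov$n_genes, 2L)
  expect_equal(cov$n_interactions, 3L)
  expect_equal(target_coverage("m9", tg)$n_genes, 0L)
  # brute-force recount on a random table + monotonicity under growth
  set.seed(33)
  big <- data.frame(mirna_id = sprintf("m%d", sample(8, 300, TRUE)),
                    gene = sprintf("G%d", sample(40, 300, TRUE)), source = "x")
  big <- big[!duplicated(big[1:2]), ]
  class(big) <- c("pg_targets", "data.frame")
  cls <- c("m1", "m3", "m5")
  ref_pairs <- big[big$mirna_id %in% cls, ]
  got <- target_coverage(cls, big)
  expect_equal(got$n_interactions, nrow(ref_pairs))
  expect_equal(got$n_genes, length(unique(ref_pairs$gene)))
  grown <- rbind(as.data.frame(big), data.frame(mirna_id = "m1", gene = "GNEW", source = "x"))
  class(grown) <- c("pg_targets", "data.frame")
  got2 <- target_coverage(cls, grown)
  expect_gte(got2$n_genes, got$n_genes)
  expect_gte(got2$n_interactions, got$n_interactions)
})

test_that("essential-gene ratios reproduce the reference proportion", {
  genes <- sprintf("G%04d", 1:5445)
  essential <- genes[1:3146]
  expect_equal(round(essential_ratio(genes, essential), 3), 0.578)
  expect_equal(essential_ratio(c("A", "B"), c("C", "D")), 0)
  expect_equal(essential_ratio(c("A", "B"), c("A", "B", "C")), 1)
  expect_error(essential_ratio(character(), "A"), "non-empty")
})

test_that("class_contrast assembles a coherent report on synthetic data", {
  sim <- generate_study_data(synthetic_config(seed = 12, n_mirna = 120,
                                              gene_pool_size = 400,
                                              mean_targets_universal = 20,
                                              mean_targets_specific = 8))
  net <- build_bipartite(sim$associations, "miRNA")
  ct <- class_contrast(net, sim$targets, sim$essential, n_perm = 499, seed = 1)
  expect_equal(ct$n_universal + ct$n_specific, 120L)
  expect_true(all(ct$biomarker_rate >= 0 & ct$biomarker_rate <= 1))
  expect_true(all(c(ct$p_fisher, ct$p_chi2, ct$p_perm) >= 0 &
                  c(ct$p_fisher, ct$p_chi2, ct$p_perm) <= 1))
  # universal miRNAs were generated with more targets per miRNA
  expect_gt(ct$targets_per_class$universal$n_interactions / ct$n_universal,
            ct$targets_per_class$specific$n_interactions / ct$n_specific)
  expect_true(all(abs(ct$essential_ratio - 0.55) < 0.1))
})
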