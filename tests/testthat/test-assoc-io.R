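test_that("miRNA name normalization applies the rewrite rules and is idempotent", {
  cases <- c("hsa-miR-146a-5p" = "miR-146a-5p",
             "miR-21-5p"       = "miR-21-5p",
             "HSA-LET-7B-3P"   = "let-7b-3p",
             "MIR-21"          = "miR-21",
             "LET-7B"          = "let-7b",
             "hsa-let-7i"      = "let-7i",
             "miR-133a"        = "miR-133a")
  expect_identical(normalize_mirna_name(names(cases)), unname(cases))
  # idempotence over a randomized alphabet of plausible raw spellings
  set.seed(11)
  raw <- paste0(sample(c("", "hsa-", "HSA-"), 50, TRUE),
                sample(c("miR", "MIR", "mir", "let", "LET"), 50, TRUE), "-",
                sample(c("21", "146A", "7b", "105", "30C"), 50, TRUE),
                sample(c("", "-5p", "-3P"), 50, TRUE))
  once <- normalize_mirna_name(raw)
  expect_identical(normalize_mirna_name(once), once)
  expect_error(normalize_mirna_name(""), "non-empty")
})

test_that("disease labels are merged through the catalog and duplicates collapse", {
  p <- write_assoc_fixture(list(
    assoc_row("miR-21-5p", disease = "Acute heart failure", biomarker = 1, direction = "up"),
    assoc_row("miR-21-5p", disease = "Heart failure", biomarker = 0, direction = "down"),
    assoc_row("H19", "lncRNA", disease = "Myocardial infarction")))
  rec <- read_associations(p)
  expect_equal(nrow(rec), 2L)
  r21 <- rec[rec$ncrna_id == "miR-21-5p", ]
  expect_identical(r21$disease, "Heart failure")
  expect_true(r21$biomarker)            # OR over duplicates
  expect_identical(r21$direction, "mixed")  # conflicting directions
})

test_that("deduplication count matches brute-force distinct-pair construction", {
  set.seed(5)
  ids <- sprintf("miR-%d", sample(40, 100, TRUE))
  dis <- sample(default_disease_catalog()$labels, 100, TRUE)
  # plant 10 exact duplicates of existing rows
  dup <- sample(90, 10)
  ids <- c(ids[1:90], ids[dup]); dis <- c(dis[1:90], dis[dup])
  p <- write_assoc_fixture(mapply(function(i, d) assoc_row(i, disease = d),
                                  ids, dis, SIMPLIFY = FALSE))
  rec <- read_associations(p)
  expect_equal(nrow(rec), length(unique(paste(normalize_mirna_name(ids), dis))))
  expect_lte(nrow(rec), 100L)  # dedup never increases the count
})

test_that("association reader validates schema, classes and disease labels", {
  p <- tempfile(); writeLines("ncrna_id\tdisease", p)
  expect_error(read_associations(p), "missing required column")
  p2 <- write_assoc_fixture(list(assoc_row("x1", "weirdRNA", disease = "Stroke")))
  expect_error(read_associations(p2), "unknown ncrna_class")
  p3 <- write_assoc_fixture(list(assoc_row("miR-1", disease = "Not a disease")))
  expect_error(read_associations(p3), "Not a disease")
  # empty data section with a valid header
  p4 <- tempfile()
  writeLines(paste(c("ncrna_id", "ncrna_class", "disease", "biomarker",
                     "direction", "pmid", "sample_note"), collapse = "\t"), p4)
  expect_equal(nrow(read_associations(p4)), 0L)
})

test_that("write/read round trip preserves the record set", {
  sim <- generate_study_data(synthetic_config(seed = 3, n_mirna = 30,
                                              n_lncrna = 5, n_circrna = 2,
                                              gene_pool_size = 50))
  p <- tempfile(fileext = ".tsv")
  write_associations(sim$associations, p)
  back <- read_associations(p)
  ord <- function(d) d[order(d$ncrna_id, d$disease),
                       c("ncrna_id", "ncrna_class", "disease", "biomarker")]
  expect_equal(ord(as.data.frame(back)), ord(as.data.frame(sim$associations)),
               ignore_attr = TRUE)
})

test_that("GMT parsing upper-cases, dedupes and rejects short lines", {
  p <- tempfile(fileext = ".gmt")
  writeLines(c("SET_A\tdesc\tTP53\tMDM2", "P53SIG\tdesc\tTP53\ttp53\tMDM2"), p)
  g <- read_gmt(p)
  expect_length(g, 2L)
  expect_setequal(g$P53SIG$genes, c("TP53", "MDM2"))
  writeLines(c("ONLY_A_NAME"), p)
  expect_error(read_gmt(p), "line 1")
})

test_that("the packaged ternary table parses to the published section counts", {
  tt <- read_ternary_table()
  expect_equal(nrow(tt), 17L)
  expect_equal(sum(tt$sponge_class == "lncRNA"), 14L)
  expect_equal(sum(tt$sponge_class == "circRNA"), 3L)
  appat <- tt[tt$sponge_id == "APPAT", ]
  expect_true(is.na(appat$mrna))       # NA sentinel preserved
  expect_identical(appat$mirna_id, "miR-647")
  expect_equal(length(unique(tt$mirna_id)), 16L)
})

test_that("ternary reader enforces section structure", {
  p <- tempfile()
  writeLines(c("SPX\tmiR-9\tNA", "lncRNA"), p)
  expect_error(read_ternary_table(p), "outside any")
  writeLines(c("lncRNA", "circRNA"), p)
  expect_equal(nrow(read_ternary_table(p)), 0L)  # empty sections
})

test_that("expression reader validates shape and values", {
  p <- pgnet_example("tissue_expression_synthetic.tsv")
  m <- read_expression(p)
  expect_equal(dim(m), c(16L, 9L))
  expect_true(all(is.finite(m)) && all(m >= 0))
  p2 <- tempfile()
  writeLines(c("mirna_id\tt1\tt2", "a\t1\t2", "a\t3\t4"), p2)
  expect_error(read_expression(p2), "duplicate")
})
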