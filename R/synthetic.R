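#' Configuration for the synthetic study-data generator
#'
#' Bundles and validates every parameter of [generate_study_data()]. The
#' defaults emulate the statistical structure of a curated cardiovascular
#' disease-ncRNA association database: 23 phenotypes; 426 miRNA, 99 lncRNA
#' and 24 circRNA entries; a power-law genotype degree distribution
#' (`gamma_target`, default 2.5, inside the scale-free band 2-3);
#' class-conditional biomarker rates 0.903 (universal, degree >= 2) and
#' 0.594 (specific, degree = 1); mean validated-target counts 142 vs 46
#' per miRNA (matching 24937/175 and 11444/251 interactions-per-miRNA);
#' an essential-gene fraction of 0.55; and a two-block tissue-expression
#' structure over 9 tissues.
#'
#' @param seed integer seed (mandatory; all randomness flows from it).
#' @param n_diseases,n_mirna,n_lncrna,n_circrna node counts.
#' @param gamma_target power-law exponent for genotype degrees (> 1).
#' @param biomarker_rate_universal,biomarker_rate_specific class-conditional
#'   biomarker probabilities.
#' @param mean_targets_universal,mean_targets_specific Poisson means of
#'   per-miRNA validated-target counts.
#' @param essential_frac probability that a pool gene is essential.
#' @param gene_pool_size size of the target-gene pool.
#' @param n_gmt_sets,gmt_set_size gene-set collection shape.
#' @param n_expr_mirna,n_tissues expression-matrix shape.
#' @param cluster_sep expression block effect size (difference of block
#'   means, arbitrary units).
#' @param expr_noise_sd within-block expression noise sd.
#' @return A validated list of class `pg_sim_config`.
#' @export
synthetic_config <- function(seed,
                             n_diseases = 23L,
                             n_mirna = 426L, n_lncrna = 99L, n_circrna = 24L,
                             gamma_target = 2.5,
                             biomarker_rate_universal = 0.903,
                             biomarker_rate_specific = 0.594,
                             mean_targets_universal = 142,
                             mean_targets_specific = 46,
                             essential_frac = 0.55,
                             gene_pool_size = 10000L,
                             n_gmt_sets = 50L, gmt_set_size = 25L,
                             n_expr_mirna = 16L, n_tissues = 9L,
                             cluster_sep = 1, expr_noise_sd = 0.1) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(seed = as.integer(seed), n_diseases = as.integer(n_diseases),
              n_mirna = as.integer(n_mirna), n_lncrna = as.integer(n_lncrna),
              n_circrna = as.integer(n_circrna), gamma_target = gamma_target,
              biomarker_rate_universal = biomarker_rate_universal,
              biomarker_rate_specific = biomarker_rate_specific,
              mean_targets_universal = mean_targets_universal,
              mean_targets_specific = mean_targets_specific,
              essential_frac = essential_frac,
              gene_pool_size = as.integer(gene_pool_size),
              n_gmt_sets = as.integer(n_gmt_sets),
              gmt_set_size = as.integer(gmt_set_size),
              n_expr_mirna = as.integer(n_expr_mirna),
              n_tissues = as.integer(n_tissues),
              cluster_sep = cluster_sep, expr_noise_sd = expr_noise_sd)
  rates <- c(cfg$biomarker_rate_universal, cfg$biomarker_rate_specific,
             cfg$essential_frac)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$gamma_target <= 1) stop("gamma_target must be > 1")
  counts <- c(cfg$n_diseases, cfg$n_mirna, cfg$n_lncrna, cfg$n_circrna,
              cfg$gene_pool_size, cfg$n_tissues, cfg$n_expr_mirna)
  if (any(counts < 1)) stop("counts must be positive")
  structure(cfg, class = "pg_sim_config")
}

# truncated discrete power law on 1..kmax: identical in law to
# redraw-until-accepted sampling from the unbounded zeta distribution
rtrunc_power_law <- function(n, gamma, kmax) {
  ks <- seq_len(kmax)
  sample(ks, n, replace = TRUE, prob = ks^(-gamma))
}

#' Generate a complete synthetic study dataset
#'
#' Draws every input the analysis pipeline consumes, with the statistical
#' structure described in [synthetic_config()]: genotype degrees are i.i.d.
#' truncated power law; each ncRNA's disease set is sampled uniformly
#' without replacement; biomarker flags are Bernoulli with the
#' class-conditional rate implied by the realized degree; per-miRNA target
#' counts are Poisson around the class mean with genes drawn from a common
#' pool; essential flags are Bernoulli over the pool; and the expression
#' matrix carries two planted row blocks separated by `cluster_sep` against
#' noise `expr_noise_sd`. The `truth` element records every latent
#' parameter and assignment so that downstream estimates can be scored
#' against them.
#'
#' @param config a `pg_sim_config` from [synthetic_config()].
#' @return An object of class `pg_sim`: list with `associations`
#'   (`pg_assoc`), `targets` (`pg_targets`), `essential` (character),
#'   `gmt` (`pg_gmt`), `expression` (matrix) and `truth` (list).
#' @examples
#' sim <- generate_study_data(synthetic_config(seed = 1))
#' table(partition_by_degree(build_bipartite(sim$associations, "miRNA"))$degree_map >= 2)
#' @export
generate_study_data <- function(config) {
  stopifnot(inherits(config, "pg_sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  diseases <- default_disease_catalog()$labels
  if (cfg$n_diseases <= length(diseases)) {
    diseases <- diseases[seq_len(cfg$n_diseases)]
  } else {
    diseases <- c(diseases, sprintf("Synthetic disease %02d",
                                    seq_len(cfg$n_diseases - length(diseases))))
  }

  ids <- list(
    miRNA = sprintf("miR-sim-%03d", seq_len(cfg$n_mirna)),
    lncRNA = sprintf("LNC-SIM-%03d", seq_len(cfg$n_lncrna)),
    circRNA = sprintf("circSIM_%03d", seq_len(cfg$n_circrna)))

  assoc <- list(); truth_deg <- list(); truth_bm <- list()
  for (cls in names(ids)) {
    nn <- length(ids[[cls]])
    deg <- rtrunc_power_law(nn, cfg$gamma_target, cfg$n_diseases)
    rate <- ifelse(deg >= 2L, cfg$biomarker_rate_universal,
                   cfg$biomarker_rate_specific)
    bm <- stats::runif(nn) < rate
    dis <- lapply(deg, function(k) sample(diseases, k))
    assoc[[cls]] <- data.frame(
      ncrna_id = rep(ids[[cls]], deg),
      ncrna_class = cls,
      disease = unlist(dis),
      biomarker = rep(bm, deg),
      direction = sample(c("up", "down"), sum(deg), replace = TRUE),
      pmid = sprintf("%08d", sample.int(99999999L, sum(deg), replace = TRUE)),
      sample_note = "synthetic",
      stringsAsFactors = FALSE)
    truth_deg[[cls]] <- stats::setNames(deg, ids[[cls]])
    truth_bm[[cls]] <- stats::setNames(bm, ids[[cls]])
  }
  associations <- as_pg_assoc(do.call(rbind, assoc))

  pool <- sprintf("G%05d", seq_len(cfg$gene_pool_size))
  essential_flag <- stats::runif(cfg$gene_pool_size) < cfg$essential_frac
  essential <- pool[essential_flag]

  mir_deg <- truth_deg$miRNA
  mean_t <- ifelse(mir_deg >= 2L, cfg$mean_targets_universal,
                   cfg$mean_targets_specific)
  n_t <- pmin(stats::rpois(length(mir_deg), mean_t), cfg$gene_pool_size)
  tg <- lapply(seq_along(mir_deg), function(i)
    if (n_t[i] > 0L) sample(pool, n_t[i]) else character())
  targets <- data.frame(
    mirna_id = rep(names(mir_deg), n_t),
    gene = unlist(tg),
    source = "synthetic",
    stringsAsFactors = FALSE)
  class(targets) <- c("pg_targets", "data.frame")

  set_size <- min(cfg$gmt_set_size, cfg$gene_pool_size)
  sets <- lapply(seq_len(cfg$n_gmt_sets), function(i)
    list(description = sprintf("synthetic set %d", i),
         genes = sample(pool, set_size)))
  names(sets) <- sprintf("SYN_SET_%03d", seq_len(cfg$n_gmt_sets))
  gmt <- structure(sets, class = "pg_gmt")

  expr <- make_expression_blocks(
    mirna_ids = names(mir_deg)[seq_len(min(cfg$n_expr_mirna, length(mir_deg)))],
    n_tissues = cfg$n_tissues, sep = cfg$cluster_sep, sd = cfg$expr_noise_sd)

  truth <- list(config = unclass(cfg),
                degrees = truth_deg, biomarker = truth_bm,
                class = lapply(truth_deg, function(d)
                  ifelse(d >= 2L, "universal", "specific")),
                essential_genes = essential, gene_pool = pool,
                expr_blocks = attr(expr, "blocks"),
                tissue_groups = attr(expr, "tissue_groups"),
                degree_truncation = paste0("degrees sampled from the power law ",
                  "renormalized on 1..", cfg$n_diseases))
  structure(list(associations = associations, targets = targets,
                 essential = essential, gmt = gmt, expression = expr,
                 truth = truth),
            class = "pg_sim")
}

make_expression_blocks <- function(mirna_ids, n_tissues, sep, sd) {
  n <- length(mirna_ids)
  tissue_names <- c("stomach", "kidney", "liver", "spleen", "bone",
                    "myocardium", "muscle", "colon", "thyroid")
  tissues <- if (n_tissues <= length(tissue_names)) tissue_names[seq_len(n_tissues)]
             else c(tissue_names, sprintf("tissue%02d",
                    seq_len(n_tissues - length(tissue_names))))
  blocks <- rep(1:2, c(ceiling(n / 2), floor(n / 2)))
  tgrp <- rep(1:2, c(ceiling(n_tissues / 2), floor(n_tissues / 2)))
  base <- 2
  mu <- outer(blocks, tgrp, function(b, g) base + sep * (b == g))
  m <- pmax(mu + matrix(stats::rnorm(n * n_tissues, sd = sd), n, n_tissues), 0)
  dimnames(m) <- list(mirna_ids, tissues)
  attr(m, "blocks") <- stats::setNames(blocks, mirna_ids)
  attr(m, "tissue_groups") <- stats::setNames(tgrp, tissues)
  m
}

#' Deterministic fixture with the published partition counts
#'
#' A seeded association table whose miRNA partition is exactly 175
#' universal (degree >= 2) and 251 specific (degree = 1) entries, 426 in
#' total — the class sizes reported for the curated CVD-miRNA network.
#' Degrees of universal entries follow the truncated power law conditioned
#' on k >= 2; biomarker flags use the class rates 0.903/0.594. Identical on
#' every call.
#'
#' @return A `pg_assoc` data frame.
#' @export
published_count_fixture <- function() {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(426L)
  diseases <- default_disease_catalog()$labels
  n_u <- 175L; n_s <- 251L
  ids <- sprintf("miR-fix-%03d", seq_len(n_u + n_s))
  ks <- 2:23
  deg <- c(sample(ks, n_u, replace = TRUE, prob = ks^(-2.5)), rep(1L, n_s))
  rate <- ifelse(deg >= 2L, 0.903, 0.594)
  bm <- stats::runif(n_u + n_s) < rate
  dis <- lapply(deg, function(k) sample(diseases, k))
  as_pg_assoc(data.frame(
    ncrna_id = rep(ids, deg), ncrna_class = "miRNA",
    disease = unlist(dis), biomarker = rep(bm, deg),
    direction = "unknown", pmid = "", sample_note = "fixture",
    stringsAsFactors = FALSE))
}

#' Write a synthetic dataset to a directory of standard files
#'
#' Materializes a `pg_sim` bundle as the same plain-text formats the
#' readers consume: `associations.tsv`, `targets.tsv`, `essential.txt`,
#' `sets.gmt`, `expression.tsv` and `truth.json`.
#'
#' @param sim a `pg_sim` from [generate_study_data()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_data <- function(sim, dir) {
  stopifnot(inherits(sim, "pg_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_associations(sim$associations, file.path(dir, "associations.tsv"))
  write.table(as.data.frame(sim$targets), file.path(dir, "targets.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$essential, file.path(dir, "essential.txt"))
  write_gmt(sim$gmt, file.path(dir, "sets.gmt"))
  expr <- data.frame(mirna_id = rownames(sim$expression), sim$expression,
                     check.names = FALSE)
  write.table(expr, file.path(dir, "expression.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
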