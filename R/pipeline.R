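#' Run the full phenotype-genotype network pipeline
#'
#' Orchestrates validate -> build -> fit -> contrast -> ora -> cluster over
#' either a simulated dataset or files on disk, writing a reproducible
#' report bundle. Stage seeds are derived deterministically from the root
#' seed (`seed + fixed per-stage offsets`), so an identical config yields a
#' byte-identical bundle.
#'
#' The config is a named list (or a YAML file with the same structure):
#' either `simulate = list(seed = ..., <synthetic_config() arguments>)` or
#' `inputs = list(associations=, targets=, essential=, gmt=, ternary=,
#' expression=)` with file paths; optional parameter blocks `fit`
#' (`xmin`, `n_boot`), `contrast` (`n_perm`), `ora` (`alpha`, `adjust`),
#' `cluster` (`k_rows`, `distance`, `linkage`), and a root `seed`.
#'
#' Outputs under `out_dir`: `net_<class>.graphml` and `.sif`,
#' `ternary.graphml` (when a ternary table is given), `fit_<class>.json`,
#' `contrast.json`, `ora_universal.tsv` / `ora_specific.tsv`,
#' `ora_overlap.json`, `clusters.tsv`, `summary.txt` and `manifest.json`.
#' Stages whose inputs are absent are skipped with a notice in the
#' summary; a stage failure aborts with the stage name.
#'
#' @param config named list or path to a YAML file.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1234L)
  par_fit <- config$fit %||% list()
  par_con <- config$contrast %||% list()
  par_ora <- config$ora %||% list()
  par_clu <- config$cluster %||% list()
  notes <- character()
  res <- list()

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- inputs -------------------------------------------------------------
  stage("inputs", {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      sim_args$seed <- as.integer(sim_args$seed %||% seed)
      cfg <- do.call(synthetic_config, sim_args)
      sim <- generate_study_data(cfg)
      res$sim <- sim
      res$associations <- sim$associations
      res$targets <- sim$targets
      res$essential <- sim$essential
      res$gmt <- sim$gmt
      res$expression <- sim$expression
    } else if (!is.null(config$inputs)) {
      ip <- config$inputs
      if (!is.null(ip$associations))
        res$associations <- read_associations(ip$associations)
      if (!is.null(ip$targets)) res$targets <- read_targets(ip$targets)
      if (!is.null(ip$essential)) res$essential <- read_essential(ip$essential)
      if (!is.null(ip$gmt)) res$gmt <- read_gmt(ip$gmt)
      if (!is.null(ip$expression)) res$expression <- read_expression(ip$expression)
      if (!is.null(ip$ternary)) res$ternary_triples <- read_ternary_table(ip$ternary)
    } else stop("config needs a 'simulate' or 'inputs' block")
  })

  # ---- bipartite networks + power-law fits --------------------------------
  if (!is.null(res$associations)) {
    for (cls in intersect(NCRNA_CLASSES, unique(res$associations$ncrna_class))) {
      net <- stage(paste0("build_", cls),
                   build_bipartite(res$associations, cls))
      res$networks[[cls]] <- net
      export_network(net, file.path(out_dir, paste0("net_", cls, ".graphml")),
                     "graphml")
      export_network(net, file.path(out_dir, paste0("net_", cls, ".sif")), "sif")
      dd <- degree_distribution(net, "genotype")
      if (max(dd$degrees) < 3L) {
        notes <- c(notes, paste0("fit skipped for ", cls,
                                 ": max degree < 3 (small-tail guard)"))
        next
      }
      fit <- stage(paste0("fit_", cls), {
        f <- fit_power_law(dd, xmin = par_fit$xmin %||% 1)
        bootstrap_ci(f, n_boot = as.integer(par_fit$n_boot %||% 500L),
                     seed = seed + 11L)
      })
      res$fits[[cls]] <- fit
      jsonlite::write_json(
        list(ncrna_class = cls, gamma = fit$gamma, xmin = fit$xmin,
             n_tail = fit$n_tail, ks_stat = fit$ks_stat, loglik = fit$loglik,
             ci_low = fit$ci[1], ci_high = fit$ci[2], method = fit$method),
        file.path(out_dir, paste0("fit_", cls, ".json")),
        auto_unbox = TRUE, digits = NA)
    }
  } else notes <- c(notes, "bipartite stages skipped: no association input")

  # ---- class contrast -----------------------------------------------------
  if (!is.null(res$networks$miRNA)) {
    res$contrast <- stage("contrast",
      class_contrast(res$networks$miRNA, res$targets, res$essential,
                     n_perm = as.integer(par_con$n_perm %||% 9999L),
                     seed = seed + 23L))
    ct <- res$contrast
    jsonlite::write_json(
      list(n_universal = ct$n_universal, n_specific = ct$n_specific,
           biomarker_rate_universal = unname(ct$biomarker_rate["universal"]),
           biomarker_rate_specific = unname(ct$biomarker_rate["specific"]),
           p_fisher = ct$p_fisher, p_chi2 = ct$p_chi2, p_perm = ct$p_perm,
           odds_ratio = ct$odds_ratio,
           targets_per_class = ct$targets_per_class,
           essential_ratio = as.list(ct$essential_ratio)),
      file.path(out_dir, "contrast.json"), auto_unbox = TRUE, digits = NA)
  } else notes <- c(notes, "contrast skipped: no miRNA network")

  # ---- over-representation ------------------------------------------------
  if (!is.null(res$contrast) && !is.null(res$targets) && !is.null(res$gmt)) {
    stage("ora", {
      part <- res$contrast$partition
      alpha <- par_ora$alpha %||% 0.01
      for (side in c("universal", "specific")) {
        genes <- target_coverage(part[[side]], res$targets)$genes
        r <- ora(genes, res$gmt,
                 adjust_method = par_ora$adjust %||% "bh")
        res$ora[[side]] <- r
        write.table(as.data.frame(r),
                    file.path(out_dir, paste0("ora_", side, ".tsv")),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      ov <- overlap_report(res$ora$universal, res$ora$specific, alpha = alpha)
      res$ora_overlap <- ov
      jsonlite::write_json(ov, file.path(out_dir, "ora_overlap.json"),
                           auto_unbox = TRUE, digits = NA)
    })
  } else notes <- c(notes, "ora skipped: needs contrast, targets and gmt")

  # ---- ternary network ----------------------------------------------------
  if (!is.null(res$ternary_triples)) {
    res$ternary <- stage("ternary", build_ternary(res$ternary_triples))
    export_network(res$ternary, file.path(out_dir, "ternary.graphml"), "graphml")
  }

  # ---- tissue clustering --------------------------------------------------
  if (!is.null(res$expression)) {
    res$clusters <- stage("cluster",
      cluster_expression(res$expression,
                         k_rows = as.integer(par_clu$k_rows %||% 2L),
                         distance = par_clu$distance %||% "correlation",
                         linkage = par_clu$linkage %||% "average"))
    write_cluster_tsv(res$expression, res$clusters,
                      file.path(out_dir, "clusters.tsv"))
  } else notes <- c(notes, "cluster skipped: no expression input")

  write_pipeline_summary(res, notes, out_dir)
  jsonlite::write_json(
    list(pgnet_version = as.character(utils::packageVersion("pgnet")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = seed, config = config, notes = notes,
         timestamp = "deterministic-bundle"),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_summary <- function(res, notes, out_dir) {
  con <- file(file.path(out_dir, "summary.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("phenotype-genotype network pipeline summary")
  w("===========================================")
  for (cls in names(res$networks)) {
    s <- network_summary(res$networks[[cls]])
    w("%s network: %d phenotypes, %d ncRNAs, %d edges (max degree %d)",
      cls, s$n_phenotypes, s$n_ncrnas, s$n_edges, s$max_degree)
  }
  for (cls in names(res$fits)) {
    f <- res$fits[[cls]]
    w("%s power-law fit: gamma = %.3f (xmin = %d, KS = %.4f, 95%% CI %.3f-%.3f)",
      cls, f$gamma, f$xmin, f$ks_stat, f$ci[1], f$ci[2])
  }
  if (!is.null(res$contrast)) {
    ct <- res$contrast
    w("contrast: %d universal vs %d specific; biomarker %.1f%% vs %.1f%%; Fisher p = %.3g",
      ct$n_universal, ct$n_specific, 100 * ct$biomarker_rate["universal"],
      100 * ct$biomarker_rate["specific"], ct$p_fisher)
    if (!is.null(ct$essential_ratio))
      w("essential-gene ratio: universal %.1f%%, specific %.1f%%",
        100 * ct$essential_ratio["universal"], 100 * ct$essential_ratio["specific"])
  }
  if (!is.null(res$ora_overlap))
    w("ora: %d enriched (universal), %d (specific), %d shared",
      res$ora_overlap$n_a, res$ora_overlap$n_b, res$ora_overlap$n_shared)
  if (!is.null(res$ternary))
    w("ternary network: %d lncRNA-miRNA and %d circRNA-miRNA pairs",
      res$ternary$pair_counts["lncRNA"], res$ternary$pair_counts["circRNA"])
  if (!is.null(res$clusters))
    w("clustering: %d rows in %d clusters",
      length(res$clusters$row_labels), length(unique(res$clusters$row_labels)))
  for (n in notes) w("note: %s", n)
}
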