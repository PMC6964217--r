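#' Over-representation analysis against a gene-set collection
#'
#' For each set in the collection, tests whether the query gene list
#' overlaps the set more than expected under hypergeometric sampling from
#' the universe: `p_raw = P(X >= overlap)` with
#' `X ~ Hypergeometric(set_size, universe - set_size, query_size)`. This is
#' the statistical skeleton shared by pathway/GO over-representation tools.
#' Sets are intersected with the universe before testing; query genes
#' outside the universe are dropped with a warning.
#'
#' @param query character vector of gene symbols.
#' @param sets a `pg_gmt` collection.
#' @param universe background gene symbols; defaults to the union of all
#'   set members.
#' @param adjust_method adjustment reported in `p_adj`: `"bh"` (default)
#'   or `"bonferroni"`; both are always available via [adjust_pvalues()].
#' @return A `data.frame` of class `pg_ora`, one row per set, sorted by
#'   `p_raw`: columns `set_name`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `ratio` (overlap/set_size), `p_raw`, `p_bh`,
#'   `p_bonf`.
#' @export
ora <- function(query, sets, universe = NULL, adjust_method = c("bh", "bonferroni")) {
  adjust_method <- match.arg(adjust_method)
  stopifnot(inherits(sets, "pg_gmt"))
  if (!length(sets)) stop("empty gene-set collection")
  query <- unique(toupper(query))
  if (is.null(universe))
    universe <- unique(unlist(lapply(sets, `[[`, "genes"), use.names = FALSE))
  universe <- unique(toupper(universe))
  if (!length(universe)) stop("empty universe")
  out <- setdiff(query, universe)
  if (length(out)) {
    warning(length(out), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  q <- length(query)
  u <- length(universe)
  rows <- lapply(names(sets), function(nm) {
    s_genes <- intersect(sets[[nm]]$genes, universe)
    s <- length(s_genes)
    ov <- length(intersect(query, s_genes))
    p <- if (s == 0L) 1 else hyper_upper_tail(ov, s, u, q)
    data.frame(set_name = nm, overlap = ov, set_size = s, query_size = q,
               universe_size = u,
               ratio = if (s) ov / s else NA_real_,
               p_raw = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bh <- adjust_pvalues(res$p_raw, "bh")
  res$p_bonf <- adjust_pvalues(res$p_raw, "bonferroni")
  res$p_adj <- if (adjust_method == "bh") res$p_bh else res$p_bonf
  res <- res[order(res$p_raw, res$set_name), ]
  rownames(res) <- NULL
  class(res) <- c("pg_ora", "data.frame")
  res
}

# P(X >= ov) for X ~ Hypergeom(s successes, u - s failures, q draws)
hyper_upper_tail <- function(ov, s, u, q) {
  if (ov <= 0L) return(1)
  stats::phyper(ov - 1L, s, u - s, q, lower.tail = FALSE)
}

#' Multiple-testing adjustment
#'
#' Benjamini-Hochberg (the shipped FDR) or Bonferroni adjustment of raw
#' p-values, preserving input order. Thin, validated wrapper over
#' [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @param method `"bh"` or `"bonferroni"`.
#' @return Adjusted p-values, same length and order as the input.
#' @export
adjust_pvalues <- function(pvals, method = c("bh", "bonferroni")) {
  method <- match.arg(method)
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = if (method == "bh") "BH" else "bonferroni")
}

#' Compare two over-representation result lists
#'
#' Counts the sets enriched at `alpha` (raw p) in each result list and the
#' sets shared between the two, matched by set name.
#'
#' @param res_a,res_b `pg_ora` results computed against the same
#'   collection.
#' @param alpha significance threshold on `p_raw` (default 0.01).
#' @param on which p-value column to threshold (`"p_raw"`, `"p_bh"`,
#'   `"p_bonf"`).
#' @return List with `n_a`, `n_b`, `n_shared` and the shared set names.
#' @export
overlap_report <- function(res_a, res_b, alpha = 0.01, on = "p_raw") {
  stopifnot(inherits(res_a, "pg_ora"), inherits(res_b, "pg_ora"))
  sig_a <- res_a$set_name[res_a[[on]] < alpha]
  sig_b <- res_b$set_name[res_b[[on]] < alpha]
  shared <- intersect(sig_a, sig_b)
  list(n_a = length(sig_a), n_b = length(sig_b), n_shared = length(shared),
       shared = shared)
}
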