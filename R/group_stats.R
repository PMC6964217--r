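#' Partition ncRNAs into universal and specific classes
#'
#' Universal ncRNAs are associated with at least two disease types (degree
#' >= 2 in the bipartite network); specific ncRNAs with exactly one
#' (degree = 1).
#'
#' @param net a `pg_bipartite`, or a `pg_degdist` of genotype-side degrees.
#' @return An object of class `pg_partition`: list with character vectors
#'   `universal` and `specific` and the named `degree_map`.
#' @export
partition_by_degree <- function(net) {
  dd <- if (inherits(net, "pg_degdist")) net else degree_distribution(net, "genotype")
  deg <- dd$degrees
  structure(list(universal = sort(names(deg)[deg >= 2L]),
                 specific = sort(names(deg)[deg == 1L]),
                 degree_map = deg),
            class = "pg_partition")
}

#' @export
print.pg_partition <- function(x, ...) {
  cat("Degree partition:", length(x$universal), "universal (k >= 2),",
      length(x$specific), "specific (k = 1)\n")
  invisible(x)
}

check_2x2 <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("expected a 2x2 table")
  if (any(m < 0) || any(m != round(m))) stop("counts must be non-negative integers")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("zero margin: every row and column total must be positive")
  m
}

#' Fisher's exact test for a 2x2 contingency table
#'
#' Exact conditional test on the hypergeometric distribution of the
#' top-left cell given fixed margins. The two-sided p-value is the sum of
#' the point probabilities of all tables (same margins) no more probable
#' than the observed one (with the conventional `1 + 1e-7` relative slack
#' for floating-point ties). The odds ratio is the sample estimate
#' `ad/bc`, with a Haldane-Anscombe 0.5 added to every cell when any cell
#' is zero.
#'
#' @param table 2x2 matrix of counts; rows = class, columns = outcome.
#' @param alternative `"two_sided"` (default), `"greater"` or `"less"`
#'   (referring to the top-left cell).
#' @return List with `p_value`, `odds_ratio` and the observed `table`.
#' @examples
#' fisher_exact(matrix(c(5, 0, 0, 5), 2, 2))$p_value  # 2/252
#' @export
fisher_exact <- function(table, alternative = c("two_sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- check_2x2(table)
  a <- m[1, 1]
  M <- sum(m[1, ]); N <- sum(m[2, ]); K <- sum(m[, 1])
  support <- max(0, K - N):min(K, M)
  probs <- stats::dhyper(support, M, N, K)
  p_obs <- stats::dhyper(a, M, N, K)
  p <- switch(alternative,
    two_sided = sum(probs[probs <= p_obs * (1 + 1e-7)]),
    greater   = sum(probs[support >= a]),
    less      = sum(probs[support <= a]))
  p <- min(1, p)
  or <- if (any(m == 0)) {
    h <- m + 0.5
    (h[1, 1] * h[2, 2]) / (h[1, 2] * h[2, 1])
  } else (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = p, odds_ratio = or, table = m)
}

#' Permutation test for a class difference in biomarker rates
#'
#' Label-permutation null for the absolute difference in biomarker rates
#' between the universal and specific classes: class labels are reshuffled
#' `n_perm` times and the p-value is
#' `(1 + #{|diff*| >= |diff|}) / (n_perm + 1)`.
#'
#' @param flags named logical vector, biomarker flag per ncRNA id; must
#'   cover both classes of `part`.
#' @param part a `pg_partition`.
#' @param n_perm number of permutations (>= 1).
#' @param seed integer seed (default 1234).
#' @return List with `p_value`, `observed` (rate difference
#'   universal - specific) and `n_perm`.
#' @export
permutation_class_test <- function(flags, part, n_perm = 9999L, seed = 1234L) {
  stopifnot(inherits(part, "pg_partition"))
  if (n_perm < 1L) stop("n_perm must be >= 1")
  if (!length(part$universal) || !length(part$specific))
    stop("both classes must be non-empty")
  miss <- setdiff(c(part$universal, part$specific), names(flags))
  if (length(miss)) stop("flags missing for: ", paste(utils::head(miss, 5), collapse = ", "))
  f <- as.logical(flags[c(part$universal, part$specific)])
  n_u <- length(part$universal)
  n <- length(f)
  obs <- mean(f[seq_len(n_u)]) - mean(f[-seq_len(n_u)])
  set.seed(seed)
  total <- sum(f)
  perm <- vapply(seq_len(n_perm), function(i) {
    s_u <- sum(f[sample.int(n, n_u)])
    s_u / n_u - (total - s_u) / (n - n_u)
  }, numeric(1))
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-12)) / (n_perm + 1)
  list(p_value = p, observed = obs, n_perm = n_perm)
}

#' Target coverage of an ncRNA class
#'
#' Restricts a validated miRNA-target table to the members of a class and
#' counts distinct target genes and (miRNA, gene) interactions.
#'
#' @param members character vector of miRNA ids (one class of a partition).
#' @param targets a `pg_targets` table.
#' @return List with `n_genes`, `n_interactions` and the gene set `genes`.
#' @export
target_coverage <- function(members, targets) {
  df <- as.data.frame(targets)
  sel <- df[df$mirna_id %in% members, , drop = FALSE]
  genes <- unique(sel$gene)
  list(n_genes = length(genes), n_interactions = nrow(sel), genes = genes)
}

#' Essential-gene ratio of a gene set
#'
#' Fraction of a class's target genes found in an essential-gene catalog:
#' `|class_genes intersect essential| / |class_genes|`.
#'
#' @param class_genes non-empty character vector of gene symbols.
#' @param essential character vector of essential-gene symbols.
#' @return Ratio in `[0, 1]`.
#' @export
essential_ratio <- function(class_genes, essential) {
  class_genes <- unique(toupper(class_genes))
  if (!length(class_genes)) stop("class_genes must be non-empty")
  length(intersect(class_genes, unique(toupper(essential)))) / length(class_genes)
}

#' Class-contrast report: universal vs specific miRNAs
#'
#' Assembles the full comparison between the universal (multi-disease) and
#' specific (single-disease) miRNA classes: biomarker rates with Fisher
#' exact, chi-square (continuity-corrected) and permutation p-values plus
#' the odds ratio, per-class target coverage, and per-class essential-gene
#' ratios.
#'
#' @param net a `pg_bipartite` built from miRNA associations.
#' @param targets optional `pg_targets` table.
#' @param essential optional character vector of essential genes.
#' @param n_perm permutations for the label test.
#' @param seed integer seed.
#' @return An object of class `pg_contrast` (a list; see fields in the
#'   examples).
#' @export
class_contrast <- function(net, targets = NULL, essential = NULL,
                           n_perm = 9999L, seed = 1234L) {
  stopifnot(inherits(net, "pg_bipartite"))
  part <- partition_by_degree(net)
  geno <- side_vertices(net, "genotype")
  flags <- stats::setNames(as.logical(geno$biomarker), geno$name)

  bm_u <- sum(flags[part$universal]); bm_s <- sum(flags[part$specific])
  n_u <- length(part$universal); n_s <- length(part$specific)
  tab <- matrix(c(bm_u, n_u - bm_u, bm_s, n_s - bm_s), 2, 2, byrow = TRUE,
                dimnames = list(c("universal", "specific"), c("biomarker", "not")))
  fe <- fisher_exact(tab)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  perm <- permutation_class_test(flags, part, n_perm = n_perm, seed = seed)

  res <- list(
    n_universal = n_u, n_specific = n_s,
    biomarker_rate = c(universal = bm_u / n_u, specific = bm_s / n_s),
    table = tab,
    p_fisher = fe$p_value, p_chi2 = unname(chi$p.value), p_perm = perm$p_value,
    odds_ratio = fe$odds_ratio)

  if (!is.null(targets)) {
    cov_u <- target_coverage(part$universal, targets)
    cov_s <- target_coverage(part$specific, targets)
    res$targets_per_class <- list(universal = cov_u[c("n_genes", "n_interactions")],
                                  specific = cov_s[c("n_genes", "n_interactions")])
    if (!is.null(essential)) {
      res$essential_ratio <- c(
        universal = if (cov_u$n_genes) essential_ratio(cov_u$genes, essential) else NA_real_,
        specific = if (cov_s$n_genes) essential_ratio(cov_s$genes, essential) else NA_real_)
    }
  }
  res$partition <- part
  structure(res, class = "pg_contrast")
}

#' @export
print.pg_contrast <- function(x, ...) {
  cat("Universal vs specific miRNA contrast\n")
  cat(sprintf("  n = %d universal, %d specific\n", x$n_universal, x$n_specific))
  cat(sprintf("  biomarker rate: %.1f%% vs %.1f%%\n",
              100 * x$biomarker_rate["universal"], 100 * x$biomarker_rate["specific"]))
  cat(sprintf("  Fisher p = %.3g, chi-square p = %.3g, permutation p = %.3g, OR = %.2f\n",
              x$p_fisher, x$p_chi2, x$p_perm, x$odds_ratio))
  if (!is.null(x$targets_per_class))
    cat(sprintf("  targets: universal %d genes / %d interactions; specific %d / %d\n",
                x$targets_per_class$universal$n_genes,
                x$targets_per_class$universal$n_interactions,
                x$targets_per_class$specific$n_genes,
                x$targets_per_class$specific$n_interactions))
  if (!is.null(x$essential_ratio))
    cat(sprintf("  essential-gene ratio: universal %.1f%%, specific %.1f%%\n",
                100 * x$essential_ratio["universal"], 100 * x$essential_ratio["specific"]))
  invisible(x)
}
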