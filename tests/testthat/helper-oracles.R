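# Independent oracles used by the tests. These deliberately avoid the code
# paths of the package implementation: point probabilities come from
# lgamma-based binomial coefficients and tail sums from explicit
# enumeration, not from dhyper/phyper.

lbinom <- function(n, k) lgamma(n + 1) - lgamma(k + 1) - lgamma(n - k + 1)

# two-sided Fisher p by exhaustive enumeration over all tables with the
# observed margins; same (1 + 1e-7) relative tie slack as the convention.
fisher_oracle <- function(a, b, c, d) {
  M <- a + b; N2 <- c + d; K <- a + c
  support <- max(0, K - N2):min(K, M)
  logp <- lbinom(M, support) + lbinom(N2, K - support) - lbinom(M + N2, K)
  probs <- exp(logp)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# P(X >= x) for the hypergeometric overlap, by explicit combinatorial sum
hyper_tail_oracle <- function(x, set_size, universe, query) {
  xs <- max(0, query + set_size - universe):min(set_size, query)
  xs <- xs[xs >= x]
  if (!length(xs)) return(0)
  sum(exp(lbinom(set_size, xs) + lbinom(universe - set_size, query - xs) -
            lbinom(universe, query)))
}

# grid-search maximizer of the zeta-tail log-likelihood (oracle for the MLE)
powerlaw_grid_oracle <- function(degrees, xmin = 1, grid = seq(1.01, 6, by = 1e-4)) {
  td <- degrees[degrees >= xmin]
  s <- sum(log(td))
  ll <- -grid * s - length(td) * log(pgnet::hurwitz_zeta(grid, xmin))
  grid[which.max(ll)]
}

# small association-table writer for reader tests
write_assoc_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

assoc_row <- function(ncrna_id, ncrna_class = "miRNA", disease, biomarker = 0,
                      direction = "up", pmid = "", sample_note = "") {
  list(ncrna_id = ncrna_id, ncrna_class = ncrna_class, disease = disease,
       biomarker = biomarker, direction = direction, pmid = pmid,
       sample_note = sample_note)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# two-block expression generator independent of the package's synthetic module
planted_expression <- function(n_rows = 13, n_cols = 9, sep = 1, sd = 0.1) {
  blocks <- rep(1:2, length.out = n_rows)
  tgrp <- rep(1:2, length.out = n_cols)
  mu <- outer(blocks, tgrp, function(b, g) 2 + sep * (b == g))
  m <- mu + matrix(rnorm(n_rows * n_cols, sd = sd), n_rows, n_cols)
  dimnames(m) <- list(paste0("miR-p", seq_len(n_rows)), paste0("t", seq_len(n_cols)))
  attr(m, "blocks") <- setNames(blocks, rownames(m))
  m
}
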