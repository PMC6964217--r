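#' Build the bipartite phenotype-genotype network
#'
#' Constructs the bipartite disease-ncRNA graph from validated association
#' records: one node per disease (phenotype side) and per ncRNA (genotype
#' side), one undirected edge per unique (disease, ncRNA) pair. Isolated
#' nodes cannot arise (every node comes from an association); ncRNA nodes
#' carry their class and OR-merged biomarker flag as attributes.
#'
#' @param records a `pg_assoc` data frame from [read_associations()] or the
#'   synthetic generator.
#' @param ncrna_class optional filter, one of `"miRNA"`, `"lncRNA"`,
#'   `"circRNA"`; `NULL` keeps all classes.
#' @param drop_others if `TRUE`, drop associations to the generalized
#'   "Others" phenotype before building.
#' @return An object of class `pg_bipartite` wrapping an igraph graph whose
#'   vertices have attributes `kind` ("phenotype"/"genotype"),
#'   `ncrna_class` and `biomarker`.
#' @examples
#' rec <- data.frame(ncrna_id = c("miR-1", "miR-1", "miR-2"),
#'                   ncrna_class = "miRNA",
#'                   disease = c("Heart failure", "Stroke", "Stroke"),
#'                   biomarker = c(TRUE, TRUE, FALSE),
#'                   direction = "up", pmid = "", sample_note = "")
#' net <- build_bipartite(rec)
#' network_summary(net)
#' @export
build_bipartite <- function(records, ncrna_class = NULL, drop_others = FALSE) {
  df <- as.data.frame(records)
  if (!is.null(ncrna_class)) {
    ncrna_class <- match.arg(ncrna_class, NCRNA_CLASSES)
    df <- df[df$ncrna_class == ncrna_class, , drop = FALSE]
  }
  if (drop_others) df <- df[df$disease != "Others", , drop = FALSE]
  if (nrow(df) == 0L) {
    warning("no association records; returning an empty network")
    g <- igraph::make_empty_graph(directed = FALSE)
    return(structure(list(graph = g), class = "pg_bipartite"))
  }
  key <- paste(df$disease, df$ncrna_id, sep = "\r")
  first <- !duplicated(key)
  df1 <- df[first, , drop = FALSE]
  # biomarker flag per ncRNA = OR over its surviving associations
  bm <- tapply(df$biomarker, df$ncrna_id, any)
  cls <- tapply(df$ncrna_class, df$ncrna_id, function(x) x[1L])

  diseases <- sort(unique(df1$disease))
  ncrnas <- sort(unique(df1$ncrna_id))
  clash <- intersect(diseases, ncrnas)
  if (length(clash))
    stop("node name used on both sides of the bipartite graph: ",
         paste(clash, collapse = ", "))
  verts <- data.frame(
    name = c(diseases, ncrnas),
    kind = rep(c("phenotype", "genotype"), c(length(diseases), length(ncrnas))),
    ncrna_class = c(rep(NA_character_, length(diseases)), unname(cls[ncrnas])),
    biomarker = c(rep(NA, length(diseases)), unname(bm[ncrnas])),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = df1$disease, to = df1$ncrna_id,
               interaction = "assoc", stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts)
  igraph::V(g)$type <- igraph::V(g)$kind == "genotype"
  structure(list(graph = g), class = "pg_bipartite")
}

side_vertices <- function(net, side = c("genotype", "phenotype")) {
  side <- match.arg(side)
  igraph::V(net$graph)[igraph::V(net$graph)$kind == side]
}

#' @export
print.pg_bipartite <- function(x, ...) {
  g <- x$graph
  cat("Bipartite phenotype-genotype network:",
      sum(igraph::V(g)$kind == "phenotype"), "phenotypes,",
      sum(igraph::V(g)$kind == "genotype"), "ncRNAs,",
      igraph::ecount(g), "edges\n")
  invisible(x)
}

#' Summary counts for a bipartite network
#' @param net a `pg_bipartite`.
#' @return List with node/edge counts and the maximum genotype degree.
#' @export
network_summary <- function(net) {
  stopifnot(inherits(net, "pg_bipartite"))
  g <- net$graph
  geno <- side_vertices(net, "genotype")
  list(n_phenotypes = sum(igraph::V(g)$kind == "phenotype"),
       n_ncrnas = length(geno),
       n_edges = igraph::ecount(g),
       n_biomarkers = sum(geno$biomarker, na.rm = TRUE),
       max_degree = if (length(geno)) max(igraph::degree(g, geno)) else 0L)
}

#' Degree distribution of one side of the bipartite network
#'
#' For the genotype side the degree of an ncRNA is the number of distinct
#' diseases it is associated with; for the phenotype side, the number of
#' distinct ncRNAs.
#'
#' @param net a `pg_bipartite`.
#' @param side `"genotype"` (default) or `"phenotype"`.
#' @return An object of class `pg_degdist` with elements `degrees` (named
#'   integer vector), `histogram` (table over k) and `pk` (empirical
#'   probabilities, summing to 1).
#' @export
degree_distribution <- function(net, side = c("genotype", "phenotype")) {
  stopifnot(inherits(net, "pg_bipartite"))
  side <- match.arg(side)
  if (igraph::vcount(net$graph) == 0L) stop("empty network")
  v <- side_vertices(net, side)
  if (!length(v)) stop("network has no ", side, " nodes")
  deg <- igraph::degree(net$graph, v)
  as_degdist(deg)
}

as_degdist <- function(deg) {
  deg <- stats::setNames(as.integer(deg), names(deg))
  if (any(deg < 1L)) stop("degree distribution requires all degrees >= 1")
  ks <- sort(unique(deg))
  hist <- vapply(ks, function(k) sum(deg == k), integer(1))
  structure(list(degrees = deg,
                 histogram = stats::setNames(hist, ks),
                 pk = stats::setNames(hist / length(deg), ks)),
            class = "pg_degdist")
}

#' @export
print.pg_degdist <- function(x, ...) {
  cat("Degree distribution:", length(x$degrees), "nodes, k in [",
      min(x$degrees), ",", max(x$degrees), "]\n")
  invisible(x)
}

#' Build a ternary sponge-miRNA-mRNA network
#'
#' Assembles the three-layer competing-endogenous-RNA network: every triple
#' contributes one sponge-miRNA edge, and one miRNA-mRNA edge per target
#' gene when the mRNA is reported (multi-gene cells like `BCL2/HSP60` are
#' split on `/`).
#'
#' @param triples a `pg_ternary_triples` data frame from
#'   [read_ternary_table()].
#' @return An object of class `pg_ternary` wrapping an igraph graph with
#'   vertex attribute `kind` in `{sponge, miRNA, mRNA}` and edge attribute
#'   `interaction` in `{sponge, targets}`, plus per-class sponge-miRNA pair
#'   counts.
#' @export
build_ternary <- function(triples) {
  df <- as.data.frame(triples)
  need <- c("sponge_id", "sponge_class", "mirna_id", "mrna")
  require_cols(df, need, "ternary triples")
  sp_edges <- unique(df[c("sponge_id", "mirna_id", "sponge_class")])
  tg <- df[!is.na(df$mrna), , drop = FALSE]
  tg_edges <- if (nrow(tg)) {
    genes <- strsplit(tg$mrna, "/", fixed = TRUE)
    unique(data.frame(
      mirna_id = rep(tg$mirna_id, lengths(genes)),
      mrna = trimws(unlist(genes)), stringsAsFactors = FALSE))
  } else data.frame(mirna_id = character(), mrna = character())

  pair_counts <- c(lncRNA = sum(sp_edges$sponge_class == "lncRNA"),
                   circRNA = sum(sp_edges$sponge_class == "circRNA"))

  verts <- rbind(
    data.frame(name = unique(df$sponge_id), kind = "sponge",
               stringsAsFactors = FALSE),
    data.frame(name = unique(df$mirna_id), kind = "miRNA",
               stringsAsFactors = FALSE),
    if (nrow(tg_edges)) data.frame(name = unique(tg_edges$mrna), kind = "mRNA",
                                   stringsAsFactors = FALSE))
  if (anyDuplicated(verts$name))
    stop("node name appears in more than one layer: ",
         paste(unique(verts$name[duplicated(verts$name)]), collapse = ", "))
  edges <- rbind(
    data.frame(from = sp_edges$sponge_id, to = sp_edges$mirna_id,
               interaction = "sponge", stringsAsFactors = FALSE),
    if (nrow(tg_edges)) data.frame(from = tg_edges$mirna_id, to = tg_edges$mrna,
                                   interaction = "targets",
                                   stringsAsFactors = FALSE))
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
  structure(list(graph = g, triples = df, pair_counts = pair_counts),
            class = "pg_ternary")
}

#' @export
print.pg_ternary <- function(x, ...) {
  cat("Ternary sponge network:",
      x$pair_counts["lncRNA"], "lncRNA-miRNA and",
      x$pair_counts["circRNA"], "circRNA-miRNA pairs,",
      igraph::ecount(x$graph), "edges\n")
  invisible(x)
}

#' Export a network for external viewers
#'
#' Writes a bipartite or ternary network as SIF (`source interaction
#' target`, tab-separated, Cytoscape-ready), GraphML (node `kind`,
#' `ncrna_class` and `biomarker` attributes carried along), or a plain
#' edge-list TSV that [import_edge_tsv()] reads back losslessly.
#'
#' @param net a `pg_bipartite` or `pg_ternary`.
#' @param path output file path.
#' @param format one of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "edge_tsv")) {
  stopifnot(inherits(net, "pg_bipartite") || inherits(net, "pg_ternary"))
  format <- match.arg(format)
  g <- net$graph
  if (format == "graphml") {
    # graphml writer rejects logical/NA attributes; recode as character
    if (!is.null(igraph::V(g)$biomarker))
      igraph::V(g)$biomarker <- ifelse(is.na(igraph::V(g)$biomarker), "",
                                       as.character(igraph::V(g)$biomarker))
    if (!is.null(igraph::V(g)$ncrna_class))
      igraph::V(g)$ncrna_class[is.na(igraph::V(g)$ncrna_class)] <- ""
    if ("type" %in% igraph::vertex_attr_names(g))
      g <- igraph::delete_vertex_attr(g, "type")
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    if (is.null(el$interaction)) el$interaction <- "assoc"
    if (format == "sif") {
      writeLines(paste(el$from, el$interaction, el$to, sep = "\t"), path)
    } else {
      write.table(el[c("from", "interaction", "to")], path, sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  }
  invisible(path)
}

#' Re-import an edge-list TSV written by [export_network()]
#' @param path edge TSV path.
#' @return A data frame with columns `from`, `interaction`, `to`.
#' @export
import_edge_tsv <- function(path) {
  df <- read_tsv_raw(path)
  require_cols(df, c("from", "interaction", "to"), "edge table")
  df[c("from", "interaction", "to")]
}
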