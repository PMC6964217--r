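#' @importFrom utils read.delim write.table
NULL

NCRNA_CLASSES <- c("miRNA", "lncRNA", "circRNA")
DIRECTIONS    <- c("up", "down", "mixed", "unknown")

ASSOC_COLS <- c("ncrna_id", "ncrna_class", "disease", "biomarker",
                "direction", "pmid", "sample_note")

# All tabular readers share one dialect: UTF-8, tab-separated, '#' comments.
read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE,
             colClasses = "character", encoding = "UTF-8",
             blank.lines.skip = TRUE)
}

require_cols <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(what, ": missing required column(s): ", paste(miss, collapse = ", "))
  invisible(df)
}

#' Normalize a miRNA name
#'
#' Rule-based unification of miRNA names: strips the species prefix
#' (`hsa-`) when present and canonicalizes case so that the family token is
#' written `miR` / `let` and everything after it is lower case (arm suffixes
#' `-5p`/`-3p` are preserved). The transformation is idempotent. No external
#' registry is consulted; the rules cover the common human miRNA name
#' vocabulary.
#'
#' @param raw character vector of raw miRNA names.
#' @return character vector of normalized names.
#' @examples
#' normalize_mirna_name("hsa-miR-146a-5p")  # "miR-146a-5p"
#' normalize_mirna_name("HSA-LET-7B-3P")    # "let-7b-3p"
#' @export
normalize_mirna_name <- function(raw) {
  raw <- as.character(raw)
  if (any(!nzchar(trimws(raw))))
    stop("miRNA name must be a non-empty string")
  x <- trimws(raw)
  x <- sub("^hsa-", "", x, ignore.case = TRUE)
  head_tok <- sub("-.*$", "", x)
  rest     <- ifelse(grepl("-", x), sub("^[^-]*", "", x), "")
  head_low <- tolower(head_tok)
  head_tok <- ifelse(head_low == "mir", "miR",
              ifelse(head_low == "let", "let", head_tok))
  paste0(head_tok, tolower(rest))
}

#' Read a curated ncRNA-disease association table
#'
#' Reads a tab-separated association export (columns `ncrna_id`,
#' `ncrna_class`, `disease`, `biomarker`, `direction`, `pmid`,
#' `sample_note`), maps every raw disease label through the catalog's merge
#' map, normalizes miRNA names, and collapses duplicate
#' (ncRNA, disease) pairs into single records. On deduplication the
#' biomarker flag is the logical OR across duplicates (one supporting report
#' suffices) and conflicting expression directions collapse to `"mixed"`.
#'
#' @param path path to the TSV file.
#' @param catalog a [disease_catalog()]; defaults to the shipped 23-label
#'   cardiovascular catalog.
#' @return A `data.frame` of class `pg_assoc` with one row per unique
#'   (ncrna_id, disease) pair; `biomarker` is logical.
#' @seealso [write_associations()], [build_bipartite()]
#' @export
read_associations <- function(path, catalog = default_disease_catalog()) {
  df <- read_tsv_raw(path)
  require_cols(df, ASSOC_COLS, "association table")
  df <- df[ASSOC_COLS]
  if (nrow(df) == 0L) return(as_pg_assoc(df[0, ]))

  bad_class <- !(df$ncrna_class %in% NCRNA_CLASSES)
  if (any(bad_class))
    stop("unknown ncrna_class value(s): ",
         paste(unique(df$ncrna_class[bad_class]), collapse = ", "),
         " (expected one of ", paste(NCRNA_CLASSES, collapse = ", "), ")")

  df$disease <- canonical_disease(df$disease, catalog)
  is_mir <- df$ncrna_class == "miRNA"
  if (any(is_mir)) df$ncrna_id[is_mir] <- normalize_mirna_name(df$ncrna_id[is_mir])

  df$biomarker <- parse_flag(df$biomarker)
  df$direction <- ifelse(df$direction %in% DIRECTIONS, df$direction, "unknown")

  dedupe_associations(df)
}

parse_flag <- function(x) {
  v <- tolower(trimws(as.character(x)))
  out <- v %in% c("1", "true", "yes", "y")
  known <- v %in% c("1", "true", "yes", "y", "0", "false", "no", "n", "")
  if (any(!known))
    stop("biomarker column: cannot parse value(s): ",
         paste(unique(x[!known]), collapse = ", "))
  out
}

dedupe_associations <- function(df) {
  key <- paste(df$ncrna_id, df$disease, sep = "\r")
  grp <- split(seq_len(nrow(df)), key)
  rows <- lapply(grp, function(i) {
    r <- df[i[1L], , drop = FALSE]
    r$biomarker <- any(df$biomarker[i])
    dirs <- unique(df$direction[i])
    dirs <- dirs[dirs != "unknown"]
    r$direction <- if (length(dirs) == 1L) dirs else if (length(dirs) > 1L) "mixed" else "unknown"
    r$pmid <- paste(unique(df$pmid[i][nzchar(df$pmid[i])]), collapse = ";")
    r
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  as_pg_assoc(out[order(out$ncrna_class, out$ncrna_id, out$disease), ])
}

as_pg_assoc <- function(df) {
  rownames(df) <- NULL
  class(df) <- c("pg_assoc", "data.frame")
  df
}

#' Write an association table
#'
#' Inverse of [read_associations()]: writing and re-reading yields an
#' identical record set (order-insensitive).
#'
#' @param records a `pg_assoc` data frame.
#' @param path output TSV path.
#' @export
write_associations <- function(records, path) {
  out <- as.data.frame(records)
  out$biomarker <- as.integer(out$biomarker)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns `mirna_id`, `gene`, `source` (provenance, free text).
#' Gene symbols are upper-cased; duplicate (miRNA, gene) pairs are dropped.
#'
#' @param path path to the TSV file.
#' @return A `data.frame` of class `pg_targets` with columns `mirna_id`,
#'   `gene`, `source`.
#' @export
read_targets <- function(path) {
  df <- read_tsv_raw(path)
  require_cols(df, c("mirna_id", "gene", "source"), "target table")
  df <- df[c("mirna_id", "gene", "source")]
  if (nrow(df)) {
    if (any(!nzchar(trimws(df$gene)))) stop("target table: empty gene symbol")
    df$mirna_id <- normalize_mirna_name(df$mirna_id)
    df$gene <- toupper(trimws(df$gene))
    df <- df[!duplicated(paste(df$mirna_id, df$gene, sep = "\r")), ]
  }
  rownames(df) <- NULL
  class(df) <- c("pg_targets", "data.frame")
  df
}

#' Read an essential-gene list
#'
#' One gene symbol per line; `#` comment lines and blank lines ignored.
#' Symbols are upper-cased and deduplicated.
#'
#' @param path path to the list file.
#' @return Character vector of essential-gene symbols.
#' @export
read_essential <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- readLines(path, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(toupper(x))
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are upper-cased and
#' deduplicated within each set.
#'
#' @param path path to the GMT file.
#' @return An object of class `pg_gmt`: a named list of sets, each a list
#'   with elements `description` and `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  idx <- which(keep)
  sets <- list()
  for (i in idx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop("GMT parse error at line ", i, ": expected >= 3 tab-separated fields")
    nm <- f[1L]
    if (nm %in% names(sets)) stop("GMT: duplicate set name: ", nm)
    genes <- unique(toupper(trimws(f[-(1:2)])))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT parse error at line ", i, ": empty gene set")
    sets[[nm]] <- list(description = f[2L], genes = genes)
  }
  structure(sets, class = "pg_gmt")
}

#' Write a GMT gene-set collection
#' @param sets a `pg_gmt` collection.
#' @param path output path.
#' @export
write_gmt <- function(sets, path) {
  stopifnot(inherits(sets, "pg_gmt"))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, sets[[nm]]$description, sets[[nm]]$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a ternary sponge-miRNA-mRNA table
#'
#' The table mixes two sections introduced by marker lines `lncRNA` and
#' `circRNA`; rows are `sponge<TAB>miRNA<TAB>mRNA` with `NA` as the sentinel
#' for an unreported mRNA. Each printed row yields one triple; multi-mRNA
#' cells such as `BCL2/HSP60` are kept verbatim here and split into separate
#' miRNA-mRNA edges by [build_ternary()].
#'
#' @param path path to the table; defaults to the packaged fixture of the
#'   published 17-row ternary table (14 lncRNA-miRNA and 3 circRNA-miRNA
#'   pairs).
#' @return A `data.frame` of class `pg_ternary_triples` with columns
#'   `sponge_id`, `sponge_class`, `mirna_id`, `mrna` (NA sentinel kept as
#'   `NA`), `mechanism`.
#' @export
read_ternary_table <- function(path = pgnet_example("ternary_table.tsv")) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  section <- NA_character_
  rows <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln %in% c("lncRNA", "circRNA")) { section <- ln; next }
    f <- trimws(strsplit(lines[i], "\t", fixed = TRUE)[[1L]])
    if (is.na(section))
      stop("ternary table parse error at line ", i,
           ": row outside any 'lncRNA'/'circRNA' section")
    if (length(f) < 3L)
      stop("ternary table parse error at line ", i, ": expected 3 fields")
    if (!nzchar(f[2L]))
      stop("ternary table parse error at line ", i, ": empty miRNA id")
    rows[[length(rows) + 1L]] <- data.frame(
      sponge_id = f[1L], sponge_class = section,
      mirna_id = normalize_mirna_name(f[2L]),
      mrna = if (toupper(f[3L]) == "NA") NA_character_ else f[3L],
      mechanism = if (length(f) >= 4L && nzchar(f[4L])) f[4L] else "unknown",
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sponge_id = character(), sponge_class = character(),
               mirna_id = character(), mrna = character(),
               mechanism = character(), stringsAsFactors = FALSE)
  mech_ok <- out$mechanism %in% c("ceRNA_sponge", "direct_target", "unknown")
  if (any(!mech_ok))
    stop("ternary table: unknown mechanism value(s): ",
         paste(unique(out$mechanism[!mech_ok]), collapse = ", "))
  rownames(out) <- NULL
  class(out) <- c("pg_ternary_triples", "data.frame")
  out
}

#' Read a miRNA-by-tissue expression matrix
#'
#' TSV whose first column holds miRNA ids and remaining columns one tissue
#' each. Values must be finite and non-negative; duplicate row or column ids
#' are rejected.
#'
#' @param path path to the TSV file.
#' @return A numeric matrix (miRNAs in rows, tissues in columns).
#' @export
read_expression <- function(path) {
  df <- read_tsv_raw(path)
  if (ncol(df) < 2L) stop("expression table: need an id column plus >= 1 tissue")
  ids <- df[[1L]]
  if (anyDuplicated(ids)) stop("expression table: duplicate miRNA ids")
  if (anyDuplicated(names(df)[-1L])) stop("expression table: duplicate tissue names")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  if (any(!is.finite(m))) stop("expression table: non-finite values")
  if (any(m < 0)) stop("expression table: negative expression values")
  rownames(m) <- ids
  m
}

#' Path to a packaged example data file
#' @param file file name under the package's `extdata/`; with no argument,
#'   lists the available files.
#' @export
pgnet_example <- function(file = NULL) {
  if (is.null(file))
    return(list.files(system.file("extdata", package = "pgnet")))
  p <- system.file("extdata", file, package = "pgnet")
  if (!nzchar(p)) stop("no packaged example file named ", file)
  p
}
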