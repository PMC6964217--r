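#' Disease catalogs
#'
#' A disease catalog is the controlled vocabulary of phenotype labels that
#' association tables are validated against, together with a merge map that
#' collapses raw literature labels (e.g. stage- or acuity-qualified variants)
#' onto their canonical form.
#'
#' @param labels character vector of canonical disease names (no duplicates).
#' @param merge_map named character vector mapping raw labels to canonical
#'   labels; every value must be a member of `labels`. Canonical labels map
#'   to themselves implicitly and need not be listed.
#' @return An object of class `pg_catalog` with elements `labels` and
#'   `merge_map` (the full map, identity entries included).
#' @examples
#' cat23 <- default_disease_catalog()
#' length(cat23$labels)  # 23
#' canonical_disease("Acute heart failure", cat23)
#' @export
disease_catalog <- function(labels, merge_map = character()) {
  labels <- as.character(labels)
  if (anyDuplicated(labels))
    stop("disease catalog labels contain duplicates: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  if (length(merge_map)) {
    if (is.null(names(merge_map)) || any(!nzchar(names(merge_map))))
      stop("merge_map must be a named character vector (raw -> canonical)")
    bad <- setdiff(unname(merge_map), labels)
    if (length(bad))
      stop("merge_map targets not in catalog labels: ",
           paste(unique(bad), collapse = ", "))
  }
  full <- c(stats::setNames(labels, labels), merge_map)
  full <- full[!duplicated(names(full))]
  structure(list(labels = labels, merge_map = full), class = "pg_catalog")
}

#' @describeIn disease_catalog The default 23-phenotype cardiovascular-disease
#'   catalog. The labels cover the CVD subtypes named in curated CVD-ncRNA
#'   association resources (ICD-10 I05-I79 range) plus the generalized
#'   "Others" category; the merge map collapses acuity-qualified heart-failure
#'   and myocardial-infarction labels onto their canonical form. The exact
#'   23-label roster is a reconstruction of that vocabulary, not a published
#'   list.
#' @export
default_disease_catalog <- function() {
  labels <- c(
    "Heart failure",
    "Myocardial infarction",
    "Atherosclerosis",
    "Cardiomyopathy",
    "Coronary heart disease",
    "Coronary artery disease",
    "Hypertension",
    "Pulmonary arterial hypertension",
    "Ischemic stroke",
    "Stroke",
    "Myocarditis",
    "Atrial fibrillation",
    "Arrhythmia",
    "Acute coronary syndrome",
    "Myocardial hypertrophy",
    "Cardiac fibrosis",
    "Aortic aneurysm",
    "Aortic stenosis",
    "Peripheral artery disease",
    "Pulmonary embolism",
    "Rheumatic heart disease",
    "Congenital heart disease",
    "Others"
  )
  merge_map <- c(
    "Acute heart failure"         = "Heart failure",
    "Chronic heart failure"       = "Heart failure",
    "Acute myocardial infarction" = "Myocardial infarction"
  )
  disease_catalog(labels, merge_map)
}

#' @describeIn disease_catalog Map raw disease labels to canonical ones;
#'   errors listing every unmappable label.
#' @param raw character vector of raw disease labels.
#' @param catalog a `pg_catalog`.
#' @export
canonical_disease <- function(raw, catalog) {
  stopifnot(inherits(catalog, "pg_catalog"))
  out <- unname(catalog$merge_map[as.character(raw)])
  if (anyNA(out))
    stop("disease labels not in catalog (extend the catalog or merge map): ",
         paste(unique(raw[is.na(out)]), collapse = ", "))
  out
}

#' @export
print.pg_catalog <- function(x, ...) {
  cat("Disease catalog:", length(x$labels), "canonical labels,",
      sum(names(x$merge_map) != unname(x$merge_map)), "merge rules\n")
  invisible(x)
}
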