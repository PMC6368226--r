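#' Validate a sample annotation table
#'
#' Checks that the annotation covers every sample of the matrix exactly
#' once, that the core columns are present and well-typed, and (for
#' cell-line experiments) that the phenotype class is constant within a
#' unit.
#'
#' @param ann Data frame with at least `sample_id`, `unit_id`, `treatment`
#'   ("untreated"/"treated"); cell-line annotations additionally
#'   `time_hours` and `phenotype_class`; cohort annotations carry clinical
#'   fields (`os_time`, `os_event`, `met_time`, `met_event`,
#'   `baseline_metastasis`, `stage`, `mut_<GENE>` columns) as needed.
#' @param m Optional [expr_matrix] the annotation must cover.
#' @return The annotation, row-ordered to match `m` when given.
#' @export
validate_annotation <- function(ann, m = NULL) {
  req <- c("sample_id", "unit_id", "treatment")
  miss <- setdiff(req, colnames(ann))
  if (length(miss))
    stopf("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$sample_id))
    stopf("duplicated sample_id in annotation: %s",
          paste(unique(ann$sample_id[duplicated(ann$sample_id)]), collapse = ", "))
  bad <- setdiff(unique(ann$treatment), c("untreated", "treated"))
  if (length(bad))
    stopf("treatment must be 'untreated' or 'treated' (got: %s)",
          paste(bad, collapse = ", "))
  if ("phenotype_class" %in% colnames(ann)) {
    n_cls <- tapply(ann$phenotype_class, ann$unit_id,
                    function(x) length(unique(x)))
    if (any(n_cls > 1))
      stopf("phenotype_class varies within unit(s): %s",
            paste(names(n_cls)[n_cls > 1], collapse = ", "))
  }
  if (!is.null(m)) {
    ids <- sample_ids(m)
    miss <- setdiff(ids, ann$sample_id)
    if (length(miss))
      stopf("samples without annotation: %s", paste(miss, collapse = ", "))
    ann <- ann[match(ids, ann$sample_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  ann
}

#' Read a sample annotation TSV
#'
#' @param path Tab-delimited annotation file with a header row.
#' @return A data frame.
#' @export
read_sample_annotation <- function(path) {
  utils::read.delim(path, header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}
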