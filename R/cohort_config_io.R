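# YAML round-trip for the cohort configuration. Matrix-valued fields are
# serialized as nested maps (row label -> named values per group) so that
# config files stay hand-editable.

COHORT_MATRIX_FIELDS <- c("tier_line_means", "tier_line_sds",
                          "drugs_per_rx_mean_sd", "nonmedicinal_rates",
                          "drug_class_probs")

#' Write a cohort configuration to YAML
#'
#' @param config A [cohort_config()].
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  out <- unclass(config)
  for (f in COHORT_MATRIX_FIELDS) {
    m <- out[[f]]
    out[[f]] <- stats::setNames(
      lapply(rownames(m), function(r) as.list(m[r, ])),
      rownames(m)
    )
  }
  # yaml drops the names of atomic vectors; serialize them as maps
  out <- lapply(out, function(x) {
    if (!is.list(x) && !is.null(names(x))) as.list(x) else x
  })
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Read a cohort configuration from YAML
#'
#' Keys mirror the arguments of [cohort_config()]; omitted keys keep the
#' default margins. Matrix-valued fields are nested maps of row label to
#' per-group values. Unknown keys are an error.
#'
#' @param path Path to the YAML file.
#' @return A validated \code{cohort_config}.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path)) abort_io(sprintf("cohort config not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(cohort_config))
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "unknown cohort config key%s: %s",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")
    ))
  }
  for (f in intersect(COHORT_MATRIX_FIELDS, names(raw))) {
    nested <- raw[[f]]
    rows <- names(nested)
    cols <- names(nested[[1]])
    m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
                dimnames = list(rows, cols))
    for (r in rows) m[r, ] <- unlist(nested[[r]])[cols]
    raw[[f]] <- m
  }
  for (f in setdiff(names(raw), COHORT_MATRIX_FIELDS)) {
    if (is.list(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(cohort_config, raw)
}
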