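#' Read an alignment from FASTA
#'
#' @param path FASTA file path.
#' @return An alignment tibble `(label, sequence)`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  alignment(names(x), as.character(x))
}

#' Write an alignment to FASTA
#'
#' @param aln An alignment tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(aln, path) {
  x <- Biostrings::BStringSet(stats::setNames(aln$sequence, aln$label))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read / write a partition table
#'
#' Partitions are TSV with columns `label`, `entity`, and optionally
#' `kind`.
#'
#' @param path TSV path.
#' @return A partition tibble.
#' @export
read_partition_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @rdname read_partition_tsv
#' @param partition A partition tibble.
#' @export
write_partition_tsv <- function(partition, path) {
  readr::write_tsv(partition, path)
  invisible(path)
}

#' Read / write a diagnostic ruleset
#'
#' Rulesets are TSV with columns `entity`, `ref_position`, `column`,
#' `state`; the fragment width travels in a `# n_columns=` header comment.
#'
#' @param path TSV path.
#' @return A `diagnostic_rules` tibble.
#' @export
read_ruleset_tsv <- function(path) {
  first <- readLines(path, n = 1)
  n_col <- as.integer(sub("^# n_columns=", "", first))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  attr(out, "entities") <- sort(unique(out$entity))
  attr(out, "n_columns") <- n_col
  class(out) <- c("diagnostic_rules", class(out))
  out
}

#' @rdname read_ruleset_tsv
#' @param rules A `diagnostic_rules` tibble.
#' @export
write_ruleset_tsv <- function(rules, path) {
  writeLines(paste0("# n_columns=", attr(rules, "n_columns")), path)
  readr::write_tsv(tibble::as_tibble(unclass(rules)[
    c("entity", "column", "ref_position", "state")]), path, append = TRUE,
    col_names = TRUE)
  invisible(path)
}

#' Write the artifacts of a GMYC fit
#'
#' Serializes a fit into a directory: `gmyc.json` (parameters,
#' log-likelihoods, LRT, confidence sets), `partition.tsv`, `profile.tsv`
#' and `ltt.tsv`, plus a `manifest.json` recording the options and a
#' content hash so identical runs are byte-identical.
#'
#' @param fit A `gmyc_fit` object.
#' @param dir Output directory (created if missing).
#' @param seed Seed to record in the manifest, if any.
#' @return `dir`, invisibly.
#' @export
write_gmyc_results <- function(fit, dir, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(
    threshold = fit$threshold,
    params = as.list(fit$params),
    logL = fit$logL,
    logL_null = fit$null$logL,
    null = list(lambda = fit$null$lambda, p = fit$null$p),
    lrt = as.list(fit$lrt),
    df = fit$df,
    K = fit$K,
    confidence = as.list(fit$confidence)
  )
  jsonlite::write_json(res, file.path(dir, "gmyc.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_tsv(fit$partition, file.path(dir, "partition.tsv"))
  readr::write_tsv(fit$profile, file.path(dir, "profile.tsv"))
  readr::write_tsv(ltt_series(fit$tree), file.path(dir, "ltt.tsv"))
  manifest <- list(
    artifact = "gmyc_fit",
    package_version = as.character(utils::packageVersion("gmycbar")),
    options = fit$options,
    seed = seed,
    content_hash = rlang::hash(res)
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
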