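# Plain-text readers/writers for every pipeline artifact. All tabular
# formats are CSV/TSV with header rows; the beta and residual matrices are
# TSV with the probe id in the first column.

#' Write a probes-x-samples matrix as TSV
#'
#' @param mat Numeric matrix with probe ids as rownames.
#' @param path Output path.
#' @param id_col Name of the first (probe id) column.
#' @return The path, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_col
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

#' Read a probes-x-samples TSV matrix
#'
#' @param path TSV path written by [write_matrix_tsv()].
#' @return Numeric matrix with probe ids as rownames.
#' @export
read_matrix_tsv <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  mat
}

#' Write every artifact of a simulated study to a directory
#'
#' Emits `applications.csv`, `addresses.csv`, `covariates.csv`,
#' `exposure_profiles.csv`, `counts.csv`, `beta.tsv`, `annotation.csv` and
#' `truth.json`.
#'
#' @param study Output of [simulate_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wcsv <- function(d, f) write.csv(d, file.path(dir, f), row.names = FALSE)
  wcsv(study$applications, "applications.csv")
  wcsv(study$addresses, "addresses.csv")
  wcsv(study$covariates, "covariates.csv")
  wcsv(study$profiles, "exposure_profiles.csv")
  wcsv(study$counts, "counts.csv")
  wcsv(study$annotation, "annotation.csv")
  write_matrix_tsv(study$beta, file.path(dir, "beta.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

read_study_tables <- function(dir) {
  rcsv <- function(f) read.csv(file.path(dir, f), stringsAsFactors = FALSE)
  list(applications = rcsv("applications.csv"),
       addresses = rcsv("addresses.csv"),
       covariates = rcsv("covariates.csv"))
}

#' Write an EWAS results table
#'
#' TSV sorted by p-value, with annotation columns when present.
#'
#' @param ewas `ewas_table` from [run_ewas()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_ewas_tsv <- function(ewas, path) {
  cols <- intersect(c("probe_id", "chromosome", "position", "gene",
                      "bicor_r", "slope", "t", "p", "p_bh", "significant"),
                    names(ewas))
  out <- as.data.frame(ewas)[order(ewas$p), cols, drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
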