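# Readers and writers for the pipeline's tabular formats. All tables are
# plain TSV/CSV; matrices carry probe/gene ids in the first column and
# sample ids in the header.

.read_matrix_tsv <- function(path, what = "matrix") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 2L) stop(what, " file must have an id column plus >= 1 sample column: ", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate row ids in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix
#'
#' Reads a probes-by-samples TSV of methylation beta values. The first
#' column holds probe ids; the header row holds sample ids. Values must be
#' in \[0, 1\] or missing.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_beta_matrix <- function(path) {
  m <- .read_matrix_tsv(path, "beta matrix")
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]: ", path)
  m
}

#' Read a probe QC matrix
#'
#' Reads a probes-by-samples TSV of detection p-values or bead counts,
#' shaped like the companion beta matrix.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (probes x samples) with dimnames.
#' @export
read_qc_matrix <- function(path) {
  .read_matrix_tsv(path, "QC matrix")
}

#' Read a sample sheet
#'
#' Reads a CSV of per-sample covariates. Requires `sample_id`; recognised
#' columns include `reported_sex` (`XX`/`XY`/`unknown`), `tissue`,
#' `gestational_age`, `cohort`, the six placental cell-type proportions
#' (`prop_nrbc`, `prop_hofbauer`, `prop_endothelial`, `prop_stromal`,
#' `prop_cytotrophoblast`, `prop_syncytiotrophoblast`), three ancestry
#' coordinates (`ancestry_1..3`), `birthweight_z`, `placental_weight_g`,
#' `maternal_age`, `epi_age_accel`. When all six cell proportions are
#' present their sum is checked against \[0.95, 1.05\].
#'
#' @param path Path to the CSV file.
#' @return data.frame of sample covariates.
#' @export
read_sample_sheet <- function(path) {
  ss <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!"sample_id" %in% names(ss)) stop("sample sheet requires a sample_id column")
  if (anyDuplicated(ss$sample_id)) stop("duplicate sample_id in sample sheet")
  cellcols <- paste0("prop_", c("nrbc", "hofbauer", "endothelial", "stromal",
                                "cytotrophoblast", "syncytiotrophoblast"))
  if (all(cellcols %in% names(ss))) {
    tot <- rowSums(ss[, cellcols])
    ok <- is.na(tot) | (tot >= 0.95 & tot <= 1.05)
    if (!all(ok)) stop("cell-type proportions must sum to 1 +/- 0.05 (sample ",
                       ss$sample_id[!ok][1L], ")")
  }
  ss
}

#' Read an allele-balance matrix
#'
#' Reads a genes-by-samples TSV of per-gene allele balances. Values in
#' \[0, 1\] are folded to `max(b, 1 - b)` so the matrix is on the skew
#' scale \[0.5, 1\]; missing values mark uninformative gene/sample pairs.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x samples), values in \[0.5, 1\] or `NA`.
#' @export
read_allele_balance <- function(path) {
  m <- .read_matrix_tsv(path, "allele-balance matrix")
  rng <- range(m, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("allele balances must lie in [0, 1]: ", path)
  fold_balance(m)
}

#' Fold allele balances onto the skew scale
#'
#' Maps a balance in \[0, 1\] to `max(b, 1 - b)` in \[0.5, 1\], the scale
#' on which the XCI thresholds are stated.
#'
#' @param b Numeric vector or matrix of balances in \[0, 1\].
#' @return Same shape, values in \[0.5, 1\] (missing preserved).
#' @export
fold_balance <- function(b) {
  pmax(b, 1 - b)
}

#' Write a table with a metadata header
#'
#' Writes a TSV preceded by `#`-prefixed metadata lines (package version
#' plus any extra key-value pairs), the convention used by all pipeline
#' outputs.
#'
#' @param x data.frame to write.
#' @param path Output path.
#' @param meta Named character vector of extra metadata lines.
#' @return Invisibly, `path`.
#' @export
write_tsv_header <- function(x, path, meta = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  version <- as.character(utils::packageVersion("xcimeth"))
  writeLines(paste0("# xcimeth ", version), con)
  if (length(meta)) {
    writeLines(paste0("# ", names(meta), "=", unname(meta)), con)
  }
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic text serialisation of a numeric matrix with ids.
.write_matrix_tsv <- function(m, path, id_name = "id") {
  df <- data.frame(rownames(m), format(m, digits = 10, trim = TRUE,
                                       scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c(id_name, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
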