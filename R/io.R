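# Readers and writers for the plain-text formats the pipeline exchanges:
# beta matrices (TSV/CSV, probes x samples), probe annotations, sample
# sheets and probe panels. All readers validate on the way in.

#' Read a beta-value matrix
#'
#' Reads a TSV/CSV matrix of methylation beta values with probes in rows
#' (first column probe identifiers, header row sample identifiers), the
#' layout used by GEO series matrices. Gzipped files are accepted.
#'
#' @param path Path to a delimited text file (`.gz` accepted).
#' @param transpose If `TRUE` the file stores samples in rows and is
#'   transposed to the probes-by-samples convention after reading.
#' @param check If `TRUE` (default) the matrix is validated: finite values
#'   in \[0, 1\], unique probe and sample identifiers.
#' @return A numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path, transpose = FALSE, check = TRUE) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    dt <- data.table::fread(text = readLines(con), header = TRUE,
                            data.table = FALSE)
  } else {
    dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  }
  if (ncol(dt) < 2) stop("beta matrix file needs an id column plus >=1 sample column")
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (transpose) m <- t(m)
  if (check) validate_beta_matrix(m)
  m
}

#' Write a beta-value matrix
#'
#' @param m Probes-by-samples numeric matrix with dimnames.
#' @param path Output path; written as CSV with a `probe_id` first column.
#' @export
write_beta_matrix <- function(m, path) {
  assert_matrix(m)
  dt <- data.table::data.table(probe_id = rownames(m), m)
  data.table::fwrite(dt, path)
  invisible(path)
}

#' Validate a beta-value matrix
#'
#' Checks the invariants expected of raw beta values: a numeric matrix with
#' unique, non-missing probe and sample identifiers and all values finite
#' within \[0, 1\]. Values outside the unit interval (or `NA`) indicate an
#' upstream processing problem and are rejected.
#'
#' @param m Probes-by-samples numeric matrix.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_beta_matrix <- function(m) {
  assert_matrix(m)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("probe identifiers (rownames) must be present and unique")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("sample identifiers (colnames) must be present and unique")
  if (anyNA(m)) {
    bad <- rownames(m)[which(rowSums(is.na(m)) > 0)]
    stop(sprintf("matrix contains missing values (e.g. probe %s); impute or drop first",
                 bad[1]))
  }
  if (any(!is.finite(m))) stop("matrix contains non-finite values")
  if (min(m) < 0 || max(m) > 1)
    stop("beta values must lie in [0, 1]")
  invisible(m)
}

#' Impute missing beta values with per-probe medians
#'
#' @param m Probes-by-samples matrix, possibly with `NA` cells.
#' @return The matrix with each `NA` replaced by the median of its probe's
#'   observed values. Probes with no observed value at all are an error.
#' @export
impute_median <- function(m) {
  assert_matrix(m)
  nas <- which(is.na(m), arr.ind = TRUE)
  if (nrow(nas) == 0L) return(m)
  med <- apply(m, 1, stats::median, na.rm = TRUE)
  if (anyNA(med[unique(nas[, 1])]))
    stop("some probes have no observed values; cannot impute")
  m[nas] <- med[nas[, 1]]
  m
}

#' Read a probe annotation table
#'
#' Expects a CSV with columns `probe_id`, `chrom`, `on_sex_chromosome`,
#' `unique_hg19_alignment`, `contains_snp`, `on_epic`. Chromosome names are
#' normalised (`"chrX"` and `"X"` are equivalent) and checked for
#' consistency with the sex-chromosome flag.
#'
#' @param path CSV path.
#' @return A data.frame, one row per probe, flags as logicals.
#' @export
read_probe_annotation <- function(path) {
  ann <- data.table::fread(path, data.table = FALSE)
  need <- c("probe_id", "chrom", "on_sex_chromosome", "unique_hg19_alignment",
            "contains_snp", "on_epic")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing columns: ", paste(miss, collapse = ", "))
  ann <- ann[, need]
  validate_probe_annotation(ann)
}

#' Validate (and normalise) a probe annotation table
#'
#' @param ann A data.frame with the six annotation columns.
#' @return The normalised annotation data.frame.
#' @export
validate_probe_annotation <- function(ann) {
  if (anyDuplicated(ann$probe_id)) stop("duplicated probe_id in annotation")
  ann$chrom <- sub("^chr", "", as.character(ann$chrom))
  for (fl in c("on_sex_chromosome", "unique_hg19_alignment", "contains_snp", "on_epic"))
    ann[[fl]] <- as.logical(ann[[fl]])
  if (anyNA(ann[c("on_sex_chromosome", "unique_hg19_alignment",
                  "contains_snp", "on_epic")]))
    stop("annotation flags must be TRUE/FALSE with no missing values")
  sexy <- ann$chrom %in% c("X", "Y")
  bad <- which(sexy != ann$on_sex_chromosome & !is.na(ann$chrom) & ann$chrom != "")
  if (length(bad))
    stop(sprintf("on_sex_chromosome flag inconsistent with chrom for probe %s",
                 ann$probe_id[bad[1]]))
  ann
}

#' Read a sample sheet
#'
#' CSV with columns `sample_id`, `batch` and optionally `class_label`.
#'
#' @param path CSV path.
#' @return A data.frame with one row per sample.
#' @export
read_sample_sheet <- function(path) {
  ss <- data.table::fread(path, data.table = FALSE)
  if (!all(c("sample_id", "batch") %in% names(ss)))
    stop("sample sheet needs 'sample_id' and 'batch' columns")
  if (anyDuplicated(ss$sample_id)) stop("duplicated sample_id in sample sheet")
  ss$sample_id <- as.character(ss$sample_id)
  ss$batch <- as.character(ss$batch)
  ss
}

#' Write / read a probe panel
#'
#' A probe panel is serialised as a two-column CSV (`probe_id`,
#' `importance`) ordered by descending importance.
#'
#' @param panel A `probe_panel` (see [rf_importance()]).
#' @param path CSV path.
#' @return `write_probe_panel`: the path, invisibly. `read_probe_panel`:
#'   the panel.
#' @export
write_probe_panel <- function(panel, path) {
  stopifnot(inherits(panel, "probe_panel"))
  data.table::fwrite(as.data.frame(unclass(panel))[c("probe_id", "importance")], path)
  invisible(path)
}

#' @rdname write_probe_panel
#' @export
read_probe_panel <- function(path) {
  df <- data.table::fread(path, data.table = FALSE)
  probe_panel(df$probe_id, df$importance)
}
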