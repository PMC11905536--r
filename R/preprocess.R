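# Preprocessing: probe filtering, log2(v + 1) transform and its inverse,
# per-probe linear-model batch correction, and a PCA-based report of how
# much principal-component variance is attributable to batch.

#' Filter probes against annotation flags
#'
#' Removes probes in any of the four exclusion categories used for
#' methylation-array classifier construction: probes on the sex
#' chromosomes, probes without a unique hg19 alignment, probes whose target
#' sequence contains a SNP, and probes absent from the EPIC chip. A probe
#' survives only if all four flags are clean; the original probe order is
#' preserved. The operation is idempotent.
#'
#' @param m Probes-by-samples beta matrix with probe rownames.
#' @param annotation Annotation data.frame as returned by
#'   [read_probe_annotation()]; must cover every probe in `m`.
#' @return The matrix restricted to retained probes.
#' @export
filter_probes <- function(m, annotation) {
  assert_matrix(m)
  annotation <- validate_probe_annotation(annotation)
  idx <- match(rownames(m), annotation$probe_id)
  if (anyNA(idx)) {
    missing <- rownames(m)[is.na(idx)]
    stop(sprintf("probe(s) not present in annotation: %s%s",
                 paste(utils::head(missing, 5), collapse = ", "),
                 if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5) else ""))
  }
  ann <- annotation[idx, ]
  keep <- !ann$on_sex_chromosome & ann$unique_hg19_alignment &
    !ann$contains_snp & ann$on_epic
  if (!any(keep)) stop("no probes survive filtering")
  m[keep, , drop = FALSE]
}

#' Log-transform beta values
#'
#' Applies the elementwise `log2(v + 1)` variance-stabilising transform.
#' Beta values in \[0, 1\] map into \[0, 1\] (`log2(2) = 1` at `v = 1`).
#'
#' @param m Numeric matrix with values `>= 0`.
#' @return Transformed matrix of the same shape.
#' @seealso [inverse_transform()]
#' @export
log_transform <- function(m) {
  if (min(m, na.rm = TRUE) < 0) stop("log_transform requires non-negative values")
  log2(m + 1)
}

#' Invert the log transform
#'
#' Elementwise `2^v - 1`, restoring values to the beta scale. Exact inverse
#' of [log_transform()] up to floating-point round-off.
#'
#' @param m Numeric matrix on the log2(v + 1) scale.
#' @return Matrix on the original scale.
#' @export
inverse_transform <- function(m) {
  2^m - 1
}

#' Clip values to the unit interval
#'
#' Batch correction can push inverse-transformed values slightly outside
#' \[0, 1\]; this clips them back and reports how many cells were affected.
#'
#' @param m Numeric matrix.
#' @param quiet Suppress the message about clipped cells.
#' @return The clipped matrix with attribute `n_clipped`.
#' @export
clip_beta <- function(m, quiet = FALSE) {
  n <- sum(m < 0 | m > 1)
  if (n > 0 && !quiet)
    message(sprintf("clipped %d of %d cells back into [0, 1]", n, length(m)))
  m[m < 0] <- 0
  m[m > 1] <- 1
  attr(m, "n_clipped") <- n
  m
}

#' Remove batch effects with a per-probe linear model
#'
#' Fits, for every probe, an ordinary-least-squares model of the
#' (log-transformed) values on an intercept plus the batch factor with
#' sum-to-zero contrasts, and subtracts the estimated batch terms so that
#' only deviations from the grand mean are removed. This is the standard
#' linear-model correction implemented by `limma::removeBatchEffect`, which
#' is used as the computational engine. A single-batch input is returned
#' unchanged. The correction is estimated without reference to class
#' labels and is idempotent.
#'
#' @param m Probes-by-samples matrix, already log-transformed.
#' @param batch Batch label per sample (character or factor, one per
#'   column of `m`).
#' @return Corrected matrix of the same shape.
#' @export
remove_batch_effect <- function(m, batch) {
  assert_matrix(m)
  if (length(batch) != ncol(m))
    stop("'batch' must supply one label per sample (column)")
  batch <- if (is.factor(batch)) batch else factor(batch)
  counts <- table(batch)
  if (any(counts == 0)) stop("batch level with zero samples: ",
                             paste(names(counts)[counts == 0], collapse = ", "))
  if (nlevels(batch) < 2) return(m)
  if (any(counts < 2))
    stop("each batch needs >= 2 samples to estimate its effect")
  limma::removeBatchEffect(m, batch = batch)
}

#' Fraction of principal-component variance associated with batch
#'
#' Computes sample-space principal components of the matrices before and
#' after correction, regresses each of the top PCs on the batch factor,
#' and summarises batch-associated variance two ways: the R-squared on PC1
#' alone, and the variance-weighted mean R-squared across the top PCs.
#' A successful correction shows `after <= before`.
#'
#' @param before,after Probes-by-samples matrices over the same samples.
#' @param batch Batch label per sample.
#' @param n_pcs Number of leading PCs to examine (capped by the data rank).
#' @return A data.frame with rows `before` and `after` and columns
#'   `pc1_r2` and `weighted_r2`.
#' @export
batch_variance_report <- function(before, after, batch, n_pcs = 10) {
  assert_matrix(before); assert_matrix(after)
  if (ncol(before) != ncol(after))
    stop("'before' and 'after' must contain the same samples")
  if (ncol(before) < 2) stop("need at least two samples for PCA")
  batch <- factor(batch)
  one <- function(m) {
    pc <- stats::prcomp(t(m), center = TRUE, scale. = FALSE)
    k <- min(n_pcs, ncol(pc$x), sum(pc$sdev > 1e-12))
    vars <- pc$sdev[seq_len(k)]^2
    r2 <- vapply(seq_len(k), function(i) {
      fit <- stats::lm(pc$x[, i] ~ batch)
      summary(fit)$r.squared
    }, numeric(1))
    c(pc1_r2 = r2[1], weighted_r2 = sum(r2 * vars) / sum(vars))
  }
  out <- rbind(before = one(before), after = one(after))
  as.data.frame(out)
}

#' Run the full preprocessing stage
#'
#' Convenience wrapper chaining probe filtering, optional median
#' imputation, the log2(v + 1) transform, batch correction, inverse
#' transform and clipping. Returns both scales because downstream
#' modelling consumes the corrected log-scale matrix while the beta-scale
#' matrix is what array tools expect on disk.
#'
#' @param m Probes-by-samples beta matrix.
#' @param annotation Probe annotation (see [filter_probes()]); `NULL`
#'   skips filtering.
#' @param batch Batch label per sample; `NULL` skips correction.
#' @param impute Impute missing cells with per-probe medians instead of
#'   rejecting them.
#' @return List with elements `log` (corrected, log scale), `beta`
#'   (corrected, clipped beta scale) and `n_clipped`.
#' @export
preprocess_beta <- function(m, annotation = NULL, batch = NULL, impute = FALSE) {
  if (impute) m <- impute_median(m)
  validate_beta_matrix(m)
  if (!is.null(annotation)) m <- filter_probes(m, annotation)
  lg <- log_transform(m)
  if (!is.null(batch)) lg <- remove_batch_effect(lg, batch)
  bt <- clip_beta(inverse_transform(lg), quiet = TRUE)
  list(log = lg, beta = bt, n_clipped = attr(bt, "n_clipped"))
}
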