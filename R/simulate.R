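# Seeded simulator of Infinium-like beta-value cohorts: bimodal
# methylation backgrounds, disjoint class-specific informative probe
# blocks, imbalanced class sizes, logit-scale batch offsets, and held-out
# novel classes for open-set experiments.

#' Specify a synthetic methylation cohort
#'
#' Defaults describe a desk-scale cohort with the features that matter for
#' the pipeline: 8 known classes with a ~7:1 imbalance (sizes
#' 40/30/20/15/12/10/8/6), 2 novel classes withheld from training, 300
#' probes of which each class owns a disjoint block of 10 informative
#' probes, 2 batches with logit-scale offsets, and Beta-distributed values
#' with concentration 20 around bimodal means (hypermethylated ~0.8 vs
#' hypomethylated ~0.2).
#'
#' @param n_known_classes Number of known classes.
#' @param class_sizes Samples per known class (recycled/validated against
#'   `n_known_classes`).
#' @param n_novel_classes Classes generated but meant to be excluded from
#'   training (their samples carry `"unknown"`-style truth downstream).
#' @param novel_class_size Samples per novel class.
#' @param n_probes Total probe count.
#' @param n_informative Informative probes per class (disjoint blocks,
#'   including the novel classes).
#' @param n_batches Number of batches (round-robin assignment).
#' @param batch_sd Standard deviation of the per-probe, per-batch
#'   logit-scale offsets (0 disables batch effects).
#' @param concentration Beta-distribution concentration `c`; a mean `m`
#'   yields shapes `(m*c, (1-m)*c)`.
#' @param seed Integer seed; generation is fully reproducible under it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_known_classes = 8,
                           class_sizes = c(40, 30, 20, 15, 12, 10, 8, 6),
                           n_novel_classes = 2,
                           novel_class_size = 15,
                           n_probes = 300,
                           n_informative = 10,
                           n_batches = 2,
                           batch_sd = 0.5,
                           concentration = 20,
                           seed = 1) {
  if (length(class_sizes) != n_known_classes)
    stop("class_sizes must have one entry per known class")
  if (any(class_sizes < 1) || (n_novel_classes > 0 && novel_class_size < 1))
    stop("class sizes must be positive")
  if (n_informative * (n_known_classes + n_novel_classes) > n_probes)
    stop("informative blocks exceed the probe count")
  if (n_batches < 1) stop("need >= 1 batch")
  structure(list(n_known_classes = n_known_classes, class_sizes = class_sizes,
                 n_novel_classes = n_novel_classes,
                 novel_class_size = novel_class_size, n_probes = n_probes,
                 n_informative = n_informative, n_batches = n_batches,
                 batch_sd = batch_sd, concentration = concentration,
                 seed = seed),
            class = "synthetic_spec")
}

#' Generate a synthetic beta-value cohort
#'
#' Every probe has a bimodal background mean (hypo ~0.2 or hyper ~0.8,
#' chosen at random per probe); each class — known and novel — owns a
#' disjoint block of informative probes whose methylation state is flipped
#' in samples of that class. Beta values are drawn from Beta distributions
#' around those means, then per-batch offsets are added on the logit scale
#' and mapped back to \[0, 1\], so batch effects survive downstream
#' transformation non-trivially. Novel classes share no informative block
#' with known classes.
#'
#' @param spec A [synthetic_spec()].
#' @return A list:
#'   \describe{
#'     \item{beta}{probes x samples beta matrix (all samples, novel last).}
#'     \item{samples}{sample sheet data.frame: `sample_id`, `class_label`
#'       (novel classes labelled `Novel1`, ...), `batch`, `is_novel`.}
#'     \item{informative}{named list: probe ids of each class's block.}
#'     \item{spec}{the input spec.}
#'   }
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    K <- spec$n_known_classes; Knov <- spec$n_novel_classes
    classes <- sprintf("Class%02d", seq_len(K))
    novel <- if (Knov > 0) sprintf("Novel%d", seq_len(Knov)) else character(0)
    sizes <- c(spec$class_sizes, rep(spec$novel_class_size, Knov))
    all_classes <- c(classes, novel)
    n <- sum(sizes)
    P <- spec$n_probes
    probes <- sprintf("cg%08d", seq_len(P))

    # bimodal background: hypo (0.2) or hyper (0.8) per probe, with jitter
    base_state <- sample(c(0.2, 0.8), P, replace = TRUE)
    base_mean <- pmin(pmax(base_state + stats::rnorm(P, 0, 0.03), 0.05), 0.95)

    blocks <- split(seq_len(spec$n_informative * length(all_classes)),
                    rep(seq_along(all_classes), each = spec$n_informative))
    names(blocks) <- all_classes

    y <- rep(all_classes, sizes)
    sample_id <- sprintf("S%04d", seq_len(n))
    batch <- rep_len(sprintf("batch%d", seq_len(spec$n_batches)), n)

    M <- matrix(base_mean, P, n)
    for (cl in all_classes) {
      cols <- which(y == cl)
      rows <- blocks[[cl]]
      M[rows, cols] <- 1 - M[rows, cols]  # flip methylation state
    }
    cc <- spec$concentration
    beta <- matrix(stats::rbeta(P * n, M * cc, (1 - M) * cc), P, n)

    if (spec$n_batches > 1 && spec$batch_sd > 0) {
      off <- matrix(stats::rnorm(P * spec$n_batches, 0, spec$batch_sd),
                    P, spec$n_batches)
      off <- off - rowMeans(off)  # identifiable: offsets sum to zero per probe
      bix <- match(batch, sprintf("batch%d", seq_len(spec$n_batches)))
      beta <- inv_logit(beta_logit(beta) + off[, bix])
    }
    dimnames(beta) <- list(probes, sample_id)

    samples <- data.frame(sample_id = sample_id, class_label = y,
                          batch = batch, is_novel = y %in% novel,
                          stringsAsFactors = FALSE)
    list(beta = beta, samples = samples,
         informative = lapply(blocks, function(ix) probes[ix]),
         spec = spec)
  })
}

#' Generate a probe annotation with planted filter categories
#'
#' Produces an annotation covering `probe_ids` with exact planted counts
#' of each exclusion category (sex-chromosome, non-unique hg19 alignment,
#' SNP-containing, absent from EPIC), assigned to disjoint random probes.
#'
#' @param probe_ids Probe identifiers to annotate.
#' @param n_sex,n_nonunique,n_snp,n_off_epic Planted counts (default 0 =
#'   all clean).
#' @param exclude Probe ids never flagged (e.g. informative probes whose
#'   signal an experiment depends on).
#' @param seed Seed for the random placement.
#' @return Annotation data.frame compatible with [filter_probes()].
#' @export
generate_probe_annotation <- function(probe_ids, n_sex = 0, n_nonunique = 0,
                                      n_snp = 0, n_off_epic = 0,
                                      exclude = character(0), seed = NULL) {
  total <- n_sex + n_nonunique + n_snp + n_off_epic
  pool <- setdiff(probe_ids, exclude)
  if (total > length(pool))
    stop("planted counts exceed the number of flaggable probes")
  with_seed(seed, {
    flagged <- sample(pool, total)
    g <- rep(c("sex", "nonunique", "snp", "epic"),
             c(n_sex, n_nonunique, n_snp, n_off_epic))
    ann <- data.frame(
      probe_id = probe_ids,
      chrom = "1",
      on_sex_chromosome = FALSE,
      unique_hg19_alignment = TRUE,
      contains_snp = FALSE,
      on_epic = TRUE,
      stringsAsFactors = FALSE
    )
    rownames(ann) <- ann$probe_id
    ann[flagged[g == "sex"], "chrom"] <- "X"
    ann[flagged[g == "sex"], "on_sex_chromosome"] <- TRUE
    ann[flagged[g == "nonunique"], "unique_hg19_alignment"] <- FALSE
    ann[flagged[g == "snp"], "contains_snp"] <- TRUE
    ann[flagged[g == "epic"], "on_epic"] <- FALSE
    rownames(ann) <- NULL
    ann
  })
}

#' Stratified train/test split of sample indices
#'
#' @param y Class label per sample.
#' @param test_fraction Fraction per class assigned to the test set; every
#'   class keeps at least one sample on each side.
#' @param seed Seed for the split.
#' @return List with integer index vectors `train` and `test`.
#' @export
split_cohort <- function(y, test_fraction = 0.25, seed = NULL) {
  if (test_fraction <= 0 || test_fraction >= 1)
    stop("test_fraction must be in (0, 1)")
  y <- as.character(y)
  with_seed(seed, {
    test <- unlist(lapply(split(seq_along(y), y), function(ix) {
      nt <- min(length(ix) - 1L, max(1L, round(test_fraction * length(ix))))
      sample(ix, nt)
    }), use.names = FALSE)
    list(train = setdiff(seq_along(y), test), test = sort(test))
  })
}

#' Write a synthetic cohort to disk
#'
#' Writes the beta matrix, sample sheet, a clean probe annotation and the
#' novel-sample manifest in the formats the pipeline reads.
#'
#' @param cohort Output of [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @param annotation Optional annotation to write instead of an all-clean
#'   one.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_beta_matrix(cohort$beta, file.path(dir, "beta_matrix.csv"))
  data.table::fwrite(cohort$samples[c("sample_id", "class_label", "batch",
                                      "is_novel")],
                     file.path(dir, "samples.csv"))
  if (is.null(annotation))
    annotation <- generate_probe_annotation(rownames(cohort$beta))
  data.table::fwrite(annotation, file.path(dir, "annotation.csv"))
  data.table::fwrite(cohort$samples[cohort$samples$is_novel,
                                    c("sample_id", "class_label")],
                     file.path(dir, "novel_manifest.csv"))
  invisible(dir)
}
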