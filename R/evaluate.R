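# Evaluation protocol: label harmonisation onto the K+1 ("known classes
# plus unknown") label set, filtered evaluation restricted to known
# truths, micro/macro F1, the noise-injection experiment, calibrated-score
# bins and the five-category decision framework.

#' Harmonise predicted/true labels onto the open-set label set
#'
#' Maps foreign labels onto the evaluation label set: by default the
#' designation `"not applicable"` (used by classifiers that defer
#' low-confidence calls to expert review) is treated as equivalent to
#' `"unknown"`; known class labels pass through unchanged.
#'
#' @param labels Character vector (or factor) of labels.
#' @param known_classes The known class labels.
#' @param aliases Named character vector mapping foreign labels to members
#'   of the evaluation set (default maps `"not applicable"` to
#'   `"unknown"`).
#' @return Factor over `c(known_classes, "unknown")`.
#' @export
harmonize_labels <- function(labels, known_classes,
                             aliases = c("not applicable" = "unknown")) {
  labels <- as.character(labels)
  hit <- labels %in% names(aliases)
  labels[hit] <- aliases[labels[hit]]
  full <- c(known_classes, "unknown")
  bad <- setdiff(unique(labels), full)
  if (length(bad))
    stop("unmapped label(s): ", paste(bad, collapse = ", "))
  factor(labels, levels = full)
}

#' Restrict an evaluation to samples with known true labels
#'
#' Builds the "filtered" evaluation set by dropping samples whose true
#' label is `"unknown"`; predictions are left untouched, so a prediction
#' of `"unknown"` for a known-class sample still counts against the
#' classifier.
#'
#' @param y_true,y_pred Harmonised label vectors of equal length.
#' @return List with the retained `y_true`, `y_pred` and the logical
#'   `keep` index.
#' @export
filter_known <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  keep <- as.character(y_true) != "unknown"
  if (!any(keep)) warning("no samples with known true labels remain")
  list(y_true = y_true[keep], y_pred = y_pred[keep], keep = keep)
}

#' Micro and macro F1 over a fixed label set
#'
#' Per-class precision, recall and F1 are computed from one-vs-rest
#' counts; the macro F1 is their unweighted mean over the *supplied* label
#' set, so classes absent from the truths contribute F1 = 0 (a fixed-set
#' convention that keeps scores comparable across evaluations). The micro
#' F1 aggregates counts over all classes first; for single-label
#' classification it equals overall accuracy.
#'
#' @param y_true,y_pred Label vectors of equal, positive length.
#' @param labels Label set to evaluate over; defaults to the union of
#'   observed labels. Must cover every observed *true* label; predictions
#'   outside the set (e.g. `"unknown"` calls in a known-classes-only
#'   evaluation) count as errors for the true class but contribute no
#'   per-class row of their own.
#' @return An `evaluation_report` list: `f1_micro`, `f1_macro`,
#'   `per_class` (data.frame with n, precision, recall, f1), `labels`,
#'   `n_samples`.
#' @export
f1_scores <- function(y_true, y_pred, labels = NULL) {
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  if (length(y_true) == 0) stop("empty evaluation set")
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (is.null(labels)) labels <- sort(unique(c(y_true, y_pred)))
  obs <- unique(y_true)
  if (!all(obs %in% labels))
    stop("labels must cover observed true labels; missing: ",
         paste(setdiff(obs, labels), collapse = ", "))
  per <- lapply(labels, function(l) {
    tp <- sum(y_true == l & y_pred == l)
    fp <- sum(y_true != l & y_pred == l)
    fn <- sum(y_true == l & y_pred != l)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(label = l, n = sum(y_true == l), precision = prec,
               recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  tp <- sum(y_true == y_pred)
  fp <- sum(y_true != y_pred)  # every error is one FP and one FN in aggregate
  micro <- if (tp + fp > 0) tp / (tp + fp) else 0
  structure(list(f1_micro = micro, f1_macro = mean(per$f1),
                 per_class = per, labels = labels,
                 n_samples = length(y_true)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("Evaluation over %d labels, %d samples\n",
              length(x$labels), x$n_samples))
  cat(sprintf("  F1-micro %.4f  F1-macro %.4f\n", x$f1_micro, x$f1_macro))
  invisible(x)
}

#' Noise-injection experiment
#'
#' Measures open-set robustness by adding increasing numbers of
#' novel-class ("noise") samples to a known-class test set and tracking
#' micro/macro F1 over the K+1 label set. The noise pool is shuffled once
#' under `seed`, then each step evaluates the known test set plus the
#' first `n` noise samples, whose true label is `"unknown"`.
#'
#' With an open-set model that detects the noise well, the macro F1 over
#' the fixed 92-label set *rises* as the (initially empty, hence F1 = 0)
#' unknown label fills with correctly flagged samples, while a closed-set
#' model (`mode = "91"`) misassigns every noise sample to a known class
#' and its macro F1 falls; the micro F1 of a good open-set model rises
#' with noise. Both behaviours are reported by this experiment.
#'
#' @param model,openmax Trained models (see [predict_open()]).
#' @param x_known,y_known Known-class test samples and their true labels.
#' @param x_noise Samples-by-features matrix of novel-class samples.
#' @param steps Integer vector of noise counts (must not exceed the pool
#'   size); 0 reproduces the base evaluation.
#' @param seed Seed for the pool shuffle.
#' @param mode `"92"` (open-set predictions, default) or `"91"`
#'   (closed-set SoftMax argmax, which can never answer "unknown").
#' @return Data.frame with columns `n_noise`, `f1_micro`, `f1_macro`.
#' @export
noise_injection_experiment <- function(model, openmax, x_known, y_known,
                                       x_noise, steps, seed = NULL,
                                       mode = c("92", "91")) {
  mode <- match.arg(mode)
  if (any(steps > nrow(x_noise)))
    stop(sprintf("step %d exceeds noise pool size %d",
                 max(steps), nrow(x_noise)))
  if (any(steps < 0)) stop("steps must be non-negative")
  ord <- with_seed(seed, sample(nrow(x_noise)))
  labels <- c(openmax$classes, "unknown")
  predict_fun <- if (mode == "92") {
    function(x) as.character(predict_open(model, openmax, x)$class)
  } else {
    function(x) as.character(predict(model, x, type = "class"))
  }
  pred_known <- predict_fun(x_known)
  pred_noise <- if (nrow(x_noise) > 0)
    predict_fun(x_noise[ord, , drop = FALSE])
  else character(0)
  y_known <- as.character(y_known)
  out <- lapply(sort(unique(steps)), function(n) {
    rep_ <- f1_scores(c(y_known, rep("unknown", n)),
                      c(pred_known, pred_noise[seq_len(n)]),
                      labels = labels)
    data.frame(n_noise = n, f1_micro = rep_$f1_micro, f1_macro = rep_$f1_macro)
  })
  do.call(rbind, out)
}

#' Bin a calibrated score
#'
#' The three interpretation ranges: `score >= 0.9` (high confidence),
#' `0.9 > score >= 0.5` (medium), `score < 0.5` (low). Both cut points are
#' closed on the left.
#'
#' @param score Numeric vector in \[0, 1\].
#' @return Factor with levels `">=0.9"`, `"0.5<=score<0.9"`, `"<0.5"`.
#' @export
bin_score <- function(score) {
  if (any(is.na(score)) || any(score < 0) || any(score > 1))
    stop("scores must lie in [0, 1]")
  lv <- c(">=0.9", "0.5<=score<0.9", "<0.5")
  factor(ifelse(score >= 0.9, lv[1], ifelse(score >= 0.5, lv[2], lv[3])),
         levels = lv)
}

#' Categorise classifier results into Decisions
#'
#' Integrates the calibrated score with an externally supplied evidence
#' status (the concordance of histopathology, clinical information and NGS
#' findings with the methylation call — expert input, never computed by
#' the software) into the five decision categories:
#' \describe{
#'   \item{Match}{score >= 0.9 and evidence concordant.}
#'   \item{Likely match}{score < 0.9 but evidence concordant.}
#'   \item{Uncertain}{evidence indeterminate, irrespective of score.}
#'   \item{No match}{evidence discordant (classifier result incorrect).}
#'   \item{Control (No match)}{sample is a normal control (e.g. very low
#'     tumour purity).}
#' }
#'
#' @param score Calibrated score(s) in \[0, 1\].
#' @param evidence Character/factor per sample, one of `"concordant"`,
#'   `"discordant"`, `"indeterminate"`, `"control"`.
#' @param sample_id Optional identifiers.
#' @return Data.frame with columns `sample_id`, `calibrated_score`,
#'   `score_bin`, `evidence`, `decision`.
#' @export
categorize_decision <- function(score, evidence, sample_id = NULL) {
  if (length(score) != length(evidence)) stop("length mismatch")
  ok <- c("concordant", "discordant", "indeterminate", "control")
  evidence <- as.character(evidence)
  if (any(is.na(evidence)) || !all(evidence %in% ok))
    stop("evidence must be one of: ", paste(ok, collapse = ", "))
  bins <- bin_score(score)
  decision <- ifelse(evidence == "control", "Control (No match)",
              ifelse(evidence == "discordant", "No match",
              ifelse(evidence == "indeterminate", "Uncertain",
              ifelse(score >= 0.9, "Match", "Likely match"))))
  data.frame(
    sample_id = if (is.null(sample_id)) seq_along(score) else sample_id,
    calibrated_score = score,
    score_bin = bins,
    evidence = evidence,
    decision = factor(decision, levels = c("Match", "Likely match", "Uncertain",
                                           "No match", "Control (No match)")),
    stringsAsFactors = FALSE
  )
}

#' Extend closed-set probabilities with an unknown label
#'
#' Adapts a closed-set (K-class) classifier to the K+1 evaluation by
#' appending an `"unknown"` entry with probability 0, strictly below every
#' attainable class probability, so the ranking over known classes is
#' unchanged and `"unknown"` is never predicted.
#'
#' @param p Probability vector over the known classes, or a samples x K
#'   matrix (each row normalised).
#' @return Input with an extra `"unknown"` entry/column equal to 0.
#' @export
append_unknown_to_closed <- function(p) {
  if (is.null(dim(p))) {
    out <- c(p, 0)
    names(out) <- c(if (is.null(names(p))) as.character(seq_along(p)) else names(p),
                    "unknown")
    out
  } else {
    out <- cbind(p, unknown = 0)
    out
  }
}
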