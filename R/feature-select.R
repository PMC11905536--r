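# Random-forest feature selection: rank probes by impurity importance on
# the (SMOTE-balanced) training matrix and keep the top-K panel.

#' Construct a probe panel
#'
#' Orders probes by decreasing importance, breaking ties by probe
#' identifier so that selection is deterministic.
#'
#' @param probe_id Character vector of probe identifiers (unique).
#' @param importance Non-negative importance score per probe.
#' @return An object of class `probe_panel`: a data.frame with columns
#'   `probe_id` and `importance` sorted non-increasingly.
#' @export
probe_panel <- function(probe_id, importance) {
  if (anyDuplicated(probe_id)) stop("duplicate probe_id in panel")
  if (length(probe_id) != length(importance)) stop("length mismatch")
  if (any(importance < 0)) stop("importance must be non-negative")
  o <- order(-importance, as.character(probe_id))
  out <- data.frame(probe_id = as.character(probe_id)[o],
                    importance = as.numeric(importance)[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_panel", "data.frame")
  out
}

#' Rank probes by random-forest importance
#'
#' Fits a classification random forest (via `ranger`) and returns probes
#' ranked by mean-decrease-in-impurity (Gini) importance, normalised to
#' sum to one. Defaults follow the published configuration: 4000 trees and
#' `mtry = sqrt(p)`.
#'
#' @param x Samples-by-probes matrix (typically SMOTE-balanced,
#'   log-transformed values); must have probe colnames.
#' @param y Class label per sample.
#' @param num_trees Number of trees (default 4000).
#' @param mtry Features tried per split; default `floor(sqrt(p))`.
#' @param seed Seed for the forest; results are deterministic under it
#'   (the forest is grown single-threaded).
#' @return A [probe_panel()] covering all probes.
#' @export
rf_importance <- function(x, y, num_trees = 4000, mtry = NULL, seed = NULL) {
  assert_matrix(x)
  if (is.null(colnames(x))) stop("x must carry probe colnames")
  y <- droplevels(factor(y))
  if (nlevels(y) < 2) stop("need >= 2 classes for importance ranking")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  fit <- ranger::ranger(
    x = x, y = y,
    num.trees = num_trees, mtry = mtry,
    importance = "impurity",
    seed = if (is.null(seed)) sample.int(.Machine$integer.max, 1) else seed,
    num.threads = 1,
    verbose = FALSE
  )
  imp <- fit$variable.importance
  if (is.null(names(imp)) || length(imp) != ncol(x)) {
    full <- stats::setNames(numeric(ncol(x)), colnames(x))
    if (length(imp)) full[names(imp)] <- imp
    imp <- full
  }
  imp[imp < 0] <- 0
  tot <- sum(imp)
  imp <- if (tot > 0) imp / tot
         else stats::setNames(rep(1 / length(imp), length(imp)), names(imp))
  probe_panel(names(imp), imp)
}

#' Keep probes with clearly above-uniform importance
#'
#' Data-driven alternative to a fixed panel size: retains probes whose
#' normalised importance exceeds `factor` times the uniform share `1/P`.
#' Probes carrying genuine class signal stand far above the uniform share,
#' while noise probes scatter around it, so this rule adapts the panel to
#' however many informative probes the cohort actually contains.
#'
#' @param panel A [probe_panel()] with importances normalised to sum 1.
#' @param factor Multiple of the uniform share required (default 2).
#' @param min_k Minimum panel size returned (default 2).
#' @return The truncated panel.
#' @export
select_above_uniform <- function(panel, factor = 2, min_k = 2) {
  stopifnot(inherits(panel, "probe_panel"))
  k <- max(min_k, sum(panel$importance > factor / nrow(panel)))
  select_top(panel, k)
}

#' Keep the top-k probes of a panel
#'
#' @param panel A [probe_panel()].
#' @param k Number of probes to keep (`1 <= k <= nrow(panel)`). The
#'   published defaults are 1000 probes, with a 767-probe mode for
#'   comparison against an existing 767-probe classifier.
#' @return The truncated panel.
#' @export
select_top <- function(panel, k) {
  stopifnot(inherits(panel, "probe_panel"))
  if (k <= 0) stop("k must be positive")
  if (k > nrow(panel)) stop(sprintf("k = %d exceeds panel size %d", k, nrow(panel)))
  out <- panel[seq_len(k), , drop = FALSE]
  class(out) <- c("probe_panel", "data.frame")
  out
}
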