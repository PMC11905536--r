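# OpenMax recalibration: per-class mean activation vectors (MAVs), Weibull
# models of the largest within-class activation distances, and the
# recalibration of SoftMax probabilities into K+1 scores that include an
# explicit "unknown" class.
#
# Two weighting modes are provided.
#   * "weibull_cdf" (default): w_k(x) = 1 - exp(-(d/sigma_k)^kappa), the
#     Weibull CDF of the distance, so w grows with atypicality — the
#     standard OpenMax construction. kappa is fitted by maximum likelihood.
#   * "as_printed": w_k(x) = exp(-(d/sigma_k)), an exponential survival
#     weight with kappa fixed at 1 and sigma_k the exponential (MLE) scale
#     of the tail. Under this formula w = 1 at the class centroid, which
#     drives probability mass *towards* "unknown" for typical samples; it
#     is retained verbatim as an alternative mode rather than silently
#     corrected, and the CDF mode is the default.

#' Per-class mean activation vectors
#'
#' For each class, averages the penultimate-layer activations of the
#' training samples the model classifies correctly (falling back, with a
#' message, to all samples of the class when none are correct) and records
#' the sorted distances of those samples to the class mean.
#'
#' @param model A trained [train_mlp()] model.
#' @param x Samples-by-features training matrix on the model's panel.
#' @param y True class label per row of `x`.
#' @param distance `"euclidean"` (default) or `"cosine"` distance between
#'   activation vectors.
#' @return A list (one element per class) of `class_activation_stats`:
#'   `class`, `mav`, sorted `distances`, `n_used`.
#' @export
fit_mavs <- function(model, x, y, distance = c("euclidean", "cosine")) {
  stopifnot(inherits(model, "mlp_model"))
  distance <- match.arg(distance)
  y <- factor(y, levels = model$classes)
  if (anyNA(y)) stop("labels outside the model's class set")
  act <- penultimate_activations(model, x)
  pred <- predict(model, x, type = "class")
  lapply(model$classes, function(cl) {
    idx <- which(y == cl & pred == cl)
    if (length(idx) == 0) {
      message(sprintf("class '%s': no correctly classified samples; using all",
                      cl))
      idx <- which(y == cl)
    }
    if (length(idx) == 0) stop(sprintf("class '%s' has no samples", cl))
    a <- act[idx, , drop = FALSE]
    mav <- colMeans(a)
    d <- activation_distance(a, mav, distance)
    structure(list(class = cl, mav = mav, distances = sort(d),
                   n_used = length(idx), distance = distance),
              class = "class_activation_stats")
  })
}

# Distance from each row of `a` to the vector `mav`.
activation_distance <- function(a, mav, distance) {
  if (distance == "euclidean") {
    sqrt(rowSums(sweep(a, 2, mav)^2))
  } else {
    num <- as.vector(a %*% mav)
    den <- sqrt(rowSums(a^2)) * sqrt(sum(mav^2))
    1 - num / pmax(den, 1e-300)
  }
}

#' Fit Weibull models to the distance tails
#'
#' Models the `tail_size` largest within-class distances per class. In
#' `"as_printed"` mode the shape is fixed at 1 and the scale is the
#' exponential maximum-likelihood estimate (the tail mean). In
#' `"weibull_cdf"` mode both scale and shape are estimated by maximum
#' likelihood (via `fitdistrplus`).
#'
#' @param stats List of per-class activation statistics from [fit_mavs()].
#' @param tail_size Number of largest distances to fit (default 20; capped
#'   at the number of available distances, minimum 2).
#' @param mode `"weibull_cdf"` (default) or `"as_printed"`.
#' @return A data.frame with one row per class: `class`, `sigma` (scale),
#'   `shape`, `tail_size`.
#' @export
fit_weibull_tails <- function(stats, tail_size = 20,
                              mode = c("weibull_cdf", "as_printed")) {
  mode <- match.arg(mode)
  rows <- lapply(stats, function(s) {
    d <- s$distances
    ts <- min(tail_size, length(d))
    if (ts < 2)
      stop(sprintf("class '%s': need >= 2 distances for a tail fit", s$class))
    tail_d <- utils::tail(d, ts)  # distances are stored sorted ascending
    if (max(tail_d) <= 0)
      stop(sprintf("class '%s': degenerate all-zero distance tail", s$class))
    if (mode == "as_printed") {
      data.frame(class = s$class, sigma = mean(tail_d), shape = 1,
                 tail_size = ts)
    } else {
      fit <- fitdistrplus::fitdist(pmax(tail_d, 1e-12), "weibull",
                                   method = "mle",
                                   start = list(shape = 1, scale = mean(tail_d)))
      data.frame(class = s$class,
                 sigma = unname(fit$estimate["scale"]),
                 shape = unname(fit$estimate["shape"]),
                 tail_size = ts)
    }
  })
  do.call(rbind, rows)
}

#' Weibull-derived atypicality weight
#'
#' @param d Non-negative distance(s) to a class MAV.
#' @param sigma,shape Weibull scale and shape for the class.
#' @param mode `"weibull_cdf"`: `w = 1 - exp(-(d/sigma)^shape)` (grows with
#'   distance); `"as_printed"`: `w = exp(-(d/sigma)^shape)` with shape 1
#'   (decays with distance).
#' @return Weight(s) in \[0, 1\].
#' @export
weibull_weight <- function(d, sigma, shape = 1,
                           mode = c("weibull_cdf", "as_printed")) {
  mode <- match.arg(mode)
  if (any(d < 0)) stop("distances must be non-negative")
  s <- exp(-(d / sigma)^shape)
  if (mode == "as_printed") s else 1 - s
}

#' Recalibrate SoftMax probabilities into OpenMax scores
#'
#' Applies the recalibration equations: per-class score
#' `f_k(x) = P(k|x) * (1 - w_k(x))`, unknown score
#' `f_u(x) = sum_k P(k|x) * w_k(x)`, and normalised probabilities
#' `P'(k|x) = f_k / (sum_j f_j + f_u)`, `P'(u|x) = f_u / (sum_j f_j + f_u)`.
#' (When `p` sums to one the denominator is identically one; the
#' normalisation is still performed as specified.) The prediction is the
#' argmax over the K known classes plus "unknown"; ties go to the known
#' class with the lowest index, with "unknown" last.
#'
#' @param p Normalised SoftMax vector over the known classes.
#' @param w Weight per known class, each in \[0, 1\].
#' @return An `openmax_output` list: `f` (recalibrated class scores),
#'   `f_u`, `p_prime` (named vector over classes plus `"unknown"`),
#'   `y_hat`.
#' @export
recalibrate <- function(p, w) {
  if (length(p) != length(w))
    stop(sprintf("length mismatch: %d probabilities vs %d weights",
                 length(p), length(w)))
  if (any(w < -1e-12) || any(w > 1 + 1e-12)) stop("weights must lie in [0, 1]")
  f <- p * (1 - w)
  f_u <- sum(p * w)
  denom <- sum(f) + f_u
  p_prime <- c(f, f_u) / denom
  labs <- c(if (!is.null(names(p))) names(p) else as.character(seq_along(p)),
            "unknown")
  names(p_prime) <- labs
  structure(list(f = f, f_u = f_u, p_prime = p_prime,
                 y_hat = labs[which.max(p_prime)]),
            class = "openmax_output")
}

#' Fit Weibull tails as the law of a class's most extreme member
#'
#' Extreme-value alternative to the direct tail fit of
#' [fit_weibull_tails()], designed for small calibration samples. A single
#' Weibull is first fitted by maximum likelihood to *all* stored distances
#' of each class (full-sample fit, `F`). The tail model for the class is
#' then the distribution of the maximum of `n_extreme` fresh draws from
#' `F` (`F^n`), re-expressed as a Weibull by matching its 25% and 75%
#' quantiles (closed form). Under the resulting CDF weight, `w_k(d)`
#' reads as "the probability that even the most atypical member of a
#' fresh class-k cohort would lie below distance `d`", so the weight
#' crosses 1/2 only beyond the plausible range of the class — rather than
#' in the middle of its upper tail, where a direct fit on few calibration
#' points places it.
#'
#' @param stats List of per-class activation statistics (see
#'   [fit_mavs()]).
#' @param n_extreme Size of the hypothetical fresh cohort per class;
#'   defaults to the number of stored distances for the class.
#' @return Tail table as in [fit_weibull_tails()] (columns `class`,
#'   `sigma`, `shape`, `tail_size`).
#' @export
fit_extreme_tails <- function(stats, n_extreme = NULL) {
  rows <- lapply(stats, function(s) {
    d <- s$distances
    if (length(d) < 3)
      stop(sprintf("class '%s': need >= 3 distances for an extreme-value fit",
                   s$class))
    if (max(d) <= 0)
      stop(sprintf("class '%s': degenerate all-zero distances", s$class))
    d <- pmax(d, 1e-12)
    # full-sample law of the distances, selected by AIC among standard
    # positive laws; the final tail weight remains a Weibull CDF
    cand <- list(
      weibull = tryCatch(
        fitdistrplus::fitdist(d, "weibull", method = "mle",
                              start = list(shape = 2, scale = mean(d))),
        error = function(e) NULL),
      lnorm = tryCatch(fitdistrplus::fitdist(d, "lnorm"),
                       error = function(e) NULL),
      gamma = tryCatch(
        fitdistrplus::fitdist(d, "gamma", method = "mle",
                              start = list(shape = 2, rate = 2 / mean(d))),
        error = function(e) NULL))
    cand <- cand[!vapply(cand, is.null, logical(1))]
    if (length(cand) == 0)
      stop(sprintf("class '%s': no distribution could be fitted", s$class))
    best <- cand[[which.min(vapply(cand, `[[`, numeric(1), "aic"))]]
    qfun <- switch(best$distname,
                   weibull = function(p) stats::qweibull(p, best$estimate["shape"],
                                                         best$estimate["scale"]),
                   lnorm = function(p) stats::qlnorm(p, best$estimate["meanlog"],
                                                     best$estimate["sdlog"]),
                   gamma = function(p) stats::qgamma(p, best$estimate["shape"],
                                                     best$estimate["rate"]))
    n <- if (is.null(n_extreme)) length(d) else n_extreme
    # quantiles of the max of n draws from the fitted law: F^n
    qmax <- function(p) qfun(p^(1 / n))
    p1 <- 0.25; p2 <- 0.75
    q1 <- qmax(p1); q2 <- qmax(p2)
    L1 <- -log(1 - p1); L2 <- -log(1 - p2)
    shape_star <- (log(L2) - log(L1)) / (log(q2) - log(q1))
    sigma_star <- q1 / L1^(1 / shape_star)
    data.frame(class = s$class, sigma = sigma_star, shape = shape_star,
               tail_size = length(d))
  })
  do.call(rbind, rows)
}

#' Fit an OpenMax model
#'
#' Computes the per-class mean activation vectors and distance lists on
#' the training data, then fits the per-class Weibull tail models that
#' drive the unknown-class weight.
#'
#' Two refinements beyond the plain construction are available and are
#' what the pipeline uses by default:
#' \itemize{
#'   \item *Held-out calibration* (`x_cal`, `y_cal`): distances measured
#'     on the training samples themselves understate how far fresh
#'     samples of a class land from its MAV. When a calibration cohort
#'     (samples never used in training) is supplied, each correctly
#'     classified calibration sample contributes a studentised distance
#'     ratio (distance to its class MAV divided by that class's median
#'     training distance); the ratios are pooled across classes — so
#'     classes with very few calibration samples still benefit — and each
#'     class's distance list is rebuilt as its median training distance
#'     times the pooled ratios.
#'   \item *Extreme-value tails* (`tail_method = "extreme"`): see
#'     [fit_extreme_tails()]. With few distances per class, the direct
#'     maximum-likelihood fit on the largest `tail_size` distances places
#'     the weight's midpoint inside the class's ordinary range; the
#'     extreme-value construction places it beyond the plausible range of
#'     a class-sized cohort.
#' }
#'
#' @inheritParams fit_mavs
#' @inheritParams fit_weibull_tails
#' @param x_cal,y_cal Optional held-out calibration samples (same feature
#'   panel) and their true labels.
#' @param tail_method `"mle"` (direct Weibull fit on the `tail_size`
#'   largest distances, the classical construction) or `"extreme"`
#'   (extreme-value construction; requires `mode = "weibull_cdf"`).
#' @param n_extreme Cohort size for the extreme-value construction;
#'   default the largest class size in `y`.
#' @return An `openmax_model`: MAV matrix (classes x hidden units), tail
#'   table, mode and distance metric.
#' @export
fit_openmax <- function(model, x, y, tail_size = 20,
                        mode = c("weibull_cdf", "as_printed"),
                        distance = c("euclidean", "cosine"),
                        x_cal = NULL, y_cal = NULL,
                        tail_method = c("mle", "extreme"),
                        n_extreme = NULL) {
  mode <- match.arg(mode); distance <- match.arg(distance)
  tail_method <- match.arg(tail_method)
  if (tail_method == "extreme" && mode != "weibull_cdf")
    stop("the extreme-value tail construction applies to mode = 'weibull_cdf'")
  stats <- fit_mavs(model, x, y, distance = distance)
  if (!is.null(x_cal)) {
    if (is.null(y_cal) || nrow(x_cal) != length(y_cal))
      stop("calibration labels must match calibration samples")
    stats <- calibrate_distances(model, stats, x_cal, y_cal, distance)
  }
  tails <- if (tail_method == "extreme") {
    if (is.null(n_extreme)) n_extreme <- max(table(factor(y)))
    fit_extreme_tails(stats, n_extreme = n_extreme)
  } else {
    fit_weibull_tails(stats, tail_size = tail_size, mode = mode)
  }
  mavs <- do.call(rbind, lapply(stats, `[[`, "mav"))
  rownames(mavs) <- vapply(stats, `[[`, character(1), "class")
  structure(list(classes = rownames(mavs), mavs = mavs, tails = tails,
                 mode = mode, distance = distance, tail_size = tail_size,
                 tail_method = tail_method,
                 calibrated = !is.null(x_cal)),
            class = "openmax_model")
}

# Replace each class's distance list with median(train distances) times
# the pooled studentised ratios of correctly classified calibration
# samples. Classes without calibration samples of their own still get a
# distance list through the pooled ratios.
calibrate_distances <- function(model, stats, x_cal, y_cal, distance) {
  classes <- vapply(stats, `[[`, character(1), "class")
  med <- vapply(stats, function(s) stats::median(s$distances), numeric(1))
  names(med) <- classes
  if (any(med <= 0))
    stop("degenerate training distances; cannot studentise calibration")
  y_cal <- as.character(y_cal)
  if (!all(y_cal %in% classes))
    stop("calibration labels outside the model's class set")
  act <- penultimate_activations(model, x_cal)
  pred <- as.character(predict(model, x_cal, type = "class"))
  ok <- which(pred == y_cal)
  if (length(ok) < 3)
    stop("fewer than 3 correctly classified calibration samples")
  ratios <- vapply(ok, function(i) {
    cl <- y_cal[i]
    mav <- stats[[which(classes == cl)]]$mav
    activation_distance(act[i, , drop = FALSE], mav, distance) / med[cl]
  }, numeric(1))
  # anchors estimated from classes with very few original samples are
  # systematically too small; when mapping the pooled dimensionless
  # tolerance back to absolute distances, floor each anchor at the
  # cohort-median anchor (the ratio pool itself keeps the raw anchors,
  # which errs on the conservative side)
  anchor <- pmax(med, stats::median(med))
  for (i in seq_along(stats)) {
    stats[[i]]$distances <- sort(anchor[i] * ratios)
    stats[[i]]$calibrated <- TRUE
  }
  stats
}

#' Open-set prediction
#'
#' For each sample: SoftMax probabilities from the MLP, distances from the
#' penultimate activations to every class MAV, Weibull weights, and the
#' recalibration of [recalibrate()]. The predicted label is the class (or
#' "unknown") with the highest recalibrated probability.
#'
#' @param model A trained `mlp_model`.
#' @param openmax An `openmax_model` from [fit_openmax()].
#' @param x Feature matrix on the model's panel.
#' @return A list: `class` (factor over known classes plus `"unknown"`),
#'   `prob` (samples x (K+1) matrix of recalibrated probabilities),
#'   `score` (calibrated score: the maximum recalibrated probability over
#'   the known classes) and `p_unknown`.
#' @export
predict_open <- function(model, openmax, x) {
  stopifnot(inherits(model, "mlp_model"))
  if (!inherits(openmax, "openmax_model"))
    stop("'openmax' must be a fitted openmax_model")
  if (!identical(openmax$classes, model$classes))
    stop("OpenMax model classes do not match the MLP's")
  z <- predict_logits(model, x)
  p <- rbind(softmax(z))
  act <- penultimate_activations(model, x)
  K <- length(openmax$classes)
  d <- vapply(seq_len(K), function(k) {
    activation_distance(act, openmax$mavs[k, ], openmax$distance)
  }, numeric(nrow(act)))
  d <- rbind(d)
  w <- vapply(seq_len(K), function(k) {
    weibull_weight(d[, k], openmax$tails$sigma[k], openmax$tails$shape[k],
                   mode = openmax$mode)
  }, numeric(nrow(d)))
  w <- rbind(w)
  labs <- c(openmax$classes, "unknown")
  prob <- matrix(NA_real_, nrow(p), K + 1, dimnames = list(rownames(x), labs))
  for (i in seq_len(nrow(p))) {
    pv <- p[i, ]; names(pv) <- openmax$classes
    prob[i, ] <- recalibrate(pv, w[i, ])$p_prime
  }
  cls <- factor(labs[apply(prob, 1, which.max)], levels = labs)
  list(class = cls,
       prob = prob,
       score = apply(prob[, seq_len(K), drop = FALSE], 1, max),
       p_unknown = prob[, K + 1])
}

#' @export
print.openmax_model <- function(x, ...) {
  cat(sprintf("OpenMax model: %d classes, %s mode, %s distance, tail size %d\n",
              length(x$classes), x$mode, x$distance, x$tail_size))
  invisible(x)
}

#' Save / load an OpenMax model
#'
#' JSON container holding the per-class Weibull parameters and MAV arrays.
#'
#' @param openmax An `openmax_model`.
#' @param path JSON file path.
#' @return `save_openmax`: the path, invisibly. `load_openmax`: the model.
#' @export
save_openmax <- function(openmax, path) {
  stopifnot(inherits(openmax, "openmax_model"))
  obj <- list(classes = openmax$classes, tails = openmax$tails,
              mode = openmax$mode, distance = openmax$distance,
              tail_size = openmax$tail_size,
              tail_method = openmax$tail_method,
              calibrated = openmax$calibrated,
              mavs = apply(openmax$mavs, 1, identity, simplify = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_openmax
#' @export
load_openmax <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mavs <- do.call(rbind, obj$mavs)
  rownames(mavs) <- obj$classes
  structure(list(classes = obj$classes, mavs = mavs,
                 tails = as.data.frame(obj$tails), mode = obj$mode,
                 distance = obj$distance, tail_size = obj$tail_size,
                 tail_method = obj$tail_method, calibrated = obj$calibrated),
            class = "openmax_model")
}
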