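# Exact t-SNE for visual inspection of where query samples fall relative
# to reference cohorts. Cohorts at inspection scale are a few hundred
# samples, where the exact O(n^2) gradient is fast; the embedding is for
# eyes only and is never used in classification.

# Per-point Gaussian bandwidths by bisection on the target perplexity.
tsne_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (iter in 1:50) {
      p <- exp(-di * beta)
      s <- sum(p)
      if (s < 1e-300) { h <- 0 } else {
        p <- p / s
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < 1e-5) break
      if (h > target) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  pmax(P, 1e-12)
}

#' t-SNE embedding of samples
#'
#' Embeds samples (e.g. reference cohort plus query samples, stacked
#' row-wise) into two dimensions with exact t-distributed stochastic
#' neighbour embedding, for visual inspection of whether a query clusters
#' with a known class or falls outside every cluster. Deterministic under
#' `seed`.
#'
#' @param x Samples-by-features matrix (>= 3 samples, >= 2 features).
#' @param perplexity Gaussian-neighbourhood size (default 30; reduced with
#'   a message when the sample count requires it).
#' @param max_iter Gradient-descent iterations (default 1000).
#' @param seed Seed for the random initialisation.
#' @param initial_dims If the input has more features, it is first reduced
#'   to this many principal components (default 50).
#' @return Samples-by-2 coordinate matrix (rownames preserved).
#' @export
embed_tsne <- function(x, perplexity = 30, max_iter = 1000, seed = NULL,
                       initial_dims = 50) {
  assert_matrix(x)
  n <- nrow(x)
  if (n < 3) stop("need at least 3 samples to embed")
  if (ncol(x) < 2) stop("need at least 2 dimensions")
  if (ncol(x) > initial_dims) {
    pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
    x <- pc$x[, seq_len(min(initial_dims, ncol(pc$x))), drop = FALSE]
  }
  maxp <- floor((n - 1) / 3)
  if (perplexity > maxp) {
    message(sprintf("perplexity reduced from %g to %d for n = %d",
                    perplexity, maxp, n))
    perplexity <- max(1, maxp)
  }
  d2 <- as.matrix(stats::dist(x))^2
  P <- tsne_affinities(d2, perplexity)

  with_seed(seed, {
    Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    dY <- matrix(0, n, 2); gains <- matrix(1, n, 2)
    eta <- 200
    exagg <- 12; stop_exagg <- min(250, max_iter %/% 4)
    for (iter in seq_len(max_iter)) {
      Pi <- if (iter <= stop_exagg) P * exagg else P
      sum_Y <- rowSums(Y^2)
      num <- 1 / (1 + outer(sum_Y, sum_Y, "+") - 2 * tcrossprod(Y))
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      L <- (Pi - Q) * num
      grad <- 4 * (diag(rowSums(L)) - L) %*% Y
      mom <- if (iter < 250) 0.5 else 0.8
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- mom * dY - eta * gains * grad
      Y <- Y + dY
      Y <- sweep(Y, 2, colMeans(Y))
    }
    colnames(Y) <- c("tsne1", "tsne2")
    rownames(Y) <- rownames(x)
    Y
  })
}
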