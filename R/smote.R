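# SMOTE: synthetic minority oversampling by interpolation between
# same-class nearest neighbours, equalising every class to the size of the
# largest. Written here rather than wrapped because no installed package
# provides it; the algorithm is the classical one (Chawla-style
# interpolation with k Euclidean nearest neighbours).

#' Equalise class sizes with SMOTE
#'
#' For every class smaller than the largest, synthetic samples are created
#' until all classes have exactly the majority size ("not majority"
#' sampling strategy). Each synthetic sample is `x + u * (x_nn - x)` where
#' `x` is a randomly chosen minority sample, `x_nn` one of its `k` nearest
#' same-class neighbours (Euclidean distance), and `u ~ Uniform(0, 1)`.
#' Original rows are retained unchanged, so synthetic points lie on
#' segments between same-class points and inherit any per-feature bounds.
#'
#' @param x Samples-by-features numeric matrix.
#' @param y Class label per row (factor or character).
#' @param k_neighbors Number of nearest neighbours to interpolate with;
#'   reduced per class (with a message) when a class has fewer than
#'   `k_neighbors + 1` members. Default 5.
#' @param seed Optional integer seed; results are reproducible under it.
#' @return A list with `x` (original rows first, then synthetic rows), `y`
#'   (labels), `synthetic` (logical flag per row) and `provenance` (for
#'   synthetic rows: base row, neighbour row and interpolation weight `u`
#'   in the output row order).
#' @export
smote_oversample <- function(x, y, k_neighbors = 5, seed = NULL) {
  assert_matrix(x)
  y <- factor(y)
  y <- droplevels(y)
  if (nrow(x) != length(y)) stop("nrow(x) must equal length(y)")
  if (nlevels(y) < 2) stop("SMOTE needs at least two classes")
  counts <- table(y)
  if (any(counts < 2))
    stop("class with a single sample cannot be interpolated: ",
         paste(names(counts)[counts < 2], collapse = ", "))
  target <- max(counts)

  with_seed(seed, {
    syn_x <- list(); syn_y <- list(); prov <- list()
    for (cl in levels(y)) {
      idx <- which(y == cl)
      need <- target - length(idx)
      if (need == 0) next
      k <- k_neighbors
      if (length(idx) - 1 < k) {
        k <- length(idx) - 1
        message(sprintf("class '%s': only %d samples, reducing k to %d",
                        cl, length(idx), k))
      }
      xc <- x[idx, , drop = FALSE]
      d <- as.matrix(stats::dist(xc))
      diag(d) <- Inf
      nn <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
      base <- sample(rep_len(seq_along(idx), need))
      pick <- nn[cbind(base, sample.int(k, need, replace = TRUE))]
      u <- stats::runif(need)
      new <- xc[base, , drop = FALSE] +
        u * (xc[pick, , drop = FALSE] - xc[base, , drop = FALSE])
      rownames(new) <- sprintf("%s_smote_%d", cl, seq_len(need))
      syn_x[[cl]] <- new
      syn_y[[cl]] <- rep(cl, need)
      prov[[cl]] <- data.frame(base = idx[base], neighbor = idx[pick], u = u)
    }
    if (length(syn_x)) {
      x_out <- rbind(x, do.call(rbind, syn_x))
      y_out <- factor(c(as.character(y), unlist(syn_y, use.names = FALSE)),
                      levels = levels(y))
      prov <- do.call(rbind, prov)
      rownames(prov) <- NULL
    } else {
      x_out <- x; y_out <- y
      prov <- data.frame(base = integer(), neighbor = integer(), u = numeric())
    }
    list(x = x_out, y = y_out,
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(x_out) - nrow(x))),
         provenance = prov)
  })
}
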