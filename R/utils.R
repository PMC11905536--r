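# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded operations do not
#' perturb the global random stream. With `seed = NULL` the expression runs
#' against the current stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)  # force RNG initialisation so state can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Derive a per-stage seed from a global seed
#'
#' Stage names are hashed onto a small integer so that each pipeline stage
#' draws from an independent, reproducible stream. Kept below 2^31 - 1.
#' @noRd
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

#' @noRd
assert_matrix <- function(x, arg = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", arg), call. = FALSE)
  }
  invisible(x)
}

#' Map beta values to the logit (M-value-like) scale and back, clamping away
#' from the boundaries so the transform stays finite.
#' @noRd
beta_logit <- function(v, eps = 1e-4) {
  v <- pmin(pmax(v, eps), 1 - eps)
  log(v / (1 - v))
}

#' @noRd
inv_logit <- function(x) 1 / (1 + exp(-x))
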