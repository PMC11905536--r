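# Shared fixtures, all generated in code.

# Toy 6-probe beta matrix with probe names matching the bundled toy
# annotation: one probe fails each of the four filter criteria, two clean.
toy_matrix <- function(n_samples = 4, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(runif(6 * n_samples), nrow = 6,
                dimnames = list(sprintf("cg%08d", 1:6),
                                sprintf("S%02d", seq_len(n_samples))))
    m
  })
}

toy_annotation <- function() {
  data.frame(
    probe_id = sprintf("cg%08d", 1:6),
    chrom = c("1", "X", "2", "3", "4", "5"),
    on_sex_chromosome = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    unique_hg19_alignment = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    contains_snp = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    on_epic = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

# Two well-separated Gaussian clusters in `p` dimensions; returns a list
# with x (samples x features) and y.
two_cluster_data <- function(n_per = 20, p = 10, sep = 4, seed = 1) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per, p),
               matrix(rnorm(n_per * p, mean = sep), n_per, p))
    colnames(x) <- sprintf("f%03d", seq_len(p))
    list(x = x, y = factor(rep(c("A", "B"), each = n_per)))
  })
}

# A deterministic hand-built MLP whose hidden activations equal its
# (non-negative) inputs and whose logits separate two 2-d classes:
# class A lives near (1, 0), class B near (0, 1).
identity_mlp <- function() {
  model <- list(
    W1 = diag(2), b1 = c(0, 0),
    W2 = 10 * diag(2), b2 = c(0, 0),
    center = c(0, 0), scale = c(1, 1), val_idx = integer(0),
    features = c("f1", "f2"), classes = c("A", "B"),
    config = list(hidden_units = 2L, leaky_slope = 0.01),
    best_epoch = 0L, val_loss = NA_real_, history = numeric(0)
  )
  class(model) <- "mlp_model"
  model
}

# The full seed-7 synthetic study run, computed once per test session.
study_env <- new.env(parent = emptyenv())
seed7_study <- function() {
  if (is.null(study_env$res)) {
    co <- generate_cohort(synthetic_spec(seed = 7))
    cfg <- pipeline_config(seed = 7, n_probes = "auto", distance = "cosine")
    study_env$cohort <- co
    study_env$res <- suppressMessages(run_pipeline(co$beta, co$samples,
                                                   config = cfg))
  }
  list(cohort = study_env$cohort, res = study_env$res)
}
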