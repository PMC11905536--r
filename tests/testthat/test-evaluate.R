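# Label harmonisation, F1 protocol, score bins, decisions, t-SNE.

test_that("foreign labels harmonise onto the open-set label set", {
  known <- c("ClassA", "ClassB")
  expect_equal(as.character(harmonize_labels(c("ClassA", "not applicable"), known)),
               c("ClassA", "unknown"))
  expect_equal(as.character(harmonize_labels(c("ClassA", "ClassB"), known)),
               c("ClassA", "ClassB"))
  expect_length(harmonize_labels(character(0), known), 0)
  expect_error(harmonize_labels(c("ClassA", "Mystery"), known), "Mystery")
  expect_equal(levels(harmonize_labels("ClassA", known)),
               c("ClassA", "ClassB", "unknown"))
})

test_that("filtering retains samples with known truths only", {
  yt <- c("A", "unknown", "B")
  yp <- c("A", "A", "unknown")
  out <- filter_known(yt, yp)
  expect_equal(out$y_true, c("A", "B"))
  expect_equal(out$y_pred, c("A", "unknown"))  # predictions untouched
  expect_equal(out$keep, c(TRUE, FALSE, TRUE))
  expect_warning(filter_known(c("unknown", "unknown"), c("A", "B")),
                 "no samples")
  # order independence with harmonisation
  known <- "A"
  h <- harmonize_labels(c("A", "not applicable"), known)
  f1 <- filter_known(h, harmonize_labels(c("A", "A"), known))
  expect_equal(as.character(f1$y_true), "A")
})

test_that("f1 scores reproduce the printed-definition examples", {
  perfect <- f1_scores(c("A", "B", "A"), c("A", "B", "A"))
  expect_equal(perfect$f1_micro, 1)
  expect_equal(perfect$f1_macro, 1)

  ex <- f1_scores(c("A", "A", "B"), c("A", "B", "B"))
  expect_equal(ex$f1_micro, 2 / 3, tolerance = 1e-12)
  expect_equal(ex$f1_macro, 2 / 3, tolerance = 1e-12)
  expect_equal(ex$per_class$f1, c(2 / 3, 2 / 3), tolerance = 1e-12)

  # absent classes in a fixed label set contribute F1 = 0 to the macro
  fixed <- f1_scores(c("A", "A"), c("A", "A"), labels = c("A", "B"))
  expect_equal(fixed$f1_macro, 0.5)
  expect_equal(fixed$f1_micro, 1)

  expect_error(f1_scores(character(0), character(0)), "empty")
  expect_error(f1_scores(c("A", "C"), c("A", "A"), labels = c("A", "B")),
               "true labels")
})

test_that("f1 scores agree with a brute-force confusion-matrix oracle", {
  withr::with_seed(2024, {
    for (i in 1:200) {
      L <- sample(2:6, 1)
      n <- sample(5:50, 1)
      labels <- LETTERS[1:L]
      yt <- sample(labels, n, replace = TRUE)
      yp <- sample(labels, n, replace = TRUE)
      got <- f1_scores(yt, yp, labels = labels)

      cm <- table(factor(yt, labels), factor(yp, labels))
      f1s <- vapply(seq_len(L), function(k) {
        tp <- cm[k, k]; fp <- sum(cm[-k, k]); fn <- sum(cm[k, -k])
        if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
      }, numeric(1))
      expect_equal(got$f1_macro, mean(f1s), tolerance = 1e-12)
      expect_equal(got$f1_micro, sum(diag(cm)) / n, tolerance = 1e-12)
    }
  })
})

test_that("score bins use the printed half-open intervals", {
  expect_equal(as.character(bin_score(0.9)), ">=0.9")
  expect_equal(as.character(bin_score(0.5)), "0.5<=score<0.9")
  expect_equal(as.character(bin_score(0.4999)), "<0.5")
  expect_equal(as.character(bin_score(c(1, 0, 0.89999))),
               c(">=0.9", "<0.5", "0.5<=score<0.9"))
  expect_error(bin_score(1.2), "\\[0, 1\\]")
  expect_error(bin_score(-0.1), "\\[0, 1\\]")
})

test_that("decisions follow the five-category rules over the whole domain", {
  expect_equal(as.character(categorize_decision(0.95, "concordant")$decision),
               "Match")
  expect_equal(as.character(categorize_decision(0.72, "concordant")$decision),
               "Likely match")
  expect_equal(as.character(categorize_decision(0.95, "indeterminate")$decision),
               "Uncertain")

  # total over the score x evidence grid
  grid <- expand.grid(
    score = c(0, 0.3, 0.5, 0.89, 0.9, 1),
    evidence = c("concordant", "discordant", "indeterminate", "control"),
    stringsAsFactors = FALSE)
  out <- categorize_decision(grid$score, grid$evidence)
  expect_false(anyNA(out$decision))
  expect_true(all(out$decision[out$evidence == "discordant"] == "No match"))
  expect_true(all(out$decision[out$evidence == "control"] == "Control (No match)"))
  expect_true(all(out$decision[out$evidence == "indeterminate"] == "Uncertain"))
  conc <- out[out$evidence == "concordant", ]
  expect_equal(as.character(conc$decision),
               ifelse(conc$calibrated_score >= 0.9, "Match", "Likely match"))
  # bin consistency
  expect_equal(out$score_bin, bin_score(out$calibrated_score))
  expect_error(categorize_decision(0.5, "maybe"), "evidence")
})

test_that("closed-set probabilities gain an unknown label ranked last", {
  expect_equal(unname(append_unknown_to_closed(c(0.6, 0.4))), c(0.6, 0.4, 0))
  p <- softmax(rnorm(5))
  out <- append_unknown_to_closed(p)
  expect_equal(unname(which.max(out)), unname(which.max(p)))
  u <- rep(1 / 91, 91)
  expect_equal(unname(which.min(append_unknown_to_closed(u))), 92L)
  pm <- matrix(c(0.6, 0.4, 0.2, 0.8), 2, byrow = TRUE)
  outm <- append_unknown_to_closed(pm)
  expect_equal(dim(outm), c(2, 3))
  expect_equal(unname(outm[, 3]), c(0, 0))
})

test_that("the noise-injection experiment degrades macro F1 monotonically at the endpoint", {
  st <- seed7_study()
  res <- st$res
  co <- st$cohort
  lg <- suppressMessages(
    remove_batch_effect(log_transform(co$beta), co$samples$batch))
  x <- t(lg)[, res$panel$probe_id]
  pk <- res$predictions[res$predictions$truth != "unknown", ]
  x_known <- x[pk$sample_id, , drop = FALSE]
  x_noise <- x[co$samples$sample_id[co$samples$is_novel], , drop = FALSE]

  curve <- noise_injection_experiment(res$model, res$openmax,
                                      x_known, pk$truth, x_noise,
                                      steps = c(0, 10, 20, 30), seed = 1)
  expect_equal(curve$n_noise, c(0, 10, 20, 30))
  # the zero-noise step equals the base known-only evaluation
  base <- f1_scores(pk$truth, pk$predicted,
                    labels = c(res$model$classes, "unknown"))
  expect_equal(curve$f1_macro[1], base$f1_macro, tolerance = 1e-12)
  # a closed-set model misassigns every noise sample: macro F1 falls
  closed <- noise_injection_experiment(res$model, res$openmax,
                                       x_known, pk$truth, x_noise,
                                       steps = c(0, 10, 20, 30), seed = 1,
                                       mode = "91")
  expect_lte(closed$f1_macro[4], closed$f1_macro[1])
  expect_true(all(diff(closed$f1_macro) <= 1e-12))
  # deterministic under seed
  again <- noise_injection_experiment(res$model, res$openmax,
                                      x_known, pk$truth, x_noise,
                                      steps = c(0, 10, 20, 30), seed = 1)
  expect_identical(curve, again)
  expect_error(noise_injection_experiment(res$model, res$openmax, x_known,
                                          pk$truth, x_noise, steps = 1000),
               "exceeds")
})

test_that("t-SNE embeddings are deterministic and respect cluster structure", {
  co <- generate_cohort(synthetic_spec(
    n_known_classes = 3, class_sizes = c(12, 12, 12), n_novel_classes = 0,
    n_probes = 60, n_informative = 8, n_batches = 1, seed = 4))
  x <- t(log_transform(co$beta))
  e1 <- suppressMessages(embed_tsne(x, perplexity = 8, max_iter = 300, seed = 9))
  e2 <- suppressMessages(embed_tsne(x, perplexity = 8, max_iter = 300, seed = 9))
  expect_identical(e1, e2)
  expect_equal(dim(e1), c(36, 2))

  # within-class pairwise distances below between-class distances
  dmat <- as.matrix(dist(e1))
  same <- outer(co$samples$class_label, co$samples$class_label, "==")
  diag(same) <- NA
  expect_lt(mean(dmat[which(same)]), mean(dmat[which(!same)]))

  # duplicated sample lands nearly coincident
  xdup <- rbind(x, x[1, , drop = FALSE])
  rownames(xdup) <- c(rownames(x), "dup")
  ed <- suppressMessages(embed_tsne(xdup, perplexity = 8, max_iter = 300,
                                    seed = 9))
  d_dup <- sqrt(sum((ed["dup", ] - ed[1, ])^2))
  expect_lt(d_dup, median(dist(ed)) * 0.1)

  expect_error(embed_tsne(x[1:2, ]), "3 samples")
  expect_error(embed_tsne(x[, 1, drop = FALSE]), "2 dimensions")
})
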