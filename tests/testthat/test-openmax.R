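# OpenMax: mean activation vectors, Weibull tails, recalibration and
# open-set prediction.

# strictly positive clusters so the leaky-ReLU identity network passes
# inputs through unchanged
cluster_fixture <- function(seed = 1, n = 30, sd = 0.05) {
  withr::with_seed(seed, {
    xa <- cbind(rnorm(n, 1.5, sd), rnorm(n, 0.5, sd))
    xb <- cbind(rnorm(n, 0.5, sd), rnorm(n, 1.5, sd))
    x <- rbind(xa, xb)
    colnames(x) <- c("f1", "f2")
    list(x = x, y = factor(rep(c("A", "B"), each = n)))
  })
}

test_that("mean activation vectors are class means over correct samples", {
  model <- identity_mlp()
  d <- cluster_fixture()
  stats <- fit_mavs(model, d$x, d$y)
  expect_equal(stats[[1]]$class, "A")
  # identity network: activations equal inputs, all samples correct
  expect_equal(stats[[1]]$mav, colMeans(d$x[d$y == "A", ]),
               ignore_attr = TRUE)
  # distances match a brute-force recomputation, sorted
  brute <- sort(sqrt(rowSums(sweep(d$x[d$y == "A", ], 2,
                                   colMeans(d$x[d$y == "A", ]))^2)))
  expect_equal(stats[[1]]$distances, brute, ignore_attr = TRUE)

  # two samples a, b: mav = (a + b) / 2, and identical rows give zero distances
  x2 <- rbind(c(1, 0), c(0.8, 0.2), c(0, 1), c(0, 1))
  colnames(x2) <- c("f1", "f2")
  y2 <- factor(c("A", "A", "B", "B"))
  st2 <- fit_mavs(model, x2, y2)
  expect_equal(st2[[1]]$mav, c(0.9, 0.1), ignore_attr = TRUE)
  expect_equal(st2[[2]]$distances, c(0, 0), ignore_attr = TRUE)
})

test_that("classes with no correct predictions fall back to all samples", {
  model <- identity_mlp()
  model$W2 <- -model$W2  # invert logits: everything misclassified
  d <- cluster_fixture()
  expect_message(stats <- fit_mavs(model, d$x, d$y), "using all")
  expect_equal(stats[[1]]$mav, colMeans(d$x[d$y == "A", ]),
               ignore_attr = TRUE)
})

test_that("exponential tails recover a planted scale (as-printed mode)", {
  st <- list(structure(list(class = "A", distances = sort(rep(3, 10))),
                       class = "class_activation_stats"))
  tails <- fit_weibull_tails(st, tail_size = 10, mode = "as_printed")
  expect_equal(tails$sigma, 3)  # exponential MLE of a constant tail = that value
  expect_equal(tails$shape, 1)

  withr::with_seed(42, {
    d <- sort(rexp(1000, rate = 1 / 2))
  })
  st <- list(structure(list(class = "A", distances = d),
                       class = "class_activation_stats"))
  tails <- fit_weibull_tails(st, tail_size = 1000, mode = "as_printed")
  expect_equal(tails$sigma, 2, tolerance = 0.1)
})

test_that("cdf-mode maximum likelihood recovers planted Weibull parameters", {
  withr::with_seed(7, {
    d <- sort(rweibull(1000, shape = 3, scale = 1.5))
  })
  st <- list(structure(list(class = "A", distances = d),
                       class = "class_activation_stats"))
  tails <- fit_weibull_tails(st, tail_size = 1000, mode = "weibull_cdf")
  expect_equal(tails$sigma, 1.5, tolerance = 0.15 * 1.5)
  expect_equal(tails$shape, 3, tolerance = 0.15 * 3)

  degenerate <- list(structure(list(class = "A", distances = c(0, 0, 0)),
                               class = "class_activation_stats"))
  expect_error(fit_weibull_tails(degenerate, tail_size = 3), "all-zero")
  short <- list(structure(list(class = "A", distances = 1),
                          class = "class_activation_stats"))
  expect_error(fit_weibull_tails(short), ">= 2 distances")
})

test_that("extreme-value tails place the weight midpoint beyond the data range", {
  withr::with_seed(11, {
    d <- sort(rweibull(30, shape = 2, scale = 1))
  })
  st <- list(structure(list(class = "A", distances = d),
                       class = "class_activation_stats"))
  tails <- fit_extreme_tails(st, n_extreme = 300)
  flip <- tails$sigma * log(2)^(1 / tails$shape)
  expect_gt(flip, max(d))
  # larger hypothetical cohorts push the midpoint further out
  tails2 <- fit_extreme_tails(st, n_extreme = 3000)
  expect_gt(tails2$sigma * log(2)^(1 / tails2$shape), flip)
})

test_that("weibull weights match the closed forms in both modes", {
  expect_equal(weibull_weight(0, 2, mode = "as_printed"), 1)
  expect_equal(weibull_weight(1e6, 2, mode = "as_printed"), 0, tolerance = 1e-9)
  expect_equal(weibull_weight(2, 2, 1, mode = "as_printed"), exp(-1),
               tolerance = 1e-12)
  # cdf mode is the complement and grows with distance
  d <- seq(0, 5, by = 0.25)
  w <- weibull_weight(d, 1.5, 3, mode = "weibull_cdf")
  expect_equal(w, 1 - weibull_weight(d, 1.5, 3, mode = "as_printed")^(1),
               tolerance = 1e-12)
  expect_true(all(diff(w) >= 0))
  expect_error(weibull_weight(-1, 1), "non-negative")
})

test_that("recalibration reproduces the worked example exactly", {
  out <- recalibrate(c(0.7, 0.3), c(0.5, 0.0))
  expect_equal(out$f, c(0.35, 0.30))
  expect_equal(out$f_u, 0.35)
  expect_equal(unname(out$p_prime), c(0.35, 0.30, 0.35))
  expect_equal(out$y_hat, "1")  # ties broken toward the lowest-index class
})

test_that("recalibration limits: w = 0 recovers SoftMax, w = 1 is all-unknown", {
  p <- softmax(c(1, 2, 0.5)); names(p) <- c("A", "B", "C")
  out0 <- recalibrate(p, rep(0, 3))
  expect_equal(out0$p_prime[1:3], p)
  expect_equal(unname(out0$p_prime["unknown"]), 0)
  expect_equal(out0$y_hat, "B")
  out1 <- recalibrate(p, rep(1, 3))
  expect_equal(unname(out1$p_prime["unknown"]), 1)
  expect_equal(unname(out1$p_prime[1:3]), c(0, 0, 0))
  expect_equal(out1$y_hat, "unknown")
  expect_error(recalibrate(p, c(0, 1)), "length mismatch")
  expect_error(recalibrate(p, c(2, 0, 0)), "\\[0, 1\\]")
})

test_that("recalibrated probabilities always sum to one", {
  withr::with_seed(123, {
    for (i in 1:200) {
      K <- sample(2:10, 1)
      p <- softmax(rnorm(K))
      w <- runif(K)
      out <- recalibrate(p, w)
      expect_equal(sum(out$p_prime), 1, tolerance = 1e-9)
      expect_true(all(out$p_prime >= 0))
    }
  })
})

test_that("the unknown probability is monotone in each class weight", {
  p <- c(0.5, 0.3, 0.2)
  w <- c(0.2, 0.4, 0.1)
  pu <- vapply(seq(0, 1, by = 0.1), function(w1) {
    unname(recalibrate(p, c(w1, w[2], w[3]))$p_prime["unknown"])
  }, numeric(1))
  expect_true(all(diff(pu) >= -1e-12))
})

test_that("open-set prediction keeps centroids and flags far outliers", {
  model <- identity_mlp()
  d <- cluster_fixture()
  om <- fit_openmax(model, d$x, d$y, tail_size = 20, mode = "weibull_cdf")
  # class centroid: small distance, prediction stays with the class
  centroid <- matrix(colMeans(d$x[d$y == "A", ]), 1,
                     dimnames = list(NULL, c("f1", "f2")))
  pc <- predict_open(model, om, centroid)
  expect_equal(as.character(pc$class), "A")
  # a point ten times farther than any training distance: unknown
  far <- matrix(c(30, -30), 1, dimnames = list(NULL, c("f1", "f2")))
  pf <- predict_open(model, om, far)
  expect_equal(as.character(pf$class), "unknown")
  expect_gt(pf$p_unknown, 0.99)
  # probabilities over K + 1 labels sum to one per sample
  expect_equal(unname(rowSums(pf$prob)), 1, tolerance = 1e-9)
})

test_that("degenerate tails (w = 0 everywhere) reduce to the SoftMax argmax", {
  model <- identity_mlp()
  d <- cluster_fixture()
  om <- fit_openmax(model, d$x, d$y, tail_size = 20)
  om$tails$sigma[] <- 1e12  # cdf weight ~ 0 at any realistic distance
  pred <- predict_open(model, om, d$x)
  expect_equal(as.character(pred$class),
               as.character(predict(model, d$x, type = "class")))
  expect_true(all(pred$p_unknown < 1e-6))
})

test_that("an OpenMax model round-trips through JSON", {
  model <- identity_mlp()
  d <- cluster_fixture()
  om <- fit_openmax(model, d$x, d$y, tail_size = 10)
  path <- withr::local_tempfile(fileext = ".json")
  save_openmax(om, path)
  back <- load_openmax(path)
  q <- d$x[c(1, 35), , drop = FALSE]
  expect_equal(predict_open(model, back, q)$prob,
               predict_open(model, om, q)$prob, tolerance = 1e-12)
})

test_that("held-out calibration rebuilds distance lists from pooled ratios", {
  model <- identity_mlp()
  d <- cluster_fixture(n = 40)
  cal <- cluster_fixture(seed = 99, n = 10)
  om_cal <- fit_openmax(model, d$x, d$y, x_cal = cal$x, y_cal = cal$y,
                        tail_method = "extreme")
  expect_true(om_cal$calibrated)
  om_plain <- fit_openmax(model, d$x, d$y, tail_method = "extreme")
  # calibration on fresh samples widens the tolerance
  expect_true(all(om_cal$tails$sigma >= om_plain$tails$sigma * 0.5))
  expect_error(fit_openmax(model, d$x, d$y, x_cal = cal$x,
                           y_cal = cal$y[1:3]),
               "calibration labels")
})
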