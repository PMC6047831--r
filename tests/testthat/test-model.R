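test_that("rank AUC matches exhaustive pair enumeration", {
  # pairs: 3>2 (1), 3>1 (1), 2 vs 2 tie (0.5), 2>1 (1) -> 3.5/4
  expect_equal(compute_auc(c(3, 2, 2, 1), c(TRUE, TRUE, FALSE, FALSE)), 0.875)
  expect_equal(compute_auc(1:10, c(rep(FALSE, 5), rep(TRUE, 5))), 1)
  expect_equal(compute_auc(1:10, c(rep(TRUE, 5), rep(FALSE, 5))), 0)
  expect_error(compute_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
  # label swap maps AUC to its complement
  set.seed(1)
  s <- rnorm(40); y <- rep(c(TRUE, FALSE), 20)
  expect_equal(compute_auc(s, !y), 1 - compute_auc(s, y))
})

test_that("rank AUC equals the trapezoidal area under the empirical ROC", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(20:80, 1)
    y <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.4, 0.6))
    if (length(unique(y)) < 2) next
    s <- rnorm(n) + y          # ties occasionally via rounding
    if (i %% 2 == 0) s <- round(s, 1)
    roc <- roc_curve(s, y)
    trap <- sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) +
                                   utils::tail(roc$tpr, -1)) / 2)
    expect_equal(compute_auc(s, y), trap, tolerance = 1e-9)
  }
})

test_that("holdout split sizes use the floor rule", {
  expect_equal(holdout_split_sizes(1409), c(train = 1268L, test = 141L))
  expect_equal(holdout_split_sizes(10, 0.9), c(train = 9L, test = 1L))
  expect_equal(holdout_split_sizes(100, 0.75), c(train = 75L, test = 25L))
})

test_that("lasso logistic fit recovers a planted sparse model", {
  set.seed(5)
  n <- 600
  x <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  eta <- 1.5 * x[, 1] - 1.2 * x[, 2]
  y <- runif(n) < plogis(eta)
  fit <- fit_l1_logistic(x, y)
  expect_gt(fit$coefficients["f1"], 0)
  expect_lt(fit$coefficients["f2"], 0)
  # most null features shrunk exactly to zero by the penalty
  expect_gte(sum(fit$coefficients[3:10] == 0), 6)
  expect_error(fit_l1_logistic(x, rep(TRUE, n)), "degenerate")
})

test_that("repeated holdout is reproducible and sized correctly", {
  set.seed(8)
  x <- matrix(rnorm(200 * 5), 200, 5,
              dimnames = list(NULL, paste0("f", 1:5)))
  y <- c(rep(TRUE, 60), rep(FALSE, 140))
  f1 <- ir_dependence(x, y, n_repeats = 10, seed = 42)
  f2 <- ir_dependence(x, y, n_repeats = 10, seed = 42)
  expect_identical(f1$aucs, f2$aucs)
  expect_identical(f1$mean_coefficients, f2$mean_coefficients)
  expect_equal(f1$n_train, 54L)
  expect_equal(f1$n_test, 6L)
  expect_true(all(diff(f1$mean_roc$tpr) >= 0))   # averaged ROC is monotone
  expect_error(ir_dependence(x[51:80, ], y[51:80]), "at least 20")
  expect_error(ir_dependence(x, rep(c(TRUE, FALSE), c(150, 50))),
               "as many negatives")
})

test_that("exchangeable classes give chance-level holdout AUC", {
  set.seed(9)
  x <- matrix(rnorm(400 * 6), 400, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rep(c(TRUE, FALSE), each = 200)     # labels independent of features
  fit <- ir_dependence(x, y, n_repeats = 60, seed = 3)
  expect_lt(abs(fit$mean_auc - 0.5), 0.03)
})

test_that("a separable feature drives holdout AUC to one", {
  set.seed(10)
  x <- cbind(sep = c(rnorm(50, 10), rnorm(100, -10)),
             noise = rnorm(150))
  y <- rep(c(TRUE, FALSE), c(50, 100))
  fit <- ir_dependence(x, y, n_repeats = 20, seed = 4)
  expect_gte(fit$mean_auc, 0.99)
  expect_gt(fit$mean_coefficients["sep"], 0)
})

test_that("transfer evaluation reuses fixed per-repeat models", {
  set.seed(12)
  n <- 300
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- runif(n) < plogis(1.8 * x[, 1] - 1.5)
  y[1:40] <- TRUE                       # ensure enough positives
  neg <- x[!y, , drop = FALSE]
  # controls relabelled positive transfer at chance level
  fit <- ir_dependence(x, y, n_repeats = 40, seed = 6,
                       alt_sets = list(ctrl_as_pos = neg))
  expect_lt(abs(fit$transfer_aucs["ctrl_as_pos"] - 0.5), 0.05)
  # post-hoc transfer_evaluate agrees with the in-loop path in expectation
  post <- transfer_evaluate(fit, list(ctrl_as_pos = neg), seed = 7)
  expect_lt(abs(post["ctrl_as_pos"] - fit$transfer_aucs["ctrl_as_pos"]), 0.05)
  # a stronger-effect positive set transfers at least as well as chance set
  strong <- matrix(rnorm(200 * 4), 200, 4,
                   dimnames = list(NULL, paste0("f", 1:4)))
  strong[, 1] <- strong[, 1] + 3
  post2 <- transfer_evaluate(fit, list(strong = strong), seed = 8)
  expect_gt(post2["strong"], 0.9)
  expect_error(transfer_evaluate(fit, list(tiny = x[1:3, ])), "smaller")
})

test_that("single-feature analysis separates signal from noise", {
  set.seed(13)
  n <- 500
  x <- cbind(strong = rnorm(n), weak = rnorm(n), none = rnorm(n))
  y <- runif(n) < plogis(2 * x[, "strong"] + 0.5 * x[, "weak"])
  sf <- single_feature_analysis(x, y, n_repeats = 40, seed = 5)
  expect_gt(sf$mean_auc[sf$feature == "strong"], sf$mean_auc[sf$feature == "weak"])
  expect_gt(sf$mean_auc[sf$feature == "weak"], sf$mean_auc[sf$feature == "none"])
  expect_lt(abs(sf$mean_auc[sf$feature == "none"] - 0.5), 0.05)
  expect_lt(sf$mean_deviance_reduction[sf$feature == "none"], 0.02)
  expect_gt(sf$mean_deviance_reduction[sf$feature == "strong"], 0.2)
  # constant features are flagged, not errors
  x2 <- cbind(x, const = 1)
  sf2 <- single_feature_analysis(x2, y, n_repeats = 5, seed = 6)
  expect_true(sf2$flagged[sf2$feature == "const"])
  expect_equal(sf2$mean_auc[sf2$feature == "const"], 0.5)
})

test_that("model methods expose coefficients, predictions and the ROC", {
  set.seed(14)
  x <- matrix(rnorm(240 * 3), 240, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- runif(240) < plogis(2 * x[, 1] - 1.5)
  y[1:30] <- TRUE
  fit <- ir_dependence(x, y, n_repeats = 15, seed = 2)
  expect_s3_class(fit, "ir_dependence")
  expect_named(coef(fit), c("(Intercept)", "a", "b", "c"))
  p <- predict(fit, x[1:10, ])
  expect_true(all(p >= 0 & p <= 1))
  expect_equal(predict(fit, x[1:10, ], type = "link"),
               qlogis(p), tolerance = 1e-8)
  s <- summary(fit)
  expect_s3_class(s, "summary.ir_dependence")
  expect_output(print(fit), "mean AUC")
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
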