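test_that("balancing under-samples the larger class reproducibly", {
  labels <- c(rep(1, 10), rep(0, 50))
  idx <- balance(labels, seed = 3)
  expect_equal(sum(labels[idx] == 1), 10)
  expect_equal(sum(labels[idx] == 0), 10)
  expect_true(all(which(labels == 1) %in% idx))   # minority untouched
  expect_identical(idx, balance(labels, seed = 3))
  # different seeds give different selections essentially always
  draws <- vapply(1:100, function(s) paste(balance(labels, s), collapse = ","),
                  "")
  expect_gt(length(unique(draws)), 95)
  # already balanced input is unchanged
  expect_identical(balance(rep(c(0, 1), 10), 1), 1:20)
  expect_error(balance(rep(1, 5), 1), "non-empty")
})

test_that("rank-sum p-values match exact permutation enumeration at small n", {
  set.seed(21)
  for (k in 1:5) {
    x1 <- round(stats::rnorm(6, 1), 6)
    x0 <- round(stats::rnorm(7), 6)
    got <- tiscall:::rank_sum_p(c(x1, x0), c(rep(1, 6), rep(0, 7)))
    expect_equal(got, oracle_ranksum_p(x1, x0), tolerance = 1e-12)
  }
})

test_that("feature selection keeps significant, uncorrelated features", {
  set.seed(7)
  n <- 40
  y <- rep(c(1, 0), each = n / 2)
  strong <- y * 3 + stats::rnorm(n, sd = 0.3)        # highly significant
  copy <- strong * 2 + 1e-9 * stats::rnorm(n)        # perfectly correlated
  weak <- stats::rnorm(n)                            # no signal
  const <- rep(1, n)
  X <- cbind(utr_length = strong, orf_length_nt = copy, kozak_class = weak,
             utr_frac_A = const)
  cfg <- training_config(alpha = 0.05, n_features_total = 4)
  sel <- select_features(X, y, cfg)
  expect_true("utr_length" %in% sel$kept)
  expect_false("orf_length_nt" %in% sel$kept)        # dropped: |r| >= 0.7
  expect_true("orf_length_nt" %in% sel$dropped_correlated)
  expect_false("kozak_class" %in% sel$kept)          # p ~ 1
  expect_true("utr_frac_A" %in% sel$dropped_constant)
  # kept set is pairwise uncorrelated below the bound
  if (length(sel$kept) > 1) {
    r <- stats::cor(X[, sel$kept])
    expect_true(all(abs(r[upper.tri(r)]) < 0.7))
  }
  expect_error(select_features(cbind(a = stats::rnorm(n)), y,
                               training_config()),
               "no significant features")
})

test_that("of two correlated significant features the smaller p-value wins", {
  set.seed(9)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  f1 <- y * 5 + stats::rnorm(n, sd = 0.2)
  f2 <- f1 + stats::rnorm(n, sd = 0.4)               # correlated, noisier
  X <- cbind(utr_length = f1, utr_conservation = f2)
  sel <- select_features(X, y, training_config(alpha = 0.05,
                                               n_features_total = 2))
  expect_lt(sel$p_values["utr_length"], sel$p_values["utr_conservation"] + 1e-15)
  expect_identical(sel$kept, "utr_length")
})

test_that("the linear fit recovers exact and noisy generating models", {
  # exact relation
  x <- matrix(seq(-2, 2, length.out = 50), dimnames = list(NULL, "f"))
  y <- 0.3 * drop(scale(x)) + 0.2
  m <- fit(x, y, training_config())
  expect_equal(unname(m$coefficients), 0.3, tolerance = 1e-9)
  expect_equal(m$intercept, 0.2, tolerance = 1e-9)

  # labels independent of features: coefficients ~ 0, intercept = mean
  set.seed(13)
  x <- matrix(stats::rnorm(400), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- rep(c(0, 1), 100)
  m <- fit(x, y, training_config())
  expect_equal(m$intercept, 0.5, tolerance = 1e-12)
  expect_lt(max(abs(m$coefficients)), 0.15)

  # coefficient recovery within 3 standard errors on simulated data
  set.seed(99)
  n <- 2000
  X <- matrix(stats::rnorm(n * 3), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  beta <- c(0.4, -0.25, 0.1)
  y <- drop(X %*% beta) + 0.5 + stats::rnorm(n, sd = 0.1)
  m <- fit(X, y, training_config())
  ols <- stats::lm(y ~ scale(X))
  se <- sqrt(diag(stats::vcov(ols)))[-1]
  expect_true(all(abs(m$coefficients - beta * apply(X, 2, stats::sd)) <
                    3 * se))
})

test_that("predicted confidences are clamped to [0, 1]", {
  m <- toy_model("f", weight = 1, intercept = 0.5, center = 0, scale = 1)
  X <- matrix(c(0.8, -0.7, 0.05), ncol = 1, dimnames = list(NULL, "f"))
  expect_equal(predict_confidence(m, X), c(1, 0, 0.55))
  expect_error(predict_confidence(m, matrix(1, ncol = 1,
                                            dimnames = list(NULL, "g"))),
               "missing feature")
})

test_that("SVR fitting records the grid choice and serializes faithfully", {
  set.seed(31)
  n <- 60
  X <- matrix(stats::rnorm(2 * n), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  y <- plogis(2 * X[, 1] - X[, 2]) + stats::rnorm(n, sd = 0.05)
  cfg <- training_config(model_kind = "svr_rbf", cv_folds = 5)
  m <- fit(X, y, cfg, seed = 4)
  expect_true(m$svr$cost %in% cfg$C_grid)
  expect_true(m$svr$epsilon %in% cfg$epsilon_grid)
  expect_equal(m$svr$kernel, "radial")
  # manual kernel prediction equals e1071's on the training rows
  ref <- e1071::svm(x = scale(X), y = y, type = "eps-regression",
                    kernel = "radial", cost = m$svr$cost,
                    epsilon = m$svr$epsilon, scale = FALSE)
  expect_equal(tiscall:::predict_raw(m, X),
               unname(stats::predict(ref, scale(X))), tolerance = 1e-6)
  # JSON round trip preserves predictions
  f <- tempfile(fileext = ".json")
  write_model(m, f)
  m2 <- read_model(f)
  expect_equal(predict_confidence(m2, X), predict_confidence(m, X),
               tolerance = 1e-12)
})

test_that("threshold scanning matches a brute-force confusion recount", {
  set.seed(41)
  conf <- round(stats::runif(20), 2)
  labels <- stats::rbinom(20, 1, 0.5)
  sc <- threshold_scan(conf, labels)
  expect_equal(nrow(sc$table), 101)
  for (t in c(0, 0.25, 0.54, 0.8, 1)) {
    o <- oracle_metrics(conf, labels, t)
    row <- sc$table[sc$table$t == t, ]
    expect_equal(row$TP, unname(o["TP"]))
    expect_equal(row$accuracy, unname(o["accuracy"]))
    expect_equal(row$sensitivity, unname(o["sensitivity"]))
    expect_equal(row$specificity, unname(o["specificity"]))
  }
  expect_equal(sc$auc, oracle_auc(conf, labels))
  # t = 0 predicts everything positive
  r0 <- sc$table[sc$table$t == 0, ]
  expect_equal(r0$sensitivity, 1)
  expect_equal(r0$specificity, 0)
  # perfectly separated scores
  sc2 <- threshold_scan(c(.9, .8, .2, .1), c(1, 1, 0, 0))
  expect_equal(sc2$best$accuracy, 1)
  expect_equal(sc2$auc, 1)
  # AUC is invariant under monotone transforms of the confidences
  expect_equal(threshold_scan(plogis(conf * 7 - 3), labels)$auc, sc$auc)
})

test_that("confidence classes follow the published bounds", {
  expect_equal(confidence_class(0.92), "very_high")
  expect_equal(confidence_class(0.81), "high")
  expect_equal(confidence_class(0.75), "moderate")
  expect_equal(confidence_class(0.60, t = 0.54), "low")
  expect_equal(confidence_class(0.50, t = 0.54), "below_threshold")
  expect_equal(confidence_class(c(0.95, 0.1), t = 0.5),
               c("very_high", "below_threshold"))
})

test_that("the repeated experiment is reproducible under a fixed seed", {
  fx <- end_to_end_fixture(sim_params(n_transcripts = 40, seed = 5,
                                      strong_signal = TRUE),
                           training_config(n_repeats = 2, seed = 5),
                           use_orthologs = FALSE, max_false = 150)
  fx2 <- end_to_end_fixture(sim_params(n_transcripts = 40, seed = 5,
                                       strong_signal = TRUE),
                            training_config(n_repeats = 2, seed = 5),
                            use_orthologs = FALSE, max_false = 150)
  expect_identical(fx$experiment$metrics, fx2$experiment$metrics)
  expect_identical(fx$experiment$best_model$coefficients,
                   fx2$experiment$best_model$coefficients)
  met <- fx$experiment$metrics
  expect_true(all(met$accuracy >= 0 & met$accuracy <= 1))
  expect_true(all(met$auc >= 0 & met$auc <= 1))
  # per-run PWMs live in the retained model and carry a proper background
  pwm <- fx$experiment$best_model$pwm
  expect_s3_class(pwm, "tis_pwm")
  expect_equal(sum(pwm$bg), 1, tolerance = 1e-9)
  expect_equal(pwm$width, 28)
})
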