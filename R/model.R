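# Regression modelling: class balancing, rank-sum + Bonferroni feature
# selection with correlation pruning, linear / SVR fits, threshold scanning
# and the repeated-balancing experiment loop.

#' Training configuration
#'
#' @param model_kind One of `"linear"`, `"svr_linear"`, `"svr_rbf"`,
#'   `"svr_poly"`.
#' @param C_grid,epsilon_grid SVR hyperparameter grids searched by
#'   cross-validation (held-out mean squared error; ties resolved in grid
#'   order).
#' @param cv_folds Cross-validation folds for the SVR grid.
#' @param train_fraction Fraction of the balanced data used for training.
#' @param n_repeats Number of balancing/splitting repetitions.
#' @param alpha Familywise significance level before Bonferroni correction.
#' @param n_features_total Bonferroni denominator (total feature-space size).
#' @param r_max Pairwise Pearson correlation bound for kept features.
#' @param top_kmers Number of most significant k-mer features admitted to
#'   the candidate pool.
#' @param seed Base RNG seed.
#' @return List of class `tis_config`.
#' @export
training_config <- function(model_kind = c("linear", "svr_linear", "svr_rbf",
                                           "svr_poly"),
                            C_grid = c(0.1, 1, 10, 100),
                            epsilon_grid = c(0.01, 0.1, 1, 10),
                            cv_folds = 10, train_fraction = 0.7,
                            n_repeats = 10, alpha = 0.01,
                            n_features_total = 1252, r_max = 0.7,
                            top_kmers = 50, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            length(C_grid) >= 1, length(epsilon_grid) >= 1)
  structure(
    list(model_kind = match.arg(model_kind), C_grid = C_grid,
         epsilon_grid = epsilon_grid, cv_folds = cv_folds,
         train_fraction = train_fraction, n_repeats = n_repeats,
         alpha = alpha, n_features_total = n_features_total, r_max = r_max,
         top_kmers = top_kmers, seed = seed),
    class = "tis_config"
  )
}

#' Balance classes by under-sampling
#'
#' Randomly under-samples the larger class (without replacement) so both
#' classes have the size of the minority class; the minority class is left
#' untouched.
#'
#' @param labels 0/1 vector.
#' @param seed RNG seed (reproducible selection).
#' @return Integer vector of retained row indices, sorted.
#' @export
balance <- function(labels, seed = 1) {
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  if (!length(i1) || !length(i0)) stop("both classes must be non-empty")
  n <- min(length(i1), length(i0))
  set.seed(seed)
  keep <- c(if (length(i1) > n) sample(i1, n) else i1,
            if (length(i0) > n) sample(i0, n) else i0)
  sort(keep)
}

#' Rank-sum feature selection with Bonferroni and correlation pruning
#'
#' Computes a two-sided Wilcoxon rank-sum p-value per feature (exact null
#' distribution when both classes have fewer than 12 samples and no ties;
#' normal approximation with tie and continuity correction otherwise). A
#' feature is significant when p < alpha / n_features_total. The candidate
#' pool is every significant biological and PWM feature plus the
#' `top_kmers` most significant significant k-mer features; the pool is then
#' greedily pruned in ascending-p order, keeping a feature only when its
#' absolute Pearson correlation with every already-kept feature is below
#' `r_max`. Constant (zero-variance) features are dropped first.
#'
#' @param X Feature matrix (balanced training data) with registry names.
#' @param labels 0/1 vector.
#' @param config [training_config()].
#' @return Object of class `tis_selection`: `p_values`, `significant`,
#'   `kept`, `dropped` (with reasons), `threshold`.
#' @export
select_features <- function(X, labels, config = training_config()) {
  thr <- config$alpha / config$n_features_total
  p <- apply(X, 2, rank_sum_p, labels = labels)
  constant <- apply(X, 2, function(v) stats::var(v) == 0)
  sig <- !is.na(p) & p < thr & !constant
  is_kmer <- startsWith(colnames(X), "kmer:")
  pool <- colnames(X)[sig & !is_kmer]
  km <- colnames(X)[sig & is_kmer]
  if (length(km) > config$top_kmers) {
    km <- km[order(p[km])][seq_len(config$top_kmers)]
  }
  pool <- c(pool, km)
  if (!length(pool)) {
    stop("no significant features (smallest p = ",
         format(suppressWarnings(min(p, na.rm = TRUE)), digits = 3),
         ", threshold = ", format(thr, digits = 3), ")")
  }
  pool <- pool[order(p[pool])]
  kept <- character(0)
  dropped <- character(0)
  for (f in pool) {
    if (!length(kept)) {
      kept <- f
      next
    }
    r <- suppressWarnings(stats::cor(X[, f], X[, kept]))
    if (all(abs(r) < config$r_max, na.rm = TRUE)) {
      kept <- c(kept, f)
    } else {
      dropped <- c(dropped, f)
    }
  }
  structure(
    list(p_values = p, significant = names(p)[sig], kept = kept,
         dropped_correlated = dropped,
         dropped_constant = colnames(X)[constant], threshold = thr),
    class = "tis_selection"
  )
}

# Two-sided rank-sum p-value; exact via pwilcox when both groups < 12 and
# tie-free, else normal approximation with tie + continuity correction
# (this is stats::wilcox.test's decision rule, forced to our size cutoff).
rank_sum_p <- function(x, labels) {
  x1 <- x[labels == 1]
  x0 <- x[labels == 0]
  if (stats::var(x) == 0) return(NA_real_)
  exact <- length(x1) < 12 && length(x0) < 12 && !any(duplicated(x))
  suppressWarnings(
    stats::wilcox.test(x1, x0, exact = exact, correct = TRUE)$p.value
  )
}

#' Fit a regression model on selected features
#'
#' Features are z-normalized (training mean and SD stored with the model).
#' The linear model is an ordinary least-squares fit (with a tiny ridge
#' jitter when the design is singular); SVR models are epsilon-regression
#' fits whose cost and epsilon are chosen by `cv_folds`-fold
#' cross-validation over the configured grids, minimizing held-out mean
#' squared error, with remaining hyperparameters at library defaults.
#'
#' @param X Matrix of selected features (training rows).
#' @param labels 0/1 responses (true start = 1).
#' @param config [training_config()].
#' @param seed RNG seed for CV fold assignment.
#' @return Object of class `tis_model`.
#' @export
fit <- function(X, labels, config = training_config(), seed = config$seed) {
  X <- as.matrix(X)
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  if (any(scl == 0)) stop("zero-variance feature passed to fit(): ",
                          paste(colnames(X)[scl == 0], collapse = ", "))
  Xs <- scale(X, center = ctr, scale = scl)
  m <- list(kind = config$model_kind, feature_names = colnames(X),
            center = ctr, scale = scl)
  if (config$model_kind == "linear") {
    A <- cbind(`(Intercept)` = 1, Xs)
    qr_A <- qr(A)
    if (qr_A$rank < ncol(A)) {
      warning("singular design; adding ridge jitter 1e-8")
      co <- solve(crossprod(A) + diag(1e-8, ncol(A)), crossprod(A, labels))
      co <- drop(co)
    } else {
      co <- qr.coef(qr_A, labels)
    }
    m$intercept <- unname(co[1])
    m$coefficients <- co[-1]
  } else {
    kernel <- switch(config$model_kind, svr_linear = "linear",
                     svr_rbf = "radial", svr_poly = "polynomial")
    grid <- expand.grid(C = config$C_grid, epsilon = config$epsilon_grid)
    set.seed(seed)
    fold <- sample(rep(seq_len(config$cv_folds), length.out = nrow(Xs)))
    mse <- vapply(seq_len(nrow(grid)), function(g) {
      errs <- vapply(seq_len(config$cv_folds), function(k) {
        tr <- fold != k
        if (!any(tr) || all(tr)) return(NA_real_)
        # an epsilon tube wider than the response range leaves no support
        # vectors; such grid points are unusable and score Inf
        tryCatch({
          f <- e1071::svm(x = Xs[tr, , drop = FALSE], y = labels[tr],
                          type = "eps-regression", kernel = kernel,
                          cost = grid$C[g], epsilon = grid$epsilon[g],
                          scale = FALSE)
          mean((stats::predict(f, Xs[!tr, , drop = FALSE]) - labels[!tr])^2)
        }, error = function(e) Inf)
      }, numeric(1))
      mean(errs, na.rm = TRUE)
    }, numeric(1))
    mse[!is.finite(mse)] <- Inf
    best <- which.min(mse)
    sv <- e1071::svm(x = Xs, y = labels, type = "eps-regression",
                     kernel = kernel, cost = grid$C[best],
                     epsilon = grid$epsilon[best], scale = FALSE)
    m$svr <- list(
      kernel = kernel, cost = grid$C[best], epsilon = grid$epsilon[best],
      gamma = sv$gamma, degree = sv$degree, coef0 = sv$coef0,
      support_vectors = unname(as.matrix(sv$SV)),
      dual_coefs = unname(drop(sv$coefs)), rho = sv$rho,
      cv_mse = matrix(mse, nrow = length(config$C_grid),
                      dimnames = list(config$C_grid, config$epsilon_grid))
    )
  }
  structure(m, class = "tis_model")
}

# Kernel evaluation matching libsvm's conventions.
svr_kernel <- function(svr, U, V) {
  switch(svr$kernel,
    linear = U %*% t(V),
    radial = {
      d2 <- outer(rowSums(U^2), rowSums(V^2), "+") - 2 * U %*% t(V)
      exp(-svr$gamma * pmax(d2, 0))
    },
    polynomial = (svr$gamma * (U %*% t(V)) + svr$coef0)^svr$degree
  )
}

# Raw (unclamped) regression output.
predict_raw <- function(model, X) {
  X <- as.matrix(X)
  miss <- setdiff(model$feature_names, colnames(X))
  if (length(miss)) stop("missing feature(s): ", paste(miss, collapse = ", "))
  X <- X[, model$feature_names, drop = FALSE]
  Xs <- scale(X, center = model$center, scale = model$scale)
  if (model$kind == "linear") {
    drop(model$intercept + Xs %*% model$coefficients)
  } else {
    K <- svr_kernel(model$svr, Xs, model$svr$support_vectors)
    drop(K %*% model$svr$dual_coefs) - model$svr$rho
  }
}

#' Predict initiation confidences
#'
#' Applies the regression model and clamps the raw output to [0, 1]: values
#' above 1 become 1, values below 0 become 0.
#'
#' @param model A `tis_model`.
#' @param X Feature matrix carrying at least the model's features (named
#'   columns).
#' @return Numeric vector of confidences in [0, 1].
#' @export
predict_confidence <- function(model, X) {
  pmin(pmax(predict_raw(model, X), 0), 1)
}

#' Scan classification thresholds
#'
#' Evaluates the 101-point grid t = 0.00, 0.01, ..., 1.00 (a start site is
#' called true when its confidence is >= t), computing the confusion counts
#' and accuracy, sensitivity, specificity and precision at every threshold.
#' The best threshold maximizes accuracy, with ties broken by minimal
#' |sensitivity - specificity| and then by the smaller t. AUC is computed
#' rank-based (Mann-Whitney), independent of the grid.
#'
#' @param confidences Numeric vector in [0, 1].
#' @param labels 0/1 vector of the same length.
#' @return Object of class `tis_scan`: `table` (per-threshold metrics),
#'   `best_t`, `best` (metrics row at `best_t`), `auc`.
#' @export
threshold_scan <- function(confidences, labels) {
  stopifnot(length(confidences) == length(labels))
  ts <- 0:100 / 100
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tab <- do.call(rbind, lapply(ts, function(t) {
    pos <- confidences >= t
    TP <- sum(pos & labels == 1); FP <- sum(pos & labels == 0)
    FN <- n1 - TP; TN <- n0 - FP
    data.frame(
      t = t, TP = TP, FP = FP, TN = TN, FN = FN,
      accuracy = (TP + TN) / (n1 + n0),
      sensitivity = if (n1 > 0) TP / n1 else NA_real_,
      specificity = if (n0 > 0) TN / n0 else NA_real_,
      precision = if (TP + FP > 0) TP / (TP + FP) else NA_real_
    )
  }))
  auc <- if (n1 > 0 && n0 > 0) {
    r <- rank(confidences)
    (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  } else NA_real_
  bal <- abs(tab$sensitivity - tab$specificity)
  ord <- order(-tab$accuracy, bal, tab$t)
  best <- ord[1]
  structure(
    list(table = tab, best_t = tab$t[best], best = tab[best, ], auc = auc),
    class = "tis_scan"
  )
}

#' Confidence class of a predicted start site
#'
#' Bins a confidence value c into "very_high" (c >= 0.9), "high"
#' (0.8 <= c < 0.9), "moderate" (0.7 <= c < 0.8), "low" (t <= c < 0.7) or
#' "below_threshold" (c < t).
#'
#' @param c Confidence value(s) in [0, 1].
#' @param t Decision threshold (must be < 0.7).
#' @return Character vector of class labels.
#' @export
confidence_class <- function(c, t = 0.54) {
  stopifnot(t < 0.7)
  ifelse(c >= 0.9, "very_high",
         ifelse(c >= 0.8, "high",
                ifelse(c >= 0.7, "moderate",
                       ifelse(c >= t, "low", "below_threshold"))))
}

#' Repeated balancing / training / evaluation experiment
#'
#' Runs `n_repeats` iterations of: balance classes, stratified 70/30
#' train/test split, PWM construction from the training split only (so the
#' test split stays independent of the matrices), PWM scoring of all
#' contexts, feature selection, model fitting, prediction on the test split
#' and a full threshold scan. Reports per-run metrics, their mean and SD,
#' and retains the best run's model (highest accuracy, ties broken by
#' minimal |sensitivity - specificity|), with the selected threshold and the
#' run's PWM model embedded.
#'
#' @param dataset A `tis_dataset` from [build_dataset()].
#' @param config [training_config()].
#' @return Object of class `tis_experiment`: `metrics` (one row per run),
#'   `summary` (mean/sd per metric), `best_model`, `best_run`, `selection`
#'   of the best run.
#' @export
run_experiment <- function(dataset, config = training_config()) {
  runs <- vector("list", config$n_repeats)
  best <- NULL
  for (rep_i in seq_len(config$n_repeats)) {
    seed_r <- config$seed + rep_i
    bal <- balance(dataset$labels, seed = seed_r)
    y <- dataset$labels[bal]
    set.seed(seed_r + 10000L)
    tr1 <- sample(which(y == 1), round(config$train_fraction * sum(y == 1)))
    tr0 <- sample(which(y == 0), round(config$train_fraction * sum(y == 0)))
    is_train <- seq_along(bal) %in% c(tr1, tr0)

    ctx <- dataset$contexts[bal]
    tx_train <- unique(dataset$candidates$transcript_id[bal][is_train])
    bg_cnt <- colSums(dataset$utr_counts[tx_train, , drop = FALSE])
    pwm <- build_pwm_model(ctx[is_train & y == 1], ctx[is_train & y == 0],
                           bg = bg_cnt / sum(bg_cnt))
    X <- dataset$features[bal, , drop = FALSE]
    X[, "pwm_pos_score"] <- pwm_score(ctx, pwm$pwm_pos)
    X[, "pwm_neg_score"] <- pwm_score(ctx, pwm$pwm_neg)
    X[, "pwm_ratio_score"] <- pwm_score(ctx, pwm$pwm_ratio)

    sel <- select_features(X[is_train, , drop = FALSE], y[is_train], config)
    model <- fit(X[is_train, sel$kept, drop = FALSE], y[is_train], config,
                 seed = seed_r + 20000L)
    conf <- predict_confidence(model, X[!is_train, , drop = FALSE])
    scan <- threshold_scan(conf, y[!is_train])
    met <- data.frame(
      run = rep_i, threshold = scan$best_t,
      accuracy = scan$best$accuracy, sensitivity = scan$best$sensitivity,
      specificity = scan$best$specificity, precision = scan$best$precision,
      auc = scan$auc, n_features = length(sel$kept),
      n_train = sum(is_train), n_test = sum(!is_train)
    )
    runs[[rep_i]] <- met
    bal_gap <- abs(met$sensitivity - met$specificity)
    if (is.null(best) || met$accuracy > best$metrics$accuracy ||
        (met$accuracy == best$metrics$accuracy && bal_gap < best$gap)) {
      model$pwm <- pwm
      model$threshold <- scan$best_t
      model$seed <- seed_r
      model$window <- dataset$window
      best <- list(model = model, metrics = met, gap = bal_gap,
                   selection = sel, scan = scan, run = rep_i)
    }
  }
  metrics <- do.call(rbind, runs)
  num <- c("threshold", "accuracy", "sensitivity", "specificity",
           "precision", "auc")
  summary <- data.frame(
    metric = num,
    mean = vapply(num, function(m) mean(metrics[[m]], na.rm = TRUE), 0),
    sd = vapply(num, function(m) stats::sd(metrics[[m]], na.rm = TRUE), 0)
  )
  structure(
    list(metrics = metrics, summary = summary, best_model = best$model,
         best_run = best$run, selection = best$selection,
         best_scan = best$scan, config = config),
    class = "tis_experiment"
  )
}

#' @export
print.tis_experiment <- function(x, ...) {
  cat("<tis_experiment> ", nrow(x$metrics), " runs (best: run ",
      x$best_run, ")\n", sep = "")
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-12s %.3f +/- %.3f\n", s$metric[i], s$mean[i], s$sd[i]))
  }
  invisible(x)
}
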