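#' Expected accuracy of a uniform random predictor
#'
#' For a three-class risk task this is 1/3 (33.33%), the chance level any
#' useful classifier must beat.
#'
#' @param n_classes Integer >= 2.
#' @return `1 / n_classes`.
#' @export
chance_level <- function(n_classes) {
  if (!is.numeric(n_classes) || length(n_classes) != 1L ||
      n_classes != round(n_classes) || n_classes < 2)
    stop("n_classes must be an integer >= 2")
  1 / n_classes
}

#' Default random-forest hyperparameter grid
#'
#' Small desk-scale grid searched within the cross-validation harness:
#' number of trees 100/300, maximum tree depth unlimited/5/10 (0 codes
#' unlimited) and features tried per split `sqrt(p)` or all `p`.
#'
#' @return Data frame with columns `num_trees`, `max_depth`, `mtry_rule`.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(100L, 300L), max_depth = c(0L, 5L, 10L),
              mtry_rule = c("sqrt", "all"), stringsAsFactors = FALSE)
}

impute_medians <- function(x) {
  med <- vapply(x, function(col) {
    m <- stats::median(col, na.rm = TRUE)
    if (is.na(m)) 0 else m
  }, numeric(1L))
  med
}

apply_imputation <- function(x, medians) {
  for (nm in names(x)) {
    i <- is.na(x[[nm]])
    if (any(i)) x[[nm]][i] <- medians[[nm]]
  }
  x
}

fit_engine <- function(x, y, params, seed, engine) {
  if (engine == "naive_bayes") {
    if (!requireNamespace("e1071", quietly = TRUE))
      stop("the naive Bayes baseline needs the e1071 package")
    return(e1071::naiveBayes(x, y))
  }
  mtry <- if (identical(params$mtry_rule, "all")) ncol(x) else
    max(1L, floor(sqrt(ncol(x))))
  ranger::ranger(x = x, y = droplevels(y), num.trees = params$num_trees,
                 mtry = mtry, max.depth = params$max_depth,
                 probability = TRUE, seed = seed, num.threads = 1L,
                 respect.unordered.factors = "order")
}

predict_engine <- function(fit, x, levels) {
  p <- if (inherits(fit, "naiveBayes"))
    stats::predict(fit, x, type = "raw")
  else
    stats::predict(fit, data = x, num.threads = 1L)$predictions
  # classes absent from training get probability zero
  full <- matrix(0, nrow(p), length(levels),
                 dimnames = list(NULL, levels))
  full[, colnames(p)] <- p
  # renormalize against accumulated rounding; rows are already ~1
  full / rowSums(full)
}

# argmax with deterministic tie-break toward the higher risk level
prob_to_label <- function(prob) {
  levels <- colnames(prob)
  idx <- apply(prob, 1L, function(p) max(which(p >= max(p))))
  factor(levels[idx], levels = levels)
}

check_training_data <- function(features, labels, min_n = 20L) {
  x <- features[, feature_names(), drop = FALSE]
  ok <- !is.na(labels)
  x <- x[ok, , drop = FALSE]
  y <- factor(as.character(labels[ok]), levels = risk_levels())
  if (nrow(x) < min_n)
    stop("need at least ", min_n, " labeled samples, got ", nrow(x))
  if (length(unique(y)) < 2L)
    stop("training data holds a single class; need at least two")
  list(x = x, y = y)
}

#' Train the three-class risk classifier
#'
#' Fits a probability random forest (or the naive Bayes baseline) on
#' labeled feature vectors. Missing feature entries are imputed with the
#' training-set medians, which are stored in the bundle and reused at
#' prediction time. Refitting with the same data and seed reproduces the
#' same predictions.
#'
#' @param features Data frame containing the 16 [feature_names()] columns.
#' @param labels Risk labels (factor over [risk_levels()]); `NA`-labeled
#'   rows are dropped.
#' @param params One row of [default_rf_grid()] (default: 300 trees,
#'   unlimited depth, sqrt mtry). Ignored by the naive Bayes engine.
#' @param seed Integer RNG seed.
#' @param engine `"random_forest"` (default) or `"naive_bayes"`.
#' @return A `risk_model` bundle: fitted model, feature order, imputation
#'   medians, hyperparameters, seed, n and a training-data fingerprint.
#' @export
rf_train <- function(features, labels, params = NULL, seed = 1L,
                     engine = c("random_forest", "naive_bayes")) {
  engine <- match.arg(engine)
  if (is.null(params))
    params <- list(num_trees = 300L, max_depth = 0L, mtry_rule = "sqrt")
  dat <- check_training_data(features, labels)
  med <- impute_medians(dat$x)
  x <- apply_imputation(dat$x, med)
  fit <- fit_engine(x, dat$y, params, seed, engine)
  structure(list(
    fit = fit, engine = engine, feature_names = feature_names(),
    medians = med, params = params, seed = as.integer(seed),
    n_train = nrow(x), label_levels = risk_levels(),
    fingerprint = paste(openssl::sha256(serialize(
      list(x, dat$y, params, as.integer(seed)), NULL)), collapse = "")),
    class = "risk_model")
}

#' Predict risk for feature vectors
#'
#' Checks that the 16 feature columns are present in the bundle's declared
#' order, imputes missing entries with the stored training medians, and
#' returns class probabilities plus the argmax label; exact probability
#' ties break toward the higher risk level (safety-first).
#'
#' @param bundle A [rf_train()] bundle.
#' @param features Data frame with the 16 feature columns (extra columns
#'   such as window bounds are carried through).
#' @return Data frame: any `window_start`/`window_end` columns, `label`,
#'   and `p_low`, `p_medium`, `p_high` (each row sums to 1).
#' @export
predict_risk <- function(bundle, features) {
  stopifnot(inherits(bundle, "risk_model"))
  present <- intersect(names(features), bundle$feature_names)
  if (!identical(present, bundle$feature_names))
    stop("feature columns must match the model's declared order: ",
         paste(bundle$feature_names, collapse = ", "))
  x <- apply_imputation(features[, bundle$feature_names, drop = FALSE],
                        bundle$medians)
  prob <- predict_engine(bundle$fit, x, bundle$label_levels)
  out <- features[, intersect(c("window_start", "window_end"),
                              names(features)), drop = FALSE]
  out$label <- prob_to_label(prob)
  out[paste0("p_", bundle$label_levels)] <- prob
  rownames(out) <- NULL
  out
}

#' Save / load a model bundle
#'
#' Thin RDS wrappers; a reloaded bundle yields byte-identical predictions.
#'
#' @param bundle A `risk_model` bundle.
#' @param path File path.
#' @return `path` (save) or the bundle (load).
#' @export
save_risk_model <- function(bundle, path) {
  stopifnot(inherits(bundle, "risk_model"))
  saveRDS(bundle, path)
  invisible(path)
}

#' @rdname save_risk_model
#' @export
load_risk_model <- function(path) {
  bundle <- readRDS(path)
  stopifnot(inherits(bundle, "risk_model"))
  bundle
}

#' 10-fold cross-validation with nested grid search
#'
#' Samples are randomly partitioned into `k` near-equal folds (sizes differ
#' by at most one); each fold is validated exactly once against a model
#' fitted on the remaining folds. When the grid has more than one row, the
#' winning hyperparameters are chosen per outer fold by an inner
#' `inner_k`-fold cross-validation run on the training folds only, so the
#' reported outer accuracy never sees validation labels (no leakage).
#' Everything is reproducible from `seed`.
#'
#' @param features Data frame with the 16 [feature_names()] columns.
#' @param labels Risk labels; `NA`-labeled rows are dropped.
#' @param grid Hyperparameter grid (default [default_rf_grid()]).
#' @param k Outer folds (default 10).
#' @param inner_k Inner folds for grid selection (default 5).
#' @param seed Integer RNG seed.
#' @param engine `"random_forest"` or `"naive_bayes"`.
#' @return A `cv_result`: `fold_accuracy` (k values), `mean_accuracy`,
#'   `sd_accuracy`, `confusion` (summed over folds, rows = truth),
#'   `n_samples`, `class_counts`, `fold_params` and `fold_id`.
#' @export
rf_crossvalidate <- function(features, labels, grid = default_rf_grid(),
                             k = 10L, inner_k = 5L, seed = 1L,
                             engine = c("random_forest", "naive_bayes")) {
  engine <- match.arg(engine)
  dat <- check_training_data(features, labels, min_n = max(20L, k))
  x <- dat$x; y <- dat$y
  n <- nrow(x)
  if (n < k) stop("fewer samples than folds")
  set.seed(as.integer(seed))
  fold <- sample(rep_len(seq_len(k), n))
  model_seeds <- sample.int(.Machine$integer.max %/% 2L, k * (nrow(grid) * inner_k + 1L))
  s_i <- 0L
  next_seed <- function() {
    s_i <<- s_i + 1L
    model_seeds[s_i]
  }
  levels <- risk_levels()
  confusion <- matrix(0L, 3L, 3L, dimnames = list(truth = levels,
                                                  predicted = levels))
  fold_acc <- numeric(k)
  fold_params <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- fold != f
    x_tr <- x[tr, , drop = FALSE]; y_tr <- y[tr]
    best <- 1L
    if (nrow(grid) > 1L) {
      inner_fold <- sample(rep_len(seq_len(inner_k), nrow(x_tr)))
      inner_acc <- numeric(nrow(grid))
      for (g in seq_len(nrow(grid))) {
        hits <- 0L
        for (ifld in seq_len(inner_k)) {
          itr <- inner_fold != ifld
          if (length(unique(y_tr[itr])) < 2L) next
          med_i <- impute_medians(x_tr[itr, , drop = FALSE])
          fit <- fit_engine(apply_imputation(x_tr[itr, , drop = FALSE], med_i),
                            droplevels(y_tr[itr]), grid[g, ], next_seed(),
                            engine)
          p <- predict_engine(fit,
                              apply_imputation(x_tr[!itr, , drop = FALSE], med_i),
                              levels(droplevels(y_tr[itr])))
          hits <- hits + sum(prob_to_label(p) == y_tr[!itr])
        }
        inner_acc[g] <- hits / nrow(x_tr)
      }
      best <- which.max(inner_acc)  # tie -> first grid row
    }
    med <- impute_medians(x_tr)
    fit <- fit_engine(apply_imputation(x_tr, med), y_tr, grid[best, ],
                      next_seed(), engine)
    p <- predict_engine(fit, apply_imputation(x[!tr, , drop = FALSE], med),
                        levels)
    pred <- prob_to_label(p)
    truth <- y[!tr]
    fold_acc[f] <- mean(pred == truth)
    confusion <- confusion + table(factor(truth, levels = levels),
                                   factor(pred, levels = levels))
    fold_params[[f]] <- as.list(grid[best, , drop = FALSE])
  }
  structure(list(
    fold_accuracy = fold_acc, mean_accuracy = mean(fold_acc),
    sd_accuracy = stats::sd(fold_acc), confusion = confusion,
    n_samples = n, class_counts = table(y), fold_id = fold,
    fold_params = fold_params, k = k, seed = as.integer(seed),
    engine = engine), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold cross-validation (%s), n = %d\n", x$k, x$engine,
              x$n_samples))
  cat(sprintf("  accuracy %.2f%% +/- %.2f%% (chance %.2f%%)\n",
              100 * x$mean_accuracy, 100 * x$sd_accuracy,
              100 * chance_level(3)))
  cat("  confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}
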