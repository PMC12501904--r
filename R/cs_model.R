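#' Build the CS-prediction training table
#'
#' Features are the wearable sensor's outputs (`r_wm2`, `g_wm2`,
#' `b_wm2`, `ir_wm2`, `lux_raw`, `cct_raw`); the target is the
#' circadian stimulus computed from each scene's SPD through the
#' spectral model.  Rows are screened with [screen_data()].
#'
#' @param records protocol records (see [lab_protocol()]).
#' @param spec sensor distortion.
#' @param seed noise seed.
#' @param tables,params,channels spectral machinery.
#' @return data.frame with the six feature columns, target `cs`, and
#'   bookkeeping columns `scenario_id`, `rep`, `daylight_fraction`.
#' @export
build_training_table <- function(records, spec = distortion_spec(),
                                 seed = 1,
                                 tables = observer_tables(),
                                 params = circadian_params(),
                                 channels = channel_set()) {
  pt <- paired_table(records, spec, seed, tables, params, channels)
  sc <- screen_data(pt)
  dat <- sc$data
  data.frame(scenario_id = dat$scenario_id, rep = dat$rep,
             r_wm2 = dat$r_wm2, g_wm2 = dat$g_wm2, b_wm2 = dat$b_wm2,
             ir_wm2 = dat$ir_wm2, lux_raw = dat$lux_raw,
             cct_raw = dat$cct_raw, cs = dat$cs_ref,
             daylight_fraction = dat$daylight_fraction)
}

cs_feature_names <- function() {
  c("r_wm2", "g_wm2", "b_wm2", "ir_wm2", "lux_raw", "cct_raw")
}

fit_cs_engine <- function(train, method, features, n_trees, min_leaf,
                          seed) {
  fml <- stats::as.formula(paste("cs ~",
                                 paste(features, collapse = " + ")))
  if (method == "linear") {
    stats::lm(fml, data = train)
  } else {
    with_seed(seed,
              randomForest::randomForest(fml, data = train,
                                         ntree = n_trees,
                                         nodesize = min_leaf,
                                         importance = TRUE))
  }
}

#' Fit a circadian-stimulus prediction model
#'
#' Linear regression or random forest (mean over trees) predicting CS
#' from the six raw sensor features, with a seeded 70/30 train/test
#' split and test-set metrics.  The forest uses 500 trees, unrestricted
#' depth and minimum node size 2 by default.
#'
#' @param table training table from [build_training_table()].
#' @param method `"linear"` or `"random_forest"`.
#' @param seed seed for the split and the forest bootstrap.
#' @param train_frac train fraction (default 0.7).
#' @param features feature columns.
#' @param n_trees,min_leaf forest hyperparameters.
#' @return An object of class `cs_model`.
#' @export
fit_cs_model <- function(table, method = c("linear", "random_forest"),
                         seed = 1, train_frac = 0.7,
                         features = cs_feature_names(),
                         n_trees = 500, min_leaf = 2) {
  method <- match.arg(method)
  stopifnot(all(c(features, "cs") %in% names(table)))
  if (nrow(table) < 20)
    stop("need at least 20 rows to fit a CS model", call. = FALSE)
  if (stats::var(table$cs) == 0)
    stop("degenerate target: cs is constant", call. = FALSE)
  idx <- with_seed(seed, sample(nrow(table)))
  n_train <- max(2L, floor(train_frac * nrow(table)))
  train <- table[sort(idx[seq_len(n_train)]), , drop = FALSE]
  test <- if (n_train < nrow(table))
    table[sort(idx[-seq_len(n_train)]), , drop = FALSE] else NULL
  fit <- fit_cs_engine(train, method, features, n_trees, min_leaf,
                       seed)
  p <- length(features)
  m_train <- compute_metrics(train$cs, stats::predict(fit, train), p)
  m_test <- if (!is.null(test))
    compute_metrics(test$cs, stats::predict(fit, test), p)
  structure(list(method = method, features = features, fit = fit,
                 hyperparams = list(n_trees = n_trees,
                                    min_leaf = min_leaf, seed = seed,
                                    train_frac = train_frac),
                 metrics = list(train = m_train, test = m_test),
                 train = train, test = test),
            class = "cs_model")
}

#' @export
print.cs_model <- function(x, ...) {
  cat(sprintf("CS prediction model (%s), features: %s\n", x$method,
              paste(x$features, collapse = ", ")))
  if (!is.null(x$metrics$test)) {
    cat("  test: ")
    print(x$metrics$test)
  }
  invisible(x)
}

#' @export
summary.cs_model <- function(object, ...) {
  print(object)
  cat("  train: ")
  print(object$metrics$train)
  if (object$method == "random_forest")
    cat(sprintf("  forest: %d trees, min node size %d\n",
                object$hyperparams$n_trees,
                object$hyperparams$min_leaf))
  invisible(object)
}

#' @export
predict.cs_model <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    stop("missing feature columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  unname(stats::predict(object$fit, newdata))
}

#' k-fold cross-validation of a CS prediction model
#'
#' Seeded partition of the rows into `k` non-overlapping folds; each
#' fold is predicted by a model trained on the other k-1 folds, and the
#' reported mean of each metric is the arithmetic mean over folds.
#'
#' @inheritParams fit_cs_model
#' @param k number of folds (default 5).
#' @return A list: `folds` (list of `metric_set`), `mean` (named list
#'   of fold-averaged metrics), `assignments` (fold index per row).
#' @export
cross_validate <- function(table, method = c("linear", "random_forest"),
                           k = 5, seed = 1,
                           features = cs_feature_names(),
                           n_trees = 500, min_leaf = 2) {
  method <- match.arg(method)
  n <- nrow(table)
  if (k < 2 || k > n) stop("need 2 <= k <= rows", call. = FALSE)
  fold <- with_seed(seed, sample(rep(seq_len(k), length.out = n)))
  folds <- lapply(seq_len(k), function(i) {
    train <- table[fold != i, , drop = FALSE]
    test <- table[fold == i, , drop = FALSE]
    fit <- fit_cs_engine(train, method, features, n_trees, min_leaf,
                         seed + i)
    compute_metrics(test$cs, stats::predict(fit, test),
                    length(features))
  })
  metric_names <- c("mae", "mse", "rmse", "r2", "adjusted_r2")
  means <- lapply(metric_names, function(m)
    mean(vapply(folds, `[[`, numeric(1), m)))
  names(means) <- metric_names
  list(folds = folds, mean = means, assignments = fold)
}

#' Dual feature importance of a fitted random forest
#'
#' Permutation importance (%IncMSE): the percent increase in held-out
#' MSE when one feature column is randomly permuted, averaged over
#' `n_repeats` seeded permutations --
#' `100 * (MSE_permuted - MSE_base) / MSE_base`.  Node-purity
#' importance (IncNodePurity): the total decrease in node variance
#' attributed to each feature across all trees, taken from the fitted
#' forest.  Both are reported with ranks (1 = most important).
#'
#' @param model a `cs_model` with `method = "random_forest"`.
#' @param newdata held-out data to permute (defaults to the model's
#'   test split).
#' @param n_repeats permutation repeats (default 10).
#' @param seed permutation seed.
#' @return data.frame: `feature`, `pct_inc_mse`, `inc_node_purity`,
#'   `rank_pct_inc_mse`, `rank_inc_node_purity`.
#' @export
feature_importance <- function(model, newdata = NULL, n_repeats = 10,
                               seed = 1) {
  if (!inherits(model, "cs_model") || model$method != "random_forest")
    stop("feature importance requires a fitted random forest",
         call. = FALSE)
  if (is.null(newdata)) newdata <- model$test
  if (is.null(newdata))
    stop("no held-out data available; supply newdata", call. = FALSE)
  base_pred <- stats::predict(model$fit, newdata)
  base_mse <- mean((newdata$cs - base_pred)^2)
  pct <- with_seed(seed, vapply(model$features, function(f) {
    mses <- vapply(seq_len(n_repeats), function(r) {
      perm <- newdata
      perm[[f]] <- sample(perm[[f]])
      mean((perm$cs - stats::predict(model$fit, perm))^2)
    }, numeric(1))
    100 * (mean(mses) - base_mse) / base_mse
  }, numeric(1)))
  purity_mat <- randomForest::importance(model$fit, type = 2)
  purity <- purity_mat[model$features, 1]
  data.frame(feature = model$features,
             pct_inc_mse = unname(pct),
             inc_node_purity = unname(purity),
             rank_pct_inc_mse = rank(-pct, ties.method = "first"),
             rank_inc_node_purity = rank(-purity,
                                         ties.method = "first"),
             row.names = NULL)
}
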