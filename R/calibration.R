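#' Regression evaluation metrics
#'
#' Mean absolute error, mean squared error, root MSE, coefficient of
#' determination `R2 = 1 - sum((y - yhat)^2) / sum((y - ybar)^2)` and
#' the Wherry adjusted R2
#' `1 - (1 - R2) * (N - 1) / (N - p - 1)`.
#'
#' @param y_true,y_pred equal-length nonempty numeric vectors.
#' @param n_features number of predictors `p` used for the adjusted R2.
#' @return A list of class `metric_set`: `mae`, `mse`, `rmse`, `r2`,
#'   `adjusted_r2`, `n`.
#' @export
compute_metrics <- function(y_true, y_pred, n_features = 1) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  if (anyNA(y_true) || anyNA(y_pred))
    stop("metrics undefined with missing values", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0)
    stop("zero variance in y_true: R2 undefined", call. = FALSE)
  n <- length(y_true)
  mae <- mean(abs(y_true - y_pred))
  mse <- mean((y_true - y_pred)^2)
  r2 <- 1 - sum((y_true - y_pred)^2) / ss_tot
  adj <- 1 - (1 - r2) * (n - 1) / (n - n_features - 1)
  structure(list(mae = mae, mse = mse, rmse = sqrt(mse), r2 = r2,
                 adjusted_r2 = adj, n = n),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("n=%d  MAE=%.4g  RMSE=%.4g  R2=%.4f  adj.R2=%.4f\n",
              x$n, x$mae, x$rmse, x$r2, x$adjusted_r2))
  invisible(x)
}

#' Screen a paired reading table for invalid rows
#'
#' Removes rows carrying negative values in any light-quantity column
#' (negative irradiances or lux are physically invalid sensor output),
#' and optionally rows flagged as clamped at the instrument range.
#'
#' @param table data.frame of paired readings.
#' @param columns light-quantity columns to check; defaults to every
#'   present column among the paired-table schema.
#' @param drop_clamped also remove rows with `clamped == TRUE` when the
#'   column is present (saturated readings carry no calibration
#'   information).
#' @return A list: `data` (cleaned table) and `report` (named integer
#'   vector of removals per column, plus `clamped`).
#' @export
screen_data <- function(table,
                        columns = intersect(
                          c("lux_ref", "cct_ref", "lux_raw", "cct_raw",
                            "r_wm2", "g_wm2", "b_wm2", "ir_wm2"),
                          names(table)),
                        drop_clamped = FALSE) {
  stopifnot(is.data.frame(table), length(columns) > 0)
  neg <- vapply(columns, function(cc) !is.na(table[[cc]]) & table[[cc]] < 0,
                logical(nrow(table)))
  neg <- matrix(neg, nrow = nrow(table))
  report <- colSums(neg)
  names(report) <- columns
  bad <- rowSums(neg) > 0
  n_clamped <- 0L
  if (drop_clamped && "clamped" %in% names(table)) {
    n_clamped <- sum(table$clamped & !bad)
    bad <- bad | table$clamped
  }
  report <- c(report, clamped = n_clamped)
  out <- table[!bad, , drop = FALSE]
  if (nrow(out) == 0)
    stop("no rows left after screening", call. = FALSE)
  list(data = out, report = report)
}

# candidate sensor features in their canonical order; the order is the
# tie-break when collinear features must be dropped
calibration_candidates <- function() {
  c("cct_raw", "ir_wm2", "lux_raw", "r_wm2", "g_wm2", "b_wm2")
}

#' Significance-based feature selection for the no-intercept calibration
#'
#' Fits the full through-the-origin least-squares model on all
#' candidate features and retains those whose coefficient p-value falls
#' below `alpha`.  Perfectly collinear candidates are resolved by
#' keeping the earliest in the canonical order
#' (`cct_raw, ir_wm2, lux_raw, r_wm2, g_wm2, b_wm2`).  If nothing is
#' significant, all candidates are kept with a warning.
#'
#' @param table screened paired table.
#' @param target name of the response column.
#' @param alpha significance level (default 0.05).
#' @param candidates candidate feature columns.
#' @param intercept include an intercept in the screening fit
#'   (default FALSE, matching the calibration form).
#' @return Character vector of selected feature names.
#' @export
select_features <- function(table, target, alpha = 0.05,
                            candidates = calibration_candidates(),
                            intercept = FALSE) {
  stopifnot(target %in% names(table),
            all(candidates %in% names(table)))
  rhs <- paste(candidates, collapse = " + ")
  fml <- stats::as.formula(paste(target, "~",
                                 if (intercept) rhs else paste("0 +", rhs)))
  fit <- stats::lm(fml, data = table)
  co <- stats::coef(fit)
  aliased <- names(co)[is.na(co)]
  kept <- setdiff(candidates, aliased)
  if (length(aliased) > 0) {
    fml <- stats::as.formula(paste(
      target, "~", if (intercept) "" else "0 +",
      paste(kept, collapse = " + ")))
    fit <- stats::lm(fml, data = table)
  }
  sm <- stats::coef(summary(fit))
  pv <- sm[, "Pr(>|t|)"]
  names(pv) <- rownames(sm)
  pv <- pv[names(pv) %in% kept]
  sel <- kept[kept %in% names(pv)[pv < alpha]]
  if (length(sel) == 0) {
    warning("no feature significant at alpha = ", alpha,
            "; keeping all candidates", call. = FALSE)
    sel <- kept
  }
  sel
}

#' Fit a wearable-sensor calibration model
#'
#' Screens the paired table, makes a seeded 70/30 train/test split,
#' selects significant features, and fits a no-intercept least-squares
#' calibration of the chosen target (true photopic lux or true CCT) on
#' the sensor outputs -- the published correction has the form
#' `lux = 0.0596*cct_raw + 1.6064*ir + 0.8432*lux_raw` (and analogously
#' for CCT), i.e. a linear map through the origin.  Train and test
#' metrics are reported, plus a refit-on-all-data variant whose metrics
#' correspond to "overall" figures.
#'
#' @param table paired table (see [paired_table()]); must have >= 10
#'   rows after screening.
#' @param target `"photopic_lux"` (response `lux_ref`) or `"cct"`
#'   (response `cct_ref`).
#' @param train_frac fraction of rows in the training set (default
#'   0.7); `1.0` disables the test split.
#' @param seed split seed.
#' @param alpha feature-selection significance level.
#' @param intercept fit with an intercept instead of through the origin
#'   (off by default, matching the published form).
#' @param drop_clamped drop range-clamped rows during screening
#'   (default TRUE).
#' @param candidates candidate feature columns offered to the
#'   significance screen.  Note that with the full default set the
#'   visible channel irradiances are strong surrogates of illuminance,
#'   so under measurement noise the no-intercept fit can legitimately
#'   spread weight across them; restrict the candidates when the goal
#'   is recovery of a known generating coefficient vector.
#' @return An object of class `light_calibration`.
#' @export
fit_calibration <- function(table, target = c("photopic_lux", "cct"),
                            train_frac = 0.7, seed = 1, alpha = 0.05,
                            intercept = FALSE, drop_clamped = TRUE,
                            candidates = calibration_candidates()) {
  target <- match.arg(target)
  response <- if (target == "photopic_lux") "lux_ref" else "cct_ref"
  sc <- screen_data(table, drop_clamped = drop_clamped)
  dat <- sc$data
  if (nrow(dat) < 10)
    stop("need at least 10 rows after screening", call. = FALSE)
  stopifnot(train_frac > 0, train_frac <= 1)
  idx <- with_seed(seed, sample(nrow(dat)))
  n_train <- max(2L, floor(train_frac * nrow(dat)))
  train <- dat[sort(idx[seq_len(n_train)]), , drop = FALSE]
  test <- if (n_train < nrow(dat))
    dat[sort(idx[-seq_len(n_train)]), , drop = FALSE] else NULL
  feats <- select_features(train, response, alpha,
                           candidates = candidates,
                           intercept = intercept)
  fml <- stats::as.formula(paste(
    response, "~", if (intercept) "" else "0 +",
    paste(feats, collapse = " + ")))
  fit <- stats::lm(fml, data = train)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design: collinear features ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "), call. = FALSE)
  p <- length(feats)
  m_train <- compute_metrics(train[[response]],
                             stats::predict(fit, train), p)
  m_test <- if (!is.null(test))
    compute_metrics(test[[response]], stats::predict(fit, test), p)
  fit_all <- stats::lm(fml, data = dat)
  m_all <- compute_metrics(dat[[response]],
                           stats::predict(fit_all, dat), p)
  structure(list(target = target, response = response,
                 features = feats,
                 coefficients = stats::coef(fit),
                 coefficients_all = stats::coef(fit_all),
                 intercept = intercept,
                 metrics = list(train = m_train, test = m_test,
                                overall = m_all),
                 screening = sc$report, seed = seed,
                 n_train = nrow(train),
                 n_test = if (is.null(test)) 0L else nrow(test)),
            class = "light_calibration")
}

#' @export
print.light_calibration <- function(x, ...) {
  cat(sprintf("Wearable-sensor calibration: %s (no intercept: %s)\n",
              x$target, !x$intercept))
  cat("  ", paste(sprintf("%s=%.4g", names(x$coefficients),
                          x$coefficients), collapse = "  "), "\n")
  cat(sprintf("  train (n=%d): ", x$n_train))
  print(x$metrics$train)
  if (!is.null(x$metrics$test)) {
    cat(sprintf("  test  (n=%d): ", x$n_test))
    print(x$metrics$test)
  }
  invisible(x)
}

#' @export
summary.light_calibration <- function(object, ...) {
  cat("Calibration target:", object$target, "\n")
  cat("Selected features:", paste(object$features, collapse = ", "),
      "\n")
  cat("Screening removals:\n")
  print(object$screening)
  cat("Train/test coefficients:\n")
  print(object$coefficients)
  cat("Refit-on-all-data coefficients:\n")
  print(object$coefficients_all)
  cat("Overall metrics: ")
  print(object$metrics$overall)
  invisible(object)
}

#' @export
coef.light_calibration <- function(object, all_data = FALSE, ...) {
  if (all_data) object$coefficients_all else object$coefficients
}

#' Apply a calibration to sensor readings
#'
#' Dot product of the fitted coefficients with the reading's feature
#' columns; vectorized over a whole log.
#'
#' @param object a `light_calibration`.
#' @param newdata data.frame containing the model's feature columns.
#' @param ... unused.
#' @return Numeric vector of calibrated values.
#' @export
predict.light_calibration <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0)
    stop("reading lacks feature columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  X <- as.matrix(newdata[object$features])
  co <- object$coefficients
  out <- drop(X %*% co[object$features])
  if (object$intercept) out <- out + co[["(Intercept)"]]
  unname(out)
}

#' Serialize a fitted calibration to JSON
#'
#' @param object a `light_calibration`.
#' @param path file to write.
#' @return `path`, invisibly.
#' @export
write_calibration_json <- function(object, path) {
  stopifnot(inherits(object, "light_calibration"))
  payload <- list(
    target = object$target, features = object$features,
    coefficients = as.list(object$coefficients),
    intercept = object$intercept, seed = object$seed,
    n_train = object$n_train, n_test = object$n_test,
    metrics = lapply(Filter(Negate(is.null), object$metrics),
                     function(m) unclass(m)))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Refit the published calibration and prediction models on a deposited
#' dataset
#'
#' Reads a paired-readings CSV in the package schema (`lux_ref`,
#' `cct_ref`, `lux_raw`, `cct_raw`, `r_wm2`, `g_wm2`, `b_wm2`,
#' `ir_wm2`, optionally `cs_ref`) -- for example an export of the
#' original laboratory dataset -- and recomputes the overall
#' calibration metrics (adjusted R2, MAE for lux and CCT) and, when
#' `cs_ref` is present, the linear and random-forest CS prediction
#' metrics.
#'
#' @param path CSV file path.
#' @param seed seed for splits/forest.
#' @return A list with elements `lux`, `cct` (each a `metric_set` from
#'   the full-data refit) and optionally `cs_linear`, `cs_forest`.
#' @export
refit_reference <- function(path, seed = 1) {
  if (!file.exists(path))
    stop("reference dataset not available at '", path,
         "': supply the deposited paired-readings CSV to reproduce ",
         "the published calibration metrics", call. = FALSE)
  tab <- utils::read.csv(path)
  lux_m <- fit_calibration(tab, "photopic_lux", seed = seed)
  cct_m <- fit_calibration(tab, "cct", seed = seed)
  out <- list(lux = lux_m$metrics$overall,
              lux_coefficients = lux_m$coefficients_all,
              cct = cct_m$metrics$overall,
              cct_coefficients = cct_m$coefficients_all)
  if ("cs_ref" %in% names(tab)) {
    pt <- tab
    pt$cs <- pt$cs_ref
    lin <- cross_validate(pt, method = "linear", seed = seed)
    rf <- cross_validate(pt, method = "random_forest", seed = seed)
    out$cs_linear <- lin$mean
    out$cs_forest <- rf$mean
  }
  out
}
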