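#' Per-subject feature table
#'
#' One row per subject with AGE (years), ERD (normalized-power units,
#' typically <= 0), HBO (concentration units) and BBS (Berg Balance Scale,
#' 0-56 points). Columns are matched by name, case-insensitively and in any
#' order; a `subject_id` column is added when absent.
#'
#' @param x A data frame with columns AGE, ERD, HBO, BBS (any case/order)
#'   and optionally subject_id.
#' @param enforce_bbs Require BBS within the clinical 0-56 range (default
#'   TRUE; the cohort simulator disables this so noiseless recovery stays
#'   exact).
#' @return `x` with canonical column names and class `feature_table`.
#' @export
feature_table <- function(x, enforce_bbs = TRUE) {
  x <- as.data.frame(x)
  names(x) <- toupper(names(x))
  need <- c("AGE", "ERD", "HBO", "BBS")
  if (!all(need %in% names(x)))
    stop(sprintf("feature table must have columns %s (missing: %s)",
                 paste(need, collapse = ", "),
                 paste(setdiff(need, names(x)), collapse = ", ")), call. = FALSE)
  id <- if ("SUBJECT_ID" %in% names(x)) as.character(x$SUBJECT_ID)
        else sprintf("S%d", seq_len(nrow(x)))
  out <- data.frame(subject_id = id, x[need])
  if (any(!vapply(out[need], is.numeric, TRUE)))
    stop("AGE, ERD, HBO, BBS must all be numeric", call. = FALSE)
  if (anyNA(out[need]))
    stop("feature table must not contain missing values", call. = FALSE)
  if (enforce_bbs && any(out$BBS < 0 | out$BBS > 56))
    stop("BBS values must lie within [0, 56]", call. = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}

#' The packaged eight-patient stroke cohort
#'
#' Age, ERD index at Cz, peak HBO and Berg Balance Scale score for the
#' eight-patient example cohort shipped with the package, the worked
#' example all regression documentation refers to.
#'
#' @return A [feature_table()] with 8 rows.
#' @examples
#' summarize_features(stroke_features())
#' @export
stroke_features <- function() {
  read_features(system.file("extdata", "stroke_cohort.csv",
                            package = "neurobalance", mustWork = TRUE))
}

#' Design matrix of the balance regression
#'
#' Fixed column order `(Constant, ERD, HBO, AGE, HBO2)`; `HBO2` is the
#' arithmetic square of HBO. No standardization is applied, so fitted
#' coefficients stay on the clinical scale.
#'
#' @param table A [feature_table()].
#' @return Numeric matrix with columns Constant, ERD, HBO, AGE, HBO2.
#' @export
build_design <- function(table) {
  table <- feature_table(table, enforce_bbs = FALSE)
  X <- cbind(Constant = 1, ERD = table$ERD, HBO = table$HBO,
             AGE = table$AGE, HBO2 = table$HBO^2)
  if (nrow(X) < ncol(X))
    stop(sprintf("need at least %d subjects to fit %d coefficients (got %d)",
                 ncol(X), ncol(X), nrow(X)), call. = FALSE)
  X
}

#' Fit the multiple linear regression of BBS on ERD, HBO, AGE and HBO^2
#'
#' Ordinary least squares of `BBS ~ ERD + HBO + AGE + HBO^2`. 95% confidence
#' intervals and two-sided p-values come from the t distribution with
#' `n - k - 1` degrees of freedom; the adjusted R^2 is
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)`.
#'
#' @param table A [feature_table()].
#' @return A `bbs_fit`: `beta` (named, order Constant, ERD, HBO, AGE, HBO2),
#'   `se`, `ci95` (2-column matrix), `p`, `r2`, `r2_adj`, `residuals`,
#'   `fitted`, `n`, `k`, and the underlying `lm` object.
#' @examples
#' fit <- fit_bbs_model(stroke_features())
#' round(fit$beta, 1)
#' @export
fit_bbs_model <- function(table) {
  table <- feature_table(table, enforce_bbs = FALSE)
  X <- build_design(table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop(sprintf("design is rank-deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  df <- data.frame(BBS = table$BBS, ERD = table$ERD, HBO = table$HBO,
                   AGE = table$AGE, HBO2 = table$HBO^2)
  fit <- stats::lm(BBS ~ ERD + HBO + AGE + HBO2, data = df)
  sm <- summary(fit)
  beta <- stats::coef(fit)
  names(beta) <- colnames(X)
  ci <- stats::confint(fit)
  rownames(ci) <- colnames(X)
  p <- sm$coefficients[, "Pr(>|t|)"]
  names(p) <- colnames(X)
  structure(list(beta = beta, se = sm$coefficients[, "Std. Error"],
                 ci95 = ci, p = p,
                 r2 = sm$r.squared, r2_adj = sm$adj.r.squared,
                 residuals = stats::residuals(fit),
                 fitted = stats::fitted(fit),
                 n = nrow(df), k = ncol(X) - 1L, lm = fit,
                 subject_id = table$subject_id),
            class = "bbs_fit")
}

#' @export
print.bbs_fit <- function(x, digits = 3, ...) {
  cat(sprintf("<bbs_fit> n = %d, predictors = %d\n", x$n, x$k))
  tab <- data.frame(beta = round(x$beta, digits),
                    ci_low = round(x$ci95[, 1], digits),
                    ci_high = round(x$ci95[, 2], digits),
                    p = signif(x$p, digits))
  print(tab)
  cat(sprintf("R^2 = %.3f, adjusted R^2 = %.3f\n", x$r2, x$r2_adj))
  invisible(x)
}

#' @export
predict.bbs_fit <- function(object, newdata, ...) {
  newdata <- feature_table(newdata, enforce_bbs = FALSE)
  df <- data.frame(ERD = newdata$ERD, HBO = newdata$HBO, AGE = newdata$AGE,
                   HBO2 = newdata$HBO^2)
  unname(stats::predict(object$lm, newdata = df))
}

#' Leave-one-out cross-validation of the balance regression
#'
#' For each subject the model is refitted on the other `n - 1` subjects and
#' the held-out BBS is predicted; the RMSE is computed over all `n` held-out
#' predictions. With n subjects this is exactly n-fold cross-validation
#' with singleton test sets. Fully deterministic and invariant to row
#' order.
#'
#' @param table A [feature_table()].
#' @param predictors Character vector of predictor columns among
#'   `c("ERD", "HBO", "AGE", "HBO2")`; `character(0)` gives the
#'   intercept-only model. Default: all four.
#' @return A `bbs_cv`: `fold_predictions` (named by subject), `actual`,
#'   `rmse`, `scheme = "leave-one-out"`.
#' @examples
#' cv <- loo_cv(stroke_features())
#' round(cv$rmse, 2)
#' @export
loo_cv <- function(table, predictors = c("ERD", "HBO", "AGE", "HBO2")) {
  table <- feature_table(table, enforce_bbs = FALSE)
  stopifnot(all(predictors %in% c("ERD", "HBO", "AGE", "HBO2")))
  k <- length(predictors) + 1L
  n <- nrow(table)
  if (n < k + 1L)
    stop(sprintf("leave-one-out needs n - 1 >= %d training rows (n = %d)", k, n),
         call. = FALSE)
  df <- data.frame(BBS = table$BBS, ERD = table$ERD, HBO = table$HBO,
                   AGE = table$AGE, HBO2 = table$HBO^2)
  form <- if (length(predictors))
    stats::as.formula(paste("BBS ~", paste(predictors, collapse = " + ")))
  else stats::as.formula("BBS ~ 1")
  preds <- numeric(n)
  for (i in seq_len(n)) {
    train <- df[-i, , drop = FALSE]
    Xt <- stats::model.matrix(form, data = train)
    if (qr(Xt)$rank < ncol(Xt))
      stop(sprintf("fold %d (holding out %s) is rank-deficient",
                   i, table$subject_id[i]), call. = FALSE)
    fit <- stats::lm(form, data = train)
    preds[i] <- stats::predict(fit, newdata = df[i, , drop = FALSE])
  }
  names(preds) <- table$subject_id
  structure(list(fold_predictions = preds, actual = stats::setNames(df$BBS, table$subject_id),
                 rmse = sqrt(mean((preds - df$BBS)^2)),
                 scheme = "leave-one-out"),
            class = "bbs_cv")
}

#' @importFrom stats as.formula model.matrix residuals fitted setNames
NULL

#' @export
print.bbs_cv <- function(x, ...) {
  cat(sprintf("<bbs_cv> %s over %d subjects: RMSE = %.3f BBS points\n",
              x$scheme, length(x$fold_predictions), x$rmse))
  invisible(x)
}

#' Column means and sample standard deviations of a feature table
#'
#' @param table A [feature_table()].
#' @return Data frame with one row per feature column (AGE, ERD, HBO, BBS)
#'   and columns `mean` and `sd` (sample sd, `n - 1` denominator; `NA` for a
#'   single row, where the sd is undefined).
#' @export
summarize_features <- function(table) {
  table <- feature_table(table, enforce_bbs = FALSE)
  cols <- c("AGE", "ERD", "HBO", "BBS")
  data.frame(row.names = cols,
             mean = vapply(table[cols], mean, 0),
             sd = vapply(table[cols], function(v)
               if (length(v) < 2L) NA_real_ else stats::sd(v), 0))
}
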