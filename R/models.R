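LR_TERMS <- c("speed", "accel_estimate", "step_frequency", "body_mass")

new_lr_model <- function(target_name, coefficients, provenance,
                         fit = NULL) {
  structure(list(target_name = target_name, coefficients = coefficients,
                 provenance = provenance, fit = fit),
            class = "lr_model")
}

#' @export
print.lr_model <- function(x, ...) {
  cat(sprintf("<lr_model> target: %s (%s)\n", x$target_name, x$provenance))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Fit the linear regression model
#'
#' Ordinary least squares of the treadmill-measured target on the four
#' predictors (acceleration-based estimate, running speed, step
#' frequency, body mass) plus an intercept, with the usual
#' normal-theory standard errors, t statistics and p values.
#'
#' @param rows data.frame of feature rows with columns
#'   `accel_estimate`, `speed`, `step_frequency`, `body_mass`,
#'   `target` (and optionally `subject_id`); at least 6 rows.
#' @param target_name label for the modelled quantity.
#' @return an `"lr_model"`: coefficient table (`term`, `B`, `SE`, `t`,
#'   `p`) plus the underlying [stats::lm] fit.
#' @export
fit_lr <- function(rows, target_name = "target") {
  need <- c(LR_TERMS, "target")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (nrow(rows) < 6L) stop("need at least 6 rows to fit 5 terms")
  if (any(!is.finite(as.matrix(rows[need]))))
    stop("predictors and target must be finite")
  fit <- stats::lm(target ~ speed + accel_estimate + step_frequency +
                     body_mass, data = rows)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; offending term(s): ",
         paste(bad, collapse = ", "))
  }
  cf <- summary(fit)$coefficients
  tab <- data.frame(term = c("intercept", LR_TERMS),
                    B = unname(cf[, 1L]), SE = unname(cf[, 2L]),
                    t = unname(cf[, 3L]), p = unname(cf[, 4L]))
  new_lr_model(target_name, tab, "fitted", fit)
}

#' Predict from a linear regression model
#'
#' Linear combination of coefficients and predictors; terms absent from
#' a reduced model (such as the bundled published equations) contribute
#' zero.
#'
#' @param model an `"lr_model"`.
#' @param rows data.frame with the predictor columns the model uses.
#' @return numeric vector of predictions.
#' @examples
#' pm <- published_models()
#' predict_lr(pm$vertical_impulse,
#'            data.frame(step_frequency = 3.0))  # 0.69 - 0.10 * 3
#' @export
predict_lr <- function(model, rows) {
  stopifnot(inherits(model, "lr_model"))
  tab <- model$coefficients
  pred <- rep(tab$B[tab$term == "intercept"], nrow(rows))
  for (term in setdiff(tab$term, "intercept")) {
    if (!term %in% names(rows))
      stop("missing predictor value: ", term)
    v <- rows[[term]]
    if (anyNA(v)) stop("missing predictor value: ", term)
    pred <- pred + tab$B[tab$term == term] * v
  }
  pred
}

#' Published linear regression equations
#'
#' The three reduced regression equations reported for predicting peak
#' vGRF, vertical impulse and contact time from sacral-accelerometer
#' features, bundled verbatim with their published coefficient
#' statistics and flagged `provenance = "published"`. Note the published
#' impulse equation (0.69 - 0.10 x step frequency) evaluated at
#' physically typical step frequencies near 3 Hz yields ~0.39 BW.s,
#' above typical observed impulses (~0.33 BW.s); the equations are
#' provided as printed, without reconciliation.
#'
#' @return named list of three `"lr_model"` objects:
#'   `peak_vgrf`, `vertical_impulse`, `contact_time`.
#' @export
published_models <- function() {
  list(
    peak_vgrf = new_lr_model("peak_vgrf", data.frame(
      term = c("intercept", "speed", "accel_estimate", "step_frequency"),
      B  = c(2.23, 0.15, 0.33, -0.34),
      SE = c(0.46, 0.03, 0.05, 0.12),
      t  = c(4.87, 4.42, 6.54, -2.84),
      p  = c(0.000, 0.000, 0.000, 0.006)), "published"),
    vertical_impulse = new_lr_model("vertical_impulse", data.frame(
      term = c("intercept", "step_frequency"),
      B  = c(0.69, -0.10),
      SE = c(0.02, 0.004),
      t  = c(31.13, -25.95),
      p  = c(0.000, 0.000)), "published"),
    contact_time = new_lr_model("contact_time", data.frame(
      term = c("intercept", "speed", "accel_estimate", "body_mass"),
      B  = c(0.230, -0.019, 0.151, 0.0007),
      SE = c(0.033, 0.002, 0.063, 0.0002),
      t  = c(6.88, -8.62, 2.42, 4.05),
      p  = c(0.000, 0.000, 0.019, 0.000)), "published")
  )
}

#' Fit the quantile regression forest model
#'
#' A 500-tree regression forest whose `mtry` (number of candidate
#' predictors per split) is selected by k-fold cross-validation with
#' folds grouped by subject — a runner's conditions never straddle a
#' fold boundary — minimizing pooled out-of-fold RMSE; ties go to the
#' smallest `mtry`. The final forest is refit on all rows with the
#' selected `mtry`, keeping per-tree predictions available.
#'
#' @param rows feature rows as in [fit_lr()]; must include
#'   `subject_id`.
#' @param n_trees trees in the ensemble.
#' @param mtry_grid candidate `mtry` values (1 to 4 predictors).
#' @param folds number of CV folds; needs at least this many distinct
#'   subjects.
#' @param seed integer seed for fold assignment and tree growing.
#' @param target_name label for the modelled quantity.
#' @return a `"qrf_model"`: the [ranger::ranger] forest, the selected
#'   `mtry`, the CV table (`mtry`, `cv_rmse`) and the training
#'   metadata.
#' @export
fit_qrf <- function(rows, n_trees = 500, mtry_grid = 1:4, folds = 5,
                    seed = 1, target_name = "target") {
  need <- c(LR_TERMS, "target", "subject_id")
  miss <- setdiff(need, names(rows))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  subs <- unique(rows$subject_id)
  if (length(subs) < folds)
    stop("need at least ", folds, " distinct subjects for ", folds,
         "-fold grouped CV (got ", length(subs), ")")
  stopifnot(all(mtry_grid >= 1), all(mtry_grid <= length(LR_TERMS)))
  set.seed(seed)
  fold_of <- sample(rep_len(seq_len(folds), length(subs)))
  names(fold_of) <- subs
  fml <- stats::as.formula(paste("target ~", paste(LR_TERMS, collapse = "+")))
  cv_rmse <- numeric(length(mtry_grid))
  for (gi in seq_along(mtry_grid)) {
    mtry <- mtry_grid[gi]
    sq_err <- numeric(0)
    for (f in seq_len(folds)) {
      hold <- rows$subject_id %in% subs[fold_of == f]
      if (!any(hold)) next
      rf <- ranger::ranger(fml, data = rows[!hold, ], num.trees = n_trees,
                           mtry = mtry, min.node.size = 5,
                           seed = seed + 1000L * gi + f)
      pr <- stats::predict(rf, rows[hold, ])$predictions
      sq_err <- c(sq_err, (pr - rows$target[hold])^2)
    }
    cv_rmse[gi] <- sqrt(mean(sq_err))
  }
  best <- mtry_grid[which.min(cv_rmse)]  # which.min takes first = smallest
  forest <- ranger::ranger(fml, data = rows, num.trees = n_trees,
                           mtry = best, min.node.size = 5, seed = seed)
  structure(list(forest = forest, mtry = best, n_trees = n_trees,
                 cv = data.frame(mtry = mtry_grid, cv_rmse = cv_rmse),
                 folds = folds, seed = seed, target_name = target_name),
            class = "qrf_model")
}

#' @export
print.qrf_model <- function(x, ...) {
  cat(sprintf("<qrf_model> target: %s, %d trees, mtry = %d (CV-selected)\n",
              x$target_name, x$n_trees, x$mtry))
  invisible(x)
}

#' Predict from the quantile regression forest
#'
#' Returns both the ensemble point prediction (the mean over trees) and
#' the full per-tree prediction vector, from which prediction
#' distributions (ridge plots, quantiles) can be derived.
#'
#' @param model a `"qrf_model"` from [fit_qrf()].
#' @param rows data.frame with the predictor columns.
#' @return list: `point` (numeric, one per row) and `tree_predictions`
#'   (matrix, rows x trees).
#' @export
predict_qrf <- function(model, rows) {
  stopifnot(inherits(model, "qrf_model"))
  pa <- stats::predict(model$forest, rows, predict.all = TRUE)$predictions
  if (is.null(dim(pa))) pa <- matrix(pa, nrow = 1L)
  list(point = rowMeans(pa), tree_predictions = pa)
}
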