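KINETIC_TARGETS <- c("peak_vgrf", "vertical_impulse", "contact_time")

#' Subject-level train/test split stratified by sex
#'
#' Randomly assigns whole subjects (never individual conditions) to a
#' held-out test set of about `test_fraction` of the cohort. Per-sex
#' test counts take the floor of the proportional share for the larger
#' strata and give the remainder to the smallest stratum, which keeps
#' each sex's representation within one subject of proportional while
#' protecting the minority sex from rounding away.
#'
#' @param subjects data.frame with `subject_id` and `sex` (one row per
#'   subject), at least 2 subjects per sex.
#' @param test_fraction held-out fraction of subjects.
#' @param seed integer seed.
#' @return list of class `"split_plan"`: `train_subjects`,
#'   `test_subjects` (character vectors), `seed`.
#' @export
split_by_subject <- function(subjects, test_fraction = 0.24, seed = 1) {
  stopifnot(all(c("subject_id", "sex") %in% names(subjects)))
  subjects <- unique(subjects[c("subject_id", "sex")])
  if (anyDuplicated(subjects$subject_id))
    stop("inconsistent sex labels for a subject")
  tab <- table(subjects$sex)
  if (any(tab < 2L)) stop("need at least 2 subjects per sex")
  n <- nrow(subjects)
  k_total <- round(test_fraction * n)
  if (k_total < 1L) stop("test_fraction yields an empty test set")
  if (k_total >= n) stop("test_fraction leaves an empty training set")
  strata <- names(sort(tab, decreasing = TRUE))  # smallest last
  k <- integer(length(strata)); names(k) <- strata
  for (s in strata[-length(strata)])
    k[s] <- floor(test_fraction * tab[[s]])
  k[strata[length(strata)]] <- k_total - sum(k)
  if (any(k < 0L) || any(k >= tab[strata]))
    stop("test_fraction incompatible with the per-sex subject counts")
  set.seed(seed)
  test <- character(0)
  for (s in strata) {
    ids <- subjects$subject_id[subjects$sex == s]
    if (k[[s]] > 0L) test <- c(test, sample(ids, k[[s]]))
  }
  structure(list(train_subjects = sort(setdiff(subjects$subject_id, test)),
                 test_subjects = sort(test), seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test subjects (seed %d)\n",
              length(x$train_subjects), length(x$test_subjects), x$seed))
  invisible(x)
}

#' Prediction accuracy metrics
#'
#' RMSE, mean absolute percentage error with its sample SD, and the
#' Pearson correlation between predictions and observations:
#' `RMSE = sqrt(mean((p - o)^2))`, `APE_i = 100 |p_i - o_i| / o_i`,
#' `MAPE = mean(APE)`, `mape_sd = sd(APE)` (n-1 denominator). When
#' either vector is constant, `pearson_r` is `NA` (undefined), the
#' other metrics are still computed.
#'
#' @param predicted,observed equal-length numeric vectors (length >=
#'   2); all observed values must be nonzero (APE is undefined at 0).
#' @param target_name,model_name labels carried into the report.
#' @return list of class `"metric_report"`: `target_name`,
#'   `model_name`, `rmse`, `mape_mean`, `mape_sd`, `pearson_r`,
#'   `n_predictions`, and the per-prediction `ape` vector (%).
#' @examples
#' m <- metrics(c(2, 4), c(2, 5))
#' m$mape_mean  # 10
#' @export
metrics <- function(predicted, observed, target_name = "target",
                    model_name = "model") {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (length(observed) < 2L) stop("need at least 2 predictions")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("values must be finite")
  if (any(observed == 0)) stop("APE undefined: observed value of 0")
  ape <- 100 * abs(predicted - observed) / abs(observed)
  r <- if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    NA_real_ else stats::cor(predicted, observed)
  structure(list(target_name = target_name, model_name = model_name,
                 rmse = sqrt(mean((predicted - observed)^2)),
                 mape_mean = mean(ape), mape_sd = stats::sd(ape),
                 pearson_r = r, n_predictions = length(observed),
                 ape = ape),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> %s / %s: RMSE %.4g, MAPE %.2f +/- %.2f%%, r %s (n = %d)\n",
              x$target_name, x$model_name, x$rmse, x$mape_mean, x$mape_sd,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              x$n_predictions))
  invisible(x)
}

#' Paired comparison of per-prediction absolute percentage errors
#'
#' Two-tailed paired t test on the per-prediction APE differences
#' between two models evaluated on the same test predictions
#' (df = n - 1). Zero-variance differences are handled explicitly:
#' identical errors give t = 0, p = 1; a constant nonzero difference is
#' the infinite-t limit, p = 0.
#'
#' @param ape_model_a,ape_model_b equal-length paired APE vectors (%),
#'   n >= 3.
#' @return list: `t`, `p`, `df`, `mean_diff` (a minus b).
#' @export
compare_mape_paired <- function(ape_model_a, ape_model_b) {
  if (length(ape_model_a) != length(ape_model_b))
    stop("paired vectors must have equal length")
  n <- length(ape_model_a)
  if (n < 3L) stop("need at least 3 pairs")
  d <- ape_model_a - ape_model_b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) return(list(t = 0, p = 1, df = n - 1L, mean_diff = 0))
    return(list(t = sign(mean(d)) * Inf, p = 0, df = n - 1L,
                mean_diff = mean(d)))
  }
  tt <- stats::t.test(ape_model_a, ape_model_b, paired = TRUE,
                      alternative = "two.sided")
  list(t = unname(tt$statistic), p = tt$p.value,
       df = as.integer(round(unname(tt$parameter))), mean_diff = mean(d))
}

#' Build model feature rows from condition summaries
#'
#' Joins each condition's acceleration-source summary (the wearable
#' pathway: acceleration-based estimate of the target plus
#' acceleration-derived step frequency) with its treadmill-source value
#' of the target.
#'
#' @param summaries data.frame from [process_cohort()] (columns of
#'   [summarize_condition()] plus `body_mass`).
#' @param target one of `"peak_vgrf"`, `"vertical_impulse"`,
#'   `"contact_time"`.
#' @return data.frame with `subject_id`, `sex`, `speed`,
#'   `accel_estimate`, `step_frequency`, `body_mass`, `target`.
#' @export
build_feature_rows <- function(summaries, target = KINETIC_TARGETS) {
  target <- match.arg(target)
  acc <- summaries[summaries$source == "acceleration", ]
  trd <- summaries[summaries$source == "treadmill", ]
  key_a <- paste(acc$subject_id, acc$speed)
  key_t <- paste(trd$subject_id, trd$speed)
  j <- match(key_a, key_t)
  if (anyNA(j)) stop("unmatched acceleration/treadmill condition pair")
  data.frame(subject_id = acc$subject_id, sex = acc$sex, speed = acc$speed,
             accel_estimate = acc[[target]],
             step_frequency = acc$step_frequency,
             body_mass = acc$body_mass,
             target = trd[[target]][j])
}

# Table-style per sex x speed summary (mean +/- SD) of observed and
# predicted values for one target.
condition_table <- function(pred_df) {
  agg <- function(v) {
    a <- stats::aggregate(v, by = list(sex = pred_df$sex,
                                       speed = pred_df$speed),
                          FUN = function(z) c(mean = mean(z),
                                              sd = stats::sd(z)))
    cbind(a[1:2], a$x)
  }
  obs <- agg(pred_df$observed)
  qrf <- agg(pred_df$qrf)
  lr <- agg(pred_df$lr)
  data.frame(target = pred_df$target_name[1L],
             sex = obs$sex, speed = obs$speed,
             observed_mean = obs$mean, observed_sd = obs$sd,
             qrf_mean = qrf$mean, qrf_sd = qrf$sd,
             lr_mean = lr$mean, lr_sd = lr$sd)
}

#' Run the full held-out evaluation experiment
#'
#' For each of the three targets (peak vGRF, vertical impulse, contact
#' time): build feature rows from the processed condition summaries,
#' split subjects ~76/24 stratified by sex, fit the linear regression
#' and the 500-tree quantile regression forest on the training
#' subjects, predict the held-out subjects, and report RMSE / MAPE /
#' Pearson r per model together with the paired APE comparison.
#'
#' @param summaries condition summaries from [process_cohort()].
#' @param seed integer seed (split, forest growing).
#' @param config a [default_config()].
#' @return list of class `"experiment_report"`:
#'   `metrics` (6-row data.frame: target x model),
#'   `paired` (3-row data.frame: t, p, df per target),
#'   `predictions` (long data.frame with observed and both model
#'   predictions per test condition),
#'   `condition_summary` (per sex x speed mean +/- SD table),
#'   `split` (the [split_by_subject()] plan), `models` (fitted model
#'   objects), `config`.
#' @export
run_experiment <- function(summaries, seed = 1, config = default_config()) {
  subjects <- unique(summaries[c("subject_id", "sex")])
  split <- split_by_subject(subjects, config$test_fraction, seed)
  met <- list(); paired <- list(); preds <- list(); models <- list()
  cond_tabs <- list()
  for (tg in KINETIC_TARGETS) {
    rows <- build_feature_rows(summaries, tg)
    train <- rows[rows$subject_id %in% split$train_subjects, ]
    test <- rows[rows$subject_id %in% split$test_subjects, ]
    lr <- fit_lr(train, target_name = tg)
    qrf <- fit_qrf(train, n_trees = config$n_trees,
                   mtry_grid = config$mtry_grid, folds = config$cv_folds,
                   seed = seed, target_name = tg)
    p_lr <- predict_lr(lr, test)
    p_qrf <- predict_qrf(qrf, test)$point
    m_lr <- metrics(p_lr, test$target, tg, "LR")
    m_qrf <- metrics(p_qrf, test$target, tg, "QRF")
    met[[paste(tg, "QRF")]] <- m_qrf
    met[[paste(tg, "LR")]] <- m_lr
    cmp <- compare_mape_paired(m_qrf$ape, m_lr$ape)
    paired[[tg]] <- data.frame(target = tg, t = cmp$t, p = cmp$p,
                               df = cmp$df,
                               mean_ape_diff_qrf_minus_lr = cmp$mean_diff)
    pd <- data.frame(target_name = tg, subject_id = test$subject_id,
                     sex = test$sex, speed = test$speed,
                     observed = test$target, qrf = p_qrf, lr = p_lr)
    preds[[tg]] <- pd
    cond_tabs[[tg]] <- condition_table(pd)
    models[[tg]] <- list(lr = lr, qrf = qrf)
  }
  metrics_df <- do.call(rbind, lapply(met, function(m)
    data.frame(target = m$target_name, model = m$model_name, rmse = m$rmse,
               mape_mean = m$mape_mean, mape_sd = m$mape_sd,
               pearson_r = m$pearson_r, n_predictions = m$n_predictions)))
  rownames(metrics_df) <- NULL
  structure(list(metrics = metrics_df,
                 paired = do.call(rbind, paired),
                 predictions = do.call(rbind, preds),
                 condition_summary = do.call(rbind, cond_tabs),
                 split = split, models = models, config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  cat(sprintf("  split: %d train / %d test subjects\n",
              length(x$split$train_subjects), length(x$split$test_subjects)))
  print(x$metrics, row.names = FALSE, digits = 4)
  invisible(x)
}
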