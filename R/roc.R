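#' Split a cohort into training and test sets
#'
#' Reproducible random partition; `floor(n * fraction)` patients go to
#' the training part. Errors (suggesting a reseed) when either part ends
#' up without events.
#'
#' @param cohort cohort data frame with a `dfs_event` column.
#' @param fraction training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list(train, test) of disjoint, exhaustive row subsets.
#' @export
split_cohort <- function(cohort, fraction = 0.7, seed = 1L) {
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(cohort)
  idx <- with_seed(seed, sample.int(n, floor(n * fraction)))
  train <- cohort[idx, , drop = FALSE]
  test <- cohort[-idx, , drop = FALSE]
  if (sum(train$dfs_event) == 0L || sum(test$dfs_event) == 0L)
    stop("a split part has zero events; try another seed")
  list(train = train, test = test,
       n_events = c(train = sum(train$dfs_event),
                    test = sum(test$dfs_event)))
}

#' Linear risk score of a fitted Cox model
#'
#' The uncentered linear predictor sum(coef * covariate), no baseline
#' term; higher scores mean higher hazard. Patients missing any model
#' covariate are excluded and counted.
#'
#' @param fit a `cox_fit`.
#' @param records data frame carrying the model covariates.
#' @return numeric scores aligned with `records` rows (`NA` for
#'   excluded patients); attribute `n_excluded`.
#' @export
risk_score <- function(fit, records) {
  stopifnot(inherits(fit, "cox_fit"))
  vars <- all.vars(stats::delete.response(stats::terms(fit$fit)))
  missing_vars <- setdiff(vars, names(records))
  if (length(missing_vars))
    stop("records lack fit covariate(s): ",
         paste(missing_vars, collapse = ", "))
  ok <- stats::complete.cases(records[, vars, drop = FALSE])
  scores <- rep(NA_real_, nrow(records))
  if (any(ok))
    scores[ok] <- unname(stats::predict(fit$fit,
                                        newdata = records[ok, , drop = FALSE],
                                        type = "lp", reference = "zero"))
  attr(scores, "n_excluded") <- sum(!ok)
  scores
}

#' ROC curve and AUC for a binary outcome
#'
#' AUC is the tie-adjusted Mann-Whitney statistic U / (n1 * n0) computed
#' from midranks (ties count one half); coordinates give sensitivity /
#' 1-specificity over all score thresholds.
#'
#' @param scores numeric risk scores.
#' @param outcomes 0/1 outcomes, both classes present.
#' @return list(auc, coords) where `coords` is a data frame of
#'   (threshold, tpr, fpr).
#' @export
roc_auc <- function(scores, outcomes) {
  ok <- !is.na(scores) & !is.na(outcomes)
  scores <- scores[ok]; outcomes <- outcomes[ok]
  n1 <- sum(outcomes == 1); n0 <- sum(outcomes == 0)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes must be present")
  r <- rank(scores)                      # midranks
  auc <- (sum(r[outcomes == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  th <- sort(unique(scores), decreasing = TRUE)
  coords <- data.frame(
    threshold = c(Inf, th),
    tpr = c(0, vapply(th, function(t) mean(scores[outcomes == 1] >= t),
                      numeric(1))),
    fpr = c(0, vapply(th, function(t) mean(scores[outcomes == 0] >= t),
                      numeric(1))))
  list(auc = auc, coords = coords)
}

# DeLong structural components: per-observation placement values.
delong_components <- function(scores, outcomes) {
  x <- scores[outcomes == 1]; y <- scores[outcomes == 0]
  m <- length(x); n <- length(y)
  # psi(x_i, y_j) = 1[x > y] + 0.5 * 1[x == y], via midranks
  rall <- rank(c(x, y))
  rx <- rank(x); ry <- rank(y)
  v10 <- (rall[seq_len(m)] - rx) / n        # mean_j psi(x_i, .)
  v01 <- 1 - (rall[m + seq_len(n)] - ry) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Compares the AUCs of two risk scores evaluated on the same patients
#' using the structural-components covariance estimate for paired AUCs;
#' two-sided normal p-value for the AUC difference. Identical score
#' vectors (degenerate zero variance) give a difference of 0 with p = 1.
#'
#' @param scores_a,scores_b paired risk scores.
#' @param outcomes 0/1 outcomes.
#' @return list(auc_a, auc_b, delta_auc, variance, z, p).
#' @export
delong_test <- function(scores_a, scores_b, outcomes) {
  ok <- !is.na(scores_a) & !is.na(scores_b) & !is.na(outcomes)
  scores_a <- scores_a[ok]; scores_b <- scores_b[ok]
  outcomes <- outcomes[ok]
  stopifnot(any(outcomes == 1), any(outcomes == 0))
  ca <- delong_components(scores_a, outcomes)
  cb <- delong_components(scores_b, outcomes)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_delta <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- ca$auc - cb$auc
  if (var_delta <= 0 || !is.finite(var_delta)) {
    z <- 0; p <- 1; delta <- if (identical(scores_a, scores_b)) 0 else delta
  } else {
    z <- delta / sqrt(var_delta)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta,
       variance = var_delta,
       var_auc_a = s10[1, 1] / m + s01[1, 1] / n,
       var_auc_b = s10[2, 2] / m + s01[2, 2] / n,
       z = z, p = p)
}

#' Compare a combined prognostic model against a clinical-only model
#'
#' Splits the cohort, fits a Cox model for each covariate set on the
#' training part, scores the test part, dichotomizes DFS at `horizon`
#' days (patients censored before the horizon are excluded and counted)
#' and compares the two test-set AUCs with DeLong's test.
#'
#' @param cohort cohort data frame.
#' @param clinical_covariates covariate names of the clinical model.
#' @param full_covariates covariate names of the combined model
#'   (clinical + sTIL + SNPs).
#' @param horizon dichotomization horizon in days (default 3 years).
#' @param train_fraction training fraction.
#' @param seed RNG seed for the split.
#' @return a `roc_comparison`: AUCs, `delta_auc`, `delong_p`, `n_test`,
#'   `n_excluded_censored`, `horizon_days`, per-model ROC coordinates.
#' @export
compare_models <- function(cohort, clinical_covariates, full_covariates,
                           horizon = 1095, train_fraction = 0.7,
                           seed = 1L) {
  sp <- split_cohort(cohort, train_fraction, seed)
  fit_full <- cox_fit(sp$train, full_covariates)
  fit_clin <- cox_fit(sp$train, clinical_covariates)
  test <- sp$test
  excl <- test$dfs_event == 0 & test$dfs_time < horizon
  test <- test[!excl, , drop = FALSE]
  outcome <- as.integer(test$dfs_event == 1 & test$dfs_time <= horizon)
  if (length(unique(outcome)) < 2L)
    stop("one-class outcome at this horizon")
  s_full <- risk_score(fit_full, test)
  s_clin <- risk_score(fit_clin, test)
  dl <- delong_test(s_full, s_clin, outcome)
  structure(list(auc_combined = dl$auc_a, auc_clinical = dl$auc_b,
                 delta_auc = dl$delta_auc, delong_p = dl$p,
                 n_test = nrow(test), n_excluded_censored = sum(excl),
                 horizon_days = horizon, seed = seed,
                 roc_combined = roc_auc(s_full, outcome)$coords,
                 roc_clinical = roc_auc(s_clin, outcome)$coords,
                 fit_combined = fit_full, fit_clinical = fit_clin),
            class = "roc_comparison")
}

#' @export
print.roc_comparison <- function(x, ...) {
  cat(sprintf(paste0(
    "<roc_comparison> AUC combined %.3f vs clinical %.3f ",
    "(delta %.3f, DeLong p = %.4g; n_test = %d, horizon %d d)\n"),
    x$auc_combined, x$auc_clinical, x$delta_auc, x$delong_p,
    x$n_test, x$horizon_days))
  invisible(x)
}
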