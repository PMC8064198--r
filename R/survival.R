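#' Derive disease-free survival from event dates
#'
#' DFS time runs from diagnosis to the earliest of recurrence, death or
#' last follow-up; the event indicator is 1 when that earliest date is a
#' recurrence or death (composite event). A death or recurrence on the
#' same day as the last follow-up counts as an event (event precedence
#' over censoring).
#'
#' @param diagnosis,recurrence,death,last_followup `Date`s or numeric
#'   day offsets; `recurrence`/`death` may be `NA`.
#' @return list(time, event) with time in days.
#' @export
derive_dfs <- function(diagnosis, recurrence = NA, death = NA,
                       last_followup) {
  days <- function(d) as.numeric(d) - as.numeric(diagnosis)
  cand <- c(recurrence = if (!is.na(recurrence)) days(recurrence) else Inf,
            death = if (!is.na(death)) days(death) else Inf,
            followup = days(last_followup))
  if (any(cand < 0, na.rm = TRUE))
    stop("event date before diagnosis")
  t <- min(cand)
  event <- as.integer(cand[["recurrence"]] <= t || cand[["death"]] <= t)
  list(time = t, event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Wraps [survival::survfit()]; the median is the smallest time at which
#' the survival estimate drops to 0.5 or below, `NA` (flagged) when the
#' curve never reaches 0.5.
#'
#' @param time,event numeric follow-up days and 0/1 event indicators.
#' @return a `km_fit`: `time`, `surv`, `n_risk`, `n_event`, `median`,
#'   `median_defined`, and the underlying `survfit` object.
#' @export
kaplan_meier <- function(time, event) {
  stopifnot(length(time) >= 1L, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  below <- which(sf$surv <= 0.5)
  med <- if (length(below)) sf$time[min(below)] else NA_real_
  structure(list(time = sf$time, surv = sf$surv, n_risk = sf$n.risk,
                 n_event = sf$n.event, median = med,
                 median_defined = length(below) > 0, fit = sf),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("<km_fit> %d time points; median survival %s days\n",
              length(x$time),
              if (x$median_defined) format(x$median) else "not reached"))
  invisible(x)
}

#' Log-rank test across groups
#'
#' Standard observed-minus-expected statistic over pooled event times
#' with hypergeometric variance, df = groups - 1
#' (via [survival::survdiff()]).
#'
#' @param time,event follow-up days and 0/1 indicators.
#' @param group grouping factor (>= 2 levels, >= 1 event overall).
#' @return list(statistic, df, p).
#' @export
log_rank <- function(time, event, group) {
  group <- factor(group)
  stopifnot(nlevels(group) >= 2L)
  if (sum(event) == 0L) stop("no events: log-rank undefined")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Complete-case Cox regression with Efron's tie correction by default
#' (Breslow available for cross-checks), via [survival::coxph()].
#' Constant covariates among the complete cases are dropped with a
#' warning. Reports per-covariate coefficient, SE, hazard ratio with
#' normal-theory 95% CI (exp(coef +/- 1.96 SE)) and the Wald p-value.
#'
#' @param data data frame with time/event columns and covariates.
#' @param covariates character vector of covariate column names.
#' @param time,event column names for follow-up and indicator.
#' @param ties "efron" or "breslow".
#' @return a `cox_fit`: `table`, `loglik`, `n`, `n_event`, `iter`,
#'   `converged`, `dropped`, and the `coxph` object as `fit`.
#' @export
cox_fit <- function(data, covariates, time = "dfs_time",
                    event = "dfs_event", ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  stopifnot(all(c(time, event, covariates) %in% names(data)))
  d <- data[, c(time, event, covariates), drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (sum(d[[event]]) < 1L) stop("no events among complete cases")
  dropped <- character(0)
  for (cv in covariates) {
    v <- d[[cv]]
    if (length(unique(v[!is.na(v)])) < 2L) dropped <- c(dropped, cv)
  }
  if (length(dropped)) {
    warning("dropping constant covariate(s): ", paste(dropped, collapse = ", "))
    covariates <- setdiff(covariates, dropped)
    if (!length(covariates)) stop("no non-constant covariates left")
  }
  f <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ",
    paste(sprintf("`%s`", covariates), collapse = " + ")))
  fit <- survival::coxph(f, data = d, ties = ties,
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && any(grepl("did not converge", fit$info)))
    stop("Cox fit did not converge")
  sm <- summary(fit)
  tab <- data.frame(term = gsub("`", "", rownames(sm$coefficients),
                                fixed = TRUE),
                    coef = sm$coefficients[, "coef"],
                    se = sm$coefficients[, "se(coef)"],
                    hr = exp(sm$coefficients[, "coef"]),
                    ci_lo = exp(sm$coefficients[, "coef"] -
                                  1.96 * sm$coefficients[, "se(coef)"]),
                    ci_hi = exp(sm$coefficients[, "coef"] +
                                  1.96 * sm$coefficients[, "se(coef)"]),
                    p = sm$coefficients[, "Pr(>|z|)"],
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2], n = nrow(d),
                 n_event = sum(d[[event]]), iter = fit$iter,
                 converged = TRUE, dropped = dropped, ties = ties,
                 fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("<cox_fit> n = %d, events = %d, ties = %s, logLik = %.2f\n",
              x$n, x$n_event, x$ties, x$loglik))
  print(transform(x$table, hr = round(hr, 3), ci_lo = round(ci_lo, 3),
                  ci_hi = round(ci_hi, 3), coef = round(coef, 4),
                  se = round(se, 4), p = signif(p, 3)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.cox_fit <- function(object, ...) {
  stats::setNames(object$table$coef, object$table$term)
}

#' Code a genotype column for Cox regression
#'
#' Reference coding yields one indicator per non-reference genotype
#' (the reference genotype is the baseline, as in a per-genotype hazard
#' table); dominant coding pools the declared `combine` genotypes into
#' the baseline and yields a single indicator for the remaining class.
#'
#' @param genotypes character vector of "X/Y" genotype strings (may
#'   contain `NA`; at most 3 observed classes).
#' @param model "reference" or "dominant".
#' @param reference reference genotype (reference model).
#' @param combine genotypes pooled into the baseline (dominant model).
#' @return numeric matrix of indicator columns (rows align with input;
#'   `NA` genotypes give `NA` rows).
#' @export
genotype_coding <- function(genotypes, model = c("reference", "dominant"),
                            reference = NULL, combine = NULL) {
  model <- match.arg(model)
  obs <- unique(genotypes[!is.na(genotypes)])
  if (length(obs) > 3L) stop("more than 3 observed genotype classes")
  if (length(obs) < 2L) stop("fewer than 2 observed genotype classes")
  if (model == "reference") {
    if (is.null(reference)) reference <- obs[1L]
    if (!reference %in% obs) stop("reference class unobserved: ", reference)
    others <- sort(setdiff(obs, reference))
    m <- vapply(others, function(g) as.numeric(genotypes == g),
                numeric(length(genotypes)))
    colnames(m) <- others
    m
  } else {
    if (is.null(combine)) stop("dominant coding requires `combine`")
    if (!all(combine %in% obs))
      stop("combined class unobserved: ",
           paste(setdiff(combine, obs), collapse = ", "))
    alt <- setdiff(obs, combine)
    if (!length(alt)) stop("dominant coding leaves no contrast class")
    m <- matrix(as.numeric(genotypes %in% alt), ncol = 1)
    colnames(m) <- paste(alt, collapse = "+")
    m[is.na(genotypes), ] <- NA
    m
  }
}

#' Multivariable SNP-prognosis analysis with an adjustment set
#'
#' Fits a Cox model of DFS on genotype indicator(s) plus the adjustment
#' covariates (default: sTIL, age, sex, first-line treatment, BMI),
#' complete cases only; warns when complete cases fall below 10 per
#' covariate.
#'
#' @param cohort cohort data frame.
#' @param snp genotype column name.
#' @param adjustment character vector of adjustment covariates (may be
#'   empty, giving the univariable genotype fit).
#' @param model,reference,combine genotype coding, see
#'   [genotype_coding()].
#' @param ties tie handling passed to [cox_fit()].
#' @return a `cox_fit`; genotype terms are prefixed with the SNP name.
#' @export
adjusted_snp_analysis <- function(cohort, snp,
                                  adjustment = c("stil", "age", "sex",
                                                 "treatment", "bmi"),
                                  model = "reference", reference = NULL,
                                  combine = NULL, ties = "efron") {
  gm <- genotype_coding(cohort[[snp]], model = model,
                        reference = reference, combine = combine)
  colnames(gm) <- paste0(snp, ":", colnames(gm))
  d <- cbind(cohort[, c("dfs_time", "dfs_event", adjustment),
                    drop = FALSE], as.data.frame(gm, check.names = FALSE))
  covs <- c(colnames(gm), adjustment)
  cc <- sum(stats::complete.cases(d))
  if (cc < 10L * length(covs))
    warning("only ", cc, " complete cases for ", length(covs),
            " covariates")
  cox_fit(d, covs, ties = ties)
}

#' Univariable SNP fits stratified by a factor
#'
#' Independent univariable Cox fits of the genotype coding within each
#' stratum (default: first-line treatment). Strata without events or
#' with degenerate genotype distributions are reported untestable.
#'
#' @inheritParams adjusted_snp_analysis
#' @param stratum stratifying column name.
#' @return named list per stratum: either a `cox_fit` or a character
#'   reason why the stratum is untestable.
#' @export
stratified_univariable <- function(cohort, snp, stratum = "treatment",
                                   model = "reference", reference = NULL,
                                   combine = NULL) {
  lv <- levels(factor(cohort[[stratum]]))
  out <- stats::setNames(vector("list", length(lv)), lv)
  for (s in lv) {
    sub <- cohort[!is.na(cohort[[stratum]]) & cohort[[stratum]] == s, ,
                  drop = FALSE]
    out[[s]] <- tryCatch({
      if (sum(sub$dfs_event, na.rm = TRUE) < 1L)
        stop("no events in stratum")
      adjusted_snp_analysis(sub, snp, adjustment = character(0),
                            model = model, reference = reference,
                            combine = combine)
    }, error = function(e) paste("untestable:", conditionMessage(e)))
  }
  out
}

#' Median follow-up time, both estimators
#'
#' Reports (a) the reverse Kaplan-Meier median (censoring distribution
#' median, events treated as censorings) and (b) the raw median
#' follow-up among censored patients; the two definitions differ and
#' are labeled.
#'
#' @param time,event follow-up days and 0/1 indicators.
#' @export
median_followup <- function(time, event) {
  rkm <- kaplan_meier(time, 1 - event)
  list(reverse_km = rkm$median,
       raw_censored = stats::median(time[event == 0]))
}
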