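test_that("DFS derivation takes the earliest event with event precedence
           on ties", {
  expect_equal(derive_dfs(0, recurrence = 100, death = 400,
                          last_followup = 500),
               list(time = 100, event = 1L))
  expect_equal(derive_dfs(0, last_followup = 851),
               list(time = 851, event = 0L))
  expect_equal(derive_dfs(0, death = 300, last_followup = 300),
               list(time = 300, event = 1L))
  expect_error(derive_dfs(100, death = 50, last_followup = 200), "before")
})

test_that("Kaplan-Meier matches the product-limit hand oracle", {
  km <- kaplan_meier(c(1, 2, 3), c(0, 1, 0))
  # at t=2: 2 at risk, 1 event -> S(2) = 0.5; median = 2
  expect_equal(km$surv[km$time == 2], 0.5)
  expect_equal(km$median, 2)

  all_cens <- kaplan_meier(c(4, 5, 6), c(0, 0, 0))
  expect_true(all(all_cens$surv == 1))
  expect_false(all_cens$median_defined)

  km_oracle <- function(time, event, at) {   # direct product over events
    s <- 1
    for (t in sort(unique(time[event == 1]))) {
      if (t > at) break
      n <- sum(time >= t); d <- sum(time == t & event == 1)
      s <- s * (1 - d / n)
    }
    s
  }
  set.seed(5)
  for (i in 1:100) {
    n <- sample(3:25, 1)
    tt <- sample(1:12, n, replace = TRUE)   # ties included
    ev <- rbinom(n, 1, 0.6)
    if (!any(ev == 1)) next
    km <- kaplan_meier(tt, ev)
    for (j in seq_along(km$time))
      expect_equal(km$surv[j], km_oracle(tt, ev, km$time[j]),
                   tolerance = 1e-12)
  }
})

test_that("log-rank matches the hypergeometric hand computation and is
           calibrated under the null", {
  d <- data.frame(time = c(5, 5, 9, 9), event = c(1, 0, 0, 0),
                  g = c(1, 2, 1, 2))
  # single event time t=5: O1 = 1, E1 = 0.5, V = 0.25 -> chi-square 1
  lr <- log_rank(d$time, d$event, d$g)
  expect_equal(lr$statistic, 1, tolerance = 1e-12)
  expect_identical(lr$df, 1L)

  same <- sim_surv_groups(30, 0.01, 0.01)
  expect_lt(log_rank(same$dfs_time, same$dfs_event, same$group)$statistic,
            20)  # finite; exact equality tested via duplicated groups
  dup <- data.frame(t = rep(c(2, 4, 7), 2), e = rep(c(1, 1, 0), 2),
                    g = rep(1:2, each = 3))
  expect_lt(log_rank(dup$t, dup$e, dup$g)$statistic, 1e-10)
  expect_error(log_rank(c(1, 2), c(0, 0), c(1, 2)), "events")

  set.seed(7)
  ps <- replicate(2000, {
    d <- sim_surv_groups(30, 0.02, 0.02, cens = 100)
    log_rank(d$dfs_time, d$dfs_event, d$group)$p
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.05)
})

test_that("log-rank agrees with the Cox score test on tie-free data", {
  set.seed(11)
  d <- sim_surv_groups(80, 0.02, 0.035, cens = 120)
  lr <- log_rank(d$dfs_time, d$dfs_event, d$group)
  fit <- cox_fit(d, "group")
  sc <- summary(fit$fit)$sctest[["test"]]
  expect_equal(lr$statistic, sc, tolerance = 5e-4)
})

test_that("Cox fitting recovers a known effect, handles ties options and
           drops constant covariates", {
  set.seed(13)
  d <- sim_surv_groups(1000, 0.01, 0.01 * exp(0.5), cens = 250)
  fit <- cox_fit(d, "group")
  est <- fit$table$coef
  expect_lt(abs(est - 0.5), 3 * fit$table$se)
  expect_true(all(fit$table$ci_lo ==
                    pmin(fit$table$ci_lo, fit$table$ci_hi)))
  expect_equal(fit$table$hr, exp(fit$table$coef), tolerance = 1e-12)

  # without ties Efron and Breslow coincide
  fe <- cox_fit(d, "group", ties = "efron")
  fb <- cox_fit(d, "group", ties = "breslow")
  expect_equal(fe$loglik, fb$loglik, tolerance = 1e-12)
  expect_equal(fe$table$coef, fb$table$coef, tolerance = 1e-10)

  d$flat <- 1
  expect_warning(fit2 <- cox_fit(d, c("group", "flat")), "constant")
  expect_identical(fit2$dropped, "flat")
  expect_error(cox_fit(transform(d, dfs_event = 0), "group"), "events")
})

test_that("genotype coding produces the reference and dominant designs", {
  g <- c("A/A", "A/C", "C/C", "A/C", NA, "A/A")
  ref <- genotype_coding(g, "reference", reference = "A/A")
  expect_identical(colnames(ref), c("A/C", "C/C"))
  expect_equal(ref[2, ], c(`A/C` = 1, `C/C` = 0))
  expect_equal(ref[3, ], c(`A/C` = 0, `C/C` = 1))
  expect_error(genotype_coding(g, "reference", reference = "C/A"),
               "unobserved")

  g2 <- c("A/A", "G/A", "G/G", "G/A", "A/A")
  dom <- genotype_coding(g2, "dominant", combine = c("A/A", "G/G"))
  expect_identical(ncol(dom), 1L)
  expect_equal(as.vector(dom), c(0, 1, 0, 1, 0))
  expect_error(genotype_coding(rep("A/A", 5), "reference"), "fewer than 2")
})

test_that("adjusted SNP analysis recovers a dominant effect and reduces
           to the univariable fit with an empty adjustment set", {
  cfg <- cohort_sim_config(
    n_patients = 1200,
    snps = list(snp_def("s1", c("A", "G"), maf = 0.3, stil_shift = 1.5,
                        loghr_dominant = 0.6)),
    seed = 17)
  co <- simulate_cohort(cfg)
  fit <- adjusted_snp_analysis(co, "s1", model = "dominant",
                               combine = "A/A")
  term <- fit$table[grepl("^s1:", fit$table$term), ]
  expect_lt(abs(term$coef - 0.6), 3 * term$se)

  uni <- adjusted_snp_analysis(co, "s1", adjustment = character(0),
                               model = "dominant", combine = "A/A")
  plain <- cox_fit(cbind(co, d1 = genotype_coding(co$s1, "dominant",
                                                  combine = "A/A")[, 1]),
                   "d1")
  expect_equal(uni$table$coef[1], plain$table$coef[1], tolerance = 1e-10)

  # adjustment covariates independent of genotype: estimates agree
  expect_lt(abs(term$coef - uni$table$coef[1]), 2 * term$se)
})

test_that("treatment-stratified univariable fits isolate strata and flag
           untestable ones", {
  cfg <- cohort_sim_config(n_patients = 900, seed = 19)
  co <- simulate_cohort(cfg)
  st <- stratified_univariable(co, "snp03", model = "dominant",
                               combine = "A/A")
  expect_setequal(names(st), levels(co$treatment))
  ok <- vapply(st, inherits, logical(1), "cox_fit")
  expect_gte(sum(ok), 3L)

  # a stratum with zero events is reported untestable, others unaffected
  co2 <- co
  co2$dfs_event[co2$treatment == "untreated"] <- 0L
  st2 <- stratified_univariable(co2, "snp03", model = "dominant",
                                combine = "A/A")
  expect_match(st2$untreated, "untestable")
  expect_true(inherits(st2$surgery, "cox_fit"))

  # single stratum equals the plain univariable fit
  sub <- co[co$treatment == "surgery", ]
  one <- stratified_univariable(sub, "snp03", model = "dominant",
                                combine = "A/A")
  direct <- adjusted_snp_analysis(sub, "snp03",
                                  adjustment = character(0),
                                  model = "dominant", combine = "A/A")
  expect_equal(one$surgery$table$coef, direct$table$coef,
               tolerance = 1e-12)
})

test_that("median follow-up reports both labeled estimators", {
  set.seed(23)
  d <- sim_surv_groups(100, 0.01, 0.01, cens = 300)
  mf <- median_followup(d$dfs_time, d$dfs_event)
  expect_named(mf, c("reverse_km", "raw_censored"))
  expect_true(is.finite(mf$raw_censored))
})
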