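#' Accuracy benchmark: sTIL recovery on synthetic tiles
#'
#' Renders tiles with true sTIL fractions spread over a target grid,
#' runs the full quantization -> lymphocyte -> scoring pipeline on each
#' (with the ground-truth tumor-region mask, so the benchmark isolates
#' the measurement algorithm from the tumor-region heuristic) and
#' compares the estimated percentage with the ground truth.
#'
#' @param n_tiles number of tiles.
#' @param targets true-sTIL targets (percent), recycled over tiles.
#' @param seed run seed.
#' @param tile_size tile side in px.
#' @param K_range candidate class counts for the Dunn selection.
#' @return data frame (target, true, estimated, K); attribute `mae`.
#' @export
stil_recovery_benchmark <- function(n_tiles = 50L,
                                    targets = seq(5, 60,
                                                  length.out = n_tiles),
                                    seed = 1L, tile_size = 512L,
                                    K_range = 2:6) {
  targets <- rep_len(targets, n_tiles)
  out <- vector("list", n_tiles)
  for (i in seq_len(n_tiles)) {
    cfg <- tile_sim_config(height = tile_size, width = tile_size,
                           seed = child_seed(seed, i))
    r <- render_tile(cfg, target_stil_percent = targets[i])
    tm <- r$truth$tumor_mask
    q <- quantify_tile(r$tile, seed = child_seed(seed, 1000L + i),
                       K_range = K_range, tumor_mask = tm,
                       tile_id = sprintf("tile%02d", i))
    out[[i]] <- data.frame(target = targets[i],
                           true = r$truth$true_stil_percent,
                           estimated = q$result$stil_percent, K = q$K)
  }
  res <- do.call(rbind, out)
  attr(res, "mae") <- mean(abs(res$true - res$estimated))
  res
}

#' Class-count selection benchmark
#'
#' Fraction of independently seeded four-prototype tiles on which the
#' Dunn criterion selects K = 4.
#'
#' @param n_seeds number of tiles.
#' @param seed run seed.
#' @param tile_size tile side in px.
#' @param K_range candidate class counts.
#' @return list(rate, selections).
#' @export
dunn_selection_benchmark <- function(n_seeds = 20L, seed = 1L,
                                     tile_size = 256L, K_range = 2:6) {
  ks <- vapply(seq_len(n_seeds), function(i) {
    cfg <- tile_sim_config(height = tile_size, width = tile_size,
                           tumor_nest_count = 2L, nest_radius = c(40, 55),
                           background_blob_count = 1L,
                           background_blob_radius = c(25, 35),
                           seed = child_seed(seed, i))
    r <- render_tile(cfg)
    select_num_classes(r$tile, K_range = K_range,
                       seed = child_seed(seed, 500L + i))$K
  }, integer(1))
  list(rate = mean(ks == 4L), selections = ks)
}

#' Type-I error of the per-SNP Kruskal-Wallis sweep under the null
#'
#' Simulates cohorts from the null generator (no genotype effect on
#' sTIL) and reports the per-SNP rejection rate at `alpha`.
#'
#' @param n_reps replicate cohorts.
#' @param n_patients cohort size.
#' @param n_snps SNPs per cohort.
#' @param alpha nominal level.
#' @param seed run seed.
#' @return list(rejection_rate, n_tests).
#' @export
kw_null_calibration <- function(n_reps = 1000L, n_patients = 969L,
                                n_snps = 101L, alpha = 0.05, seed = 1L) {
  snps <- null_snp_panel(n_snps)
  nm <- vapply(snps, `[[`, character(1), "name")
  rej <- 0L; total <- 0L
  for (i in seq_len(n_reps)) {
    cfg <- cohort_sim_config(n_patients = n_patients, snps = snps,
                             seed = child_seed(seed, i))
    co <- simulate_cohort(cfg)
    sw <- snp_sweep(co, nm, alpha = alpha, genotype_table = FALSE)
    rej <- rej + sum(sw$tests$significant)
    total <- total + nrow(sw$tests)
  }
  list(rejection_rate = rej / total, n_tests = total)
}

#' Wald-test calibration of the Cox fit under the null
#'
#' A covariate independent of survival: the Wald p-value should be
#' uniform, with rejection at `alpha` near nominal.
#'
#' @param n_reps replicates.
#' @param n sample size per replicate.
#' @param alpha nominal level.
#' @param rate baseline exponential hazard (per day).
#' @param censor_window uniform censoring window (days).
#' @param seed run seed.
#' @return list(rejection_rate, p_values).
#' @export
cox_null_calibration <- function(n_reps = 2000L, n = 500L, alpha = 0.05,
                                 rate = 1e-3, censor_window = 2000,
                                 seed = 1L) {
  ps <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    x <- stats::rnorm(n)
    tt <- stats::rexp(n, rate)
    cc <- stats::runif(n, 0, censor_window)
    d <- data.frame(dfs_time = pmin(tt, cc),
                    dfs_event = as.integer(tt <= cc), x = x)
    cox_fit(d, "x")$table$p
  }, numeric(1)))
  list(rejection_rate = mean(ps < alpha), p_values = ps)
}

#' DeLong-test calibration under the null
#'
#' Two correlated risk scores, both independent of the outcome: the
#' test should reject at the nominal rate.
#'
#' @param n_reps replicates.
#' @param n patients per replicate.
#' @param alpha nominal level.
#' @param seed run seed.
#' @return list(rejection_rate, p_values).
#' @export
delong_null_calibration <- function(n_reps = 500L, n = 200L, alpha = 0.05,
                                    seed = 1L) {
  ps <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    y <- stats::rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) return(NA_real_)
    a <- stats::rnorm(n)
    b <- 0.6 * a + stats::rnorm(n, 0, 0.8)
    delong_test(a, b, y)$p
  }, numeric(1)))
  ps <- ps[!is.na(ps)]
  list(rejection_rate = mean(ps < alpha), p_values = ps)
}

#' Parameter recovery of the Cox fit
#'
#' Two-group exponential survival with a known log hazard ratio;
#' reports the mean estimate, bias and 95% CI coverage.
#'
#' @param n_reps replicates.
#' @param n patients per replicate.
#' @param loghr true log hazard ratio.
#' @param rate baseline hazard.
#' @param censor_window uniform censoring window (days).
#' @param seed run seed.
#' @return list(mean_estimate, bias, coverage).
#' @export
cox_recovery_benchmark <- function(n_reps = 200L, n = 1000L, loghr = 0.5,
                                   rate = 1e-3, censor_window = 2500,
                                   seed = 1L) {
  res <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
    g <- stats::rbinom(n, 1, 0.5)
    tt <- stats::rexp(n, rate * exp(loghr * g))
    cc <- stats::runif(n, 0, censor_window)
    d <- data.frame(dfs_time = pmin(tt, cc),
                    dfs_event = as.integer(tt <= cc), g = g)
    tab <- cox_fit(d, "g")$table
    c(tab$coef, tab$coef - 1.96 * tab$se, tab$coef + 1.96 * tab$se)
  }, numeric(3)))
  list(mean_estimate = mean(res[1, ]),
       bias = mean(res[1, ]) - loghr,
       coverage = mean(res[2, ] <= loghr & loghr <= res[3, ]))
}

#' Recovery of the generator's genotype-sTIL shift
#'
#' Difference in mean sTIL between minor- and major-allele homozygotes
#' at a SNP with a known additive shift.
#'
#' @param n cohort size.
#' @param shift_per_allele additive shift (percentage points).
#' @param seed run seed.
#' @return list(recovered, expected).
#' @export
stil_shift_recovery <- function(n = 1e4L, shift_per_allele = 2.5,
                                seed = 1L) {
  cfg <- cohort_sim_config(
    n_patients = n,
    snps = list(snp_def("s1", c("A", "B"), maf = 0.5,
                        stil_shift = shift_per_allele)),
    stil_sd = 1, seed = seed)
  co <- simulate_cohort(cfg)
  list(recovered = mean(co$stil[co$s1 == "B/B"]) -
         mean(co$stil[co$s1 == "A/A"]),
       expected = 2 * shift_per_allele)
}

#' Added prognostic value of sTIL + SNPs over clinical covariates
#'
#' Replicated train/test model comparisons on cohorts simulated with the
#' generator's default (nonzero) sTIL and SNP effects; reports how often
#' the combined model's test-set AUC exceeds the clinical model's, and
#' the mean AUCs.
#'
#' @param n_reps replicate cohorts.
#' @param n_patients cohort size.
#' @param seed run seed.
#' @return list(gain_rate, mean_auc_combined, mean_auc_clinical,
#'   mean_delong_p).
#' @export
auc_gain_benchmark <- function(n_reps = 100L, n_patients = 969L,
                               seed = 1L) {
  clin <- c("age", "sex", "grade", "treatment", "bmi", "tea")
  full <- c(clin, "stil", "snp02", "snp03", "snp04")
  res <- vapply(seq_len(n_reps), function(i) {
    co <- simulate_cohort(cohort_sim_config(n_patients = n_patients,
                                            seed = child_seed(seed, i)))
    cmp <- compare_models(co, clin, full,
                          seed = child_seed(seed, 3000L + i))
    c(cmp$auc_combined, cmp$auc_clinical, cmp$delong_p)
  }, numeric(3))
  list(gain_rate = mean(res[1, ] > res[2, ]),
       mean_auc_combined = mean(res[1, ]),
       mean_auc_clinical = mean(res[2, ]),
       mean_delong_p = mean(res[3, ]))
}
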