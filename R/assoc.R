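#' Kruskal-Wallis H test across genotype groups
#'
#' Tie-corrected Kruskal-Wallis H with a chi-square reference
#' distribution (df = k - 1), the screen used for genotype-sTIL
#' association since sTIL percentages are not normally distributed.
#' H is computed from midranks over the pooled values,
#' H_raw = 12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1), divided by
#' the tie-correction factor 1 - sum(t^3 - t) / (N^3 - N); it agrees
#' with [stats::kruskal.test()] to machine precision. The fully tied
#' case (every value identical, tie-correction denominator zero) is
#' resolved to H = 0, p = 1. Group summaries report n, mean and the
#' normal-theory 95% CI of the mean (mean +/- 1.96 sd/sqrt(n)).
#'
#' @param groups list of k >= 2 non-empty numeric vectors.
#' @return a `kw_result`: `H`, `df`, `p`, `summaries` data frame,
#'   `tie_correction_factor`.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L)
  if (any(vapply(groups, length, integer(1)) == 0L))
    stop("empty group")
  x <- unlist(groups, use.names = FALSE)
  sizes <- vapply(groups, length, integer(1))
  N <- length(x)
  stopifnot(N >= length(groups) + 1L)
  r <- rank(x)                                   # midranks
  tie_len <- rle(sort(x))$lengths
  tie_corr <- 1 - sum(tie_len^3 - tie_len) / (N^3 - N)
  if (tie_corr <= 0) {                           # all values identical
    H <- 0; p <- 1
  } else {
    ends <- cumsum(sizes)
    rsum <- vapply(seq_along(groups), function(j)
      sum(r[(ends[j] - sizes[j] + 1L):ends[j]]), numeric(1))
    h_raw <- 12 / (N * (N + 1)) * sum(rsum^2 / sizes) - 3 * (N + 1)
    H <- h_raw / tie_corr
    p <- stats::pchisq(H, length(groups) - 1L, lower.tail = FALSE)
  }
  ns <- vapply(groups, length, integer(1))
  mu <- vapply(groups, mean, numeric(1))
  se <- vapply(groups, stats::sd, numeric(1)) / sqrt(ns)
  summ <- data.frame(
    group = names(groups) %||% as.character(seq_along(groups)),
    n = ns, mean = mu, ci_lo = mu - 1.96 * se, ci_hi = mu + 1.96 * se,
    row.names = NULL)
  structure(list(H = H, df = length(groups) - 1L, p = p,
                 summaries = summ, tie_correction_factor = tie_corr),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("<kw_result> H = %.4f, df = %d, p = %.4g\n", x$H, x$df, x$p))
  print(x$summaries, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Pairwise post-hoc rank-sum comparisons
#'
#' All unordered group pairs compared by the two-sample Mann-Whitney
#' test (normal approximation with tie correction), unadjusted p-values,
#' flagged at `alpha`. Pairs with a group of fewer than 2 observations
#' are reported untestable.
#'
#' @param groups named list of numeric vectors.
#' @param alpha flagging threshold.
#' @return data frame of (group1, group2, U, p, significant, testable).
#' @export
pairwise_posthoc <- function(groups, alpha = 0.01) {
  k <- length(groups)
  stopifnot(k >= 2L)
  nm <- names(groups) %||% as.character(seq_len(k))
  out <- list()
  for (a in seq_len(k - 1L)) for (b in seq(a + 1L, k)) {
    ga <- groups[[a]]; gb <- groups[[b]]
    if (length(ga) < 2L || length(gb) < 2L) {
      out[[length(out) + 1L]] <- data.frame(
        group1 = nm[a], group2 = nm[b], U = NA_real_, p = NA_real_,
        significant = NA, testable = FALSE)
      next
    }
    wt <- suppressWarnings(stats::wilcox.test(ga, gb, exact = FALSE,
                                              correct = FALSE))
    out[[length(out) + 1L]] <- data.frame(
      group1 = nm[a], group2 = nm[b], U = unname(wt$statistic),
      p = wt$p.value, significant = wt$p.value < alpha, testable = TRUE)
  }
  do.call(rbind, out)
}

#' Chi-square test of independence for an r x c count table
#'
#' Pearson statistic without continuity correction; expected counts
#' below 5 raise a warning, a zero marginal is an error.
#'
#' @param tab r x c matrix of counts.
#' @return list (statistic, df, p, expected).
#' @export
chi_square_independence <- function(tab) {
  tab <- as.matrix(tab)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero marginal in contingency table")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected counts below 5; chi-square approximation is weak")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = expected)
}

#' Genotype-sTIL association sweep over a SNP panel
#'
#' Complete-case Kruskal-Wallis per SNP: rows with a missing genotype
#' are dropped for that SNP only and counted in a `missing` column.
#' Unadjusted p-values are compared to `alpha` (no multiplicity
#' correction by default, mirroring a per-SNP screening analysis; set
#' `adjust = "BH"` for Benjamini-Hochberg-adjusted flags, clearly
#' labeled in the output). SNPs with fewer than two observed genotype
#' classes are skipped with a reason.
#'
#' @param cohort cohort data frame with a `stil` column and genotype
#'   columns.
#' @param snp_names character vector of genotype columns.
#' @param alpha significance threshold (unadjusted).
#' @param adjust "none" (default) or "BH".
#' @param genotype_table build the per-genotype summary table (disable
#'   for large calibration sweeps that only need the test results).
#' @return a `snp_sweep` list: `table` (one row per SNP-genotype, the
#'   per-genotype n, %, sTIL mean and 95% CI, and the SNP p-value),
#'   `tests` (one row per SNP), `skipped`.
#' @export
snp_sweep <- function(cohort, snp_names, alpha = 0.05,
                      adjust = c("none", "BH"), genotype_table = TRUE) {
  adjust <- match.arg(adjust)
  acc <- list(snp = character(), H = numeric(), df = integer(),
              p = numeric(), n = integer(), missing = integer())
  rows <- list(); skipped_snp <- character()
  for (snp in snp_names) {
    gt <- cohort[[snp]]
    if (is.null(gt)) stop("genotype column absent: ", snp)
    ok <- !is.na(gt) & !is.na(cohort$stil)
    n_missing <- sum(!ok)
    if (!any(ok) || length(unique(gt[ok])) < 2L) {
      skipped_snp <- c(skipped_snp, snp)
      next
    }
    groups <- split(cohort$stil[ok], gt[ok])
    kw <- kruskal_wallis(groups)
    acc$snp <- c(acc$snp, snp); acc$H <- c(acc$H, kw$H)
    acc$df <- c(acc$df, kw$df); acc$p <- c(acc$p, kw$p)
    acc$n <- c(acc$n, sum(ok)); acc$missing <- c(acc$missing, n_missing)
    if (genotype_table) {
      s <- kw$summaries
      rows[[length(rows) + 1L]] <- data.frame(
        snp = snp, genotype = s$group, n = s$n,
        pct = round(100 * s$n / length(gt), 1),
        stil_mean = s$mean, ci_lo = s$ci_lo, ci_hi = s$ci_hi, p = kw$p,
        missing = n_missing)
    }
  }
  tests <- as.data.frame(acc, stringsAsFactors = FALSE)
  skipped <- if (length(skipped_snp))
    list(data.frame(snp = skipped_snp,
                    reason = "fewer than 2 observed genotype classes"))
  else list()
  if (nrow(tests)) {
    tests$significant <- if (adjust == "BH") {
      tests$p_bh <- stats::p.adjust(tests$p, "BH")
      tests$p_bh < alpha
    } else tests$p < alpha
  }
  structure(list(table = if (length(rows)) do.call(rbind, rows) else NULL,
                 tests = tests,
                 skipped = if (length(skipped)) do.call(rbind, skipped)
                           else NULL,
                 alpha = alpha, adjust = adjust),
            class = "snp_sweep")
}

#' @export
print.snp_sweep <- function(x, ...) {
  sig <- sum(x$tests$significant)
  cat(sprintf("<snp_sweep> %d SNPs tested, %d significant at alpha = %g (%s)\n",
              nrow(x$tests), sig, x$alpha,
              if (x$adjust == "none") "unadjusted" else x$adjust))
  if (!is.null(x$skipped))
    cat(sprintf("  %d SNPs skipped\n", nrow(x$skipped)))
  invisible(x)
}
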