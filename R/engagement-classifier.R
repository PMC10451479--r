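# Univariate quadratic discriminant classification of block-2 RBD against
# healthy controls, plus the group-comparison statistics used to profile
# the resulting engaged/disengaged subgroups.

#' Quadratic discriminant boundary between two univariate Gaussians
#'
#' Solves `log[pi_1 phi(x; mu_1, sd_1)] = log[pi_2 phi(x; mu_2, sd_2)]`, a
#' quadratic in `x`, for the class densities of healthy controls (class 1)
#' and depressed subjects (class 2). With unequal variances the boundary
#' has two roots; the operative cutoff is the root above the control mean
#' beyond which the depressed posterior dominates for all larger values —
#' the geometry of a single upper threshold. The other root is reported
#' but not used for labeling.
#'
#' @param mean_hc,sd_hc,mean_mdd,sd_mdd class means and standard
#'   deviations (sds strictly positive).
#' @param prior_hc,prior_mdd class priors summing to 1.
#' @return List with `roots` (sorted, length 2; equal when the boundary is
#'   linear) and `cutoff`.
#' @export
qda_boundary <- function(mean_hc, sd_hc, mean_mdd, sd_mdd,
                         prior_hc = 0.5, prior_mdd = 0.5) {
  if (sd_hc <= 0 || sd_mdd <= 0)
    stop("degenerate model: class standard deviations must be positive",
         call. = FALSE)
  if (abs(prior_hc + prior_mdd - 1) > 1e-8)
    stop("priors must sum to 1", call. = FALSE)
  # f(x) = log posterior(MDD) - log posterior(HC) = a x^2 + b x + c
  a <- 1 / (2 * sd_hc^2) - 1 / (2 * sd_mdd^2)
  b <- mean_mdd / sd_mdd^2 - mean_hc / sd_hc^2
  cc <- mean_hc^2 / (2 * sd_hc^2) - mean_mdd^2 / (2 * sd_mdd^2) +
    log(prior_mdd / prior_hc) + log(sd_hc / sd_mdd)
  f <- function(x) a * x^2 + b * x + cc

  if (abs(a) < 1e-12) {
    if (abs(b) < 1e-12)
      stop("no boundary: class distributions are identical", call. = FALSE)
    root <- -cc / b
    roots <- c(root, root)
  } else {
    disc <- b^2 - 4 * a * cc
    if (disc < 0)
      stop("no boundary: one class dominates everywhere", call. = FALSE)
    roots <- sort(((-b) + c(-1, 1) * sqrt(disc)) / (2 * a))
  }
  # operative cutoff: smallest root r with r > mean_hc (if any) such that
  # the MDD posterior dominates just above it
  eps <- 1e-6 * max(1, abs(roots))
  cand <- roots[roots > mean_hc & f(roots + eps) > 0]
  cutoff <- if (length(cand) > 0L) min(cand)
            else if (any(f(roots + eps) > 0)) min(roots[f(roots + eps) > 0])
            else max(roots)
  list(roots = roots, cutoff = cutoff)
}

#' Fit a univariate quadratic discriminant engagement model
#'
#' Estimates per-class Gaussian parameters (unbiased variance) from
#' block-2 RBD values of depressed and control subjects and derives the
#' disengagement cutoff from [qda_boundary()]. Values at or above the
#' cutoff classify as disengaged.
#'
#' @param values_mdd,values_hc block-2 RBD values per group (at least two
#'   each, nonzero within-group variance).
#' @param priors `"empirical"` (class frequencies; default), `"equal"`, or
#'   a numeric vector `c(hc, mdd)` summing to 1.
#' @return An object of class `engagement_model` with the class
#'   parameters, priors, both boundary roots and the cutoff.
#' @export
fit_qda_1d <- function(values_mdd, values_hc, priors = "empirical") {
  values_mdd <- values_mdd[!is.na(values_mdd)]
  values_hc <- values_hc[!is.na(values_hc)]
  if (length(values_mdd) < 2L || length(values_hc) < 2L)
    stop("need at least two values per group", call. = FALSE)
  sd_mdd <- stats::sd(values_mdd)
  sd_hc <- stats::sd(values_hc)
  if (sd_mdd == 0 || sd_hc == 0)
    stop("degenerate model: zero within-group variance", call. = FALSE)
  p <- if (identical(priors, "empirical")) {
    n <- length(values_mdd) + length(values_hc)
    c(length(values_hc) / n, length(values_mdd) / n)
  } else if (identical(priors, "equal")) c(0.5, 0.5)
  else {
    if (!is.numeric(priors) || length(priors) != 2L ||
        abs(sum(priors) - 1) > 1e-8)
      stop("priors must be 'empirical', 'equal', or two numbers summing ",
           "to 1 (hc, mdd)", call. = FALSE)
    priors
  }
  bnd <- qda_boundary(mean(values_hc), sd_hc, mean(values_mdd), sd_mdd,
                      prior_hc = p[1L], prior_mdd = p[2L])
  structure(list(mean_hc = mean(values_hc), sd_hc = sd_hc,
                 mean_mdd = mean(values_mdd), sd_mdd = sd_mdd,
                 prior_hc = p[1L], prior_mdd = p[2L],
                 roots = bnd$roots, cutoff = bnd$cutoff,
                 n_mdd = length(values_mdd), n_hc = length(values_hc)),
            class = "engagement_model")
}

#' @export
print.engagement_model <- function(x, ...) {
  cat("Univariate QDA engagement model\n")
  cat(sprintf("  HC : mean %.4f, sd %.4f, prior %.3f (n = %d)\n",
              x$mean_hc, x$sd_hc, x$prior_hc, x$n_hc))
  cat(sprintf("  MDD: mean %.4f, sd %.4f, prior %.3f (n = %d)\n",
              x$mean_mdd, x$sd_mdd, x$prior_mdd, x$n_mdd))
  cat(sprintf("  boundary roots: %.4f, %.4f\n", x$roots[1L], x$roots[2L]))
  cat(sprintf("  cutoff: %.4f (value >= cutoff => disengaged)\n", x$cutoff))
  invisible(x)
}

#' Classify values as engaged or disengaged
#'
#' Applies the single-threshold rule of the fitted model: a value greater
#' than or equal to the cutoff is labelled `disengaged`, otherwise
#' `engaged` (boundary values are disengaged).
#'
#' @param values numeric block-2 RBD values.
#' @param model an `engagement_model` from [fit_qda_1d()].
#' @return Character vector of labels.
#' @export
classify <- function(values, model) {
  ifelse(values >= model$cutoff, "disengaged", "engaged")
}

.wilson_ci <- function(x, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(center - half, center + half)
}

#' Sensitivity and specificity of the disengagement flag
#'
#' Treats `disengaged` as the positive test for depressed-group
#' membership: sensitivity is the fraction of MDD subjects flagged
#' disengaged, specificity the fraction of HC subjects flagged engaged.
#' Confidence intervals are Wilson score intervals by default.
#'
#' @param labels classifier output (`"engaged"`/`"disengaged"`).
#' @param true_groups true group per subject (`"MDD"`/`"HC"`).
#' @param conf confidence level (default 0.95).
#' @param ci_method `"wilson"` (default) or `"clopper-pearson"`.
#' @return List with confusion counts (`tp`, `fn`, `tn`, `fp`),
#'   `sensitivity` and `specificity`, each with `ci_low`/`ci_high`.
#' @export
diagnostic_stats <- function(labels, true_groups, conf = 0.95,
                             ci_method = c("wilson", "clopper-pearson")) {
  ci_method <- match.arg(ci_method)
  n_mdd <- sum(true_groups == "MDD")
  n_hc <- sum(true_groups == "HC")
  if (n_mdd == 0L || n_hc == 0L)
    stop("undefined statistic: need both MDD and HC subjects", call. = FALSE)
  tp <- sum(labels == "disengaged" & true_groups == "MDD")
  fn <- sum(labels == "engaged" & true_groups == "MDD")
  tn <- sum(labels == "engaged" & true_groups == "HC")
  fp <- sum(labels == "disengaged" & true_groups == "HC")
  ci <- function(x, n) {
    if (ci_method == "wilson") .wilson_ci(x, n, conf)
    else as.numeric(stats::binom.test(x, n, conf.level = conf)$conf.int)
  }
  ci_sens <- ci(tp, n_mdd)
  ci_spec <- ci(tn, n_hc)
  list(tp = tp, fn = fn, tn = tn, fp = fp,
       sensitivity = tp / n_mdd,
       sensitivity_ci = ci_sens,
       specificity = tn / n_hc,
       specificity_ci = ci_spec,
       conf = conf, ci_method = ci_method)
}

#' Pearson chi-square test of independence
#'
#' Uncorrected Pearson statistic `sum (O - E)^2 / E` on an r x c
#' contingency table, with `df = (r - 1)(c - 1)`. The continuity
#' correction is off by default (it is only defined for 2 x 2 tables and
#' is not applied in the comparisons this package reproduces).
#'
#' @param table matrix of counts.
#' @param correct apply the Yates continuity correction (2 x 2 only).
#' @return List with `statistic`, `df`, `p_value` and `expected` counts.
#' @export
chisq_independence <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("degenerate table: zero marginal", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  if (any(ht$expected <= 0))
    stop("degenerate table: nonpositive expected cell", call. = FALSE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value), expected = ht$expected)
}

#' Two-sample t-test with the Cochran-Cox approximation
#'
#' Computes the unequal-variance statistic
#' `t = (mean(x) - mean(y)) / sqrt(s_x^2/n_x + s_y^2/n_y)` and assesses
#' significance two ways: by the Cochran-Cox approximation, which compares
#' `|t|` to the variance-weighted combination of the per-sample Student
#' critical values, and by the Welch-Satterthwaite degrees of freedom.
#' Both are reported; the Cochran-Cox result is primary. The Cochran-Cox
#' p-value is obtained by solving for the level at which `|t|` equals its
#' weighted critical value.
#'
#' @param x,y numeric samples (at least two values each).
#' @param alpha level for the Cochran-Cox critical value (default 0.05).
#' @return An object of class `cochran_cox_test`: `statistic`, per-sample
#'   summaries, `df_satterthwaite` and `p_welch`, the Cochran-Cox
#'   `critical_value`, `significant` flag and `p_cochran_cox`.
#' @export
cochran_cox_ttest <- function(x, y, alpha = 0.05) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L)
    stop("need at least two values per sample", call. = FALSE)
  nx <- length(x); ny <- length(y)
  vx <- stats::var(x); vy <- stats::var(y)
  wx <- vx / nx; wy <- vy / ny
  if (wx + wy == 0) stop("degenerate samples: zero combined variance",
                         call. = FALSE)
  tstat <- (mean(x) - mean(y)) / sqrt(wx + wy)
  df_sw <- (wx + wy)^2 / (wx^2 / (nx - 1) + wy^2 / (ny - 1))
  p_welch <- 2 * stats::pt(-abs(tstat), df_sw)
  crit <- function(a) {
    (wx * stats::qt(1 - a / 2, nx - 1) + wy * stats::qt(1 - a / 2, ny - 1)) /
      (wx + wy)
  }
  critical_value <- crit(alpha)
  # invert the weighted critical value to an approximate p-value
  p_cc <- if (abs(tstat) >= crit(1e-12)) 1e-12
          else if (abs(tstat) <= crit(1 - 1e-9)) 1
          else stats::uniroot(function(a) crit(a) - abs(tstat),
                              c(1e-12, 1 - 1e-9), tol = 1e-12)$root
  structure(list(statistic = tstat,
                 mean_x = mean(x), mean_y = mean(y),
                 var_x = vx, var_y = vy, n_x = nx, n_y = ny,
                 df_satterthwaite = df_sw, p_welch = p_welch,
                 alpha = alpha, critical_value = critical_value,
                 significant = abs(tstat) >= critical_value,
                 p_cochran_cox = p_cc),
            class = "cochran_cox_test")
}

#' @export
print.cochran_cox_test <- function(x, ...) {
  cat(sprintf("Unequal-variance t-test: t = %.4f\n", x$statistic))
  cat(sprintf("  Cochran-Cox: critical |t| = %.4f at alpha = %.3f -> %s",
              x$critical_value, x$alpha,
              if (x$significant) "significant\n" else "not significant\n"))
  cat(sprintf("  approximate Cochran-Cox p = %.4g\n", x$p_cochran_cox))
  cat(sprintf("  Welch-Satterthwaite: df = %.1f, p = %.4g\n",
              x$df_satterthwaite, x$p_welch))
  invisible(x)
}

#' Compare engaged and disengaged subgroups on baseline features
#'
#' Builds, per feature, either a contingency table with an uncorrected
#' chi-square test (categorical features) or an unequal-variance t-test
#' with the Cochran-Cox approximation (continuous scales). Missing values
#' are dropped pairwise per feature.
#'
#' @param demographics one row per subject with the feature columns.
#' @param labels named character vector or data frame
#'   (`subject_id`, `label`) of engagement labels for the subjects to
#'   compare.
#' @param categorical,continuous feature column names; defaults cover the
#'   standard baseline profile (sex, race where present, marital status,
#'   employment, binned income, episode length, lifetime episodes,
#'   comorbidities; age and the HAMD-17 / QIDS-SR / SHAPS scales).
#' @return An object of class `group_comparison`: a data frame `report`
#'   (feature, type, statistic, df, p_value) and the per-feature detail
#'   objects.
#' @export
compare_groups <- function(demographics, labels,
                           categorical = c("sex", "marital_status",
                                           "employment", "monthly_income",
                                           "episode_length", "lifetime_mdes",
                                           "comorbidities"),
                           continuous = c("age", "hamd17_baseline",
                                          "qids_sr", "shaps")) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$subject_id)
  dem <- demographics[demographics$subject_id %in% names(labels), ]
  lab <- labels[dem$subject_id]
  categorical <- intersect(categorical, names(dem))
  continuous <- intersect(continuous, names(dem))
  unknown <- setdiff(c(categorical, continuous), names(dem))
  if (length(unknown) > 0L)
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  details <- list()
  rows <- list()
  for (f in categorical) {
    ok <- !is.na(dem[[f]])
    tab <- table(dem[[f]][ok], lab[ok])
    if (nrow(tab) < 2L || ncol(tab) < 2L)
      stop("degenerate table for feature '", f,
           "': fewer than two observed levels per margin", call. = FALSE)
    res <- chisq_independence(tab)
    details[[f]] <- list(table = tab, test = res)
    rows[[f]] <- data.frame(feature = f, type = "categorical",
                            statistic = res$statistic, df = res$df,
                            p_value = res$p_value,
                            stringsAsFactors = FALSE)
  }
  for (f in continuous) {
    ok <- !is.na(dem[[f]])
    res <- cochran_cox_ttest(dem[[f]][ok & lab == "disengaged"],
                             dem[[f]][ok & lab == "engaged"])
    details[[f]] <- res
    rows[[f]] <- data.frame(feature = f, type = "continuous",
                            statistic = res$statistic,
                            df = res$df_satterthwaite,
                            p_value = res$p_welch,
                            stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  structure(list(report = report, details = details),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Baseline feature comparison (disengaged vs engaged)\n")
  print(x$report, row.names = FALSE)
  invisible(x)
}
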