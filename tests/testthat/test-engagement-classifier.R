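test_that("the discriminant boundary solves known geometries", {
  # equal variances and priors: boundary is the midpoint
  eq <- qda_boundary(4.0, 1.0, 6.0, 1.0)
  expect_equal(eq$cutoff, 5.0, tolerance = 1e-10)

  # unequal variances: both roots of the quadratic, upper one operative
  b <- qda_boundary(4.6, 0.3, 4.9, 0.9)
  expect_equal(b$roots, c(4.0776, 5.0474), tolerance = 1e-4)
  expect_equal(b$cutoff, 5.0474, tolerance = 1e-4)

  expect_error(qda_boundary(5, 1, 5, 1), "no boundary")
  expect_error(qda_boundary(4, 0, 5, 1), "degenerate")
})

test_that("the analytic cutoff matches a dense grid search of the posterior crossing", {
  set.seed(55)
  n_checked <- 0L
  for (i in 1:60) {
    mu_hc <- runif(1, 3, 5); sd_hc <- runif(1, 0.2, 0.8)
    mu_mdd <- mu_hc + runif(1, 0.2, 1.5)
    sd_mdd <- sd_hc * runif(1, 1.3, 3)
    pri <- runif(1, 0.2, 0.8)
    x <- seq(mu_hc - 8 * sd_mdd, mu_hc + 8 * sd_mdd, length.out = 2e5)
    post <- log(1 - pri) + dnorm(x, mu_mdd, sd_mdd, log = TRUE) -
      log(pri) - dnorm(x, mu_hc, sd_hc, log = TRUE)
    sgn <- diff(sign(post))
    crossings <- x[which(sgn != 0)]
    upward <- x[which(sgn > 0)]       # MDD posterior takes over here
    b <- tryCatch(qda_boundary(mu_hc, sd_hc, mu_mdd, sd_mdd,
                               pri, 1 - pri),
                  error = function(e) e)
    if (inherits(b, "error")) {
      # the analytic no-boundary verdict must agree with the grid
      expect_length(crossings, 0L)
    } else {
      # same selection rule as the analytic path: smallest upward
      # crossing above the control mean, else the upward crossing itself
      cand <- upward[upward > mu_hc]
      grid_cut <- if (length(cand) > 0L) min(cand) else min(upward)
      expect_equal(b$cutoff, grid_cut, tolerance = diff(x[1:2]) * 2)
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 30L)
})

test_that("fitting, classification rule, and shift invariance behave as specified", {
  set.seed(8)
  hc <- rnorm(40, 4.6, 0.3)
  mdd <- c(rnorm(140, 4.6, 0.3), rnorm(60, 6.0, 0.5))
  m <- fit_qda_1d(mdd, hc, priors = "equal")
  expect_equal(m$prior_hc, 0.5)
  # boundary value labels disengaged (the >= rule)
  expect_equal(classify(m$cutoff, m), "disengaged")
  expect_equal(classify(m$cutoff - 1e-9, m), "engaged")
  # a value below both roots is engaged under the single-threshold rule
  expect_equal(classify(min(m$roots) - 1, m), "engaged")

  shifted <- fit_qda_1d(mdd + 10, hc + 10, priors = "equal")
  expect_equal(shifted$cutoff, m$cutoff + 10, tolerance = 1e-8)
  expect_identical(classify(mdd + 10, shifted), classify(mdd, m))

  # phenotypes 3 sd on each side of the boundary are recovered almost
  # perfectly when the model is fit on the two component distributions
  accs <- replicate(10, {
    engaged <- rnorm(140, 4.5, 0.3)
    disengaged <- rnorm(60, 6.3, 0.3)   # boundary near 5.4, 3 sd from each
    msep <- fit_qda_1d(disengaged, engaged, priors = "equal")
    truth <- rep(c("engaged", "disengaged"), c(140, 60))
    mean(classify(c(engaged, disengaged), msep) == truth)
  })
  expect_gt(mean(accs), 0.95)

  expect_error(fit_qda_1d(mdd, 4.6), "at least two")
  expect_error(fit_qda_1d(rep(5, 10), hc), "zero within-group variance")
})

test_that("fitted cutoffs recover the analytic boundary across replicates", {
  mu_hc <- 4.6; sd_hc <- 0.3; mu_mdd <- 4.9; sd_mdd <- 0.9
  truth <- qda_boundary(mu_hc, sd_hc, mu_mdd, sd_mdd)$cutoff
  set.seed(202)
  cuts <- replicate(200, {
    fit_qda_1d(rnorm(195, mu_mdd, sd_mdd), rnorm(40, mu_hc, sd_hc),
               priors = "equal")$cutoff
  })
  se <- sd(cuts) / sqrt(length(cuts))
  expect_lt(abs(mean(cuts) - truth), 2 * se + 0.02)
})

test_that("diagnostic statistics count the confusion table and bound it with valid CIs", {
  lab <- rep(c("disengaged", "engaged", "engaged", "disengaged"),
             c(9, 1, 8, 2))
  grp <- rep(c("MDD", "HC"), c(10, 10))
  d <- diagnostic_stats(lab, grp)
  expect_equal(d$sensitivity, 0.9)
  expect_equal(d$specificity, 0.8)
  expect_true(d$sensitivity_ci[1] <= 0.9 && 0.9 <= d$sensitivity_ci[2])
  expect_true(d$specificity_ci[1] <= 0.8 && 0.8 <= d$specificity_ci[2])

  perfect <- diagnostic_stats(rep(c("disengaged", "engaged"), c(5, 5)),
                              rep(c("MDD", "HC"), c(5, 5)))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)
  allpos <- diagnostic_stats(rep("disengaged", 10),
                             rep(c("MDD", "HC"), c(5, 5)))
  expect_equal(allpos$sensitivity, 1)
  expect_equal(allpos$specificity, 0)
  cp <- diagnostic_stats(lab, grp, ci_method = "clopper-pearson")
  expect_true(cp$sensitivity_ci[1] < d$sensitivity_ci[1])
})

test_that("the chi-square test equals the textbook sum over observed and expected counts", {
  expect_equal(chisq_independence(matrix(c(137, 35, 58, 5), 2))$statistic,
               5.03, tolerance = 0.005)
  prop <- matrix(c(10, 20, 30, 60), 2)   # proportional rows
  expect_equal(chisq_independence(prop)$statistic, 0, tolerance = 1e-12)

  set.seed(13)
  for (i in 1:25) {
    tab <- matrix(rpois(6, lambda = 30) + 1L, 2, 3)
    res <- chisq_independence(tab)
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    expect_equal(res$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
    expect_equal(res$df, 2)
  }
  expect_error(chisq_independence(matrix(c(0, 0, 5, 5), 2)),
               "zero marginal")
})

test_that("the unequal-variance t-test matches hand arithmetic and reduces to the pooled t", {
  same <- cochran_cox_ttest(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$statistic, 0)
  expect_false(same$significant)

  # equal n and variance: equals the pooled two-sample t statistic
  x <- c(1, 2, 3, 4, 5); y <- x + 2
  cc <- cochran_cox_ttest(x, y)
  pooled <- t.test(x, y, var.equal = TRUE)$statistic
  expect_equal(cc$statistic, unname(pooled), tolerance = 1e-12)

  # hand-computed oracle
  x <- c(1, 2, 3, 4, 5); y <- c(2, 4, 6, 8, 10, 12)
  cc <- cochran_cox_ttest(x, y)
  wx <- var(x) / 5; wy <- var(y) / 6
  expect_equal(cc$statistic, (3 - 7) / sqrt(wx + wy), tolerance = 1e-12)
  expect_equal(cc$df_satterthwaite,
               (wx + wy)^2 / (wx^2 / 4 + wy^2 / 5), tolerance = 1e-12)
  # the Cochran-Cox critical value is the variance-weighted Student value
  expect_equal(cc$critical_value,
               (wx * qt(0.975, 4) + wy * qt(0.975, 5)) / (wx + wy),
               tolerance = 1e-12)
  # inverting the critical value recovers |t| at the reported level
  a <- cc$p_cochran_cox
  crit_at_p <- (wx * qt(1 - a / 2, 4) + wy * qt(1 - a / 2, 5)) / (wx + wy)
  expect_equal(crit_at_p, abs(cc$statistic), tolerance = 1e-6)
  # Cochran-Cox is the more conservative of the two approximations
  expect_gte(cc$p_cochran_cox, cc$p_welch - 1e-12)
})

test_that("group comparison dispatches by feature type and controls its false positives", {
  coh <- simulate_cohort(small_cohort(seed = 88L))
  dem <- coh$demographics[coh$demographics$group == "MDD", ]
  set.seed(42)
  # labels independent of every feature
  n_sig <- 0L; n_feat <- 0L
  for (r in 1:12) {
    lab <- setNames(sample(c("engaged", "disengaged"), nrow(dem), TRUE,
                           prob = c(0.7, 0.3)), dem$subject_id)
    cmp <- compare_groups(dem, lab)
    n_sig <- n_sig + sum(cmp$report$p_value < 0.05)
    n_feat <- n_feat + nrow(cmp$report)
  }
  expect_lt(n_sig / n_feat, 0.15)
  cmp <- compare_groups(dem, setNames(
    ifelse(seq_len(nrow(dem)) %% 3L == 0L, "disengaged", "engaged"),
    dem$subject_id))
  expect_setequal(cmp$report$type, c("categorical", "continuous"))
  expect_true(all(c("sex", "monthly_income", "age", "shaps") %in%
                    cmp$report$feature))

  single <- dem; single$sex <- "female"
  lab <- setNames(rep(c("engaged", "disengaged"), length.out = nrow(dem)),
                  dem$subject_id)
  expect_error(compare_groups(single, lab, categorical = "sex",
                              continuous = character()),
               "degenerate table")
})
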