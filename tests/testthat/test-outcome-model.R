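# helper: simulate one trial's worth of outcome data with known structure
sim_visits <- function(seed, n = 80L, slopes = c(engaged_placebo = -3,
                                                 engaged_sertraline = -3,
                                                 disengaged_placebo = -1.5,
                                                 disengaged_sertraline = -4.5),
                       rho = 0.5, intercept_sd = 3, residual_sd = 3,
                       missing_prob = 0.05) {
  cfg <- cohort_config(n_mdd = n, n_hc = 10L, seed = seed)
  coh <- simulate_cohort(cfg)
  par <- outcome_gen_params(slopes = slopes, rho = rho,
                            intercept_sd = intercept_sd,
                            residual_sd = residual_sd,
                            missing_prob = missing_prob)
  v <- simulate_outcomes(coh$demographics, par, seed = seed + 1L)
  dem <- coh$demographics[coh$demographics$group == "MDD", ]
  list(visits = v, labels = setNames(dem$phenotype, dem$subject_id))
}

test_that("with no random intercept and independent residuals the likelihood matches least squares", {
  d <- sim_visits(301L, n = 60L, rho = 0, intercept_sd = 0,
                  missing_prob = 0)
  fit <- fit_moderation_model(d$visits, d$labels,
                              moderation_spec(method = "ML",
                                              random_intercept = FALSE,
                                              rho = 0))
  frame <- fit$data
  ols <- lm(hamd17 ~ baseline + treatment * label * logweek, data = frame)
  expect_equal(fit$logLik, as.numeric(logLik(ols)), tolerance = 1e-4)
  expect_equal(fit$varcomp$rho, 0)
})

test_that("the fit recovers generating variance components and the 3-way coefficient", {
  d <- sim_visits(117L, n = 160L)
  fit <- fit_moderation_model(d$visits, d$labels)
  expect_equal(fit$varcomp$rho, 0.5, tolerance = 0.25)
  expect_equal(fit$varcomp$intercept_sd, 3, tolerance = 1.2)
  # truth: (dis_sert - dis_plac) - (eng_sert - eng_plac) = -3
  expect_lt(abs(fit$interaction$estimate - (-3)) / fit$interaction$se, 3)
  expect_equal(fit$interaction$wald_chisq, fit$interaction$wald_z^2)
})

test_that("variance components are invariant to swapping factor reference levels", {
  d <- sim_visits(55L, n = 60L)
  fit <- fit_moderation_model(d$visits, d$labels)
  flipped <- ifelse(d$labels == "engaged", "disengaged", "engaged")
  names(flipped) <- names(d$labels)
  fit2 <- fit_moderation_model(d$visits, flipped)
  expect_equal(fit$varcomp$intercept_sd, fit2$varcomp$intercept_sd,
               tolerance = 1e-4)
  expect_equal(fit$varcomp$residual_sd, fit2$varcomp$residual_sd,
               tolerance = 1e-4)
  expect_equal(fit$varcomp$rho, fit2$varcomp$rho, tolerance = 1e-4)
  # the 3-way coefficient changes sign but not magnitude or test
  expect_equal(fit$interaction$estimate, -fit2$interaction$estimate,
               tolerance = 1e-4)
})

test_that("missing design cells are reported by name", {
  d <- sim_visits(66L, n = 40L)
  all_sert <- d$visits
  all_sert$treatment <- "sertraline"
  expect_error(fit_moderation_model(all_sert, d$labels),
               "empty design cell.*placebo")
})

test_that("fitted trajectories equal the linear predictor and expose the moderation pattern", {
  d <- sim_visits(204L, n = 160L)
  fit <- fit_moderation_model(d$visits, d$labels)
  traj <- fitted_trajectories(fit)
  expect_equal(nrow(traj), 24L)   # 6 weeks x 4 cells
  # closed-form check for one cell at one week
  beta <- setNames(fit$coef_table$estimate, fit$coef_table$term)
  w <- 6
  pred <- beta[["(Intercept)"]] + beta[["baseline"]] * mean(fit$data$baseline) +
    beta[["logweek"]] * log(w)
  expect_equal(traj$hamd17_hat[traj$week == w & traj$treatment == "placebo" &
                                 traj$label == "engaged"],
               unname(pred), tolerance = 1e-10)
  # under the generating slopes the disengaged-sertraline arm is lowest by week 8
  wk8 <- traj[traj$week == 8, ]
  expect_equal(wk8$treatment[which.min(wk8$hamd17_hat)], "sertraline")
  expect_equal(wk8$label[which.min(wk8$hamd17_hat)], "disengaged")
  expect_warning(fitted_trajectories(fit, weeks = c(8, 10)),
                 "extrapolating")
  expect_error(fitted_trajectories(fit, weeks = 0), "positive")
})
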