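# Repeated-measures mixed model of HAMD-17 trajectories. The residual
# spatial-power structure (correlation rho^|delta week| between visits
# delta week apart) is a continuous-time first-order autoregression over
# the real-valued week axis, so the unequal 4 -> 6 -> 8 week spacing is
# handled exactly; nlme's corCAR1 implements it.

#' Specification of the moderation model
#'
#' Fixed effects: baseline HAMD-17 (covariate), treatment, engagement
#' label, log(week), and all their interactions up to
#' treatment x label x log(week). Random intercept per subject; residual
#' correlation `rho^|delta week|` between a subject's visits. The
#' baseline week never enters the response (it is the covariate), so the
#' log transform only sees weeks >= 1.
#'
#' @param method `"REML"` (default) or `"ML"`.
#' @param random_intercept include the per-subject random intercept
#'   (default `TRUE`; `FALSE` fits a marginal model).
#' @param rho `NULL` to estimate the residual autocorrelation (profiled
#'   from the starts `rho_starts`), or a fixed value in `[0, 1)`; `0`
#'   fixes independent residuals.
#' @param rho_starts starting values tried when estimating `rho`; the fit
#'   with the best restricted likelihood wins.
#' @return An object of class `moderation_spec`.
#' @export
moderation_spec <- function(method = c("REML", "ML"),
                            random_intercept = TRUE, rho = NULL,
                            rho_starts = c(0.2, 0.5, 0.8)) {
  method <- match.arg(method)
  if (!is.null(rho) && (rho < 0 || rho >= 1))
    stop("fixed rho must lie in [0, 1)", call. = FALSE)
  structure(list(method = method, random_intercept = random_intercept,
                 rho = rho, rho_starts = rho_starts),
            class = "moderation_spec")
}

.build_model_frame <- function(visits, labels) {
  if (is.data.frame(labels))
    labels <- stats::setNames(labels$label, labels$subject_id)
  visits <- visits[visits$subject_id %in% names(labels), ]
  base <- visits[visits$week == 0, c("subject_id", "hamd17")]
  names(base)[2L] <- "baseline"
  post <- visits[visits$week > 0, ]
  d <- merge(post, base, by = "subject_id")
  d$label <- unname(labels[d$subject_id])
  d$logweek <- log(d$week)
  d$treatment <- factor(d$treatment, levels = c("placebo", "sertraline"))
  d$label <- factor(d$label, levels = c("engaged", "disengaged"))
  d <- d[order(d$subject_id, d$week), ]
  d
}

#' Fit the engagement-moderation mixed model
#'
#' Restricted-maximum-likelihood fit of HAMD-17 at weeks 1-8 on baseline
#' HAMD-17 plus the full treatment x engagement x log(week) factorial,
#' with a subject random intercept and spatial-power residual
#' correlation. The moderation hypothesis is the three-way
#' treatment x engagement x log(week) coefficient, tested by a
#' large-sample Wald z (primary) and reported alongside the fit's own
#' conditional t-test.
#'
#' @param visits a `prt_visits` data frame including the week-0 baseline
#'   visit per subject.
#' @param labels engagement labels: named character vector or data frame
#'   (`subject_id`, `label`).
#' @param spec a [moderation_spec()].
#' @return An object of class `moderation_fit`: coefficient table,
#'   variance components (`intercept_sd`, `residual_sd`, `rho`),
#'   `interaction` (estimate, se, Wald z/chi-square/p and the conditional
#'   t and df), the underlying `nlme` fit and the analysis frame.
#' @export
fit_moderation_model <- function(visits, labels,
                                 spec = moderation_spec()) {
  d <- .build_model_frame(visits, labels)
  cells <- table(d$treatment, d$label)
  if (any(cells == 0)) {
    empty <- which(cells == 0, arr.ind = TRUE)
    stop("rank deficiency: empty design cell(s): ",
         paste(rownames(cells)[empty[, 1L]], colnames(cells)[empty[, 2L]],
               sep = " x ", collapse = "; "), call. = FALSE)
  }
  nvis <- table(d$subject_id)
  if (mean(nvis >= 2) < 0.5)
    stop("fewer than half the subjects have two or more post-baseline ",
         "visits", call. = FALSE)

  form <- hamd17 ~ baseline + treatment * label * logweek
  make_cor <- function(value, fixed) {
    if (!is.null(value) && value == 0 && fixed) NULL
    else nlme::corCAR1(value = value %||% 0.2, form = ~ week | subject_id,
                       fixed = fixed)
  }
  fit_one <- function(start, fixed) {
    corr <- make_cor(start, fixed)
    if (spec$random_intercept)
      nlme::lme(form, random = ~ 1 | subject_id, correlation = corr,
                data = d, method = spec$method, na.action = stats::na.omit,
                control = nlme::lmeControl(opt = "optim", maxIter = 200,
                                           msMaxIter = 200, tolerance = 1e-8))
    else
      nlme::gls(form, correlation = corr, data = d, method = spec$method,
                control = nlme::glsControl(tolerance = 1e-8))
  }
  if (is.null(spec$rho)) {
    fits <- list()
    for (s in spec$rho_starts) {
      f <- tryCatch(fit_one(s, fixed = FALSE), error = function(e) e)
      if (!inherits(f, "error")) fits[[length(fits) + 1L]] <- f
    }
    if (length(fits) == 0L) {
      f <- tryCatch(fit_one(spec$rho_starts[1L], fixed = FALSE),
                    error = identity)
      stop("mixed model failed to converge from all starting values ",
           "(rho starts ", paste(spec$rho_starts, collapse = ", "),
           "); last error: ", conditionMessage(f), call. = FALSE)
    }
    fit <- fits[[which.max(vapply(fits, stats::logLik, numeric(1L)))]]
  } else {
    fit <- fit_one(spec$rho, fixed = TRUE)
  }

  tt <- if (inherits(fit, "lme")) summary(fit)$tTable else {
    ct <- summary(fit)$tTable
    cbind(ct[, 1:2], DF = NA, ct[, 3:4])
  }
  coef_table <- data.frame(term = rownames(tt), estimate = tt[, 1L],
                           se = tt[, 2L], stringsAsFactors = FALSE)
  rownames(coef_table) <- NULL

  term <- "treatmentsertraline:labeldisengaged:logweek"
  i <- match(term, rownames(tt))
  est <- tt[i, 1L]; se <- tt[i, 2L]
  z <- est / se
  rho_hat <- if (!is.null(fit$modelStruct$corStruct))
    unname(stats::coef(fit$modelStruct$corStruct, unconstrained = FALSE))
  else 0
  vc <- if (inherits(fit, "lme")) {
    v <- nlme::VarCorr(fit)
    c(intercept_sd = as.numeric(v["(Intercept)", "StdDev"]),
      residual_sd = as.numeric(v["Residual", "StdDev"]))
  } else c(intercept_sd = 0, residual_sd = fit$sigma)

  structure(list(
    coef_table = coef_table,
    varcomp = list(intercept_sd = unname(vc["intercept_sd"]),
                   residual_sd = unname(vc["residual_sd"]),
                   rho = rho_hat),
    interaction = list(term = term, estimate = est, se = se,
                       wald_z = z, wald_chisq = z^2,
                       p_value = 2 * stats::pnorm(-abs(z)),
                       t_value = tt[i, ncol(tt) - 1L],
                       t_df = if (inherits(fit, "lme")) tt[i, 3L] else NA,
                       p_conditional_t = tt[i, ncol(tt)]),
    logLik = as.numeric(stats::logLik(fit)),
    method = spec$method,
    fit = fit, data = d), class = "moderation_fit")
}

#' @export
print.moderation_fit <- function(x, ...) {
  cat("Engagement-moderation mixed model (", x$method, ")\n", sep = "")
  cat(sprintf("  random intercept sd %.3f, residual sd %.3f, rho %.3f\n",
              x$varcomp$intercept_sd, x$varcomp$residual_sd, x$varcomp$rho))
  with(x$interaction, cat(sprintf(
    "  3-way interaction %s:\n    estimate %.4f (se %.4f), Wald z = %.3f, p = %.4g\n",
    term, estimate, se, wald_z, p_value)))
  invisible(x)
}

#' Fitted mean trajectories per treatment-by-engagement cell
#'
#' Evaluates the fitted fixed-effect predictor at the mean baseline for
#' each of the four cells over the requested weeks.
#'
#' @param result a `moderation_fit`.
#' @param weeks positive weeks at which to predict (default the visit
#'   schedule 1, 2, 3, 4, 6, 8). Weeks beyond 8 trigger an extrapolation
#'   warning.
#' @return Data frame `week`, `treatment`, `label`, `hamd17_hat`.
#' @export
fitted_trajectories <- function(result, weeks = c(1, 2, 3, 4, 6, 8)) {
  if (any(weeks <= 0))
    stop("weeks must be positive (baseline is a covariate, not a ",
         "predicted visit)", call. = FALSE)
  if (any(weeks > 8))
    warning("extrapolating beyond week 8")
  grid <- expand.grid(week = weeks,
                      treatment = c("placebo", "sertraline"),
                      label = c("engaged", "disengaged"),
                      stringsAsFactors = FALSE)
  grid$logweek <- log(grid$week)
  grid$baseline <- mean(result$data$baseline)
  grid$treatment <- factor(grid$treatment,
                           levels = c("placebo", "sertraline"))
  grid$label <- factor(grid$label, levels = c("engaged", "disengaged"))
  X <- stats::model.matrix(~ baseline + treatment * label * logweek, grid)
  beta <- stats::setNames(result$coef_table$estimate,
                          result$coef_table$term)
  grid$hamd17_hat <- as.numeric(X %*% beta[colnames(X)])
  grid$treatment <- as.character(grid$treatment)
  grid$label <- as.character(grid$label)
  grid[, c("week", "treatment", "label", "hamd17_hat")]
}

#' Plot fitted HAMD-17 trajectories
#'
#' Minimal panel plot of the fitted mean trajectories, one panel per
#' engagement label with one line per treatment arm. Requires ggplot2.
#'
#' @param result a `moderation_fit`.
#' @param weeks weeks at which to draw the curves.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(result, weeks = c(1, 2, 3, 4, 6, 8)) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  traj <- fitted_trajectories(result, weeks)
  ggplot2::ggplot(traj, ggplot2::aes(x = week, y = hamd17_hat,
                                     linetype = treatment)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~label) +
    ggplot2::labs(x = "Week", y = "Fitted HAMD-17",
                  linetype = "Treatment") +
    ggplot2::theme_minimal()
}
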