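# Parametric cohort simulator. Sessions come from an equal-variance
# Gaussian signal-detection agent whose block-2 criterion has moved a
# fraction `engagement` of the way from its starting point toward the
# reward-maximizing criterion; HAMD-17 trajectories follow the same
# mixed-model structure that the outcome module fits.

#' Reward schedule configuration
#'
#' The PRT reinforcement schedule: trials per block, reward magnitude and
#' per-block reward targets. The default 30 rich + 10 lean rewards per
#' 100-trial block realises the canonical 3:1 rich:lean asymmetry with
#' equiprobable stimuli; other published variants (e.g. 40:13) are
#' reachable through the targets.
#'
#' @param trials_per_block trials in each block (default 100).
#' @param blocks number of blocks (default 2).
#' @param reward_cents reward magnitude in cents (default 20).
#' @param target_rich_rewards,target_lean_rewards rewards scheduled per
#'   block for the rich and lean stimulus (defaults 30 and 10).
#' @param stimulus_probability_rich probability a trial shows the rich
#'   stimulus (default 0.5).
#' @return An object of class `schedule_config`; `rich_lean_ratio` is
#'   derived from the targets.
#' @export
schedule_config <- function(trials_per_block = 100L, blocks = 2L,
                            reward_cents = 20,
                            target_rich_rewards = 30L,
                            target_lean_rewards = 10L,
                            stimulus_probability_rich = 0.5) {
  if (trials_per_block < 1L || blocks < 1L)
    stop("schedule config error: need at least one trial and one block",
         call. = FALSE)
  if (target_rich_rewards + target_lean_rewards > trials_per_block)
    stop("schedule config error: reward targets exceed trials per block",
         call. = FALSE)
  exp_rich <- trials_per_block * stimulus_probability_rich
  exp_lean <- trials_per_block * (1 - stimulus_probability_rich)
  if (target_rich_rewards > exp_rich || target_lean_rewards > exp_lean)
    stop("schedule config error: reward targets exceed expected correct ",
         "responses per stimulus", call. = FALSE)
  structure(list(
    trials_per_block = as.integer(trials_per_block),
    blocks = as.integer(blocks),
    reward_cents = reward_cents,
    target_rich_rewards = as.integer(target_rich_rewards),
    target_lean_rewards = as.integer(target_lean_rewards),
    rich_lean_ratio = target_rich_rewards / target_lean_rewards,
    stimulus_probability_rich = stimulus_probability_rich),
    class = "schedule_config")
}

#' Payoff structure implied by a reward schedule
#'
#' Converts per-block reward targets into the per-stimulus reward
#' probabilities of [payoff_structure()]: a scheduled target of 30 rich
#' rewards among an expected 50 rich trials gives
#' `p_reward_given_correct_rich = 0.6`.
#'
#' @param schedule a [schedule_config()].
#' @return A [payoff_structure()].
#' @export
payoff_from_schedule <- function(schedule) {
  exp_rich <- schedule$trials_per_block * schedule$stimulus_probability_rich
  exp_lean <- schedule$trials_per_block - exp_rich
  payoff_structure(
    reward_cents = schedule$reward_cents,
    p_reward_given_correct_rich = schedule$target_rich_rewards / exp_rich,
    p_reward_given_correct_lean = schedule$target_lean_rewards / exp_lean,
    stimulus_probability_rich = schedule$stimulus_probability_rich)
}

#' Signal-detection agent parameters
#'
#' @param d_prime perceptual sensitivity (nonnegative).
#' @param criterion_start decision criterion in block 1 (default 0,
#'   neutral; positive values favor "lean" responses).
#' @param engagement fraction in `[0, 1]` of the distance from
#'   `criterion_start` toward the reward-maximizing criterion traversed by
#'   block 2. 1 = fully engaged (optimal by block 2), 0 = no adjustment.
#' @param lapse_rate probability of replacing the evidence-based response
#'   with a uniform random one.
#' @param rt_mean_ms,rt_sd_ms optional Gaussian reaction-time parameters;
#'   `NULL` omits reaction times.
#' @return An object of class `agent_params`.
#' @export
agent_params <- function(d_prime = 1.5, criterion_start = 0,
                         engagement = 0.8, lapse_rate = 0.05,
                         rt_mean_ms = NULL, rt_sd_ms = NULL) {
  if (d_prime < 0) stop("d_prime must be nonnegative", call. = FALSE)
  if (engagement < 0 || engagement > 1)
    stop("engagement must lie in [0, 1]", call. = FALSE)
  if (lapse_rate < 0 || lapse_rate > 1)
    stop("lapse_rate must lie in [0, 1]", call. = FALSE)
  structure(list(d_prime = d_prime, criterion_start = criterion_start,
                 engagement = engagement, lapse_rate = lapse_rate,
                 rt_mean_ms = rt_mean_ms, rt_sd_ms = rt_sd_ms),
            class = "agent_params")
}

# Controlled reward scheduler for one block: `target` rewards are attached
# to randomly chosen trials of each stimulus; a reward whose trial is
# answered incorrectly stays pending and is delivered at the next correct
# response to the owed stimulus. Guarantees rewarded => correct and
# delivered <= target.
.deliver_rewards <- function(stimulus, correct, target_rich, target_lean) {
  n <- length(stimulus)
  scheduled <- logical(n)
  for (stim in c("rich", "lean")) {
    idx <- which(stimulus == stim)
    tgt <- if (stim == "rich") target_rich else target_lean
    k <- min(tgt, length(idx))
    if (k > 0L) scheduled[sample(idx, k)] <- TRUE
  }
  rewarded <- logical(n)
  pending <- c(rich = 0L, lean = 0L)
  for (i in seq_len(n)) {
    s <- stimulus[i]
    if (scheduled[i]) pending[s] <- pending[s] + 1L
    if (correct[i] && pending[s] > 0L) {
      rewarded[i] <- TRUE
      pending[s] <- pending[s] - 1L
    }
  }
  rewarded
}

#' Simulate one PRT session
#'
#' Draws stimuli, evidence and responses for all blocks of one subject.
#' Evidence is unit-variance Gaussian centered at `+d'/2` (rich) or
#' `-d'/2` (lean); the response is "rich" iff evidence exceeds the block's
#' criterion, overridden by a uniform random response with probability
#' `lapse_rate`. The block-2 criterion is
#' `criterion_start + engagement * (c_opt - criterion_start)` with `c_opt`
#' from [optimal_criterion()] under the schedule's payoff. Rewards are
#' delivered by the controlled scheduler (pending rewards carry to the
#' next correct response of the owed stimulus).
#'
#' @param agent an [agent_params()].
#' @param schedule a [schedule_config()].
#' @param seed integer seed; the session is a pure function of
#'   (agent, schedule, seed).
#' @param subject_id,group identifiers stamped on each trial.
#' @return A validated `prt_trials` data frame.
#' @export
simulate_session <- function(agent, schedule = schedule_config(), seed = 1L,
                             subject_id = "s1", group = "MDD") {
  set.seed(seed)
  payoff <- payoff_from_schedule(schedule)
  d <- agent$d_prime
  c_opt <- optimal_criterion(payoff, max(d, 1e-6))
  crits <- c(agent$criterion_start,
             agent$criterion_start +
               agent$engagement * (c_opt - agent$criterion_start))
  crits <- rep_len(crits, schedule$blocks)

  blocks <- lapply(seq_len(schedule$blocks), function(b) {
    n <- schedule$trials_per_block
    stim <- ifelse(stats::runif(n) < schedule$stimulus_probability_rich,
                   "rich", "lean")
    evid <- stats::rnorm(n, mean = ifelse(stim == "rich", d / 2, -d / 2))
    resp <- ifelse(evid > crits[b], "rich", "lean")
    lapse <- stats::runif(n) < agent$lapse_rate
    resp[lapse] <- ifelse(stats::runif(sum(lapse)) < 0.5, "rich",
                          "lean")[seq_len(sum(lapse))]
    correct <- resp == stim
    rewarded <- .deliver_rewards(stim, correct,
                                 schedule$target_rich_rewards,
                                 schedule$target_lean_rewards)
    rt <- if (!is.null(agent$rt_mean_ms))
      pmax(0, stats::rnorm(n, agent$rt_mean_ms, agent$rt_sd_ms %||% 0))
    else NA_real_
    data.frame(subject_id = subject_id, group = group, block = b,
               trial = seq_len(n), stimulus = stim, response = resp,
               correct = correct, rewarded = rewarded, rt_ms = rt,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)
  validate_trials(out)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generating parameters for HAMD-17 trajectories
#'
#' Mirrors the structure of the fitted outcome model: latent baseline plus
#' a per-cell slope on log(week), a subject random intercept, and
#' residuals with continuous-time first-order autoregressive correlation
#' `rho^|delta week|`. The default slopes give sertraline an advantage
#' over placebo only in the disengaged phenotype, with no drug-placebo
#' separation among the engaged.
#'
#' @param baseline_mean,baseline_sd latent baseline HAMD-17 distribution
#'   (defaults 22 and 4: moderate-to-severe depression).
#' @param slopes named numeric vector of HAMD-17 change per unit log(week)
#'   for the four treatment-by-phenotype cells (`engaged_placebo`,
#'   `engaged_sertraline`, `disengaged_placebo`, `disengaged_sertraline`).
#' @param intercept_sd subject random-intercept standard deviation.
#' @param residual_sd visit-level residual standard deviation.
#' @param rho residual autocorrelation per unit week, in `(-1, 1)`.
#' @param missing_prob probability a post-baseline visit is missing
#'   completely at random (default 0.05).
#' @return An object of class `outcome_gen_params`.
#' @export
outcome_gen_params <- function(baseline_mean = 22, baseline_sd = 4,
                               slopes = c(engaged_placebo = -3.0,
                                          engaged_sertraline = -3.0,
                                          disengaged_placebo = -1.5,
                                          disengaged_sertraline = -4.5),
                               intercept_sd = 3, residual_sd = 3,
                               rho = 0.5, missing_prob = 0.05) {
  need <- c("engaged_placebo", "engaged_sertraline",
            "disengaged_placebo", "disengaged_sertraline")
  if (!all(need %in% names(slopes)))
    stop("slopes must name all four treatment x phenotype cells",
         call. = FALSE)
  if (baseline_sd < 0 || intercept_sd < 0 || residual_sd < 0)
    stop("standard deviations must be nonnegative", call. = FALSE)
  if (abs(rho) >= 1) stop("|rho| must be < 1", call. = FALSE)
  if (missing_prob < 0 || missing_prob > 1)
    stop("missing_prob must lie in [0, 1]", call. = FALSE)
  structure(list(baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 slopes = slopes[need], intercept_sd = intercept_sd,
                 residual_sd = residual_sd, rho = rho,
                 missing_prob = missing_prob),
            class = "outcome_gen_params")
}

#' Cohort configuration
#'
#' Study conditions for the simulator: group sizes, the engaged/disengaged
#' mixture within the depressed group, and the phenotype-level agent
#' parameter distributions. Defaults emulate a 195 MDD + 40 HC sample with
#' a 30% disengaged fraction; healthy controls and engaged MDD share an
#' agent distribution that moves most of the way to the optimal criterion
#' by block 2, while disengaged MDD barely adjust.
#'
#' @param n_mdd,n_hc group sizes (defaults 195 and 40).
#' @param mdd_disengaged_fraction probability an MDD subject belongs to
#'   the disengaged phenotype (default 0.30).
#' @param engaged,disengaged,hc per-phenotype parameter distributions:
#'   lists with elements `d_prime_mean`, `d_prime_sd`, `engagement_mean`,
#'   `engagement_sd`, `lapse_rate`. The defaults realise well-separated
#'   phenotypes: engaged subjects (and controls) traverse most of the
#'   distance to the optimal criterion and respond consistently, while
#'   disengaged subjects barely adjust their criterion and lapse into
#'   random responding on a fifth of trials — haphazard responding being
#'   part of the disengagement construct itself.
#' @param schedule a [schedule_config()].
#' @param outcome an [outcome_gen_params()].
#' @param seed integer seed.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_mdd = 195L, n_hc = 40L,
                          mdd_disengaged_fraction = 0.30,
                          engaged = list(d_prime_mean = 1.0, d_prime_sd = 0.15,
                                         engagement_mean = 0.85,
                                         engagement_sd = 0.05,
                                         lapse_rate = 0.02),
                          disengaged = list(d_prime_mean = 1.0,
                                            d_prime_sd = 0.15,
                                            engagement_mean = 0.05,
                                            engagement_sd = 0.03,
                                            lapse_rate = 0.20),
                          hc = list(d_prime_mean = 1.0, d_prime_sd = 0.15,
                                    engagement_mean = 0.85,
                                    engagement_sd = 0.05,
                                    lapse_rate = 0.02),
                          schedule = schedule_config(),
                          outcome = outcome_gen_params(),
                          seed = 1L) {
  if (mdd_disengaged_fraction < 0 || mdd_disengaged_fraction > 1)
    stop("mdd_disengaged_fraction must lie in [0, 1]", call. = FALSE)
  if (n_mdd < 0L || n_hc < 0L) stop("group sizes must be nonnegative",
                                    call. = FALSE)
  structure(list(n_mdd = as.integer(n_mdd), n_hc = as.integer(n_hc),
                 mdd_disengaged_fraction = mdd_disengaged_fraction,
                 engaged = engaged, disengaged = disengaged, hc = hc,
                 schedule = schedule, outcome = outcome,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

.draw_agent <- function(pheno) {
  agent_params(
    d_prime = max(0.2, stats::rnorm(1L, pheno$d_prime_mean,
                                    pheno$d_prime_sd)),
    criterion_start = 0,
    engagement = min(1, max(0, stats::rnorm(1L, pheno$engagement_mean,
                                            pheno$engagement_sd))),
    lapse_rate = pheno$lapse_rate)
}

#' Simulate a full cohort
#'
#' Draws phenotype labels for the depressed group, samples agent
#' parameters per subject, simulates every PRT session, randomizes MDD
#' subjects 1:1 to sertraline or placebo, and samples demographics with
#' margins resembling a moderate-to-severe outpatient depression sample.
#' The true phenotype is retained in the demographics table for recovery
#' tests.
#'
#' @param config a [cohort_config()].
#' @return List with `trials` (a `prt_trials` data frame for all
#'   subjects) and `demographics` (one row per subject: group, true
#'   phenotype, treatment, age, sex, baseline scales, binned
#'   sociodemographic features).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  n <- config$n_mdd + config$n_hc
  ids <- sprintf("S%04d", seq_len(n))
  group <- c(rep("MDD", config$n_mdd), rep("HC", config$n_hc))
  phenotype <- ifelse(
    group == "HC", "engaged",
    ifelse(stats::runif(n) < config$mdd_disengaged_fraction,
           "disengaged", "engaged"))
  treatment <- ifelse(group == "MDD",
                      ifelse(seq_len(n) %% 2L == 1L, "sertraline", "placebo"),
                      NA_character_)
  # randomize the alternation so arms are exchangeable
  mdd_idx <- which(group == "MDD")
  treatment[mdd_idx] <- sample(treatment[mdd_idx])

  session_seeds <- sample.int(.Machine$integer.max, n)
  agents <- lapply(seq_len(n), function(i) {
    pheno <- if (group[i] == "HC") config$hc
             else if (phenotype[i] == "disengaged") config$disengaged
             else config$engaged
    .draw_agent(pheno)
  })
  set.seed(config$seed + 1L)
  age <- round(pmin(65, pmax(18, stats::rnorm(n, 37.3, 13.5))))
  sex <- ifelse(stats::runif(n) < 0.655, "female", "male")
  education_years <- round(pmin(22, pmax(8, stats::rnorm(n, 15, 2.4))))
  is_mdd <- group == "MDD"
  hamd17_baseline <- ifelse(is_mdd,
                            round(pmin(40, pmax(14, stats::rnorm(n, 22, 4)))),
                            round(pmax(0, stats::rnorm(n, 1.5, 1.5))))
  qids_sr <- ifelse(is_mdd,
                    round(pmin(27, pmax(15, stats::rnorm(n, 17.5, 2)))),
                    round(pmin(7, pmax(0, stats::rnorm(n, 3, 2)))))
  shaps <- ifelse(is_mdd,
                  round(pmin(56, pmax(14, stats::rnorm(n, 33, 7)))),
                  round(pmin(56, pmax(14, stats::rnorm(n, 21, 4)))))
  monthly_income <- sample(c("<2000", "2000-4000", ">4000"), n, TRUE,
                           prob = c(0.50, 0.29, 0.21))
  episode_length <- ifelse(is_mdd,
                           sample(c("0-6mo", "7-24mo", ">24mo"), n, TRUE,
                                  prob = c(0.35, 0.26, 0.39)),
                           NA_character_)
  lifetime_mdes <- ifelse(is_mdd,
                          sample(c("<3", "3-5", ">5"), n, TRUE,
                                 prob = c(0.26, 0.19, 0.55)),
                          NA_character_)
  comorbidities <- sample(c("0", "1", "2", "3+"), n, TRUE,
                          prob = c(0.45, 0.12, 0.15, 0.28))
  marital <- sample(c("married_partnered", "single"), n, TRUE,
                    prob = c(0.21, 0.79))
  employment <- sample(c("full-time", "part-time", "unemployed"), n, TRUE,
                       prob = c(0.28, 0.24, 0.48))

  trials <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_session(agents[[i]], config$schedule,
                     seed = session_seeds[i],
                     subject_id = ids[i], group = group[i])))
  demographics <- data.frame(
    subject_id = ids, group = group, phenotype = phenotype,
    treatment = treatment, age = age, sex = sex,
    education_years = education_years,
    hamd17_baseline = hamd17_baseline, qids_sr = qids_sr, shaps = shaps,
    monthly_income = monthly_income, episode_length = episode_length,
    lifetime_mdes = lifetime_mdes, comorbidities = comorbidities,
    marital_status = marital, employment = employment,
    stringsAsFactors = FALSE)
  list(trials = validate_trials(trials), demographics = demographics)
}

#' Simulate longitudinal HAMD-17 outcomes
#'
#' Generates visits at weeks 0, 1, 2, 3, 4, 6 and 8 for the depressed
#' subjects of a cohort:
#' `hamd(w) = baseline + b_i + slope(cell) * log(w) + e(w)` for `w >= 1`
#' (the log term is zero at baseline), with subject random intercept
#' `b_i`, residuals autocorrelated as `rho^|delta week|`, and values
#' rounded then clamped to 0..52 after noise. Post-baseline visits are
#' dropped completely at random with probability `missing_prob`; the
#' baseline visit is always retained.
#'
#' @param demographics cohort demographics from [simulate_cohort()]; must
#'   carry `treatment` and true `phenotype` for the MDD rows.
#' @param params an [outcome_gen_params()].
#' @param seed integer seed.
#' @return A validated `prt_visits` data frame.
#' @export
simulate_outcomes <- function(demographics, params = outcome_gen_params(),
                              seed = 1L) {
  set.seed(seed)
  dem <- demographics[demographics$group == "MDD", ]
  if (nrow(dem) == 0L)
    stop("no MDD subjects with treatment assignments", call. = FALSE)
  if (any(is.na(dem$treatment)))
    stop("all MDD subjects need a treatment assignment", call. = FALSE)
  weeks <- c(0, 1, 2, 3, 4, 6, 8)
  rows <- lapply(seq_len(nrow(dem)), function(i) {
    cell <- paste(dem$phenotype[i], dem$treatment[i], sep = "_")
    slope <- params$slopes[[cell]]
    base <- stats::rnorm(1L, params$baseline_mean, params$baseline_sd)
    b <- stats::rnorm(1L, 0, params$intercept_sd)
    e <- numeric(length(weeks))
    e[1L] <- stats::rnorm(1L, 0, params$residual_sd)
    for (j in 2L:length(weeks)) {
      r <- params$rho ^ (weeks[j] - weeks[j - 1L])
      e[j] <- r * e[j - 1L] +
        stats::rnorm(1L, 0, params$residual_sd * sqrt(1 - r^2))
    }
    logw <- ifelse(weeks > 0, log(weeks), 0)
    mu <- base + ifelse(weeks > 0, b + slope * logw, 0)
    hamd <- pmin(52, pmax(0, round(mu + e)))
    keep <- c(TRUE, stats::runif(length(weeks) - 1L) >= params$missing_prob)
    data.frame(subject_id = dem$subject_id[i], week = weeks,
               hamd17 = as.integer(hamd), treatment = dem$treatment[i],
               stringsAsFactors = FALSE)[keep, ]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  validate_visits(out)
  out
}
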