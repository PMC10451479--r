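# In-code fixtures shared across test files.

# one hand-built 8-trial session (4 trials per block, balanced stimuli)
toy_session <- function() {
  data.frame(
    subject_id = "T1", group = "MDD",
    block    = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L),
    trial    = c(1L, 2L, 3L, 4L, 1L, 2L, 3L, 4L),
    stimulus = c("rich", "rich", "lean", "lean",
                 "rich", "lean", "rich", "lean"),
    response = c("rich", "lean", "lean", "rich",
                 "rich", "lean", "rich", "rich"),
    correct  = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE),
    rewarded = c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE),
    rt_ms    = NA_real_,
    stringsAsFactors = FALSE)
}

# block-count row builder
counts_row <- function(rc, ri, lc, li, subject_id = "x", block = 2L) {
  data.frame(subject_id = subject_id, block = block,
             rich_correct = rc, rich_incorrect = ri,
             lean_correct = lc, lean_incorrect = li,
             n_trials = rc + ri + lc + li,
             rewards_delivered = 0L, stringsAsFactors = FALSE)
}

# block counts consistent with a Gaussian operating point (c, d'), using
# huge per-stimulus totals so quantization is negligible
counts_from_point <- function(c_hat, d_hat, n_per_stim = 1e6) {
  h <- pnorm(d_hat / 2 - c_hat)
  f <- pnorm(-d_hat / 2 - c_hat)
  counts_row(round(h * n_per_stim), round((1 - h) * n_per_stim),
             round((1 - f) * n_per_stim), round(f * n_per_stim))
}

# small cohort configuration that keeps simulation-heavy tests quick
small_cohort <- function(seed = 402L, n_mdd = 60L, n_hc = 20L) {
  cohort_config(n_mdd = n_mdd, n_hc = n_hc, seed = seed)
}
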