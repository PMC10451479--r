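# Classical PRT signal-detection measures. Conventions follow the PRT
# literature: base-10 logarithms; when any cell of the 2x2 tally is zero,
# 0.5 is added to every cell (all-or-none) so both indices stay finite.

#' Tabulate per-block signal-detection counts
#'
#' Collapses a trial table into one row per subject and block holding the
#' 2x2 stimulus-by-accuracy tally and the number of rewards delivered.
#'
#' @param trials a `prt_trials` data frame (see [validate_trials()]).
#' @return Data frame with columns `subject_id`, `group`, `block`,
#'   `rich_correct`, `rich_incorrect`, `lean_correct`, `lean_incorrect`,
#'   `n_trials`, `rewards_delivered`. Cells partition the block's trials.
#' @export
tabulate_blocks <- function(trials) {
  trials <- validate_trials(trials)
  key <- interaction(trials$subject_id, trials$block, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(trials)), key), function(idx) {
    tr <- trials[idx, ]
    data.frame(
      subject_id     = tr$subject_id[1L],
      group          = tr$group[1L],
      block          = tr$block[1L],
      rich_correct   = sum(tr$stimulus == "rich" & tr$correct),
      rich_incorrect = sum(tr$stimulus == "rich" & !tr$correct),
      lean_correct   = sum(tr$stimulus == "lean" & tr$correct),
      lean_incorrect = sum(tr$stimulus == "lean" & !tr$correct),
      n_trials       = nrow(tr),
      rewards_delivered = sum(tr$rewarded),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$subject_id, out$block), ]
  rownames(out) <- NULL
  out
}

.sdt_cells <- function(counts) {
  cells <- cbind(counts$rich_correct, counts$rich_incorrect,
                 counts$lean_correct, counts$lean_incorrect)
  if (any(cells < 0)) stop("negative cell count", call. = FALSE)
  corrected <- apply(cells == 0, 1L, any)
  cells[corrected, ] <- cells[corrected, , drop = FALSE] + 0.5
  list(cells = cells, corrected = corrected)
}

#' Response bias (log b)
#'
#' Signal-detection index of the systematic preference for the rich
#' response: `0.5 * log10((rich_correct * lean_incorrect) /
#' (rich_incorrect * lean_correct))`. Positive values indicate a bias
#' toward the rich stimulus.
#'
#' @param counts data frame of block counts as returned by
#'   [tabulate_blocks()] (only the four cell columns are used); vectorized
#'   over rows.
#' @return Numeric vector of log b values, zero-cell corrected.
#' @export
response_bias <- function(counts) {
  s <- .sdt_cells(counts)
  0.5 * log10((s$cells[, 1L] * s$cells[, 4L]) /
                (s$cells[, 2L] * s$cells[, 3L]))
}

#' Discriminability (log d)
#'
#' Signal-detection index of perceptual accuracy independent of bias:
#' `0.5 * log10((rich_correct * lean_correct) /
#' (rich_incorrect * lean_incorrect))`.
#'
#' @inheritParams response_bias
#' @return Numeric vector of log d values, zero-cell corrected.
#' @export
discriminability <- function(counts) {
  s <- .sdt_cells(counts)
  0.5 * log10((s$cells[, 1L] * s$cells[, 3L]) /
                (s$cells[, 2L] * s$cells[, 4L]))
}

#' Per-block signal-detection measure table
#'
#' @param counts block count table from [tabulate_blocks()].
#' @return `counts` augmented with `log_b`, `log_d` and
#'   `correction_applied` (whether the 0.5 zero-cell correction was used).
#' @export
sdt_measures <- function(counts) {
  s <- .sdt_cells(counts)
  data.frame(
    subject_id = counts$subject_id,
    block      = counts$block,
    log_b      = response_bias(counts),
    log_d      = discriminability(counts),
    correction_applied = s$corrected,
    stringsAsFactors = FALSE)
}
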