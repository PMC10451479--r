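#' @keywords internal
"_PACKAGE"

# Column schemas for the delimited-text interchange files. Booleans travel as
# 0/1, missing reaction times as empty fields; weeks are numeric.
.trial_cols <- c("subject_id", "group", "block", "trial", "stimulus",
                 "response", "correct", "rewarded", "rt_ms")
.visit_cols <- c("subject_id", "week", "hamd17", "treatment")

#' Validate a trial-level PRT table
#'
#' Checks the invariants of the trial schema: `correct` must equal
#' `response == stimulus`, rewards are only delivered on correct trials,
#' blocks are 1 or 2, trial indices are unique within subject and block, and
#' every block of a subject holds the same number of trials.
#'
#' @param trials data frame with columns `subject_id`, `group` (`"MDD"` or
#'   `"HC"`), `block` (1 or 2), `trial` (index within block), `stimulus` and
#'   `response` (`"rich"` or `"lean"`), logical `correct` and `rewarded`, and
#'   optional numeric `rt_ms`.
#' @return The input, invisibly, with class `prt_trials` prepended. Errors
#'   identify the offending rows.
#' @export
validate_trials <- function(trials) {
  missing <- setdiff(setdiff(.trial_cols, "rt_ms"), names(trials))
  if (length(missing) > 0L)
    stop("trial table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_

  bad_level <- function(x, levels) which(!is.na(x) & !x %in% levels)
  for (col in c("stimulus", "response")) {
    bad <- bad_level(trials[[col]], c("rich", "lean"))
    if (length(bad) > 0L)
      stop("trial table value error: non-binary ", col, " in row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  }
  bad <- bad_level(trials$group, c("MDD", "HC"))
  if (length(bad) > 0L)
    stop("trial table value error: group must be MDD or HC, row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!trials$block %in% c(1L, 2L))
  if (length(bad) > 0L)
    stop("trial table value error: block must be 1 or 2, row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)

  bad <- which(trials$correct != (trials$response == trials$stimulus))
  if (length(bad) > 0L)
    stop("trial table integrity error: correct disagrees with ",
         "response == stimulus in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(trials$rewarded & !trials$correct)
  if (length(bad) > 0L)
    stop("trial table integrity error: rewarded on incorrect trial in ",
         "row(s) ", paste(utils::head(bad, 5L), collapse = ", "),
         call. = FALSE)

  key <- paste(trials$subject_id, trials$block, trials$trial)
  if (anyDuplicated(key))
    stop("trial table integrity error: duplicate subject x block x trial ",
         "in row(s) ",
         paste(utils::head(which(duplicated(key)), 5L), collapse = ", "),
         call. = FALSE)

  per_block <- table(trials$subject_id, trials$block)
  if (nrow(per_block) > 0L && length(unique(per_block[per_block > 0])) > 1L)
    stop("trial table integrity error: unequal trial counts across ",
         "subject-blocks", call. = FALSE)

  class(trials) <- unique(c("prt_trials", class(trials)))
  invisible(trials)
}

#' Read trial-level PRT data
#'
#' Reads a comma-delimited trial file (header
#' `subject_id,group,block,trial,stimulus,response,correct,rewarded,rt_ms`)
#' and validates all schema invariants.
#'
#' @param path path to an existing file.
#' @return A validated `prt_trials` data frame, one row per trial.
#' @seealso [write_trials()], [validate_trials()]
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("trial file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(setdiff(.trial_cols, "rt_ms"), names(raw))
  if (length(missing) > 0L)
    stop("trial file schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  trials <- data.frame(
    subject_id = raw$subject_id,
    group      = raw$group,
    block      = as.integer(raw$block),
    trial      = as.integer(raw$trial),
    stimulus   = raw$stimulus,
    response   = raw$response,
    correct    = as.integer(raw$correct) == 1L,
    rewarded   = as.integer(raw$rewarded) == 1L,
    rt_ms      = if ("rt_ms" %in% names(raw))
                   suppressWarnings(as.numeric(raw$rt_ms)) else NA_real_,
    stringsAsFactors = FALSE)
  out <- validate_trials(trials)
  # read back visibly
  out
}

#' Write trial-level PRT data
#'
#' Serializes a validated trial table to comma-delimited UTF-8 text with the
#' documented header. Output is byte-stable given a fixed row ordering:
#' booleans become 0/1 and missing reaction times become empty fields.
#'
#' @param trials a `prt_trials` data frame (or anything passing
#'   [validate_trials()]); may have zero rows.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  if (nrow(trials) > 0L) trials <- validate_trials(trials)
  if (!"rt_ms" %in% names(trials)) trials$rt_ms <- NA_real_
  out <- data.frame(
    subject_id = trials$subject_id,
    group      = trials$group,
    block      = trials$block,
    trial      = trials$trial,
    stimulus   = trials$stimulus,
    response   = trials$response,
    correct    = as.integer(trials$correct),
    rewarded   = as.integer(trials$rewarded),
    rt_ms      = ifelse(is.na(trials$rt_ms), "",
                        format(trials$rt_ms, trim = TRUE, scientific = FALSE)),
    stringsAsFactors = FALSE)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(out, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' Validate a subject-visit outcome table
#'
#' @param visits data frame with columns `subject_id`, `week` (one of 0, 1,
#'   2, 3, 4, 6, 8), `hamd17` (integer 0..52) and `treatment` (`"sertraline"`
#'   or `"placebo"`).
#' @return The input, invisibly, with class `prt_visits` prepended.
#' @export
validate_visits <- function(visits) {
  missing <- setdiff(.visit_cols, names(visits))
  if (length(missing) > 0L)
    stop("visit table schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!visits$week %in% c(0, 1, 2, 3, 4, 6, 8))
  if (length(bad) > 0L)
    stop("visit table value error: week outside schedule in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(visits$hamd17 < 0 | visits$hamd17 > 52)
  if (length(bad) > 0L)
    stop("visit table value error: hamd17 outside 0..52 in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  bad <- which(!is.na(visits$treatment) &
                 !visits$treatment %in% c("sertraline", "placebo"))
  if (length(bad) > 0L)
    stop("visit table value error: unknown treatment in row(s) ",
         paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
  if (anyDuplicated(paste(visits$subject_id, visits$week)))
    stop("visit table integrity error: duplicate subject x week",
         call. = FALSE)
  class(visits) <- unique(c("prt_visits", class(visits)))
  invisible(visits)
}

#' Read a subject-visit outcome table
#'
#' @param path path to a comma-delimited file with header
#'   `subject_id,week,hamd17,treatment`.
#' @return A validated `prt_visits` data frame.
#' @export
read_visits <- function(path) {
  if (!file.exists(path)) stop("visit file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character")
  missing <- setdiff(.visit_cols, names(raw))
  if (length(missing) > 0L)
    stop("visit file schema error: missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  visits <- data.frame(
    subject_id = raw$subject_id,
    week       = as.numeric(raw$week),
    hamd17     = as.integer(raw$hamd17),
    treatment  = raw$treatment,
    stringsAsFactors = FALSE)
  out <- validate_visits(visits)
  out
}

#' Write a subject-visit outcome table
#'
#' @param visits a validated `prt_visits` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_visits <- function(visits, path) {
  if (nrow(visits) > 0L) visits <- validate_visits(visits)
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.csv(visits[, .visit_cols], con, row.names = FALSE,
                   quote = FALSE, eol = "\n")
  invisible(path)
}
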