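# End-to-end pipeline: simulate -> score -> classify -> outcomes ->
# report. Every stage is wrapped so a failure aborts with the stage name,
# and the whole run is a pure function of (config, seed).

#' Pipeline configuration
#'
#' Bundles the cohort, scoring, classifier and outcome-model options for
#' [run_pipeline()]. All randomness derives from `cohort$seed`.
#'
#' @param cohort a [cohort_config()].
#' @param payoff payoff used for RBD scoring; defaults to the payoff
#'   implied by the cohort's schedule.
#' @param rbd_method registered RBD method tag.
#' @param priors QDA priors (see [fit_qda_1d()]). The pipeline defaults
#'   to equal priors: the cutoff's job is to delimit the healthy range,
#'   and under the cohort's roughly 5:1 group imbalance empirical priors
#'   can make the depressed posterior dominate everywhere, leaving no
#'   boundary.
#' @param model a [moderation_spec()].
#' @param out_dir optional directory; when set, the report's tables are
#'   written there as delimited text.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            payoff = NULL,
                            rbd_method = "ev_shortfall",
                            priors = "equal",
                            model = moderation_spec(),
                            out_dir = NULL) {
  structure(list(cohort = cohort,
                 payoff = payoff %||% payoff_from_schedule(cohort$schedule),
                 rbd_method = rbd_method, priors = priors, model = model,
                 out_dir = out_dir), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' Reads a YAML (or JSON) file whose top-level keys override the defaults
#' of [pipeline_config()] and [cohort_config()]: `n_mdd`, `n_hc`,
#' `mdd_disengaged_fraction`, `seed`, `rbd_method`, `priors`, `out_dir`,
#' plus nested `schedule` and `outcome` parameter blocks.
#'
#' @param path path to the configuration file.
#' @param seed optional seed overriding the file's value.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, seed = NULL) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read configuration files",
         call. = FALSE)
  raw <- yaml::read_yaml(path)
  sched <- do.call(schedule_config, raw$schedule %||% list())
  outc <- do.call(outcome_gen_params, raw$outcome %||% list())
  coh_args <- raw[intersect(names(raw),
                            c("n_mdd", "n_hc", "mdd_disengaged_fraction",
                              "engaged", "disengaged", "hc", "seed"))]
  coh_args$schedule <- sched
  coh_args$outcome <- outc
  if (!is.null(seed)) coh_args$seed <- seed
  cohort <- do.call(cohort_config, coh_args)
  pipeline_config(cohort = cohort,
                  rbd_method = raw$rbd_method %||% "ev_shortfall",
                  priors = raw$priors %||% "equal",
                  out_dir = raw$out_dir)
}

.param_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  # strip environments so the hash depends only on parameter values
  saveRDS(rapply(x, function(v) v, how = "replace"), f,
          compress = FALSE, version = 2L)
  unname(tools::md5sum(f))
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Chains simulation, per-block scoring, QDA classification and the
#' moderation mixed model. The report bundle contains five artifacts: the
#' per-subject-block score table, the classification table, the baseline
#' group comparison, the moderation summary, and a run log (seed, group
#' sizes, parameter hash, package version). Any stage failure aborts with
#' an error naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return An object of class `rbd_report` with elements `scores`,
#'   `classification`, `group_comparison`, `moderation`, `log`, plus the
#'   intermediate `cohort`, `visits`, `model` and `diagnostics`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cohort <- .stage("simulate", {
    if (config$cohort$n_mdd == 0L || config$cohort$n_hc == 0L)
      stop("classifier stages need both MDD and HC subjects")
    simulate_cohort(config$cohort)
  })
  visits <- .stage("simulate", simulate_outcomes(
    cohort$demographics, config$cohort$outcome,
    seed = config$cohort$seed + 2L))

  scores <- .stage("score", {
    counts <- tabulate_blocks(cohort$trials)
    sdt <- sdt_measures(counts)
    rbd <- compute_rbd(counts, config$payoff, method = config$rbd_method)
    cbind(counts[c("subject_id", "group", "block")],
          sdt[c("log_b", "log_d", "correction_applied")],
          rbd[c("rbd", "method_tag")])
  })

  classification <- .stage("classify", {
    b2 <- scores[scores$block == 2L, ]
    model <- fit_qda_1d(b2$rbd[b2$group == "MDD"],
                        b2$rbd[b2$group == "HC"],
                        priors = config$priors)
    label <- classify(b2$rbd, model)
    diag_tab <- table(factor(label, c("engaged", "disengaged")),
                      factor(b2$group, c("MDD", "HC")))
    list(table = data.frame(subject_id = b2$subject_id,
                            group = b2$group, block2_rbd = b2$rbd,
                            label = label, cutoff = model$cutoff,
                            stringsAsFactors = FALSE),
         model = model,
         diagnostics = diagnostic_stats(label, b2$group),
         group_test = chisq_independence(diag_tab))
  })

  group_comparison <- .stage("report", {
    mdd <- classification$table[classification$table$group == "MDD", ]
    compare_groups(cohort$demographics,
                   stats::setNames(mdd$label, mdd$subject_id))
  })

  moderation <- .stage("outcomes", {
    mdd <- classification$table[classification$table$group == "MDD", ]
    fit_moderation_model(visits,
                         stats::setNames(mdd$label, mdd$subject_id),
                         spec = config$model)
  })

  log <- list(seed = config$cohort$seed,
              n_mdd = config$cohort$n_mdd, n_hc = config$cohort$n_hc,
              param_hash = .param_hash(config[c("cohort", "payoff",
                                                "rbd_method", "priors")]),
              package_version =
                as.character(utils::packageVersion("rbdprt")),
              timestamp_free = TRUE)

  report <- structure(list(
    scores = scores,
    classification = classification$table,
    group_comparison = group_comparison,
    moderation = list(
      coef_table = moderation$coef_table,
      varcomp = moderation$varcomp,
      interaction = moderation$interaction),
    log = log,
    cohort = cohort, visits = visits,
    model = classification$model,
    diagnostics = classification$diagnostics,
    group_test = classification$group_test,
    moderation_fit = moderation), class = "rbd_report")

  if (!is.null(config$out_dir)) .stage("report", {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(d, f) utils::write.csv(
      d, file.path(config$out_dir, f), row.names = FALSE, quote = FALSE)
    wr(report$scores, "scores.csv")
    wr(report$classification, "classification.csv")
    wr(report$group_comparison$report, "group_comparison.csv")
    wr(report$moderation$coef_table, "moderation_coefficients.csv")
    writeLines(c(paste("seed:", log$seed),
                 paste("n_mdd:", log$n_mdd),
                 paste("n_hc:", log$n_hc),
                 paste("param_hash:", log$param_hash),
                 paste("package_version:", log$package_version)),
               file.path(config$out_dir, "run_log.txt"))
  })
  report
}

#' @export
print.rbd_report <- function(x, ...) {
  cat("PRT disengagement pipeline report\n")
  cat(sprintf("  seed %d, %d MDD + %d HC subjects (hash %s)\n",
              x$log$seed, x$log$n_mdd, x$log$n_hc,
              substr(x$log$param_hash, 1L, 8L)))
  cat(sprintf("  QDA cutoff on block-2 RBD: %.4f\n", x$model$cutoff))
  lab <- table(x$classification$label[x$classification$group == "MDD"])
  cat(sprintf("  MDD classification: %d engaged, %d disengaged\n",
              lab["engaged"], lab["disengaged"]))
  with(x$moderation$interaction, cat(sprintf(
    "  moderation (3-way) estimate %.3f, Wald z = %.3f, p = %.4g\n",
    estimate, wald_z, p_value)))
  invisible(x)
}
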