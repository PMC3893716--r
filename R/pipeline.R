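sem <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

group_summary <- function(data, value_col, by_cols) {
  agg <- function(f, name) {
    out <- stats::aggregate(data[[value_col]], data[by_cols], f)
    names(out)[ncol(out)] <- name
    out
  }
  m <- agg(function(x) mean(x, na.rm = TRUE), "mean")
  s <- agg(sem, "sem")
  n <- agg(function(x) sum(!is.na(x)), "n")
  out <- merge(merge(m, s, by = by_cols), n, by = by_cols)
  out[do.call(order, out[by_cols]), , drop = FALSE]
}

#' Compute all metrics and statistics from a trial log
#'
#' The analysis half of the replication pipeline: block-normalized shift
#' preferences, learning-bias scores, risky-choice scores, accuracy series,
#' the ANOVA/t-test/correlation battery and the qualitative group-ordering
#' checks, from a trial log plus its session manifest (simulated or
#' user-supplied).
#'
#' @param trials trial-log data.frame (see [write_trial_log()] for the
#'   dialect).
#' @param sessions session manifest data.frame.
#' @return list with `metrics` (per-subject tables), `tables` (group
#'   mean/sem/n summaries), `anovas`, `ttests`, `correlations` and `checks`.
#' @export
analyze_cohort <- function(trials, sessions) {
  sbt <- shift_block_table(trials, sessions, kind = "small")
  bias <- learning_bias_table(trials, sessions)
  risk <- risky_choice_scores(trials, sessions)
  acc <- accuracy_series(trials)
  disc <- discrimination_preferences(trials, sessions)

  metrics <- list(shift_blocks = sbt, bias = bias, risk = risk,
                  accuracy = acc, discrimination = disc)

  tables <- list(
    block_preference = group_summary(sbt, "normalized",
                                     c("group", "shift", "block")),
    risk = risk_group_table(risk),
    pavlovian = pav_group_table(acc),
    forced_accuracy = group_summary(acc, "forced_accuracy", "group"),
    bias = group_summary(bias, "bias", "group")
  )

  anovas <- list()
  complete <- !is.na(sbt$normalized)
  complete_subjects <- setdiff(unique(sbt$subject_id),
                               unique(sbt$subject_id[!complete]))
  sbt_c <- sbt[sbt$subject_id %in% complete_subjects, , drop = FALSE]
  anovas$shift <- mixed_anova(sbt_c, dv = "normalized", subject = "subject_id",
                              between = "group", within = c("shift", "block"))
  risk_long <- stats::reshape(
    risk[!is.na(risk$average_risky),
         c("subject_id", "group", "risky_better", "even", "safe_better")],
    direction = "long", idvar = c("subject_id", "group"),
    varying = c("risky_better", "even", "safe_better"),
    v.names = "risky_choice", timevar = "condition",
    times = c("risky_better", "even", "safe_better")
  )
  anovas$risk <- mixed_anova(risk_long, dv = "risky_choice",
                             subject = "subject_id", between = "group",
                             within = "condition")
  pav_long <- pav_long_table(acc)
  if (nrow(pav_long) > 0L && !anyNA(pav_long$accuracy)) {
    anovas$pavlovian <- mixed_anova(pav_long, dv = "accuracy",
                                    subject = "subject_id",
                                    between = "group", within = "session")
  }

  grp <- function(tab, col) {
    list(a = tab[[col]][tab$group == "cLH_like"],
         b = tab[[col]][tab$group == "WT_like"])
  }
  ttests <- list()
  g <- grp(bias, "bias")
  ttests$bias <- student_t(g$a, g$b)
  g <- grp(risk, "average_risky")
  ttests$average_risky <- student_t(g$a, g$b)
  g <- grp(acc, "forced_accuracy")
  ttests$forced_accuracy <- student_t(g$a, g$b)
  for (k in sort(unique(disc$disc_index))) {
    d <- disc[disc$disc_index == k, ]
    g <- grp(d, "preference")
    ttests[[paste0("discrimination_", k)]] <- student_t(g$a, g$b)
  }

  correlations <- list()
  scatter <- merge(bias[, c("subject_id", "group", "bias")],
                   risk[, c("subject_id", "average_risky")],
                   by = "subject_id")
  scatter <- merge(scatter, acc[, c("subject_id", "forced_accuracy")],
                   by = "subject_id")
  correlations$bias_vs_risky <- pearson_r(scatter$bias,
                                          scatter$average_risky)
  clh <- scatter[scatter$group == "cLH_like", ]
  if (sum(!is.na(clh$bias) & !is.na(clh$average_risky)) >= 3L) {
    correlations$bias_vs_risky_cLH <- pearson_r(clh$bias, clh$average_risky)
  }
  correlations$bias_vs_forced_accuracy <- pearson_r(scatter$bias,
                                                    scatter$forced_accuracy)

  checks <- qualitative_checks(sbt, risk, correlations$bias_vs_risky)

  list(metrics = metrics, tables = tables, anovas = anovas, ttests = ttests,
       correlations = correlations, checks = checks, scatter = scatter)
}

risk_group_table <- function(risk) {
  long <- stats::reshape(
    risk[, c("subject_id", "group", "risky_better", "even", "safe_better",
             "average_risky")],
    direction = "long", idvar = c("subject_id", "group"),
    varying = c("risky_better", "even", "safe_better", "average_risky"),
    v.names = "risky_choice", timevar = "condition",
    times = c("risky_better", "even", "safe_better", "average_risky")
  )
  group_summary(long, "risky_choice", c("group", "condition"))
}

pav_long_table <- function(acc) {
  cols <- paste0("pav_", 1:5)
  long <- stats::reshape(acc[, c("subject_id", "group", cols)],
                         direction = "long",
                         idvar = c("subject_id", "group"), varying = cols,
                         v.names = "accuracy", timevar = "session",
                         times = 1:5)
  long[!is.na(long$accuracy) | TRUE, , drop = FALSE]
}

pav_group_table <- function(acc) {
  long <- pav_long_table(acc)
  group_summary(long[!is.na(long$accuracy), , drop = FALSE], "accuracy",
                c("group", "session"))
}

# The four qualitative group-ordering checks the replication is judged on:
# cLH-like subjects switch faster after a downshift (lower normalized block-2
# preference for the downshifted side), slower after an upshift (lower
# normalized block-1 preference for the upshifted side), choose the risky
# side less on average, and learning bias correlates positively with risky
# choice across subjects.
qualitative_checks <- function(sbt, risk, bias_risk_cor) {
  mean_block <- function(shift, block, group) {
    sel <- sbt$shift == shift & sbt$block == block & sbt$group == group
    mean(sbt$normalized[sel], na.rm = TRUE)
  }
  down_clh <- mean_block("down", "b2", "cLH_like")
  down_wt <- mean_block("down", "b2", "WT_like")
  up_clh <- mean_block("up", "b1", "cLH_like")
  up_wt <- mean_block("up", "b1", "WT_like")
  risky_clh <- mean(risk$average_risky[risk$group == "cLH_like"],
                    na.rm = TRUE)
  risky_wt <- mean(risk$average_risky[risk$group == "WT_like"], na.rm = TRUE)
  r <- bias_risk_cor$estimate
  list(
    downshift_faster = list(
      description = "cLH-like mean normalized block-2 preference for the downshifted side is below the WT-like mean",
      cLH = down_clh, WT = down_wt, pass = isTRUE(down_clh < down_wt)),
    upshift_slower = list(
      description = "cLH-like mean normalized block-1 preference for the upshifted side is below the WT-like mean",
      cLH = up_clh, WT = up_wt, pass = isTRUE(up_clh < up_wt)),
    risk_averse = list(
      description = "cLH-like mean average risky-choice score is below the WT-like mean",
      cLH = risky_clh, WT = risky_wt, pass = isTRUE(risky_clh < risky_wt)),
    bias_risk_positive = list(
      description = "learning bias correlates positively with average risky choice across subjects",
      r = r, pass = isTRUE(r > 0))
  )
}

#' Run the full in-silico replication
#'
#' Simulates the configured cohorts through the full protocol, computes every
#' metric and statistic, and assembles a reproducible run report. The report
#' is a pure function of the configuration and seed.
#'
#' @param config cohort configuration, see [default_cohort_config()].
#' @param seed optional integer overriding `config$seed`.
#' @return an object of class `run_report`: list with `config`, `seed`,
#'   `cohort` (subject counts and per-subject parameters), `metrics`,
#'   `tables`, `anovas`, `ttests`, `correlations`, `scatter`, `checks` and
#'   `null_cohort` (flag set when both groups share identical parameter
#'   distributions, in which case the group-ordering checks are expected to
#'   fail).
#' @export
run_replication <- function(config = default_cohort_config(), seed = NULL) {
  if (!is.null(seed)) config$seed <- as.integer(seed)
  cohort <- simulate_cohorts(config)
  analysis <- analyze_cohort(cohort$trials, cohort$sessions)
  null_cohort <- identical(config$groups$cLH_like$params,
                           config$groups$WT_like$params)
  structure(
    c(list(
      config = config,
      seed = config$seed,
      cohort = list(
        n_cLH_like = config$groups$cLH_like$n,
        n_WT_like = config$groups$WT_like$n,
        params = cohort$params
      ),
      null_cohort = null_cohort,
      trials = cohort$trials,
      sessions = cohort$sessions
    ), analysis),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$seed, "|", x$cohort$n_cLH_like, "cLH-like +",
      x$cohort$n_WT_like, "WT-like subjects\n")
  if (isTRUE(x$null_cohort)) cat("  NULL COHORT: groups share identical",
                                 "parameter distributions\n")
  cat("\nGroup-ordering checks:\n")
  for (nm in names(x$checks)) {
    ck <- x$checks[[nm]]
    cat(sprintf("  [%s] %s\n", if (isTRUE(ck$pass)) "PASS" else "FAIL", nm))
  }
  cat("\nShift ANOVA (group x shift x block, normalized preference):\n")
  print(x$anovas$shift)
  cat("\nBias vs average risky choice: ")
  print(x$correlations$bias_vs_risky)
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes the trial log, session manifest, per-subject metric tables, group
#' tables, the flat statistics table and a JSON report into `dir`.
#'
#' @param report a [run_replication()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_log(report$trials, file.path(dir, "trials.csv"))
  write_session_manifest(report$sessions, file.path(dir, "sessions.csv"))
  utils::write.csv(report$cohort$params, file.path(dir, "params.csv"),
                   row.names = FALSE)
  write_analysis_outputs(report, dir)
  json <- list(
    seed = report$seed,
    cohort = list(n_cLH_like = report$cohort$n_cLH_like,
                  n_WT_like = report$cohort$n_WT_like),
    null_cohort = report$null_cohort,
    tables = report$tables,
    stats = stats_table(report),
    checks = report$checks
  )
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

# Shared by `analyze` and `replicate`: per-subject metric tables plus the
# flat statistics table.
write_analysis_outputs <- function(analysis, dir) {
  m <- analysis$metrics
  utils::write.csv(m$shift_blocks, file.path(dir, "metrics_shift_blocks.csv"),
                   row.names = FALSE)
  utils::write.csv(m$bias, file.path(dir, "metrics_bias.csv"),
                   row.names = FALSE)
  utils::write.csv(m$risk, file.path(dir, "metrics_risk.csv"),
                   row.names = FALSE)
  utils::write.csv(m$accuracy, file.path(dir, "metrics_accuracy.csv"),
                   row.names = FALSE)
  utils::write.csv(m$discrimination,
                   file.path(dir, "metrics_discrimination.csv"),
                   row.names = FALSE)
  utils::write.csv(stats_table(analysis), file.path(dir, "stats.csv"),
                   row.names = FALSE)
  invisible(dir)
}

# Flatten every fitted statistic into one table: ANOVA effects, t tests and
# correlations.
stats_table <- function(analysis) {
  rows <- list()
  for (nm in names(analysis$anovas)) {
    a <- as.data.frame(analysis$anovas[[nm]])
    rows[[length(rows) + 1L]] <- data.frame(
      test = paste0("anova_", nm), effect = a$effect, statistic = "F",
      value = a$statistic, df1 = a$df_num, df2 = a$df_den,
      p_value = a$p_value, stringsAsFactors = FALSE)
  }
  for (nm in names(analysis$ttests)) {
    t <- analysis$ttests[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      test = paste0("ttest_", nm), effect = "group", statistic = "t",
      value = t$statistic, df1 = t$df, df2 = NA_real_, p_value = t$p_value,
      stringsAsFactors = FALSE)
  }
  for (nm in names(analysis$correlations)) {
    r <- analysis$correlations[[nm]]
    rows[[length(rows) + 1L]] <- data.frame(
      test = paste0("cor_", nm), effect = paste0("n=", r$n), statistic = "r",
      value = r$estimate, df1 = r$df, df2 = NA_real_, p_value = r$p_value,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
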