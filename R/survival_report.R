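#' @title Kaplan-Meier estimation, log-rank tests and the cohort report
#'
#' @description Survival endpoints (months, right-censored) are summarized
#' per ctDNA group with the product-limit estimator
#' \eqn{S(t) = \prod_{t_i \le t} (1 - d_i / n_i)} and compared across
#' groups with the log-rank test. Median survival is the smallest observed
#' time with \eqn{S(t) \le 0.5}, undefined when the curve never reaches
#' 0.5; events precede censorings at tied times (the standard convention).
#' The estimation itself is delegated to the survival package; this module
#' provides the pipeline-facing surface and the report rendering.
#'
#' @name survival_report
NULL

new_survival_records <- function(df) {
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("survival records missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$time)) || any(df$time <= 0))
    stop("survival times must be finite and positive", call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event must be 0 (censored) or 1 (event observed)", call. = FALSE)
  df
}

#' Product-limit (Kaplan-Meier) estimate
#'
#' @param records data.frame with `sample_id`, `time` (months > 0) and
#'   `event` (1 = event observed, 0 = censored).
#' @return list of class `km_estimate`: `time` (ordered event times),
#'   `surv` (survival probabilities, non-increasing, starting from 1),
#'   `n_risk`, `n_event`, `median` (smallest time with S(t) <= 0.5, `NA`
#'   if never reached), and `median_ci` (95% log-log interval when
#'   estimable).
#' @export
km_estimate <- function(records) {
  records <- new_survival_records(records)
  if (!nrow(records)) stop("no survival records", call. = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                           conf.type = "log-log")
  med <- smallest_time_below(fit$time, fit$surv, 0.5)
  ci <- c(smallest_time_below(fit$time, fit$lower, 0.5),
          smallest_time_below(fit$time, fit$upper, 0.5))
  structure(list(time = fit$time, surv = fit$surv, n_risk = fit$n.risk,
                 n_event = fit$n.event, n = fit$n, median = med,
                 median_ci = ci),
            class = "km_estimate")
}

smallest_time_below <- function(time, surv, level) {
  i <- which(!is.na(surv) & surv <= level)
  if (!length(i)) NA_real_ else time[min(i)]
}

#' Log-rank test across two or more groups
#'
#' Standard log-rank chi-square over the pooled event times; the p-value
#' comes from a chi-square distribution with (k - 1) degrees of freedom.
#'
#' @param records data.frame with `time`, `event` and a `group` column
#'   (two or more non-empty groups).
#' @return list with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(records) {
  records <- new_survival_records(records)
  if (is.null(records$group))
    stop("log-rank test needs a group column", call. = FALSE)
  tab <- table(records$group)
  if (length(tab) < 2L || any(tab == 0))
    stop("log-rank test needs >= 2 non-empty groups", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records)
  df <- length(sd$n) - 1L
  list(statistic = unname(sd$chisq), df = df,
       p_value = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

#' Benjamini-Hochberg adjustment for multiple pairwise comparisons
#'
#' Applied when the report performs more than one pairwise group
#' comparison.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values (FDR).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Assemble the cohort report
#'
#' Joins classifications, survival follow-up and per-sample features by
#' `sample_id` and renders group counts, percent positive, per-group KM
#' medians, the overall log-rank test, pairwise log-rank tests
#' (BH-adjusted) and feature frequencies, as a machine-readable list (JSON
#' serializable) plus a plain-text rendering.
#'
#' @param classifications data.frame from [classify_cohort()].
#' @param survival_records data.frame with `sample_id`, `time`, `event`.
#' @param features_list optional list of `sample_features`.
#' @return list of class `cohort_report` with `summary`, `km` (per group),
#'   `logrank`, `pairwise`, and `text`.
#' @export
cohort_report <- function(classifications, survival_records,
                          features_list = NULL) {
  cls <- as_classification_df(classifications)
  sv <- new_survival_records(survival_records)
  orphans <- c(setdiff(cls$sample_id, sv$sample_id),
               setdiff(sv$sample_id, cls$sample_id))
  if (length(orphans))
    stop("sample_id mismatch between classifications and survival: ",
         paste(utils::head(orphans, 5), collapse = ", "),
         if (length(orphans) > 5) " ...", call. = FALSE)
  sv$group <- cls$group[match(sv$sample_id, cls$sample_id)]
  summary <- summarize_cohort(cls, features_list)
  km <- lapply(split(sv, sv$group), km_estimate)
  lr <- logrank_test(sv)
  groups <- sort(unique(sv$group))
  pairwise <- NULL
  if (length(groups) > 2L) {
    pairs <- utils::combn(groups, 2, simplify = FALSE)
    pw <- lapply(pairs, function(pr)
      logrank_test(sv[sv$group %in% pr, , drop = FALSE]))
    pairwise <- data.frame(
      group_a = vapply(pairs, `[`, "", 1),
      group_b = vapply(pairs, `[`, "", 2),
      statistic = vapply(pw, `[[`, 0, "statistic"),
      p_value = vapply(pw, `[[`, 0, "p_value"),
      stringsAsFactors = FALSE)
    pairwise$p_adjusted <- adjust_bh(pairwise$p_value)
  }
  med_line <- vapply(names(km), function(g)
    sprintf("%s: median %.1f months (n=%d)", g,
            km[[g]]$median, km[[g]]$n), "")
  text <- c(
    sprintf("Cohort: n=%d; ctDNA-positive %d (%d%%)", summary$n,
            summary$n_positive, summary$percent_positive),
    sprintf("Groups: G1=%d G2=%d G3=%d", summary$counts[["Group1"]],
            summary$counts[["Group2"]], summary$counts[["Group3"]]),
    med_line,
    sprintf("Log-rank: chisq=%.2f df=%d p=%.3g", lr$statistic, lr$df,
            lr$p_value))
  structure(list(summary = summary, km = km, logrank = lr,
                 pairwise = pairwise, text = text),
            class = "cohort_report")
}

#' Write a cohort report as JSON (plus a plain-text sidecar)
#'
#' @param report `cohort_report`.
#' @param path output JSON path; the text rendering goes to `<path>.txt`.
#' @return `path`, invisibly.
#' @export
write_cohort_report <- function(report, path) {
  km <- lapply(report$km, function(k)
    list(n = k$n, median = k$median, median_ci = k$median_ci))
  obj <- list(
    n = report$summary$n,
    counts = as.list(report$summary$counts),
    n_positive = report$summary$n_positive,
    percent_positive = report$summary$percent_positive,
    feature_frequency = report$summary$feature_frequency,
    km = km,
    logrank = report$logrank,
    pairwise = report$pairwise)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", dataframe = "rows")
  writeLines(report$text, paste0(path, ".txt"))
  invisible(path)
}

#' Read a survival TSV (`sample_id`, `time_months`, `event`)
#' @param path TSV file.
#' @return validated survival data.frame (`time` column in months).
#' @export
read_survival_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if ("time_months" %in% names(df)) {
    df$time <- df$time_months
    df$time_months <- NULL
  }
  new_survival_records(df)
}

#' @export
print.km_estimate <- function(x, ...) {
  cat("<km_estimate> n =", x$n, " events =", sum(x$n_event),
      " median =", x$median, "months\n")
  invisible(x)
}
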