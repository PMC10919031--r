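## System-attribute metrics: every quantity is a ratio of ledger counts,
## rendered as an integer percent under one round-half-up rule (see pct()).

#' Usefulness metrics
#'
#' Escalation share (events escalated as alerts out of all events
#' triggered), response share (alerts closed — indicating some form of
#' response — out of alerts escalated), and the composition of escalated
#' alerts by CCD code.
#'
#' @param s a `cbs_summary`.
#' @return list of [pct()] objects: `escalation`, `response`,
#'   `supervisor_dismissal`, and `composition` (one per code).
#' @export
usefulness <- function(s) {
  comp <- lapply(s$per_code_escalated, function(k) pct(k, s$n_alerts_escalated))
  list(
    escalation = pct(s$n_alerts_escalated, s$n_events),
    supervisor_dismissal = pct(s$n_events_dismissed, s$n_events),
    response = pct(s$n_alerts_closed, s$n_alerts_escalated),
    composition = comp
  )
}

#' Simplicity metrics
#'
#' Signal-level shares: signals verified by the supervisor out of all
#' signals sent, and signals kept as health events (matching the CCD) out
#' of those verified.
#'
#' @param s a `cbs_summary`.
#' @return list of [pct()]: `verified_of_sent`, `kept_of_verified`.
#' @export
simplicity <- function(s) {
  list(
    verified_of_sent = pct(s$n_signals_verified, s$n_signals_sent),
    kept_of_verified = pct(s$n_signals_kept, s$n_signals_verified)
  )
}

#' Data-quality metrics
#'
#' Correct-format share of all reports and the period-average weekly
#' completeness (volunteers with at least one report per week).
#'
#' @param s a `cbs_summary`.
#' @return list: `correct_format` ([pct()]) and
#'   `weekly_completeness_avg_pct` (numeric, on the 0-100 scale, `NA` when
#'   no week has active volunteers).
#' @export
data_quality <- function(s) {
  list(
    correct_format = pct(s$n_correct_format, s$n_reports),
    weekly_completeness_avg_pct =
      if (is.na(s$weekly_completeness_avg)) NA_real_
      else 100 * s$weekly_completeness_avg
  )
}

#' Sensitivity proxies
#'
#' Direct sensitivity (all true events detected) is unobservable from the
#' ledger alone; these are the documented-outcome proxies: outcome
#' documentation, action taken, authority dismissal, and laboratory
#' confirmation among action-taken alerts. When no outcome is documented
#' at all, every proxy is a typed null and the report is flagged
#' `"insufficient documentation"`.
#'
#' @param s a `cbs_summary`.
#' @return list of [pct()]: `documented_outcome` (of closed alerts),
#'   `action_taken` (of documented), `lab_confirmed_of_actioned`,
#'   `dismissed_by_authorities` (of escalated), plus `note`.
#' @export
sensitivity_proxies <- function(s) {
  insufficient <- s$n_documented == 0
  list(
    documented_outcome = pct(s$n_documented, s$n_alerts_closed),
    action_taken = pct(s$n_action_taken, s$n_documented),
    lab_confirmed_of_actioned = pct(s$n_lab_confirmed, s$n_action_taken),
    dismissed_by_authorities = pct(s$n_dismissed_by_authorities,
                                   s$n_alerts_escalated),
    note = if (insufficient) "insufficient documentation" else ""
  )
}

#' Timeliness metrics
#'
#' Verification cuts use closed bounds (a delay of exactly 12 h counts as
#' within 12 h) with all triggered events as the denominator; the closure
#' cut uses all closed alerts.
#'
#' @param s a `cbs_summary`.
#' @return list of [pct()]: `verified_within_12h`, `verified_within_24h`,
#'   `closed_within_48h`.
#' @export
timeliness <- function(s) {
  list(
    verified_within_12h = pct(s$n_verified_within_12h, s$n_events),
    verified_within_24h = pct(s$n_verified_within_24h, s$n_events),
    closed_within_48h = pct(s$n_closed_within_48h, s$n_alerts_closed)
  )
}

#' Full surveillance-system attribute report
#'
#' Assembles usefulness, simplicity, data-quality, sensitivity-proxy and
#' timeliness metrics for a ledger (or a precomputed summary). Every
#' percentage carries its raw fraction; zero denominators propagate as
#' typed nulls, never as errors.
#'
#' @param x a `cbs_ledger` or `cbs_summary`.
#' @return object of class `cbs_attribute_report`.
#' @export
cbs_attributes <- function(x) {
  s <- if (inherits(x, "cbs_ledger")) summary(x) else x
  if (!inherits(s, "cbs_summary")) {
    cbs_stop("need a cbs_ledger or cbs_summary", "cbs_bad_input")
  }
  structure(list(
    region = s$region,
    summary = s,
    usefulness = usefulness(s),
    simplicity = simplicity(s),
    data_quality = data_quality(s),
    sensitivity = sensitivity_proxies(s),
    timeliness = timeliness(s),
    footnote = paste(
      "Percentages are round-half-up to integers; complements may differ",
      "from 100 by 1 point, and ratios near a half point may differ by 1",
      "from reports using truncation.")
  ), class = "cbs_attribute_report")
}

fmt_pct_row <- function(label, p) {
  if (is.na(p$percent)) {
    sprintf("| %s | %d | -- |", label, p$numerator)
  } else {
    sprintf("| %s | %d | %d%% |", label, p$numerator, p$percent)
  }
}

#' Render an attribute report as a Markdown table
#'
#' Rows follow the descriptive-results layout of the programme evaluation:
#' totals, verification, escalation with per-code composition, closure and
#' outcomes, report volumes and data quality, then signal-level shares.
#'
#' @param x a `cbs_attribute_report`.
#' @return character vector of Markdown lines.
#' @export
attributes_markdown <- function(x) {
  s <- x$summary
  code_names <- stats::setNames(x$summary$per_code_escalated, NULL)
  lines <- c(
    sprintf("### CBS system attributes - %s", x$region),
    "", "| Quantity | n | % |", "| --- | --- | --- |",
    sprintf("| Total signals triggered (events) | %d | -- |", s$n_events),
    fmt_pct_row("Events verified within 12 h", x$timeliness$verified_within_12h),
    fmt_pct_row("Events verified within 24 h", x$timeliness$verified_within_24h),
    fmt_pct_row("Signals dismissed by supervisor", x$usefulness$supervisor_dismissal),
    fmt_pct_row("Alerts escalated", x$usefulness$escalation)
  )
  for (cd in names(x$usefulness$composition)) {
    lines <- c(lines, fmt_pct_row(sprintf("&nbsp;&nbsp;code %s", cd),
                                  x$usefulness$composition[[cd]]))
  }
  lines <- c(lines,
    fmt_pct_row("Alerts closed", x$usefulness$response),
    fmt_pct_row("Alerts dismissed by authorities", x$sensitivity$dismissed_by_authorities),
    fmt_pct_row("Alerts with documented outcome", x$sensitivity$documented_outcome),
    fmt_pct_row("&nbsp;&nbsp;action taken", x$sensitivity$action_taken),
    fmt_pct_row("&nbsp;&nbsp;lab confirmed (of actioned)", x$sensitivity$lab_confirmed_of_actioned),
    fmt_pct_row("Alerts closed within 48 h", x$timeliness$closed_within_48h),
    sprintf("| Total reports sent | %d | -- |", s$n_reports),
    fmt_pct_row("Correct format of report", x$data_quality$correct_format),
    if (is.na(x$data_quality$weekly_completeness_avg_pct))
      "| Weekly completeness (avg) | -- | -- |"
    else sprintf("| Weekly completeness (avg) | -- | %.0f%% |",
                 x$data_quality$weekly_completeness_avg_pct),
    sprintf("| Total signals sent | %d | -- |", s$n_signals_sent),
    fmt_pct_row("Signals verified", x$simplicity$verified_of_sent),
    fmt_pct_row("Verified events - signals matching CCD", x$simplicity$kept_of_verified),
    "",
    paste0("_", x$footnote, "_")
  )
  if (nzchar(x$sensitivity$note)) {
    lines <- c(lines, paste0("_Sensitivity proxies: ", x$sensitivity$note, "._"))
  }
  lines
}

#' @export
print.cbs_attribute_report <- function(x, ...) {
  cat(attributes_markdown(x), sep = "\n")
  invisible(x)
}

## flat numeric view used by the pipeline's JSON artifact
attributes_flat <- function(x) {
  comp <- vapply(x$usefulness$composition, pct_or_na, integer(1))
  names(comp) <- paste0("composition_code_", names(x$usefulness$composition), "_pct")
  c(list(
    escalation_pct = x$usefulness$escalation$percent,
    supervisor_dismissal_pct = x$usefulness$supervisor_dismissal$percent,
    response_pct = x$usefulness$response$percent,
    verified_of_sent_pct = x$simplicity$verified_of_sent$percent,
    kept_of_verified_pct = x$simplicity$kept_of_verified$percent,
    correct_format_pct = x$data_quality$correct_format$percent,
    weekly_completeness_avg_pct = x$data_quality$weekly_completeness_avg_pct,
    documented_outcome_pct = x$sensitivity$documented_outcome$percent,
    action_taken_pct = x$sensitivity$action_taken$percent,
    lab_confirmed_of_actioned_pct = x$sensitivity$lab_confirmed_of_actioned$percent,
    dismissed_by_authorities_pct = x$sensitivity$dismissed_by_authorities$percent,
    verified_within_12h_pct = x$timeliness$verified_within_12h$percent,
    verified_within_24h_pct = x$timeliness$verified_within_24h$percent,
    closed_within_48h_pct = x$timeliness$closed_within_48h$percent
  ), as.list(comp))
}
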