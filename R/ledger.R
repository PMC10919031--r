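## Schema helpers: empty typed tables so every ledger shares one layout. ----

empty_volunteers <- function() {
  data.frame(volunteer_id = character(0), village_id = character(0),
             phone_token = character(0), lat = numeric(0), lon = numeric(0),
             active_from = as.POSIXct(character(0), tz = "UTC"),
             active_to = as.POSIXct(character(0), tz = "UTC"),
             stringsAsFactors = FALSE)
}

empty_reports <- function() {
  data.frame(report_id = character(0), volunteer_id = character(0),
             received_at = as.POSIXct(character(0), tz = "UTC"),
             payload = character(0), parse_status = character(0),
             code = integer(0), stringsAsFactors = FALSE)
}

empty_events <- function() {
  data.frame(event_id = character(0), code = integer(0),
             member_report_ids = character(0),
             triggered_at = as.POSIXct(character(0), tz = "UTC"),
             anchor_lat = numeric(0), anchor_lon = numeric(0),
             verification_status = character(0), dismissal_reason = character(0),
             verified_at = as.POSIXct(character(0), tz = "UTC"),
             stringsAsFactors = FALSE)
}

empty_alerts <- function() {
  data.frame(alert_id = character(0), event_id = character(0),
             escalated_at = as.POSIXct(character(0), tz = "UTC"),
             status = character(0),
             closed_at = as.POSIXct(character(0), tz = "UTC"),
             documented = logical(0), action_taken = logical(0),
             lab_confirmed = logical(0), notes = character(0),
             stringsAsFactors = FALSE)
}

## append-only transition log: a list of 4-field records (cheap to append)
empty_log <- function() list()

#' Transition log of a ledger as a data.frame
#'
#' The log is append-only: every verify/escalate/close transition adds one
#' record; corrections are new entries, never mutations.
#'
#' @param ledger a `cbs_ledger`.
#' @return data.frame with columns `at`, `op`, `id`, `detail`.
#' @export
ledger_log <- function(ledger) {
  if (length(ledger$log) == 0) {
    return(data.frame(at = character(0), op = character(0), id = character(0),
                      detail = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(ledger$log, function(e)
    as.data.frame(e, stringsAsFactors = FALSE)))
}

split_members <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0) else strsplit(x, ";", fixed = TRUE)[[1]]
}
join_members <- function(ids) paste(ids, collapse = ";")

DISMISSAL_REASONS <- c("not_matching_ccd", "duplicate", "sent_incorrectly", "none")

#' Construct a CBS programme ledger
#'
#' The ledger is the auditable container for one region-period of a
#' community-based surveillance programme: the volunteer roster with village
#' coordinates, all raw coded reports, the health events produced by the
#' alert thresholds, and the alerts escalated to the health authority. All
#' lifecycle operations (`verify_event()`, `escalate_event()`,
#' `close_alert()`) take and return a ledger; the transition log is
#' append-only, so corrections are new entries rather than mutations.
#'
#' @param region region label.
#' @param period_start,period_end reporting period bounds (UTC).
#' @param volunteers,reports,events,alerts component tables (see
#'   `empty_*()` internals for the schemas); defaults are empty.
#' @param ccd a `cbs_ccd_config`.
#' @param validate run full referential-integrity validation (default TRUE).
#' @return object of class `cbs_ledger`.
#' @export
cbs_ledger <- function(region, period_start, period_end,
                       volunteers = empty_volunteers(),
                       reports = empty_reports(),
                       events = empty_events(),
                       alerts = empty_alerts(),
                       ccd = default_ccd_config(),
                       validate = TRUE) {
  rownames(volunteers) <- NULL; rownames(reports) <- NULL
  rownames(events) <- NULL; rownames(alerts) <- NULL
  led <- structure(list(
    region = region,
    period_start = as_utc(period_start),
    period_end = as_utc(period_end),
    volunteers = volunteers, reports = reports,
    events = events, alerts = alerts,
    ccd = ccd, log = empty_log()
  ), class = "cbs_ledger")
  if (led$period_start >= led$period_end) {
    cbs_stop("period_start must precede period_end", "cbs_bad_config")
  }
  if (validate) validate_ledger(led)
  led
}

#' Validate a ledger's referential integrity and invariants
#'
#' Checks id uniqueness, cross-table references, coordinate ranges,
#' lifecycle-state invariants (only kept events carry alerts; closure
#' implies a closure time; documented outcomes dominate action/lab flags),
#' and that every event's members are signal reports of the event's code
#' meeting its CCD threshold.
#'
#' @param ledger a `cbs_ledger`.
#' @return the ledger, invisibly; otherwise a classed error.
#' @export
validate_ledger <- function(ledger) {
  v <- ledger$volunteers; r <- ledger$reports
  e <- ledger$events; a <- ledger$alerts
  chk <- function(ok, msg) if (!ok) cbs_stop(msg, "cbs_invalid_ledger")

  chk(!anyDuplicated(v$volunteer_id), "duplicate volunteer ids")
  chk(!anyDuplicated(r$report_id), "duplicate report ids")
  chk(!anyDuplicated(e$event_id), "duplicate event ids")
  chk(!anyDuplicated(a$alert_id), "duplicate alert ids")
  chk(all(v$lat >= -90 & v$lat <= 90), "volunteer latitude out of range")
  chk(all(v$lon >= -180 & v$lon <= 180), "volunteer longitude out of range")
  chk(all(v$active_from < v$active_to), "volunteer active_from must precede active_to")
  chk(all(r$volunteer_id %in% v$volunteer_id), "report references unknown volunteer")
  chk(all(r$parse_status %in% c("signal", "zero", "malformed")),
      "invalid parse_status")
  chk(all(!is.na(r$code[r$parse_status == "signal"])),
      "signal reports must carry a code")
  chk(all(is.na(r$code[r$parse_status != "signal"])),
      "non-signal reports must not carry a code")
  chk(all(e$verification_status %in% c("pending", "kept", "dismissed")),
      "invalid verification_status")
  chk(all(e$dismissal_reason %in% DISMISSAL_REASONS), "invalid dismissal_reason")
  chk(all((e$dismissal_reason != "none") == (e$verification_status == "dismissed")),
      "dismissal_reason set iff dismissed")
  chk(all(is.na(e$verified_at) | e$verified_at >= e$triggered_at),
      "verified_at before triggered_at")
  chk(all(!is.na(e$verified_at) | e$verification_status == "pending"),
      "verified events need verified_at")

  sig_ids <- r$report_id[r$parse_status == "signal"]
  code_of <- stats::setNames(r$code, r$report_id)
  for (i in seq_len(nrow(e))) {
    mem <- split_members(e$member_report_ids[i])
    chk(length(mem) >= 1, sprintf("event %s has no members", e$event_id[i]))
    chk(all(mem %in% sig_ids),
        sprintf("event %s members must be signal reports", e$event_id[i]))
    chk(all(code_of[mem] == e$code[i]),
        sprintf("event %s members must share its code", e$event_id[i]))
    def <- active_ccd(ledger$ccd, e$code[i], e$triggered_at[i])
    chk(!is.null(def), sprintf("event %s has unconfigured code %d",
                               e$event_id[i], e$code[i]))
    chk(length(mem) >= def$threshold_count,
        sprintf("event %s below its CCD threshold", e$event_id[i]))
  }
  ## one event membership per signal per code
  all_mem <- unlist(lapply(e$member_report_ids, split_members))
  chk(!anyDuplicated(all_mem), "a signal belongs to more than one event")

  chk(all(a$event_id %in% e$event_id), "alert references unknown event")
  chk(!anyDuplicated(a$event_id), "more than one alert for an event")
  kept_ids <- e$event_id[e$verification_status == "kept"]
  chk(all(a$event_id %in% kept_ids), "only kept events may carry an alert")
  chk(all(a$status %in% c("escalated", "closed", "dismissed_by_authorities")),
      "invalid alert status")
  terminal <- a$status %in% c("closed", "dismissed_by_authorities")
  chk(all(!terminal | !is.na(a$closed_at)), "terminal alerts need closed_at")
  chk(all(is.na(a$closed_at) | a$closed_at >= a$escalated_at),
      "closed_at before escalated_at")
  chk(all(!(a$action_taken | a$lab_confirmed) | a$documented),
      "action_taken/lab_confirmed require a documented outcome")
  invisible(ledger)
}

log_op <- function(ledger, op, id, at, detail = "") {
  ledger$log[[length(ledger$log) + 1]] <- list(
    at = fmt_utc(as_utc(at)), op = op, id = id, detail = detail)
  ledger
}

## Lifecycle transitions -----------------------------------------------------

#' Record the supervisor's verification decision on a pending event
#'
#' Supervisors contact the reporting volunteer(s) to check that the signals
#' match the community case definition and are neither duplicates nor sent
#' incorrectly; the target is a decision within 12 hours of the event
#' triggering.
#'
#' @param ledger a `cbs_ledger`.
#' @param event_id id of a pending event.
#' @param decision `"kept"` or `"dismissed"`.
#' @param at decision timestamp (UTC), not earlier than `triggered_at`.
#' @param reason dismissal reason (`"not_matching_ccd"`, `"duplicate"`,
#'   `"sent_incorrectly"`); required iff dismissing.
#' @return the updated ledger.
#' @export
verify_event <- function(ledger, event_id, decision, at, reason = "none") {
  i <- match(event_id, ledger$events$event_id)
  if (is.na(i)) cbs_stop(sprintf("unknown event id '%s'", event_id), "cbs_unknown_id")
  ev <- ledger$events[i, ]
  if (ev$verification_status != "pending") {
    cbs_stop(sprintf("event '%s' already %s", event_id, ev$verification_status),
             "cbs_bad_state")
  }
  if (!decision %in% c("kept", "dismissed")) {
    cbs_stop("decision must be 'kept' or 'dismissed'", "cbs_bad_input")
  }
  at <- as_utc(at)
  if (at < ev$triggered_at) {
    cbs_stop("verification cannot precede the event trigger", "cbs_bad_time")
  }
  if (decision == "dismissed") {
    if (!reason %in% setdiff(DISMISSAL_REASONS, "none")) {
      cbs_stop("dismissal needs a reason", "cbs_bad_input")
    }
  } else {
    reason <- "none"
  }
  ledger$events$verification_status[i] <- decision
  ledger$events$dismissal_reason[i] <- reason
  ledger$events$verified_at[i] <- at
  log_op(ledger, "verify", event_id, at,
         if (decision == "kept") "kept" else paste0("dismissed:", reason))
}

#' Escalate a kept event as an alert to the health authority
#'
#' @param ledger a `cbs_ledger`.
#' @param event_id id of a kept, not-yet-escalated event.
#' @param at escalation timestamp, not earlier than `verified_at`.
#' @return the updated ledger, with a new alert in status `"escalated"`.
#' @export
escalate_event <- function(ledger, event_id, at) {
  i <- match(event_id, ledger$events$event_id)
  if (is.na(i)) cbs_stop(sprintf("unknown event id '%s'", event_id), "cbs_unknown_id")
  ev <- ledger$events[i, ]
  if (ev$verification_status != "kept") {
    cbs_stop(sprintf("cannot escalate a %s event", ev$verification_status),
             "cbs_bad_state")
  }
  if (event_id %in% ledger$alerts$event_id) {
    cbs_stop(sprintf("event '%s' already escalated", event_id), "cbs_bad_state")
  }
  at <- as_utc(at)
  if (at < ev$verified_at) {
    cbs_stop("escalation cannot precede verification", "cbs_bad_time")
  }
  alert_id <- sprintf("A%05d", nrow(ledger$alerts) + 1L)
  ledger$alerts <- rbind(ledger$alerts, data.frame(
    alert_id = alert_id, event_id = event_id, escalated_at = at,
    status = "escalated", closed_at = as.POSIXct(NA, tz = "UTC"),
    documented = FALSE, action_taken = FALSE, lab_confirmed = FALSE,
    notes = "", stringsAsFactors = FALSE))
  log_op(ledger, "escalate", alert_id, at, event_id)
}

#' Close an escalated alert with its documented outcome
#'
#' Closure records that some form of response occurred (referral,
#' community-level investigation, or a public-health action); the outcome
#' record captures whether anything was documented in the event log, whether
#' action was taken, and whether a laboratory test confirmed a disease.
#' Alerts the authorities rejected are closed with
#' `dismissed_by_authorities = TRUE`, a terminal status counted as a subset
#' of closed alerts.
#'
#' @param ledger a `cbs_ledger`.
#' @param alert_id id of an alert in status `"escalated"`.
#' @param at closure timestamp, not earlier than `escalated_at`.
#' @param documented,action_taken,lab_confirmed outcome flags; action or lab
#'   confirmation without documentation is an invariant breach.
#' @param dismissed_by_authorities close as authority-dismissed instead.
#' @param notes free-text outcome notes.
#' @return the updated ledger.
#' @export
close_alert <- function(ledger, alert_id, at, documented = FALSE,
                        action_taken = FALSE, lab_confirmed = FALSE,
                        dismissed_by_authorities = FALSE, notes = "") {
  i <- match(alert_id, ledger$alerts$alert_id)
  if (is.na(i)) cbs_stop(sprintf("unknown alert id '%s'", alert_id), "cbs_unknown_id")
  al <- ledger$alerts[i, ]
  if (al$status != "escalated") {
    cbs_stop(sprintf("alert '%s' is already %s", alert_id, al$status), "cbs_bad_state")
  }
  at <- as_utc(at)
  if (at < al$escalated_at) {
    cbs_stop("closure cannot precede escalation", "cbs_bad_time")
  }
  if ((action_taken || lab_confirmed) && !documented) {
    cbs_stop("action_taken/lab_confirmed require documented = TRUE",
             "cbs_invariant")
  }
  ledger$alerts$status[i] <- if (dismissed_by_authorities)
    "dismissed_by_authorities" else "closed"
  ledger$alerts$closed_at[i] <- at
  ledger$alerts$documented[i] <- documented
  ledger$alerts$action_taken[i] <- action_taken
  ledger$alerts$lab_confirmed[i] <- lab_confirmed
  ledger$alerts$notes[i] <- notes
  log_op(ledger, "close", alert_id, at,
         paste0(ledger$alerts$status[i],
                if (documented) ";documented" else "",
                if (action_taken) ";action" else "",
                if (lab_confirmed) ";lab" else ""))
}

#' Replay an ordered transition log onto a ledger
#'
#' Applies verify/escalate/close transitions in order. Replaying the same
#' log onto the same initial ledger is deterministic: the final ledgers are
#' identical.
#'
#' @param ledger the initial `cbs_ledger`.
#' @param transitions data.frame with columns `op`
#'   (verify/escalate/close), `id`, `at`, and optional `decision`, `reason`,
#'   `documented`, `action_taken`, `lab_confirmed`, `dismissed_by_authorities`.
#' @return the final ledger.
#' @export
replay_transitions <- function(ledger, transitions) {
  get_col <- function(nm, i, default) {
    if (nm %in% names(transitions)) transitions[[nm]][i] else default
  }
  for (i in seq_len(nrow(transitions))) {
    op <- transitions$op[i]
    ledger <- switch(op,
      verify = verify_event(ledger, transitions$id[i],
                            get_col("decision", i, "kept"),
                            transitions$at[i], get_col("reason", i, "none")),
      escalate = escalate_event(ledger, transitions$id[i], transitions$at[i]),
      close = close_alert(ledger, transitions$id[i], transitions$at[i],
                          documented = isTRUE(get_col("documented", i, FALSE)),
                          action_taken = isTRUE(get_col("action_taken", i, FALSE)),
                          lab_confirmed = isTRUE(get_col("lab_confirmed", i, FALSE)),
                          dismissed_by_authorities =
                            isTRUE(get_col("dismissed_by_authorities", i, FALSE))),
      cbs_stop(sprintf("unknown transition op '%s'", op), "cbs_bad_input")
    )
  }
  ledger
}

## Summary -------------------------------------------------------------------

#' Summarise a ledger into the counts behind the system-attribute metrics
#'
#' Computes exact set cardinalities: report totals by parse status, signal
#' verification totals, event counts by verification status, alert counts by
#' lifecycle status, outcome-documentation counts, per-code escalated
#' composition, verification/closure delay vectors, the 12 h / 24 h / 48 h
#' timeliness cuts, and per-week per-volunteer reporting presence.
#'
#' @param object a `cbs_ledger`.
#' @param ... unused.
#' @return object of class `cbs_summary` (a named list of counts plus the
#'   weekly completeness table).
#' @export
summary.cbs_ledger <- function(object, ...) {
  r <- object$reports; e <- object$events; a <- object$alerts
  verified <- e[e$verification_status != "pending", , drop = FALSE]
  kept <- e[e$verification_status == "kept", , drop = FALSE]
  dismissed <- e[e$verification_status == "dismissed", , drop = FALSE]
  members_of <- function(ev) unlist(lapply(ev$member_report_ids, split_members))

  closed_mask <- a$status %in% c("closed", "dismissed_by_authorities")
  closed <- a[closed_mask, , drop = FALSE]

  esc_codes <- e$code[match(a$event_id, e$event_id)]
  codes <- configured_codes(object$ccd)
  per_code <- stats::setNames(
    vapply(codes, function(cd) sum(esc_codes == cd), integer(1)),
    as.character(codes))

  ver_delay <- hours_between(verified$triggered_at, verified$verified_at)
  close_delay <- hours_between(closed$escalated_at, closed$closed_at)

  wk <- weekly_completeness(r, object$volunteers,
                            week_calendar(object$period_start, object$period_end))

  structure(list(
    region = object$region,
    period_start = object$period_start, period_end = object$period_end,
    n_volunteers = nrow(object$volunteers),
    n_reports = nrow(r),
    n_correct_format = sum(r$parse_status != "malformed"),
    n_malformed = sum(r$parse_status == "malformed"),
    n_zero_reports = sum(r$parse_status == "zero"),
    n_signals_sent = sum(r$parse_status == "signal"),
    n_signals_verified = length(members_of(verified)),
    n_signals_kept = length(members_of(kept)),
    n_events = nrow(e),
    n_events_kept = nrow(kept),
    n_events_dismissed = nrow(dismissed),
    n_events_pending = sum(e$verification_status == "pending"),
    n_alerts_escalated = nrow(a),
    n_alerts_closed = nrow(closed),
    n_alerts_open = sum(a$status == "escalated"),
    n_dismissed_by_authorities = sum(a$status == "dismissed_by_authorities"),
    n_documented = sum(closed$documented),
    n_action_taken = sum(closed$action_taken),
    n_lab_confirmed = sum(closed$lab_confirmed),
    per_code_escalated = per_code,
    verification_delays_h = ver_delay,
    closure_delays_h = close_delay,
    n_verified_within_12h = sum(ver_delay <= 12),
    n_verified_within_24h = sum(ver_delay <= 24),
    n_closed_within_48h = sum(close_delay <= 48),
    weekly_presence = wk$weekly,
    weekly_completeness_avg = wk$average
  ), class = "cbs_summary")
}

#' @export
print.cbs_summary <- function(x, ...) {
  cat(sprintf("CBS ledger summary - %s (%s to %s)\n", x$region,
              format(x$period_start, "%Y-%m-%d"), format(x$period_end, "%Y-%m-%d")))
  cat(sprintf("  volunteers: %d; reports: %d (%d correct format, %d zero, %d malformed)\n",
              x$n_volunteers, x$n_reports, x$n_correct_format,
              x$n_zero_reports, x$n_malformed))
  cat(sprintf("  signals: %d sent / %d verified / %d kept\n",
              x$n_signals_sent, x$n_signals_verified, x$n_signals_kept))
  cat(sprintf("  events: %d triggered = %d kept + %d dismissed + %d pending\n",
              x$n_events, x$n_events_kept, x$n_events_dismissed, x$n_events_pending))
  cat(sprintf("  alerts: %d escalated, %d closed (%d dismissed by authorities), %d open\n",
              x$n_alerts_escalated, x$n_alerts_closed,
              x$n_dismissed_by_authorities, x$n_alerts_open))
  cat(sprintf("  outcomes: %d documented, %d action taken, %d lab confirmed\n",
              x$n_documented, x$n_action_taken, x$n_lab_confirmed))
  if (!is.na(x$weekly_completeness_avg)) {
    cat(sprintf("  weekly completeness: average %.1f%% over %d weeks\n",
                100 * x$weekly_completeness_avg, nrow(x$weekly_presence)))
  }
  invisible(x)
}

#' @export
print.cbs_ledger <- function(x, ...) {
  cat(sprintf("<cbs_ledger> %s: %d volunteers, %d reports, %d events, %d alerts\n",
              x$region, nrow(x$volunteers), nrow(x$reports),
              nrow(x$events), nrow(x$alerts)))
  invisible(x)
}

#' Plot weekly completeness for a ledger summary
#'
#' @param x a `cbs_summary`.
#' @param ... passed to `plot()`.
#' @export
plot.cbs_summary <- function(x, ...) {
  wp <- x$weekly_presence
  wp <- wp[wp$n_active > 0, , drop = FALSE]
  if (nrow(wp) == 0) {
    cbs_stop("no weeks with active volunteers to plot", "cbs_bad_input")
  }
  graphics::plot(seq_len(nrow(wp)), 100 * wp$fraction, type = "b", pch = 16,
                 xlab = "week of period", ylab = "weekly completeness (%)",
                 ylim = c(0, 100),
                 main = sprintf("%s: volunteers reporting each week", x$region), ...)
  graphics::abline(h = 100 * x$weekly_completeness_avg, lty = 2, col = "grey40")
  invisible(x)
}
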