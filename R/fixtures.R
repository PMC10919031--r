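#' Marginal counts describing one region-year of a CBS programme
#'
#' A fixture spec is the full set of descriptive counts for one region:
#' report volumes, signal verification totals, event and alert lifecycle
#' counts, per-code composition of escalated alerts, outcome documentation
#' and the timeliness cuts. [fixture_from_marginals()] materialises a
#' ledger whose [summary.cbs_ledger()] reproduces every one of these counts
#' exactly.
#'
#' @param region region label.
#' @param n_villages,n_volunteers roster size.
#' @param events_triggered,events_kept,events_dismissed event counts (all
#'   kept events are escalated).
#' @param per_code_escalated named integer vector over CCD codes, summing
#'   to `events_kept`.
#' @param dismissed_by_authorities,documented,action_taken,lab_confirmed
#'   alert outcome counts (all escalated alerts are closed).
#' @param total_reports,correct_format report volumes.
#' @param signals_sent,signals_verified,signals_kept signal-level totals.
#' @param verified_within_12h,verified_within_24h,closed_within_48h
#'   timeliness-cut counts.
#' @return object of class `cbs_fixture_spec`.
#' @export
fixture_spec <- function(region, n_villages, n_volunteers,
                         events_triggered, events_kept, events_dismissed,
                         per_code_escalated,
                         dismissed_by_authorities, documented, action_taken,
                         lab_confirmed,
                         total_reports, correct_format,
                         signals_sent, signals_verified, signals_kept,
                         verified_within_12h, verified_within_24h,
                         closed_within_48h) {
  spec <- structure(as.list(environment()), class = "cbs_fixture_spec")
  validate_fixture_spec(spec)
  spec
}

validate_fixture_spec <- function(spec) {
  bad <- function(ineq) {
    cbs_stop(paste("inconsistent fixture spec:", ineq), "cbs_bad_fixture_spec")
  }
  with(spec, {
    if (events_kept + events_dismissed != events_triggered)
      bad("events_kept + events_dismissed != events_triggered")
    if (sum(per_code_escalated) != events_kept)
      bad("sum(per_code_escalated) != events_kept")
    if (dismissed_by_authorities > events_kept)
      bad("dismissed_by_authorities > alerts closed")
    if (documented > events_kept) bad("documented > alerts closed")
    if (action_taken > documented) bad("action_taken > documented")
    if (lab_confirmed > action_taken) bad("lab_confirmed > action_taken")
    if (correct_format > total_reports) bad("correct_format > total_reports")
    if (signals_sent > correct_format) bad("signals_sent > correct_format")
    if (signals_verified > signals_sent) bad("signals_verified > signals_sent")
    if (signals_kept > signals_verified) bad("signals_kept > signals_verified")
    if (verified_within_12h > verified_within_24h)
      bad("verified_within_12h > verified_within_24h")
    if (verified_within_24h > events_triggered)
      bad("verified_within_24h > events_triggered")
    if (closed_within_48h > events_kept) bad("closed_within_48h > alerts closed")

    cluster_kept <- per_code_escalated[["2"]]
    singles_kept <- events_kept - cluster_kept
    m_kept <- signals_kept - singles_kept
    if (m_kept < 5 * cluster_kept)
      bad("signals_kept too small for the cluster events (need >= 5 members each)")
    if (cluster_kept == 0 && m_kept > 0)
      bad("signals_kept exceeds kept single-report events with no cluster events")
    m_dis <- signals_verified - signals_kept
    if (m_dis < events_dismissed)
      bad("signals_verified - signals_kept < events_dismissed")
    extra <- m_dis - events_dismissed
    if (extra > 0 && (events_dismissed == 0 || extra < 4))
      bad("dismissed-event members cannot be partitioned (singles take 1, cluster events >= 5)")
  })
  invisible(spec)
}

#' The published Awdal 2021 marginals
#'
#' 100 volunteers in 23 villages; 4318 reports (96 percent correct format);
#' 395 signals of which 331 verified and 295 kept; 138 events (115
#' escalated, 23 dismissed); all 115 alerts closed, 10 dismissed by the
#' authorities, 72 with a documented outcome, 61 with action taken;
#' verification within 12/24 h for 104/116 events, closure within 48 h for
#' 77 alerts.
#'
#' @return a `cbs_fixture_spec`.
#' @export
awdal_fixture_spec <- function() {
  fixture_spec(
    region = "Awdal", n_villages = 23L, n_volunteers = 100L,
    events_triggered = 138L, events_kept = 115L, events_dismissed = 23L,
    per_code_escalated = c("2" = 29L, "4" = 31L, "9" = 53L, "14" = 2L),
    dismissed_by_authorities = 10L, documented = 72L, action_taken = 61L,
    lab_confirmed = 0L,
    total_reports = 4318L, correct_format = 4144L,
    signals_sent = 395L, signals_verified = 331L, signals_kept = 295L,
    verified_within_12h = 104L, verified_within_24h = 116L,
    closed_within_48h = 77L)
}

#' The published Togdheer 2021 marginals
#'
#' 139 volunteers in 67 villages; 5243 reports (99 percent correct format);
#' 548 signals of which 507 verified and 502 kept; 218 events (213
#' escalated, 5 dismissed); all 213 alerts closed, 2 dismissed by the
#' authorities, 136 documented, 133 with action taken, 15 laboratory
#' confirmed; verification within 12/24 h for 202/212 events, closure
#' within 48 h for 161 alerts.
#'
#' @return a `cbs_fixture_spec`.
#' @export
togdheer_fixture_spec <- function() {
  fixture_spec(
    region = "Togdheer", n_villages = 67L, n_volunteers = 139L,
    events_triggered = 218L, events_kept = 213L, events_dismissed = 5L,
    per_code_escalated = c("2" = 44L, "4" = 35L, "9" = 122L, "14" = 12L),
    dismissed_by_authorities = 2L, documented = 136L, action_taken = 133L,
    lab_confirmed = 15L,
    total_reports = 5243L, correct_format = 5210L,
    signals_sent = 548L, signals_verified = 507L, signals_kept = 502L,
    verified_within_12h = 202L, verified_within_24h = 212L,
    closed_within_48h = 161L)
}

#' Materialise a deterministic ledger from marginal counts
#'
#' Builds, without any randomness, a complete ledger whose summary
#' reproduces every count of the spec exactly. Villages sit on a fixed
#' coordinate grid spaced far beyond the cluster radius; events sit on an
#' hourly grid with verification delays of 1, 18 or 36 h chosen to hit the
#' 12 h / 24 h cuts exactly, and closure delays of 24 or 72 h for the 48 h
#' cut. Cluster-code events hold at least five co-located member signals;
#' single-report events hold exactly one. Zero reports and malformed
#' reports are spread round-robin over volunteer-weeks.
#'
#' @param spec a [fixture_spec()].
#' @return a validated `cbs_ledger`.
#' @export
fixture_from_marginals <- function(spec) {
  validate_fixture_spec(spec)
  ps <- as_utc("2021-01-04"); pe <- as_utc("2022-01-03")
  ccd <- default_ccd_config()
  dialect <- dialect_config(configured_codes(ccd))
  cal <- week_calendar(ps, pe)
  cal <- cal[cal$week_end <= pe + 1, , drop = FALSE]
  n_wk <- nrow(cal)

  ## village grid: 0.6 degree spacing (> 60 km) so villages never co-cluster
  nv <- spec$n_villages
  gi <- (seq_len(nv) - 1) %% 8; gj <- (seq_len(nv) - 1) %/% 8
  vlat <- 8.5 + 0.6 * gi; vlon <- 43.5 + 0.6 * gj
  vil_of <- ((seq_len(spec$n_volunteers) - 1) %% nv) + 1
  volunteers <- data.frame(
    volunteer_id = make_ids("V", spec$n_volunteers, 4),
    village_id = sprintf("VG%03d", vil_of),
    phone_token = sprintf("T%04d", seq_len(spec$n_volunteers)),
    lat = vlat[vil_of], lon = vlon[vil_of],
    active_from = ps, active_to = pe, stringsAsFactors = FALSE)
  vols_in_vil <- split(seq_len(spec$n_volunteers), vil_of)

  ## --- event plan ----------------------------------------------------------
  ## kept events first (escalation order), then dismissed events
  cl_kept <- spec$per_code_escalated[["2"]]
  singles_kept <- c(rep(4L, spec$per_code_escalated[["4"]]),
                    rep(9L, spec$per_code_escalated[["9"]]),
                    rep(14L, spec$per_code_escalated[["14"]]))
  m_kept <- spec$signals_kept - length(singles_kept)
  kept_sizes <- if (cl_kept > 0) {
    sz <- rep(5L, cl_kept); sz[1] <- sz[1] + (m_kept - 5L * cl_kept); sz
  } else integer(0)
  m_dis <- spec$signals_verified - spec$signals_kept
  extra <- m_dis - spec$events_dismissed
  if (extra >= 4) {
    dis_codes <- c(2L, rep(4L, spec$events_dismissed - 1L))
    dis_sizes <- c(5L + (extra - 4L), rep(1L, spec$events_dismissed - 1L))
  } else {
    dis_codes <- rep(4L, spec$events_dismissed)
    dis_sizes <- rep(1L, spec$events_dismissed)
  }
  ev_code <- c(rep(2L, cl_kept), singles_kept, dis_codes)
  ev_size <- c(kept_sizes, rep(1L, length(singles_kept)), dis_sizes)
  ev_kept <- c(rep(TRUE, spec$events_kept), rep(FALSE, spec$events_dismissed))
  n_ev <- length(ev_code)

  ## hourly trigger grid; verification delays hit the 12/24 h cuts exactly
  trig <- ps + 3600 * seq_len(n_ev)
  v_delay_h <- c(rep(1, spec$verified_within_12h),
                 rep(18, spec$verified_within_24h - spec$verified_within_12h),
                 rep(36, n_ev - spec$verified_within_24h))
  ver_at <- trig + 3600 * v_delay_h

  ## member signals: event i gets ev_size[i] signals at its village, minutes
  ## before the trigger (cluster members co-located, inside window/radius)
  mem_rows <- vector("list", n_ev)
  mem_ids <- vector("list", n_ev)
  sid <- 0L
  for (i in seq_len(n_ev)) {
    k <- ev_size[i]
    vil <- ((i - 1) %% nv) + 1
    vv <- vols_in_vil[[vil]]
    ids <- make_ids("S", k + sid, 5)[(sid + 1):(sid + k)]
    sid <- sid + k
    mem_ids[[i]] <- ids
    mem_rows[[i]] <- data.frame(
      report_id = ids,
      volunteer_id = volunteers$volunteer_id[vv[((seq_len(k) - 1) %% length(vv)) + 1]],
      received_at = trig[i] - 60 * (k - seq_len(k)),
      payload = as.character(ev_code[i]), stringsAsFactors = FALSE)
  }

  ## loose signals (sent but never part of a verified event): code 2, at
  ## most one per village-week so they can never form a cluster
  n_loose <- spec$signals_sent - spec$signals_verified
  loose <- if (n_loose > 0) {
    j <- seq_len(n_loose) - 1L
    vil <- (j %% nv) + 1L
    wk <- ((j %/% nv) %% n_wk) + 1L
    data.frame(
      report_id = make_ids("S", sid + n_loose, 5)[(sid + 1):(sid + n_loose)],
      volunteer_id = volunteers$volunteer_id[vapply(vil, function(v) vols_in_vil[[v]][1], integer(1))],
      received_at = cal$week_start[wk] + 3 * 24 * 3600 + 60 * j,
      payload = "2", stringsAsFactors = FALSE)
  } else NULL

  ## zero reports round-robin over volunteer-weeks, near the week end
  n_zero <- spec$correct_format - spec$signals_sent
  zero <- if (n_zero > 0) {
    j <- seq_len(n_zero) - 1L
    vol <- (j %% spec$n_volunteers) + 1L
    wk <- ((j %/% spec$n_volunteers) %% n_wk) + 1L
    data.frame(
      report_id = make_ids("Z", n_zero, 5),
      volunteer_id = volunteers$volunteer_id[vol],
      received_at = cal$week_start[wk] + (6 * 24 + 12) * 3600 + j,
      payload = dialect$zero_token, stringsAsFactors = FALSE)
  } else NULL

  n_mal <- spec$total_reports - spec$correct_format
  mal <- if (n_mal > 0) {
    j <- seq_len(n_mal) - 1L
    data.frame(
      report_id = make_ids("M", n_mal, 5),
      volunteer_id = volunteers$volunteer_id[(j %% spec$n_volunteers) + 1L],
      received_at = cal$week_start[(j %% n_wk) + 1L] + 2 * 24 * 3600 + j,
      payload = "XX", stringsAsFactors = FALSE)
  } else NULL

  raw <- do.call(rbind, c(mem_rows, list(loose, zero, mal)))
  reports <- parse_reports(raw, dialect)

  events <- data.frame(
    event_id = make_ids("E", n_ev, 5),
    code = ev_code,
    member_report_ids = vapply(mem_ids, join_members, character(1)),
    triggered_at = trig,
    anchor_lat = vlat[((seq_len(n_ev) - 1) %% nv) + 1],
    anchor_lon = vlon[((seq_len(n_ev) - 1) %% nv) + 1],
    verification_status = ifelse(ev_kept, "kept", "dismissed"),
    dismissal_reason = ifelse(ev_kept, "none", "not_matching_ccd"),
    verified_at = ver_at, stringsAsFactors = FALSE)

  ## alerts: one per kept event, escalated at verification; closure delays
  ## of 24 h (within the 48 h cut) or 72 h; outcomes assigned front-to-back,
  ## authority dismissals back-to-front
  ka <- which(ev_kept)
  n_al <- length(ka)
  c_delay_h <- c(rep(24, spec$closed_within_48h),
                 rep(72, n_al - spec$closed_within_48h))
  al_idx <- seq_len(n_al)
  dba <- al_idx > n_al - spec$dismissed_by_authorities
  doc <- al_idx <= spec$documented
  act <- al_idx <= spec$action_taken
  lab <- al_idx <= spec$lab_confirmed
  alerts <- data.frame(
    alert_id = make_ids("A", n_al, 5),
    event_id = events$event_id[ka],
    escalated_at = events$verified_at[ka],
    status = ifelse(dba, "dismissed_by_authorities", "closed"),
    closed_at = events$verified_at[ka] + 3600 * c_delay_h,
    documented = doc, action_taken = act, lab_confirmed = lab,
    notes = "", stringsAsFactors = FALSE)

  cbs_ledger(spec$region, ps, pe, volunteers = volunteers, reports = reports,
             events = events, alerts = alerts, ccd = ccd, validate = TRUE)
}
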