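## Ledger serialisation: a directory of four RFC-4180 CSV tables plus the
## CCD configuration (JSON), period metadata, and the append-only
## transition log as JSON lines. All timestamps ISO-8601 UTC; all files
## UTF-8. write_ledger() %>% read_ledger() is the identity on every field.

ts_cols <- list(
  volunteers = c("active_from", "active_to"),
  reports = "received_at",
  events = c("triggered_at", "verified_at"),
  alerts = c("escalated_at", "closed_at")
)

#' Write a ledger to a directory
#'
#' @param ledger a `cbs_ledger`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_ledger <- function(ledger, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in c("volunteers", "reports", "events", "alerts")) {
    df <- ledger[[tab]]
    for (cl in ts_cols[[tab]]) df[[cl]] <- fmt_utc(df[[cl]])
    utils::write.csv(df, file.path(dir, paste0(tab, ".csv")),
                     row.names = FALSE, na = "", fileEncoding = "UTF-8")
  }
  write_ccd_config(ledger$ccd, file.path(dir, "ccd_config.json"))
  jsonlite::write_json(
    list(region = ledger$region,
         period_start = fmt_utc(ledger$period_start),
         period_end = fmt_utc(ledger$period_end)),
    file.path(dir, "meta.json"), auto_unbox = TRUE, pretty = TRUE)
  ## structured event log: one JSON object per transition
  con <- file(file.path(dir, "log.jsonl"), open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (entry in ledger$log) {
    writeLines(jsonlite::toJSON(entry, auto_unbox = TRUE), con)
  }
  invisible(dir)
}

read_table_utc <- function(path, tabs, col_classes) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = col_classes, fileEncoding = "UTF-8")
  for (cl in ts_cols[[tabs]]) {
    x <- as.character(df[[cl]])
    x[!is.na(x) & x == ""] <- NA_character_
    df[[cl]] <- as_utc(x)
  }
  df
}

#' Read a ledger directory
#'
#' @param dir directory written by [write_ledger()].
#' @param validate run [validate_ledger()] after reading (default TRUE).
#' @return a `cbs_ledger`.
#' @export
read_ledger <- function(dir, validate = TRUE) {
  need <- file.path(dir, c("volunteers.csv", "reports.csv", "events.csv",
                           "alerts.csv", "ccd_config.json", "meta.json"))
  missing <- need[!file.exists(need)]
  if (length(missing)) {
    cbs_stop(paste("missing ledger files:", paste(basename(missing), collapse = ", ")),
             "cbs_bad_input")
  }
  meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  vol <- read_table_utc(file.path(dir, "volunteers.csv"), "volunteers",
                        c(volunteer_id = "character", village_id = "character",
                          phone_token = "character", lat = "numeric",
                          lon = "numeric", active_from = "character",
                          active_to = "character"))
  rep <- read_table_utc(file.path(dir, "reports.csv"), "reports",
                        c(report_id = "character", volunteer_id = "character",
                          received_at = "character", payload = "character",
                          parse_status = "character", code = "integer"))
  ev <- read_table_utc(file.path(dir, "events.csv"), "events",
                       c(event_id = "character", code = "integer",
                         member_report_ids = "character",
                         triggered_at = "character", anchor_lat = "numeric",
                         anchor_lon = "numeric",
                         verification_status = "character",
                         dismissal_reason = "character",
                         verified_at = "character"))
  al <- read_table_utc(file.path(dir, "alerts.csv"), "alerts",
                       c(alert_id = "character", event_id = "character",
                         escalated_at = "character", status = "character",
                         closed_at = "character", documented = "logical",
                         action_taken = "logical", lab_confirmed = "logical",
                         notes = "character"))
  al$notes[is.na(al$notes)] <- ""
  led <- cbs_ledger(meta$region, meta$period_start, meta$period_end,
                    volunteers = vol, reports = rep, events = ev, alerts = al,
                    ccd = read_ccd_config(file.path(dir, "ccd_config.json")),
                    validate = validate)
  logp <- file.path(dir, "log.jsonl")
  if (file.exists(logp)) {
    lines <- readLines(logp, encoding = "UTF-8")
    led$log <- lapply(lines, function(l) jsonlite::fromJSON(l))
  }
  led
}

#' Export ledger point locations as GeoJSON
#'
#' Writes a FeatureCollection of points: either every signal report
#' (located at the reporting volunteer's village) or every event/alert
#' anchor.
#'
#' @param ledger a `cbs_ledger`.
#' @param path output file.
#' @param what `"signals"` or `"events"`.
#' @return `path`, invisibly.
#' @export
export_geojson <- function(ledger, path, what = c("events", "signals")) {
  what <- match.arg(what)
  if (what == "signals") {
    sig <- ledger$reports[ledger$reports$parse_status == "signal", , drop = FALSE]
    i <- match(sig$volunteer_id, ledger$volunteers$volunteer_id)
    feats <- lapply(seq_len(nrow(sig)), function(k) list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(ledger$volunteers$lon[i[k]],
                                      ledger$volunteers$lat[i[k]])),
      properties = list(report_id = sig$report_id[k], code = sig$code[k],
                        received_at = fmt_utc(sig$received_at[k]))))
  } else {
    ev <- ledger$events
    feats <- lapply(seq_len(nrow(ev)), function(k) list(
      type = "Feature",
      geometry = list(type = "Point",
                      coordinates = c(ev$anchor_lon[k], ev$anchor_lat[k])),
      properties = list(event_id = ev$event_id[k], code = ev$code[k],
                        triggered_at = fmt_utc(ev$triggered_at[k]),
                        verification_status = ev$verification_status[k])))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run the evaluated pipeline end to end
#'
#' Stages, in the programme's flow order: load (or build) the ledger,
#' validate it, evaluate thresholds for any unprocessed raw input,
#' summarise, compute the attribute report, and write artifacts — the
#' ledger directory, `attributes.json` (flat metrics plus counts),
#' `metrics.md` (human-readable table), an events GeoJSON, and
#' `manifest.json` with the checksums of every input and output, so a rerun
#' on identical inputs provably reproduces identical outputs. A stage
#' failure aborts with the failing stage named.
#'
#' @param ledger_dir directory of an existing ledger; or
#' @param raw_reports data.frame of raw submissions (volunteer_id,
#'   received_at, payload) with `roster`, `region`, `period_start`,
#'   `period_end` to build a fresh ledger (events are evaluated, left
#'   pending).
#' @param roster volunteers data.frame (only with `raw_reports`).
#' @param region,period_start,period_end ledger frame (only with
#'   `raw_reports`).
#' @param ccd a `cbs_ccd_config`.
#' @param dialect a `cbs_dialect`.
#' @param out_dir output directory.
#' @return the `cbs_attribute_report`, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(ledger_dir = NULL, raw_reports = NULL, roster = NULL,
                         region = "region", period_start = NULL,
                         period_end = NULL,
                         ccd = default_ccd_config(),
                         dialect = dialect_config(configured_codes(ccd)),
                         out_dir) {
  stage <- function(name, expr) {
    tryCatch(force(expr), error = function(e) {
      cbs_stop(sprintf("pipeline stage '%s' failed: %s", name,
                       conditionMessage(e)), "cbs_stage_failure")
    })
  }
  if (is.null(ledger_dir) == is.null(raw_reports)) {
    cbs_stop("give exactly one of ledger_dir or raw_reports", "cbs_bad_config")
  }
  inputs <- character(0)
  if (!is.null(ledger_dir)) {
    ledger <- stage("load", read_ledger(ledger_dir, validate = TRUE))
    inputs <- list.files(ledger_dir, full.names = TRUE)
  } else {
    if (is.null(roster) || is.null(period_start) || is.null(period_end)) {
      cbs_stop("raw_reports mode needs roster, period_start, period_end",
               "cbs_bad_config")
    }
    reports <- stage("ingest", parse_reports(raw_reports, dialect))
    events <- stage("alerts", evaluate_stream(reports, roster, ccd))
    ledger <- stage("assemble",
                    cbs_ledger(region, period_start, period_end,
                               volunteers = roster, reports = reports,
                               events = events, ccd = ccd))
  }
  s <- stage("summarize", summary(ledger))
  rep <- stage("metrics", cbs_attributes(s))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  led_dir <- file.path(out_dir, "ledger")
  stage("write", {
    write_ledger(ledger, led_dir)
    jsonlite::write_json(
      c(list(region = ledger$region), attributes_flat(rep),
        list(counts = s[grep("^n_", names(s))])),
      file.path(out_dir, "attributes.json"),
      auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
    writeLines(attributes_markdown(rep), file.path(out_dir, "metrics.md"))
    export_geojson(ledger, file.path(out_dir, "events.geojson"), "events")
  })
  outputs <- c(list.files(led_dir, full.names = TRUE),
               file.path(out_dir, c("attributes.json", "metrics.md",
                                    "events.geojson")))
  manifest <- list(
    package_version = as.character(utils::packageVersion("cbsengine")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    inputs = as.list(tools::md5sum(inputs)),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(rep)
}
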