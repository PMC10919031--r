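test_that("pct renders integer percentages under round-half-up", {
  expect_equal(pct(115, 138)$percent, 83L)
  expect_equal(pct(61, 72)$percent, 85L)
  expect_equal(pct(0, 17)$percent, 0L)
  expect_equal(pct(17, 17)$percent, 100L)
  expect_equal(pct(185, 200)$percent, 93L)   # 92.5 rounds up
  expect_equal(pct(1, 200)$percent, 1L)      # 0.5 rounds up
  expect_equal(pct(213, 218)$percent, 98L)   # 97.7
  expect_true(is.na(pct(0, 0)$percent))
  expect_cbs_error(pct(5, 4), "cbs_bad_input")
  expect_equal(pct(29, 115)$fraction, 29 / 115)
})

## the full expected renderings for the two regional fixtures, frozen from
## the published descriptive counts
expected_attributes <- list(
  Awdal = list(escalation = 83L, supervisor_dismissal = 17L, response = 100L,
               composition = c("2" = 25L, "4" = 27L, "9" = 46L, "14" = 2L),
               verified_of_sent = 84L, kept_of_verified = 89L,
               correct_format = 96L,
               documented_outcome = 63L, action_taken = 85L,
               lab_confirmed_of_actioned = 0L, dismissed_by_authorities = 9L,
               verified_within_12h = 75L, verified_within_24h = 84L,
               closed_within_48h = 67L),
  Togdheer = list(escalation = 98L, supervisor_dismissal = 2L, response = 100L,
                  composition = c("2" = 21L, "4" = 16L, "9" = 57L, "14" = 6L),
                  verified_of_sent = 93L, kept_of_verified = 99L,
                  correct_format = 99L,
                  documented_outcome = 64L, action_taken = 98L,
                  lab_confirmed_of_actioned = 11L, dismissed_by_authorities = 1L,
                  verified_within_12h = 93L, verified_within_24h = 97L,
                  closed_within_48h = 76L)
)

test_that("regional fixtures reproduce every published attribute rendering", {
  specs <- list(Awdal = awdal_fixture_spec(), Togdheer = togdheer_fixture_spec())
  for (rg in names(specs)) {
    rep <- cbs_attributes(fixture_from_marginals(specs[[rg]]))
    want <- expected_attributes[[rg]]
    expect_equal(rep$usefulness$escalation$percent, want$escalation, info = rg)
    expect_equal(rep$usefulness$supervisor_dismissal$percent,
                 want$supervisor_dismissal, info = rg)
    expect_equal(rep$usefulness$response$percent, want$response, info = rg)
    got_comp <- vapply(rep$usefulness$composition, function(p) p$percent, integer(1))
    expect_equal(got_comp, want$composition, info = rg)
    expect_equal(rep$simplicity$verified_of_sent$percent, want$verified_of_sent,
                 info = rg)
    expect_equal(rep$simplicity$kept_of_verified$percent, want$kept_of_verified,
                 info = rg)
    expect_equal(rep$data_quality$correct_format$percent, want$correct_format,
                 info = rg)
    expect_equal(rep$sensitivity$documented_outcome$percent,
                 want$documented_outcome, info = rg)
    expect_equal(rep$sensitivity$action_taken$percent, want$action_taken, info = rg)
    expect_equal(rep$sensitivity$lab_confirmed_of_actioned$percent,
                 want$lab_confirmed_of_actioned, info = rg)
    expect_equal(rep$sensitivity$dismissed_by_authorities$percent,
                 want$dismissed_by_authorities, info = rg)
    expect_equal(rep$timeliness$verified_within_12h$percent,
                 want$verified_within_12h, info = rg)
    expect_equal(rep$timeliness$verified_within_24h$percent,
                 want$verified_within_24h, info = rg)
    expect_equal(rep$timeliness$closed_within_48h$percent,
                 want$closed_within_48h, info = rg)
  }
})

test_that("zero denominators propagate typed nulls, never errors", {
  led <- cbs_ledger("void", "2021-01-04", "2021-02-01")
  rep <- cbs_attributes(led)
  expect_true(is.na(rep$usefulness$escalation$percent))
  expect_true(is.na(rep$simplicity$verified_of_sent$percent))
  expect_true(is.na(rep$timeliness$closed_within_48h$percent))
  expect_true(is.na(rep$data_quality$correct_format$percent))
  expect_equal(rep$sensitivity$note, "insufficient documentation")
  expect_no_error(attributes_markdown(rep))
})

test_that("attribute reports are invariant under row permutation of the ledger", {
  led <- simulate_programme(rand_sim_config(4242))
  shuf <- led
  set.seed(1)
  shuf$reports <- shuf$reports[sample(nrow(shuf$reports)), , drop = FALSE]
  shuf$events <- shuf$events[sample(nrow(shuf$events)), , drop = FALSE]
  shuf$alerts <- shuf$alerts[sample(nrow(shuf$alerts)), , drop = FALSE]
  a <- cbs_attributes(led); b <- cbs_attributes(shuf)
  for (grp in c("usefulness", "simplicity", "data_quality", "sensitivity",
                "timeliness")) {
    expect_equal(a[[grp]], b[[grp]], info = grp)
  }
})

test_that("escalation and supervisor-dismissal shares reconstruct 100%", {
  for (seed in 1:15) {
    led <- simulate_programme(rand_sim_config(3300 + seed))
    s <- summary(led)
    if (s$n_events == 0 || s$n_events_pending > 0) next
    u <- usefulness(s)
    expect_lte(abs(u$escalation$percent + u$supervisor_dismissal$percent - 100), 1)
  }
})

test_that("metrics on a large simulated ledger converge to the configured rates", {
  ## ~10,000 single-report events: every signal becomes an event
  cfg <- sim_config(n_villages = 400, volunteers_per_village = 2,
                    p_weekly_report = 0.5, p_malformed = 0.04,
                    background_rates = c("2" = 0, "4" = 0.24, "9" = 0.24, "14" = 0),
                    p_verify_within_12h = 0.8, p_supervisor_dismiss = 0.1,
                    p_close_within_48h = 0.7, p_documented = 0.6,
                    seed = 77L)
  s <- summary(simulate_programme(cfg))
  expect_gt(s$n_events, 8000)
  se <- function(p, n) sqrt(p * (1 - p) / n)
  expect_lt(abs(s$n_verified_within_12h / s$n_events - 0.8),
            3 * se(0.8, s$n_events))
  expect_lt(abs(s$n_closed_within_48h / s$n_alerts_closed - 0.7),
            3 * se(0.7, s$n_alerts_closed))
  expect_lt(abs(s$n_documented / s$n_alerts_closed - 0.6),
            3 * se(0.6, s$n_alerts_closed))
  expect_lt(abs(s$n_correct_format / s$n_reports - 0.96),
            3 * se(0.96, s$n_reports))
  expect_lt(abs(s$n_events_dismissed / s$n_events - 0.1),
            3 * se(0.1, s$n_events))
})
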