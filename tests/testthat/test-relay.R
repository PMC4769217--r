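# A wired store+relay pair with one HCP and two experts.
relay_setup <- function(at = "2026-03-01T12:00:00Z", on_call = "exp1") {
  clk <- fixed_clock(at)
  st <- case_store(clock = clk)
  register_user(st, "hcp1", "hcp")
  rl <- relay(clock = clk, on_call_expert = on_call)
  for (u in c("exp1", "exp2")) register_user(rl, u, "expert")
  for (u in c("hcp1", "hcp2")) register_user(rl, u, "hcp")
  register_user(rl, "root", "admin")
  list(store = st, relay = rl)
}

test_that("enqueue alerts the on-call expert exactly once per case", {
  s <- relay_setup()
  case <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  expect_identical(case$status, "pending_expert")
  expect_length(s$relay$outbox, 1)
  n <- s$relay$outbox[[1]]
  expect_identical(n$channel, "sms")
  expect_identical(n$recipient, "exp1")
  expect_identical(n$kind, "new_case")
  # second enqueue of the same case is a no-op
  enqueue_case(s$relay, case)
  expect_length(s$relay$outbox, 1)
  # no expert on call is a configuration error
  s2 <- relay_setup(on_call = NULL)
  expect_error(submit_case(make_complete_case(s2$store, TEST_AVATAR, TEST_LB),
                           s2$relay),
               class = "burnflow_config_error")
})

test_that("pending lists are per-expert and oldest-first", {
  s <- relay_setup()
  expect_length(pending_cases(s$relay, "exp1", open_session(s$relay, "exp1")),
                0)
  c1 <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  s$store$clock <- fixed_clock("2026-03-01T13:00:00Z")
  s$relay$clock <- s$store$clock
  c2 <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  session <- open_session(s$relay, "exp1")
  got <- pending_cases(s$relay, "exp1", session)
  expect_identical(vapply(got, function(x) x$reference_id, character(1)),
                   c(c1$reference_id, c2$reference_id))
  # another expert's queue never shows these cases
  s2 <- open_session(s$relay, "exp2")
  expect_length(pending_cases(s$relay, "exp2", s2), 0)
})

test_that("responding attaches advice, notifies HCP twice, closes the metric", {
  s <- relay_setup()
  case <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  # respond 45 minutes after submission
  s$relay$clock <- fixed_clock("2026-03-01T12:45:00Z")
  advice <- expert_advice(where_to_treat = "refer", transport_required = TRUE,
                          fluids_advice = "continue Parkland plan")
  case <- respond(s$relay, "exp1", case$reference_id, advice)
  expect_identical(case$status, "advised")
  expect_identical(case$expert_advice$responder, "exp1")
  hcp_notes <- Filter(function(n) n$kind == "new_advice", s$relay$outbox)
  expect_length(hcp_notes, 2)
  expect_setequal(vapply(hcp_notes, function(n) n$channel, character(1)),
                  c("sms", "email"))
  expect_true(all(vapply(hcp_notes, function(n) n$recipient, character(1)) ==
                    "hcp1"))
  m <- s$relay$metrics[[case$reference_id]]
  expect_equal(m$expert_response_duration_min, 45)

  # only the assigned expert may respond; advice must be non-empty
  case2 <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  expect_error(respond(s$relay, "exp2", case2$reference_id, advice),
               class = "burnflow_auth_error")
  expect_error(expert_advice(), class = "burnflow_validation_error")
})

test_that("follow-up reopens the consultation and notifies the expert", {
  s <- relay_setup()
  case <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  case <- respond(s$relay, "exp1", case$reference_id,
                  expert_advice(free_text = "dress and review tomorrow"))
  n_before <- length(s$relay$outbox)
  expect_error(hcp_followup(s$relay, "hcp2", case$reference_id, "hm"),
               class = "burnflow_auth_error")
  case <- hcp_followup(s$relay, "hcp1", case$reference_id,
                       "wound looks deeper today")
  expect_identical(case$status, "pending_expert")
  events <- vapply(case$audit_log, `[[`, character(1), "event")
  expect_true("followup_comment" %in% events)
  last <- s$relay$outbox[[length(s$relay$outbox)]]
  expect_identical(length(s$relay$outbox), n_before + 1L)
  expect_identical(last$recipient, "exp1")
  # the reopened case can be advised again (follow-up loop)
  case <- respond(s$relay, "exp1", case$reference_id,
                  expert_advice(free_text = "refer to burns unit"))
  expect_identical(case$status, "advised")
})

test_that("access is allowed only for owner, assignee and admin", {
  s <- relay_setup()
  case <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB), s$relay)
  ref <- case$reference_id
  expect_identical(access_check(s$relay, "hcp1", ref), "allow")
  expect_identical(access_check(s$relay, "exp1", ref), "allow")
  expect_identical(access_check(s$relay, "root", ref), "allow")
  expect_identical(access_check(s$relay, "hcp2", ref), "deny")
  expect_identical(access_check(s$relay, "exp2", ref), "deny")
  expect_error(access_check(s$relay, "hcp1", "no-such-case"),
               class = "burnflow_not_found_error")
  # randomized ownership configurations against the ownership-record oracle
  set.seed(77)
  users <- c("hcp1", "hcp2", "exp1", "exp2", "root", "stranger")
  for (k in 1:50) {
    owner <- sample(c("hcp1", "hcp2"), 1)
    expert <- sample(c("exp1", "exp2", NA), 1)
    cs <- s$relay$cases[[ref]]
    cs$owner_hcp <- owner
    cs$assigned_expert <- if (is.na(expert)) NULL else expert
    s$relay$cases[[ref]] <- cs
    for (u in users) {
      want <- u == owner || (!is.na(expert) && u == expert) || u == "root"
      expect_identical(access_check(s$relay, u, ref),
                       if (want) "allow" else "deny")
    }
  }
})

test_that("sessions expire after five idle minutes and touch resets the timer", {
  s <- relay_setup()
  t0 <- s$relay$clock()
  session <- open_session(s$relay, "exp1")
  expect_false(expire_check(session, t0 + 4 * 60 + 59))
  expect_true(expire_check(session, t0 + 5 * 60))
  session <- touch_session(s$relay, session, t0 + 2 * 60)
  expect_false(expire_check(session, t0 + 2 * 60 + 3 * 60 - 1))
  expect_true(expire_check(session, t0 + 7 * 60))
  # expired sessions reject operations
  s$relay$clock <- fixed_clock(t0 + 10 * 60)
  expect_error(pending_cases(s$relay, "exp1", session),
               class = "burnflow_session_error")
  expect_error(touch_session(s$relay, session, t0 + 10 * 60),
               class = "burnflow_session_error")
  # a custom timeout is honoured
  s$relay$timeout_minutes <- 30
  s30 <- open_session(s$relay, "exp2")
  expect_false(expire_check(s30, t0 + 10 * 60 + 20 * 60 - 1))
})

test_that("metrics aggregate composition, response, pictures and failures", {
  s <- relay_setup()
  empty <- metrics_report(s$relay)
  expect_identical(empty$n_cases, 0L)
  expect_true(is.na(empty$median_response_min))
  expect_identical(empty$n_failure_events, 0L)

  refs <- character(3)
  durations <- c(10, 20, 90)
  for (i in 1:3) {
    case <- submit_case(make_complete_case(s$store, TEST_AVATAR, TEST_LB),
                        s$relay)
    refs[i] <- case$reference_id
    s$relay$clock <- fixed_clock(case$submitted_at + durations[i] * 60)
    respond(s$relay, "exp1", refs[i], expert_advice(free_text = "ok"),
            complementary_info_requested = i == 2)
    s$relay$clock <- fixed_clock(parse_time("2026-03-01T12:00:00Z"))
  }
  record_failure(s$relay, refs[1], "upload_retry")
  m <- metrics_report(s$relay)
  expect_identical(m$n_cases, 3L)
  expect_equal(m$median_response_min, 20)
  expect_equal(m$mean_picture_count, 1)
  expect_identical(m$n_complementary_info_requests, 1L)
  expect_identical(m$n_failure_events, 1L)
  # single-case store: the summary equals that case's values
  s1 <- relay_setup()
  c1 <- submit_case(make_complete_case(s1$store, TEST_AVATAR, TEST_LB), s1$relay)
  s1$relay$clock <- fixed_clock(c1$submitted_at + 30 * 60)
  respond(s1$relay, "exp1", c1$reference_id, expert_advice(free_text = "ok"))
  m1 <- metrics_report(s1$relay)
  expect_equal(m1$median_response_min, 30)
  expect_equal(m1$mean_picture_count, length(c1$photos))
})
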