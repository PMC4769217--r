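test_that("reference ids are unique, URL-safe and collision-checked", {
  set.seed(1)
  ids <- replicate(10000, generate_reference_id())
  expect_identical(anyDuplicated(ids), 0L)
  expect_true(all(grepl("^[A-Za-z0-9_-]{12}$", ids)))
  st <- case_store(clock = test_clock())
  register_user(st, "hcp1", "hcp")
  c1 <- create_case(st, "hcp1"); c2 <- create_case(st, "hcp1")
  expect_false(identical(c1$reference_id, c2$reference_id))
})

test_that("a new case is a pseudonymous draft with one creation audit event", {
  st <- case_store(clock = test_clock())
  register_user(st, "hcp1", "hcp")
  case <- create_case(st, "hcp1")
  expect_identical(case$status, "draft")
  expect_length(case$audit_log, 1)
  expect_identical(case$audit_log[[1]]$event, "case_created")
  # the record type has no identifying fields at all, by construction
  expect_false(any(c("name", "date_of_birth", "dob", "address") %in%
                     c(names(case), names(unlist(case)))))
  expect_error(create_case(st, "nobody"), class = "burnflow_auth_error")
  register_user(st, "exp1", "expert")
  expect_error(create_case(st, "exp1"), class = "burnflow_auth_error")
})

test_that("demographics validation enforces the age representation rule", {
  # under one year must be recorded in months, not years
  expect_error(patient_demographics("male", age_years = 0),
               class = "burnflow_validation_error")
  d <- patient_demographics("male", age_months = 7)
  expect_identical(d$age_months, 7L)
  expect_error(patient_demographics("male", age_years = 2, age_months = 3),
               class = "burnflow_validation_error")
  expect_error(patient_demographics("male"),
               class = "burnflow_validation_error")
  expect_error(patient_demographics("male", age_months = 12),
               class = "burnflow_validation_error")
  expect_error(patient_demographics("male", age_years = 30, weight_kg = -1),
               class = "burnflow_validation_error")
  expect_error(patient_demographics("male", age_years = 30,
                                    preexisting_conditions = "gout"),
               class = "burnflow_validation_error")
  expect_error(patient_demographics("unknown_sex_token", age_years = 30),
               class = "burnflow_validation_error")
})

test_that("injury entry rejects future times and unknown causes", {
  st <- case_store(clock = test_clock("2026-03-01T12:00:00Z"))
  register_user(st, "hcp1", "hcp")
  case <- create_case(st, "hcp1")
  expect_error(injury_info("spontaneous_combustion", "2026-03-01T10:00:00Z"),
               class = "burnflow_validation_error")
  expect_error(set_injury(case, injury_info("flame", "2026-03-01T12:00:01Z")),
               class = "burnflow_validation_error")
  case <- set_injury(case, injury_info("scald", "2026-03-01T11:00:00Z"))
  expect_identical(case$injury$cause, "scald")
  # edits are draft-only
  expect_error(case_photo(as.raw(1), character(), test_clock()()),
               class = "burnflow_validation_error")
})

test_that("workflow strata match the consent rules at every boundary", {
  expect_identical(assign_workflow_stratum(age_years = 6), "child_0_6")
  expect_identical(assign_workflow_stratum(age_years = 7), "child_7_17")
  expect_identical(assign_workflow_stratum(age_years = 17), "child_7_17")
  expect_identical(assign_workflow_stratum(age_years = 18), "adult")
  expect_identical(assign_workflow_stratum(age_years = 80), "adult")
  expect_identical(assign_workflow_stratum(age_months = 11), "child_0_6")
  expect_error(assign_workflow_stratum(age_years = -2),
               class = "burnflow_validation_error")
})

test_that("completeness follows the linear entry order", {
  st <- case_store(clock = test_clock())
  register_user(st, "hcp1", "hcp")
  case <- create_case(st, "hcp1")
  expect_identical(check_completeness(case),
                   c("demographics", "injury", "photos", "painting"))
  case <- set_demographics(case, patient_demographics("male", age_years = 30,
                                                      weight_kg = 70))
  case <- set_injury(case, injury_info("flame", st$clock() - 3600))
  bm <- burn_map(list(paint_layer("anterior", "partial",
                                  TEST_AVATAR$regions$trunk_ant$mask)))
  case2 <- set_burn_map(case, bm, avatar = TEST_AVATAR, table = TEST_LB)
  expect_identical(check_completeness(case2), "photos")
  case2 <- add_photo(case2, case_photo(as.raw(1:4), "trunk_front",
                                       st$clock() - 600))
  expect_identical(check_completeness(case2), character(0))
})

test_that("submission requires completeness and a reachable relay", {
  st <- case_store(clock = test_clock())
  register_user(st, "hcp1", "hcp")
  rl <- relay(clock = test_clock(), on_call_expert = "exp1")
  register_user(rl, "exp1", "expert")

  incomplete <- create_case(st, "hcp1")
  err <- expect_error(submit_case(incomplete, rl),
                      class = "burnflow_completeness_error")
  expect_match(conditionMessage(err), "demographics")
  expect_match(conditionMessage(err), "painting")

  case <- make_complete_case(st, TEST_AVATAR, TEST_LB)
  # relay down: the case stays draft and unsynced for retry
  rl$online <- FALSE
  case <- submit_case(case, rl)
  expect_identical(case$status, "draft")
  expect_false(case$uploaded)
  # relay back up
  rl$online <- TRUE
  case <- submit_case(case, rl)
  expect_identical(case$status, "pending_expert")
  expect_true(case$uploaded)
  expect_identical(case$assigned_expert, "exp1")
  # resubmission of a non-draft case is rejected
  expect_error(submit_case(case, rl), class = "burnflow_validation_error")
})

test_that("transfer moves rights atomically and is recorded", {
  st <- case_store(clock = test_clock())
  register_user(st, "hcp1", "hcp"); register_user(st, "hcp2", "hcp")
  rl <- relay(clock = test_clock(), on_call_expert = "exp1")
  for (u in c("exp1", "exp2")) register_user(rl, u, "expert")
  for (u in c("hcp1", "hcp2")) register_user(rl, u, "hcp")
  case <- submit_case(make_complete_case(st, TEST_AVATAR, TEST_LB), rl)

  before <- case
  case <- transfer_case(case, "hcp1", "hcp2")
  expect_identical(case$owner_hcp, "hcp2")
  expect_identical(access_check(rl, "hcp2", case$reference_id), "allow")
  expect_identical(access_check(rl, "hcp1", case$reference_id), "deny")
  # content unchanged apart from ownership and the audit entry
  skip_fields <- c("owner_hcp", "audit_log")
  expect_identical(case[setdiff(names(case), skip_fields)],
                   before[setdiff(names(before), skip_fields)])

  case <- transfer_case(case, "exp1", "exp2")
  expect_identical(case$assigned_expert, "exp2")
  expect_error(transfer_case(case, "hcp1", "hcp1"),
               class = "burnflow_auth_error")
})

test_that("the retention sweep wipes only old unsynced cases, idempotently", {
  t0 <- parse_time("2026-03-02T12:00:00Z")
  st <- case_store(clock = fixed_clock(t0 - 25 * 3600))
  register_user(st, "hcp1", "hcp")
  old_unsynced <- create_case(st, "hcp1")
  st$clock <- fixed_clock(t0 - 23 * 3600)
  fresh_unsynced <- create_case(st, "hcp1")
  st$clock <- fixed_clock(t0 - 100 * 3600)
  old_synced <- create_case(st, "hcp1")
  old_synced$uploaded <- TRUE
  st$cases[[old_synced$reference_id]] <- old_synced

  purged <- purge_unsynced(st, now = t0)
  expect_identical(purged, old_unsynced$reference_id)
  expect_setequal(names(st$cases), c(fresh_unsynced$reference_id,
                                     old_synced$reference_id))
  # idempotent at a fixed clock time
  expect_identical(purge_unsynced(st, now = t0), character(0))
  # the 23 h case falls once another two hours pass
  expect_identical(purge_unsynced(st, now = t0 + 2 * 3600),
                   fresh_unsynced$reference_id)
})

test_that("random operation sequences never produce an illegal transition", {
  legal <- list(draft = "submitted", submitted = "pending_expert",
                pending_expert = "advised",
                advised = c("closed", "pending_expert"),
                closed = character())
  statuses <- names(legal)
  set.seed(2026)
  n_ops <- 0L
  for (seq_i in 1:200) {
    st <- case_store(clock = test_clock())
    register_user(st, "hcp1", "hcp")
    case <- create_case(st, "hcp1")
    for (op in 1:50) {
      target <- sample(statuses, 1)
      from <- case$status
      res <- tryCatch(burnflow:::transition_case(case, target),
                      burnflow_validation_error = function(e) e)
      n_ops <- n_ops + 1L
      if (inherits(res, "case_record")) {
        expect_true(target %in% legal[[from]])
        case <- res
      } else {
        expect_false(target %in% legal[[from]])
      }
    }
  }
  expect_gte(n_ops, 10000L)
})
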