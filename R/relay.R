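# Simulated store-and-forward consultation relay.
#
# Runs the cloud side in-process: an expert queue with SMS alerts, structured
# advice with SMS+email notification back to the HCP, owner/assignee access
# control, idle-timeout sessions, and teleconsultation metrics. SMS/email
# delivery goes through a pluggable gateway; the default is an in-memory
# outbox. All time flows through the relay's injectable clock.

#' Create a relay
#'
#' @param clock A clock function ([sys_clock()] / [fixed_clock()]).
#' @param on_call_expert User id of the expert currently on call, or `NULL`.
#' @param timeout_minutes Idle minutes after which a session expires
#'   (default 5, matching the auto-logout rule).
#' @param retention_hours Retention window advertised to clients (default 24).
#' @param gateway A gateway function `function(notification)`; the default
#'   records into the relay's in-memory outbox.
#' @return A `relay` environment.
#' @export
relay <- function(clock = sys_clock(), on_call_expert = NULL,
                  timeout_minutes = 5, retention_hours = 24,
                  gateway = NULL) {
  rl <- new.env(parent = emptyenv())
  rl$clock <- clock
  rl$on_call_expert <- on_call_expert
  rl$timeout_minutes <- timeout_minutes
  rl$retention_hours <- retention_hours
  rl$online <- TRUE
  rl$cases <- list()
  rl$users <- list()
  rl$sessions <- list()
  rl$outbox <- list()
  rl$metrics <- list()
  rl$gateway <- gateway %||% function(notification) {
    rl$outbox[[length(rl$outbox) + 1L]] <- notification
    invisible(notification)
  }
  class(rl) <- "relay"
  rl
}

#' Load a relay from a YAML configuration
#'
#' @param path YAML with keys `on_call_expert`, `timeout_minutes`,
#'   `retention_hours`, optional `users` (map id -> role).
#' @param clock Clock function.
#' @return A [relay()].
#' @export
read_relay_config <- function(path, clock = sys_clock()) {
  cfg <- yaml::read_yaml(path)
  rl <- relay(clock = clock, on_call_expert = cfg$on_call_expert,
              timeout_minutes = cfg$timeout_minutes %||% 5,
              retention_hours = cfg$retention_hours %||% 24)
  for (uid in names(cfg$users %||% list()))
    register_user(rl, uid, cfg$users[[uid]])
  rl
}

#' @export
print.relay <- function(x, ...) {
  cat(sprintf("<relay> %s, %d case(s), %d notification(s), on-call expert: %s\n",
              if (x$online) "online" else "offline", length(x$cases),
              length(x$outbox), x$on_call_expert %||% "none"))
  invisible(x)
}

make_notification <- function(channel, recipient, case_ref, kind, sent_at) {
  structure(list(channel = channel, recipient = recipient, case_ref = case_ref,
                 kind = kind, sent_at = sent_at), class = "relay_notification")
}

notify <- function(rl, channel, recipient, case_ref, kind) {
  n <- make_notification(channel, recipient, case_ref, kind, rl$clock())
  rl$gateway(n)
  bf_log(sprintf("notify_%s_%s", channel, kind), case_ref)
  n
}

relay_case <- function(rl, case_ref) {
  case <- rl$cases[[case_ref]]
  if (is.null(case)) not_found_error(sprintf("unknown case '%s'", case_ref))
  case
}

relay_put_case <- function(rl, case) {
  attr(case, "relay") <- rl
  rl$cases[[case$reference_id]] <- case
  st <- attr(case, "store")
  if (!is.null(st)) st$cases[[case$reference_id]] <- case
  case
}

# Queue ------------------------------------------------------------------

#' Queue a submitted case for the on-call expert
#'
#' Assigns the case to the configured on-call expert, moves it to
#' `pending_expert` and sends one SMS alert. Re-enqueueing an already
#' assigned case is a no-op (no duplicate notification).
#'
#' @param rl A [relay()].
#' @param case A `case_record` with status `submitted`.
#' @return The updated case record.
#' @export
enqueue_case <- function(rl, case) {
  if (!is.null(rl$cases[[case$reference_id]]) &&
      !is.null(relay_case(rl, case$reference_id)$assigned_expert))
    return(relay_case(rl, case$reference_id))
  if (case$status != "submitted")
    validation_error(sprintf("only submitted cases can be queued (status is %s)",
                             case$status))
  if (is.null(rl$on_call_expert))
    config_error("no on-call expert is configured on the relay")
  case$assigned_expert <- rl$on_call_expert
  case <- transition_case(case, "pending_expert")
  case <- relay_put_case(rl, case)
  notify(rl, "sms", rl$on_call_expert, case$reference_id, "new_case")
  m <- rl$metrics[[case$reference_id]] %||% list()
  m$submission_time <- case$submitted_at %||% rl$clock()
  m$composition_duration_min <-
    mins_between(case$created_at, m$submission_time)
  m$picture_count <- length(case$photos)
  m$complementary_info_requested <- FALSE
  m$failure_events <- m$failure_events %||% character()
  rl$metrics[[case$reference_id]] <- m
  case
}

# Sessions ----------------------------------------------------------------

#' Open, touch and expiry-check user sessions
#'
#' Sessions expire after `timeout_minutes` of idleness (default 5 minutes,
#' the auto-logout rule); an expired session rejects all operations.
#' `touch_session()` resets the idle timer; `expire_check()` reports
#' whether a session has expired at `now`.
#'
#' @param rl A [relay()].
#' @param user_id Registered user id.
#' @param session A `session_state` returned by `open_session()`.
#' @param now Optional `POSIXct`; defaults to the relay clock's now.
#' @return `open_session()` / `touch_session()` a `session_state`;
#'   `expire_check()` `TRUE` (expired) or `FALSE`.
#' @export
open_session <- function(rl, user_id) {
  user_role(rl, user_id)
  now <- rl$clock()
  s <- structure(list(user_id = user_id, authenticated_at = now,
                      last_activity_at = now,
                      timeout_minutes = rl$timeout_minutes),
                 class = "session_state")
  rl$sessions[[user_id]] <- s
  s
}

#' @rdname open_session
#' @export
touch_session <- function(rl, session, now = NULL) {
  now <- now %||% rl$clock()
  if (expire_check(session, now))
    session_error("session has expired; log in again")
  session$last_activity_at <- now
  rl$sessions[[session$user_id]] <- session
  session
}

#' @rdname open_session
#' @export
expire_check <- function(session, now) {
  mins_between(session$last_activity_at, now) >= session$timeout_minutes
}

require_session <- function(rl, session, user_id = NULL) {
  if (!inherits(session, "session_state")) session_error("a session is required")
  if (expire_check(session, rl$clock()))
    session_error("session has expired; log in again")
  if (!is.null(user_id) && !identical(session$user_id, user_id))
    session_error("session does not belong to this user")
  invisible(session)
}

# Access control -----------------------------------------------------------

#' Access decision for a user on a case
#'
#' Experts and HCPs only have access to the cases they are managing: the
#' decision is `"allow"` iff the user is the current owner HCP, the
#' assigned expert, or an administrator.
#'
#' @param rl A [relay()].
#' @param user_id Registered user id.
#' @param case_ref Case reference id.
#' @return `"allow"` or `"deny"`.
#' @export
access_check <- function(rl, user_id, case_ref) {
  case <- relay_case(rl, case_ref)
  role <- rl$users[[user_id]]
  allow <- identical(user_id, case$owner_hcp) ||
    identical(user_id, case$assigned_expert) ||
    identical(role, "admin")
  if (allow) "allow" else "deny"
}

# Expert side ---------------------------------------------------------------

#' Pending cases for an expert
#'
#' @param rl A [relay()].
#' @param expert Expert user id.
#' @param session An unexpired session belonging to the expert.
#' @return List of `case_record`s assigned to this expert and still
#'   `pending_expert`, oldest submission first.
#' @export
pending_cases <- function(rl, expert, session) {
  require_session(rl, session, expert)
  mine <- Filter(function(cs) identical(cs$assigned_expert, expert) &&
                   cs$status == "pending_expert", rl$cases)
  times <- vapply(mine, function(cs)
    as.numeric(cs$submitted_at %||% cs$created_at), numeric(1))
  unname(mine[order(times)])
}

#' Structured tele-expert advice
#'
#' The five advice categories: where to treat (with transport flag), fluids,
#' medication, dressings, and other specific instructions, plus free text.
#' At least one category or the free text must be nonempty.
#'
#' @param where_to_treat `"local"` or `"refer"`, or `NULL`.
#' @param transport_required Logical flag (meaningful when referring).
#' @param fluids_advice,medication_advice,dressings_advice,other_instructions,free_text
#'   Text fields (may be empty).
#' @return An `expert_advice` object (responder and timestamps are filled
#'   in by [respond()]).
#' @export
expert_advice <- function(where_to_treat = NULL, transport_required = FALSE,
                          fluids_advice = "", medication_advice = "",
                          dressings_advice = "", other_instructions = "",
                          free_text = "") {
  if (!is.null(where_to_treat))
    where_to_treat <- match.arg(where_to_treat, c("local", "refer"))
  filled <- c(!is.null(where_to_treat), nzchar(fluids_advice),
              nzchar(medication_advice), nzchar(dressings_advice),
              nzchar(other_instructions), nzchar(free_text))
  if (!any(filled))
    validation_error("advice must fill at least one category or the free-text field")
  structure(list(case_ref = NULL, where_to_treat = where_to_treat,
                 transport_required = isTRUE(transport_required),
                 fluids_advice = fluids_advice,
                 medication_advice = medication_advice,
                 dressings_advice = dressings_advice,
                 other_instructions = other_instructions,
                 free_text = free_text, responder = NULL, responded_at = NULL),
            class = "expert_advice")
}

#' Respond to a pending case
#'
#' Attaches the advice, marks the case `advised`, notifies the owning HCP by
#' both SMS and email, and closes the response-duration metric.
#'
#' @param rl A [relay()].
#' @param expert The assigned expert's user id.
#' @param case_ref Case reference id.
#' @param advice An [expert_advice()].
#' @param complementary_info_requested Flag: the expert asked for more
#'   information rather than giving final advice.
#' @return The updated case record.
#' @export
respond <- function(rl, expert, case_ref, advice,
                    complementary_info_requested = FALSE) {
  case <- relay_case(rl, case_ref)
  if (!identical(case$assigned_expert, expert))
    auth_error(sprintf("expert '%s' is not assigned to case %s", expert, case_ref))
  stopifnot(inherits(advice, "expert_advice"))
  advice$case_ref <- case_ref
  advice$responder <- expert
  advice$responded_at <- rl$clock()
  case$expert_advice <- advice
  case <- transition_case(case, "advised", actor = expert)
  case <- relay_put_case(rl, case)
  notify(rl, "sms", case$owner_hcp, case_ref, "new_advice")
  notify(rl, "email", case$owner_hcp, case_ref, "new_advice")
  m <- rl$metrics[[case_ref]] %||% list()
  if (!is.null(m$submission_time))
    m$expert_response_duration_min <-
      mins_between(m$submission_time, advice$responded_at)
  if (complementary_info_requested) m$complementary_info_requested <- TRUE
  rl$metrics[[case_ref]] <- m
  case
}

#' Send a follow-up comment on an advised case
#'
#' Reopens the consultation: the owning HCP appends a comment, the case
#' returns to `pending_expert`, and the assigned expert is notified.
#'
#' @param rl A [relay()].
#' @param hcp The owning HCP's user id.
#' @param case_ref Case reference id.
#' @param comment Free-text comment.
#' @return The updated case record.
#' @export
hcp_followup <- function(rl, hcp, case_ref, comment) {
  case <- relay_case(rl, case_ref)
  if (!identical(case$owner_hcp, hcp))
    auth_error(sprintf("user '%s' does not own case %s", hcp, case_ref))
  if (case$status != "advised")
    validation_error("follow-up comments can only be sent on advised cases")
  case <- transition_case(case, "pending_expert", actor = hcp)
  case <- append_audit(case, "followup_comment", actor = hcp, detail = comment)
  case <- relay_put_case(rl, case)
  notify(rl, "sms", case$assigned_expert, case_ref, "new_case")
  case
}

# Metrics -------------------------------------------------------------------

#' Teleconsultation metrics summary
#'
#' Aggregates the per-case point-of-care and tele-expert measures: median
#' composition duration, median expert response duration, mean picture
#' count, complementary-information requests and failure events.
#' Deterministic given the relay contents.
#'
#' @param rl A [relay()].
#' @return A `consult_metrics` list.
#' @export
metrics_report <- function(rl) {
  ms <- rl$metrics
  num <- function(field) {
    v <- unlist(lapply(ms, function(m) m[[field]]))
    if (is.null(v)) numeric() else v
  }
  resp <- num("expert_response_duration_min")
  comp <- num("composition_duration_min")
  pics <- num("picture_count")
  structure(list(
    n_cases = length(ms),
    median_composition_min = if (length(comp)) stats::median(comp) else NA_real_,
    median_response_min = if (length(resp)) stats::median(resp) else NA_real_,
    mean_picture_count = if (length(pics)) mean(pics) else NA_real_,
    n_complementary_info_requests =
      sum(vapply(ms, function(m) isTRUE(m$complementary_info_requested), logical(1))),
    n_failure_events = sum(vapply(ms, function(m)
      length(m$failure_events %||% character()), integer(1)))),
    class = "consult_metrics")
}

#' @export
print.consult_metrics <- function(x, ...) {
  cat(sprintf(paste0("<consult_metrics> %d case(s); median composition %.1f min; ",
                     "median response %.1f min; mean pictures %.2f; ",
                     "%d info request(s); %d failure event(s)\n"),
              x$n_cases, x$median_composition_min, x$median_response_min,
              x$mean_picture_count, x$n_complementary_info_requests,
              x$n_failure_events))
  invisible(x)
}

#' Record a system failure event against a case
#'
#' @param rl A [relay()].
#' @param case_ref Case reference id.
#' @param what Short description token.
#' @return Invisibly, the updated failure-event list.
#' @export
record_failure <- function(rl, case_ref, what) {
  m <- rl$metrics[[case_ref]] %||% list()
  m$failure_events <- c(m$failure_events %||% character(), what)
  rl$metrics[[case_ref]] <- m
  invisible(m$failure_events)
}
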