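# Pseudonymized case records and the point-of-care workflow.
#
# A case is identified only by an opaque reference number: the record type
# has no fields for name, date of birth or address, so direct identifiers
# cannot be stored even by mistake (the reference number is kept in the
# hospital record, outside this system). Status moves through a strict
# state machine and every operation appends to an append-only audit log.

CASE_STATUSES <- c("draft", "submitted", "pending_expert", "advised", "closed")
LEGAL_TRANSITIONS <- list(
  draft          = "submitted",
  submitted      = "pending_expert",
  pending_expert = "advised",
  advised        = c("closed", "pending_expert"),  # follow-up question reopens
  closed         = character())

REFERENCE_ID_ALPHABET <- c(LETTERS, letters, 0:9, "-", "_")
REFERENCE_ID_LENGTH <- 12L

WORKFLOW_SECTIONS <- c("reference", "demographics", "injury", "photos", "painting")

# Store ------------------------------------------------------------------

#' Create a local case store
#'
#' The on-device store: registered users, cases keyed by reference id, and
#' the injectable clock every time-dependent operation reads.
#'
#' @param clock A clock function, e.g. [sys_clock()] or [fixed_clock()].
#' @return A `case_store` environment.
#' @export
case_store <- function(clock = sys_clock()) {
  st <- new.env(parent = emptyenv())
  st$cases <- list()
  st$users <- list()
  st$clock <- clock
  class(st) <- "case_store"
  st
}

#' Register a user with a role
#'
#' @param registry A [case_store()] or [relay()].
#' @param user_id User token.
#' @param role `"hcp"`, `"expert"` or `"admin"`.
#' @return `user_id`, invisibly.
#' @export
register_user <- function(registry, user_id, role = c("hcp", "expert", "admin")) {
  role <- match.arg(role)
  registry$users[[user_id]] <- role
  invisible(user_id)
}

user_role <- function(registry, user_id) {
  r <- registry$users[[user_id]]
  if (is.null(r)) auth_error(sprintf("user '%s' is not registered", user_id))
  r
}

sync_case <- function(case) {
  st <- attr(case, "store")
  if (!is.null(st)) st$cases[[case$reference_id]] <- case
  rl <- attr(case, "relay")
  if (!is.null(rl) && !is.null(rl$cases[[case$reference_id]]))
    rl$cases[[case$reference_id]] <- case
  case
}

case_clock <- function(case) {
  st <- attr(case, "store")
  if (!is.null(st)) st$clock else sys_clock()
}

append_audit <- function(case, event, actor = NULL, detail = NULL) {
  now <- case_clock(case)()
  case$audit_log[[length(case$audit_log) + 1L]] <-
    list(time = now, event = event, actor = actor, detail = detail)
  case
}

# Reference ids -----------------------------------------------------------

#' Generate a pseudonymous reference identifier
#'
#' A random 12-character URL-safe token (letters, digits, `-`, `_`) used in
#' place of all patient identifiers; collision-checked against the local
#' store if one is given.
#'
#' @param store Optional [case_store()] to collision-check against.
#' @return A character token.
#' @export
generate_reference_id <- function(store = NULL) {
  repeat {
    id <- paste(sample(REFERENCE_ID_ALPHABET, REFERENCE_ID_LENGTH,
                       replace = TRUE), collapse = "")
    if (is.null(store) || is.null(store$cases[[id]])) return(id)
  }
}

# Construction ------------------------------------------------------------

#' Open a new draft case
#'
#' @param store A [case_store()].
#' @param owner_hcp Registered HCP user id who will own the case.
#' @return A draft `case_record` (also written to the store).
#' @export
create_case <- function(store, owner_hcp) {
  role <- user_role(store, owner_hcp)
  if (role != "hcp") auth_error("only an HCP can open a case")
  ref <- generate_reference_id(store)
  case <- structure(list(
    reference_id = ref, demographics = NULL, injury = NULL,
    photos = list(), burnmap = NULL, tbsa_result = NULL, fluid_plan = NULL,
    immediate_advice = NULL, status = "draft", owner_hcp = owner_hcp,
    assigned_expert = NULL, uploaded = FALSE, submitted_at = NULL,
    created_at = store$clock(), audit_log = list()),
    class = "case_record")
  attr(case, "store") <- store
  case <- append_audit(case, "case_created", actor = owner_hcp)
  bf_log("case_created", ref)
  sync_case(case)
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record> %s status=%s owner=%s expert=%s uploaded=%s\n",
              x$reference_id, x$status, x$owner_hcp,
              x$assigned_expert %||% "-", x$uploaded))
  missing <- check_completeness(x)
  if (length(missing)) cat("  missing sections:", paste(missing, collapse = ", "), "\n")
  if (!is.null(x$tbsa_result))
    cat(sprintf("  fluid-eligible TBSA %.1f%%\n",
                x$tbsa_result$fluid_eligible_percent))
  invisible(x)
}

transition_case <- function(case, to, actor = NULL) {
  legal <- LEGAL_TRANSITIONS[[case$status]]
  if (!to %in% legal)
    validation_error(sprintf("illegal case status transition %s -> %s",
                             case$status, to))
  case$status <- to
  append_audit(case, sprintf("status_%s", to), actor = actor)
}

# Coded sections ----------------------------------------------------------

#' Patient demographics (pseudonymized)
#'
#' Age is either whole years (>= 1) or, for infants under one year, months
#' 0-11 — exactly one of the two. There are deliberately no fields for
#' name, date of birth or address.
#'
#' @param sex Token from the packaged enumeration.
#' @param age_years Integer age in years (>= 1), or `NULL`.
#' @param age_months Integer age in months (0-11), or `NULL`.
#' @param weight_kg Positive weight in kg; may be `NULL` if not yet known
#'   (the fluid plan is then withheld with an advisory).
#' @param preexisting_conditions Character vector of coded condition tokens.
#' @param enums Controlled vocabularies, see [read_enumerations()].
#' @return A `patient_demographics` object.
#' @export
patient_demographics <- function(sex, age_years = NULL, age_months = NULL,
                                 weight_kg = NULL,
                                 preexisting_conditions = character(),
                                 enums = read_enumerations()) {
  check_token(sex, "sex", enums$sexes)
  if (is.null(age_years) == is.null(age_months))
    validation_error("provide exactly one of age_years or age_months")
  if (!is.null(age_years)) {
    if (!is.numeric(age_years) || age_years != trunc(age_years) || age_years < 1)
      validation_error("age_years must be an integer >= 1; record infants in age_months")
    age_years <- as.integer(age_years)
  }
  if (!is.null(age_months)) {
    if (!is.numeric(age_months) || age_months != trunc(age_months) ||
        age_months < 0 || age_months > 11)
      validation_error("age_months must be an integer between 0 and 11")
    age_months <- as.integer(age_months)
  }
  if (!is.null(weight_kg) && (!is.numeric(weight_kg) || weight_kg <= 0))
    validation_error("weight_kg must be positive")
  check_tokens(preexisting_conditions, "pre-existing condition",
               enums$preexisting_conditions)
  structure(list(sex = sex, age_years = age_years, age_months = age_months,
                 weight_kg = weight_kg,
                 preexisting_conditions = preexisting_conditions),
            class = "patient_demographics")
}

#' Injury information
#'
#' @param cause Coded cause token from the packaged enumeration.
#' @param injury_time `POSIXct` or ISO-8601 string; must not be in the
#'   future relative to the store clock when attached to a case.
#' @param enums Controlled vocabularies.
#' @return An `injury_info` object.
#' @export
injury_info <- function(cause, injury_time, enums = read_enumerations()) {
  check_token(cause, "burn cause", enums$burn_causes)
  structure(list(cause = cause, injury_time = as_utc_time(injury_time)),
            class = "injury_info")
}

#' A wound photograph (opaque payload plus required body-part tags)
#'
#' Photo content is never analysed; at least one body-part tag is required
#' so the expert can match photographs to painted locations.
#'
#' @param payload Raw vector (image bytes).
#' @param body_part_tags Nonempty character vector of category tokens.
#' @param captured_at `POSIXct` or ISO-8601 string.
#' @param photo_id Optional id; generated if omitted.
#' @param enums Controlled vocabularies.
#' @return A `case_photo` object.
#' @export
case_photo <- function(payload, body_part_tags, captured_at, photo_id = NULL,
                       enums = read_enumerations()) {
  if (!is.raw(payload)) validation_error("photo payload must be raw bytes")
  if (!length(body_part_tags))
    validation_error("a photo needs at least one body-part tag")
  check_tokens(body_part_tags, "body part category", enums$body_part_categories)
  structure(list(photo_id = photo_id %||% generate_reference_id(),
                 body_part_tags = body_part_tags,
                 captured_at = as_utc_time(captured_at), payload = payload),
            class = "case_photo")
}

# Entry operations --------------------------------------------------------

require_draft <- function(case) {
  if (case$status != "draft")
    validation_error(sprintf("case %s is %s; entries can only be edited in draft",
                             case$reference_id, case$status))
}

#' Attach validated sections to a draft case
#'
#' `set_demographics()` and `set_injury()` store a validated section on a
#' draft case and append an audit entry. `set_injury()` additionally
#' rejects injury times later than the store clock's now.
#'
#' @param case A draft `case_record`.
#' @param demographics A [patient_demographics()].
#' @param injury An [injury_info()].
#' @return The updated case record.
#' @export
set_demographics <- function(case, demographics) {
  require_draft(case)
  stopifnot(inherits(demographics, "patient_demographics"))
  case$demographics <- demographics
  sync_case(append_audit(case, "demographics_set"))
}

#' @rdname set_demographics
#' @export
set_injury <- function(case, injury) {
  require_draft(case)
  stopifnot(inherits(injury, "injury_info"))
  now <- case_clock(case)()
  if (injury$injury_time > now)
    validation_error("injury_time cannot be in the future")
  case$injury <- injury
  sync_case(append_audit(case, "injury_set"))
}

#' Attach a photograph to a draft case
#'
#' @param case A draft `case_record`.
#' @param photo A [case_photo()].
#' @return The updated case record.
#' @export
add_photo <- function(case, photo) {
  require_draft(case)
  stopifnot(inherits(photo, "case_photo"))
  case$photos[[length(case$photos) + 1L]] <- photo
  sync_case(append_audit(case, "photo_added", detail = photo$photo_id))
}

#' Attach a burn painting and evaluate the case
#'
#' Stores the (clipped, overlap-resolved) burn map, computes TBSA with the
#' age from the case demographics, derives the Parkland plan and the
#' offline advice bundle, and records everything on the case.
#'
#' @param case A draft `case_record` with demographics set.
#' @param burnmap A [burn_map()].
#' @param avatar,table,rules Assets; packaged defaults.
#' @return The updated case record.
#' @export
set_burn_map <- function(case, burnmap, avatar = default_avatar(),
                         table = default_lund_browder_table(),
                         rules = read_advice_rules()) {
  require_draft(case)
  if (is.null(case$demographics))
    validation_error("enter demographics before painting: TBSA needs the patient's age")
  if (!isTRUE(burnmap$resolved)) burnmap <- resolve_depth_overlaps(burnmap)
  case$burnmap <- burnmap
  case$tbsa_result <- compute_tbsa(
    burnmap, age_years = case$demographics$age_years, table = table,
    avatar = avatar, age_months = case$demographics$age_months)
  bundle <- immediate_advice(case, case$tbsa_result, rules = rules)
  case$fluid_plan <- bundle$fluid_plan
  case$immediate_advice <- bundle
  sync_case(append_audit(case, "painting_set"))
}

# Strata, completeness, submission ----------------------------------------

#' Assign the consent/workflow age stratum
#'
#' Separate workflows exist for (a) adults, (b) children older than 6 but
#' younger than 18, and (c) children aged 6 years and younger. Age 18 is
#' adult; infants recorded in months fall in the youngest stratum.
#'
#' @param age_years,age_months Exactly one of the two (months for < 1 year).
#' @return `"adult"`, `"child_7_17"` or `"child_0_6"`.
#' @examples
#' assign_workflow_stratum(age_years = 6)   # "child_0_6"
#' assign_workflow_stratum(age_years = 18)  # "adult"
#' @export
assign_workflow_stratum <- function(age_years = NULL, age_months = NULL) {
  age <- effective_age_years(age_years, age_months)
  if (age >= 18) "adult" else if (age > 6) "child_7_17" else "child_0_6"
}

#' List the workflow sections still missing from a case
#'
#' The entry workflow is linear (reference, demographics, injury, photos,
#' painting) and a case can only be submitted once every section is
#' present; the returned vector follows that order.
#'
#' @param case A `case_record`.
#' @return Character vector of missing section names (empty iff submittable).
#' @export
check_completeness <- function(case) {
  missing <- character()
  if (is.null(case$reference_id) || !nzchar(case$reference_id))
    missing <- c(missing, "reference")
  if (is.null(case$demographics)) missing <- c(missing, "demographics")
  if (is.null(case$injury)) missing <- c(missing, "injury")
  if (!length(case$photos)) missing <- c(missing, "photos")
  if (is.null(case$burnmap)) missing <- c(missing, "painting")
  missing
}

#' Submit a complete case to the relay
#'
#' A complete draft case is marked submitted and handed to the relay; on
#' acknowledgement it is assigned to the on-call expert (status
#' `pending_expert`) and the uploaded flag is set. If the relay is
#' unreachable the case stays in draft with `uploaded = FALSE` so it can be
#' retried — and will be wiped by the retention sweep if it never syncs.
#'
#' @param case A complete draft `case_record`.
#' @param relay A [relay()], or `NULL` for no connectivity.
#' @return The updated case record.
#' @export
submit_case <- function(case, relay) {
  missing <- check_completeness(case)
  if (length(missing))
    completeness_error(sprintf("case %s is incomplete: missing %s",
                               case$reference_id,
                               paste(missing, collapse = ", ")),
                       missing = missing)
  if (case$status != "draft")
    validation_error(sprintf("case %s has already been submitted", case$reference_id))
  if (is.null(relay) || !isTRUE(relay$online)) {
    case <- append_audit(case, "upload_failed_relay_unreachable")
    bf_log("upload_failed", case$reference_id)
    return(sync_case(case))
  }
  case <- transition_case(case, "submitted", actor = case$owner_hcp)
  case$submitted_at <- case_clock(case)()
  case$uploaded <- TRUE
  case <- sync_case(case)
  enqueue_case(relay, case)
}

#' Transfer case rights between users
#'
#' Hands the case over: if `from_user` is the owning HCP, ownership moves
#' to `to_user`; if `from_user` is the assigned expert, the assignment
#' moves. The previous holder loses access; content is untouched apart
#' from ownership and the audit entry.
#'
#' @param case A `case_record`.
#' @param from_user Current holder of the role being transferred.
#' @param to_user New holder.
#' @return The updated case record.
#' @export
transfer_case <- function(case, from_user, to_user) {
  if (identical(from_user, case$owner_hcp)) {
    case$owner_hcp <- to_user
    case <- append_audit(case, "ownership_transferred", actor = from_user,
                         detail = to_user)
  } else if (identical(from_user, case$assigned_expert)) {
    case$assigned_expert <- to_user
    case <- append_audit(case, "expert_reassigned", actor = from_user,
                         detail = to_user)
  } else {
    auth_error(sprintf("user '%s' holds no transferable role on case %s",
                       from_user, case$reference_id))
  }
  sync_case(case)
}

#' Retention sweep for unsynced cases
#'
#' Deletes from the local store every case that has not been successfully
#' uploaded and is at least `retention_hours` old. Uploaded cases are never
#' touched. Idempotent for a fixed clock time.
#'
#' @param store A [case_store()].
#' @param now `POSIXct`; defaults to the store clock's now.
#' @param retention_hours Retention window in hours (default 24).
#' @return Character vector of purged reference ids (sorted).
#' @export
purge_unsynced <- function(store, now = NULL, retention_hours = 24) {
  now <- now %||% store$clock()
  purged <- character()
  for (ref in names(store$cases)) {
    case <- store$cases[[ref]]
    if (!isTRUE(case$uploaded) &&
        hours_between(case$created_at, now) >= retention_hours)
      purged <- c(purged, ref)
  }
  store$cases[purged] <- NULL
  bf_log(sprintf("retention_sweep purged=%d", length(purged)))
  sort(purged)
}
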