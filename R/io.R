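# Case file I/O: JSON case documents, ndjson audit/outbox logs.
#
# The case document schema is enforced by validate_case_json(); violations
# report a JSON-pointer-style path to the offending field. Masks are stored
# as run-length encodings of the column-major pixel vector, which is exact
# and compact for painted regions.

encode_rle_mask <- function(mask) {
  r <- rle(as.vector(mask))
  list(width = ncol(mask), height = nrow(mask),
       first = r$values[1] %||% FALSE, lengths = as.integer(r$lengths))
}

decode_rle_mask <- function(x) {
  lens <- as.integer(unlist(x$lengths))
  vals <- rep(c(isTRUE(x$first), !isTRUE(x$first)),
              length.out = length(lens))
  m <- matrix(inverse.rle(structure(list(lengths = lens, values = vals),
                                    class = "rle")),
              nrow = x$height, ncol = x$width)
  m
}

time_or_null <- function(t) if (is.null(t)) NULL else format_time(t)
num_or_str <- function(x) if (is.infinite(x)) "inf" else x

case_to_list <- function(case) {
  demo <- case$demographics
  inj <- case$injury
  tb <- case$tbsa_result
  fp <- case$fluid_plan
  adv <- case$immediate_advice
  ea <- case$expert_advice
  list(
    schema_version = 1L,
    reference_id = case$reference_id,
    status = case$status,
    owner_hcp = case$owner_hcp,
    assigned_expert = case$assigned_expert,
    uploaded = isTRUE(case$uploaded),
    created_at = format_time(case$created_at),
    submitted_at = time_or_null(case$submitted_at),
    demographics = if (is.null(demo)) NULL else list(
      sex = demo$sex, age_years = demo$age_years, age_months = demo$age_months,
      weight_kg = demo$weight_kg,
      preexisting_conditions = as.list(demo$preexisting_conditions)),
    injury = if (is.null(inj)) NULL else list(
      cause = inj$cause, injury_time = format_time(inj$injury_time)),
    photos = lapply(case$photos, function(p) list(
      photo_id = p$photo_id, body_part_tags = as.list(p$body_part_tags),
      captured_at = format_time(p$captured_at),
      payload_base64 = jsonlite::base64_enc(p$payload))),
    burnmap = if (is.null(case$burnmap)) NULL else list(
      resolved = isTRUE(case$burnmap$resolved),
      layers = lapply(unname(case$burnmap$layers), function(l)
        c(list(view = l$view, depth = l$depth), encode_rle_mask(l$mask)))),
    tbsa_result = if (is.null(tb)) NULL else list(
      per_depth_percent = tb$per_depth_percent,
      fluid_eligible_percent = tb$fluid_eligible_percent,
      superficial_percent = tb$superficial_percent,
      per_region = lapply(seq_len(nrow(tb$per_region)), function(i) list(
        region_id = tb$per_region$region_id[i], depth = tb$per_region$depth[i],
        painted_fraction = tb$per_region$painted_fraction[i],
        percent = tb$per_region$percent[i])),
      age_band_used = list(lower = tb$age_band_used[["lower"]],
                           upper = num_or_str(tb$age_band_used[["upper"]]))),
    fluid_plan = if (is.null(fp)) NULL else fluid_plan_to_list(fp),
    immediate_advice = if (is.null(adv)) NULL else list(
      general_advice = as.list(adv$general_advice),
      triggered_rules = as.list(adv$triggered_rules),
      advisories = as.list(adv$advisories)),
    expert_advice = if (is.null(ea)) NULL else list(
      case_ref = ea$case_ref, where_to_treat = ea$where_to_treat,
      transport_required = ea$transport_required,
      fluids_advice = ea$fluids_advice, medication_advice = ea$medication_advice,
      dressings_advice = ea$dressings_advice,
      other_instructions = ea$other_instructions, free_text = ea$free_text,
      responder = ea$responder, responded_at = time_or_null(ea$responded_at)),
    audit_log = lapply(case$audit_log, function(e) list(
      time = format_time(e$time), event = e$event, actor = e$actor,
      detail = e$detail)))
}

fluid_plan_to_list <- function(fp) {
  list(total_ml = fp$total_ml, first_phase_ml = fp$first_phase_ml,
       second_phase_ml = fp$second_phase_ml,
       first_window = list(start = format_time(fp$phase_windows$first[["start"]]),
                           end = format_time(fp$phase_windows$first[["end"]])),
       second_window = list(start = format_time(fp$phase_windows$second[["start"]]),
                            end = format_time(fp$phase_windows$second[["end"]])),
       first_phase_rate_ml_per_h = fp$first_phase_rate_ml_per_h,
       second_phase_rate_ml_per_h = fp$second_phase_rate_ml_per_h)
}

fluid_plan_from_list <- function(x) {
  structure(list(
    total_ml = as.numeric(x$total_ml),
    first_phase_ml = as.numeric(x$first_phase_ml),
    second_phase_ml = as.numeric(x$second_phase_ml),
    phase_windows = list(
      first = c(start = parse_time(x$first_window$start),
                end = parse_time(x$first_window$end)),
      second = c(start = parse_time(x$second_window$start),
                 end = parse_time(x$second_window$end))),
    first_phase_rate_ml_per_h = as.numeric(x$first_phase_rate_ml_per_h),
    second_phase_rate_ml_per_h = as.numeric(x$second_phase_rate_ml_per_h)),
    class = "fluid_plan")
}

#' Validate a case document against the shipped schema
#'
#' A structural check of the case JSON document; violations raise a
#' validation error whose message carries a JSON-pointer path to the
#' offending field (e.g. `/injury/injury_time`).
#'
#' @param x A list as decoded from a case JSON file.
#' @return `TRUE`, invisibly.
#' @export
validate_case_json <- function(x) {
  req <- function(obj, field, pointer, type = NULL) {
    v <- obj[[field]]
    if (is.null(v)) schema_error(sprintf("required field '%s' is missing", field),
                                 paste0(pointer, "/", field))
    if (!is.null(type) && !type(v))
      schema_error(sprintf("field '%s' has the wrong type", field),
                   paste0(pointer, "/", field))
    v
  }
  is_str <- function(v) is.character(v) && length(v) == 1L
  is_flag <- function(v) is.logical(v) && length(v) == 1L
  req(x, "reference_id", "", is_str)
  status <- req(x, "status", "", is_str)
  if (!status %in% CASE_STATUSES)
    schema_error(sprintf("unknown status '%s'", status), "/status")
  req(x, "owner_hcp", "", is_str)
  req(x, "uploaded", "", is_flag)
  req(x, "created_at", "", is_str)
  req(x, "audit_log", "", is.list)
  if (!is.null(x$demographics)) {
    d <- x$demographics
    req(d, "sex", "/demographics", is_str)
    if (is.null(d$age_years) == is.null(d$age_months))
      schema_error("exactly one of age_years or age_months is required",
                   "/demographics/age_years")
    if (!is.null(d$weight_kg) && (!is.numeric(d$weight_kg) || d$weight_kg <= 0))
      schema_error("weight_kg must be positive", "/demographics/weight_kg")
  }
  if (!is.null(x$injury)) {
    req(x$injury, "cause", "/injury", is_str)
    req(x$injury, "injury_time", "/injury", is_str)
  }
  for (i in seq_along(x$photos)) {
    p <- x$photos[[i]]
    ptr <- sprintf("/photos/%d", i - 1L)
    req(p, "photo_id", ptr, is_str)
    tags <- req(p, "body_part_tags", ptr, is.list)
    if (!length(tags))
      schema_error("a photo needs at least one body-part tag",
                   paste0(ptr, "/body_part_tags"))
    req(p, "captured_at", ptr, is_str)
    req(p, "payload_base64", ptr, is_str)
  }
  invisible(TRUE)
}

#' Write and read case JSON documents
#'
#' `write_case()` serializes a case record to a self-contained JSON document
#' (photos base64-encoded, paint masks run-length encoded);
#' `read_case()` validates the document and reconstructs the record, so
#' that write-then-read is the identity.
#'
#' @param case A `case_record`.
#' @param path File path.
#' @param store Optional [case_store()] the loaded case should be attached to.
#' @return `read_case()` the case record; `write_case()` `path`, invisibly.
#' @export
write_case <- function(case, path) {
  jsonlite::write_json(case_to_list(case), path, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_case
#' @export
read_case <- function(path, store = NULL) {
  if (!file.exists(path)) not_found_error(sprintf("case file not found: %s", path))
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_case_json(x)
  case <- structure(list(
    reference_id = x$reference_id,
    demographics = if (is.null(x$demographics)) NULL else {
      d <- x$demographics
      patient_demographics(d$sex,
                           age_years = d$age_years, age_months = d$age_months,
                           weight_kg = d$weight_kg,
                           preexisting_conditions =
                             as.character(unlist(d$preexisting_conditions)))
    },
    injury = if (is.null(x$injury)) NULL else
      injury_info(x$injury$cause, x$injury$injury_time),
    photos = lapply(x$photos, function(p)
      case_photo(jsonlite::base64_dec(p$payload_base64),
                 as.character(unlist(p$body_part_tags)),
                 p$captured_at, photo_id = p$photo_id)),
    burnmap = if (is.null(x$burnmap)) NULL else
      burn_map(lapply(x$burnmap$layers, function(l)
        paint_layer(l$view, l$depth, decode_rle_mask(l))),
        resolved = isTRUE(x$burnmap$resolved)),
    tbsa_result = if (is.null(x$tbsa_result)) NULL else {
      tb <- x$tbsa_result
      pr <- tb$per_region
      structure(list(
        per_depth_percent = lapply(tb$per_depth_percent, as.numeric),
        fluid_eligible_percent = as.numeric(tb$fluid_eligible_percent),
        superficial_percent = as.numeric(tb$superficial_percent),
        per_region = if (length(pr)) do.call(rbind, lapply(pr, function(r)
          data.frame(region_id = r$region_id, depth = r$depth,
                     painted_fraction = r$painted_fraction,
                     percent = r$percent)))
          else data.frame(region_id = character(), depth = character(),
                          painted_fraction = numeric(), percent = numeric()),
        age_band_used = c(
          lower = as.numeric(tb$age_band_used$lower),
          upper = if (identical(tb$age_band_used$upper, "inf")) Inf
                  else as.numeric(tb$age_band_used$upper))),
        class = "tbsa_result")
    },
    fluid_plan = if (is.null(x$fluid_plan)) NULL else
      fluid_plan_from_list(x$fluid_plan),
    immediate_advice = if (is.null(x$immediate_advice)) NULL else
      structure(list(
        fluid_plan = if (is.null(x$fluid_plan)) NULL else
          fluid_plan_from_list(x$fluid_plan),
        general_advice = as.character(unlist(x$immediate_advice$general_advice)),
        triggered_rules = as.character(unlist(x$immediate_advice$triggered_rules)),
        advisories = as.character(unlist(x$immediate_advice$advisories))),
        class = "advice_bundle"),
    expert_advice = if (is.null(x$expert_advice)) NULL else {
      ea <- x$expert_advice
      a <- expert_advice(ea$where_to_treat, isTRUE(ea$transport_required),
                         ea$fluids_advice %||% "", ea$medication_advice %||% "",
                         ea$dressings_advice %||% "",
                         ea$other_instructions %||% "", ea$free_text %||% "")
      a$case_ref <- ea$case_ref
      a$responder <- ea$responder
      a$responded_at <- if (is.null(ea$responded_at)) NULL else
        parse_time(ea$responded_at)
      a
    },
    status = x$status, owner_hcp = x$owner_hcp,
    assigned_expert = x$assigned_expert,
    uploaded = isTRUE(x$uploaded),
    submitted_at = if (is.null(x$submitted_at)) NULL else
      parse_time(x$submitted_at),
    created_at = parse_time(x$created_at),
    audit_log = lapply(x$audit_log, function(e)
      list(time = parse_time(e$time), event = e$event,
           actor = e$actor, detail = e$detail))),
    class = "case_record")
  if (is.null(x$expert_advice)) case$expert_advice <- NULL
  # restore canonical field order used by the constructors
  ord <- intersect(c("reference_id", "demographics", "injury", "photos",
                     "burnmap", "tbsa_result", "fluid_plan",
                     "immediate_advice", "status", "owner_hcp",
                     "assigned_expert", "uploaded", "submitted_at",
                     "created_at", "audit_log", "expert_advice"),
                   names(case))
  case <- structure(case[ord], class = "case_record")
  if (!is.null(store)) {
    attr(case, "store") <- store
    store$cases[[case$reference_id]] <- case
  }
  case
}

#' Export logs as newline-delimited JSON
#'
#' `write_audit_log()` writes a case's append-only audit trail;
#' `write_outbox()` writes the relay's notification outbox.
#'
#' @param case A `case_record`.
#' @param rl A [relay()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_audit_log <- function(case, path) {
  lines <- vapply(case$audit_log, function(e)
    jsonlite::toJSON(list(time = format_time(e$time), event = e$event,
                          actor = e$actor, detail = e$detail),
                     auto_unbox = TRUE, null = "null"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_audit_log
#' @export
write_outbox <- function(rl, path) {
  lines <- vapply(rl$outbox, function(n)
    jsonlite::toJSON(list(channel = n$channel, recipient = n$recipient,
                          case_ref = n$case_ref, kind = n$kind,
                          sent_at = format_time(n$sent_at)),
                     auto_unbox = TRUE), character(1))
  writeLines(lines, path)
  invisible(path)
}
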