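# Parkland fluid resuscitation planning and offline immediate advice.

#' Parkland formula resuscitation volume
#'
#' Total crystalloid volume for the first 24 hours after injury:
#' 4 ml x body mass (kg) x fluid-eligible %TBSA, rounded to the nearest ml.
#' Superficial burn area must already be excluded from the TBSA argument.
#'
#' @param mass_kg Body mass in kilograms (> 0).
#' @param fluid_tbsa_percent Fluid-eligible TBSA in percent, 0-100.
#' @return Volume in millilitres (integer-valued double).
#' @examples
#' parkland_volume(70, 20)  # 5600 ml
#' @export
parkland_volume <- function(mass_kg, fluid_tbsa_percent) {
  if (!is.numeric(mass_kg) || length(mass_kg) != 1L || is.na(mass_kg) ||
      mass_kg <= 0)
    validation_error("mass_kg must be a single positive number")
  if (!is.numeric(fluid_tbsa_percent) || length(fluid_tbsa_percent) != 1L ||
      is.na(fluid_tbsa_percent) || fluid_tbsa_percent < 0 ||
      fluid_tbsa_percent > 100)
    validation_error("fluid_tbsa_percent must be between 0 and 100")
  round(4 * mass_kg * fluid_tbsa_percent)
}

# 50/50 phase split on whole millilitres; an odd total gives the extra ml to
# the first (0-8 h) phase. Vectorised so the conservation property can be
# checked over large ranges.
split_phase_volumes <- function(total_ml) {
  first <- (total_ml + 1) %/% 2
  cbind(first = first, second = total_ml - first)
}

#' Build the phased fluid administration schedule
#'
#' Half of the 24-hour volume is given in the first 8 hours after injury and
#' the remaining half over the subsequent 16 hours. Phase windows are
#' anchored at the time of injury (not presentation). Volumes are whole
#' millilitres (an odd total puts the extra ml in the first phase); rates
#' are reported to 0.1 ml/h.
#'
#' @param total_ml Total 24-hour volume in ml (>= 0).
#' @param injury_time `POSIXct` or ISO-8601 string: time of the burn.
#' @return A `fluid_plan` object.
#' @examples
#' build_schedule(5600, "2026-03-01T10:00:00Z")
#' @export
build_schedule <- function(total_ml, injury_time) {
  if (!is.numeric(total_ml) || length(total_ml) != 1L || is.na(total_ml) ||
      total_ml < 0)
    validation_error("total_ml must be a single non-negative number")
  total_ml <- round(total_ml)
  t0 <- as_utc_time(injury_time)
  phases <- split_phase_volumes(total_ml)
  windows <- list(first = c(start = t0, end = t0 + 8 * 3600),
                  second = c(start = t0 + 8 * 3600, end = t0 + 24 * 3600))
  structure(list(
    total_ml = total_ml,
    first_phase_ml = unname(phases[1, "first"]),
    second_phase_ml = unname(phases[1, "second"]),
    phase_windows = windows,
    first_phase_rate_ml_per_h = unname(round(phases[1, "first"] / 8, 1)),
    second_phase_rate_ml_per_h = unname(round(phases[1, "second"] / 16, 1))),
    class = "fluid_plan")
}

#' @export
print.fluid_plan <- function(x, ...) {
  cat(sprintf("<fluid_plan> total %d ml over 24 h from injury\n", x$total_ml))
  cat(sprintf("  0-8 h : %d ml (%.1f ml/h), %s to %s\n", x$first_phase_ml,
              x$first_phase_rate_ml_per_h,
              format_time(x$phase_windows$first[["start"]]),
              format_time(x$phase_windows$first[["end"]])))
  cat(sprintf("  8-24 h: %d ml (%.1f ml/h), %s to %s\n", x$second_phase_ml,
              x$second_phase_rate_ml_per_h,
              format_time(x$phase_windows$second[["start"]]),
              format_time(x$phase_windows$second[["end"]])))
  invisible(x)
}

#' Read an advice rule table
#'
#' @param path YAML rule list; defaults to the packaged table.
#' @return List of rules (`rule_id`, `condition`, `advice`).
#' @export
read_advice_rules <- function(path = NULL) {
  yaml::read_yaml(path %||% extdata_path("advice_rules.yaml"))
}

#' Immediate offline treatment advice
#'
#' Evaluates the packaged (editable) rule table against the case and its
#' TBSA estimate and attaches the Parkland fluid plan. This runs entirely
#' locally: it never touches the relay, so standardised care advice is
#' available the moment the assessment is entered, with or without network.
#' If the patient's weight is missing the fluid plan is omitted and an
#' explicit "weight required" advisory is emitted instead.
#'
#' @param case_record A [case_record] with demographics (and ideally injury
#'   info) set.
#' @param tbsa_result A [compute_tbsa()] result.
#' @param rules Rule table from [read_advice_rules()].
#' @return An `advice_bundle`: `fluid_plan` (or `NULL`), `general_advice`
#'   (ordered character vector), `triggered_rules`, `advisories`.
#' @export
immediate_advice <- function(case_record, tbsa_result,
                             rules = read_advice_rules()) {
  demo <- case_record$demographics
  if (is.null(demo))
    validation_error("demographics must be entered before advice can be generated")
  age <- effective_age_years(demo$age_years, demo$age_months)
  env <- list2env(list(
    age_years = age,
    stratum = assign_workflow_stratum(age_years = demo$age_years,
                                      age_months = demo$age_months),
    weight_known = !is.null(demo$weight_kg),
    tbsa = tbsa_result$fluid_eligible_percent,
    superficial_tbsa = tbsa_result$superficial_percent,
    cause = if (is.null(case_record$injury)) NA_character_ else case_record$injury$cause,
    conditions = demo$preexisting_conditions %||% character()),
    parent = baseenv())

  advice <- character(); triggered <- character()
  for (rule in rules) {
    hit <- isTRUE(eval(parse(text = rule$condition), envir = env))
    if (hit) {
      advice <- c(advice, rule$advice)
      triggered <- c(triggered, rule$rule_id)
    }
  }

  advisories <- character(); plan <- NULL
  if (is.null(demo$weight_kg)) {
    advisories <- "weight required: enter patient weight to obtain the fluid plan"
  } else {
    total <- parkland_volume(demo$weight_kg, tbsa_result$fluid_eligible_percent)
    t0 <- if (!is.null(case_record$injury)) case_record$injury$injury_time
          else case_record$created_at
    plan <- build_schedule(total, t0)
    if (is.null(case_record$injury))
      advisories <- "injury time not yet entered: fluid phases anchored at case creation time"
  }
  structure(list(fluid_plan = plan, general_advice = advice,
                 triggered_rules = triggered, advisories = advisories),
            class = "advice_bundle")
}

#' @export
print.advice_bundle <- function(x, ...) {
  cat("<advice_bundle>\n")
  if (!is.null(x$fluid_plan))
    cat(sprintf("  fluids: %d ml / 24 h (%d ml first 8 h)\n",
                x$fluid_plan$total_ml, x$fluid_plan$first_phase_ml))
  for (a in x$advisories) cat(sprintf("  ! %s\n", a))
  for (a in x$general_advice) cat(sprintf("  - %s\n", a))
  invisible(x)
}
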