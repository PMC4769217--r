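#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------
# Every domain error is a classed condition under "burnflow_error" so callers
# (and the CLI) can distinguish domain failures from programming errors.

bf_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "burnflow_error"), call = call))
}

geometry_error    <- function(msg) bf_stop(msg, "burnflow_geometry_error")
partition_error   <- function(msg) bf_stop(msg, "burnflow_partition_error")
containment_error <- function(msg) bf_stop(msg, "burnflow_containment_error")
validation_error  <- function(msg) bf_stop(msg, "burnflow_validation_error")
lookup_error      <- function(msg) bf_stop(msg, "burnflow_lookup_error")
auth_error        <- function(msg) bf_stop(msg, "burnflow_auth_error")
session_error     <- function(msg) bf_stop(msg, "burnflow_session_error")
completeness_error <- function(msg, missing = character()) {
  stop(errorCondition(msg, missing = missing,
                      class = c("burnflow_completeness_error", "burnflow_error")))
}
config_error    <- function(msg) bf_stop(msg, "burnflow_config_error")
not_found_error <- function(msg) bf_stop(msg, "burnflow_not_found_error")
schema_error <- function(msg, pointer) {
  stop(errorCondition(sprintf("%s (at %s)", msg, pointer), pointer = pointer,
                      class = c("burnflow_schema_error",
                                "burnflow_validation_error", "burnflow_error")))
}

# Clocks ----------------------------------------------------------------------

#' Injectable clocks
#'
#' All time-dependent behaviour (session expiry, retention sweeps,
#' consultation metrics, audit timestamps) reads time from a clock function
#' passed in by the caller, never from the wall clock inside core logic.
#' `sys_clock()` returns the real time (UTC, truncated to whole seconds so
#' that serialized timestamps round-trip exactly); `fixed_clock()` returns a
#' clock frozen at a given instant, for tests and simulations.
#'
#' @param time A `POSIXct` time, or a string parseable by [parse_time()].
#' @return A zero-argument function returning a UTC `POSIXct` time.
#' @examples
#' clk <- fixed_clock("2026-01-01T08:00:00Z")
#' clk()
#' @export
fixed_clock <- function(time) {
  t <- as_utc_time(time)
  force(t)
  function() t
}

#' @rdname fixed_clock
#' @export
sys_clock <- function() {
  function() {
    t <- Sys.time()
    as.POSIXct(floor(as.numeric(t)), origin = "1970-01-01", tz = "UTC")
  }
}

as_utc_time <- function(x) {
  if (is.character(x)) return(parse_time(x))
  if (!inherits(x, "POSIXct")) validation_error("expected a POSIXct time or ISO-8601 string")
  as.POSIXct(floor(as.numeric(x)), origin = "1970-01-01", tz = "UTC")
}

#' Format and parse UTC ISO-8601 timestamps
#'
#' Audit logs and case JSON store all instants as `YYYY-MM-DDTHH:MM:SSZ`.
#'
#' @param t A `POSIXct` time.
#' @param s A string in the above format.
#' @return `format_time()` a string; `parse_time()` a UTC `POSIXct`.
#' @export
format_time <- function(t) format(t, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

#' @rdname format_time
#' @export
parse_time <- function(s) {
  t <- as.POSIXct(s, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  if (any(is.na(t))) validation_error(sprintf("invalid ISO-8601 UTC timestamp: %s",
                                              paste(s[is.na(t)], collapse = ", ")))
  t
}

hours_between <- function(from, to) as.numeric(difftime(to, from, units = "hours"))
mins_between  <- function(from, to) as.numeric(difftime(to, from, units = "mins"))

# Logging ---------------------------------------------------------------------
# Confidentiality by construction: log lines carry reference ids and event
# kinds only, never case payload fields.

bf_log <- function(event, ref = NULL, quiet = getOption("burnflow.quiet", TRUE)) {
  if (isTRUE(quiet)) return(invisible(NULL))
  line <- if (is.null(ref)) event else sprintf("%s ref=%s", event, ref)
  message(sprintf("[burnflow] %s", line))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

extdata_path <- function(...) {
  p <- system.file("extdata", ..., package = "burnflow")
  if (!nzchar(p)) bf_stop(sprintf("packaged asset not found: %s",
                                  file.path(...)), "burnflow_config_error")
  p
}
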