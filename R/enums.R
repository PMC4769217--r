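# Controlled vocabularies (editable YAML asset).

enum_cache <- new.env(parent = emptyenv())

#' Read the packaged controlled vocabularies
#'
#' Coded value lists for burn causes, pre-existing conditions, body-part
#' categories and sex. These are editable stand-ins for the app's full data
#' dictionary, seeded from the examples the system description gives.
#'
#' @param path Optional alternative YAML file.
#' @return Named list of character vectors.
#' @export
read_enumerations <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(enum_cache$default))
      enum_cache$default <- yaml::read_yaml(extdata_path("enumerations.yaml"))
    return(enum_cache$default)
  }
  yaml::read_yaml(path)
}

check_token <- function(value, what, allowed) {
  if (!is.character(value) || length(value) != 1L || !value %in% allowed)
    validation_error(sprintf("unknown %s token '%s' (allowed: %s)", what,
                             paste(value, collapse = ","),
                             paste(allowed, collapse = ", ")))
  value
}

check_tokens <- function(values, what, allowed) {
  bad <- setdiff(values, allowed)
  if (length(bad))
    validation_error(sprintf("unknown %s token(s): %s", what,
                             paste(bad, collapse = ", ")))
  values
}
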