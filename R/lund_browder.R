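# Age-adjusted Lund-Browder surface-area table.
#
# The chart assigns each body area a percentage of total body surface that
# varies with age: infants have proportionally larger heads and smaller
# thighs/legs; all other areas are age-constant. The app's own chart values
# are not published, so the package ships the standard published chart,
# with each whole-body area's percentage split across the avatar regions
# that realise it (anterior/posterior halves, left/right sides). The table
# is an editable YAML asset guarded by the sum-to-100 invariant.

#' Construct a Lund-Browder table
#'
#' @param age_bands Data frame with numeric columns `lower`, `upper`:
#'   half-open age intervals `[lower, upper)` in years, ordered, contiguous.
#' @param percent Numeric matrix, one row per age band, one column per
#'   avatar `region_id`; values are percent of total body surface area.
#' @return An `lb_table` object.
#' @export
lb_table <- function(age_bands, percent) {
  stopifnot(is.data.frame(age_bands), is.matrix(percent),
            nrow(age_bands) == nrow(percent))
  if (any(diff(age_bands$lower) <= 0) ||
      !all(age_bands$upper[-nrow(age_bands)] == age_bands$lower[-1]))
    validation_error("age bands must be ordered and contiguous")
  if (any(percent < 0)) validation_error("Lund-Browder percentages must be >= 0")
  sums <- rowSums(percent)
  if (any(abs(sums - 100) > 1e-6))
    validation_error(sprintf(
      "every age band must sum to 100%% of body surface; got %s",
      paste(sprintf("%.4f", sums[abs(sums - 100) > 1e-6]), collapse = ", ")))
  structure(list(age_bands = age_bands, percent = percent), class = "lb_table")
}

#' @export
print.lb_table <- function(x, ...) {
  cat(sprintf("<lb_table> %d age bands x %d regions (each band sums to 100%%)\n",
              nrow(x$age_bands), ncol(x$percent)))
  invisible(x)
}

#' Read a Lund-Browder table from YAML
#'
#' @param path YAML file with `age_bands` (list of `{lower, upper}`; `upper:
#'   .inf` for the open adult band) and `percent` (one map region_id ->
#'   percent per band, same order as `age_bands`).
#' @return An [lb_table()].
#' @export
read_lb_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  bands <- do.call(rbind, lapply(cfg$age_bands, function(b)
    data.frame(lower = as.numeric(b$lower), upper = as.numeric(b$upper))))
  ids <- names(cfg$percent[[1]])
  pm <- do.call(rbind, lapply(cfg$percent, function(row) {
    if (!setequal(names(row), ids))
      validation_error("all age-band rows must cover the same region_ids")
    unlist(row)[ids]
  }))
  colnames(pm) <- ids
  lb_table(bands, pm)
}

#' The packaged Lund-Browder table
#'
#' Standard published chart values over age bands `[0,1)`, `[1,5)`, `[5,10)`,
#' `[10,15)`, `[15,18)`, `[18,Inf)` years, mapped onto the packaged avatar's
#' regions (whole-body areas split evenly between the anterior and posterior
#' half of each area, and between left and right for paired limbs).
#'
#' @return An [lb_table()].
#' @examples
#' t <- default_lund_browder_table()
#' rowSums(t$percent)  # each band sums to 100
#' @export
default_lund_browder_table <- function() {
  read_lb_table(extdata_path("lund_browder.yaml"))
}

lb_band_index <- function(table, age_years) {
  if (!is.numeric(age_years) || length(age_years) != 1L || is.na(age_years) ||
      age_years < 0)
    validation_error("age must be a single non-negative number of years")
  b <- table$age_bands
  i <- which(age_years >= b$lower & age_years < b$upper)
  if (length(i) != 1L) validation_error(sprintf("no age band covers age %s", age_years))
  i
}

#' Look up the Lund-Browder percentage for a region at a given age
#'
#' A step-function lookup: the band whose half-open interval `[lower, upper)`
#' contains `age_years` is used; there is no interpolation, so an age exactly
#' on a boundary resolves to the band it opens.
#'
#' @param table An [lb_table()].
#' @param region_id Avatar region token.
#' @param age_years Age in years (infants: months / 12).
#' @return Percent of total body surface area carried by that region.
#' @export
lb_percent <- function(table, region_id, age_years) {
  i <- lb_band_index(table, age_years)
  if (!region_id %in% colnames(table$percent))
    lookup_error(sprintf("region '%s' has no entry in the Lund-Browder table",
                         region_id))
  unname(table$percent[i, region_id])
}

#' Burn depth categories
#'
#' The four depth categories with their display colour keys. Only partial,
#' full and indeterminate are selectable in the painting flow; superficial
#' burns are recordable for the clinical notes but excluded from fluid
#' calculations.
#'
#' @return Data frame with columns `depth`, `colour_key`, `paintable`,
#'   `fluid_eligible`.
#' @export
depth_categories <- function() {
  data.frame(depth = DEPTH_CATEGORIES,
             colour_key = unname(DEPTH_COLOUR_KEY[DEPTH_CATEGORIES]),
             paintable = DEPTH_CATEGORIES %in% PAINTABLE_DEPTHS,
             fluid_eligible = DEPTH_CATEGORIES != "superficial")
}
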