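# TBSA estimation: paint pixels -> age-adjusted percent of body surface.

#' Compute total body surface area burned
#'
#' Converts a depth-layered painting into an age-adjusted TBSA estimate.
#' For each avatar region and depth, the contribution is the painted
#' fraction of the region multiplied by the region's Lund-Browder
#' percentage at the patient's age; per-depth totals are sums over regions.
#' Superficial burns are recorded but excluded from the fluid-eligible
#' total; partial, full and indeterminate depths all count towards it
#' (conservative practice treats an indeterminate depth as burn area until
#' reassessed).
#'
#' @param burnmap A clipped, overlap-resolved [burn_map()].
#' @param age_years Age in years; for infants under one year pass
#'   `age_months` instead.
#' @param table An [lb_table()]; defaults to the packaged chart.
#' @param avatar An [avatar_model()]; defaults to the packaged avatar.
#' @param age_months Age in months (0-11) for infants; mutually exclusive
#'   with `age_years`. Band selection uses `age_months / 12`.
#' @return A `tbsa_result` with per-depth percentages, the fluid-eligible
#'   total, the superficial (record-only) percentage, per-(region, depth)
#'   contributions and the age band used. Values are double precision;
#'   printing rounds to 0.1%.
#' @examples
#' av <- default_avatar(scale = 0.2)
#' bm <- burn_map(list(paint_layer("anterior", "partial",
#'                                 av$regions$trunk_ant$mask)))
#' compute_tbsa(resolve_depth_overlaps(bm), age_years = 30, avatar = av)
#' @export
compute_tbsa <- function(burnmap, age_years = NULL,
                         table = default_lund_browder_table(),
                         avatar = default_avatar(), age_months = NULL) {
  age <- effective_age_years(age_years, age_months)
  if (!isTRUE(burnmap$resolved))
    validation_error("burn map must be overlap-resolved before TBSA is computed; call resolve_depth_overlaps()")

  band <- lb_band_index(table, age)
  per_region <- list()
  per_depth <- stats::setNames(numeric(length(DEPTH_CATEGORIES)), DEPTH_CATEGORIES)
  for (depth in DEPTH_CATEGORIES) {
    for (region in avatar$regions) {
      l <- burnmap_layer(burnmap, region$view, depth)
      if (is.null(l)) next
      frac <- painted_fraction(l, region)
      if (frac == 0) next
      contrib <- frac * lb_percent(table, region$region_id, age)
      per_depth[[depth]] <- per_depth[[depth]] + contrib
      per_region[[length(per_region) + 1L]] <-
        data.frame(region_id = region$region_id, depth = depth,
                   painted_fraction = frac, percent = contrib)
    }
  }
  per_region <- if (length(per_region)) do.call(rbind, per_region)
                else data.frame(region_id = character(), depth = character(),
                                painted_fraction = numeric(), percent = numeric())
  structure(list(
    per_depth_percent = as.list(per_depth),
    fluid_eligible_percent = sum(per_depth[PAINTABLE_DEPTHS]),
    superficial_percent = per_depth[["superficial"]],
    per_region = per_region,
    age_band_used = c(lower = table$age_bands$lower[band],
                      upper = table$age_bands$upper[band])),
    class = "tbsa_result")
}

effective_age_years <- function(age_years, age_months) {
  if (is.null(age_years) == is.null(age_months))
    validation_error("provide exactly one of age_years or age_months")
  if (!is.null(age_months)) {
    if (!is.numeric(age_months) || age_months < 0 || age_months > 11)
      validation_error("age_months must be between 0 and 11; use age_years from one year on")
    return(age_months / 12)
  }
  if (!is.numeric(age_years) || length(age_years) != 1L || is.na(age_years) ||
      age_years < 0)
    validation_error("age_years must be a single non-negative number")
  age_years
}

#' @export
print.tbsa_result <- function(x, ...) {
  cat("<tbsa_result>\n")
  for (d in DEPTH_CATEGORIES)
    cat(sprintf("  %-13s %5.1f%%\n", d, round(x$per_depth_percent[[d]], 1)))
  cat(sprintf("  fluid-eligible TBSA: %.1f%% (superficial %.1f%% recorded only)\n",
              round(x$fluid_eligible_percent, 1), round(x$superficial_percent, 1)))
  cat(sprintf("  age band used: [%g, %g) years\n",
              x$age_band_used[["lower"]], x$age_band_used[["upper"]]))
  invisible(x)
}
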