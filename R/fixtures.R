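# Deterministic synthetic fixture generator.
#
# Produces complete synthetic cases (demographics, injury, placeholder
# photos, paintings) whose paintings are unions of whole and half body
# regions, so the ground-truth TBSA is known in closed form from region
# pixel counts and is stored alongside each case for pipeline verification.
# All randomness flows through one seeded generator; identical specs yield
# byte-identical output trees.

FIXTURE_BASE_TIME <- "2026-01-15T08:00:00Z"

#' Specify a synthetic fixture set
#'
#' Defaults describe a plausible emergency-burns case mix: half adults with
#' a substantial paediatric share, fluid-eligible burns between 5 and 40%
#' TBSA, mostly partial-thickness with some full-thickness and
#' indeterminate areas, and one to four wound photographs per case.
#'
#' @param seed Integer seed; same spec (incl. seed) means byte-identical output.
#' @param n_cases Number of cases to generate.
#' @param age_mix Named probabilities over strata
#'   `c(adult=, child_7_17=, child_0_6=)`; must sum to 1.
#' @param tbsa_range Target fluid-eligible TBSA range in percent.
#' @param depth_mix Named probabilities over paintable depths
#'   `c(partial=, full=, indeterminate=)`; must sum to 1.
#' @param picture_count_range Integer `c(min, max)` photographs per case.
#' @return A `fixture_spec` object.
#' @export
fixture_spec <- function(seed, n_cases,
                         age_mix = c(adult = 0.5, child_7_17 = 0.2,
                                     child_0_6 = 0.3),
                         tbsa_range = c(5, 40),
                         depth_mix = c(partial = 0.6, full = 0.25,
                                       indeterminate = 0.15),
                         picture_count_range = c(1L, 4L)) {
  stopifnot(length(seed) == 1L, n_cases >= 0)
  if (abs(sum(age_mix) - 1) > 1e-9 || abs(sum(depth_mix) - 1) > 1e-9)
    validation_error("age_mix and depth_mix probabilities must each sum to 1")
  if (!setequal(names(depth_mix), PAINTABLE_DEPTHS))
    validation_error("depth_mix must cover exactly the paintable depths")
  if (tbsa_range[1] > tbsa_range[2] || tbsa_range[1] < 0 || tbsa_range[2] > 100)
    validation_error("tbsa_range must be an increasing range within [0, 100]")
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 age_mix = age_mix, tbsa_range = tbsa_range,
                 depth_mix = depth_mix,
                 picture_count_range = as.integer(picture_count_range)),
            class = "fixture_spec")
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Half of a region: its rows up to the median painted row. Fractions stay
# exact ratios of pixel counts, keeping the ground truth closed-form.
half_region_mask <- function(mask) {
  rows <- which(apply(mask, 1, any))
  cut <- rows[ceiling(length(rows) / 2)]
  if (cut >= nrow(mask)) return(mask)
  m <- mask
  m[(cut + 1):nrow(m), ] <- FALSE
  m
}

sample_int_range <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1)

placeholder_photo_png <- function() {
  png::writePNG(matrix(c(0.3, 0.6, 0.6, 0.3), 2, 2))
}

generate_fixture_case <- function(spec, avatar, table, idx) {
  enums <- read_enumerations()
  base <- parse_time(FIXTURE_BASE_TIME)
  created <- base + idx * 3600

  stratum <- sample(names(spec$age_mix), 1, prob = spec$age_mix)
  age_years <- NULL; age_months <- NULL
  if (stratum == "adult") age_years <- sample(18:85, 1)
  else if (stratum == "child_7_17") age_years <- sample(7:17, 1)
  else {
    y <- sample(0:6, 1)
    if (y == 0) age_months <- sample(0:11, 1) else age_years <- y
  }
  weight <- if (!is.null(age_months)) round(runif(1, 3, 10), 1)
            else if (age_years < 7) round(runif(1, 10, 25), 1)
            else if (age_years < 18) round(runif(1, 20, 60), 1)
            else round(runif(1, 50, 100), 1)
  sex <- sample(c("female", "male"), 1)
  conditions <- character()
  if (runif(1) < 0.2) {
    pool <- setdiff(enums$preexisting_conditions, "pregnancy")
    if (sex == "female" && !is.null(age_years) && age_years >= 18)
      pool <- enums$preexisting_conditions
    conditions <- sample(pool, 1)
  }
  demo <- patient_demographics(sex, age_years = age_years,
                               age_months = age_months, weight_kg = weight,
                               preexisting_conditions = conditions)
  injury <- injury_info(sample(enums$burn_causes, 1),
                        created - round(runif(1, 0.5, 12) * 3600))

  # painting: add whole (70%) or half (30%) regions until the closed-form
  # fluid-eligible TBSA reaches a target drawn from the spec range
  age_eff <- effective_age_years(demo$age_years, demo$age_months)
  target <- runif(1, spec$tbsa_range[1], spec$tbsa_range[2])
  order_ids <- sample(names(avatar$regions))
  sel <- list(); truth_eligible <- 0; truth_by_depth <-
    stats::setNames(numeric(length(PAINTABLE_DEPTHS)), PAINTABLE_DEPTHS)
  for (rid in order_ids) {
    if (truth_eligible >= target) break
    region <- avatar$regions[[rid]]
    whole <- runif(1) < 0.7
    mask <- if (whole) region$mask else half_region_mask(region$mask)
    frac <- sum(mask) / sum(region$mask)
    depth <- sample(PAINTABLE_DEPTHS, 1, prob = spec$depth_mix)
    contrib <- frac * lb_percent(table, rid, age_eff)
    sel[[length(sel) + 1L]] <- list(view = region$view, depth = depth,
                                    mask = mask)
    truth_eligible <- truth_eligible + contrib
    truth_by_depth[[depth]] <- truth_by_depth[[depth]] + contrib
  }
  layers <- list()
  for (s in sel) {
    k <- layer_key(s$view, s$depth)
    layers[[k]] <- if (is.null(layers[[k]])) s$mask else layers[[k]] | s$mask
  }
  bm <- burn_map(lapply(names(layers), function(k) {
    parts <- strsplit(k, "_", fixed = TRUE)[[1]]
    paint_layer(parts[1], parts[2], layers[[k]])
  }))
  # disjoint by construction (regions are a partition and each selected
  # region is painted once), so resolution leaves the truth intact
  bm <- resolve_depth_overlaps(bm)

  n_pics <- sample_int_range(spec$picture_count_range[1],
                             spec$picture_count_range[2])
  photos <- lapply(seq_len(n_pics), function(j)
    case_photo(placeholder_photo_png(),
               sample(enums$body_part_categories, 1),
               created - 600 + j * 30,
               photo_id = sprintf("photo-%03d-%d", idx, j)))

  store <- case_store(clock = fixed_clock(created))
  register_user(store, "fixture_hcp", "hcp")
  case <- create_case(store, "fixture_hcp")
  case <- set_demographics(case, demo)
  case <- set_injury(case, injury)
  for (p in photos) case <- add_photo(case, p)
  case <- set_burn_map(case, bm, avatar = avatar, table = table)

  list(case = case, burnmap = bm,
       truth = list(fluid_eligible_percent = truth_eligible,
                    per_depth_percent = as.list(truth_by_depth),
                    stratum = stratum))
}

#' Generate a directory tree of synthetic cases
#'
#' Writes, per case, `case.json`, the paint masks under `masks/`, and the
#' closed-form `ground_truth.json` (fluid-eligible TBSA and per-depth
#' breakdown computed from region pixel counts, independently of
#' [compute_tbsa()]).
#'
#' @param spec A [fixture_spec()].
#' @param dir Output directory.
#' @param avatar,table Assets; packaged defaults.
#' @return Character vector of case directories, invisibly.
#' @export
generate_fixture <- function(spec, dir, avatar = default_avatar(),
                             table = default_lund_browder_table()) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dirs <- character()
  with_seed(spec$seed, {
    for (i in seq_len(spec$n_cases)) {
      g <- generate_fixture_case(spec, avatar, table, i)
      cdir <- file.path(dir, sprintf("case_%03d", i))
      dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
      write_case(g$case, file.path(cdir, "case.json"))
      write_paint_masks(g$burnmap, file.path(cdir, "masks"))
      jsonlite::write_json(g$truth, file.path(cdir, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      dirs <- c(dirs, cdir)
    }
  })
  invisible(dirs)
}
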