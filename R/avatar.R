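# Body avatar: two-view raster silhouette partitioned into named regions.
#
# Masks are logical matrices indexed [row, col] with origin at the top-left
# (0-based pixel coordinates in external formats map to R's 1-based matrix
# indices); any nonzero pixel in an 8-bit raster counts as painted.

DEPTH_CATEGORIES <- c("superficial", "partial", "full", "indeterminate")
# Precedence when one pixel carries several depths (deepest wins):
DEPTH_PRECEDENCE <- c("full", "partial", "indeterminate", "superficial")
# Depths selectable in the painting flow; superficial is recordable only.
PAINTABLE_DEPTHS <- c("partial", "full", "indeterminate")
DEPTH_COLOUR_KEY <- c(superficial = "yellow", partial = "red",
                      full = "darkred", indeterminate = "orange")

AVATAR_VIEWS <- c("anterior", "posterior")
LATERALITIES <- c("left", "right", "midline")

as_mask <- function(x, resolution = NULL) {
  if (is.logical(x) && is.matrix(x)) m <- x
  else if (is.numeric(x) && is.matrix(x)) m <- x != 0
  else if (is.array(x) && length(dim(x)) == 3) m <- x[, , 1] != 0
  else validation_error("a mask must be a logical or numeric matrix")
  if (!is.null(resolution) &&
      !identical(dim(m), c(resolution[2L], resolution[1L])))
    geometry_error(sprintf(
      "mask resolution %dx%d does not match avatar resolution %dx%d (width x height)",
      ncol(m), nrow(m), resolution[1L], resolution[2L]))
  m
}

#' Construct a body region
#'
#' A region is one named piece of the avatar partition on one view, with a
#' laterality (so left/right limbs can carry Lund-Browder half-limb
#' percentages independently) and the body-part category token used by the
#' photo-tagging index.
#'
#' @param region_id Short stable token, unique across the avatar.
#' @param display_name Human-readable name.
#' @param view `"anterior"` or `"posterior"`.
#' @param laterality `"left"`, `"right"` or `"midline"`.
#' @param mask Logical (or 0/1 numeric) matrix; `TRUE` pixels belong to the
#'   region. Must be nonempty.
#' @param body_part_category Token from [body_part_categories()].
#' @return A `body_region` object.
#' @export
body_region <- function(region_id, display_name, view, laterality, mask,
                        body_part_category) {
  view <- match.arg(view, AVATAR_VIEWS)
  laterality <- match.arg(laterality, LATERALITIES)
  mask <- as_mask(mask)
  if (!any(mask)) validation_error(sprintf("region '%s' has an empty mask", region_id))
  structure(list(region_id = region_id, display_name = display_name,
                 view = view, laterality = laterality, mask = mask,
                 body_part_category = body_part_category),
            class = "body_region")
}

#' Construct and validate an avatar model
#'
#' The avatar is the computational counterpart of the app's front/back body
#' diagram: per view a binary silhouette plus a *strict partition* of that
#' silhouette into body regions. Validation enforces the partition contract:
#' every region inside its silhouette, regions pairwise disjoint, and the
#' union of regions equal to the silhouette exactly.
#'
#' @param resolution Integer `c(width, height)` in pixels, shared by both views.
#' @param silhouettes Named list `list(anterior = , posterior = )` of masks.
#' @param regions List of [body_region()] objects.
#' @return An `avatar_model` object.
#' @export
avatar_model <- function(resolution, silhouettes, regions) {
  resolution <- as.integer(resolution)
  if (length(resolution) != 2L || any(resolution < 1L))
    validation_error("resolution must be positive c(width, height)")
  if (!setequal(names(silhouettes), AVATAR_VIEWS))
    validation_error("avatar needs exactly an anterior and a posterior silhouette")
  silhouettes <- lapply(silhouettes[AVATAR_VIEWS], as_mask, resolution = resolution)

  ids <- vapply(regions, function(r) r$region_id, character(1))
  if (anyDuplicated(ids))
    validation_error(sprintf("duplicate region_id: %s",
                             paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  names(regions) <- ids

  for (view in AVATAR_VIEWS) {
    sil <- silhouettes[[view]]
    in_view <- Filter(function(r) r$view == view, regions)
    cover <- matrix(FALSE, nrow(sil), ncol(sil))
    for (r in in_view) {
      m <- as_mask(r$mask, resolution)
      if (any(m & !sil))
        containment_error(sprintf(
          "region '%s' has %d pixel(s) outside the %s silhouette",
          r$region_id, sum(m & !sil), view))
      if (any(m & cover)) {
        # name the offending pair for the error message
        for (r2 in in_view) {
          if (identical(r2$region_id, r$region_id)) break
          if (any(m & r2$mask))
            partition_error(sprintf(
              "regions '%s' and '%s' overlap on the %s view",
              r2$region_id, r$region_id, view))
        }
      }
      cover <- cover | m
    }
    if (any(sil & !cover))
      partition_error(sprintf(
        "%d silhouette pixel(s) on the %s view belong to no region",
        sum(sil & !cover), view))
  }

  structure(list(resolution = resolution, silhouettes = silhouettes,
                 regions = regions),
            class = "avatar_model")
}

#' @export
print.avatar_model <- function(x, ...) {
  cat(sprintf("<avatar_model> %dx%d px, %d regions\n",
              x$resolution[1L], x$resolution[2L], length(x$regions)))
  for (view in AVATAR_VIEWS) {
    n <- sum(vapply(x$regions, function(r) r$view == view, logical(1)))
    cat(sprintf("  %s: silhouette %d px, %d regions\n",
                view, sum(x$silhouettes[[view]]), n))
  }
  invisible(x)
}

#' Load an avatar from a manifest
#'
#' Reads a YAML manifest naming the resolution, per-view silhouette PNGs and
#' per-region PNG masks (single channel, any nonzero pixel painted), then
#' validates the partition contract. An already-assembled list with in-memory
#' masks is accepted too. Loading is deterministic.
#'
#' @param config_source Path to a manifest YAML (mask file paths resolved
#'   relative to its directory), or a list with elements `resolution`,
#'   `silhouettes`, `regions`.
#' @return A validated [avatar_model()].
#' @export
load_avatar <- function(config_source) {
  if (is.character(config_source)) {
    dir <- dirname(config_source)
    cfg <- yaml::read_yaml(config_source)
    res <- c(cfg$resolution$width, cfg$resolution$height)
    sils <- lapply(cfg$silhouettes, function(f) read_mask_png(file.path(dir, f)))
    regions <- lapply(cfg$regions, function(rg) {
      body_region(rg$region_id, rg$display_name %||% rg$region_id, rg$view,
                  rg$laterality, read_mask_png(file.path(dir, rg$file)),
                  rg$body_part_category)
    })
    avatar_model(res, sils, regions)
  } else {
    avatar_model(config_source$resolution, config_source$silhouettes,
                 config_source$regions)
  }
}

read_mask_png <- function(path) {
  if (!file.exists(path)) not_found_error(sprintf("mask file not found: %s", path))
  as_mask(png::readPNG(path))
}

write_mask_png <- function(mask, path) {
  png::writePNG(mask * 1.0, path)
  invisible(path)
}

#' Export an avatar to PNG masks plus a YAML manifest
#'
#' The inverse of [load_avatar()]: writes one silhouette PNG per view, one
#' mask PNG per region, and `avatar.yaml`, so the packaged avatar can be
#' inspected or replaced with real artwork.
#'
#' @param avatar An [avatar_model()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_avatar <- function(avatar, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sil_files <- list()
  for (view in AVATAR_VIEWS) {
    f <- sprintf("silhouette_%s.png", view)
    write_mask_png(avatar$silhouettes[[view]], file.path(dir, f))
    sil_files[[view]] <- f
  }
  regions <- lapply(unname(avatar$regions), function(r) {
    f <- sprintf("region_%s.png", r$region_id)
    write_mask_png(r$mask, file.path(dir, f))
    list(region_id = r$region_id, file = f, view = r$view,
         laterality = r$laterality, display_name = r$display_name,
         body_part_category = r$body_part_category)
  })
  manifest <- list(
    resolution = list(width = avatar$resolution[1L], height = avatar$resolution[2L]),
    silhouettes = sil_files, regions = regions)
  path <- file.path(dir, "avatar.yaml")
  yaml::write_yaml(manifest, path)
  invisible(path)
}

#' Construct a paint layer
#'
#' One binary paint mask for one burn-depth category on one avatar view.
#'
#' @param view `"anterior"` or `"posterior"`.
#' @param depth One of `"superficial"`, `"partial"`, `"full"`,
#'   `"indeterminate"`.
#' @param mask Logical matrix at avatar resolution.
#' @return A `paint_layer` object.
#' @export
paint_layer <- function(view, depth, mask) {
  view <- match.arg(view, AVATAR_VIEWS)
  depth <- match.arg(depth, DEPTH_CATEGORIES)
  structure(list(view = view, depth = depth, mask = as_mask(mask)),
            class = "paint_layer")
}

#' Clip a raw paint mask to the avatar silhouette
#'
#' Normalises a painted area so that no pixels lie outside the avatar,
#' preventing TBSA overestimation through stray strokes. The operation is the
#' set intersection with the view silhouette and is idempotent.
#'
#' @param raw_mask Logical or 0/1 matrix at avatar resolution.
#' @param avatar An [avatar_model()].
#' @param view Which view's silhouette to clip against.
#' @return A logical mask, subset of the silhouette.
#' @export
clip_to_silhouette <- function(raw_mask, avatar, view) {
  view <- match.arg(view, AVATAR_VIEWS)
  m <- as_mask(raw_mask, avatar$resolution)
  m & avatar$silhouettes[[view]]
}

#' Fraction of a body region covered by a paint layer
#'
#' The pixel-counting core of the TBSA estimate: the number of painted pixels
#' that fall inside the region, divided by the region's pixel count.
#'
#' @param layer A [paint_layer()] already clipped to the silhouette.
#' @param region A [body_region()] on the same view.
#' @return A fraction in `[0, 1]`.
#' @export
painted_fraction <- function(layer, region) {
  if (!identical(layer$view, region$view))
    geometry_error(sprintf("layer view '%s' does not match region view '%s'",
                           layer$view, region$view))
  if (!identical(dim(layer$mask), dim(region$mask)))
    geometry_error("layer and region masks have different resolutions")
  sum(layer$mask & region$mask) / sum(region$mask)
}
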