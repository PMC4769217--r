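# Depth-layered burn paintings over the avatar.

layer_key <- function(view, depth) paste(view, depth, sep = "_")

#' Construct a burn map
#'
#' A collection of paint layers, at most one per (view, depth) pair.
#' Multiple burned areas and multiple depths may be present; overlaps
#' between depths on the same view are resolved by
#' [resolve_depth_overlaps()] before TBSA is computed.
#'
#' @param layers List of [paint_layer()] objects.
#' @param resolved Logical: have depth overlaps already been resolved?
#' @return A `burn_map` object.
#' @export
burn_map <- function(layers = list(), resolved = FALSE) {
  keys <- vapply(layers, function(l) layer_key(l$view, l$depth), character(1))
  if (anyDuplicated(keys))
    validation_error("at most one paint layer per (view, depth) pair")
  names(layers) <- keys
  structure(list(layers = layers, resolved = resolved), class = "burn_map")
}

#' @export
print.burn_map <- function(x, ...) {
  cat(sprintf("<burn_map> %d layer(s)%s\n", length(x$layers),
              if (x$resolved) ", overlap-resolved" else ""))
  for (l in x$layers)
    cat(sprintf("  %s/%s: %d px\n", l$view, l$depth, sum(l$mask)))
  invisible(x)
}

burnmap_layer <- function(bm, view, depth) bm$layers[[layer_key(view, depth)]]

#' Resolve depth overlaps in a burn map
#'
#' When the same pixel has been painted with more than one depth on one
#' view, the deepest category wins: full > partial > indeterminate >
#' superficial. The union of painted pixels is preserved exactly; the
#' operation is deterministic and idempotent.
#'
#' @param burnmap A [burn_map()] whose layers are already clipped to the
#'   silhouette.
#' @return A [burn_map()] with pairwise-disjoint layers per view.
#' @export
resolve_depth_overlaps <- function(burnmap) {
  out <- list()
  for (view in AVATAR_VIEWS) {
    claimed <- NULL
    for (depth in DEPTH_PRECEDENCE) {
      l <- burnmap_layer(burnmap, view, depth)
      if (is.null(l)) next
      m <- l$mask
      if (is.null(claimed)) claimed <- matrix(FALSE, nrow(m), ncol(m))
      m <- m & !claimed
      claimed <- claimed | m
      out[[layer_key(view, depth)]] <- paint_layer(view, depth, m)
    }
  }
  burn_map(unname(out), resolved = TRUE)
}

#' Read a burn map from per-depth PNG masks
#'
#' File-based stand-in for the painting interface: one single-channel PNG
#' per (view, depth), named `<view>_<depth>.png` (e.g.
#' `anterior_partial.png`), at avatar resolution. Masks are clipped to the
#' silhouette and overlap-resolved.
#'
#' @param dir Directory containing the PNG masks; an empty directory yields
#'   an empty burn map.
#' @param avatar An [avatar_model()].
#' @return A clipped, overlap-resolved [burn_map()].
#' @export
read_paint_masks <- function(dir, avatar) {
  files <- sort(list.files(dir, pattern = "\\.png$"))
  layers <- list()
  for (f in files) {
    parts <- strsplit(tools::file_path_sans_ext(f), "_", fixed = TRUE)[[1]]
    if (length(parts) != 2L || !parts[1] %in% AVATAR_VIEWS ||
        !parts[2] %in% DEPTH_CATEGORIES)
      bf_stop(sprintf(
        "cannot parse mask file name '%s' (expected <view>_<depth>.png)", f),
        "burnflow_naming_error")
    raw <- read_mask_png(file.path(dir, f))
    clipped <- clip_to_silhouette(raw, avatar, parts[1])
    layers[[length(layers) + 1L]] <- paint_layer(parts[1], parts[2], clipped)
  }
  resolve_depth_overlaps(burn_map(layers))
}

#' Write a burn map as per-depth PNG masks
#'
#' Inverse of [read_paint_masks()]; used by the fixture generator.
#'
#' @param burnmap A [burn_map()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_paint_masks <- function(burnmap, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (l in burnmap$layers)
    write_mask_png(l$mask, file.path(dir, sprintf("%s_%s.png", l$view, l$depth)))
  invisible(dir)
}
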