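# Packaged default avatar.
#
# The avatar artwork used in the phone app is not published, so the package
# ships a synthetic stand-in with the same structural contract: two 480x800
# views (mirroring the trial device screen), each strictly partitioned into
# the Lund-Browder body areas, with left/right limbs as separate regions so
# half-limb percentages can be assigned per side. Regions are axis-aligned
# rectangles, which keeps pixel counts exact and the partition trivially
# verifiable; real artwork can be dropped in via load_avatar().

# region_id, view, laterality, body part category, row1, row2, col1, col2
DEFAULT_AVATAR_REGIONS <- list(
  list("head_ant",           "anterior",  "midline", "head",        40, 140, 190, 290),
  list("neck_ant",           "anterior",  "midline", "neck",       141, 170, 215, 265),
  list("trunk_ant",          "anterior",  "midline", "trunk_front",171, 430, 145, 335),
  list("arm_upper_left_ant", "anterior",  "left",    "upper_arm",  171, 300, 345, 400),
  list("arm_upper_right_ant","anterior",  "right",   "upper_arm",  171, 300,  80, 135),
  list("arm_lower_left_ant", "anterior",  "left",    "lower_arm",  301, 400, 345, 400),
  list("arm_lower_right_ant","anterior",  "right",   "lower_arm",  301, 400,  80, 135),
  list("hand_left_ant",      "anterior",  "left",    "hand",       401, 460, 345, 400),
  list("hand_right_ant",     "anterior",  "right",   "hand",       401, 460,  80, 135),
  list("genitalia",          "anterior",  "midline", "genitalia",  431, 465, 225, 255),
  list("thigh_left_ant",     "anterior",  "left",    "thigh",      431, 580, 256, 335),
  list("thigh_right_ant",    "anterior",  "right",   "thigh",      431, 580, 145, 224),
  list("leg_left_ant",       "anterior",  "left",    "lower_leg",  581, 720, 256, 330),
  list("leg_right_ant",      "anterior",  "right",   "lower_leg",  581, 720, 150, 224),
  list("foot_left_ant",      "anterior",  "left",    "foot",       721, 780, 256, 330),
  list("foot_right_ant",     "anterior",  "right",   "foot",       721, 780, 150, 224),
  list("head_post",           "posterior", "midline", "head",       40, 140, 190, 290),
  list("neck_post",           "posterior", "midline", "neck",      141, 170, 215, 265),
  list("trunk_post",          "posterior", "midline", "trunk_back",171, 400, 145, 335),
  list("buttock_left",        "posterior", "left",    "buttock",   401, 430, 241, 335),
  list("buttock_right",       "posterior", "right",   "buttock",   401, 430, 145, 240),
  list("arm_upper_left_post", "posterior", "left",    "upper_arm", 171, 300, 345, 400),
  list("arm_upper_right_post","posterior", "right",   "upper_arm", 171, 300,  80, 135),
  list("arm_lower_left_post", "posterior", "left",    "lower_arm", 301, 400, 345, 400),
  list("arm_lower_right_post","posterior", "right",   "lower_arm", 301, 400,  80, 135),
  list("hand_left_post",      "posterior", "left",    "hand",      401, 460, 345, 400),
  list("hand_right_post",     "posterior", "right",   "hand",      401, 460,  80, 135),
  list("thigh_left_post",     "posterior", "left",    "thigh",     431, 580, 256, 335),
  list("thigh_right_post",    "posterior", "right",   "thigh",     431, 580, 145, 224),
  list("leg_left_post",       "posterior", "left",    "lower_leg", 581, 720, 256, 330),
  list("leg_right_post",      "posterior", "right",   "lower_leg", 581, 720, 150, 224),
  list("foot_left_post",      "posterior", "left",    "foot",      721, 780, 256, 330),
  list("foot_right_post",     "posterior", "right",   "foot",      721, 780, 150, 224)
)

rect_mask <- function(width, height, r1, r2, c1, c2) {
  m <- matrix(FALSE, nrow = height, ncol = width)
  m[r1:r2, c1:c2] <- TRUE
  m
}

#' The packaged default body avatar
#'
#' Builds the synthetic two-view avatar described above. The default
#' resolution of 480x800 pixels per view matches a typical handset screen;
#' pass `scale` to shrink it proportionally (useful in tests).
#'
#' @param scale Positive scale factor applied to the 480x800 base geometry.
#' @return A validated [avatar_model()].
#' @examples
#' av <- default_avatar(scale = 0.25)
#' length(av$regions)
#' @export
default_avatar <- function(scale = 1) {
  stopifnot(scale > 0)
  w <- as.integer(round(480 * scale)); h <- as.integer(round(800 * scale))
  sc <- function(x, lo = TRUE) {
    v <- as.integer(if (lo) ceiling((x - 1) * scale) + 1L else floor(x * scale))
    max(1L, v)
  }
  regions <- lapply(DEFAULT_AVATAR_REGIONS, function(rg) {
    r1 <- sc(rg[[5]]); r2 <- min(h, sc(rg[[6]], lo = FALSE))
    c1 <- sc(rg[[7]]); c2 <- min(w, sc(rg[[8]], lo = FALSE))
    if (r2 < r1 || c2 < c1)
      validation_error("avatar scale too small: a region collapsed to zero pixels")
    disp <- gsub("_", " ", rg[[1]])
    body_region(rg[[1]], disp, rg[[2]], rg[[3]],
                rect_mask(w, h, r1, r2, c1, c2), rg[[4]])
  })
  sils <- list()
  for (view in AVATAR_VIEWS) {
    m <- matrix(FALSE, nrow = h, ncol = w)
    for (r in regions) if (r$view == view) m <- m | r$mask
    sils[[view]] <- m
  }
  avatar_model(c(w, h), sils, regions)
}

#' Body-part category index
#'
#' The controlled list used both to tag wound photographs and to categorise
#' avatar regions, so the expert can match photos to painted locations. The
#' token set is an editable stand-in for the app's published data dictionary.
#'
#' @return Character vector of category tokens.
#' @export
body_part_categories <- function() {
  enums <- read_enumerations()
  enums$body_part_categories
}
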