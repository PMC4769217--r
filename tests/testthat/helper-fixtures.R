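# Shared fixtures and independent oracles.
#
# The oracles deliberately use naive per-pixel loops so they share no code
# path with the vectorised implementation they check.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Naive double-loop painted fraction.
oracle_painted_fraction <- function(layer_mask, region_mask) {
  hit <- 0L; tot <- 0L
  for (i in seq_len(nrow(region_mask))) {
    for (j in seq_len(ncol(region_mask))) {
      if (region_mask[i, j]) {
        tot <- tot + 1L
        if (layer_mask[i, j]) hit <- hit + 1L
      }
    }
  }
  hit / tot
}

# Per-pixel TBSA oracle: every painted pixel contributes
# lb_percent(its region) / |region mask| percent.
oracle_tbsa <- function(masks_by_view, avatar, table, age) {
  total <- 0
  for (view in names(masks_by_view)) {
    mask <- masks_by_view[[view]]
    regions <- Filter(function(r) r$view == view, avatar$regions)
    idx <- matrix(NA_character_, nrow(mask), ncol(mask))
    for (r in regions) idx[r$mask] <- r$region_id
    ids <- vapply(regions, function(r) r$region_id, character(1))
    size <- vapply(regions, function(r) sum(r$mask), numeric(1))
    # percent carried by one pixel of each region
    per_px <- vapply(ids, function(rid) lb_percent(table, rid, age),
                     numeric(1)) / size
    names(per_px) <- ids
    painted <- which(mask)
    for (p in painted) {
      rid <- idx[[p]]
      if (is.na(rid)) next  # outside silhouette
      total <- total + per_px[[rid]]
    }
  }
  total
}

# A toy avatar: silhouette is a sub-rectangle of a w x h grid, partitioned
# into n_regions horizontal bands (exact pixel counts, trivially disjoint).
toy_avatar <- function(width = 10, height = 10, n_regions = 3,
                       sil = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sil)) sil <- list(r1 = 1, r2 = height, c1 = 1, c2 = width)
  rows <- sil$r1:sil$r2
  cuts <- sort(sample(seq_len(length(rows) - 1), n_regions - 1))
  bounds <- c(0, cuts, length(rows))
  mk <- function(r1, r2, c1, c2) {
    m <- matrix(FALSE, height, width); m[r1:r2, c1:c2] <- TRUE; m
  }
  regions <- list()
  for (view in c("anterior", "posterior")) {
    for (k in seq_len(n_regions)) {
      rr <- rows[(bounds[k] + 1):bounds[k + 1]]
      regions[[length(regions) + 1L]] <- body_region(
        sprintf("%s_band%d", substr(view, 1, 3), k),
        sprintf("band %d", k), view, "midline",
        mk(min(rr), max(rr), sil$c1, sil$c2), "trunk_front")
    }
  }
  silm <- mk(sil$r1, sil$r2, sil$c1, sil$c2)
  avatar_model(c(width, height), list(anterior = silm, posterior = silm),
               regions)
}

# A toy Lund-Browder table covering the given avatar with a single
# all-ages band (random positive weights normalised to 100).
toy_table <- function(avatar, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(avatar$regions)
  w <- stats::runif(length(ids), 0.5, 2)
  pm <- matrix(100 * w / sum(w), nrow = 1, dimnames = list(NULL, ids))
  lb_table(data.frame(lower = 0, upper = Inf), pm)
}

random_mask <- function(width, height, p = 0.5) {
  matrix(stats::runif(width * height) < p, nrow = height, ncol = width)
}

# A complete draft case on the given store.
make_complete_case <- function(store, avatar, table, hcp = "hcp1",
                               age_years = 30, weight_kg = 70) {
  case <- create_case(store, hcp)
  case <- set_demographics(case, patient_demographics(
    "male", age_years = age_years, weight_kg = weight_kg))
  case <- set_injury(case, injury_info(
    "flame", store$clock() - 2 * 3600))
  case <- add_photo(case, case_photo(as.raw(1:8), "hand", store$clock() - 3600))
  bm <- burn_map(list(paint_layer("anterior", "partial",
                                  avatar$regions[[1]]$mask)))
  set_burn_map(case, bm, avatar = avatar, table = table)
}

test_clock <- function(at = "2026-03-01T12:00:00Z") fixed_clock(at)

# Small cached assets; tests share them read-only.
TEST_AVATAR <- default_avatar(scale = 0.2)
TEST_LB <- default_lund_browder_table()
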