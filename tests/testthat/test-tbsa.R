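test_that("depth overlap resolution keeps the union and applies precedence", {
  av <- toy_avatar(10, 10, 2, seed = 5)
  r1 <- av$regions[[1]]$mask; r2 <- av$regions[[2]]$mask
  # disjoint layers pass through unchanged
  bm <- resolve_depth_overlaps(burn_map(list(
    paint_layer("anterior", "full", r1),
    paint_layer("anterior", "partial", r2))))
  expect_identical(bm$layers$anterior_full$mask, r1)
  expect_identical(bm$layers$anterior_partial$mask, r2)

  # a pixel painted both full and partial stays full only
  both <- r1 | r2
  bm2 <- resolve_depth_overlaps(burn_map(list(
    paint_layer("anterior", "partial", both),
    paint_layer("anterior", "full", r1))))
  expect_identical(bm2$layers$anterior_full$mask, r1)
  expect_identical(bm2$layers$anterior_partial$mask, both & !r1)

  # random overlaps: output union equals input union pixelwise, layers disjoint
  set.seed(99)
  for (k in 1:20) {
    masks <- lapply(1:3, function(i) random_mask(10, 10, 0.4))
    depths <- sample(c("superficial", "partial", "full", "indeterminate"), 3)
    inp <- burn_map(Map(function(d, m) paint_layer("anterior", d, m),
                        depths, masks))
    out <- resolve_depth_overlaps(inp)
    union_in <- Reduce(`|`, masks)
    union_out <- Reduce(`|`, lapply(out$layers, `[[`, "mask"))
    expect_identical(union_out, union_in)
    overlap <- Reduce(`+`, lapply(out$layers, function(l) l$mask * 1L))
    expect_true(all(overlap <= 1L))
    # idempotent
    expect_identical(resolve_depth_overlaps(out)$layers, out$layers)
  }
})

test_that("compute_tbsa handles the canonical whole-body and empty cases", {
  av <- TEST_AVATAR; t <- TEST_LB
  full_paint <- resolve_depth_overlaps(burn_map(list(
    paint_layer("anterior", "partial", av$silhouettes$anterior),
    paint_layer("posterior", "partial", av$silhouettes$posterior))))
  res <- compute_tbsa(full_paint, age_years = 30, table = t, avatar = av)
  expect_equal(res$fluid_eligible_percent, 100)
  empty <- resolve_depth_overlaps(burn_map())
  res0 <- compute_tbsa(empty, age_years = 30, table = t, avatar = av)
  expect_identical(res0$fluid_eligible_percent, 0)
  expect_identical(res0$superficial_percent, 0)
  expect_identical(nrow(res0$per_region), 0L)
})

test_that("superficial paint is recorded but never fluid-eligible", {
  av <- TEST_AVATAR; t <- TEST_LB
  bm <- resolve_depth_overlaps(burn_map(list(
    paint_layer("anterior", "superficial", av$regions$trunk_ant$mask))))
  res <- compute_tbsa(bm, age_years = 30, table = t, avatar = av)
  expect_identical(res$fluid_eligible_percent, 0)
  expect_gt(res$superficial_percent, 0)
  expect_equal(res$superficial_percent, lb_percent(t, "trunk_ant", 30))
})

test_that("a single fully painted region contributes exactly its chart percent", {
  av <- TEST_AVATAR; t <- TEST_LB
  for (rid in c("trunk_ant", "hand_left_ant", "head_post")) {
    region <- av$regions[[rid]]
    bm <- resolve_depth_overlaps(burn_map(list(
      paint_layer(region$view, "full", region$mask))))
    res <- compute_tbsa(bm, age_years = 30, table = t, avatar = av)
    expect_equal(res$fluid_eligible_percent, lb_percent(t, rid, 30))
    expect_equal(res$per_depth_percent$full, lb_percent(t, rid, 30))
  }
})

test_that("age changes the weights but never the painted fractions", {
  av <- TEST_AVATAR; t <- TEST_LB
  bm <- resolve_depth_overlaps(burn_map(list(
    paint_layer("anterior", "partial", av$regions$head_ant$mask),
    paint_layer("anterior", "full", av$regions$thigh_left_ant$mask))))
  ages <- list(list(age_years = 30), list(age_years = 8), list(age_months = 6))
  fracs <- lapply(ages, function(a) {
    res <- do.call(compute_tbsa,
                   c(list(burnmap = bm, table = t, avatar = av), a))
    res$per_region[order(res$per_region$region_id),
                   c("region_id", "painted_fraction")]
  })
  expect_identical(fracs[[1]], fracs[[2]])
  expect_identical(fracs[[1]], fracs[[3]])
  # head weighs more in infancy than adulthood
  head_pct <- vapply(ages, function(a) {
    res <- do.call(compute_tbsa, c(list(burnmap = bm, table = t, avatar = av), a))
    res$per_region$percent[res$per_region$region_id == "head_ant"]
  }, numeric(1))
  expect_true(head_pct[3] > head_pct[2] && head_pct[2] > head_pct[1])
})

test_that("adding eligible paint is monotone and contributions are conserved", {
  set.seed(31)
  for (k in 1:10) {
    av <- toy_avatar(sample(10:20, 1), sample(10:20, 1), 3)
    t <- toy_table(av)
    m1 <- clip_to_silhouette(random_mask(av$resolution[1], av$resolution[2], 0.3),
                             av, "anterior")
    m2 <- m1 | clip_to_silhouette(
      random_mask(av$resolution[1], av$resolution[2], 0.3), av, "anterior")
    r1 <- compute_tbsa(resolve_depth_overlaps(burn_map(list(
      paint_layer("anterior", "partial", m1)))), 30, t, av)
    r2 <- compute_tbsa(resolve_depth_overlaps(burn_map(list(
      paint_layer("anterior", "partial", m2)))), 30, t, av)
    expect_gte(r2$fluid_eligible_percent, r1$fluid_eligible_percent)
    # conservation: per-region contributions sum to the per-depth totals
    expect_equal(sum(r2$per_region$percent),
                 sum(unlist(r2$per_depth_percent)), tolerance = 1e-9)
  }
})

test_that("compute_tbsa requires overlap resolution and a valid age", {
  av <- TEST_AVATAR
  raw <- burn_map(list(paint_layer("anterior", "partial",
                                   av$regions$trunk_ant$mask)))
  expect_error(compute_tbsa(raw, age_years = 30, avatar = av, table = TEST_LB),
               class = "burnflow_validation_error")
  bm <- resolve_depth_overlaps(raw)
  expect_error(compute_tbsa(bm, age_years = 30, age_months = 3,
                            avatar = av, table = TEST_LB),
               class = "burnflow_validation_error")
  expect_error(compute_tbsa(bm, avatar = av, table = TEST_LB),
               class = "burnflow_validation_error")
  expect_error(compute_tbsa(bm, age_months = 12, avatar = av, table = TEST_LB),
               class = "burnflow_validation_error")
})
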