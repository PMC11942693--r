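test_that("axis points classify into the expected restoration stack", {
  # healthy: occlusal enamel cap
  expect_equal(classify_point(build_scenario("healthy"), c(0, 0, 20.9)),
               "ENAMEL")
  # small insert scenario: cap is z in (19, 21), insert z in (17.3, 19)
  g <- build_scenario("small_ic")
  expect_equal(classify_point(g, c(0, 0, 20)), "COMPOSITE")
  expect_equal(classify_point(g, c(0, 0, 18)), "INSERT")
  # big insert scenario: depth 2 + 0.5 + 4.7 = 7.2, floor at 13.8, and the
  # 0.5 mm cement bowl sits directly beneath the insert
  gb <- build_scenario("big_ic")
  expect_equal(gb$cavity_depth, 7.2)
  expect_equal(gb$cavity_floor_z, 13.8)
  expect_equal(classify_point(gb, c(0, 0, 13.9)), "CEMENT")
  # composite-only control fills the whole cavity
  expect_equal(classify_point(build_scenario("small_c"), c(0, 0, 18)),
               "COMPOSITE")
})

test_that("tissue points classify correctly and bad points error", {
  g <- build_scenario("healthy")
  expect_equal(classify_point(g, c(7, 7, 3)), "BONE")
  for (sc in SCENARIO_IDS)
    expect_equal(classify_point(build_scenario(sc), c(0, 0, 7)), "PULP")
  # below the CEJ, just outside the tooth ellipse: PDL shell
  expect_equal(classify_point(g, c(5.1, 0, 6)), "PDL")
  expect_equal(classify_point(g, c(4.9, 0, 6)), "DENTIN")
  expect_error(classify_point(g, c(0, 0, 30)), "out-of-domain")
})

test_that("classification is total over the bounding box", {
  g <- build_scenario("big_ic")
  bb <- g$bbox
  set.seed(42)
  n <- 1e5
  pts <- cbind(runif(n, bb[1, 1], bb[2, 1]),
               runif(n, bb[1, 2], bb[2, 2]),
               runif(n, bb[1, 3], bb[2, 3]))
  lab <- classify_points(g, pts)
  expect_equal(length(lab), n)
  expect_true(all(lab %in% c(REGION_LEVELS, "OUTSIDE")))
})

test_that("restoration nests inside the cavity cylinder and pulp inside the tooth", {
  g <- build_scenario("big_ic")
  d <- g$dims
  set.seed(7)
  n <- 5e4
  bb <- g$bbox
  pts <- cbind(runif(n, bb[1, 1], bb[2, 1]),
               runif(n, bb[1, 2], bb[2, 2]),
               runif(n, bb[1, 3], bb[2, 3]))
  lab <- classify_points(g, pts)
  resto <- lab %in% c("COMPOSITE", "CEMENT", "INSERT")
  rc <- d$cavity_diameter / 2
  expect_true(all(pts[resto, 1]^2 + pts[resto, 2]^2 <= rc^2 + 1e-12))
  expect_true(all(pts[resto, 3] >= g$cavity_floor_z - 1e-12))
  pulp <- lab == "PULP"
  expect_true(all((pts[pulp, 1] / (d$vo_width / 2))^2 +
                    (pts[pulp, 2] / (d$md_width / 2))^2 <= 1 + 1e-12))
})

test_that("control and insert scenarios differ only inside the cavity", {
  gc_ <- build_scenario("small_c")
  gi <- build_scenario("small_ic")
  set.seed(11)
  n <- 5e4
  bb <- gc_$bbox
  pts <- cbind(runif(n, bb[1, 1], bb[2, 1]),
               runif(n, bb[1, 2], bb[2, 2]),
               runif(n, bb[1, 3], bb[2, 3]))
  lc <- classify_points(gc_, pts)
  li <- classify_points(gi, pts)
  differ <- lc != li
  rc <- gc_$dims$cavity_diameter / 2
  in_cav <- pts[, 1]^2 + pts[, 2]^2 <= rc^2 & pts[, 3] >= gc_$cavity_floor_z
  expect_true(all(in_cav[differ]))
})

test_that("invalid cavity geometries are rejected", {
  deep <- tooth_dims(insert_thickness_big = 19)
  expect_error(build_scenario("big_ic", deep), "invalid-geometry")
  tall_pulp <- tooth_dims(pulp_z_range = c(2, 17))
  expect_error(build_scenario("big_c", tall_pulp), "intersects the pulp")
  expect_error(tooth_dims(cavity_diameter = 12), "invalid-geometry")
  expect_error(tooth_dims(insert_diameter = 6), "invalid-geometry")
})

test_that("closed-form restoration volumes match cylinder formulas", {
  vs <- expected_region_volumes(build_scenario("small_ic"))
  vol <- function(tb, r) tb$volume[tb$region == r]
  expect_equal(vol(vs, "INSERT"), pi * 2.35^2 * 1.7, tolerance = 1e-12)
  vb <- expected_region_volumes(build_scenario("big_ic"))
  expect_equal(vol(vb, "INSERT"), pi * 2.35^2 * 4.7, tolerance = 1e-12)
  # spot values quoted as decimals
  expect_equal(vol(vs, "INSERT"), 29.50, tolerance = 1e-3)
  expect_equal(vol(vb, "INSERT"), 81.55, tolerance = 1e-3)
  # cement = annulus around insert + floor disk; composite = cap disk
  expect_equal(vol(vs, "CEMENT"),
               pi * (2.75^2 - 2.35^2) * 1.7 + pi * 2.75^2 * 0.5,
               tolerance = 1e-12)
  expect_equal(vol(vs, "COMPOSITE"), pi * 2.75^2 * 2.0, tolerance = 1e-12)
  vh <- expected_region_volumes(build_scenario("healthy"))
  expect_true(all(vh$volume == 0))
})

test_that("Monte-Carlo volumes agree with closed forms within 3 SE", {
  g <- build_scenario("big_ic")
  closed <- expected_region_volumes(g)
  mc <- mc_region_volumes(g, n = 2e5, seed = 123)
  for (r in c("INSERT", "CEMENT", "COMPOSITE")) {
    v0 <- closed$volume[closed$region == r]
    vm <- mc$volume[mc$region == r]
    se <- mc$se[mc$region == r]
    expect_lt(abs(vm - v0), 3 * se)
  }
})
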