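test_that("region statistics follow the descriptive-statistics definitions", {
  sol <- fake_solution(vm = 7, region = "ENAMEL")
  st <- region_stats(sol, "enamel")
  expect_equal(st$average, 7)
  expect_equal(st$median, 7)
  expect_equal(st$max_vm, 7)
  expect_equal(st$stdev, 0)
  # quartiles by linear interpolation between order statistics
  sol4 <- fake_solution(vm = c(1, 2, 3, 4), region = rep("DENTIN", 4))
  st4 <- region_stats(sol4, "dentin")
  expect_equal(st4$median, 2.5)
  expect_equal(st4$q1, 1.75)
  expect_equal(st4$q3, 3.25)
  expect_equal(st4$average, 2.5)
  expect_equal(st4$stdev, sd(1:4))
  # absent group: zero-row result, not zeros
  expect_equal(nrow(region_stats(sol4, "restoration")), 0L)
})

test_that("region statistics are invariant under element reordering", {
  set.seed(5)
  vm <- runif(20, 0, 50)
  reg <- sample(c("ENAMEL", "DENTIN", "COMPOSITE"), 20, replace = TRUE)
  a <- solution_region_stats(fake_solution(vm, reg))
  perm <- sample(20)
  b <- solution_region_stats(fake_solution(vm[perm], reg[perm]))
  expect_equal(a[order(a$group), setdiff(names(a), "max_displacement")],
               b[order(b$group), setdiff(names(b), "max_displacement")])
})

test_that("contraction rate recovers analytic uniform strain", {
  fc <- cached_free_cylinder_phase1()
  mesh <- fc$fixture$mesh
  eps <- 0.01
  sol <- fake_solution(vm = numeric(mesh$n_elements), region = mesh$region)
  sol$mesh <- mesh
  sol$u <- eps * mesh$nodes
  cr <- contraction_rate(sol)
  expect_equal(cr$rate, rep(100 * (1 - (1 + eps)^3), 2), tolerance = 1e-9)
  # zero displacement: zero contraction
  sol$u <- 0 * mesh$nodes
  expect_equal(contraction_rate(sol)$rate, c(0, 0))
  # solved free shrinkage: the two methods agree within 10 % relative
  cs <- contraction_rate(fc$solution)
  expect_lt(abs(cs$rate[1] - cs$rate[2]) / abs(cs$rate[1]), 0.1)
  expect_error(contraction_rate(fake_solution(1, "ENAMEL")),
               "empty restoration")
})

test_that("percent decrease reproduces the published pairs and flags increases", {
  expect_equal(as.numeric(percent_decrease(518.47, 322.63)), 37.77,
               tolerance = 1e-4)
  pd <- percent_decrease(186.43, 192.59)
  expect_equal(as.numeric(pd), -3.304, tolerance = 1e-3)
  expect_true(attr(pd, "increase"))
  expect_false(attr(percent_decrease(518.47, 322.63), "increase"))
  expect_equal(as.numeric(percent_decrease(5, 5)), 0)
  expect_error(percent_decrease(0, 1), "positive")
  # consistency: insert value reconstructs from control and decrease
  c0 <- 243.7; i0 <- 117.2
  pd0 <- as.numeric(percent_decrease(c0, i0))
  expect_equal(c0 * (1 - pd0 / 100), i0, tolerance = 1e-12)
})

test_that("near-floor stress guards its preconditions", {
  mat <- default_material_table()
  mh <- generate_mesh(build_scenario("healthy"), h = 2,
                      support_mode = "simple")
  sh <- run_phase(mh, mat, "mechanical_only")
  expect_error(near_floor_stress(sh), "cavity scenario")
  fx <- make_fixture("tiny_tooth")
  s2 <- run_phase(fx$mesh, fx$materials, "phase2_thermal_plus_occlusal")
  expect_error(near_floor_stress(s2, distance = 1e-9), "empty-selection")
  expect_error(near_floor_stress(s2, distance = 0), "distance")
  expect_gt(near_floor_stress(s2, distance = 1.5), 0)
})

test_that("study reports round-trip through JSON and CSV", {
  cfg <- study_config(scenarios = c("healthy", "small_c"), h = 2,
                      support_mode = "simple")
  rep <- run_study(cfg)
  dir <- file.path(tempdir(), "toothfea-report")
  paths <- write_report(rep, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "descriptive_stats.csv")))
  back <- read_report(dir)
  expect_equal(back$stats, rep$stats, tolerance = 1e-12)
  expect_equal(back$contraction, rep$contraction, tolerance = 1e-12)
  expect_equal(back$near_floor, rep$near_floor, tolerance = 1e-12)
  unlink(dir, recursive = TRUE)
})

test_that("an empty study writes headers-only tables", {
  empty <- structure(list(stats = toothfea:::empty_stats(),
                          percent_decrease = toothfea:::empty_decrease(),
                          contraction = toothfea:::empty_contraction(),
                          near_floor = toothfea:::empty_near_floor(),
                          failures = toothfea:::empty_failures(),
                          meta = list(h = 1)), class = "study_report")
  dir <- file.path(tempdir(), "toothfea-empty")
  write_report(empty, dir)
  csv <- readLines(file.path(dir, "descriptive_stats.csv"))
  expect_equal(length(csv), 1L)
  expect_match(csv, "scenario")
  unlink(dir, recursive = TRUE)
})
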