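test_that("treatment schedules assemble and validate", {
  sch <- make_treatment_schedule(42, onset = 40, total = 165,
                                 perm_p(), treat_p())
  expect_equal(length(sch$seasons), 3)
  expect_equal(sch$total_duration, 165)
  expect_equal(sch$treatment_length, 42)
  expect_equal(sch$onset, 40)

  # zero-length treatment drops the season
  sch0 <- make_treatment_schedule(0, onset = 40, total = 165,
                                  perm_p(), treat_p())
  expect_equal(length(sch0$seasons), 2)
  expect_true(all(vapply(sch0$seasons, `[[`, character(1), "label") ==
                  "permissive"))

  expect_error(make_treatment_schedule(200, 40, 165, perm_p(), treat_p()),
               "exceeds")
  expect_error(environment_schedule(list(
    list(duration = 1, label = "permissive", params = perm_p(1)),
    list(duration = 1, label = "treatment", params = treat_p(2)))),
    "same n_on")
})

test_that("the default grid has 84 unit-step sequences of total 165", {
  grid <- make_grid(permissive_params = perm_p(), treatment_params = treat_p())
  expect_length(grid, 84)
  expect_true(all(vapply(grid, `[[`, numeric(1), "total_duration") == 165))
  lens <- vapply(grid, `[[`, numeric(1), "treatment_length")
  expect_equal(lens, 1:84)
  g1 <- make_grid(1, permissive_params = perm_p(), treatment_params = treat_p())
  expect_length(g1, 1)
  expect_equal(g1[[1]]$treatment_length, 1)
  expect_error(make_grid(200, permissive_params = perm_p(),
                         treatment_params = treat_p()), "exceeds")
})

test_that("piecewise integration is continuous and degenerate seasons are inert", {
  sch <- make_treatment_schedule(10, onset = 5, total = 30,
                                 perm_p(3), treat_p(3))
  tr <- integrate_schedule(sch, all_off_state(3), dt_out = 0.1)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 30)
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(tr$total_population > 0))

  # zero-length treatment equals an all-permissive run
  a <- integrate_schedule(make_treatment_schedule(0, 5, 20, perm_p(2),
                                                  treat_p(2)),
                          all_off_state(2), dt_out = 0.25)
  b <- integrate_ode(perm_p(2), all_off_state(2), t_end = 20, dt_out = 0.25)
  expect_equal(a$states, b$states, tolerance = 1e-10)
})

test_that("a purely permissive sequence gives g = 0.02 t and r = 0", {
  sch0 <- make_treatment_schedule(0, 40, 165, perm_p(), treat_p())
  for (n in c(1, 4, 17)) {
    rec <- lineage_fitness(n, sch0)
    expect_equal(rec$g_m, 0.02 * 165, tolerance = 1e-8)
    expect_equal(rec$g_mless, 0.02 * 165, tolerance = 1e-8)
    expect_equal(rec$r, 0, tolerance = 1e-12)
  }
})

test_that("the memoryless lineage is its own comparator (r identically 0)", {
  grid <- make_grid(permissive_params = perm_p(), treatment_params = treat_p())
  for (sch in grid[c(1, 30, 84)]) {
    rec <- lineage_fitness(1, sch)
    expect_equal(rec$r, 0, tolerance = 1e-14)
    expect_equal(rec$epsilon_memoryless, rec$epsilon)
  }
})

test_that("memory is inconsequential under lengthy sustained treatment", {
  sch <- make_treatment_schedule(2000, onset = 0, total = 2000,
                                 perm_p(), treat_p())
  for (n in c(2, 4, 9, 23, 31)) {
    rec <- lineage_fitness(n, sch)
    expect_lt(abs(rec$r), 1e-4)
  }
})

test_that("absolute growth is non-increasing in treatment length", {
  grid <- make_grid(permissive_params = perm_p(), treatment_params = treat_p())
  for (n in c(1, 6, 31)) {
    cache <- new.env(parent = emptyenv())
    g <- vapply(grid, function(s) lineage_fitness(n, s, cache = cache)$g_m,
                numeric(1))
    expect_true(all(diff(g) <= 1e-10))
  }
})

test_that("short treatment penalizes long memory", {
  sch <- make_treatment_schedule(2, 40, 165, perm_p(), treat_p())
  rec <- lineage_fitness(31, sch)
  expect_lt(rec$r, 0)
})

test_that("lineage fitness matches an explicit trajectory computation", {
  # independent route: full integrate_schedule on re-sized parameters
  n <- 5
  sch <- make_treatment_schedule(20, 40, 165, perm_p(n), treat_p(n))
  tr <- integrate_schedule(sch, all_off_state(n), dt_out = 0.05)
  g_direct <- log(tr$total_population[length(tr$times)] / 1000)
  sch1 <- make_treatment_schedule(20, 40, 165, perm_p(), treat_p())
  rec <- lineage_fitness(n, sch1)
  expect_equal(rec$g_m, g_direct, tolerance = 1e-8)
})

test_that("schedules round-trip through the season table format", {
  sch <- make_treatment_schedule(42, 40, 165, perm_p(2), treat_p(2))
  path <- tempfile(fileext = ".tsv")
  write_schedule(sch, path)
  back <- read_schedule(path, n_on = 2)
  expect_equal(back$total_duration, sch$total_duration)
  expect_equal(back$treatment_length, sch$treatment_length)
  for (i in seq_along(sch$seasons)) {
    expect_equal(back$seasons[[i]]$params, sch$seasons[[i]]$params)
    expect_equal(back$seasons[[i]]$duration, sch$seasons[[i]]$duration)
  }
})

test_that("landscape output writer keeps the documented columns", {
  land <- fitness_landscape(c(1, 3), make_grid(
    3, permissive_params = perm_p(), treatment_params = treat_p()))
  expect_equal(nrow(land), 6)
  path <- tempfile(fileext = ".tsv")
  write_landscape(land, path)
  df <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(names(df),
               c("schedule_id", "treatment_length", "onset", "n_on",
                 "epsilon", "epsilon_memoryless", "g_m", "g_mless", "r",
                 "extinct_flag"))
})
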