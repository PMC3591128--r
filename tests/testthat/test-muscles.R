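test_that("local muscle work follows the line integral of F . ds", {
  # zero force does no work
  traj <- rbind(c(0, 0, 0), c(0, 0, 25), c(0, 0, 50))
  expect_equal(local_work(list(magnitude = 0, anchor = c(0, 0, 1e7)), traj), 0)
  # constant 10 N force parallel to a straight 50 mm displacement: 0.5 J
  W <- local_work(list(magnitude = 10, anchor = c(0, 0, 1e8)), traj)
  expect_equal(W, 0.5, tolerance = 1e-4)
  # force perpendicular to the displacement does no work
  Wp <- local_work(list(magnitude = 10, anchor = c(1e8, 0, 25)), traj)
  expect_equal(Wp, 0, tolerance = 1e-4)
  expect_error(local_work(list(magnitude = 1, anchor = c(0, 0, 1)),
                          rbind(c(0, 0, 0))), "two configurations")
})

test_that("global muscle work is moment times rotation", {
  expect_equal(global_work(list(magnitude = 15), 0), 0)
  expect_equal(global_work(list(magnitude = 15), 0.2), 3.0)
  expect_equal(global_work(list(magnitude = 6), 0.1), 0.6)
  # ramped moment over a rotation history (trapezoid)
  alphas <- seq(0, 0.2, length.out = 5)
  Ms <- seq(0, 15, length.out = 5)
  expect_equal(global_work(list(magnitude = Ms), alphas),
               sum(0.5 * (Ms[-1] + Ms[-5]) * diff(alphas)))
})

toy_muscle <- list(list(name = "ext_toy", type = "global", vertebra = "L5",
                        axis = "FLX", magnitude = 0))

test_that("single-muscle toy calibration matches a dense grid-search oracle", {
  target <- 2
  cal <- calibrate("FLX", targets = c(target), geometry = geom_toy,
                   cards = card_h, muscles = toy_muscle, preload = 0)
  expect_true(all(cal$magnitudes$magnitude >= 0))
  expect_lt(abs(cal$achieved$cumulative_deg[1] - target), 0.25)

  # brute-force grid over the moment magnitude
  grid <- seq(8, 20, by = 0.1)
  angs <- vapply(grid, function(M) {
    mus <- toy_muscle
    mus[[1]]$magnitude <- M
    lc <- load_case("FLX", preload = 0, moment = 0, muscles = mus)
    st <- solve_equilibrium(lc, geom_toy, card_h)
    measure_state(st, geom_toy, "FLX")$cumulative_deg[1]
  }, numeric(1))
  M_star <- grid[which.min(abs(angs - target))]
  expect_lt(abs(cal$magnitudes$magnitude[1] - M_star), 0.1 * 1.01)
})

test_that("a redundant muscle pair reproduces the single-muscle total with the min-norm tie-break", {
  pair <- list(
    list(name = "m1", type = "global", vertebra = "L5", axis = "FLX",
         magnitude = 0),
    list(name = "m2", type = "global", vertebra = "L5", axis = "FLX",
         magnitude = 0)
  )
  target <- 2
  cal1 <- calibrate("FLX", targets = c(target), geometry = geom_toy,
                    cards = card_h, muscles = toy_muscle, preload = 0)
  cal2 <- calibrate("FLX", targets = c(target), geometry = geom_toy,
                    cards = card_h, muscles = pair, preload = 0)
  expect_equal(sum(cal2$magnitudes$magnitude),
               sum(cal1$magnitudes$magnitude), tolerance = 0.02)
  # sum-of-squares tie-break drives the split towards equality
  expect_lt(abs(diff(cal2$magnitudes$magnitude)),
            0.5 * sum(cal2$magnitudes$magnitude))
})

test_that("zero targets need no muscle action", {
  cal <- calibrate("FLX", targets = c(0), geometry = geom_toy,
                   cards = card_h, muscles = toy_muscle, preload = 0)
  expect_equal(sum(cal$magnitudes$magnitude), 0)
  expect_equal(cal$energy_J, 0)
})

test_that("calibration invariants: nonnegative magnitudes, monotone merit, work bookkeeping", {
  cal <- calibrate("FLX", targets = c(6), geometry = geom_toy,
                   cards = card_h, muscles = toy_muscle, preload = 0)
  expect_true(all(cal$magnitudes$magnitude >= 0))
  expect_true(all(diff(cal$merit_history) <= 1e-9))
  expect_equal(cal$energy_J, sum(cal$magnitudes$work_J), tolerance = 1e-12)
  # the reported work of a constant global moment equals M * alpha
  M <- cal$magnitudes$magnitude[1]
  alpha <- deg2rad(cal$achieved$cumulative_deg[1])
  expect_equal(cal$energy_J, M * alpha, tolerance = 0.02 * max(M * alpha, 1e-9))
})
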