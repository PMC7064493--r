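small_params <- function(...) {
  args <- utils::modifyList(
    list(world_width = 20, world_height = 20, max_ticks = 300), list(...))
  do.call(wsp_params, args)
}

test_that("initial placement honours densities and seeds", {
  p <- wsp_params(world_width = 100, world_height = 100,
                  sheep_density = 0.0384, wolf_density = 0)
  st <- wsp_init(p, seed = 1)
  expect_identical(nrow(st$sheep), 384L)  # round(0.0384 * 10000)
  expect_identical(nrow(st$wolves), 0L)
  expect_true(all(st$sheep[, "x"] >= 0 & st$sheep[, "x"] < 100))
  expect_true(all(st$sheep[, "energy"] >= 0 &
                    st$sheep[, "energy"] < 2 * p$sheep_gain))
  expect_true(all(st$grass >= 0 & st$grass <= p$grass_regrowth_time))
  # same seed, same state
  expect_identical(st, wsp_init(p, seed = 1))
  expect_error(wsp_params(world_width = 0), "world_width")
})

test_that("no spontaneous generation: absent wolves never appear", {
  p <- small_params(wolf_density = 0)
  tr <- wsp_run(p, seed = 2)
  expect_true(all(tr$wolves == 0))
  expect_true(all(tr$sheep >= 0))
})

test_that("identical (params, seed) give bit-identical traces", {
  p <- small_params()
  t1 <- wsp_run(p, seed = 5)
  t2 <- wsp_run(p, seed = 5)
  expect_identical(as.data.frame(t1), as.data.frame(t2))
  t3 <- wsp_run(p, seed = 6)
  expect_false(identical(as.data.frame(t1), as.data.frame(t3)))
})

test_that("counts stay within physical bounds", {
  p <- small_params()
  tr <- wsp_run(p, seed = 9)
  area <- p$world_width * p$world_height
  expect_true(all(tr$grass >= 0 & tr$grass <= area))
  expect_true(all(tr$wolves >= 0 & tr$sheep >= 0))
})

test_that("with no animals, grass regrows monotonically to full cover", {
  p <- small_params(sheep_density = 0, wolf_density = 0,
                    grass_regrowth_time = 30)
  tr <- wsp_run(p, seed = 3)
  expect_true(all(diff(tr$grass) >= 0))
  expect_identical(tail(tr$grass, 1), 400L)
  # run ends as soon as the absorbing state is reached
  expect_lte(max(tr$tick), p$max_ticks)
})

test_that("death rule is energy < 0 after the move", {
  # one sheep, no grass anywhere (all countdowns high), energy = move_cost:
  # survives the first step at exactly 0, dies on the second
  p <- small_params(grass_regrowth_time = 100, sheep_reproduce = 0)
  st <- structure(list(
    grass = matrix(100L, 20, 20),
    wolves = matrix(numeric(0), 0, 3,
                    dimnames = list(NULL, c("x", "y", "energy"))),
    sheep = matrix(c(5, 5, p$move_cost), 1, 3,
                   dimnames = list(NULL, c("x", "y", "energy")))),
    class = "wsp_state")
  set.seed(4)
  s1 <- wsp_step(st, p)
  expect_identical(nrow(s1$sheep), 1L)
  expect_equal(s1$sheep[1, "energy"], 0, ignore_attr = TRUE)
  s2 <- wsp_step(s1, p)
  expect_identical(nrow(s2$sheep), 0L)
})

test_that("an eaten cell regrows after exactly grass_regrowth_time ticks", {
  # immobile-ish scenario: a 1x1 world forces the sheep to stay in place
  p <- wsp_params(world_width = 1, world_height = 1, sheep_density = 1,
                  wolf_density = 0, grass_regrowth_time = 5,
                  sheep_reproduce = 0, max_ticks = 20, sheep_gain = 100)
  set.seed(8)
  st <- wsp_init(p)
  st$grass[1, 1] <- 0L  # start grassy
  st$sheep[1, "energy"] <- 50
  # eaten at tick 1: bare through tick 5, grassy again at tick 1 + 5
  states <- Reduce(function(s, i) wsp_step(s, p), 1:6, init = st,
                   accumulate = TRUE)
  bare <- vapply(states[-1], function(s) s$grass[1, 1] > 0, logical(1))
  expect_identical(bare, c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
})

test_that("mean sheep growth increases with reproduction probability", {
  mean_final <- function(pr) {
    mean(vapply(1:8, function(s) {
      p <- wsp_params(world_width = 15, world_height = 15,
                      wolf_density = 0, grass_regrowth_time = 1,
                      sheep_reproduce = pr, max_ticks = 60)
      tail(wsp_run(p, seed = 100 + s)$sheep, 1)
    }, numeric(1)))
  }
  lo <- mean_final(0.02)
  hi <- mean_final(0.12)
  expect_gt(hi, lo)
})

test_that("modular runs sum independent sub-worlds exactly", {
  p <- small_params(max_ticks = 150)
  # one module of height 100 equals a plain run under the aligned seed
  tr_mod <- wsp_run_modular(100, p, seed = 77)
  p1 <- p
  p1$world_height <- 100L
  p1$world_width <- 100L
  tr_single <- wsp_run(p1, seed = derive_seed(77, "wsp_module", 100, 1))
  expect_identical(tr_mod$wolves, tr_single$wolves)
  expect_identical(tr_mod$sheep, tr_single$sheep)
  expect_identical(tr_mod$grass, tr_single$grass)

  # 50 modules of height 2: conservation of total area
  tr2 <- wsp_run_modular(2, p, seed = 78)
  expect_true(all(tr2$grass <= 10000))
  expect_identical(attr(tr2, "params")$n_modules, 50L)
  expect_error(wsp_run_modular(3, p), "module_height")
})
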