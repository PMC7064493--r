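test_that("breakpoint matches hand-enumerated splits", {
  # clean step: split after position 3 with zero residual
  bp <- find_breakpoint(c(0, 0, 0, 10, 10, 10), min_seg_frac = 1 / 3)
  expect_identical(bp$index, 3L)
  expect_equal(bp$rss, 0)
  # noisy step: admissible splits k = 2,3,4 give RSS 57, 4/3, 57
  bp <- find_breakpoint(c(0, 0, 1, 9, 10, 10), min_seg_frac = 1 / 3)
  expect_identical(bp$index, 3L)
  expect_equal(bp$rss, 4 / 3, tolerance = 1e-12)
  # constant series: every split ties at 0, earliest wins
  bp <- find_breakpoint(rep(5, 6), min_seg_frac = 1 / 3)
  expect_identical(bp$index, 2L)
  expect_equal(bp$rss, 0)
  expect_error(find_breakpoint(c(1, 2, 3), min_seg_frac = 0.4),
               "too short")
})

test_that("breakpoint equals the exhaustive oracle on random series", {
  set.seed(42)
  for (i in 1:200) {
    n <- sample(6:60, 1)
    x <- cumsum(rnorm(n)) + c(rep(0, n %/% 2), rep(rnorm(1, 0, 5),
                                                   n - n %/% 2))
    got <- find_breakpoint(x, 0.15)
    want <- brute_breakpoint(x, 0.15)
    expect_identical(got$index, want$index)
    expect_equal(got$rss, want$rss, tolerance = 1e-8)
  }
})

test_that("breakpoint location is shift and scale invariant", {
  set.seed(7)
  x <- c(rnorm(20, 10), rnorm(15, 2))
  k <- find_breakpoint(x, 0.15)$index
  expect_identical(find_breakpoint(x + 100, 0.15)$index, k)
  expect_identical(find_breakpoint(x * 3.7, 0.15)$index, k)
})

test_that("wolf-sheep shifts are extracted per channel", {
  mk_trace <- function(wolves, sheep, grass, area) {
    new_sim_trace <- getFromNamespace("new_sim_trace", "ecoshift")
    new_sim_trace(tibble::tibble(tick = seq_along(wolves) - 1L,
                                 wolves = wolves, sheep = sheep,
                                 grass = grass),
                  model = "wsp", params = list(area = area))
  }
  wolves <- c(rep(50, 10), 20, 5, 0, rep(0, 10))
  sheep <- rep(30, 23)
  grass <- c(rep(400, 20), 500, 510, 512)
  tr <- mk_trace(wolves, sheep, grass, area = 512)
  ev <- detect_wsp_shifts(tr)
  w <- ev[ev$channel == "wolves", ]
  expect_identical(w$status, "shifted")
  expect_identical(w$end_tick, 12)  # first zero
  # start from the two-segment oracle on the wolves series
  bp <- brute_breakpoint(wolves, 0.15)
  expect_identical(w$start_tick, as.numeric(bp$index))
  expect_identical(w$duration, w$end_tick - w$start_tick)
  # sheep never collapse
  expect_identical(ev[ev$channel == "sheep", ]$status, "no_shift")
  # grass ends at full coverage
  g <- ev[ev$channel == "grass", ]
  expect_identical(g$status, "shifted")
  expect_identical(g$end_tick, 22)

  # channel that starts collapsed is no_shift, not a zero-length shift
  tr0 <- mk_trace(rep(0, 23), sheep, rep(400, 23), area = 512)
  expect_identical(detect_wsp_shifts(tr0)$status,
                   c("no_shift", "no_shift", "no_shift"))
})

test_that("unstable-start durations follow the end rules", {
  mk <- function(df, params) {
    getFromNamespace("new_sim_trace", "ecoshift")(df, "x", params)
  }
  # language saturation
  tr <- mk(tibble::tibble(tick = 0:5, l1_count = c(2, 4, 7, 9, 10, 10)),
           list(n_nodes = 10))
  ev <- duration_unstable_start(tr, "all_same_language")
  expect_identical(ev$duration, 4)
  # saturated from the start: duration 0
  tr <- mk(tibble::tibble(tick = 0:2, l1_count = c(10, 10, 10)),
           list(n_nodes = 10))
  expect_identical(duration_unstable_start(tr, "all_same_language")$duration,
                   0)
  # all-L2 absorbed: no shift
  tr <- mk(tibble::tibble(tick = 0:2, l1_count = c(0, 0, 0)),
           list(n_nodes = 10))
  expect_identical(duration_unstable_start(tr, "all_same_language")$status,
                   "no_shift")
  # count stability: constant tail of 101 equal values ending the series
  alive <- c(60, 50, 40, rep(33, 101))
  tr <- mk(tibble::tibble(tick = seq_along(alive) - 1L, alive = alive),
           list())
  ev <- duration_unstable_start(tr, "count_stable_100")
  expect_identical(ev$duration, 3)
  # zooplankton extinction
  tr <- mk(tibble::tibble(tick = 0:4, Z = c(2, 1, 0.5, 0, 0)), list())
  expect_identical(duration_unstable_start(tr, "z_zero")$duration, 3)
  expect_error(duration_unstable_start(tr, "no_such_rule"))
})

test_that("events serialize to both CSV and JSON", {
  ev <- getFromNamespace("new_shift_event", "ecoshift")("alive", 0, 12,
                                                        "shifted")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, csv)
  expect_identical(readr::read_csv(csv, show_col_types = FALSE)$duration,
                   12)
  js <- withr::local_tempfile(fileext = ".json")
  write_events(ev, js)
  parsed <- jsonlite::read_json(js)
  expect_identical(parsed[[1]]$channel, "alive")
  expect_equal(as.numeric(parsed[[1]]$duration), 12)
})

test_that("filter_shifted preserves order and subsets exactly", {
  ev <- dplyr::bind_rows(
    getFromNamespace("new_shift_event", "ecoshift")("a", 0, 5, "shifted"),
    getFromNamespace("new_shift_event", "ecoshift")("b", NA, NA, "no_shift"),
    getFromNamespace("new_shift_event", "ecoshift")("c", 2, 9, "shifted"))
  out <- filter_shifted(ev)
  expect_identical(out$channel, c("a", "c"))
  expect_identical(nrow(filter_shifted(ev[ev$status == "no_shift", ])), 0L)
  expect_identical(filter_shifted(out), out)
})
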