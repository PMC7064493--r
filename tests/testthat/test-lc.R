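test_that("network construction honours the link rules", {
  # requested links below n - 1 default up to the spanning tree
  net <- lc_build(3, n_links = 1, seed = 1)
  expect_identical(nrow(net$edges), 2L)
  # complete graph: all pairs, degree sd 0
  k5 <- lc_build(5, n_links = 10, seed = 2)
  expect_identical(nrow(k5$edges), 10L)
  expect_equal(lc_degree_sd(k5), 0)
  # no duplicates or self loops, connected by construction
  net <- lc_build(40, n_links = 200, seed = 3)
  key <- paste(pmin(net$edges[, 1], net$edges[, 2]),
               pmax(net$edges[, 1], net$edges[, 2]))
  expect_identical(anyDuplicated(key), 0L)
  expect_true(all(net$edges[, 1] != net$edges[, 2]))
  expect_identical(nrow(net$edges), 200L)
  expect_true(all(lengths(net$adj) >= 1))
  # all-L1 initialisation
  expect_true(all(lc_build(10, init_l1_fraction = 1, seed = 4)$is_l1))
  expect_error(lc_build(5, n_links = 11), "exceeds")
})

test_that("degree heterogeneity matches closed forms", {
  # star over n nodes: degrees {n-1, 1, ..., 1}
  n <- 11
  star <- manual_lc_network(n, cbind(1L, 2:n), rep(FALSE, n))
  mu <- (2 * (n - 1)) / n
  want <- sqrt(((n - 1 - mu)^2 + (n - 1) * (1 - mu)^2) / n)
  expect_equal(lc_degree_sd(star), want, tolerance = 1e-12)
  # regular ring lattice: all degrees 2
  ring <- manual_lc_network(6, cbind(1:6, c(2:6, 1L)), rep(FALSE, 6))
  expect_equal(lc_degree_sd(ring), 0)
})

test_that("adoption is monotone and absorbing", {
  net <- lc_build(60, n_links = 120, init_l1_fraction = 0.1, seed = 5)
  out <- lc_run(net, seed = 6)
  expect_true(all(diff(out$trace$l1_count) >= 0))
  expect_identical(out$event$status, "shifted")
  expect_identical(tail(out$trace$l1_count, 1), 60L)
  # an L2 node surrounded by L1 flips deterministically
  path3 <- manual_lc_network(3, cbind(c(1L, 2L), c(2L, 3L)),
                             c(TRUE, FALSE, TRUE))
  set.seed(7)
  expect_true(all(lc_step(path3)$is_l1))
  # L1 nodes never revert even among all-L2 neighbours
  hubl1 <- manual_lc_network(3, cbind(c(1L, 1L), c(2L, 3L)),
                             c(TRUE, FALSE, FALSE))
  set.seed(8)
  expect_true(lc_step(hubl1)$is_l1[1])
  # no L1 anywhere: absorbed in all-L2, no shift
  none <- lc_build(10, init_l1_fraction = 0, seed = 9)
  out <- lc_run(none, seed = 10)
  expect_identical(out$event$status, "no_shift")
  expect_identical(nrow(out$trace), 1L)
})

test_that("absorption times match the exact Markov oracle", {
  # two-node path, one L1: forced in one tick
  two <- manual_lc_network(3, cbind(c(1L, 2L), c(2L, 3L)),
                           c(TRUE, TRUE, FALSE))
  # (3-node path with two L1: the L2 leaf copies its L1 neighbour)
  set.seed(11)
  expect_identical(lc_run(two)$event$duration, 1)

  # star, hub L1, leaves L2: every leaf copies the hub in tick one
  n_leaves <- 10
  star_hub_l1 <- manual_lc_network(
    n_leaves + 1, cbind(1L, 2:(n_leaves + 1)),
    c(TRUE, rep(FALSE, n_leaves)))
  durs <- vapply(1:25, function(s) {
    lc_run(star_hub_l1, seed = 100 + s)$event$duration
  }, numeric(1))
  expect_true(all(durs == 1))
  # hub L2, one leaf L1: geometric hub wait then one saturating tick
  star_leaf_l1 <- manual_lc_network(
    n_leaves + 1, cbind(1L, 2:(n_leaves + 1)),
    c(FALSE, TRUE, rep(FALSE, n_leaves - 1)))
  durs <- vapply(1:400, function(s) {
    lc_run(star_leaf_l1, seed = 2000 + s)$event$duration
  }, numeric(1))
  want <- star_absorption_mean(n_leaves, 1)  # 11 ticks
  se <- stats::sd(durs) / sqrt(length(durs))
  expect_lt(abs(mean(durs) - want), 3 * se)
})

test_that("runs with an L1 seed on a connected graph always saturate", {
  statuses <- vapply(1:20, function(s) {
    net <- lc_build(30, n_links = 45, init_l1_fraction = 0.1,
                    seed = 300 + s)
    lc_run(net, max_ticks = 5000)$event$status
  }, character(1))
  expect_true(all(statuses == "shifted"))
})

test_that("network io writes edges and states", {
  net <- lc_build(12, n_links = 20, seed = 13)
  path <- withr::local_tempfile(fileext = ".csv")
  lc_write_network(net, path)
  edges <- readr::read_csv(path, show_col_types = FALSE)
  expect_identical(nrow(edges), 20L)
  states <- readr::read_csv(sub("\\.csv$", "_state.csv", path),
                            show_col_types = FALSE)
  expect_identical(nrow(states), 12L)
  expect_true(all(states$language %in% c("L1", "L2")))
})
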