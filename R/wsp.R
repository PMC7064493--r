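#' Parameters for the wolf-sheep-grass predator-prey simulator
#'
#' A grid-based stochastic predator-prey model with a renewable grass
#' layer: wolves must eat sheep and sheep must eat grass to replenish
#' energy, every move costs energy, animals that run out of energy die,
#' every animal reproduces with a fixed per-tick probability, and eaten
#' grass regrows after a fixed number of ticks. The defaults are the
#' widely documented settings of the standard library model, with the
#' sheep reproduction rate fixed at 7% so the system is unstable and can
#' undergo its three regime shifts (wolf extinction, sheep extinction,
#' progression to full grassland).
#'
#' @param world_width,world_height World dimensions in cells (>= 1); the
#'   world is a torus.
#' @param sheep_density,wolf_density Initial animals per cell; the default
#'   densities keep the standard 100 sheep and 50 wolves on a 51 x 51
#'   world constant across world sizes.
#' @param sheep_gain,wolf_gain Energy gained per grass patch / sheep eaten.
#' @param move_cost Energy spent per tick.
#' @param sheep_reproduce,wolf_reproduce Per-tick reproduction
#'   probabilities in [0, 1].
#' @param grass_regrowth_time Ticks an eaten cell needs to regrow (>= 0;
#'   0 means grass regrows immediately).
#' @param mobility Cells moved per tick along a random heading (>= 1).
#' @param max_ticks Simulation horizon.
#' @return A validated `wsp_params` list.
#' @export
wsp_params <- function(world_width = 51, world_height = 51,
                       sheep_density = 100 / 2601,
                       wolf_density = 50 / 2601,
                       sheep_gain = 4, wolf_gain = 20, move_cost = 1,
                       sheep_reproduce = 0.07, wolf_reproduce = 0.05,
                       grass_regrowth_time = 50, mobility = 1,
                       max_ticks = 5000) {
  check_scalar(world_width, "world_width", lo = 1, integer = TRUE)
  check_scalar(world_height, "world_height", lo = 1, integer = TRUE)
  check_scalar(sheep_density, "sheep_density", lo = 0)
  check_scalar(wolf_density, "wolf_density", lo = 0)
  check_scalar(sheep_gain, "sheep_gain", lo = 0)
  check_scalar(wolf_gain, "wolf_gain", lo = 0)
  check_scalar(move_cost, "move_cost", lo = 0)
  check_scalar(sheep_reproduce, "sheep_reproduce", lo = 0, hi = 1)
  check_scalar(wolf_reproduce, "wolf_reproduce", lo = 0, hi = 1)
  check_scalar(grass_regrowth_time, "grass_regrowth_time", lo = 0,
               integer = TRUE)  # 0 = grass regrows immediately
  check_scalar(mobility, "mobility", lo = 1)
  check_scalar(max_ticks, "max_ticks", lo = 1, integer = TRUE)
  structure(list(world_width = as.integer(world_width),
                 world_height = as.integer(world_height),
                 torus = TRUE,
                 sheep_density = sheep_density,
                 wolf_density = wolf_density,
                 sheep_gain = sheep_gain, wolf_gain = wolf_gain,
                 move_cost = move_cost,
                 sheep_reproduce = sheep_reproduce,
                 wolf_reproduce = wolf_reproduce,
                 grass_regrowth_time = as.integer(grass_regrowth_time),
                 mobility = mobility,
                 max_ticks = as.integer(max_ticks)),
            class = "wsp_params")
}

#' Initialise a wolf-sheep-grass world
#'
#' Places `round(density * cells)` animals of each kind uniformly at
#' random with initial energies uniform on `[0, 2 * gain)`; each cell
#' starts grassy with probability 0.5, otherwise its regrowth countdown is
#' uniform on `[1, grass_regrowth_time]`.
#'
#' @param params A [wsp_params()] object.
#' @param seed Optional integer seed.
#' @return A `wsp_state`: list with `grass` (integer countdown matrix,
#'   0 = grassy) and `wolves`/`sheep` matrices with columns `x`, `y`
#'   (0-based cell coordinates) and `energy`.
#' @export
wsp_init <- function(params, seed = NULL) {
  stopifnot(inherits(params, "wsp_params"))
  if (!is.null(seed)) set.seed(seed)
  w <- params$world_width
  h <- params$world_height
  cells <- w * h
  place <- function(n, gain) {
    cbind(x = sample.int(w, n, replace = TRUE) - 1L,
          y = sample.int(h, n, replace = TRUE) - 1L,
          energy = stats::runif(n, 0, 2 * gain))
  }
  n_sheep <- round(params$sheep_density * cells)
  n_wolves <- round(params$wolf_density * cells)
  grassy <- stats::runif(cells) < 0.5
  countdown <- if (params$grass_regrowth_time == 0L) rep(0L, cells) else
    ifelse(grassy, 0L, sample.int(params$grass_regrowth_time, cells,
                                  replace = TRUE))
  structure(list(grass = matrix(as.integer(countdown), nrow = h, ncol = w),
                 wolves = place(n_wolves, params$wolf_gain),
                 sheep = place(n_sheep, params$sheep_gain)),
            class = "wsp_state")
}

wsp_counts <- function(state) {
  c(wolves = nrow(state$wolves), sheep = nrow(state$sheep),
    grass = sum(state$grass == 0L))
}

#' Advance a wolf-sheep-grass state by one tick
#'
#' Uses the R random number stream, so results are reproducible under
#' [set.seed()].
#'
#' @param state A `wsp_state` from [wsp_init()] or a previous step.
#' @param params The matching [wsp_params()].
#' @return The new `wsp_state`.
#' @export
wsp_step <- function(state, params) {
  stopifnot(inherits(state, "wsp_state"), inherits(params, "wsp_params"))
  res <- wsp_ticks_cpp(state$grass, state$wolves, state$sheep, params,
                       1L, FALSE)
  structure(list(grass = res$grass, wolves = res$wolves,
                 sheep = res$sheep), class = "wsp_state")
}

#' Run the wolf-sheep-grass simulator
#'
#' Iterates the model to `max_ticks`, or stops early once all three regime
#' shifts have completed (wolves extinct, sheep extinct, grass at full
#' coverage), after which the state is absorbing.
#'
#' @param params A [wsp_params()] object.
#' @param seed Integer seed.
#' @return A `sim_trace` tibble with columns `tick` (0-based), `wolves`,
#'   `sheep`, `grass` (grass-covered cell count).
#' @examples
#' tr <- wsp_run(wsp_params(world_width = 15, world_height = 15,
#'                          max_ticks = 200), seed = 1)
#' detect_wsp_shifts(tr)
#' @export
wsp_run <- function(params, seed = NULL) {
  stopifnot(inherits(params, "wsp_params"))
  if (!is.null(seed)) set.seed(seed)
  state <- wsp_init(params)
  c0 <- wsp_counts(state)
  res <- wsp_ticks_cpp(state$grass, state$wolves, state$sheep, params,
                       params$max_ticks, TRUE)
  p <- unclass(params)
  p$area <- params$world_width * params$world_height
  new_sim_trace(
    tibble::tibble(tick = 0:res$ticks_done,
                   wolves = c(c0[["wolves"]], res$wolves_trace),
                   sheep = c(c0[["sheep"]], res$sheep_trace),
                   grass = c(c0[["grass"]], res$grass_trace)),
    model = "wsp", params = p, seed = seed)
}

#' Run a modular wolf-sheep-grass system of constant total area
#'
#' Divides a fixed 100 x 100 world into `100 / module_height` independent
#' `module_height` x 100 sub-worlds, runs each with its own derived seed,
#' and returns the tick-wise sum of their wolf, sheep and grass channels.
#' Modules that reach their absorbing state before the longest module are
#' held constant at their final counts, so the summed series is exact.
#'
#' @param module_height One of 2, 5, 10, 20, 50, 100.
#' @param params A [wsp_params()] object; world dimensions are overridden
#'   per module.
#' @param seed Master seed from which per-module seeds are derived.
#' @return A `sim_trace` of the summed system (total area 10000 cells).
#' @export
wsp_run_modular <- function(module_height, params = wsp_params(),
                            seed = NULL) {
  if (!module_height %in% c(2, 5, 10, 20, 50, 100) ||
      100 %% module_height != 0)
    stop("`module_height` must divide 100 (one of 2, 5, 10, 20, 50, 100)",
         call. = FALSE)
  n_mod <- 100L %/% as.integer(module_height)
  p <- params
  p$world_height <- as.integer(module_height)
  p$world_width <- 100L
  traces <- lapply(seq_len(n_mod), function(i) {
    wsp_run(p, seed = derive_seed(seed %||% 0, "wsp_module", module_height,
                                  i))
  })
  len <- max(vapply(traces, nrow, integer(1)))
  pad <- function(v) c(v, rep(v[length(v)], len - length(v)))
  out <- tibble::tibble(
    tick = 0:(len - 1L),
    wolves = Reduce(`+`, lapply(traces, function(t) pad(t$wolves))),
    sheep = Reduce(`+`, lapply(traces, function(t) pad(t$sheep))),
    grass = Reduce(`+`, lapply(traces, function(t) pad(t$grass))))
  pp <- unclass(params)
  pp$area <- 10000L
  pp$module_height <- module_height
  pp$n_modules <- n_mod
  new_sim_trace(out, model = "wsp_modular", params = pp, seed = seed)
}
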