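#' Seed a random cellular-automaton grid
#'
#' Each cell is independently alive with probability `density`. An initial
#' density of 35% leaves the automaton inherently unstable: the alive-cell
#' count decays from tick 0 until a stable count is reached, which is the
#' single regime shift this model can undergo.
#'
#' @param width,height Grid dimensions in cells (>= 1).
#' @param density Probability a cell starts alive, in [0, 1].
#' @param seed Optional integer seed.
#' @return Integer 0/1 matrix with `height` rows and `width` columns.
#' @export
gol_seed <- function(width, height, density = 0.35, seed = NULL) {
  check_scalar(width, "width", lo = 1, integer = TRUE)
  check_scalar(height, "height", lo = 1, integer = TRUE)
  check_scalar(density, "density", lo = 0, hi = 1)
  if (!is.null(seed)) set.seed(seed)
  matrix(as.integer(stats::runif(width * height) < density),
         nrow = height, ncol = width)
}

#' Synchronous cellular-automaton update
#'
#' Standard birth/survival rules on a torus: a live cell survives with 2
#' or 3 live neighbours, a dead cell becomes alive with exactly 3. The
#' `vonneumann4` variant restricts the neighbourhood to the four
#' orthogonal cells while keeping the same thresholds, reducing the
#' directions along which change can propagate.
#'
#' @param grid Integer/logical 0-1 matrix.
#' @param neighborhood `"moore8"` (default) or `"vonneumann4"`.
#' @return The updated integer matrix.
#' @export
gol_step <- function(grid, neighborhood = c("moore8", "vonneumann4")) {
  neighborhood <- match.arg(neighborhood)
  gol_step_cpp(matrix(as.integer(grid != 0), nrow(grid), ncol(grid)),
               if (neighborhood == "moore8") 8L else 4L)
}

gol_event_from_counts <- function(counts, window = 100L) {
  end <- stable_window_start(counts, seq_along(counts) - 1L, window)
  if (is.na(end)) new_shift_event("alive", NA, NA, "no_shift")
  else new_shift_event("alive", 0, end, "shifted")
}

#' Run the cellular automaton to stability
#'
#' Iterates the automaton from a random grid until the alive-cell count
#' has not changed for 100 consecutive steps or `max_ticks` is reached.
#' The model starts unstable, so the shift starts at tick 0 and its
#' duration is the first tick of the unchanged window. Note the criterion
#' is count-based: configurations whose cells change while conserving the
#' alive count (e.g. a lone blinker) register as stable.
#'
#' @param width,height Grid dimensions.
#' @param density Initial alive density.
#' @param neighborhood `"moore8"` or `"vonneumann4"`.
#' @param max_ticks Horizon (default 5000).
#' @param seed Optional integer seed.
#' @param grid Optional explicit starting grid (overrides
#'   `width`/`height`/`density`).
#' @param stable_window Number of unchanged steps that define stability.
#' @return List with `trace` (a `sim_trace` with columns `tick`, `alive`)
#'   and `event` (a one-row shift-event tibble).
#' @examples
#' gol_run(20, 20, density = 0.35, seed = 1)$event
#' @export
gol_run <- function(width, height, density = 0.35,
                    neighborhood = c("moore8", "vonneumann4"),
                    max_ticks = 5000, seed = NULL, grid = NULL,
                    stable_window = 100L) {
  neighborhood <- match.arg(neighborhood)
  if (is.null(grid)) grid <- gol_seed(width, height, density, seed)
  else grid <- matrix(as.integer(grid != 0), nrow(grid), ncol(grid))
  res <- gol_run_cpp(grid, if (neighborhood == "moore8") 8L else 4L,
                     as.integer(max_ticks), as.integer(stable_window))
  params <- list(width = ncol(grid), height = nrow(grid),
                 density = density, neighborhood = neighborhood,
                 max_ticks = max_ticks, stable_window = stable_window,
                 area = length(grid))
  trace <- new_sim_trace(
    tibble::tibble(tick = seq_along(res$counts) - 1L, alive = res$counts),
    model = "gol", params = params, seed = seed)
  list(trace = trace,
       event = gol_event_from_counts(res$counts, stable_window),
       grid = res$grid)
}

#' Run a modular cellular-automaton system of constant total area
#'
#' Divides a fixed 100 x 100 grid into `100 / module_height` independent
#' `module_height` x 100 sub-grids with derived seeds and sums their
#' alive-cell counts tick-wise; sub-grids that stop early are held at
#' their final (stable) count. The shift duration is the first tick the
#' summed count is unchanged for 100 steps.
#'
#' @param module_height One of 2, 5, 10, 20, 50, 100.
#' @param density Initial alive density.
#' @param seed Master seed; per-module seeds are derived from it.
#' @param neighborhood,max_ticks,stable_window As in [gol_run()].
#' @return List with `trace` (summed `sim_trace`) and `event`.
#' @export
gol_run_modular <- function(module_height, density = 0.35, seed = NULL,
                            neighborhood = c("moore8", "vonneumann4"),
                            max_ticks = 5000, stable_window = 100L) {
  neighborhood <- match.arg(neighborhood)
  if (!module_height %in% c(2, 5, 10, 20, 50, 100) ||
      100 %% module_height != 0)
    stop("`module_height` must divide 100 (one of 2, 5, 10, 20, 50, 100)",
         call. = FALSE)
  n_mod <- 100L %/% as.integer(module_height)
  counts <- lapply(seq_len(n_mod), function(i) {
    g <- gol_seed(100L, as.integer(module_height), density,
                  seed = derive_seed(seed %||% 0, "gol_module",
                                     module_height, i))
    gol_run_cpp(g, if (neighborhood == "moore8") 8L else 4L,
                as.integer(max_ticks), as.integer(stable_window))$counts
  })
  len <- max(lengths(counts))
  pad <- function(v) c(v, rep(v[length(v)], len - length(v)))
  total <- Reduce(`+`, lapply(counts, pad))
  params <- list(width = 100L, height = 100L, density = density,
                 neighborhood = neighborhood, module_height = module_height,
                 n_modules = n_mod, max_ticks = max_ticks,
                 stable_window = stable_window, area = 10000L)
  trace <- new_sim_trace(
    tibble::tibble(tick = seq_len(len) - 1L, alive = total),
    model = "gol_modular", params = params, seed = seed)
  list(trace = trace, event = gol_event_from_counts(total, stable_window))
}
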