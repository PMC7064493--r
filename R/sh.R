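#' Parameters for the two-compartment algae-zooplankton model
#'
#' A deterministic predator-prey ODE system in which zooplankton graze
#' algae in one compartment (A1) while the algae of a second compartment
#' (A2) are predation free; a fraction `d` of volume is exchanged between
#' the compartments per unit time. Algae grow logistically towards the
#' carrying capacity `K` (the model's proxy for system size); grazing
#' saturates with a Monod/Holling type-II term. The single regime shift
#' this model undergoes is the extirpation of zooplankton.
#'
#' @param r Algal growth rate per unit time.
#' @param K Algal carrying capacity (> 0), the model's system-size proxy.
#'   The default places the reference system inside the extirpation
#'   regime (below the zooplankton subsistence threshold
#'   `h * m / (e * g - m)`), so that fluidity experiments at fixed size
#'   produce shift durations.
#' @param g Maximum grazing rate.
#' @param h Half-saturation algal level of the grazing response.
#' @param e Assimilation efficiency in (0, 1].
#' @param m Zooplankton mortality per unit time.
#' @param d Exchanged volume fraction per unit time, in [0, 1].
#' @param dt Integration step (RK4); must divide 1 evenly.
#' @param t_max Horizon in unit time steps.
#' @param z_eps Extinction threshold below which zooplankton are set to 0
#'   (a continuous flow never reaches exactly zero).
#' @return A validated `sh_params` list.
#' @export
sh_params <- function(r = 0.5, K = 10, g = 0.4, h = 10, e = 0.6, m = 0.15,
                      d = 0.05, dt = 0.01, t_max = 10000, z_eps = 1e-6) {
  check_scalar(r, "r", lo = 0)
  check_scalar(K, "K")
  if (K <= 0) stop("`K` must be > 0", call. = FALSE)
  check_scalar(g, "g", lo = 0)
  check_scalar(h, "h", lo = 0)
  check_scalar(e, "e", lo = 0, hi = 1)
  check_scalar(m, "m", lo = 0)
  check_scalar(d, "d", lo = 0, hi = 1)
  check_scalar(dt, "dt")
  if (dt <= 0 || abs(1 / dt - round(1 / dt)) > 1e-8)
    stop("`dt` must be positive and divide 1 evenly", call. = FALSE)
  check_scalar(t_max, "t_max", lo = 1, integer = TRUE)
  check_scalar(z_eps, "z_eps", lo = 0)
  structure(list(r = r, K = K, g = g, h = h, e = e, m = m, d = d, dt = dt,
                 t_max = as.integer(t_max), z_eps = z_eps),
            class = "sh_params")
}

#' Instantaneous rates of the algae-zooplankton model
#'
#' \deqn{dA_1/dt = r A_1 (1 - A_1/K) - g Z A_1/(A_1+h) + d (A_2 - A_1)}
#' \deqn{dA_2/dt = r A_2 (1 - A_2/K) + d (A_1 - A_2)}
#' \deqn{dZ/dt = e g Z A_1/(A_1+h) - m Z}
#'
#' @param state Named numeric vector or list with `A1`, `A2`, `Z` (>= 0).
#' @param p An [sh_params()] object.
#' @return Named numeric vector `c(dA1, dA2, dZ)`.
#' @export
sh_rates <- function(state, p) {
  stopifnot(inherits(p, "sh_params"))
  A1 <- state[["A1"]]; A2 <- state[["A2"]]; Z <- state[["Z"]]
  graze <- p$g * Z * A1 / (A1 + p$h)
  c(dA1 = p$r * A1 * (1 - A1 / p$K) - graze + p$d * (A2 - A1),
    dA2 = p$r * A2 * (1 - A2 / p$K) + p$d * (A1 - A2),
    dZ = p$e * graze - p$m * Z)
}

#' Default initial state: algae at capacity, a small zooplankton inoculum
#'
#' @param p An [sh_params()] object.
#' @param Z0 Initial zooplankton concentration.
#' @return Named state vector.
#' @export
sh_init <- function(p, Z0 = 1) {
  stopifnot(inherits(p, "sh_params"))
  c(A1 = p$K, A2 = p$K, Z = Z0)
}

#' Run the algae-zooplankton model
#'
#' Deterministic fixed-step RK4 integration, recorded once per unit time
#' step. Zooplankton are clamped to zero once they fall below `z_eps`
#' (extinction is absorbing); the shift duration is the first recorded
#' step at which the zooplankton concentration equals zero, with the run
#' reported as `no_shift` if the horizon is reached with zooplankton still
#' present.
#'
#' @param p An [sh_params()] object.
#' @param init Initial state (named vector with `A1`, `A2`, `Z`); defaults
#'   to [sh_init()].
#' @param stop_at_extinction Stop recording once zooplankton reach zero
#'   (the remaining dynamics are plain logistic relaxation).
#' @return List with `trace` (a `sim_trace` with columns `tick`, `A1`,
#'   `A2`, `Z`) and `event` (one-row shift-event tibble).
#' @examples
#' out <- sh_run(sh_params(K = 10, t_max = 500))
#' out$event
#' @export
sh_run <- function(p, init = sh_init(p), stop_at_extinction = TRUE) {
  stopifnot(inherits(p, "sh_params"))
  stopifnot(all(c("A1", "A2", "Z") %in% names(init)),
            all(is.finite(unlist(init[c("A1", "A2", "Z")]))),
            all(unlist(init[c("A1", "A2", "Z")]) >= 0))
  mat <- sh_run_cpp(init[["A1"]], init[["A2"]], init[["Z"]], unclass(p),
                    stop_at_extinction)
  trace <- new_sim_trace(
    tibble::tibble(tick = mat[, "tick"], A1 = mat[, "A1"],
                   A2 = mat[, "A2"], Z = mat[, "Z"]),
    model = "sh", params = c(unclass(p), list(init = as.list(init))))
  list(trace = trace, event = duration_unstable_start(trace, "z_zero"))
}
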