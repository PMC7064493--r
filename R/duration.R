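#' Two-segment breakpoint search on a time series
#'
#' Regime departure in a stable-start simulation is located by fitting a
#' two-segment piecewise-constant-mean model: every admissible split of the
#' series into a pre-shift and a post-shift segment is scored by the pooled
#' residual sum of squares, and the split minimising it is returned. This
#' assumes a priori that the series consists of exactly two statistically
#' distinct segments (the pre-collapse regime and the collapsed regime).
#'
#' @param series Numeric vector (ordered in time).
#' @param min_seg_frac Minimum fraction of the series each segment must
#'   contain; both segments must hold at least
#'   `ceil(min_seg_frac * length(series))` points.
#' @return List with `index` (the last position of the first segment;
#'   earliest split on ties) and `rss` (pooled residual sum of squares).
#' @examples
#' find_breakpoint(c(0, 0, 0, 10, 10, 10), min_seg_frac = 1 / 3)
#' @export
find_breakpoint <- function(series, min_seg_frac = 0.15) {
  x <- as.numeric(series)
  n <- length(x)
  check_scalar(min_seg_frac, "min_seg_frac", lo = 0, hi = 0.5)
  m <- max(1L, as.integer(ceiling(min_seg_frac * n)))
  if (n < 2L * m || n < 2L)
    stop(sprintf("series of length %d too short for min_seg_frac %.3g",
                 n, min_seg_frac), call. = FALSE)
  s <- cumsum(x)
  q <- cumsum(x^2)
  ks <- m:(n - m)
  rss1 <- q[ks] - s[ks]^2 / ks
  rss2 <- (q[n] - q[ks]) - (s[n] - s[ks])^2 / (n - ks)
  total <- pmax(rss1, 0) + pmax(rss2, 0)  # guard tiny negative round-off
  best <- which.min(total)                # which.min takes the earliest tie
  list(index = ks[best], rss = total[best])
}

new_shift_event <- function(channel, start_tick, end_tick, status,
                            flagged = FALSE) {
  shifted <- status == "shifted"
  tibble::tibble(
    channel = channel,
    start_tick = ifelse(shifted, start_tick, NA_real_),
    end_tick = ifelse(shifted, end_tick, NA_real_),
    duration = ifelse(shifted, end_tick - start_tick, NA_real_),
    status = status,
    flagged = flagged)
}

#' Extract the three wolf-sheep regime shifts from a trace
#'
#' The wolf-sheep-grass system starts stable, so the start of each shift is
#' located by [find_breakpoint()] on that channel's series. The end of the
#' wolf and sheep shifts is the first tick their abundance reaches zero;
#' the grass shift ends when grass completely covers the system. Channels
#' whose end condition is never met, or that already start in the collapsed
#' state, are reported as `no_shift`.
#'
#' @param trace A `sim_trace` from [wsp_run()] or [wsp_run_modular()] with
#'   columns `tick`, `wolves`, `sheep`, `grass`.
#' @param area Total cell count of the system (full grass coverage). Taken
#'   from the trace's parameters when omitted.
#' @param min_seg_frac Passed to [find_breakpoint()].
#' @return Tibble of shift events, one row per channel, with columns
#'   `channel`, `start_tick`, `end_tick`, `duration`, `status`, `flagged`
#'   (`TRUE` when the breakpoint fell after the end tick and the start was
#'   clamped).
#' @export
detect_wsp_shifts <- function(trace, area = NULL, min_seg_frac = 0.15) {
  stopifnot(all(c("tick", "wolves", "sheep", "grass") %in% names(trace)))
  p <- attr(trace, "params")
  area <- area %||% (p$area %||% (p$world_width * p$world_height))
  if (is.null(area)) stop("`area` not supplied and not in trace params",
                          call. = FALSE)
  target <- c(wolves = 0, sheep = 0, grass = area)
  rows <- lapply(names(target), function(ch) {
    x <- trace[[ch]]
    hit <- which(x == target[[ch]])
    if (x[1] == target[[ch]] || length(hit) == 0)
      return(new_shift_event(ch, NA, NA, "no_shift"))
    end_tick <- trace$tick[hit[1]]
    bp <- find_breakpoint(x, min_seg_frac)
    start_tick <- trace$tick[bp$index + 1L]  # first point of second segment
    flagged <- FALSE
    if (start_tick > end_tick) {             # pathological short collapse
      start_tick <- end_tick
      flagged <- TRUE
    }
    new_shift_event(ch, start_tick, end_tick, "shifted", flagged)
  })
  dplyr::bind_rows(rows)
}

#' Shift duration for models that start in an unstable state
#'
#' The cellular automaton, the language-adoption network and the
#' algae-zooplankton model begin their runs already out of equilibrium, so
#' the start of the regime shift coincides with the first time step and the
#' duration equals the tick at which the end rule first holds:
#' `all_same_language` (every node speaks the dominant language),
#' `count_stable_100` (the alive-cell count unchanged for 100 consecutive
#' steps; the end is the first tick of the unchanged window), or `z_zero`
#' (zooplankton concentration reaches zero).
#'
#' @param trace A `sim_trace`.
#' @param end_rule One of `"all_same_language"`, `"count_stable_100"`,
#'   `"z_zero"`.
#' @param channel Column to inspect; defaults to `l1_count`, `alive` or `Z`
#'   according to the rule.
#' @param n_nodes Node count for `all_same_language`; taken from the trace
#'   parameters when omitted.
#' @return One-row shift-event tibble (see [detect_wsp_shifts()]).
#' @export
duration_unstable_start <- function(trace,
                                    end_rule = c("all_same_language",
                                                 "count_stable_100",
                                                 "z_zero"),
                                    channel = NULL, n_nodes = NULL) {
  end_rule <- match.arg(end_rule)
  p <- attr(trace, "params")
  channel <- channel %||% switch(end_rule,
                                 all_same_language = "l1_count",
                                 count_stable_100 = "alive",
                                 z_zero = "Z")
  x <- trace[[channel]]
  if (is.null(x)) stop("trace has no channel '", channel, "'", call. = FALSE)
  end_tick <- switch(end_rule,
    all_same_language = {
      n <- n_nodes %||% p$n_nodes
      if (is.null(n)) stop("`n_nodes` required for all_same_language",
                           call. = FALSE)
      hit <- which(x == n)
      if (length(hit)) trace$tick[hit[1]] else NA
    },
    count_stable_100 = stable_window_start(x, trace$tick, 100L),
    z_zero = {
      hit <- which(x == 0)
      if (length(hit)) trace$tick[hit[1]] else NA
    })
  if (is.na(end_tick)) return(new_shift_event(channel, NA, NA, "no_shift"))
  new_shift_event(channel, 0, end_tick, "shifted")
}

# first tick from which `x` stays unchanged for `window` consecutive steps
# (window + 1 equal values); NA if no such window exists
stable_window_start <- function(x, ticks, window) {
  n <- length(x)
  if (n < window + 1L) return(NA)
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  ok <- which(r$lengths >= window + 1L)
  if (length(ok) == 0) return(NA)
  ticks[starts[ok[1]]]
}

#' Keep only the runs that underwent a shift
#'
#' Runs that never reached the collapsed state within the horizon carry no
#' duration and are omitted from scaling analyses.
#'
#' @param events Shift-event tibble.
#' @return The subset with `status == "shifted"`, original order preserved.
#' @export
filter_shifted <- function(events) {
  events[events$status == "shifted", , drop = FALSE]
}

#' Write shift events as CSV or JSON
#'
#' The format follows the file extension: `.json` writes an array of
#' event objects, anything else a CSV table.
#'
#' @param events Shift-event tibble (optionally with a `run_id` column).
#' @param path Output path.
#' @export
write_events <- function(events, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(events, path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    readr::write_csv(events, path)
  }
  invisible(path)
}
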