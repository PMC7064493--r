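#' Derive a reproducible per-run seed from a master seed
#'
#' Experiments run many simulator instances; each needs its own RNG stream
#' that is stable regardless of which subset of runs is executed. The
#' per-run seed is a deterministic hash of the master seed together with an
#' arbitrary set of labels (experiment id, parameter value, repeat index).
#'
#' @param master Integer master seed.
#' @param ... Further atomic values identifying the run; coerced to
#'   character and folded into the hash.
#' @return A single integer in `[1, 2^31 - 2]`, usable with [set.seed()].
#' @examples
#' derive_seed(1, "2.1", 40, 3)
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- paste(c(format(master), vapply(list(...), function(x)
    paste(format(x), collapse = ","), character(1))), collapse = "|")
  # 31-adic rolling hash, exact in double precision below 2^53
  h <- 0
  for (code in utf8ToInt(key)) h <- (h * 31 + code) %% 2147483647
  as.integer(h %% 2147483645L + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# shared check helper: scalar in closed range
check_scalar <- function(x, name, lo = -Inf, hi = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (x < lo || x > hi)
    stop(sprintf("`%s` must be in [%s, %s], got %s", name, lo, hi, x),
         call. = FALSE)
  if (integer && x != round(x))
    stop(sprintf("`%s` must be a whole number, got %s", name, x),
         call. = FALSE)
  invisible(x)
}

new_sim_trace <- function(df, model, params, seed = NULL) {
  out <- tibble::as_tibble(df)
  attr(out, "model") <- model
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  class(out) <- c("sim_trace", class(out))
  out
}

#' @export
print.sim_trace <- function(x, ...) {
  cat(sprintf("<sim_trace: %s, %d ticks>\n", attr(x, "model"),
              nrow(x) - 1L))
  NextMethod()
}

#' Write / read a simulator trace as CSV with a JSON parameter sidecar
#'
#' The trace itself is plain CSV (one row per tick); the simulator
#' parameters and seed are stored next to it in `<path>.json` so a run can
#' be identified later.
#'
#' @param trace A `sim_trace` as returned by the `*_run()` functions.
#' @param path Output CSV path.
#' @return `write_trace()` returns `path` invisibly; `read_trace()` returns
#'   the `sim_trace`.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(tibble::as_tibble(trace), path)
  side <- list(model = attr(trace, "model"),
               params = attr(trace, "params"),
               seed = attr(trace, "seed"))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path)) jsonlite::read_json(side_path) else
    list(model = NA_character_, params = NULL, seed = NULL)
  new_sim_trace(df, model = side$model %||% NA_character_,
                params = side$params, seed = side$seed)
}
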