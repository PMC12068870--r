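# Interval and RNG helpers shared across modules. All analysis windows are
# half-open [a, b): an event overlaps a window iff the intersection has
# positive length, or the event is zero-duration and its timestamp lies in
# the window.

overlap_length <- function(start, end, w_start, w_end) {
  pmax(0, pmin(end, w_end) - pmax(start, w_start))
}

event_overlaps <- function(start, end, w_start, w_end) {
  ifelse(end > start,
         overlap_length(start, end, w_start, w_end) > 0,
         start >= w_start & start < w_end)
}

check_window <- function(window, what = "window") {
  if (!is.numeric(window) || length(window) != 2L || any(!is.finite(window)))
    stop(what, " must be a finite numeric vector c(start, end)", call. = FALSE)
  if (window[2] <= window[1])
    stop(what, " must have end > start", call. = FALSE)
  invisible(window)
}

norm_behavior <- function(x) tolower(trimws(x))

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded to `seed`,
#' restoring the previous RNG state afterwards, so seeded generators do not
#' perturb the caller's random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# One independent substream seed per unit (trial/cell/replicate), drawn as a
# prefix-stable sequence: extending n never changes the first seeds already
# handed out, so adding trials to a cohort leaves earlier trials untouched.
substream_seeds <- function(seed, n) {
  stopifnot(n >= 0)
  if (n == 0L) return(integer(0))
  with_seed(seed, vapply(seq_len(n), function(i) sample.int(.Machine$integer.max - 1L, 1L),
                         integer(1)))
}

fmt_num <- function(x) formatC(x, digits = 9, format = "g")
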