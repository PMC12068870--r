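# Stretch dose-response recruitment: per-cell thresholds, cumulative
# responder fractions, and newly recruited fractions across increasing
# stretch magnitudes.

#' Stretch response series
#'
#' Per-cell boolean responses across an increasing series of stretch
#' magnitudes (percent radial stretch, e.g. 0.5, 1, 2.5, 5).
#'
#' @param magnitudes Strictly increasing numeric vector of stretch
#'   magnitudes.
#' @param responses Logical matrix, cells x magnitudes.
#' @return Object of class `stretch_series`.
#' @export
stretch_series <- function(magnitudes, responses) {
  magnitudes <- as.numeric(magnitudes)
  if (any(diff(magnitudes) <= 0))
    stop("magnitudes must be strictly increasing", call. = FALSE)
  responses <- as.matrix(responses)
  if (ncol(responses) != length(magnitudes))
    stop("responses must have one column per magnitude", call. = FALSE)
  mode(responses) <- "logical"
  colnames(responses) <- as.character(magnitudes)
  structure(list(magnitudes = magnitudes, responses = responses),
            class = "stretch_series")
}

#' @export
print.stretch_series <- function(x, ...) {
  cat(sprintf("<stretch_series> %d cells x magnitudes {%s}%%\n",
              nrow(x$responses), paste(x$magnitudes, collapse = ", ")))
  invisible(x)
}

#' Dose-response recruitment curve and per-cell thresholds
#'
#' Each cell's stretch threshold is the smallest magnitude at which it
#' responds (absent if it never responds). The cumulative fraction at
#' magnitude m is the fraction of cells with threshold <= m; the newly
#' recruited fraction at m is the increment over the previous magnitude.
#' The overall responsive fraction is the cumulative fraction at the
#' largest magnitude.
#'
#' @param series A [stretch_series()].
#' @return List of class `recruitment_curve`: `magnitudes`, `cumulative`,
#'   `newly_recruited`, `thresholds` (responding cells only),
#'   `overall_fraction`, `n_cells`.
#' @export
recruitment_curve <- function(series) {
  stopifnot(inherits(series, "stretch_series"))
  resp <- series$responses
  n <- nrow(resp)
  if (n < 1L) stop("need at least one cell", call. = FALSE)
  thr <- apply(resp, 1L, function(row) {
    k <- which(row)[1]
    if (is.na(k)) NA_real_ else series$magnitudes[k]
  })
  cum <- vapply(series$magnitudes,
                function(m) sum(!is.na(thr) & thr <= m) / n, numeric(1))
  newly <- diff(c(0, cum))
  structure(list(magnitudes = series$magnitudes, cumulative = cum,
                 newly_recruited = newly,
                 thresholds = thr[!is.na(thr)],
                 overall_fraction = cum[length(cum)], n_cells = n),
            class = "recruitment_curve")
}

#' @export
print.recruitment_curve <- function(x, ...) {
  cat(sprintf("<recruitment_curve> n = %d cells, overall responsive %.1f%%\n",
              x$n_cells, 100 * x$overall_fraction))
  print(data.frame(magnitude = x$magnitudes, cumulative = x$cumulative,
                   newly_recruited = x$newly_recruited))
  invisible(x)
}

#' Relative reduction of a responsive fraction under treatment
#'
#' Given responsive fractions of a control and a treated population (or
#' their non-responder complements), the fractional loss of responsiveness
#' `(f_control - f_treated) / f_control`, reported as a percentage. Used
#' to express how pharmacological store depletion or channel block shrinks
#' the stretch-sensitive population.
#'
#' @param control,treated Responsive fractions in \\[0, 1\\].
#' @param nonresponder Set TRUE when the inputs are non-responder
#'   fractions; they are complemented first.
#' @return Percent relative reduction.
#' @export
relative_reduction <- function(control, treated, nonresponder = FALSE) {
  if (nonresponder) { control <- 1 - control; treated <- 1 - treated }
  if (control <= 0) stop("control responsive fraction must be > 0", call. = FALSE)
  100 * (control - treated) / control
}
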