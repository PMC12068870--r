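# Two-stimulus sensitization statistics: potentiation index, enhancement
# recovery curves, and the RNAi-screen z-score hit-calling procedure.

#' Potentiation statistics from responder counts
#'
#' Given responder counts to two successive stimuli, computes the roll
#' probabilities `P1 = rollers1/n1`, `P2 = rollers2/n2`, the nociceptive
#' potentiation index `(P2 - P1) / P1` and the enhancement `P2 - P1`. The
#' index is undefined (NA, flagged) when `P1 == 0`; when defined it is
#' always `>= -1`.
#'
#' @param rollers1,n1 Responders and trials for stimulus 1 (`n1 > 0`).
#' @param rollers2,n2 Responders and trials for stimulus 2 (`n2 > 0`).
#' @return Object of class `potentiation` with fields `P1`, `P2`, `n1`,
#'   `n2`, `index`, `enhancement`, `defined`.
#' @export
potentiation_from_counts <- function(rollers1, n1, rollers2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("n must be > 0", call. = FALSE)
  if (rollers1 < 0 || rollers2 < 0 || rollers1 > n1 || rollers2 > n2)
    stop("responder counts must lie in [0, n]", call. = FALSE)
  P1 <- rollers1 / n1
  P2 <- rollers2 / n2
  defined <- P1 > 0
  structure(list(P1 = P1, P2 = P2, n1 = as.integer(n1), n2 = as.integer(n2),
                 index = if (defined) (P2 - P1) / P1 else NA_real_,
                 enhancement = P2 - P1, defined = defined),
            class = "potentiation")
}

#' @export
print.potentiation <- function(x, ...) {
  cat(sprintf("<potentiation> P1 = %.3f (n=%d), P2 = %.3f (n=%d)\n",
              x$P1, x$n1, x$P2, x$n2))
  cat(sprintf("  enhancement (P2 - P1): %.3f\n", x$enhancement))
  if (x$defined) cat(sprintf("  potentiation index:    %.3f\n", x$index))
  else cat("  potentiation index:    undefined (P1 = 0)\n")
  invisible(x)
}

#' Potentiation statistics from a paired two-stimulus trial table
#'
#' @param trials data.frame with logical `responded1`, `responded2` (see
#'   [read_two_stim_table()]); the paired design implies `n1 == n2`.
#' @param strict If TRUE (default), mixed genotypes in `trials` are an
#'   error; group the table first.
#' @return A `potentiation` object (see [potentiation_from_counts()]).
#' @export
potentiation_from_trials <- function(trials, strict = TRUE) {
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  if (strict && "genotype" %in% names(trials) &&
      length(unique(trials$genotype)) > 1L)
    stop("trials span multiple genotypes; group before computing potentiation",
         call. = FALSE)
  potentiation_from_counts(sum(trials$responded1), nrow(trials),
                           sum(trials$responded2), nrow(trials))
}

#' Enhancement recovery curve over inter-stimulus intervals
#'
#' Groups two-stimulus trials by recovery interval and computes, per
#' interval, the enhancement `P2 - P1`. By default `P1` is computed within
#' each interval group; `pooled_p1 = TRUE` uses a single first-stimulus
#' probability pooled across all trials (one experiment family sharing a
#' baseline).
#'
#' @param trials Two-stimulus trial data.frame (logical `responded1`,
#'   `responded2`, numeric `interval`).
#' @param pooled_p1 Pool `P1` across intervals (default FALSE).
#' @return data.frame with one row per interval: `interval`, `P1`, `P2`,
#'   `enhancement`, `n`, sorted by interval.
#' @export
recovery_curve <- function(trials, pooled_p1 = FALSE) {
  if (!nrow(trials)) stop("empty trial table", call. = FALSE)
  p1_pooled <- mean(trials$responded1)
  groups <- split(trials, trials$interval)
  rows <- lapply(groups, function(g) {
    if (!nrow(g)) return(NULL)
    P1 <- if (pooled_p1) p1_pooled else mean(g$responded1)
    P2 <- mean(g$responded2)
    data.frame(interval = g$interval[1], P1 = P1, P2 = P2,
               enhancement = P2 - P1, n = nrow(g))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$interval), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen z-scores and hit calls from potentiation indices
#'
#' Standardizes per-genotype potentiation indices and flags hits with
#' `|z| > 2` (strict inequality). By default the mean and SD (population
#' convention, divisor n) are computed across all defined indices in the
#' input; alternatively a vector of control/reference indices can supply
#' the standardization. Genotypes with undefined indices (first-stimulus
#' probability 0) get `z = NA` and are never hits.
#'
#' @param rows data.frame with columns `genotype` and `index` (NA allowed
#'   for undefined indices).
#' @param reference Optional numeric vector of reference indices used for
#'   mean/SD instead of the full screen distribution.
#' @param z_cut Hit threshold on `|z|` (default 2).
#' @return data.frame `genotype`, `index`, `z`, `hit`.
#' @export
screen_zscores <- function(rows, reference = NULL, z_cut = 2) {
  stopifnot(is.data.frame(rows), all(c("genotype", "index") %in% names(rows)))
  idx <- rows$index
  base <- if (is.null(reference)) idx[!is.na(idx)] else reference[!is.na(reference)]
  if (length(base) < 3L)
    stop("need >= 3 defined indices to standardize", call. = FALSE)
  mu <- mean(base)
  sdev <- sqrt(mean((base - mu)^2))
  if (sdev == 0) stop("zero SD across indices; z-scores undefined", call. = FALSE)
  z <- (idx - mu) / sdev
  hit <- !is.na(z) & abs(z) > z_cut
  data.frame(genotype = rows$genotype, index = idx, z = z, hit = hit,
             stringsAsFactors = FALSE)
}

#' Screen table pipeline: counts to index, z and hit columns
#'
#' Takes a screen table with per-genotype responder counts to two
#' successive stimuli and appends the potentiation index, z-score and hit
#' flag.
#'
#' @param counts data.frame with columns `genotype`, `rollers1`, `n1`,
#'   `rollers2`, `n2`.
#' @inheritParams screen_zscores
#' @return data.frame with added `P1`, `P2`, `index`, `z`, `hit` columns.
#' @export
screen_from_counts <- function(counts, reference = NULL, z_cut = 2) {
  stopifnot(all(c("genotype", "rollers1", "n1", "rollers2", "n2") %in% names(counts)))
  pots <- lapply(seq_len(nrow(counts)), function(i)
    potentiation_from_counts(counts$rollers1[i], counts$n1[i],
                             counts$rollers2[i], counts$n2[i]))
  counts$P1 <- vapply(pots, `[[`, numeric(1), "P1")
  counts$P2 <- vapply(pots, `[[`, numeric(1), "P2")
  counts$index <- vapply(pots, `[[`, numeric(1), "index")
  zz <- screen_zscores(counts[, c("genotype", "index")],
                       reference = reference, z_cut = z_cut)
  counts$z <- zz$z
  counts$hit <- zz$hit
  counts
}
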