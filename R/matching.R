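#' Zero-lag spectral cross-correlation
#'
#' The call-eardrum matching statistic: both magnitude spectra are restricted
#' to their common frequency band, resampled onto the coarser of the two
#' grids by linear interpolation, mean-centered and scaled to unit variance;
#' the statistic is the zero-lag normalized product, i.e. the Pearson
#' correlation across frequency bins. Linear magnitudes are correlated by
#' default; `db = TRUE` correlates decibel spectra instead.
#'
#' @param a,b `power_spectrum` objects (or lists with `frequency`,
#'   `magnitude`, `resolution_hz`).
#' @param db Correlate dB magnitudes instead of linear (default FALSE).
#' @param db_floor Floor in dB below each spectrum's maximum used when
#'   `db = TRUE` (default -80).
#' @return Correlation in `[-1, 1]`.
#' @export
zero_lag_cross_correlation <- function(a, b, db = FALSE, db_floor = -80) {
  lo <- max(min(a$frequency), min(b$frequency))
  hi <- min(max(a$frequency), max(b$frequency))
  if (lo >= hi) stop("spectra have no overlapping frequency band", call. = FALSE)
  res <- max(a$resolution_hz, b$resolution_hz)
  grid <- seq(lo, hi, by = res)
  ya <- stats::approx(a$frequency, a$magnitude, xout = grid)$y
  yb <- stats::approx(b$frequency, b$magnitude, xout = grid)$y
  if (db) {
    ya <- 20 * log10(pmax(ya, max(ya) * 10^(db_floor / 20)))
    yb <- 20 * log10(pmax(yb, max(yb) * 10^(db_floor / 20)))
  }
  sa <- stats::sd(ya)
  sb <- stats::sd(yb)
  if (sa == 0 || sb == 0) {
    stop("zero-variance spectrum: correlation undefined", call. = FALSE)
  }
  mean((ya - mean(ya)) * (yb - mean(yb))) * length(ya) / (length(ya) - 1) /
    (sa * sb)
}

#' Mismatch between best frequency and call dominant frequency
#'
#' Absolute difference between the tympanic best frequency and the call's
#' dominant frequency, reported in kHz.
#'
#' @param best_frequency_hz Tympanic best frequency, Hz.
#' @param dominant_hz Call dominant frequency, Hz.
#' @return Distance in kHz.
#' @export
mismatch_distance <- function(best_frequency_hz, dominant_hz) {
  if (best_frequency_hz <= 0 || dominant_hz <= 0) {
    stop("frequencies must be positive", call. = FALSE)
  }
  abs(best_frequency_hz - dominant_hz) / 1000
}

#' Call-eardrum match table
#'
#' Cross-correlates each individual's tympanic response spectrum at each
#' sound level with the synthetic call spectrum of each population, labelling
#' rows as local (call from the individual's own population) or non-local.
#' Missing individual x SPL cells produce a warning and are omitted.
#'
#' @param tympanic_spectra Nested list: `tympanic_spectra[[individual]][[as
#'   character(spl)]]` is either a single `power_spectrum` (one tympanic
#'   sensitivity spectrum, correlated with both calls) or a named list with
#'   one response spectrum per call (`central`, `southern`), in which case
#'   each is correlated with the spectrum of the call that evoked it.
#' @param populations Named character vector mapping individual id to
#'   `"central"` or `"southern"`.
#' @param call_spectra Named list with `power_spectrum` entries `central` and
#'   `southern`.
#' @param spls Sound levels to tabulate (default `c(55, 60, 70, 80)`).
#' @param db Passed to [zero_lag_cross_correlation()].
#' @return A long-format data frame with columns `individual`, `population`,
#'   `spl`, `call`, `call_origin` (`local`/`nonlocal`) and `correlation`.
#' @export
match_table <- function(tympanic_spectra, populations, call_spectra,
                        spls = c(55, 60, 70, 80), db = FALSE) {
  stopifnot(all(c("central", "southern") %in% names(call_spectra)))
  rows <- list()
  for (id in names(tympanic_spectra)) {
    pop <- populations[[id]]
    for (spl in spls) {
      spec <- tympanic_spectra[[id]][[as.character(spl)]]
      if (is.null(spec)) {
        warning(sprintf("missing spectrum for %s at %g dB SPL; row omitted",
                        id, spl), call. = FALSE)
        next
      }
      per_call <- inherits(spec, "power_spectrum") == FALSE && is.list(spec)
      for (call_pop in c("central", "southern")) {
        tymp <- if (per_call) spec[[call_pop]] else spec
        if (is.null(tymp)) {
          warning(sprintf("missing %s-call response for %s at %g dB SPL",
                          call_pop, id, spl), call. = FALSE)
          next
        }
        rows[[length(rows) + 1]] <- data.frame(
          individual = id,
          population = pop,
          spl = spl,
          call = call_pop,
          call_origin = if (identical(call_pop, pop)) "local" else "nonlocal",
          correlation = zero_lag_cross_correlation(tymp,
                                                   call_spectra[[call_pop]],
                                                   db = db)
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
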