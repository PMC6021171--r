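#' Time-dependent background estimation
#'
#' Estimates per-channel, per-excitation-slot background rates on a
#' regular time grid by maximum-likelihood exponential fits to
#' inter-photon delays, excluding burst photons: within each window the
#' rate is first estimated from all delays, then delays shorter than
#' twice the current mean delay (burst photons) are discarded and the
#' rate re-estimated with the left-truncation correction
#' \eqn{1/\hat\lambda = \bar d_{>c} - c}; two iterations. Rates are
#' wall-clock rates of each photon stream (already including the ALEX
#' duty cycle). Windows with fewer than 20 usable delays inherit the
#' nearest neighbouring window's rate and are flagged.
#'
#' @param stream a \code{\linkS4class{PhotonStream}}
#' @param window estimation window (s)
#' @return object of class \code{BackgroundEstimate}: list with
#'   \code{breaks} (window starts, s), per-stream rate vectors
#'   (\code{DexDem}, \code{DexAem}, \code{AexAem}, \code{AexDem}, plus
#'   the derived \code{Dex} sum used by the dual-channel burst search)
#'   and a \code{flags} matrix.
#' @export
estimateBackground <- function(stream, window = 10) {
  stopifnot(is(stream, "PhotonStream"))
  if (nPhotons(stream) == 0) stop("empty photon stream")
  dur <- streamDuration(stream)
  if (window >= dur)
    window <- dur  # single window covering the stream
  t <- photonTimes(stream)
  ph <- photonData(stream)
  breaks <- seq(0, dur, by = window)
  if (breaks[length(breaks)] < dur) breaks <- c(breaks, dur)
  nwin <- length(breaks) - 1L
  keys <- c(DexDem = 1, DexAem = 2, AexAem = 3, AexDem = 4)
  sel <- list(ph$slot == 0 & ph$channel == 0,
              ph$slot == 0 & ph$channel == 1,
              ph$slot == 1 & ph$channel == 1,
              ph$slot == 1 & ph$channel == 0)
  rates <- matrix(NA_real_, nwin, 4,
                  dimnames = list(NULL, names(keys)))
  flags <- matrix(FALSE, nwin, 4, dimnames = list(NULL, names(keys)))
  for (k in 1:4) {
    ts <- t[sel[[k]]]
    wi <- findInterval(ts, breaks, rightmost.closed = TRUE)
    for (w in seq_len(nwin)) {
      d <- diff(ts[wi == w])
      d <- d[d > 0]
      if (length(d) < 20) { flags[w, k] <- TRUE; next }
      rate <- 1 / mean(d)
      for (it in 1:2) {
        thr <- 2 / rate
        dk <- d[d > thr]
        if (length(dk) < 20) break
        rate <- 1 / (mean(dk) - thr)
      }
      rates[w, k] <- rate
    }
    # carry over from nearest estimated neighbour
    if (anyNA(rates[, k]) && !all(is.na(rates[, k]))) {
      ok <- which(!is.na(rates[, k]))
      for (w in which(is.na(rates[, k])))
        rates[w, k] <- rates[ok[which.min(abs(ok - w))], k]
    }
    rates[is.na(rates[, k]), k] <- 0
  }
  structure(list(window = window, breaks = breaks,
                 rates = cbind(rates, Dex = rates[, 1] + rates[, 2]),
                 flags = flags),
            class = "BackgroundEstimate")
}

#' @export
print.BackgroundEstimate <- function(x, ...) {
  cat("BackgroundEstimate on", length(x$breaks) - 1L, "windows of",
      x$window, "s\n")
  cat("  mean rates (Hz):",
      paste(colnames(x$rates),
            format(colMeans(x$rates), digits = 3), collapse = ", "),
      "\n")
  invisible(x)
}

# rate of a named stream at times tt (piecewise constant)
bgRateAt <- function(bg, key, tt) {
  w <- pmin(pmax(findInterval(tt, bg$breaks, rightmost.closed = TRUE),
                 1L), nrow(bg$rates))
  bg$rates[w, key]
}
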