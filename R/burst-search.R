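#' Dual-channel burst search (DCBS) in sliding-window mode
#'
#' A burst is a maximal photon run in which the local rate over \code{m}
#' consecutive photons exceeds \code{F} times the local background rate
#' simultaneously in the donor-excitation stream (both detectors) and in
#' the acceptor-excitation acceptor stream. The rate criterion is
#' evaluated at every photon (sliding window); the two single-stream hot
#' regions are intersected, which suppresses donor-only and
#' acceptor-blinked artifacts. Burst records carry raw and
#' background-corrected counts split by channel x slot.
#'
#' @param stream a \code{\linkS4class{PhotonStream}}
#' @param background a \code{\link{estimateBackground}} result
#' @param m photons per sliding window (default 10)
#' @param F rate threshold as a multiple of the background rate
#'   (default 6)
#' @return a \code{\linkS4class{BurstSet}} keeping the stream and the
#'   per-burst photon index ranges (columns \code{i_first}/\code{i_last})
#'   for photon-level analyses
#' @export
searchBurstsDCBS <- function(stream, background, m = 10, F = 6) {
  stopifnot(is(stream, "PhotonStream"),
            inherits(background, "BackgroundEstimate"))
  if (m < 2) stop("parameter error: m must be >= 2")
  if (F <= 1) stop("parameter error: F must be > 1")
  ph <- photonData(stream)
  t <- photonTimes(stream)
  idx_dex <- which(ph$slot == 0)
  idx_aa <- which(ph$slot == 1 & ph$channel == 1)
  iv1 <- hotIntervals(t[idx_dex], m, F, background, "Dex")
  iv2 <- hotIntervals(t[idx_aa], m, F, background, "AexAem")
  iv <- intersectIntervals(iv1, iv2)
  if (!nrow(iv)) {
    return(new("BurstSet",
               bursts = data.frame(id = integer(), t_start = numeric(),
                                   t_stop = numeric(), n_DD = integer(),
                                   n_DA = integer(), n_AA = integer()),
               stream = stream, params = list(m = m, F = F)))
  }
  # assign photons: all photons whose time falls inside a burst interval
  lo <- findInterval(iv$start, t, left.open = TRUE) + 1L
  hi <- findInterval(iv$stop, t)
  ok <- hi >= lo
  iv <- iv[ok, , drop = FALSE]; lo <- lo[ok]; hi <- hi[ok]
  nb <- nrow(iv)
  cnt <- function(cond) {
    cs <- cumsum(cond)
    cs[hi] - c(0, cs)[lo]
  }
  n_dd <- cnt(ph$slot == 0 & ph$channel == 0)
  n_da <- cnt(ph$slot == 0 & ph$channel == 1)
  n_aa <- cnt(ph$slot == 1 & ph$channel == 1)
  dur <- iv$stop - iv$start
  mid <- (iv$start + iv$stop) / 2
  b <- data.frame(id = seq_len(nb), t_start = iv$start,
                  t_stop = iv$stop, i_first = lo, i_last = hi,
                  n_DD = n_dd, n_DA = n_da, n_AA = n_aa,
                  n_DD_corr = n_dd - bgRateAt(background, "DexDem", mid) * dur,
                  n_DA_corr = n_da - bgRateAt(background, "DexAem", mid) * dur,
                  n_AA_corr = n_aa - bgRateAt(background, "AexAem", mid) * dur)
  if ("particle" %in% names(ph)) {
    b$particle <- vapply(seq_len(nb), function(i) {
      p <- ph$particle[lo[i]:hi[i]]
      p <- p[p > 0]
      if (!length(p)) 0L else as.integer(names(which.max(table(p))))
    }, integer(1))
  }
  new("BurstSet", bursts = b, stream = stream,
      params = list(m = m, F = F, background = background))
}

# maximal hot intervals of one stream under the sliding m-photon
# criterion
hotIntervals <- function(ts, m, F, background, key) {
  if (length(ts) < m)
    return(data.frame(start = numeric(), stop = numeric()))
  nb <- length(background$breaks) - 1L
  hot <- cpp_sliding_hot(ts, as.integer(m), F,
                         background$breaks[seq_len(nb)],
                         background$rates[, key])
  r <- rle(as.logical(hot))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = ts[starts[keep]], stop = ts[ends[keep]])
}

intersectIntervals <- function(a, b) {
  if (!nrow(a) || !nrow(b))
    return(data.frame(start = numeric(), stop = numeric()))
  out_s <- numeric(); out_e <- numeric()
  i <- 1L; j <- 1L
  while (i <= nrow(a) && j <= nrow(b)) {
    s <- max(a$start[i], b$start[j])
    e <- min(a$stop[i], b$stop[j])
    if (s < e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
    if (a$stop[i] < b$stop[j]) i <- i + 1L else j <- j + 1L
  }
  data.frame(start = out_s, stop = out_e)
}
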