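#' Sub-burst partitioning for burst variance analysis
#'
#' Divides each burst's donor-excitation photon sequence into
#' contiguous, non-overlapping windows of exactly \code{n} photons
#' (trailing remainder discarded); bursts yielding fewer than 2 windows
#' are excluded. BVA deliberately works on raw photon partitions and the
#' proximity ratio: detected counts split binomially between the two
#' detectors with success probability PR, so the shot-noise reference of
#' the analysis holds for PR but would be biased for corrected E.
#' A time-based partitioner (fixed window duration, e.g. 0.1 ms for a
#' sub-millisecond probe) is available via \code{windowSeconds}.
#'
#' @param bursts a \code{\linkS4class{BurstSet}} retaining its photon
#'   stream
#' @param n photons per sub-burst (>= 2, default 5)
#' @param windowSeconds if non-NULL, partition by time windows of this
#'   duration instead of photon count; windows keep their own photon
#'   counts
#' @return data.frame, one row per sub-burst window: burst id, window
#'   acceptor count \code{F_A}, window photon count \code{n}, window
#'   proximity ratio \code{E_p}
#' @export
subdivideBursts <- function(bursts, n = 5, windowSeconds = NULL) {
  stopifnot(is(bursts, "BurstSet"))
  if (is.null(windowSeconds) && n < 2)
    stop("parameter error: n must be >= 2")
  b <- burstData(bursts)
  if (!all(c("i_first", "i_last") %in% names(b)))
    stop("photon-level structure required (run searchBurstsDCBS)")
  ph <- photonData(bursts@stream)
  out <- vector("list", nrow(b))
  for (i in seq_len(nrow(b))) {
    idx <- b$i_first[i]:b$i_last[i]
    dex <- idx[ph$slot[idx] == 0]
    acc <- ph$channel[dex] == 1
    if (is.null(windowSeconds)) {
      nw <- length(dex) %/% n
      if (nw < 2) next
      w <- rep(seq_len(nw), each = n)
      fa <- tapply(acc[seq_len(nw * n)], w, sum)
      nn <- rep(n, nw)
    } else {
      tw <- ph$tick[dex] / clockRate(bursts@stream)
      w <- floor((tw - tw[1]) / windowSeconds) + 1
      nn <- as.vector(table(w))
      if (length(nn) < 2) next
      fa <- tapply(acc, w, sum)
    }
    out[[i]] <- data.frame(id = b$id[i], window = seq_along(fa),
                           F_A = as.vector(fa), n = nn,
                           E_p = as.vector(fa) / nn)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(id = integer(), window = integer(),
                      F_A = integer(), n = integer(), E_p = numeric())
  rownames(res) <- NULL
  res
}

#' Per-burst empirical sub-burst standard deviation
#'
#' For each partitioned burst, the mean sub-burst proximity ratio
#' \eqn{E_p} and the standard deviation \eqn{s_E} of the window
#' proximity ratios (population denominator N, matching the Monte Carlo
#' reference distribution).
#'
#' @param partition output of \code{\link{subdivideBursts}}
#' @return data.frame (id, M = windows, E_p, s_E)
#' @export
burstSD <- function(partition) {
  stopifnot(all(c("id", "E_p") %in% names(partition)))
  sp <- split(partition$E_p, partition$id)
  data.frame(id = as.integer(names(sp)),
             M = lengths(sp),
             E_p = vapply(sp, mean, numeric(1)),
             s_E = vapply(sp, function(x)
               sqrt(mean((x - mean(x))^2)), numeric(1)),
             row.names = NULL)
}

#' Shot-noise-limited standard deviation of the sub-burst proximity
#' ratio
#'
#' Closed form \eqn{\sqrt{E_p (1 - E_p) / n}} for binomially partitioned
#' counts; the static expectation against which \eqn{s_E} is compared.
#'
#' @param Ep proximity ratio in [0, 1]
#' @param n photons per sub-burst
#' @return standard deviation(s)
#' @export
shotNoiseSD <- function(Ep, n) {
  if (any(Ep < 0 | Ep > 1))
    stop("parameter error: Ep must lie in [0, 1]")
  stopifnot(all(n >= 1))
  sqrt(Ep * (1 - Ep) / n)
}

#' Monte Carlo confidence thresholds for BVA
#'
#' For each proximity-ratio bin \eqn{[L, U)}, simulates the sampling
#' distribution of the pooled shot-noise standard deviation: for every
#' burst i in the bin, \eqn{M_i} window acceptor counts are drawn as
#' \eqn{F_{Aij} \sim Binomial(n, PR_i)} and the pooled statistic
#' \deqn{s = \sqrt{\sum_i \sum_j (F_{Aij}/n - \mu)^2 / \sum_i M_i}}
#' (with \eqn{\mu} the pooled mean of \eqn{F_{Aij}/n}) is recorded;
#' the threshold is the \eqn{(1-\alpha)} quantile over replicates.
#'
#' @param partition output of \code{\link{subdivideBursts}} (photon
#'   partitioner)
#' @param binEdges proximity-ratio bin edges over [0, 1]
#' @param alpha per-bin confidence level (default 0.001)
#' @param nRep Monte Carlo replicates (default 999)
#' @param seed integer seed
#' @return data.frame per occupied bin: L, U, nBursts, nWindows,
#'   pooled observed \code{s_obs}, Monte Carlo \code{threshold}
#' @export
mcConfidence <- function(partition, binEdges = seq(0, 1, by = 0.05),
                         alpha = 0.001, nRep = 999, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1)
  per <- burstSD(partition)
  if (!nrow(per)) stop("no partitioned bursts")
  nph <- partition$n[match(per$id, partition$id)]
  bin <- findInterval(per$E_p, binEdges, rightmost.closed = TRUE)
  withSeed(seed, {
    res <- lapply(sort(unique(bin)), function(bb) {
      ids <- per$id[bin == bb]
      pw <- partition[partition$id %in% ids, ]
      M <- nrow(pw)
      mu_obs <- mean(pw$E_p)
      s_obs <- sqrt(mean((pw$E_p - mu_obs)^2))
      nvec <- pw$n
      pr <- per$E_p[match(pw$id, per$id)]
      draws <- matrix(rbinom(nRep * M, rep(nvec, nRep),
                             rep(pr, nRep)) / rep(nvec, nRep),
                      nrow = M)
      mu <- colMeans(draws)
      s_mc <- sqrt(colMeans(sweep(draws, 2, mu)^2))
      data.frame(L = binEdges[bb], U = binEdges[bb + 1],
                 nBursts = length(ids), nWindows = M,
                 meanEp = mu_obs, s_obs = s_obs,
                 threshold = unname(quantile(s_mc, 1 - alpha)))
    })
    do.call(rbind, res)
  })
}

#' Burst variance analysis
#'
#' Full BVA: sub-burst partitioning, per-burst \eqn{s_E} against the
#' shot-noise curve, Monte Carlo per-bin thresholds, and a
#' static/dynamic verdict per proximity-ratio bin (dynamic iff the
#' pooled observed standard deviation exceeds the Monte Carlo
#' threshold).
#'
#' @param bursts a \code{\linkS4class{BurstSet}} retaining its photon
#'   stream
#' @param n photons per sub-burst
#' @param windowSeconds optional time-based partitioner (see
#'   \code{\link{subdivideBursts}})
#' @param binEdges proximity-ratio bin edges
#' @param alpha confidence level
#' @param nRep Monte Carlo replicates
#' @param seed integer seed
#' @return object of class \code{BVAResult}: per-burst table, per-bin
#'   table with verdicts, settings
#' @export
burstVarianceAnalysis <- function(bursts, n = 5, windowSeconds = NULL,
                                  binEdges = seq(0, 1, by = 0.05),
                                  alpha = 0.001, nRep = 999,
                                  seed = 1L) {
  part <- subdivideBursts(bursts, n = n, windowSeconds = windowSeconds)
  if (!nrow(part)) stop("no bursts with >= 2 sub-burst windows")
  per <- burstSD(part)
  bins <- mcConfidence(part, binEdges = binEdges, alpha = alpha,
                       nRep = nRep, seed = seed)
  bins$shotNoiseSD <- shotNoiseSD(bins$meanEp,
                                  if (is.null(windowSeconds)) n
                                  else mean(part$n))
  bins$dynamic <- bins$s_obs > bins$threshold
  structure(list(perBurst = per, bins = bins,
                 settings = list(n = n, windowSeconds = windowSeconds,
                                 alpha = alpha, nRep = nRep)),
            class = "BVAResult")
}

#' Per-bin verdict table for plotting
#'
#' @param bva a \code{\link{burstVarianceAnalysis}} result
#' @return data.frame (E_p bin, mean s_E, shot-noise SD, threshold,
#'   verdict), the table behind s_E-vs-E_p plots
#' @export
classifyDynamics <- function(bva) {
  stopifnot(inherits(bva, "BVAResult"))
  data.frame(E_p = (bva$bins$L + bva$bins$U) / 2,
             s_E = bva$bins$s_obs,
             shot_noise = bva$bins$shotNoiseSD,
             threshold = bva$bins$threshold,
             verdict = ifelse(bva$bins$dynamic, "dynamic", "static"))
}

#' @export
print.BVAResult <- function(x, ...) {
  cat("BVAResult:", nrow(x$perBurst), "bursts in", nrow(x$bins),
      "occupied bins;", sum(x$bins$dynamic), "dynamic\n")
  invisible(x)
}
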