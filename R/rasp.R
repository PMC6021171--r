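#' Burst-time autocorrelation and same-molecule probability
#'
#' The burst start times form a point process; bursts from distinct,
#' non-interacting molecules are uncorrelated while recurrences of the
#' same molecule cluster in time. \eqn{g(\tau)} is the burst-time
#' autocorrelation estimated by direct pair counting in bins, normalised
#' by the expectation for a Poisson process of the same mean burst rate,
#' and the same-molecule probability is
#' \eqn{P_{same}(\tau) = 1 - 1/g(\tau)} (clipped at 0).
#'
#' @param bursts a \code{\linkS4class{BurstSet}} (>= 2 bursts)
#' @param tauMax longest lag (s)
#' @param binWidth lag bin width (s), default 1 ms
#' @return object of class \code{SameMoleculeCurve}: data.frame-backed
#'   list with \code{tau} (bin midpoints), \code{g}, \code{p_same} and
#'   pair counts
#' @export
burstAutocorrelation <- function(bursts, tauMax = 0.1,
                                 binWidth = 1e-3) {
  stopifnot(is(bursts, "BurstSet"))
  tb <- sort(burstData(bursts)$t_start)
  n <- length(tb)
  if (n < 2) stop("need at least 2 bursts")
  Trec <- streamDuration(bursts@stream)
  if (Trec <= 0) Trec <- diff(range(tb))
  if (tauMax >= Trec) {
    warning("lag grid exceeds record length; truncated")
    tauMax <- Trec / 2
  }
  pr <- lagPairs(tb, tauMax)
  brk <- seq(0, tauMax, by = binWidth)
  cnt <- tabulate(findInterval(pr$lag, brk, rightmost.closed = TRUE),
                  nbins = length(brk) - 1L)
  expct <- n * (n - 1) / Trec * binWidth
  g <- cnt / expct
  structure(list(tau = brk[-length(brk)] + binWidth / 2, g = g,
                 p_same = pmax(0, 1 - 1 / pmax(g, 1e-12)),
                 pairs = cnt, rate = n / Trec),
            class = "SameMoleculeCurve")
}

#' @export
print.SameMoleculeCurve <- function(x, ...) {
  cat("SameMoleculeCurve over", length(x$tau), "lag bins up to",
      format(max(x$tau) * 1e3, digits = 3), "ms\n")
  cat("  P_same at first/last bin:",
      format(x$p_same[1], digits = 3), "/",
      format(x$p_same[length(x$p_same)], digits = 3), "\n")
  invisible(x)
}

#' Evaluate a same-molecule curve at given lags
#' @param curve a \code{SameMoleculeCurve}
#' @param tau lags (s)
#' @return interpolated \eqn{P_{same}} values
#' @export
pSameAt <- function(curve, tau) {
  if (length(curve$tau) == 1L) return(rep(curve$p_same, length(tau)))
  approx(curve$tau, curve$p_same, xout = tau, rule = 2)$y
}

# ordered pairs (i < j in time) with lag in (0, tauMax]
lagPairs <- function(tb, tauMax) {
  n <- length(tb)
  hi <- findInterval(tb + tauMax, tb)
  lo <- seq_len(n)
  cnt <- hi - lo
  i <- rep.int(lo, cnt)
  j <- sequence(cnt, from = lo + 1L)
  data.frame(i = i, j = j, lag = tb[j] - tb[i])
}

#' Select recurrence burst pairs
#'
#' Returns the set of ordered burst pairs \{b1, b2\} with the initial
#' burst's transfer efficiency inside \code{e1Range} and the lag between
#' detection times inside the recurrence interval
#' \code{T = (t1, t2]}. A burst may serve in several pairs. The same E
#' estimator (PR or corrected E, whatever \code{computeBurstES} stored
#' in column \code{E}) is used throughout one analysis.
#'
#' @param bursts a \code{\linkS4class{BurstSet}} with E computed
#' @param e1Range initial-E window, length-2 numeric
#' @param interval recurrence interval (t1, t2) in seconds, t1 < t2
#' @return object of class \code{RecurrenceSet}: data.frame (i1, i2,
#'   lag, E1, E2) plus the selection metadata
#' @export
selectRecurrencePairs <- function(bursts, e1Range, interval) {
  stopifnot(is(bursts, "BurstSet"), length(e1Range) == 2,
            length(interval) == 2)
  if (interval[1] >= interval[2] && !(interval[1] == 0 &&
                                      interval[2] == 0))
    stop("recurrence interval must have t1 < t2")
  b <- burstData(bursts)
  if (is.null(b$E)) stop("compute E first (computeBurstES)")
  ord <- order(b$t_start)
  b <- b[ord, , drop = FALSE]
  out <- if (interval[2] <= interval[1]) {
    data.frame(i1 = integer(), i2 = integer(), lag = numeric(),
               E1 = numeric(), E2 = numeric())
  } else {
    pr <- lagPairs(b$t_start, interval[2])
    keep <- pr$lag > interval[1] & !is.na(b$E[pr$i]) &
      b$E[pr$i] >= e1Range[1] & b$E[pr$i] <= e1Range[2] &
      !is.na(b$E[pr$j])
    data.frame(i1 = b$id[pr$i[keep]], i2 = b$id[pr$j[keep]],
               lag = pr$lag[keep], E1 = b$E[pr$i[keep]],
               E2 = b$E[pr$j[keep]])
  }
  structure(list(pairs = out, e1Range = e1Range, interval = interval),
            class = "RecurrenceSet")
}

#' @export
print.RecurrenceSet <- function(x, ...) {
  cat("RecurrenceSet:", nrow(x$pairs), "pairs, E1 in [",
      x$e1Range[1], ",", x$e1Range[2], "], T = (",
      x$interval[1] * 1e3, ",", x$interval[2] * 1e3, "] ms\n")
  invisible(x)
}

#' Recurrence transfer efficiency histogram
#'
#' Density-normalised histogram of the second-burst transfer
#' efficiencies of a recurrence set.
#'
#' @param rset a \code{\link{selectRecurrencePairs}} result
#' @param breaks histogram bin edges over [0, 1]
#' @return data.frame (mid, density, count)
#' @export
recurrenceHistogram <- function(rset, breaks = seq(0, 1, by = 0.02)) {
  stopifnot(inherits(rset, "RecurrenceSet"))
  e2 <- pmin(pmax(rset$pairs$E2, 0), 1)
  if (!length(e2)) warning("empty recurrence set")
  cnt <- tabulate(findInterval(e2, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  w <- diff(breaks)
  dens <- if (sum(cnt)) cnt / sum(cnt) / w else rep(0, length(cnt))
  data.frame(mid = breaks[-length(breaks)] + w / 2, density = dens,
             count = cnt)
}

#' 2D transition density over (E1, E2)
#'
#' Gaussian kernel density estimate over all burst pairs within a
#' recurrence interval: static mixtures concentrate on the diagonal,
#' within-interval interconversion produces off-diagonal cross-peaks.
#'
#' @param bursts a \code{\linkS4class{BurstSet}} with E computed
#' @param interval recurrence interval (t1, t2) in seconds
#' @param gridSize number of grid points per axis over [0, 1]
#' @param bandwidth kernel bandwidth (both axes); must be > 0
#' @return list (x, y, z) as from \code{MASS::kde2d}, plus the pair
#'   count
#' @export
transitionDensity2D <- function(bursts, interval, gridSize = 101,
                                bandwidth = 0.05) {
  if (bandwidth <= 0) stop("parameter error: bandwidth must be > 0")
  rset <- selectRecurrencePairs(bursts, c(0, 1), interval)
  p <- rset$pairs
  if (!nrow(p)) stop("no burst pairs in the recurrence interval")
  kd <- MASS::kde2d(pmin(pmax(p$E1, 0), 1), pmin(pmax(p$E2, 0), 1),
                    h = bandwidth * 4, n = gridSize,
                    lims = c(0, 1, 0, 1))
  kd$nPairs <- nrow(p)
  kd
}

# --- kinetic recurrence analysis ------------------------------------

# Global two-peak model across recurrence-interval histograms: Gaussian
# means and widths shared by every interval, only the per-interval
# weight free. Fitting all histograms jointly keeps the peak model
# identifiable even though individual interval histograms are sparse
# and the short-interval histograms are enriched in one state.
# The peak widths are tied equal and the separation bounded away from
# zero: with free widths one component degenerates into a broad
# envelope of the whole histogram and the weights lose their meaning as
# state occupancies.
globalTwoPeakFit <- function(countMat, breaks, e2all) {
  K <- nrow(countMat)
  n_k <- rowSums(countMat)
  use <- which(n_k > 0)
  y <- countMat[use, , drop = FALSE] / n_k[use]
  q <- quantile(e2all, c(0.15, 0.85))
  init <- c(m1 = unname(q[1]),
            lsep = log(max(unname(diff(q)), 0.08)),
            ls = log(0.06), z = rep(0, length(use)))
  obj <- function(p) {
    s <- exp(p[3])
    m1 <- p[1]; m2 <- m1 + 0.05 + exp(p[2])
    A <- gaussBinMass(breaks, m1, s)
    B <- gaussBinMass(breaks, m2, s)
    w <- plogis(p[-(1:3)])
    m <- outer(w, A) + outer(1 - w, B)
    sum(n_k[use] * rowSums((y - m)^2))
  }
  fit <- optim(init, obj, method = "L-BFGS-B",
               lower = c(0.02, log(0.01), log(0.015),
                         rep(-6, length(use))),
               upper = c(0.9, log(0.6), log(0.25),
                         rep(6, length(use))),
               control = list(maxit = 500))
  p <- fit$par
  w <- rep(NA_real_, K)
  w[use] <- plogis(p[-(1:3)])
  list(meanA = unname(p[1]), sdA = exp(p[3]),
       meanB = unname(p[1] + 0.05 + exp(p[2])), sdB = exp(p[3]),
       weights = w)
}

# fraction of a two-component Gaussian mixture attributable to
# component A, fitted to a histogram by least squares with the peak
# shapes fixed (only the weight free)
peakAreaFraction <- function(counts, breaks, peaks) {
  n <- sum(counts)
  if (n == 0) return(NA_real_)
  A <- gaussBinMass(breaks, peaks$meanA, peaks$sdA)
  B <- gaussBinMass(breaks, peaks$meanB, peaks$sdB)
  y <- counts / n
  den <- sum((A - B)^2)
  if (den == 0) return(NA_real_)
  min(max(sum((y - B) * (A - B)) / den, 0), 1)
}

ratePAmodel <- function(tau, lambda, rhoEq, rho0, eps) {
  rho <- rhoEq + (rho0 - rhoEq) * exp(-lambda * tau)
  if (eps == 1) return(rho)
  1 / (1 + eps * (1 / pmin(pmax(rho, 1e-9), 1) - 1))
}

#' Global two-state kinetic fit from recurrence histograms
#'
#' For each recurrence interval the recurrence E histogram is decomposed
#' into two Gaussian peaks (means and widths shared across all
#' intervals, only the weight free), giving the apparent state-A
#' fraction \eqn{p_A(\tau)}. These fractions are then fit globally by
#' \deqn{p_A(\tau) = P_{same}(\tau)\,p_A^{recur}(\tau) +
#'   (1-P_{same}(\tau))\,p_A^{new}}
#' with \eqn{p_A^{recur} = (1 + \epsilon(1/\rho_A - 1))^{-1}} and
#' \eqn{\rho_A(\tau) = \rho_A^{eq} +
#'   (\rho_A(0) - \rho_A^{eq})\,e^{-\lambda\tau}}; \eqn{\lambda} is the
#' sum of the opening and closing rate constants and \eqn{p_A^{new}}
#' (the state-A probability of a newly arriving molecule) is a single
#' constant shared across intervals — by default it is determined from
#' the globally fitted peak areas of the pooled (equilibrium) burst
#' histogram, since a newly arriving molecule is an equilibrium sample;
#' set \code{pNewFree = TRUE} to fit it instead. State A is the peak
#' nearer the
#' centre of the initial-E window. Time constants follow from
#' \eqn{\lambda} and \eqn{\rho_A^{eq}}: the rate out of A is
#' \eqn{\lambda(1-\rho_A^{eq})} and the rate into A is
#' \eqn{\lambda\rho_A^{eq}}. Uncertainties are percentile bootstrap over
#' bursts.
#'
#' @param bursts filtered \code{\linkS4class{BurstSet}} with E computed
#' @param e1Range initial-E window (on one of the two peaks)
#' @param intervals list of recurrence intervals (s); default 8
#'   logarithmic bins between 0.5 and 80 ms
#' @param pSame a \code{\link{burstAutocorrelation}} curve
#' @param peaks optional list (meanA, sdA, meanB, sdB); pre-fit from the
#'   pooled E histogram when \code{NULL}
#' @param eps brightness ratio \eqn{\epsilon} of state A to state B
#'   (default 1: equal brightness, in which case
#'   \eqn{p_A^{recur} \equiv \rho_A})
#' @param breaks E histogram bin edges
#' @param e1RangeB optional second initial-E window on the other
#'   state's peak; when supplied, the recurrence trajectories of both
#'   selections are fitted jointly with shared \eqn{\lambda} and
#'   \eqn{\rho_A^{eq}} (each selection keeps its own
#'   \eqn{\rho_A(0)}), which pins the relaxation rate from both
#'   directions
#' @param pNewFree fit \eqn{p_A^{new}} as a free parameter instead of
#'   computing it from the pooled burst histogram
#' @param nBoot bootstrap resamples (default 200)
#' @param seed seed for the bootstrap
#' @return object of class \code{KineticFit}: lambda (1/s), rhoEq,
#'   rho0, pNew, tauIntoA_s, tauOutOfA_s, per-interval table, bootstrap
#'   CIs, flags
#' @export
fitRecurrenceKinetics <- function(bursts, e1Range,
                                  intervals = logIntervals(5e-4, 0.08, 8),
                                  pSame, peaks = NULL, eps = 1,
                                  breaks = seq(0, 1, by = 0.02),
                                  e1RangeB = NULL, pNewFree = FALSE,
                                  nBoot = 200, seed = 1L) {
  stopifnot(is(bursts, "BurstSet"), length(intervals) >= 4)
  b <- burstData(bursts)
  if (is.null(b$E)) stop("compute E first (computeBurstES)")

  dur <- streamDuration(bursts@stream)
  histsOf <- function(bset, e1) {
    bd <- burstData(bset)
    rateAll <- nrow(bd) / max(dur, max(bd$t_start))
    nSel <- sum(!is.na(bd$E) & bd$E >= e1[1] & bd$E <= e1[2])
    res <- lapply(intervals, function(iv) {
      rs <- selectRecurrencePairs(bset, e1, iv)
      cnt <- tabulate(findInterval(pmin(pmax(rs$pairs$E2, 0), 1),
                                   breaks, rightmost.closed = TRUE),
                      nbins = length(breaks) - 1L)
      list(cnt = cnt,
           tau = if (nrow(rs$pairs)) mean(rs$pairs$lag) else mean(iv),
           eNew = nSel * rateAll * (iv[2] - iv[1]),
           e2 = rs$pairs$E2)
    })
    list(cnt = do.call(rbind, lapply(res, `[[`, "cnt")),
         tau = vapply(res, `[[`, numeric(1), "tau"),
         eNew = vapply(res, `[[`, numeric(1), "eNew"),
         e2 = unlist(lapply(res, `[[`, "e2")))
  }
  fullH <- histsOf(bursts, e1Range)
  fullHB <- if (!is.null(e1RangeB)) histsOf(bursts, e1RangeB)
  if (is.null(peaks)) {
    cntAll <- rbind(fullH$cnt, if (!is.null(fullHB)) fullHB$cnt)
    gp <- globalTwoPeakFit(cntAll, breaks,
                           c(fullH$e2, fullHB$e2))
    peaks <- gp[c("meanA", "sdA", "meanB", "sdB")]
  }
  # state A = peak nearer the initial-E window centre
  mid <- mean(e1Range)
  if (abs(peaks$meanB - mid) < abs(peaks$meanA - mid))
    peaks <- list(meanA = peaks$meanB, sdA = peaks$sdB,
                  meanB = peaks$meanA, sdB = peaks$sdA)

  pooledPA <- function(bb) {
    cnt <- tabulate(findInterval(pmin(pmax(bb$E[!is.na(bb$E)], 0), 1),
                                 breaks, rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    peakAreaFraction(cnt, breaks, peaks)
  }

  makeTab <- function(h) {
    tab <- data.frame(
      t1 = vapply(intervals, `[`, numeric(1), 1),
      t2 = vapply(intervals, `[`, numeric(1), 2),
      tau = h$tau, n = rowSums(h$cnt),
      pA = vapply(seq_along(intervals), function(k)
        peakAreaFraction(h$cnt[k, ], breaks, peaks), numeric(1)))
    # same-molecule probability per interval: the burst-time
    # correlation logic of the P_same curve, evaluated on the interval
    # itself — observed pairs in excess of the Poisson expectation for
    # newly arriving molecules are recurrences
    psDirect <- ifelse(tab$n > 0, pmax(0, 1 - h$eNew / tab$n),
                       NA_real_)
    psCurve <- pSameAt(pSame, tab$tau)
    tab$p_same <- ifelse(is.na(psDirect), psCurve, psDirect)
    tab
  }

  # joint least squares over one or two selection trajectories:
  # shared lambda, rhoEq (and pNew); one rho(0) per selection
  fitOnce <- function(h, hB, pooled) {
    tab <- makeTab(h)
    tabB <- if (!is.null(hB)) makeTab(hB)
    use <- tab$n > 0 & !is.na(tab$pA)
    useB <- if (is.null(tabB)) logical(0) else
      tabB$n > 0 & !is.na(tabB$pA)
    if (sum(use) + sum(useB) < 4)
      return(list(par = rep(NA_real_, 5), tab = tab, tabB = tabB))
    two <- !is.null(tabB)
    ss <- function(t_, u_, lam, rhoEq, rho0, pn) {
      pa <- t_$p_same[u_] *
        ratePAmodel(t_$tau[u_], lam, rhoEq, rho0, eps) +
        (1 - t_$p_same[u_]) * pn
      sum(t_$n[u_] * (t_$pA[u_] - pa)^2)
    }
    obj <- function(p) {
      pn <- if (pNewFree) p[length(p)] else pooled
      v <- ss(tab, use, p[1], p[2], p[3], pn)
      if (two) v <- v + ss(tabB, useB, p[1], p[2], p[4], pn)
      v
    }
    st <- c(lambda = 1 / max(median(tab$tau[use]), 1e-4),
            rhoEq = mean(tab$pA[use][which.max(tab$tau[use])]),
            rho0 = tab$pA[use][1])
    if (two) st <- c(st, rho0B = tabB$pA[useB][1])
    if (pNewFree) st <- c(st, pNew = pooled)
    st[is.na(st)] <- 0.5
    # the initial conditions act as effective amplitudes (selection
    # purity times blur attenuation), so they are not clamped to the
    # probability range: a hard bound at 1 would bias lambda downward
    # whenever noise pushes the apparent amplitude above it
    lo <- rep(1e-3, length(st)); hi <- rep(1 - 1e-3, length(st))
    ir0 <- grep("^rho0", names(st))
    lo[ir0] <- -0.5; hi[ir0] <- 1.5
    hi[1] <- 5e3
    fit <- optim(st, obj, method = "L-BFGS-B", lower = lo,
                 upper = hi)
    par <- fit$par
    out <- c(lambda = unname(par[1]), rhoEq = unname(par[2]),
             rho0 = unname(par[3]),
             rho0B = if (two) unname(par[4]) else NA_real_,
             pNew = if (pNewFree) unname(par[length(par)])
                    else pooled)
    list(par = out, tab = tab, tabB = tabB)
  }

  full <- fitOnce(fullH, fullHB, pooledPA(b))
  par <- full$par
  # bootstrap over bursts (peaks and P_same kept from the full fit)
  boot <- withSeed(seed, {
    t(vapply(seq_len(nBoot), function(r) {
      idx <- sample.int(nrow(b), replace = TRUE)
      bres <- transform(b[idx, , drop = FALSE], id = seq_along(idx))
      bs <- initialize(bursts, bursts = bres)
      fitOnce(histsOf(bs, e1Range),
              if (!is.null(e1RangeB)) histsOf(bs, e1RangeB),
              pooledPA(bres))$par
    }, numeric(5)))
  })
  colnames(boot) <- c("lambda", "rhoEq", "rho0", "rho0B", "pNew")
  lam <- par[1]; rhoEq <- par[2]
  flags <- character()
  if (!is.na(lam) && all(full$tab$t2 < 1 / lam))
    flags <- c(flags, "unidentifiable: all intervals shorter than 1/lambda")
  # relaxation towards equilibrium must be monotone beyond noise
  tb <- full$tab[full$tab$n > 0 & !is.na(full$tab$pA), ]
  if (nrow(tb) >= 2 && !is.na(par[3]) && !is.na(rhoEq)) {
    dirn <- sign(par[3] - rhoEq)
    dp <- dirn * diff(tb$pA)
    tolst <- 2 * sqrt(tb$pA * (1 - tb$pA) / pmax(tb$n, 1))
    bad <- dp > (tolst[-1] + tolst[-nrow(tb)])
    if (any(bad)) {
      flags <- c(flags, "pA trajectory non-monotone beyond noise")
      warning("recurrence pA trajectory is non-monotone beyond ",
              "counting noise; check peak model and intervals")
    }
  }
  ci <- function(x) unname(quantile(x, c(0.025, 0.975), na.rm = TRUE))
  out <- list(lambda = unname(lam), rhoEq = unname(rhoEq),
              rho0 = unname(par[3]), rho0B = unname(par[4]),
              pNew = unname(par[5]), eps = eps,
              tauOutOfA_s = unname(1 / (lam * (1 - rhoEq))),
              tauIntoA_s = unname(1 / (lam * rhoEq)),
              peaks = peaks, intervals = full$tab,
              intervalsB = full$tabB,
              ci = list(lambda = ci(boot[, "lambda"]),
                        rhoEq = ci(boot[, "rhoEq"]),
                        tauOutOfA_s = ci(1 / (boot[, "lambda"] *
                                            (1 - boot[, "rhoEq"]))),
                        tauIntoA_s = ci(1 / (boot[, "lambda"] *
                                           boot[, "rhoEq"]))),
              boot = boot, flags = flags)
  class(out) <- "KineticFit"
  out
}

#' @export
print.KineticFit <- function(x, ...) {
  cat("Two-state kinetic fit (recurrence analysis)\n")
  cat(sprintf("  lambda = %.1f 1/s  [%.1f, %.1f]\n", x$lambda,
              x$ci$lambda[1], x$ci$lambda[2]))
  cat(sprintf("  rhoA_eq = %.3f, rhoA(0) = %.3f, pA_new = %.3f\n",
              x$rhoEq, x$rho0, x$pNew))
  cat(sprintf("  tau out of A = %.2f ms  [%.2f, %.2f]\n",
              1e3 * x$tauOutOfA_s, 1e3 * x$ci$tauOutOfA_s[1],
              1e3 * x$ci$tauOutOfA_s[2]))
  cat(sprintf("  tau into A  = %.2f ms\n", 1e3 * x$tauIntoA_s))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "),
                           "\n")
  invisible(x)
}

#' Logarithmic recurrence-interval grid
#' @param from,to first interval start and last interval end (s)
#' @param n number of intervals
#' @return list of length-2 numeric intervals
#' @export
logIntervals <- function(from = 5e-4, to = 0.08, n = 8) {
  e <- exp(seq(log(from), log(to), length.out = n + 1))
  lapply(seq_len(n), function(i) c(e[i], e[i + 1]))
}
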