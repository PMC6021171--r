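#' Per-frame FRET efficiency and stoichiometry of TIRF traces
#'
#' Frame-wise analogues of the burst formulas:
#' \eqn{E = I_{DA}/(I_{DD}+I_{DA})} (or the corrected form with leakage,
#' direct excitation and gamma, as in \code{\link{computeBurstES}}) and
#' \eqn{S = (I_{DD}+I_{DA})/(I_{DD}+I_{DA}+I_{AA})}. Frames without
#' donor-excitation signal (e.g. after donor bleach) get E = NA.
#'
#' @param traces a \code{\linkS4class{TirfTraceSet}}
#' @param corrections a \code{\link{correctionFactors}} or \code{NULL}
#' @param minSignal total donor-excitation intensity below which a frame
#'   is treated as signal-free
#' @return the \code{\linkS4class{TirfTraceSet}} with \code{E} and
#'   \code{S} frame columns
#' @export
traceES <- function(traces, corrections = NULL, minSignal = 0.2) {
  stopifnot(is(traces, "TirfTraceSet"))
  fr <- traces@frames
  idd <- pmax(fr$I_DD, 0); ida <- pmax(fr$I_DA, 0)
  iaa <- pmax(fr$I_AA, 0)
  tot <- idd + ida
  if (is.null(corrections)) {
    e <- ifelse(tot > minSignal, ida / tot, NA_real_)
  } else {
    stopifnot(inherits(corrections, "CorrectionFactors"))
    l <- corrections$leakage; d <- corrections$directExcitation
    g <- corrections$gamma
    num <- ida - l * idd - d * iaa
    den <- g * idd + num
    e <- ifelse(tot > minSignal & den > 0, num / den, NA_real_)
  }
  fr$E <- e
  fr$S <- ifelse(tot + iaa > 0, tot / (tot + iaa), NA_real_)
  initialize(traces, frames = fr)
}

# single-step change point of one channel: largest drop split by a
# cusum-style scan. Returns frame index of the first post-step frame and
# the step size, or NULL if no step above the detection limit.
detectSteps <- function(y, noiseSD, minStep = 4, maxSteps = 3) {
  findStep <- function(lo, hi) {
    if (hi - lo < 4) return(NULL)
    seg <- y[lo:hi]
    n <- length(seg)
    cs <- cumsum(seg)
    k <- seq_len(n - 1)
    m1 <- cs[k] / k
    m2 <- (cs[n] - cs[k]) / (n - k)
    stat <- abs(m1 - m2) * sqrt(k * (n - k) / n)
    kk <- which.max(stat)
    if (abs(m1[kk] - m2[kk]) >= minStep * noiseSD)
      list(at = lo + kk, size = m2[kk] - m1[kk])
    else NULL
  }
  steps <- list()
  segs <- list(c(1L, length(y)))
  for (pass in seq_len(maxSteps)) {
    newsegs <- list()
    for (sg in segs) {
      st <- findStep(sg[1], sg[2])
      if (!is.null(st)) {
        steps[[length(steps) + 1L]] <- st
        newsegs <- c(newsegs, list(c(sg[1], st$at - 1L)),
                     list(c(st$at, sg[2])))
      }
    }
    if (!length(newsegs)) break
    segs <- newsegs
  }
  steps
}

#' Quality control of TIRF traces
#'
#' Applies the selection criteria used for trace-level analysis:
#' \itemize{
#'   \item stoichiometry: the median pre-bleach S must lie in
#'     \code{sWindow} (removes single-dye complexes);
#'   \item anticorrelation: the Pearson correlation of donor and
#'     acceptor intensities over frames near candidate transitions must
#'     be below \code{anticorrThreshold} (traces without candidate
#'     transitions pass this criterion vacuously and are handled later
#'     by the responsiveness filter);
#'   \item bleaching: each channel must show at most one downward
#'     change-point step (cumulative-sum detector, minimum step 4x the
#'     frame noise SD); two-step drops (double labelling) are excluded.
#'     Donor-bleach traces are retained up to the bleach frame and the
#'     bleach time recorded for the photobleaching correction;
#'   \item blinking: transient dark excursions that recover are flagged
#'     and the trace excluded.
#' }
#'
#' @param traces a \code{\linkS4class{TirfTraceSet}} with E/S computed
#' @param sWindow stoichiometry window (default 0.25-0.75)
#' @param anticorrThreshold Pearson threshold (default -0.3)
#' @return the \code{\linkS4class{TirfTraceSet}} restricted to passing
#'   traces, with a per-trace QC report in the \code{qc} slot
#'   (trace_id, medianS, anticorr, bleach_s, bleach frame, flags, pass)
#' @export
qcTraces <- function(traces, sWindow = c(0.25, 0.75),
                     anticorrThreshold = -0.3) {
  stopifnot(is(traces, "TirfTraceSet"))
  fr <- traces@frames
  if (is.null(fr$E)) stop("compute E/S first (traceES)")
  rep_list <- lapply(split(seq_len(nrow(fr)), fr$trace_id),
                     function(ix) {
    tr <- fr[ix, ]
    noise <- function(y) max(mad(diff(y)) / sqrt(2), 1e-6)
    # bleach: downward steps on the donor-excitation total and on AA
    tot <- tr$I_DD + tr$I_DA
    st_d <- detectSteps(tot, noise(tot))
    st_a <- detectSteps(tr$I_AA, noise(tr$I_AA))
    down_d <- Filter(function(s) s$size < 0, st_d)
    down_a <- Filter(function(s) s$size < 0, st_a)
    multi <- length(down_d) > 1 || length(down_a) > 1
    bleachFrame <- if (length(down_d) || length(down_a))
      min(vapply(c(down_d, down_a), `[[`, numeric(1), "at"))
    else nrow(tr) + 1L
    pre <- seq_len(bleachFrame - 1L)
    medS <- median(tr$S[pre], na.rm = TRUE)
    sPass <- !is.na(medS) && medS >= sWindow[1] && medS <= sWindow[2]
    # blinking: dark excursion (both channels low) that recovers
    dark <- which(tot[pre] < 0.5 * median(tot[pre]))
    blink <- length(dark) > 0 && max(dark) < length(pre) - 1
    # anticorrelation near candidate transitions
    e <- tr$E[pre]
    cand <- which(abs(diff(e)) > 3 * noise(e[!is.na(e)]))
    anticorr <- NA_real_
    if (length(cand) && length(pre) > 5) {
      near <- unique(pmin(pmax(rep(cand, each = 5) + (-2:2), 1),
                          length(pre)))
      if (length(near) >= 4)
        anticorr <- suppressWarnings(
          cor(tr$I_DD[near], tr$I_DA[near]))
    }
    acPass <- is.na(anticorr) || anticorr < anticorrThreshold
    data.frame(trace_id = tr$trace_id[1], medianS = medS,
               anticorr = anticorr,
               bleach_frame = bleachFrame,
               bleach_s = if (bleachFrame <= nrow(tr))
                 tr$time_s[bleachFrame] else NA_real_,
               multiStep = multi, blinking = blink,
               sPass = sPass, acPass = acPass,
               pass = sPass && acPass && !multi && !blink)
  })
  qc <- do.call(rbind, rep_list)
  rownames(qc) <- NULL
  keep <- qc$trace_id[qc$pass]
  initialize(traces,
             frames = fr[fr$trace_id %in% keep, , drop = FALSE],
             qc = qc)
}

#' Two-state hidden Markov segmentation of a TIRF trace
#'
#' Fits a two-state Gaussian-emission hidden Markov model to the
#' pre-bleach per-frame FRET efficiencies (means initialised at the
#' open/closed values 0.2 and 0.4), decodes the most probable state
#' path, and extracts the dwell list. Dwells tile the pre-bleach trace;
#' the terminal dwell is marked censored. Traces with fewer than 10
#' usable frames are skipped; traces with zero decoded transitions are
#' flagged non-responsive (such complexes, facing the vesicle interior,
#' are excluded from histograms).
#'
#' @param traces a \code{\linkS4class{TirfTraceSet}} with E computed
#'   (post-QC; bleach frames from the QC report are honoured)
#' @param meansInit initial state means on E
#' @return data.frame of dwells: trace_id, state ("open"/"closed"),
#'   t_start, duration_s, censored, responsive; plus attribute
#'   \code{"segmentation"} with per-trace HMM parameters
#' @export
segmentStatesHmm <- function(traces, meansInit = c(0.2, 0.4)) {
  stopifnot(is(traces, "TirfTraceSet"))
  fr <- traces@frames
  if (is.null(fr$E)) stop("compute E first (traceES)")
  qc <- traces@qc
  dt <- traces@framePeriod
  res <- list(); seg <- list()
  for (id in traceIds(traces)) {
    tr <- fr[fr$trace_id == id, ]
    nb <- if (nrow(qc)) qc$bleach_frame[match(id, qc$trace_id)] else NA
    if (!is.na(nb) && nb <= nrow(tr)) tr <- tr[seq_len(nb - 1L), ]
    e <- tr$E
    ok <- !is.na(e)
    if (sum(ok) < 10) next
    e <- e[ok]; tt <- tr$time_s[ok]
    hmm <- fitHmm2(e, means0 = meansInit)
    path <- viterbi2(e, hmm)
    # responsiveness: the two-state model must beat a single Gaussian
    # by BIC, otherwise the decoded "transitions" are noise
    ll1 <- sum(dnorm(e, mean(e), max(sd(e), 1e-6), log = TRUE))
    bic1 <- -2 * ll1 + 2 * log(length(e))
    bic2 <- -2 * hmm$logLik + 7 * log(length(e))
    # state 1 = lower mean = open
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    responsive <- length(r$lengths) > 1 && bic2 < bic1
    res[[length(res) + 1L]] <- data.frame(
      trace_id = id,
      state = ifelse(r$values == 1L, "open", "closed"),
      t_start = tt[starts] - dt / 2,
      duration_s = r$lengths * dt,
      censored = seq_along(r$lengths) == length(r$lengths),
      responsive = responsive)
    seg[[as.character(id)]] <- hmm
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(trace_id = integer(), state = character(),
               t_start = numeric(), duration_s = numeric(),
               censored = logical(), responsive = logical())
  rownames(out) <- NULL
  attr(out, "segmentation") <- seg
  out
}

#' Orientation correction of a FRET histogram
#'
#' Reconstituted complexes insert in both orientations; a fraction
#' \code{f} faces the vesicle interior, cannot engage the ATPase, and
#' contributes the unresponsive reference distribution. The corrected
#' histogram is \eqn{(mixture - f \cdot reference)/(1 - f)}, clipped at
#' zero and renormalised. Both inputs must be density-normalised on the
#' same grid.
#'
#' @param activeHist density vector of the measured mixture
#' @param referenceHist density vector of the reference (inactive-only)
#'   sample on the same bins
#' @param invertedFraction fraction f of inverted complexes
#'   (default 0.5)
#' @param binWidth bin width used for renormalisation
#' @return corrected density vector
#' @export
correctOrientationHistogram <- function(activeHist, referenceHist,
                                        invertedFraction = 0.5,
                                        binWidth = NULL) {
  if (invertedFraction >= 1)
    stop("parameter error: inverted fraction must be < 1")
  stopifnot(length(activeHist) == length(referenceHist))
  raw <- (activeHist - invertedFraction * referenceHist) /
    (1 - invertedFraction)
  negMass <- -sum(raw[raw < 0])
  if (sum(abs(raw)) > 0 && negMass / sum(abs(raw)) > 0.1)
    warning("more than 10% negative mass before clipping; the ",
            "reference may not describe the inactive fraction")
  cor <- pmax(raw, 0)
  if (is.null(binWidth)) binWidth <- 1
  tot <- sum(cor) * binWidth
  if (tot > 0) cor <- cor / tot
  cor
}

#' Two-component Gaussian mixture fit of a FRET distribution
#'
#' Weighted least squares on the binned density (bin width 0.02 by
#' default), the estimator used for subpopulation areas in E
#' histograms. Components are ordered by ascending mean; a floor on the
#' component SD guards against degenerate collapse.
#'
#' @param e vector of E values (>= 50 for a meaningful fit) or a
#'   pre-binned density (with \code{breaks} supplied matching it)
#' @param breaks histogram bin edges
#' @param sdFloor minimum component SD
#' @return list of class \code{MixtureFit}: mean, sd, weight (each
#'   length 2, weights summing to 1), overlap flag, residual
#' @export
fitGaussianMixture <- function(e, breaks = seq(0, 1, by = 0.02),
                               sdFloor = 0.01) {
  if (length(e) == length(breaks) - 1L && any(e > 1)) {
    dens <- e / sum(e) / diff(breaks)
  } else if (length(e) == length(breaks) - 1L &&
             abs(sum(e * diff(breaks)) - 1) < 1e-6) {
    dens <- e
  } else {
    e <- e[!is.na(e)]
    if (length(e) < 50)
      warning("fewer than 50 observations for the mixture fit")
    cnt <- tabulate(findInterval(pmin(pmax(e, 0), 1), breaks,
                                 rightmost.closed = TRUE),
                    nbins = length(breaks) - 1L)
    dens <- cnt / sum(cnt) / diff(breaks)
  }
  mids <- breaks[-length(breaks)] + diff(breaks) / 2
  q <- quantile(rep(mids, round(dens * 1e4 * diff(breaks)) + 1L),
                c(0.25, 0.75))
  st <- c(m1 = unname(q[1]), m2 = unname(q[2]), ls1 = log(0.05),
          ls2 = log(0.05), w = 0.5)
  obj <- function(p) {
    d <- p["w"] * dnorm(mids, p["m1"], max(exp(p["ls1"]), sdFloor)) +
      (1 - p["w"]) * dnorm(mids, p["m2"], max(exp(p["ls2"]), sdFloor))
    sum((d - dens)^2)
  }
  fit <- optim(st, obj, method = "L-BFGS-B",
               lower = c(0, 0, log(sdFloor), log(sdFloor), 1e-3),
               upper = c(1, 1, log(0.5), log(0.5), 1 - 1e-3))
  p <- fit$par
  mean_ <- c(p["m1"], p["m2"])
  sd_ <- pmax(exp(c(p["ls1"], p["ls2"])), sdFloor)
  w_ <- c(p["w"], 1 - p["w"])
  if (mean_[1] > mean_[2]) {
    mean_ <- rev(mean_); sd_ <- rev(sd_); w_ <- rev(w_)
  }
  overlap <- abs(mean_[2] - mean_[1]) < (sd_[1] + sd_[2])
  structure(list(mean = unname(mean_), sd = unname(sd_),
                 weight = unname(w_), overlap = overlap,
                 residual = fit$value),
            class = "MixtureFit")
}

#' @export
print.MixtureFit <- function(x, ...) {
  cat(sprintf("MixtureFit: %.3f (sd %.3f, w %.2f) + %.3f (sd %.3f, w %.2f)%s\n",
              x$mean[1], x$sd[1], x$weight[1], x$mean[2], x$sd[2],
              x$weight[2],
              if (x$overlap) "  [overlapping]" else ""))
  invisible(x)
}
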