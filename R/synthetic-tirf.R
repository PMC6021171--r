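#' TIRF simulation configuration
#'
#' Study conditions for the immobilised-vesicle msALEX TIRF simulation.
#' Open-state dwells are gamma distributed with mean
#' \code{offset + length / rate} (the dwell model behind the
#' substrate-length regression); closed dwells are exponential;
#' each dye photobleaches at an exponential time, truncating the trace
#' with a single-step drop. One frame is a full 200 ms alternation cycle
#' (100 ms donor excitation + 100 ms acceptor excitation).
#'
#' @param lengths substrate lengths in amino acids
#' @param rate translocation rate (aa/s); default per-residue time
#'   25.25 ms, i.e. ~39.6 aa/s
#' @param offset length-independent open-dwell offset (s): ~4.7 s
#'   without SecB, ~0.5 s with SecB
#' @param closedMean mean closed-state dwell (s)
#' @param gammaShape shape of the gamma open-dwell law
#' @param photobleachMean mean photobleaching time per trace (s); the
#'   two dyes each bleach at exponential times with mean
#'   \code{2 * photobleachMean} so the first bleach has this mean
#' @param framePeriod full alternation cycle period (s)
#' @param excitationPeriod single-colour excitation period (ms)
#' @param snr detection signal-to-noise: ratio of the open/closed
#'   intensity separation to the per-channel read noise SD (SNR 3
#'   means transitions are 3 noise SDs tall)
#' @param shotScale photons per intensity unit for the scaled-Poisson
#'   shot-noise component
#' @param eOpen,eClosed state FRET efficiencies
#' @param nTraces traces per substrate length (recycled)
#' @param maxDuration maximum trace duration (s)
#' @param seed integer seed
#' @return a validated list of class \code{TirfSimConfig}
#' @export
tirfSimConfig <- function(lengths = c(100, 233, 354, 683),
                          rate = 1000 / 25.25, offset = 4.7,
                          closedMean = 3, gammaShape = 4,
                          photobleachMean = 60, framePeriod = 0.2,
                          excitationPeriod = 100, snr = 6,
                          shotScale = 400, eOpen = 0.2, eClosed = 0.4,
                          nTraces = 50, maxDuration = 300, seed = 1L) {
  if (!length(lengths)) stop("configuration error: empty length list")
  stopifnot(all(lengths > 0), rate > 0, offset >= 0, framePeriod > 0,
            closedMean > 0, gammaShape > 0, photobleachMean > 0,
            snr > 0, all(nTraces >= 1))
  structure(list(lengths = lengths, rate = rate, offset = offset,
                 closedMean = closedMean, gammaShape = gammaShape,
                 photobleachMean = photobleachMean,
                 framePeriod = framePeriod,
                 excitationPeriod = excitationPeriod, snr = snr,
                 shotScale = shotScale, eOpen = eOpen,
                 eClosed = eClosed,
                 nTraces = rep_len(nTraces, length(lengths)),
                 maxDuration = maxDuration, seed = as.integer(seed)),
            class = "TirfSimConfig")
}

# frame intensities for a given dwell sequence; dwells is a data.frame
# (state, duration). Returns noiseless I_DD/I_DA/I_AA per frame up to
# bleach/maxDuration, with the bleach signature of whichever dye went
# first.
traceIntensities <- function(dwells, cfg, bleachDonor, bleachAcceptor,
                             nFrames) {
  tmid <- (seq_len(nFrames) - 0.5) * cfg$framePeriod
  edges <- cumsum(c(0, dwells$duration))
  idx <- pmin(findInterval(tmid, edges, rightmost.closed = FALSE),
              nrow(dwells))
  e <- ifelse(dwells$state[idx] == "open", cfg$eOpen, cfg$eClosed)
  idd <- 1 - e
  ida <- e
  iaa <- rep(1, nFrames)
  post_d <- tmid >= bleachDonor
  post_a <- tmid >= bleachAcceptor
  # donor bleach kills both donor-excited channels; acceptor bleach kills
  # FRET and direct acceptor signal, donor recovers to full
  idd[post_a & !post_d] <- 1
  ida[post_a | post_d] <- 0
  idd[post_d] <- 0
  iaa[post_a] <- 0
  data.frame(time_s = tmid, I_DD = idd, I_DA = ida, I_AA = iaa)
}

#' Build one TIRF trace from an explicit dwell sequence
#'
#' Deterministic constructor used for fixtures and closed-form checks:
#' frame intensities follow the given alternating dwell sequence exactly,
#' with optional noise and bleach times.
#'
#' @param states character vector of states ("closed"/"open")
#' @param durations dwell durations (s)
#' @param cfg a \code{\link{tirfSimConfig}}
#' @param noise logical; add the configured noise model
#' @param bleachDonor,bleachAcceptor bleach times (s); default beyond the
#'   trace
#' @param traceId trace identifier
#' @return data.frame of frames (trace_id, time_s, I_DD, I_DA, I_AA)
#' @export
tirfTraceFromDwells <- function(states, durations, cfg, noise = FALSE,
                                bleachDonor = Inf, bleachAcceptor = Inf,
                                traceId = 1L) {
  stopifnot(length(states) == length(durations), all(durations > 0))
  nFrames <- floor(min(sum(durations), cfg$maxDuration) / cfg$framePeriod)
  fr <- traceIntensities(data.frame(state = states,
                                    duration = durations),
                         cfg, bleachDonor, bleachAcceptor, nFrames)
  if (noise) fr <- addTirfNoise(fr, cfg)
  cbind(trace_id = traceId, fr)
}

addTirfNoise <- function(fr, cfg) {
  n <- nrow(fr)
  shot <- function(i) rpois(n, pmax(i, 0) * cfg$shotScale) /
    cfg$shotScale - pmax(i, 0)
  rd <- (cfg$eClosed - cfg$eOpen) / cfg$snr
  fr$I_DD <- fr$I_DD + shot(fr$I_DD) + rnorm(n, 0, rd)
  fr$I_DA <- fr$I_DA + shot(fr$I_DA) + rnorm(n, 0, rd)
  fr$I_AA <- fr$I_AA + shot(fr$I_AA) + rnorm(n, 0, rd)
  fr
}

#' Simulate msALEX TIRF traces with ground-truth dwells
#'
#' For each trace, closed (exponential) and open (gamma, mean
#' \code{offset + L/rate}) dwells alternate starting from a closed state
#' at time zero; per-frame donor/acceptor intensities follow the state's
#' FRET efficiency with EMCCD-like noise (scaled-Poisson shot noise plus
#' Gaussian read noise); each dye bleaches at an exponential time and the
#' trace shows the corresponding single-step drop. Ground-truth dwell and
#' bleach tables are returned in the \code{truth} slot.
#'
#' @param cfg a \code{\link{tirfSimConfig}}
#' @return a \code{\linkS4class{TirfTraceSet}}; \code{groundTruth(x)}
#'   holds \code{dwells} (trace_id, length, state, t_start, duration_s,
#'   complete flag: dwell ended before the first bleach) and
#'   \code{bleach} (trace_id, bleach_s, dye)
#' @export
simulateTirfTraces <- function(cfg) {
  stopifnot(inherits(cfg, "TirfSimConfig"))
  withSeed(cfg$seed, {
    frames <- vector("list", sum(cfg$nTraces))
    truths <- vector("list", sum(cfg$nTraces))
    bleaches <- vector("list", sum(cfg$nTraces))
    id <- 0L
    for (li in seq_along(cfg$lengths)) {
      L <- cfg$lengths[li]
      openMean <- cfg$offset + L / cfg$rate
      for (tr in seq_len(cfg$nTraces[li])) {
        id <- id + 1L
        bl_d <- rexp(1, 1 / (2 * cfg$photobleachMean))
        bl_a <- rexp(1, 1 / (2 * cfg$photobleachMean))
        bleach <- min(bl_d, bl_a, cfg$maxDuration)
        # draw alternating dwells until past bleach (plus margin so the
        # post-bleach step is visible in the frames)
        tmax <- min(bleach + 20, cfg$maxDuration)
        st <- character(); du <- numeric(); tt <- 0
        state <- "closed"
        while (tt < tmax) {
          d <- if (state == "closed") rexp(1, 1 / cfg$closedMean) else
            rgamma(1, shape = cfg$gammaShape,
                   scale = openMean / cfg$gammaShape)
          st <- c(st, state); du <- c(du, d)
          tt <- tt + d
          state <- if (state == "closed") "open" else "closed"
        }
        nFrames <- max(2L, floor(tmax / cfg$framePeriod))
        fr <- traceIntensities(data.frame(state = st, duration = du),
                               cfg, bl_d, bl_a, nFrames)
        fr <- addTirfNoise(fr, cfg)
        frames[[id]] <- cbind(trace_id = id, fr)
        starts <- cumsum(c(0, du[-length(du)]))
        truths[[id]] <- data.frame(trace_id = id, length = L,
                                   state = st, t_start = starts,
                                   duration_s = du,
                                   complete = starts + du <= bleach)
        bleaches[[id]] <- data.frame(trace_id = id, length = L,
                                     bleach_s = bleach,
                                     dye = if (bl_d < bl_a) "donor"
                                           else "acceptor")
      }
    }
    new("TirfTraceSet", frames = do.call(rbind, frames),
        framePeriod = cfg$framePeriod,
        truth = list(dwells = do.call(rbind, truths),
                     bleach = do.call(rbind, bleaches), config = cfg),
        qc = data.frame())
  })
}

#' Read and write TIRF trace tables
#'
#' TSV with one row per frame: trace_id, time_s, I_DD, I_DA, I_AA.
#' Frames are sorted by time within trace on read. Ground-truth dwell
#' tables travel in a companion TSV (\code{truthPath}).
#'
#' @param traces a \code{\linkS4class{TirfTraceSet}}
#' @param path frame TSV path
#' @param truthPath optional companion TSV for ground-truth dwells
#' @param framePeriod frame period (s) used on read
#' @return \code{readTraces} returns a \code{\linkS4class{TirfTraceSet}}
#' @export
writeTraces <- function(traces, path, truthPath = NULL) {
  stopifnot(is(traces, "TirfTraceSet"))
  keep <- c("trace_id", "time_s", "I_DD", "I_DA", "I_AA")
  write.table(traces@frames[, keep], path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  if (!is.null(truthPath) && !is.null(traces@truth$dwells))
    write.table(traces@truth$dwells, truthPath, sep = "\t",
                row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeTraces
#' @export
readTraces <- function(path, truthPath = NULL, framePeriod = 0.2) {
  fr <- read.delim(path, sep = "\t")
  need <- c("trace_id", "time_s", "I_DD", "I_DA", "I_AA")
  miss <- setdiff(need, names(fr))
  if (length(miss))
    stop("format error: missing column(s) ", paste(miss, collapse = ", "))
  fr <- fr[order(fr$trace_id, fr$time_s), , drop = FALSE]
  rownames(fr) <- NULL
  # negative intensities are legitimate for baseline-subtracted data,
  # but values far below zero indicate a subtraction problem
  for (ch in c("I_DD", "I_DA", "I_AA")) {
    noise <- mad(diff(fr[[ch]])) / sqrt(2)
    if (any(fr[[ch]] < -5 * max(noise, 1e-12)))
      warning("column ", ch, " has values far below zero ",
              "(< -5x the frame noise); check baseline subtraction")
  }
  truth <- list()
  if (!is.null(truthPath) && file.exists(truthPath))
    truth$dwells <- read.delim(truthPath, sep = "\t")
  new("TirfTraceSet", frames = fr, framePeriod = framePeriod,
      truth = truth, qc = data.frame())
}
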