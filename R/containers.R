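#' PhotonStream: a timestamped two-channel ALEX photon record
#'
#' Container for a microsecond-ALEX photon stream. Photons are stored as a
#' data.frame with one row per photon: \code{tick} (integer clock ticks,
#' monotone non-decreasing, stored as doubles so streams longer than 2^31
#' ticks are exact), \code{channel} (0 = donor detector, 1 = acceptor
#' detector) and \code{slot} (0 = donor excitation, 1 = acceptor
#' excitation). Simulated streams additionally carry \code{particle}
#' (0 = background) and \code{state} (1 = open, 0 = closed, -1 =
#' background) ground-truth columns.
#'
#' @slot photons data.frame of per-photon records (see above)
#' @slot clockRate clock frequency in ticks per second
#' @slot alternationPeriod ALEX alternation period in ticks
#' @slot dutyCycle fraction of the period with the donor laser on
#' @slot truth list of ground-truth annotations (state path, config) for
#'   simulated streams; empty for experimental data
#'
#' @export
setClass("PhotonStream",
  representation(photons = "data.frame", clockRate = "numeric",
                 alternationPeriod = "numeric", dutyCycle = "numeric",
                 truth = "list"))

setValidity("PhotonStream", function(object) {
  ph <- object@photons
  msg <- character()
  need <- c("tick", "channel", "slot")
  if (!all(need %in% names(ph)))
    msg <- c(msg, paste("photons must have columns",
                        paste(need, collapse = ", ")))
  else {
    if (is.unsorted(ph$tick))
      msg <- c(msg, "photon timestamps must be monotone non-decreasing")
    if (nrow(ph) && !all(ph$channel %in% 0:1))
      msg <- c(msg, "channel must be 0 (donor) or 1 (acceptor)")
    if (nrow(ph) && !all(ph$slot %in% 0:1))
      msg <- c(msg, "slot must be 0 (donor-exc) or 1 (acceptor-exc)")
  }
  if (length(object@clockRate) != 1L || object@clockRate <= 0)
    msg <- c(msg, "clockRate must be a single positive number")
  if (length(object@alternationPeriod) != 1L ||
      (!is.na(object@alternationPeriod) &&
         object@alternationPeriod <= 0))
    msg <- c(msg, "alternationPeriod must be a single positive number ",
             "(or NA when per-photon slots are supplied)")
  if (length(object@dutyCycle) != 1L || object@dutyCycle <= 0 ||
      object@dutyCycle >= 1)
    msg <- c(msg, "dutyCycle must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' Construct a PhotonStream
#'
#' @param tick numeric vector of photon timestamps in clock ticks
#' @param channel integer vector, 0 donor / 1 acceptor detector
#' @param slot integer vector, 0 donor-excitation / 1 acceptor-excitation;
#'   if \code{NULL}, recomputed from the timestamps and alternation
#'   metadata
#' @param clockRate ticks per second
#' @param alternationPeriod alternation period in ticks
#' @param dutyCycle donor-laser duty cycle (fraction of the period)
#' @param particle,state optional ground-truth columns
#' @param truth optional list of ground-truth annotations
#' @return a \code{\linkS4class{PhotonStream}}
#' @export
PhotonStream <- function(tick, channel, slot = NULL, clockRate,
                         alternationPeriod = NA_real_,
                         dutyCycle = 0.4, particle = NULL,
                         state = NULL, truth = list()) {
  if (is.null(slot)) {
    if (is.na(alternationPeriod))
      stop("alternation metadata required to derive excitation slots")
    slot <- as.integer((tick %% alternationPeriod) >=
                         dutyCycle * alternationPeriod)
  }
  ph <- data.frame(tick = as.numeric(tick), channel = as.integer(channel),
                   slot = as.integer(slot))
  if (!is.null(particle)) ph$particle <- as.integer(particle)
  if (!is.null(state)) ph$state <- as.integer(state)
  new("PhotonStream", photons = ph, clockRate = clockRate,
      alternationPeriod = alternationPeriod, dutyCycle = dutyCycle,
      truth = truth)
}

#' @rdname plugdyn-generics
#' @export
setMethod("photonData", "PhotonStream", function(object) object@photons)

#' @rdname plugdyn-generics
#' @export
setMethod("nPhotons", "PhotonStream",
          function(object) nrow(object@photons))

#' @rdname plugdyn-generics
#' @export
setMethod("clockRate", "PhotonStream", function(object) object@clockRate)

#' @rdname plugdyn-generics
#' @export
setMethod("alternationPeriod", "PhotonStream",
          function(object) object@alternationPeriod)

#' @rdname plugdyn-generics
#' @export
setMethod("groundTruth", "PhotonStream", function(object) object@truth)

#' Photon arrival times in seconds
#' @param stream a \code{\linkS4class{PhotonStream}}
#' @return numeric vector of arrival times (s)
#' @export
photonTimes <- function(stream) {
  stopifnot(is(stream, "PhotonStream"))
  stream@photons$tick / stream@clockRate
}

#' Stream duration in seconds
#' @param stream a \code{\linkS4class{PhotonStream}}
#' @return duration (s); recorded duration if simulated, else last photon
#' @export
streamDuration <- function(stream) {
  stopifnot(is(stream, "PhotonStream"))
  if (!is.null(stream@truth$duration)) return(stream@truth$duration)
  if (nPhotons(stream) == 0) return(0)
  max(stream@photons$tick) / stream@clockRate
}

setMethod("show", "PhotonStream", function(object) {
  cat("PhotonStream with", nPhotons(object), "photons over",
      format(streamDuration(object), digits = 4), "s\n")
  cat("  clock:", object@clockRate, "ticks/s; alternation:",
      object@alternationPeriod / object@clockRate * 1e6,
      "us at duty", object@dutyCycle, "\n")
  ph <- object@photons
  if (nrow(ph)) {
    cat("  counts DexDem/DexAem/AexAem:",
        sum(ph$slot == 0 & ph$channel == 0),
        sum(ph$slot == 0 & ph$channel == 1),
        sum(ph$slot == 1 & ph$channel == 1), "\n")
  }
  if (length(object@truth))
    cat("  ground truth:", paste(names(object@truth), collapse = ", "),
        "\n")
})

#' BurstSet: bursts found in a photon stream
#'
#' One row per burst with photon index range into the originating stream
#' (kept for sub-burst analyses such as BVA), raw and background-corrected
#' counts split by channel x excitation slot, proximity ratio, corrected E
#' and stoichiometry.
#'
#' @slot bursts data.frame, one row per burst
#' @slot stream the originating \code{\linkS4class{PhotonStream}} (may be
#'   an empty stream after TSV round-trip)
#' @slot params list of search and correction parameters
#' @export
setClass("BurstSet",
  representation(bursts = "data.frame", stream = "PhotonStream",
                 params = "list"))

setValidity("BurstSet", function(object) {
  b <- object@bursts
  msg <- character()
  need <- c("id", "t_start", "t_stop", "n_DD", "n_DA", "n_AA")
  if (!all(need %in% names(b)))
    msg <- c(msg, paste("bursts must have columns",
                        paste(need, collapse = ", ")))
  else if (nrow(b)) {
    if (any(b$t_stop < b$t_start))
      msg <- c(msg, "burst stop must not precede start")
    if (any(b$n_DD < 0 | b$n_DA < 0 | b$n_AA < 0))
      msg <- c(msg, "raw counts must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname plugdyn-generics
#' @export
setMethod("burstData", "BurstSet", function(object) object@bursts)

#' @rdname plugdyn-generics
#' @export
setMethod("nBursts", "BurstSet", function(object) nrow(object@bursts))

setMethod("show", "BurstSet", function(object) {
  b <- object@bursts
  cat("BurstSet with", nrow(b), "bursts\n")
  if (nrow(b)) {
    cat("  median size:",
        median(b$n_DD + b$n_DA + b$n_AA), "photons; median duration:",
        format(median((b$t_stop - b$t_start) * 1e3), digits = 3), "ms\n")
    if ("E" %in% names(b))
      cat("  E:", paste(format(quantile(b$E, c(.25, .5, .75),
                                        na.rm = TRUE), digits = 2),
                        collapse = " / "), "(quartiles)\n")
  }
})

#' TirfTraceSet: per-frame two-channel TIRF intensity traces
#'
#' Frames are full msALEX alternation cycles: each row carries the
#' donor-excitation intensities \code{I_DD}, \code{I_DA} and the
#' acceptor-excitation intensity \code{I_AA} of one cycle.
#'
#' @slot frames data.frame with columns trace_id, time_s, I_DD, I_DA,
#'   I_AA (plus E, S and QC columns once computed)
#' @slot framePeriod frame (full cycle) period in seconds
#' @slot truth list with ground-truth dwell and bleach tables for
#'   simulated data
#' @slot qc per-trace QC report (filled by \code{\link{qcTraces}})
#' @export
setClass("TirfTraceSet",
  representation(frames = "data.frame", framePeriod = "numeric",
                 truth = "list", qc = "data.frame"))

setValidity("TirfTraceSet", function(object) {
  fr <- object@frames
  msg <- character()
  need <- c("trace_id", "time_s", "I_DD", "I_DA", "I_AA")
  if (!all(need %in% names(fr)))
    msg <- c(msg, paste("frames must have columns",
                        paste(need, collapse = ", ")))
  if (length(object@framePeriod) != 1L || object@framePeriod <= 0)
    msg <- c(msg, "framePeriod must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname plugdyn-generics
#' @export
setMethod("frameData", "TirfTraceSet", function(object) object@frames)

#' @rdname plugdyn-generics
#' @export
setMethod("framePeriod", "TirfTraceSet",
          function(object) object@framePeriod)

#' @rdname plugdyn-generics
#' @export
setMethod("traceIds", "TirfTraceSet",
          function(object) unique(object@frames$trace_id))

#' @rdname plugdyn-generics
#' @export
setMethod("groundTruth", "TirfTraceSet", function(object) object@truth)

setMethod("show", "TirfTraceSet", function(object) {
  cat("TirfTraceSet with", length(traceIds(object)), "traces,",
      nrow(object@frames), "frames at", object@framePeriod, "s/frame\n")
  if (nrow(object@qc))
    cat("  QC: ", sum(object@qc$pass), "of", nrow(object@qc),
        "traces pass\n")
})

#' AVCloud: Monte Carlo accessible volume of a tethered dye
#'
#' @slot positions numeric matrix (n x 3) of accepted dye-centre
#'   positions in Angstrom
#' @slot attachment attachment-atom coordinates (Angstrom)
#' @slot params list with linker length/width, dye radius, sample count,
#'   accepted fraction, seed
#' @export
setClass("AVCloud",
  representation(positions = "matrix", attachment = "numeric",
                 params = "list"))

setValidity("AVCloud", function(object) {
  msg <- character()
  if (ncol(object@positions) != 3L)
    msg <- c(msg, "positions must be an n x 3 matrix")
  if (length(object@attachment) != 3L)
    msg <- c(msg, "attachment must be an xyz coordinate")
  ll <- object@params$linkerLength
  if (!is.null(ll) && nrow(object@positions)) {
    d <- sqrt(rowSums(sweep(object@positions, 2,
                            object@attachment)^2))
    if (any(d > ll + 1e-6))
      msg <- c(msg, "accepted positions must lie within linker reach")
  }
  if (length(msg)) msg else TRUE
})

#' @rdname plugdyn-generics
#' @export
setMethod("avPositions", "AVCloud", function(object) object@positions)

setMethod("show", "AVCloud", function(object) {
  cat("AVCloud:", nrow(object@positions), "accepted dye positions",
      sprintf("(%.1f%% of %d samples)\n",
              100 * object@params$acceptedFraction,
              object@params$nSamples))
})
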