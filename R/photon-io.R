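#' Read and write photon streams
#'
#' Photon streams persist to a single self-describing text file: a header
#' line \code{#photon-stream <JSON>} holding the clock rate, alternation
#' metadata and any simulation ground truth, followed by a tab-separated
#' photon table (tick, channel, slot, and optional truth columns). The
#' layout mirrors the fields of timestamp-based single-molecule photon
#' containers; round-trips are lossless.
#'
#' @param stream a \code{\linkS4class{PhotonStream}}
#' @param path file path
#' @return \code{readPhotonStream} returns a
#'   \code{\linkS4class{PhotonStream}}; \code{writePhotonStream} returns
#'   \code{path} invisibly.
#' @examples
#' s <- PhotonStream(tick = c(0, 10, 400), channel = c(0, 1, 1),
#'                   clockRate = 1e7, alternationPeriod = 400)
#' f <- tempfile(fileext = ".tsv")
#' writePhotonStream(s, f)
#' identical(photonData(readPhotonStream(f))$tick, photonData(s)$tick)
#' @export
writePhotonStream <- function(stream, path) {
  stopifnot(is(stream, "PhotonStream"))
  meta <- list(clock_rate = stream@clockRate,
               alternation_period = stream@alternationPeriod,
               duty_cycle = stream@dutyCycle,
               truth = stream@truth["duration"])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#photon-stream ",
                    jsonlite::toJSON(meta, auto_unbox = TRUE,
                                     digits = NA)), con)
  write.table(stream@photons, con, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname writePhotonStream
#' @export
readPhotonStream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 1L)
  if (!startsWith(hdr, "#photon-stream "))
    stop("format error: missing photon-stream metadata header (clock ",
         "rate and alternation metadata are required)")
  meta <- jsonlite::fromJSON(sub("^#photon-stream ", "", hdr))
  if (is.null(meta$clock_rate))
    stop("format error: clock metadata missing")
  ph <- read.delim(path, skip = 1L, sep = "\t")
  if (is.null(meta$alternation_period) && !("slot" %in% names(ph)))
    stop("format error: neither alternation metadata nor per-photon ",
         "excitation slots present")
  if (is.unsorted(ph$tick))
    stop("data error: photon timestamps are not sorted")
  truth <- list()
  if (!is.null(meta$truth$duration)) truth$duration <- meta$truth$duration
  PhotonStream(tick = ph$tick, channel = ph$channel,
               slot = if ("slot" %in% names(ph)) ph$slot else NULL,
               clockRate = meta$clock_rate,
               alternationPeriod = meta$alternation_period %||%
                 NA_real_,
               dutyCycle = meta$duty_cycle %||% 0.4,
               particle = if ("particle" %in% names(ph)) ph$particle,
               state = if ("state" %in% names(ph)) ph$state,
               truth = truth)
}

#' Export bursts to a TSV table / import them back
#'
#' One row per burst: id, start time (s), duration (ms), raw counts,
#' proximity ratio, corrected E and stoichiometry. The photon-level
#' structure (needed by BVA) stays with the in-memory
#' \code{\linkS4class{BurstSet}} and is not serialised.
#'
#' @param bursts a \code{\linkS4class{BurstSet}}
#' @param path file path
#' @return \code{readBursts} returns a \code{\linkS4class{BurstSet}}
#'   without photon-level structure.
#' @export
writeBursts <- function(bursts, path) {
  stopifnot(is(bursts, "BurstSet"))
  b <- bursts@bursts
  out <- data.frame(id = b$id, t_start_s = b$t_start,
                    duration_ms = (b$t_stop - b$t_start) * 1e3,
                    n_DD = b$n_DD, n_DA = b$n_DA, n_AA = b$n_AA,
                    PR = b$PR %||% NA, E_corr = b$E %||% NA,
                    S = b$S %||% NA)
  write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeBursts
#' @export
readBursts <- function(path) {
  tb <- read.delim(path, sep = "\t")
  b <- data.frame(id = tb$id, t_start = tb$t_start_s,
                  t_stop = tb$t_start_s + tb$duration_ms / 1e3,
                  n_DD = tb$n_DD, n_DA = tb$n_DA, n_AA = tb$n_AA,
                  PR = tb$PR, E = tb$E_corr, S = tb$S)
  new("BurstSet", bursts = b,
      stream = PhotonStream(numeric(), integer(), integer(),
                            clockRate = 1, alternationPeriod = 1),
      params = list(from_tsv = TRUE))
}
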