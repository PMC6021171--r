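#' Correction factors for FRET efficiency
#'
#' Donor leakage into the acceptor channel (\code{l}), direct acceptor
#' excitation by the donor laser (\code{d}) and the detection-efficiency
#' gamma factor. The identity factors (0, 0, 1) leave the proximity
#' ratio unchanged. Calibration of the factors themselves (polyproline
#' standards) is an input, not computed here.
#'
#' @param leakage donor leakage fraction (>= 0)
#' @param directExcitation direct acceptor excitation fraction (>= 0)
#' @param gamma detection-efficiency factor (> 0)
#' @return list of class \code{CorrectionFactors}
#' @export
correctionFactors <- function(leakage = 0, directExcitation = 0,
                              gamma = 1) {
  stopifnot(leakage >= 0, directExcitation >= 0, gamma > 0)
  structure(list(leakage = leakage,
                 directExcitation = directExcitation, gamma = gamma),
            class = "CorrectionFactors")
}

#' Compute burst-wise proximity ratio, corrected E and stoichiometry
#'
#' The proximity ratio \eqn{PR = n_{DA}/(n_{DD}+n_{DA})} and
#' stoichiometry \eqn{S = (n_{DD}+n_{DA})/(n_{DD}+n_{DA}+n_{AA})} are
#' always computed from background-corrected counts. When correction
#' factors are supplied, corrected E is the population-level transform
#' \deqn{E = \frac{n_{DA} - l\,n_{DD} - d\,n_{AA}}
#'   {\gamma\,n_{DD} + n_{DA} - l\,n_{DD} - d\,n_{AA}}}
#' applied to each burst's totals (never per-photon reweighting).
#' Bursts with no donor-excitation signal are flagged and get E = NA.
#'
#' @param bursts a \code{\linkS4class{BurstSet}} with counts populated
#' @param corrections a \code{\link{correctionFactors}} or \code{NULL}
#' @return the \code{\linkS4class{BurstSet}} with \code{PR}, \code{E},
#'   \code{S} and \code{flagged} columns
#' @examples
#' shotNoiseSD(0.5, 100)  # companion closed form used by BVA
#' @export
computeBurstES <- function(bursts, corrections = NULL) {
  stopifnot(is(bursts, "BurstSet"))
  b <- bursts@bursts
  if (!nrow(b)) return(bursts)
  ndd <- pmax(b$n_DD_corr %||% b$n_DD, 0)
  nda <- pmax(b$n_DA_corr %||% b$n_DA, 0)
  naa <- pmax(b$n_AA_corr %||% b$n_AA, 0)
  tot <- ndd + nda
  b$flagged <- tot <= 0
  b$PR <- ifelse(tot > 0, pmin(pmax(nda / tot, 0), 1), NA_real_)
  b$S <- ifelse(tot + naa > 0, tot / (tot + naa), NA_real_)
  if (is.null(corrections)) {
    b$E <- b$PR
  } else {
    stopifnot(inherits(corrections, "CorrectionFactors"))
    l <- corrections$leakage; d <- corrections$directExcitation
    g <- corrections$gamma
    num <- nda - l * ndd - d * naa
    den <- g * ndd + num
    b$E <- ifelse(den > 0, num / den, NA_real_)
    b$S <- ifelse(tot + naa > 0,
                  (g * ndd + num) / (g * ndd + num + naa), b$S)
  }
  initialize(bursts, bursts = b,
             params = c(bursts@params,
                        list(corrections = corrections)))
}

#' Stoichiometry and size filtering of bursts
#'
#' Retains bursts whose stoichiometry lies within the closed interval
#' \code{[sMin, sMax]} (removing donor-only S ~ 1 and acceptor-only
#' S ~ 0 species) and whose total raw counts reach \code{minSize}.
#'
#' @param bursts a \code{\linkS4class{BurstSet}} with S computed
#' @param sMin,sMax stoichiometry window (default 0.25-0.75)
#' @param minSize minimum total photon count per burst
#' @return the filtered \code{\linkS4class{BurstSet}}
#' @export
filterBursts <- function(bursts, sMin = 0.25, sMax = 0.75,
                         minSize = 30) {
  stopifnot(is(bursts, "BurstSet"))
  if (sMin >= sMax) stop("parameter error: sMin must be < sMax")
  b <- bursts@bursts
  if (!nrow(b)) return(bursts)
  if (is.null(b$S)) stop("compute S first (computeBurstES)")
  keep <- !is.na(b$S) & b$S >= sMin & b$S <= sMax &
    (b$n_DD + b$n_DA + b$n_AA) >= minSize
  if (!any(keep)) warning("no bursts retained by the S/size filter")
  b <- b[keep, , drop = FALSE]
  rownames(b) <- NULL
  initialize(bursts, bursts = b,
             params = c(bursts@params,
                        list(sWindow = c(sMin, sMax),
                             minSize = minSize)))
}
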