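#' Simulate an ATP-dependence series of opening time constants
#'
#' Mean time constants follow the steady-state hyperbola
#' \eqn{\tau(S) = \tau_{min} (1 + K / S)}: opening slows as ATP becomes
#' sub-saturating, with half-maximal rate at \eqn{S = K}. Replicates
#' scatter log-normally at the configured coefficient of variation.
#'
#' @param tauMin limiting time constant at saturating ATP (s)
#' @param K half-saturation concentration (same units as \code{atp})
#' @param atp vector of ATP concentrations (> 0)
#' @param cv coefficient of variation of replicate scatter
#' @param n replicates per concentration
#' @param seed integer seed
#' @return data.frame (atp, tau)
#' @examples
#' head(makeAtpSeries(0.010, 0.056, c(0.05, 0.5), n = 3, seed = 1))
#' @export
makeAtpSeries <- function(tauMin, K, atp, cv = 0.1, n = 50, seed = 1L) {
  stopifnot(tauMin > 0, K > 0)
  if (any(atp <= 0))
    stop("configuration error: ATP concentrations must be > 0")
  withSeed(seed, {
    s <- rep(atp, each = n)
    mu <- tauMin * (1 + K / s)
    sdlog <- sqrt(log(1 + cv^2))
    data.frame(atp = s,
               tau = rlnorm(length(s), log(mu) - sdlog^2 / 2, sdlog))
  })
}

#' Simulate a temperature series of rate constants
#'
#' Arrhenius law: \eqn{\ln k = \ln A + s / T} with slope
#' \eqn{s = -E_a / R} in Kelvin, plus log-normal scatter.
#'
#' @param lnA log pre-exponential factor
#' @param slope Arrhenius slope in Kelvin (\eqn{-E_a/R}; negative for a
#'   positive activation energy)
#' @param temperatures absolute temperatures (K)
#' @param cv coefficient of variation of replicate scatter
#' @param n replicates per temperature
#' @param seed integer seed
#' @return data.frame (temperature, k)
#' @export
makeTemperatureSeries <- function(lnA, slope, temperatures, cv = 0.05,
                                  n = 20, seed = 1L) {
  if (!length(temperatures))
    stop("configuration error: empty temperature grid")
  stopifnot(all(temperatures > 0))
  withSeed(seed, {
    tt <- rep(temperatures, each = n)
    mu <- exp(lnA + slope / tt)
    sdlog <- sqrt(log(1 + cv^2))
    data.frame(temperature = tt,
               k = rlnorm(length(tt), log(mu) - sdlog^2 / 2, sdlog))
  })
}
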