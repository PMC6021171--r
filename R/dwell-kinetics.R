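#' Photobleaching time distribution
#'
#' Maximum-likelihood exponential fit to the per-trace photobleaching
#' times (right-censored events — traces that never bleached within the
#' record — enter the likelihood through their observation time), plus
#' an empirical-histogram alternative. With fewer than 20 bleach events
#' only the nonparametric form is trusted and the fit is flagged.
#'
#' @param bleachTimes observed bleaching times (s) of bleached traces
#' @param censoredTimes observation times of traces without a bleach
#'   event
#' @param breaks optional histogram bin edges
#' @return object of class \code{PhotobleachPDF}: \code{rate},
#'   \code{mean}, empirical histogram, event count, flags; the survival
#'   function is available via \code{\link{pbSurvival}}
#' @export
photobleachPdf <- function(bleachTimes, censoredTimes = numeric(),
                           breaks = NULL) {
  if (!length(bleachTimes)) stop("no bleach events")
  stopifnot(all(bleachTimes > 0))
  n <- length(bleachTimes)
  flags <- character()
  if (n < 20) flags <- c(flags, "fewer than 20 events: parametric fit unreliable, use the empirical form")
  if (sd(bleachTimes) < 1e-12) {
    flags <- c(flags, "degenerate: all bleach times equal")
    rate <- NA_real_
  } else {
    rate <- n / (sum(bleachTimes) + sum(censoredTimes))
  }
  if (is.null(breaks))
    breaks <- seq(0, max(bleachTimes) * 1.05, length.out = 31)
  cnt <- tabulate(findInterval(bleachTimes, breaks,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  structure(list(rate = rate, mean = if (is.na(rate)) NA_real_
                                     else 1 / rate,
                 n = n,
                 hist = data.frame(mid = breaks[-length(breaks)] +
                                     diff(breaks) / 2,
                                   density = cnt / n / diff(breaks)),
                 breaks = breaks, flags = flags),
            class = "PhotobleachPDF")
}

#' Photobleaching survival probability
#' @param pb a \code{\link{photobleachPdf}} result
#' @param t times (s)
#' @param empirical use the empirical histogram instead of the
#'   exponential fit
#' @return P(bleach time > t)
#' @export
pbSurvival <- function(pb, t, empirical = FALSE) {
  stopifnot(inherits(pb, "PhotobleachPDF"))
  if (!empirical && !is.na(pb$rate)) return(exp(-pb$rate * t))
  w <- diff(pb$breaks)
  cdf <- cumsum(pb$hist$density * w)
  1 - approx(pb$breaks[-1], cdf, xout = t, yleft = 0, yright = 1,
             rule = 2)$y
}

#' @export
print.PhotobleachPDF <- function(x, ...) {
  cat(sprintf("PhotobleachPDF: %d events, exponential mean %.3g s%s\n",
              x$n, x$mean,
              if (length(x$flags)) paste0(" [", x$flags[1], "]")
              else ""))
  invisible(x)
}

#' Photobleaching correction of a dwell-time distribution
#'
#' Bleaching right-censors dwell observation: a dwell is seen complete
#' only if it ends before the dye bleaches, so the density of complete
#' observed dwells is the true density tilted by the bleaching survival
#' function, \eqn{P_{measured}(t) \propto
#' P_{estimate}(t)\,S_{bleach}(t)}. This routine recovers the
#' uncensored gamma-form dwell law by maximum likelihood under the
#' tilted density (the binned least-squares distance between the
#' tilted model and the empirical histogram is reported as a
#' goodness-of-fit diagnostic), and also
#' returns a regularised nonparametric reconstruction (empirical
#' density divided by the survival function, smoothed by a
#' second-difference penalty, clipped at zero and renormalised).
#'
#' @param dwells complete (uncensored) observed dwell times (s)
#' @param pb a \code{\link{photobleachPdf}}
#' @param breaks optional histogram bin edges
#' @param regularization second-difference smoothing weight for the
#'   nonparametric reconstruction (default 1e-3)
#' @return object of class \code{DwellDeconvolution}: gamma
#'   \code{shape} and \code{scale}, corrected \code{mean}, corrected
#'   histogram (parametric and nonparametric), convergence and
#'   identifiability flags
#' @export
deconvolveDwells <- function(dwells, pb, breaks = NULL,
                             regularization = 1e-3) {
  stopifnot(inherits(pb, "PhotobleachPDF"))
  dwells <- dwells[!is.na(dwells)]
  if (!length(dwells)) stop("empty dwell set")
  stopifnot(all(dwells > 0))
  if (is.null(breaks))
    breaks <- seq(0, max(dwells) * 1.1, length.out = 31)
  w <- diff(breaks)
  mids <- breaks[-length(breaks)] + w / 2
  cnt <- tabulate(findInterval(dwells, breaks,
                               rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  emp <- cnt / sum(cnt) / w
  S <- pbSurvival(pb, mids)
  # likelihood under the tilted density f(t) S(t) / Z with the
  # normaliser computed on a fine grid (general for empirical S)
  grid <- seq(0, max(dwells) * 4, length.out = 2048)
  gw <- grid[2] - grid[1]
  Sg <- pbSurvival(pb, grid)
  logS_obs <- log(pmax(pbSurvival(pb, dwells), 1e-300))
  n <- length(dwells)
  nll <- function(p) {
    k <- exp(p[1]); th <- exp(p[2])
    Z <- sum(dgamma(grid, shape = k, scale = th) * Sg) * gw
    if (!is.finite(Z) || Z <= 0) return(1e10)
    -(sum(dgamma(dwells, shape = k, scale = th, log = TRUE)) +
        sum(logS_obs) - n * log(Z))
  }
  mu <- mean(dwells); v <- var(dwells)
  st <- c(log(max(mu^2 / max(v, 1e-12), 0.2)),
          log(max(v / mu, 1e-6)))
  fit <- optim(st, nll, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  shape <- exp(fit$par[1]); scale <- exp(fit$par[2])
  flags <- character()
  if (fit$convergence != 0)
    flags <- c(flags, "optimizer did not converge")
  # binned least-squares distance of the tilted fit, as a diagnostic
  mfit <- dgamma(mids, shape = shape, scale = scale) * S
  mtot <- sum(mfit * w)
  lsResid <- if (mtot > 0) sum((mfit / mtot - emp)^2) else NA_real_
  if (!is.na(pb$mean) && pb$mean < mu)
    flags <- c(flags, "weakly identifiable: bleaching faster than dwells")
  # nonparametric: divide out the survival, then ridge-smooth
  x0 <- emp / pmax(S, 1e-6)
  nb <- length(x0)
  D <- diff(diag(nb), differences = 2)
  x <- solve(diag(nb) + regularization * nb^2 * crossprod(D), x0)
  x <- pmax(x, 0)
  if (sum(x * w) > 0) x <- x / sum(x * w)
  par_dens <- dgamma(mids, shape = shape, scale = scale)
  structure(list(shape = shape, scale = scale, mean = shape * scale,
                 hist = data.frame(mid = mids, observed = emp,
                                   corrected = par_dens,
                                   corrected_np = as.vector(x)),
                 breaks = breaks, residual = lsResid,
                 logLik = -fit$value, flags = flags, pb = pb),
            class = "DwellDeconvolution")
}

#' @export
print.DwellDeconvolution <- function(x, ...) {
  cat(sprintf("DwellDeconvolution: gamma(shape %.3g, scale %.3g), corrected mean %.3g s%s\n",
              x$shape, x$scale, x$mean,
              if (length(x$flags)) paste0(" [",
                paste(x$flags, collapse = "; "), "]") else ""))
  invisible(x)
}

#' Photobleaching-corrected per-dwell times
#'
#' Maps each complete observed dwell onto the corrected distribution by
#' quantile matching: the empirical (bleach-tilted) CDF value of each
#' dwell is carried to the quantile of the deconvolved gamma law. The
#' mapped sample has the corrected distribution, so downstream
#' regressions can use every dwell as a data point.
#'
#' @param dwells complete observed dwell times (s)
#' @param deconv a \code{\link{deconvolveDwells}} result
#' @return corrected dwell times (s), same length and order
#' @export
correctDwellTimes <- function(dwells, deconv) {
  stopifnot(inherits(deconv, "DwellDeconvolution"))
  tmax <- max(dwells, deconv$breaks) * 2
  grid <- seq(0, tmax, length.out = 2048)
  f <- dgamma(grid, shape = deconv$shape, scale = deconv$scale) *
    pbSurvival(deconv$pb, grid)
  cdf <- cumsum(f) - f / 2
  cdf <- cdf / cdf[length(cdf)]
  u <- approx(grid, cdf, xout = dwells, rule = 2)$y
  qgamma(pmin(pmax(u, 1e-9), 1 - 1e-9), shape = deconv$shape,
         scale = deconv$scale)
}

#' Gamma fit of dwell times
#'
#' Maximum-likelihood gamma fit with a Kolmogorov-Smirnov
#' goodness-of-fit statistic. Censored dwells are excluded upstream;
#' exponential dwells come back with shape ~ 1.
#'
#' @param dwells positive dwell times (s); >= 30 recommended
#' @return list of class \code{GammaFit}: shape, scale (and SEs), mean,
#'   KS statistic and p-value, flags
#' @export
fitGammaDwells <- function(dwells) {
  dwells <- dwells[!is.na(dwells)]
  if (any(dwells <= 0)) stop("data error: non-positive dwell time")
  flags <- character()
  if (length(dwells) < 30)
    flags <- c(flags, "fewer than 30 dwells")
  if (sd(dwells) / mean(dwells) < 1e-3) {
    return(structure(list(shape = Inf, scale = 0,
                          mean = mean(dwells), se = c(NA, NA),
                          ks = NA, ks_p = NA,
                          flags = c(flags, "degenerate: near-constant dwells")),
                     class = "GammaFit"))
  }
  fd <- suppressWarnings(MASS::fitdistr(dwells, "gamma"))
  shape <- unname(fd$estimate["shape"])
  scale <- 1 / unname(fd$estimate["rate"])
  ks <- suppressWarnings(ks.test(dwells, "pgamma", shape = shape,
                                 rate = 1 / scale))
  structure(list(shape = shape, scale = scale, mean = shape * scale,
                 se = c(shape = unname(fd$sd["shape"]),
                        rate = unname(fd$sd["rate"])),
                 ks = unname(ks$statistic), ks_p = ks$p.value,
                 flags = flags),
            class = "GammaFit")
}

#' @export
print.GammaFit <- function(x, ...) {
  cat(sprintf("GammaFit: shape %.3g, scale %.3g s (mean %.3g s), KS %.3g\n",
              x$shape, x$scale, x$mean, x$ks))
  invisible(x)
}

#' Substrate-length regression of dwell times
#'
#' Ordinary least squares of individual (photobleaching-corrected)
#' open-state dwell times against substrate length, every dwell a data
#' point. The slope is the mean translocation time per residue, its
#' reciprocal the translocation rate in aa/s, and the intercept the
#' length-independent dwell component.
#'
#' @param data data.frame with columns \code{length} (aa) and
#'   \code{dwell} (s)
#' @param weights optional per-point weights (the default, NULL, is the
#'   unweighted regression)
#' @return object of class \code{RateFit}: slope (s/aa) and intercept
#'   (s) with SEs, rate = 1/slope (aa/s) with propagated SE, per-length
#'   dwell counts, flags
#' @examples
#' d <- data.frame(length = rep(c(100, 233, 354, 683), each = 2))
#' d$dwell <- 0.5 + d$length / 40
#' fitLengthDependence(d)
#' @export
fitLengthDependence <- function(data, weights = NULL) {
  stopifnot(all(c("length", "dwell") %in% names(data)))
  if (length(unique(data$length)) < 2)
    stop("single substrate length: report mean dwells instead of a ",
         "length regression")
  fit <- lm(dwell ~ length, data = data, weights = weights)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  slope <- unname(cf["length"]); slopeSE <- unname(se["length"])
  flags <- character()
  rate <- NA_real_; rateSE <- NA_real_
  if (slope <= 0) {
    flags <- c(flags, "non-positive slope: rate undefined")
  } else {
    rate <- 1 / slope
    rateSE <- slopeSE / slope^2
    if (slope < 2 * slopeSE)
      flags <- c(flags, "slope not distinguishable from 0")
  }
  structure(list(slope = slope, slopeSE = slopeSE,
                 intercept = unname(cf["(Intercept)"]),
                 interceptSE = unname(se["(Intercept)"]),
                 rate = rate, rateSE = rateSE,
                 nPerLength = table(data$length), fit = fit,
                 flags = flags),
            class = "RateFit")
}

#' @export
print.RateFit <- function(x, ...) {
  cat(sprintf("RateFit: slope %.4g +/- %.2g s/aa -> rate %.3g +/- %.2g aa/s\n",
              x$slope, x$slopeSE, x$rate, x$rateSE))
  cat(sprintf("  intercept %.3g +/- %.2g s\n", x$intercept,
              x$interceptSE))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = "; "),
                           "\n")
  invisible(x)
}

#' Steady-state ATP model of the mean open dwell
#'
#' Fits \eqn{dwell(S) = A (1 + K_M / S)} with \eqn{K_M} fixed (default
#' 50 uM = 0.05 mM) and only the amplitude free, mirroring the
#' scaled steady-state curve laid over dwell-vs-ATP data.
#'
#' @param data data.frame with columns \code{atp} and \code{dwell}
#' @param KM fixed Michaelis constant, same units as \code{atp}
#'   (default 0.05, i.e. 50 uM in mM)
#' @return list of class \code{DwellAtpFit}: amplitude A with SE, KM,
#'   fitted curve function
#' @export
fitDwellAtpModel <- function(data, KM = 0.05) {
  stopifnot(all(c("atp", "dwell") %in% names(data)))
  if (any(data$atp <= 0)) stop("data error: non-positive concentration")
  if (length(unique(data$atp)) < 2) stop("need >= 2 ATP levels")
  x <- 1 + KM / data$atp
  fit <- lm(dwell ~ 0 + x, data = data.frame(dwell = data$dwell, x = x))
  A <- unname(coef(fit)[1]); se <- unname(sqrt(diag(vcov(fit)))[1])
  structure(list(A = A, A_SE = se, KM = KM,
                 curve = function(s) A * (1 + KM / s), fit = fit),
            class = "DwellAtpFit")
}

#' @export
print.DwellAtpFit <- function(x, ...) {
  cat(sprintf("DwellAtpFit: A = %.3g +/- %.2g s at fixed KM = %.3g\n",
              x$A, x$A_SE, x$KM))
  invisible(x)
}
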