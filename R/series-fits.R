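#' Hyperbolic ATP dependence of a transition time constant
#'
#' Weighted least-squares fit of the steady-state model
#' \eqn{\tau(S) = \tau_{min}(1 + K/S)}: the transition time constant
#' saturates at \eqn{\tau_{min}} at high ATP and doubles at
#' \eqn{S = K} (the half-maximal-rate concentration).
#'
#' @param data data.frame with columns \code{atp} and \code{tau}
#' @param weights optional per-point weights
#' @return list of class \code{AtpFit} with \code{tauMin}, \code{K},
#'   standard errors, 95\% confidence intervals and the \code{nls}
#'   object
#' @examples
#' d <- makeAtpSeries(0.010, 0.056,
#'                    c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2), seed = 2)
#' fitAtpDependence(d)$K
#' @export
fitAtpDependence <- function(data, weights = NULL) {
  stopifnot(all(c("atp", "tau") %in% names(data)))
  if (any(data$atp <= 0)) stop("data error: non-positive concentration")
  if (length(unique(data$atp)) < 3) stop("need >= 3 ATP levels")
  # the model is linear in 1/S: tau = tauMin + (tauMin K) / S, which
  # gives closed-form starting values
  lin <- coef(lm(tau ~ I(1 / atp), data = data))
  st <- list(tauMin = max(unname(lin[1]), 1e-9),
             K = max(unname(lin[2]) / max(unname(lin[1]), 1e-9), 1e-9))
  args <- list(tau ~ tauMin * (1 + K / atp), data = data, start = st)
  if (!is.null(weights)) args$weights <- weights
  fit <- do.call(minpack.lm::nlsLM, args)
  cf <- coef(fit); se <- sqrt(diag(vcov(fit)))
  structure(list(tauMin = unname(cf["tauMin"]), K = unname(cf["K"]),
                 se = setNames(se, names(cf)),
                 ci95 = rbind(tauMin = cf["tauMin"] +
                                c(-1, 1) * 1.96 * se["tauMin"],
                              K = cf["K"] + c(-1, 1) * 1.96 * se["K"]),
                 fit = fit),
            class = "AtpFit")
}

#' @export
print.AtpFit <- function(x, ...) {
  cat(sprintf("ATP dependence: tau_min = %.4g (SE %.2g), K = %.4g (SE %.2g)\n",
              x$tauMin, x$se["tauMin"], x$K, x$se["K"]))
  invisible(x)
}

#' Arrhenius fit of rate constants
#'
#' Linear fit of \eqn{\ln k} against \eqn{1/T}; the activation energy is
#' \eqn{E_a = -\mathrm{slope} \cdot R} with R = 8.314 J/mol/K.
#'
#' @param data data.frame with columns \code{temperature} (K) and
#'   \code{k} (> 0)
#' @return list of class \code{ArrheniusFit} with \code{Ea_kJmol},
#'   \code{lnA}, standard errors, 95\% CI on Ea, slope and the \code{lm}
#'   object
#' @export
fitArrhenius <- function(data) {
  stopifnot(all(c("temperature", "k") %in% names(data)))
  if (any(data$k <= 0)) stop("data error: rate constants must be > 0")
  if (length(unique(data$temperature)) < 2)
    stop("need >= 2 temperatures")
  fit <- lm(log(k) ~ I(1 / temperature), data = data)
  R <- 8.314
  sl <- coef(fit)[2]; se <- sqrt(diag(vcov(fit)))[2]
  ea <- -sl * R / 1e3
  se_ea <- se * R / 1e3
  structure(list(Ea_kJmol = unname(ea), lnA = unname(coef(fit)[1]),
                 slope_K = unname(sl),
                 se = c(Ea_kJmol = unname(se_ea),
                        lnA = unname(sqrt(diag(vcov(fit)))[1])),
                 ci95_Ea = unname(ea + c(-1, 1) * 1.96 * se_ea),
                 fit = fit),
            class = "ArrheniusFit")
}

#' @export
print.ArrheniusFit <- function(x, ...) {
  cat(sprintf("Arrhenius: Ea = %.1f kJ/mol (SE %.2f), lnA = %.2f\n",
              x$Ea_kJmol, x$se["Ea_kJmol"], x$lnA))
  invisible(x)
}
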