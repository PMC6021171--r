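#' Two-state plug model
#'
#' Parameters of the two-state (open/closed) emitter: FRET efficiencies of
#' the two plug conformations, interconversion rates, and the brightness
#' ratio between the states. The sum \code{kOpen + kClose} is the
#' relaxation rate constant recovered by the recurrence analysis.
#'
#' @param eOpen FRET efficiency of the open state (default 0.2)
#' @param eClosed FRET efficiency of the closed state (default 0.4)
#' @param kOpen opening rate constant, closed to open (1/s)
#' @param kClose closing rate constant, open to closed (1/s)
#' @param brightnessRatio ratio of mean detected count rate of the open
#'   state to the closed state (dimensionless, default 1)
#' @return a validated list of class \code{TwoStateModel}
#' @export
twoStateModel <- function(eOpen = 0.2, eClosed = 0.4, kOpen = 0,
                          kClose = 0, brightnessRatio = 1) {
  stopifnot(eOpen >= 0, eOpen <= 1, eClosed >= 0, eClosed <= 1,
            kOpen >= 0, kClose >= 0, brightnessRatio > 0)
  structure(list(eOpen = eOpen, eClosed = eClosed, kOpen = kOpen,
                 kClose = kClose, brightnessRatio = brightnessRatio),
            class = "TwoStateModel")
}

#' Confocal simulation configuration
#'
#' Geometry, photophysics and timing of the diffusing-vesicle usALEX
#' simulation. Defaults emulate 100 nm proteoliposomes in water at 25 C
#' (Stokes-Einstein D ~ 4.4 um^2/s) observed in a confocal volume with
#' 0.35 um lateral / 1.5 um axial 1/e^2 waists, at a dilution where
#' recurrence of the same particle dominates over new arrivals. The
#' alternation period is 40 us with a 40% donor duty cycle.
#'
#' @param diffusionCoefficient particle diffusion coefficient (um^2/s)
#' @param waistLateral,waistAxial 1/e^2 radii of the 3D-Gaussian
#'   detection profile (um)
#' @param boxFactor periodic box size as a multiple of each waist
#' @param nParticles number of particles in the box
#' @param peakRateDex detected count rate at focus under donor
#'   excitation, closed state (photons/s)
#' @param peakRateAex detected acceptor count rate at focus under
#'   acceptor excitation (photons/s); the default gives stoichiometry
#'   ~0.5 for a doubly labelled particle at a 40% duty cycle
#' @param bgDonor,bgAcceptor continuous background rates per detection
#'   channel (photons/s)
#' @param alternationPeriod ALEX alternation period (s)
#' @param dutyCycle donor-laser duty cycle
#' @param clockRate timestamp clock (ticks/s)
#' @param diffusionStep Brownian time step (s)
#' @param duration simulated time (s)
#' @param startState "stationary", "closed" or "open"
#' @param startAtFocus logical; start all particles at the focus (for
#'   closed-form checks with immobile particles)
#' @param seed integer seed
#' @return a validated list of class \code{ConfocalSimConfig}
#' @export
confocalSimConfig <- function(diffusionCoefficient = 4.4,
                              waistLateral = 0.35, waistAxial = 1.5,
                              boxFactor = 10, nParticles = 3,
                              peakRateDex = 150e3,
                              peakRateAex = peakRateDex * 2 / 3,
                              bgDonor = 1000, bgAcceptor = 1000,
                              alternationPeriod = 40e-6,
                              dutyCycle = 0.4, clockRate = 1e7,
                              diffusionStep = 10e-6, duration = 10,
                              startState = "stationary",
                              startAtFocus = FALSE, seed = 1L) {
  if (duration <= 0) stop("configuration error: duration must be > 0")
  if (clockRate <= 0 || diffusionStep <= 0)
    stop("configuration error: clock resolution and diffusion step must ",
         "be > 0")
  stopifnot(diffusionCoefficient >= 0, peakRateDex >= 0, peakRateAex >= 0,
            bgDonor >= 0, bgAcceptor >= 0, dutyCycle > 0, dutyCycle < 1,
            nParticles >= 0)
  startState <- match.arg(startState, c("stationary", "closed", "open"))
  structure(list(diffusionCoefficient = diffusionCoefficient,
                 waistLateral = waistLateral, waistAxial = waistAxial,
                 boxFactor = boxFactor, nParticles = nParticles,
                 peakRateDex = peakRateDex, peakRateAex = peakRateAex,
                 bgDonor = bgDonor, bgAcceptor = bgAcceptor,
                 alternationPeriod = alternationPeriod,
                 dutyCycle = dutyCycle, clockRate = clockRate,
                 diffusionStep = diffusionStep, duration = duration,
                 startState = startState, startAtFocus = startAtFocus,
                 seed = as.integer(seed)),
            class = "ConfocalSimConfig")
}

#' Simulate a diffusing two-state usALEX photon stream
#'
#' Particles perform Brownian motion in a periodic box (re-entering the
#' detection volume and so producing recurrence trains), switch between
#' the open and closed plug conformations as a continuous-time Markov
#' chain, and emit photons as an inhomogeneous Poisson process whose rate
#' follows the 3D-Gaussian detection profile. Under donor excitation,
#' photons fall on the acceptor detector with probability equal to the
#' current state's FRET efficiency; under acceptor excitation the
#' acceptor is excited directly. Continuous per-channel background is
#' added. Ground truth (per-photon particle identity and state, and the
#' full state path) is retained alongside.
#'
#' @param model a \code{\link{twoStateModel}}
#' @param cfg a \code{\link{confocalSimConfig}}
#' @return a \code{\linkS4class{PhotonStream}} with ground-truth columns
#'   and a \code{truth} list (state path, duration, config)
#' @examples
#' st <- simulateConfocalPhotons(
#'   twoStateModel(kOpen = 50, kClose = 50),
#'   confocalSimConfig(duration = 1, seed = 7))
#' st
#' @export
simulateConfocalPhotons <- function(model, cfg) {
  stopifnot(inherits(model, "TwoStateModel"),
            inherits(cfg, "ConfocalSimConfig"))
  start_state <- switch(cfg$startState, stationary = -1L, closed = 0L,
                        open = 1L)
  res <- withSeed(cfg$seed,
    cpp_simulate_confocal(
      n_particles = cfg$nParticles,
      box_x = cfg$boxFactor * cfg$waistLateral,
      box_y = cfg$boxFactor * cfg$waistLateral,
      box_z = cfg$boxFactor * cfg$waistAxial,
      D = cfg$diffusionCoefficient, dt = cfg$diffusionStep,
      wxy = cfg$waistLateral, wz = cfg$waistAxial,
      peak_rate_dex = cfg$peakRateDex, peak_rate_aex = cfg$peakRateAex,
      e_open = model$eOpen, e_closed = model$eClosed,
      k_open = model$kOpen, k_close = model$kClose,
      eps_brightness = model$brightnessRatio,
      bg_donor = cfg$bgDonor, bg_acceptor = cfg$bgAcceptor,
      alt_period = cfg$alternationPeriod, duty = cfg$dutyCycle,
      duration = cfg$duration, start_state = start_state,
      start_at_focus = cfg$startAtFocus))
  tick <- round(res$time_s * cfg$clockRate)
  # enforce strictly sorted ticks after rounding
  ord <- order(tick)
  PhotonStream(tick = tick[ord], channel = res$channel[ord],
               slot = as.integer((tick[ord] %%
                 (cfg$alternationPeriod * cfg$clockRate)) >=
                 cfg$dutyCycle * cfg$alternationPeriod * cfg$clockRate),
               clockRate = cfg$clockRate,
               alternationPeriod = cfg$alternationPeriod * cfg$clockRate,
               dutyCycle = cfg$dutyCycle,
               particle = res$particle[ord], state = res$state[ord],
               truth = list(duration = cfg$duration,
                            statePath = data.frame(
                              particle = res$truth_particle,
                              time_s = res$truth_time,
                              state = res$truth_state),
                            model = model, config = cfg))
}
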