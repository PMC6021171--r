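makeTraceSet <- function(frames, framePeriod = 0.2) {
  new("TirfTraceSet", frames = frames, framePeriod = framePeriod,
      truth = list(), qc = data.frame())
}

test_that("frame-wise E and S evaluate the burst formulas", {
  fr <- data.frame(trace_id = 1L, time_s = c(0.1, 0.3, 0.5),
                   I_DD = c(100, 100, 0), I_DA = c(100, 0, 0),
                   I_AA = c(200, 100, 100))
  tr <- traceES(makeTraceSet(fr))
  d <- frameData(tr)
  expect_equal(d$E[1], 0.5)
  expect_equal(d$S[1], 0.5)
  expect_equal(d$E[2], 0)
  expect_true(is.na(d$E[3]))   # post-donor-bleach frame
  # identity corrections equal the raw ratio
  d2 <- frameData(traceES(makeTraceSet(fr), correctionFactors()))
  expect_equal(d2$E[1:2], d$E[1:2])
})

test_that("QC excludes single-dye and double-labelled traces", {
  cfg <- tirfSimConfig(seed = 2, snr = 30)
  good <- tirfTraceFromDwells(c("closed", "open", "closed"),
                              c(6, 8, 10), cfg, noise = TRUE,
                              bleachDonor = 22, traceId = 1L)
  # donor-only species: no acceptor signal at all, S ~ 1
  donorOnly <- good
  donorOnly$trace_id <- 2L
  donorOnly$I_DA <- rnorm(nrow(good), 0, 0.03)
  donorOnly$I_AA <- rnorm(nrow(good), 0, 0.03)
  donorOnly$I_DD <- 1 + rnorm(nrow(good), 0, 0.03)
  # two-step donor drop (double labelling)
  twoStep <- good
  twoStep$trace_id <- 3L
  half <- nrow(good) %/% 2
  scale <- rep(c(2, 1), c(half, nrow(good) - half))
  twoStep$I_DD <- twoStep$I_DD * scale
  twoStep$I_DA <- twoStep$I_DA * scale
  traces <- traceES(makeTraceSet(rbind(good, donorOnly, twoStep)))
  out <- qcTraces(traces)
  qc <- out@qc
  expect_true(qc$pass[qc$trace_id == 1])
  expect_false(qc$pass[qc$trace_id == 2])   # S outside the window
  expect_false(qc$pass[qc$trace_id == 3])   # multi-step bleach
  expect_true(qc$multiStep[qc$trace_id == 3])
  # the passing anticorrelated trace keeps a negative correlation
  expect_lt(qc$anticorr[qc$trace_id == 1], -0.3)
  # donor bleach time recorded near 22 s
  expect_equal(qc$bleach_s[qc$trace_id == 1], 22, tolerance = 1)
})

test_that("HMM segmentation recovers dwells exactly on noiseless traces", {
  cfg <- tirfSimConfig(seed = 3)
  fr <- tirfTraceFromDwells(c("closed", "open", "closed", "open"),
                            c(4, 6, 5, 7), cfg, noise = FALSE)
  tr <- traceES(makeTraceSet(fr))
  dw <- segmentStatesHmm(tr)
  expect_equal(dw$state, c("closed", "open", "closed", "open"))
  expect_equal(dw$duration_s, c(4, 6, 5, 7), tolerance = 0.21)
  expect_true(all(dw$responsive))
  expect_equal(dw$censored, c(FALSE, FALSE, FALSE, TRUE))
  # dwells tile the trace
  expect_equal(sum(dw$duration_s), nrow(fr) * 0.2, tolerance = 1e-9)
})

test_that("segmentation recovers dwell means from noisy simulations", {
  cfg <- tirfSimConfig(lengths = 100, rate = 40, offset = 0.5,
                       closedMean = 2, photobleachMean = 1e4,
                       nTraces = 12, maxDuration = 150, snr = 3,
                       seed = 4)
  tr <- traceES(simulateTirfTraces(cfg))
  dw <- segmentStatesHmm(tr)
  op <- dw$duration_s[dw$state == "open" & !dw$censored]
  truth <- 0.5 + 100 / 40
  expect_gt(length(op), 200)
  expect_lt(abs(mean(op) - truth) / truth, 0.10)
})

test_that("constant traces are non-responsive; short traces skipped", {
  cfg <- tirfSimConfig(seed = 5)
  fr <- tirfTraceFromDwells("closed", 30, cfg, noise = TRUE)
  dw <- segmentStatesHmm(traceES(makeTraceSet(fr)))
  expect_true(all(!dw$responsive))
  short <- fr[1:5, ]
  expect_equal(nrow(segmentStatesHmm(traceES(makeTraceSet(short)))),
               0L)
})

test_that("steady-state open fraction matches the rate ratio", {
  cfg <- tirfSimConfig(lengths = 40, rate = 40, offset = 2,
                       closedMean = 3, gammaShape = 1,
                       photobleachMean = 1e4, nTraces = 10,
                       maxDuration = 200, snr = 4, seed = 6)
  tr <- traceES(simulateTirfTraces(cfg))
  dw <- segmentStatesHmm(tr)
  occ <- sum(dw$duration_s[dw$state == "open"]) / sum(dw$duration_s)
  expect_lt(abs(occ - 0.5), 0.03)
})

test_that("orientation correction inverts the mixture exactly", {
  breaks <- seq(0, 1, by = 0.02)
  mids <- breaks[-51] + 0.01
  ref <- dnorm(mids, 0.4, 0.05); ref <- ref / sum(ref * 0.02)
  sig <- dnorm(mids, 0.2, 0.06); sig <- sig / sum(sig * 0.02)
  mix <- 0.5 * ref + 0.5 * sig
  rec <- correctOrientationHistogram(mix, ref, 0.5, binWidth = 0.02)
  expect_equal(rec, sig, tolerance = 1e-8)
  expect_equal(correctOrientationHistogram(mix, ref, 0,
                                           binWidth = 0.02), mix)
  expect_error(correctOrientationHistogram(mix, ref, 1), "fraction")
})

test_that("orientation correction is the mixture inverse for random shapes", {
  set.seed(71)
  breaks <- seq(0, 1, by = 0.02)
  mids <- breaks[-51] + 0.01
  for (i in 1:20) {
    f <- runif(1, 0.05, 0.9)
    ref <- runif(50); ref <- ref / sum(ref * 0.02)
    sig <- runif(50); sig <- sig / sum(sig * 0.02)
    mix <- f * ref + (1 - f) * sig
    rec <- correctOrientationHistogram(mix, ref, f, binWidth = 0.02)
    expect_equal(rec, sig, tolerance = 1e-6)
  }
})

test_that("orientation correction of counting-noise histograms", {
  set.seed(72)
  breaks <- seq(0, 1, by = 0.02)
  toDens <- function(x) {
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
                    nbins = 50)
    cnt / sum(cnt) / 0.02
  }
  ref <- toDens(rnorm(4000, 0.4, 0.05))
  mix <- toDens(c(rnorm(2000, 0.4, 0.05), rnorm(2000, 0.2, 0.05)))
  rec <- correctOrientationHistogram(mix, ref, 0.5, binWidth = 0.02)
  mids <- breaks[-51] + 0.01
  recMean <- sum(mids * rec * 0.02)
  expect_lt(abs(recMean - 0.2), 0.02)
})

test_that("two-Gaussian mixture fit recovers separated components", {
  set.seed(73)
  e <- c(rnorm(1500, 0.2, 0.05), rnorm(1500, 0.4, 0.05))
  fit <- fitGaussianMixture(e)
  expect_equal(fit$mean, c(0.2, 0.4), tolerance = 0.02)
  expect_equal(fit$weight[1], 0.5, tolerance = 0.05)
  expect_false(fit$overlap)
  single <- fitGaussianMixture(rnorm(1000, 0.3, 0.05))
  expect_true(single$overlap)
})
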