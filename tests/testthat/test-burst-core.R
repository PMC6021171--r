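test_that("photon stream files round-trip losslessly", {
  st <- simulateConfocalPhotons(twoStateModel(kOpen = 20, kClose = 20),
                                confocalSimConfig(duration = 0.5,
                                                  seed = 21))
  f <- tempfile(fileext = ".phstream")
  writePhotonStream(st, f)
  back <- readPhotonStream(f)
  expect_identical(photonData(back)$tick, photonData(st)$tick)
  expect_identical(photonData(back)$channel, photonData(st)$channel)
  expect_identical(photonData(back)$slot, photonData(st)$slot)
  expect_equal(clockRate(back), clockRate(st))
})

test_that("streams without metadata or with unsorted photons are rejected", {
  f <- tempfile()
  writeLines(c("tick\tchannel\tslot", "1\t0\t0"), f)
  expect_error(readPhotonStream(f), "metadata")
  st <- PhotonStream(tick = c(0, 100, 200), channel = c(0, 1, 0),
                     clockRate = 1e7, alternationPeriod = 400)
  writePhotonStream(st, f)
  tab <- readLines(f)
  tab <- c(tab[1:2], tab[4], tab[3], tab[5])  # swap two photons
  writeLines(tab, f)
  expect_error(readPhotonStream(f), "sorted")
  # per-photon slots substitute for missing alternation metadata
  f2 <- tempfile()
  writeLines(c(paste0("#photon-stream ", '{"clock_rate":1e7}'),
               "tick\tchannel\tslot", "0\t0\t0", "150\t1\t0",
               "250\t1\t1"), f2)
  ok <- readPhotonStream(f2)
  expect_equal(photonData(ok)$slot, c(0L, 0L, 1L))
  # but a file with neither is rejected
  writeLines(c(paste0("#photon-stream ", '{"clock_rate":1e7}'),
               "tick\tchannel", "0\t0", "150\t1"), f2)
  expect_error(readPhotonStream(f2), "slots")
  # in-memory construction enforces the same invariant
  expect_error(validObject(
    PhotonStream(tick = c(10, 5), channel = c(0, 0), clockRate = 1e7,
                 alternationPeriod = 400)), "monotone")
})

test_that("background MLE recovers Poisson rates per segment", {
  set.seed(31)
  t1 <- cumsum(rexp(30000, 3000))            # 3 kHz for ~10 s
  t2 <- max(t1) + cumsum(rexp(15000, 1500))  # then 1.5 kHz
  tick <- round(c(t1, t2) * 1e7)
  st <- PhotonStream(tick = tick,
                     channel = rbinom(length(tick), 1, 0.5),
                     clockRate = 1e7, alternationPeriod = 400,
                     truth = list(duration = max(tick) / 1e7))
  bg <- estimateBackground(st, window = 5)
  mids <- bg$breaks[-length(bg$breaks)] + diff(bg$breaks) / 2
  tot <- rowSums(bg$rates[, c("DexDem", "DexAem", "AexAem", "AexDem")])
  seg1 <- mean(tot[mids < max(t1) - 2])
  seg2 <- mean(tot[mids > max(t1) + 2])
  expect_lt(abs(seg1 - 3000) / 3000, 0.05)
  expect_lt(abs(seg2 - 1500) / 1500, 0.08)
  expect_error(estimateBackground(
    PhotonStream(numeric(), integer(), integer(), clockRate = 1e7,
                 alternationPeriod = 400)), "empty")
})

test_that("DCBS finds a dense two-channel cluster and nothing else", {
  # brute-force oracle: 100 photons in 10 ms inside 10 s of 100 Hz
  # background; the cluster rate (10 kHz) is far above F x background
  st <- fixtureStream(duration = 10, bgRate = 100,
                      clusters = list(list(t0 = 5, n = 100,
                                           duration = 0.01)))
  bg <- estimateBackground(st, window = 10)
  bursts <- searchBurstsDCBS(st, bg, m = 10, F = 6)
  expect_equal(nBursts(bursts), 1L)
  b <- burstData(bursts)
  expect_gte(b$n_DD + b$n_DA + b$n_AA, 90)
  # sliding windows may attach a short tail of background photons
  expect_true(b$t_start >= 4.95 && b$t_stop <= 5.06)
})

test_that("donor-excitation-only clusters yield no DCBS bursts", {
  st <- fixtureStream(duration = 10, bgRate = 100,
                      clusters = list(list(t0 = 5, n = 100,
                                           duration = 0.01)),
                      clusterChannels = "dex-only")
  bg <- estimateBackground(st, window = 10)
  expect_equal(nBursts(searchBurstsDCBS(st, bg)), 0L)
})

test_that("pure background produces no false bursts at defaults", {
  set.seed(33)
  tick <- sort(round(runif(10000, 0, 10) * 1e7))
  tick <- tick[!duplicated(tick)]
  st <- PhotonStream(tick = tick,
                     channel = rbinom(length(tick), 1, 0.5),
                     clockRate = 1e7, alternationPeriod = 400,
                     truth = list(duration = 10))
  bg <- estimateBackground(st, window = 10)
  expect_equal(nBursts(searchBurstsDCBS(st, bg)), 0L)
})

test_that("burst search is invariant to a constant timestamp shift", {
  st <- fixtureStream(duration = 10, bgRate = 100,
                      clusters = list(list(t0 = 3, n = 120,
                                           duration = 0.012)))
  ph <- photonData(st)
  st2 <- PhotonStream(tick = ph$tick + 40000 * 25, channel = ph$channel,
                      clockRate = clockRate(st),
                      alternationPeriod = 400,
                      truth = list(duration = 10.1))
  b1 <- burstData(searchBurstsDCBS(st, estimateBackground(st, 10)))
  b2 <- burstData(searchBurstsDCBS(st2, estimateBackground(st2, 10)))
  expect_equal(nrow(b1), nrow(b2))
  expect_equal(b2$t_start - b1$t_start,
               rep(0.1, nrow(b1)), tolerance = 1e-6)
  expect_equal(b1$n_DD + b1$n_DA, b2$n_DD + b2$n_DA)
})

test_that("burst search parameter validation", {
  st <- fixtureStream(duration = 2, bgRate = 100)
  bg <- estimateBackground(st, 2)
  expect_error(searchBurstsDCBS(st, bg, m = 1), "m must be")
  expect_error(searchBurstsDCBS(st, bg, F = 1), "F must be")
})

test_that("detected bursts overlap true focal transits", {
  # precision property: photon spans of detected bursts align with
  # periods where a particle is actually near the focus
  st <- simulateConfocalPhotons(
    twoStateModel(),
    confocalSimConfig(duration = 60, seed = 22))
  bg <- estimateBackground(st, 10)
  bursts <- searchBurstsDCBS(st, bg)
  b <- burstData(bursts)
  ph <- photonData(st)
  frac_signal <- vapply(seq_len(nrow(b)), function(i) {
    p <- ph$particle[b$i_first[i]:b$i_last[i]]
    mean(p > 0)
  }, numeric(1))
  expect_gt(mean(frac_signal > 0.5), 0.95)
})

test_that("E, S and the correction formula evaluate as specified", {
  b <- fixtureBursts(t = c(1, 2, 3), E = c(0, 0, 0))
  bb <- b@bursts
  bb$n_DD <- c(50L, 80L, 90L); bb$n_DA <- c(50L, 0L, 10L)
  bb$n_AA <- c(100L, 20L, 100L)
  bb$E <- bb$S <- bb$PR <- NULL
  bset <- initialize(b, bursts = bb)
  es <- burstData(computeBurstES(bset))
  expect_equal(es$PR, c(0.5, 0, 0.1))
  expect_equal(es$S[1], 0.5)
  # hand evaluation: l = 0.1, d = 0, gamma = 1:
  # E = (10 - 9) / (90 + 10 - 9) = 1/91
  esc <- burstData(computeBurstES(bset,
                                  correctionFactors(leakage = 0.1)))
  expect_equal(esc$E[3], 1 / 91, tolerance = 1e-12)
  # identity corrections leave PR unchanged
  es0 <- burstData(computeBurstES(bset, correctionFactors()))
  expect_equal(es0$E, es$PR)
})

test_that("zero donor-excitation signal flags the burst", {
  b <- fixtureBursts(1, 0)
  bb <- b@bursts
  bb$n_DD <- 0L; bb$n_DA <- 0L; bb$n_AA <- 50L
  bb$E <- bb$S <- bb$PR <- NULL
  es <- burstData(computeBurstES(initialize(b, bursts = bb)))
  expect_true(es$flagged)
  expect_true(is.na(es$PR))
})

test_that("stoichiometry filter keeps the closed interval", {
  b <- fixtureBursts(t = 1:5, E = rep(0.3, 5))
  bb <- b@bursts
  bb$S <- c(0.2, 0.25, 0.5, 0.75, 0.8)
  bset <- initialize(b, bursts = bb)
  kept <- burstData(filterBursts(bset, minSize = 0))
  expect_equal(sort(kept$S), c(0.25, 0.5, 0.75))
  expect_warning(filterBursts(bset, minSize = 1e6), "no bursts")
  expect_error(filterBursts(bset, sMin = 0.8, sMax = 0.2), "sMin")
})

test_that("static species PR variance matches the binomial law", {
  # PR of a static emitter is binomial about its true E: compare the
  # observed variance with E(1-E)/n over many simulated bursts
  set.seed(41)
  n <- 80
  pr <- rbinom(2000, n, 0.3) / n
  expect_lt(abs(var(pr) - 0.3 * 0.7 / n) / (0.3 * 0.7 / n), 0.10)
})

test_that("burst TSV export round-trips the summary columns", {
  b <- fixtureBursts(t = c(1, 2), E = c(0.2, 0.4))
  f <- tempfile(fileext = ".tsv")
  writeBursts(b, f)
  back <- readBursts(f)
  expect_equal(burstData(back)$E, c(0.2, 0.4))
  expect_equal(burstData(back)$t_start, c(1, 2))
})
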