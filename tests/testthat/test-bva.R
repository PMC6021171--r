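test_that("sub-burst partitioning is exact integer division", {
  set.seed(61)
  b <- fixtureBurstSet(list(rep(0.3, 23), rep(0.3, 9)))
  part <- subdivideBursts(b, n = 5)
  expect_equal(unique(part$id), 1L)           # 9-photon burst excluded
  expect_equal(nrow(part), 4L)                 # 23 %/% 5
  expect_true(all(part$n == 5))
  expect_error(subdivideBursts(b, n = 1), "n must be")
})

test_that("window acceptor counts equal a brute-force recount", {
  set.seed(62)
  b <- fixtureBurstSet(list(rep(0.5, 40), rep(0.2, 25)))
  part <- subdivideBursts(b, n = 5)
  ph <- photonData(b@stream)
  for (i in unique(part$id)) {
    brow <- burstData(b)[i, ]
    acc <- ph$channel[brow$i_first:brow$i_last]
    ref <- vapply(split(acc[seq_len(5 * (length(acc) %/% 5))],
                        rep(seq_len(length(acc) %/% 5), each = 5)),
                  sum, integer(1))
    expect_equal(part$F_A[part$id == i], unname(ref))
  }
})

test_that("per-burst SD uses the population denominator", {
  part <- data.frame(id = c(1, 1, 2, 2), window = c(1, 2, 1, 2),
                     F_A = c(1, 2, 1, 1), n = 5,
                     E_p = c(0.2, 0.4, 0.3, 0.3))
  per <- burstSD(part)
  expect_equal(per$s_E, c(0.1, 0))   # population SD of {0.2, 0.4}
  expect_equal(per$E_p, c(0.3, 0.3))
})

test_that("shot-noise SD closed form", {
  expect_equal(shotNoiseSD(0.5, 100), 0.05)
  expect_equal(shotNoiseSD(0, 10), 0)
  expect_equal(shotNoiseSD(1, 10), 0)
  expect_equal(shotNoiseSD(0.2, 50), sqrt(0.2 * 0.8 / 50))
  expect_equal(round(shotNoiseSD(0.2, 50), 4), 0.0566)
  expect_error(shotNoiseSD(1.2, 10), "Ep")
})

test_that("MC threshold at alpha = 0.5 sits near the median", {
  set.seed(63)
  b <- fixtureBurstSet(replicate(30, rep(0.3, 25), simplify = FALSE))
  part <- subdivideBursts(b, n = 5)
  th50 <- mcConfidence(part, alpha = 0.5, nRep = 2001, seed = 1)
  th001 <- mcConfidence(part, alpha = 0.001, nRep = 2001, seed = 1)
  expect_true(all(th50$threshold < th001$threshold))
  expect_equal(th50$threshold, shotNoiseSD(th50$meanEp, 5),
               tolerance = 0.1)
  # shot noise vanishes with window size: thresholds shrink with n
  partBig <- subdivideBursts(fixtureBurstSet(
    replicate(30, rep(0.3, 500), simplify = FALSE)), n = 100)
  thBig <- mcConfidence(partBig, alpha = 0.5, nRep = 500, seed = 1)
  expect_lt(thBig$threshold[1], th50$threshold[1] / 3)
})

test_that("static mixtures stay on the shot-noise curve", {
  set.seed(64)
  paths <- lapply(1:120, function(i)
    rep(if (i %% 2) 0.2 else 0.4, 40))
  bva <- burstVarianceAnalysis(fixtureBurstSet(paths), n = 5,
                               nRep = 499, seed = 2)
  expect_true(all(!bva$bins$dynamic))
  tab <- classifyDynamics(bva)
  expect_true(all(tab$verdict == "static"))
})

test_that("within-burst switching is flagged dynamic in mid-range bins", {
  set.seed(65)
  # ~2 transitions per 100-photon burst between E 0.2 and 0.4; at
  # n = 5 the per-window shot noise is large, so detection relies on
  # the pooled per-bin statistic over many windows
  paths <- lapply(1:600, function(i) {
    state <- (i %% 2 == 0)
    out <- numeric(100)
    for (j in 1:100) {
      if (runif(1) < 0.02) state <- !state
      out[j] <- if (state) 0.4 else 0.2
    }
    out
  })
  bva <- burstVarianceAnalysis(fixtureBurstSet(paths), n = 5,
                               nRep = 1999, seed = 3)
  # mid-range = bins strictly between the two state efficiencies;
  # bins at the state peaks hold bursts that never switched
  mid <- bva$bins$L >= 0.25 & bva$bins$U <= 0.35 &
    bva$bins$nBursts >= 20
  expect_gt(sum(mid), 0)
  expect_gt(mean(bva$bins$dynamic[mid]), 0.8)
})

test_that("false-positive rate of the dynamic verdict is calibrated", {
  # static binomial bursts analysed over many seeds: the fraction of
  # bins called dynamic must not exceed twice the confidence level
  alpha <- 0.01
  flagged <- 0L; total <- 0L
  for (s in 1:100) {
    set.seed(1000 + s)
    paths <- lapply(1:40, function(i)
      rep(if (i %% 2) 0.25 else 0.45, 30))
    bva <- burstVarianceAnalysis(fixtureBurstSet(paths), n = 5,
                                 alpha = alpha, nRep = 499,
                                 seed = 2000 + s)
    flagged <- flagged + sum(bva$bins$dynamic)
    total <- total + nrow(bva$bins)
  }
  expect_lte(flagged / total, 2 * alpha)
})

test_that("a static sample probed at 0.1 ms sub-bursts stays static", {
  set.seed(66)
  paths <- lapply(1:80, function(i) rep(if (i %% 2) 0.2 else 0.4, 60))
  # photons every 20 us -> 0.1 ms windows hold ~5 photons
  b <- fixtureBurstSet(paths, photonSpacing = 2e-5)
  bva <- burstVarianceAnalysis(b, windowSeconds = 1e-4, nRep = 499,
                               seed = 4)
  expect_true(all(!bva$bins$dynamic))
})
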