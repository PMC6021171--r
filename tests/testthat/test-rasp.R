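test_that("P_same follows 1 - 1/g", {
  # direct evaluation of the identity on constructed autocorrelation
  # values, plus the clip at zero for anticorrelated lags
  curve <- structure(list(tau = c(0.01, 0.02, 0.03),
                          g = c(2, 1, 0.5),
                          p_same = pmax(0, 1 - 1 / c(2, 1, 0.5)),
                          pairs = c(10, 10, 10), rate = 1),
                     class = "SameMoleculeCurve")
  expect_equal(curve$p_same, c(0.5, 0, 0))
  expect_equal(pSameAt(curve, 0.01), 0.5)
})

test_that("Poisson burst times give g ~ 1 and P_same ~ 0", {
  set.seed(51)
  b <- fixtureBursts(t = sort(runif(5000, 0, 250)),
                     E = rep(0.3, 5000))
  curve <- burstAutocorrelation(b, tauMax = 0.1)
  expect_lt(mean(curve$p_same), 0.1)
  expect_lt(abs(mean(curve$g) - 1), 0.05)
})

test_that("recurrence pair selection matches exhaustive enumeration", {
  t <- c(0.00, 0.01, 0.02, 0.50, 0.52)
  E <- c(0.25, 0.45, 0.28, 0.27, 0.60)
  b <- fixtureBursts(t, E)
  oracle <- function(e1, iv) {
    out <- NULL
    for (i in 1:5) for (j in 1:5) {
      lag <- t[j] - t[i]
      if (E[i] >= e1[1] && E[i] <= e1[2] && lag > iv[1] && lag <= iv[2])
        out <- rbind(out, c(i, j))
    }
    out
  }
  for (case in list(list(e1 = c(0.2, 0.3), iv = c(0, 0.05)),
                    list(e1 = c(0.2, 0.3), iv = c(0.05, 1)),
                    list(e1 = c(0, 1), iv = c(0, Inf)))) {
    rs <- selectRecurrencePairs(b, case$e1, case$iv)
    ref <- oracle(case$e1, case$iv)
    expect_equal(nrow(rs$pairs), if (is.null(ref)) 0L else nrow(ref))
    if (!is.null(ref))
      expect_equal(rs$pairs[order(rs$pairs$i1, rs$pairs$i2),
                            c("i1", "i2")],
                   data.frame(i1 = ref[order(ref[, 1], ref[, 2]), 1],
                              i2 = ref[order(ref[, 1], ref[, 2]), 2]),
                   ignore_attr = TRUE)
  }
  # degenerate interval -> empty set; full window -> all ordered pairs
  expect_equal(nrow(selectRecurrencePairs(b, c(0, 1), c(0, 0))$pairs),
               0L)
  expect_equal(nrow(selectRecurrencePairs(b, c(0, 1),
                                          c(0, Inf))$pairs), 10L)
})

test_that("recurrence histograms are density-normalised", {
  b <- fixtureBursts(t = c(0, 0.01, 0.02), E = c(0.3, 0.3, 0.3))
  rs <- selectRecurrencePairs(b, c(0, 1), c(0, 0.1))
  h <- recurrenceHistogram(rs)
  expect_equal(sum(h$density * 0.02), 1)
  expect_equal(sum(h$count > 0), 1L)  # all E2 identical
})

test_that("transition density peaks at the only pair", {
  b <- fixtureBursts(t = c(0, 0.01), E = c(0.3, 0.6))
  kd <- transitionDensity2D(b, c(0, 0.1), gridSize = 51,
                            bandwidth = 0.03)
  peak <- which(kd$z == max(kd$z), arr.ind = TRUE)
  expect_equal(kd$x[peak[1]], 0.3, tolerance = 0.03)
  expect_equal(kd$y[peak[2]], 0.6, tolerance = 0.03)
  expect_error(transitionDensity2D(b, c(0, 0.1), bandwidth = 0),
               "bandwidth")
})

test_that("a static mixture concentrates on the diagonal, dynamics off it", {
  set.seed(52)
  n <- 2000
  # static: each molecule keeps its E across recurrences; train starts
  # are sparse so that cross-molecule pairs are rare in the interval
  stateA <- rbinom(n, 1, 0.5)
  tb <- cumsum(rexp(n, 1))
  eStatic <- ifelse(stateA == 1, 0.2, 0.4) + rnorm(n, 0, 0.015)
  # trains of 2 bursts 10 ms apart from the same molecule
  t2 <- as.vector(rbind(tb, tb + 0.01))
  eS <- as.vector(rbind(eStatic, eStatic + rnorm(n, 0, 0.015)))
  bS <- fixtureBursts(t2, eS)
  offDiagMass <- function(b) {
    kd <- transitionDensity2D(b, c(0.005, 0.015), gridSize = 41,
                              bandwidth = 0.03)
    gx <- outer(kd$x, kd$y, function(a, b) abs(a - b))
    sum(kd$z[gx > 0.12]) / sum(kd$z)
  }
  mS <- offDiagMass(bS)
  # dynamic: the state decorrelates between the paired bursts
  eD1 <- ifelse(stateA == 1, 0.2, 0.4) + rnorm(n, 0, 0.015)
  eD2 <- ifelse(rbinom(n, 1, 0.5) == 1, 0.2, 0.4) + rnorm(n, 0, 0.015)
  bD <- fixtureBursts(t2, as.vector(rbind(eD1, eD2)))
  mD <- offDiagMass(bD)
  expect_lt(mS, 0.05)
  expect_gt(mD, mS * 3)
})

test_that("Eq-5 brightness mapping is the identity at eps = 1", {
  rho <- seq(0.01, 0.99, by = 0.01)
  expect_equal(plugdyn:::ratePAmodel(0, 1, rho, rho, eps = 1), rho)
  # and biased towards the brighter state otherwise
  expect_true(all(plugdyn:::ratePAmodel(0, 1, rho, rho, eps = 0.5) >=
                    rho))
})

test_that("ATP dependence fit recovers tau_min and K", {
  atp <- c(0.025, 0.05, 0.1, 0.25, 0.5, 1, 2)
  noiseless <- data.frame(atp = atp, tau = 0.01 * (1 + 0.056 / atp))
  fit <- fitAtpDependence(noiseless)
  expect_equal(fit$tauMin, 0.01, tolerance = 1e-6)
  expect_equal(fit$K, 0.056, tolerance = 1e-6)
  # tau at S = K equals 2 tau_min
  expect_equal(0.01 * (1 + 0.056 / 0.056), 2 * fit$tauMin,
               tolerance = 1e-6)
  noisy <- makeAtpSeries(0.01, 0.056, atp, cv = 0.10, n = 50,
                         seed = 53)
  fitN <- fitAtpDependence(noisy)
  expect_lt(abs(fitN$K - 0.056) / 0.056, 0.15)
  expect_error(fitAtpDependence(data.frame(atp = c(-1, 1, 2),
                                           tau = c(1, 1, 1))),
               "concentration")
})

test_that("Arrhenius fit converts slope to activation energy", {
  tt <- c(288, 298, 310)
  d <- data.frame(temperature = tt, k = exp(30 - 7337 / tt))
  fit <- fitArrhenius(d)
  expect_equal(fit$Ea_kJmol, 7337 * 8.314 / 1e3, tolerance = 1e-6)
  expect_equal(fit$Ea_kJmol, 61.0, tolerance = 0.01)
  d0 <- data.frame(temperature = tt, k = rep(5, 3))
  expect_equal(fitArrhenius(d0)$Ea_kJmol, 0, tolerance = 1e-9)
  expect_error(fitArrhenius(data.frame(temperature = tt,
                                       k = c(1, -1, 1))), "rate")
})
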