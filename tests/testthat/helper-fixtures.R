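# Fixtures built in code: hand-constructed photon streams and burst
# sets with exactly known structure.

# A photon stream consisting of sparse background plus optional dense
# two-channel clusters. Background photons alternate channels on a
# regular grid (rate per channel in Hz); clusters are lists of
# (t0, n, duration) placing n photons per stream in [t0, t0+duration].
fixtureStream <- function(duration = 10, bgRate = 100, clusters = list(),
                          clockRate = 1e7, altPeriod = 400,
                          clusterChannels = c("both", "dex-only")) {
  clusterChannels <- match.arg(clusterChannels)
  # background: regular grid, split between the four channel x slot
  # streams; regularity keeps delays well away from the burst criterion
  nbg <- round(bgRate * 2 * duration)
  tb <- seq(0, duration, length.out = nbg + 2)[-c(1, nbg + 2)]
  ch <- rep_len(c(0L, 1L, 1L, 0L), nbg)
  # force excitation slot by nudging into the wanted part of the period
  slotWant <- rep_len(c(0L, 0L, 1L, 1L), nbg)
  tick <- round(tb * clockRate)
  phase <- tick %% altPeriod
  on <- 0.4 * altPeriod
  tick <- tick - phase + ifelse(slotWant == 0L, 0.2 * on,
                                on + 0.3 * (altPeriod - on))
  df <- data.frame(tick = tick, channel = ch)
  for (cl in clusters) {
    n <- cl$n
    tt <- seq(cl$t0, cl$t0 + cl$duration, length.out = n)
    tick <- round(tt * clockRate)
    phase <- tick %% altPeriod
    # interleave DexDem, DexAem, AexAem photons
    kind <- rep_len(1:3, n)
    slotWant <- ifelse(kind == 3L, 1L, 0L)
    if (clusterChannels == "dex-only") { kind <- rep_len(1:2, n); slotWant <- 0L }
    tick <- tick - phase + ifelse(slotWant == 0L, 0.2 * on,
                                  on + 0.3 * (altPeriod - on))
    df <- rbind(df, data.frame(tick = tick,
                               channel = as.integer(kind >= 2L)))
  }
  df <- df[order(df$tick), ]
  df <- df[!duplicated(df$tick), ]
  PhotonStream(tick = df$tick, channel = df$channel,
               clockRate = clockRate, alternationPeriod = altPeriod,
               dutyCycle = 0.4, truth = list(duration = duration))
}

# BurstSet with fully controlled photon-level content, for BVA: each
# burst is a sequence of donor-excitation photons whose acceptor
# assignment follows a given per-photon probability path.
fixtureBurstSet <- function(prPaths, photonSpacing = 1e-4,
                            burstSpacing = 1) {
  ticks <- integer(); chans <- integer(); slots <- integer()
  rows <- list()
  clock <- 1e7
  for (i in seq_along(prPaths)) {
    pr <- prPaths[[i]]
    t0 <- (i - 1) * burstSpacing
    tt <- t0 + seq_along(pr) * photonSpacing
    tick <- round(tt * clock)
    acc <- rbinom(length(pr), 1L, pr)
    i_first <- length(ticks) + 1L
    ticks <- c(ticks, tick)
    chans <- c(chans, acc)
    slots <- c(slots, rep(0L, length(pr)))
    rows[[i]] <- data.frame(id = i, t_start = min(tt), t_stop = max(tt),
                            i_first = i_first, i_last = length(ticks),
                            n_DD = sum(acc == 0L), n_DA = sum(acc == 1L),
                            n_AA = 0L)
  }
  stream <- PhotonStream(tick = ticks, channel = chans, slot = slots,
                         clockRate = clock, alternationPeriod = 400,
                         truth = list(duration = length(prPaths) *
                                        burstSpacing))
  new("BurstSet", bursts = do.call(rbind, rows), stream = stream,
      params = list(fixture = TRUE))
}

# hand-built BurstSet without photon structure (for RASP pair logic)
fixtureBursts <- function(t, E) {
  b <- data.frame(id = seq_along(t), t_start = t, t_stop = t + 1e-3,
                  n_DD = 50L, n_DA = 50L, n_AA = 100L, E = E,
                  S = 0.5, PR = E)
  new("BurstSet", bursts = b,
      stream = PhotonStream(numeric(), integer(), integer(),
                            clockRate = 1e7, alternationPeriod = 400,
                            truth = list(duration = max(t) + 1)),
      params = list(fixture = TRUE))
}

# minimal synthetic PDB text (three atoms), for structure loading
fixturePdbLines <- function() {
  c(paste0("ATOM      1  CA  ALA A   1      ",
           " 0.000   0.000   0.000  1.00  0.00           C"),
    paste0("ATOM      2  CB  ALA A   1      ",
           " 2.000   0.000   0.000  1.00  0.00           C"),
    paste0("ATOM      3  N   ALA A   2      ",
           " 0.000   3.000   0.000  1.00  0.00           N"),
    "END")
}
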