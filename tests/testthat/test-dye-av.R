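writePdbFixture <- function(path) {
  atoms <- data.frame(
    serial = 1:3, name = c("CA", "CB", "N"),
    resn = c("ALA", "ALA", "ALA"), chain = "A", resno = c(1, 1, 2),
    x = c(0, 2, 0), y = c(0, 0, 3), z = 0,
    elem = c("C", "C", "N"))
  lines <- sprintf(
    "ATOM  %5d  %-3s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    atoms$serial, atoms$name, atoms$resn, atoms$chain, atoms$resno,
    atoms$x, atoms$y, atoms$z, atoms$elem)
  writeLines(c(lines, "END"), path)
  path
}

writeCifFixture <- function(path) {
  writeLines(c(
    "data_test", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id",
             "label_alt_id", "label_comp_id", "label_asym_id",
             "label_entity_id", "label_seq_id", "pdbx_PDB_ins_code",
             "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
             "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")),
    "ATOM 1 C CA . ALA A 1 1 ? 0.000 0.000 0.000 1.00 0.00 ? 1 ALA A CA 1",
    "ATOM 2 C CB . ALA A 1 1 ? 2.000 0.000 0.000 1.00 0.00 ? 1 ALA A CB 1",
    "ATOM 3 N N . ALA A 1 2 ? 0.000 3.000 0.000 1.00 0.00 ? 2 ALA A N 1"),
    path)
  path
}

test_that("PDB fixtures load with coordinates and radii", {
  f <- writePdbFixture(tempfile(fileext = ".pdb"))
  s <- loadStructure(f)
  expect_equal(nrow(s$atoms), 3L)
  expect_equal(s$atoms$x, c(0, 2, 0))
  expect_equal(s$atoms$radius, c(1.70, 1.70, 1.55))
  expect_error(loadStructure(tempfile(fileext = ".pdb")), "no such")
})

test_that("an mmCIF of the same content gives an identical model", {
  sPdb <- loadStructure(writePdbFixture(tempfile(fileext = ".pdb")))
  sCif <- suppressWarnings(
    loadStructure(writeCifFixture(tempfile(fileext = ".cif"))))
  expect_equal(sCif$atoms[, c("chain", "resno", "atomName", "element",
                              "x", "y", "z", "radius")],
               sPdb$atoms[, c("chain", "resno", "atomName", "element",
                              "x", "y", "z", "radius")],
               ignore_attr = TRUE)
})

test_that("missing element columns fall back to atom names with a warning", {
  f <- tempfile(fileext = ".pdb")
  lines <- readLines(writePdbFixture(tempfile(fileext = ".pdb")))
  writeLines(substr(lines, 1, 66), f)   # strip the element column
  expect_warning(s <- loadStructure(f), "fallback")
  expect_equal(s$atoms$element, c("C", "C", "N"))
})

test_that("a free attachment point accepts the whole linker sphere", {
  f <- writePdbFixture(tempfile(fileext = ".pdb"))
  s <- loadStructure(f)
  # keep only the attachment atom: nothing to clash with
  s$atoms <- s$atoms[3, , drop = FALSE]
  av <- computeAV(s, "A:2:N", linkerLength = 10, nSamples = 5000,
                  seed = 1)
  expect_equal(av@params$acceptedFraction, 1)
  d <- sqrt(rowSums(sweep(avPositions(av), 2, av@attachment)^2))
  expect_true(all(d <= 10 + 1e-9))
  # volume sampling is uniform: mean radius of uniform ball = 3/4 R
  expect_equal(mean(d), 7.5, tolerance = 0.1)
})

test_that("buried sites fail and acceptance is monotone in dye radius", {
  f <- writePdbFixture(tempfile(fileext = ".pdb"))
  s <- loadStructure(f)
  # enclose the attachment atom in a tight shell of atoms
  dirs <- as.matrix(expand.grid(x = -1:1, y = -1:1, z = -1:1))
  dirs <- dirs[rowSums(abs(dirs)) > 0, ]
  dirs <- dirs / sqrt(rowSums(dirs^2)) * 2.5
  shell <- data.frame(chain = "B", resno = 99, atomName = "X",
                      element = "C", x = dirs[, 1], y = dirs[, 2],
                      z = dirs[, 3], radius = 2.5)
  sBuried <- s
  sBuried$atoms <- rbind(s$atoms[3, , drop = FALSE], shell)
  expect_error(computeAV(sBuried, "A:2:N", linkerLength = 8,
                         nSamples = 500, seed = 2), "buried")
  # halving the dye radius never decreases the accepted count
  avBig <- computeAV(s, "A:1:CA", dyeRadius = 3.5, nSamples = 4000,
                     seed = 3)
  avSmall <- computeAV(s, "A:1:CA", dyeRadius = 1.75, nSamples = 4000,
                       seed = 3)
  expect_gte(nrow(avPositions(avSmall)), nrow(avPositions(avBig)))
  # deterministic given the seed
  avBig2 <- computeAV(s, "A:1:CA", dyeRadius = 3.5, nSamples = 4000,
                      seed = 3)
  expect_identical(avPositions(avBig), avPositions(avBig2))
})

test_that("distance distributions match a brute-force oracle", {
  mkCloud <- function(center, n, seed) {
    set.seed(seed)
    pos <- sweep(matrix(runif(n * 3), ncol = 3), 2, center, `+`)
    new("AVCloud", positions = pos, attachment = center,
        params = list(nSamples = n, acceptedFraction = 1))
  }
  c1 <- mkCloud(c(0, 0, 0), 200, 1)
  c2 <- mkCloud(c(45, 0, 0), 200, 2)
  dd <- distanceDistribution(c1, c2, nPairs = 4e4, seed = 3)
  # brute force over the full cross product
  ref <- as.vector(sqrt(outer(rowSums(avPositions(c1)^2),
                              rowSums(avPositions(c2)^2), `+`) -
                          2 * avPositions(c1) %*% t(avPositions(c2))))
  expect_equal(dd$mean, mean(ref), tolerance = 0.01)
  expect_equal(dd$sd, sd(ref), tolerance = 0.05)
  # two point-like clouds separated by 45 A -> 4.5 nm delta
  p1 <- new("AVCloud", positions = matrix(0, 1, 3),
            attachment = c(0, 0, 0), params = list())
  p2 <- new("AVCloud", positions = matrix(c(45, 0, 0), 1, 3),
            attachment = c(45, 0, 0), params = list())
  dp <- distanceDistribution(p1, p2, seed = 4)
  expect_equal(unique(dp$distances_nm), 4.5)
  # identical overlapping clouds include near-zero distances
  dSelf <- distanceDistribution(c1, c1, nPairs = 5e4, seed = 5)
  expect_lt(min(dSelf$distances), 0.2)
})

test_that("Forster conversion from distance to efficiency", {
  expect_equal(efretFromDistances(6, R0 = 6)$E, 0.5)
  expect_equal(efretFromDistances(12, R0 = 6)$E, 1 / 65)
  expect_gt(efretFromDistances(0.01, R0 = 6)$E, 0.999)
  expect_error(efretFromDistances(5, R0 = 0), "R0")
  # AV-to-E chain: clouds at closed-like separation (~4.5 nm) give
  # E ~ 0.4-0.6; open-like (~7 nm) give low E
  p1 <- new("AVCloud", positions = matrix(0, 1, 3),
            attachment = c(0, 0, 0), params = list())
  mk <- function(d) new("AVCloud", positions = matrix(c(d, 0, 0), 1, 3),
                        attachment = c(d, 0, 0), params = list())
  eClosed <- efretFromDistances(distanceDistribution(p1, mk(55),
                                                     seed = 1))
  eOpen <- efretFromDistances(distanceDistribution(p1, mk(75),
                                                   seed = 1))
  expect_gt(eClosed$meanE, 0.35)
  expect_lt(eOpen$meanE, 0.25)
})
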