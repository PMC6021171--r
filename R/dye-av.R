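#' Load an atomic structure for accessible-volume modelling
#'
#' Reads PDB or mmCIF coordinates (via bio3d) and assigns element-based
#' van der Waals radii. Waters and other hetero groups are stripped by
#' default. Missing element assignments fall back to the first letter of
#' the atom name, with a warning.
#'
#' @param path PDB (.pdb/.ent) or mmCIF (.cif) file
#' @param stripHetero drop water/hetero records (default TRUE)
#' @return list of class \code{StructureModel}: data.frame \code{atoms}
#'   (chain, resno, atomName, element, x, y, z, radius in Angstrom)
#' @export
loadStructure <- function(path, stripHetero = TRUE) {
  if (!file.exists(path)) stop("format error: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path) else bio3d::read.pdb(path),
    error = function(e) stop("format error: unreadable structure: ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (stripHetero) at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("format error: no atoms")
  elem <- toupper(trimws(at$elesy %||% ""))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) {
    warning("element column missing for some atoms; ",
            "using atom-name fallback")
    elem[bad] <- substr(gsub("[0-9]", "", toupper(at$elety[bad])), 1, 1)
  }
  vdw <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
           SE = 1.90, FE = 1.80)
  r <- unname(vdw[elem])
  r[is.na(r)] <- 1.70
  structure(list(atoms = data.frame(chain = at$chain, resno = at$resno,
                                    atomName = trimws(at$elety),
                                    element = elem,
                                    x = at$x, y = at$y, z = at$z,
                                    radius = r)),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat("StructureModel:", nrow(x$atoms), "atoms,",
      length(unique(x$atoms$chain)), "chain(s)\n")
  invisible(x)
}

parseSite <- function(site) {
  if (is.character(site) && length(site) == 1) {
    p <- strsplit(site, ":", fixed = TRUE)[[1]]
    if (length(p) != 3) stop("site must be 'chain:resno:atom'")
    list(chain = p[1], resno = as.integer(p[2]), atom = p[3])
  } else site
}

#' Monte Carlo accessible volume of a tethered dye
#'
#' Rejection-samples candidate dye-centre positions uniformly within the
#' linker-length sphere around the attachment atom, discarding positions
#' that clash with any structure atom (centre distance below atom radius
#' + dye radius) or that cannot be reached by a clash-free straight
#' linker segment of the given width from the attachment point. Accepted
#' positions carry uniform weights. Default geometry (20 Angstrom
#' linker, 4.5 Angstrom width, 3.5 Angstrom dye radius) is typical for
#' Alexa-maleimide dyes.
#'
#' @param structure a \code{\link{loadStructure}} model
#' @param site attachment site, \code{"chain:resno:atomName"} or a list
#' @param linkerLength linker length (Angstrom)
#' @param linkerWidth linker width (Angstrom)
#' @param dyeRadius dye radius (Angstrom)
#' @param nSamples Monte Carlo candidates
#' @param seed integer seed
#' @return an \code{\linkS4class{AVCloud}}
#' @export
computeAV <- function(structure, site, linkerLength = 20,
                      linkerWidth = 4.5, dyeRadius = 3.5,
                      nSamples = 20000, seed = 1L) {
  stopifnot(inherits(structure, "StructureModel"), linkerLength > 0,
            linkerWidth > 0, dyeRadius > 0)
  s <- parseSite(site)
  at <- structure$atoms
  hit <- which(at$chain == s$chain & at$resno == s$resno &
                 at$atomName == s$atom)
  if (!length(hit)) stop("site not found in structure")
  origin <- c(at$x[hit[1]], at$y[hit[1]], at$z[hit[1]])
  # atoms considered for clashes: everything except the attachment atom,
  # restricted to the reach sphere for speed
  xyz <- as.matrix(at[-hit[1], c("x", "y", "z")])
  rad <- at$radius[-hit[1]]
  if (nrow(xyz)) {
    d0 <- sqrt(rowSums(sweep(xyz, 2, origin)^2))
    keep <- d0 <= linkerLength + dyeRadius + max(rad)
    xyz <- xyz[keep, , drop = FALSE]; rad <- rad[keep]
  }
  withSeed(seed, {
    # uniform in the sphere of radius linkerLength
    u <- matrix(rnorm(nSamples * 3), ncol = 3)
    u <- u / sqrt(rowSums(u^2))
    r <- linkerLength * runif(nSamples)^(1 / 3)
    cand <- sweep(u * r, 2, origin, `+`)
    ok <- rep(TRUE, nSamples)
    if (nrow(xyz)) {
      # dye-body clash
      ok <- avClashFree(cand, xyz, rad + dyeRadius)
      # straight-segment linker reachability at half-width
      nseg <- max(2L, ceiling(linkerLength / (linkerWidth / 2)))
      fr <- seq(0, 1, length.out = nseg + 1L)[-c(1L, nseg + 1L)]
      for (f in fr) {
        idx <- which(ok)
        if (!length(idx)) break
        pts <- sweep(cand[idx, , drop = FALSE] * f, 2,
                     origin * (1 - f), `+`)
        ok[idx] <- avClashFree(pts, xyz, rad + linkerWidth / 2)
      }
    }
    if (!any(ok))
      stop("site buried: no accessible dye positions")
    new("AVCloud", positions = cand[ok, , drop = FALSE],
        attachment = origin,
        params = list(site = s, linkerLength = linkerLength,
                      linkerWidth = linkerWidth, dyeRadius = dyeRadius,
                      nSamples = nSamples,
                      acceptedFraction = mean(ok), seed = seed))
  })
}

# TRUE where point i clashes with no atom (chunked pairwise distances)
avClashFree <- function(pts, xyz, clearance) {
  n <- nrow(pts)
  ok <- logical(n)
  chunk <- max(1L, floor(2e7 / max(nrow(xyz), 1L)))
  for (st in seq(1L, n, by = chunk)) {
    en <- min(st + chunk - 1L, n)
    block <- pts[st:en, , drop = FALSE]
    d2 <- outer(rowSums(block^2), rowSums(xyz^2), `+`) -
      2 * block %*% t(xyz)
    ok[st:en] <- !apply(sweep(d2, 2, clearance^2) < 0, 1, any)
  }
  ok
}

#' Inter-dye distance distribution of two accessible volumes
#'
#' Distances over random pairs of positions from the two clouds
#' (uniform weights), with summary mean and SD, in Angstrom and nm.
#'
#' @param av1,av2 \code{\linkS4class{AVCloud}} objects
#' @param nPairs number of sampled pairs (capped at the full cross
#'   product)
#' @param seed integer seed
#' @return list of class \code{DistanceDistribution}: \code{distances}
#'   (Angstrom), \code{distances_nm}, \code{mean}, \code{sd} (Angstrom)
#' @export
distanceDistribution <- function(av1, av2, nPairs = 1e5, seed = 1L) {
  stopifnot(is(av1, "AVCloud"), is(av2, "AVCloud"))
  p1 <- avPositions(av1); p2 <- avPositions(av2)
  if (!nrow(p1) || !nrow(p2)) stop("empty accessible volume")
  withSeed(seed, {
    n <- min(nPairs, as.double(nrow(p1)) * nrow(p2))
    i <- sample.int(nrow(p1), n, replace = TRUE)
    j <- sample.int(nrow(p2), n, replace = TRUE)
    d <- sqrt(rowSums((p1[i, , drop = FALSE] -
                         p2[j, , drop = FALSE])^2))
    structure(list(distances = d, distances_nm = d / 10,
                   mean = mean(d), sd = sd(d)),
              class = "DistanceDistribution")
  })
}

#' @export
print.DistanceDistribution <- function(x, ...) {
  cat(sprintf("DistanceDistribution: mean %.1f A (%.2f nm), sd %.1f A, n = %d\n",
              x$mean, x$mean / 10, x$sd, length(x$distances)))
  invisible(x)
}

#' FRET efficiency prediction from inter-dye distances
#'
#' Pointwise \eqn{E = 1 / (1 + (r/R_0)^6)} with the Forster radius of
#' the Alexa 488/594 pair (6 nm) as default, plus a histogram on
#' [0, 1].
#'
#' @param distances inter-dye distances, or a
#'   \code{\link{distanceDistribution}} (its nm distances are used)
#' @param R0 Forster radius in the same units as \code{distances}
#'   (default 6, i.e. nm)
#' @param breaks histogram bin edges over [0, 1]
#' @return list of class \code{EfretPrediction}: \code{E} values,
#'   \code{meanE}, histogram data.frame
#' @examples
#' efretFromDistances(6)$E      # r = R0 -> 0.5
#' efretFromDistances(12)$E     # r = 2 R0 -> 1/65
#' @export
efretFromDistances <- function(distances, R0 = 6,
                               breaks = seq(0, 1, by = 0.02)) {
  if (R0 <= 0) stop("parameter error: R0 must be > 0")
  if (inherits(distances, "DistanceDistribution"))
    distances <- distances$distances_nm
  stopifnot(all(distances > 0))
  e <- 1 / (1 + (distances / R0)^6)
  cnt <- tabulate(findInterval(e, breaks, rightmost.closed = TRUE),
                  nbins = length(breaks) - 1L)
  structure(list(E = e, meanE = mean(e),
                 hist = data.frame(mid = breaks[-length(breaks)] +
                                     diff(breaks) / 2,
                                   density = cnt / length(e) /
                                     diff(breaks))),
            class = "EfretPrediction")
}

#' @export
print.EfretPrediction <- function(x, ...) {
  cat(sprintf("EfretPrediction: mean E = %.3f over %d distances\n",
              x$meanE, length(x$E)))
  invisible(x)
}
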