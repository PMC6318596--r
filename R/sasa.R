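#' Shrake-Rupley solvent accessible surface area
#'
#' Classic test-point SASA: each atom's van der Waals sphere is expanded by
#' the probe radius, a quasi-uniform set of test points (golden-spiral /
#' Fibonacci lattice) is placed on the expanded sphere, and the accessible
#' fraction is the share of points lying outside every neighbour's expanded
#' sphere. Per-atom area = accessible fraction x 4 pi (r_vdw + r_probe)^2.
#' Chains are made whole across periodic boundaries before the calculation;
#' no periodic images are considered (the two-chain ensemble is treated as
#' an isolated solute, appropriate for a box much larger than the solute).
#'
#' @param frame frame list from [getFrame()].
#' @param system a [SystemTopology-class] (provides per-atom vdW radii;
#'   hydrogens, when present in the topology, are included with their own
#'   radius).
#' @param probeRadius solvent probe radius, nm (default 0.14, a water-sized
#'   probe).
#' @param nPoints test points per atom (>= 32; default 960).
#' @param selection optional 1-based global atom rows; default all atoms.
#' @param unwrap make chains whole first (default TRUE).
#' @return list with \code{total} (nm^2), \code{perAtom} (numeric vector,
#'   nm^2), \code{probeRadius} and \code{nPoints}.
#' @export
shrakeRupleySasa <- function(frame, system, probeRadius = 0.14,
                             nPoints = 960L, selection = NULL,
                             unwrap = TRUE) {
    if (nPoints < 32L) stop("nPoints must be at least 32")
    at <- atomTable(system)
    co <- frame$coords
    if (unwrap) co <- unwrapChains(co, system, frame$box)
    if (is.null(selection)) selection <- seq_len(nrow(at))
    co <- co[selection, , drop = FALSE]
    radii <- at$vdw[selection] + probeRadius
    if (any(is.na(radii)))
        stop("missing van der Waals radius for selected atom(s)")
    n <- nrow(co)
    sph <- .fibonacciSphere(as.integer(nPoints))
    # neighbour lists: spheres that can overlap
    dmat <- as.matrix(stats::dist(co))
    perAtom <- numeric(n)
    for (i in seq_len(n)) {
        nb <- which(dmat[i, ] < radii[i] + radii & seq_len(n) != i)
        pts <- sweep(sph * radii[i], 2L, co[i, ], "+")
        acc <- rep(TRUE, nPoints)
        for (j in nb) {
            if (!any(acc)) break
            dd <- sweep(pts[acc, , drop = FALSE], 2L, co[j, ])
            acc[acc] <- rowSums(dd * dd) >= radii[j]^2
        }
        perAtom[i] <- mean(acc) * 4 * pi * radii[i]^2
    }
    list(total = sum(perAtom), perAtom = perAtom,
         probeRadius = probeRadius, nPoints = as.integer(nPoints))
}

## quasi-uniform points on the unit sphere (golden-spiral lattice)
.fibonacciSphere <- function(n) {
    k <- seq_len(n) - 0.5
    phi <- pi * (1 + sqrt(5)) * k
    z <- 1 - 2 * k / n
    r <- sqrt(pmax(0, 1 - z^2))
    cbind(r * cos(phi), r * sin(phi), z)
}

#' Per-frame SASA over a trajectory
#'
#' @param traj a [Trajectory-class].
#' @param system a [SystemTopology-class].
#' @param ... passed to [shrakeRupleySasa()].
#' @return data.frame with \code{time} (ps) and \code{sasa} (nm^2).
#' @export
sasaTimeSeries <- function(traj, system, ...) {
    nf <- nFrames(traj)
    out <- numeric(nf)
    for (f in seq_len(nf))
        out[f] <- shrakeRupleySasa(getFrame(traj, f), system, ...)$total
    data.frame(time = frameTimes(traj), sasa = out)
}
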