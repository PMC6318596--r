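#' SynthConfig: synthetic trajectory generator settings
#'
#' @slot nRes residues per chain (default 30).
#' @slot box cubic box edge, nm (default 9).
#' @slot nFrames number of frames.
#' @slot samplingInterval frame spacing, ps (default 5).
#' @slot mode one of "separated", "touching", "aggregated", "planted".
#' @slot plantedContacts two-column matrix (residue of A, residue of B);
#'   required exactly when mode is "planted".
#' @slot jitterSD per-coordinate frame jitter SD, nm.
#' @slot seed integer seed.
#' @export
setClass("SynthConfig", representation(
    nRes = "integer", box = "numeric", nFrames = "integer",
    samplingInterval = "numeric", mode = "character",
    plantedContacts = "matrix", jitterSD = "numeric", seed = "integer"
))

setValidity("SynthConfig", function(object) {
    if (!object@mode %in% c("separated", "touching", "aggregated", "planted"))
        return("mode must be separated, touching, aggregated or planted")
    planted <- nrow(object@plantedContacts) > 0L
    if (object@mode == "planted" && !planted)
        return("planted mode requires plantedContacts")
    if (object@mode != "planted" && planted)
        return("plantedContacts only allowed in planted mode")
    if (planted) {
        pc <- object@plantedContacts
        if (ncol(pc) != 2L)
            return("plantedContacts must have two columns (resA, resB)")
        if (any(pc < 1L) || any(pc > object@nRes))
            return("planted residue indices must lie in 1..nRes")
    }
    if (object@nRes < 2L) return("nRes must be >= 2")
    if (object@box <= 0) return("box edge must be positive")
    if (object@nFrames < 1L) return("nFrames must be >= 1")
    TRUE
})

#' Construct a SynthConfig
#'
#' Defaults mirror the reference study geometry: two 30-residue chains in a
#' 9 x 9 x 9 nm cubic box, one frame every 5 ps.
#'
#' @param nRes,box,nFrames,samplingInterval,mode,plantedContacts,jitterSD,seed
#'   see [SynthConfig-class].
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nRes = 30L, box = 9.0, nFrames = 5L,
                        samplingInterval = 5, mode = "separated",
                        plantedContacts = NULL, jitterSD = 0.02,
                        seed = 1L) {
    if (is.null(plantedContacts))
        plantedContacts <- matrix(integer(0), 0L, 2L)
    if (is.list(plantedContacts) && !is.matrix(plantedContacts))
        plantedContacts <- do.call(rbind, plantedContacts)
    new("SynthConfig", nRes = as.integer(nRes), box = box,
        nFrames = as.integer(nFrames), samplingInterval = samplingInterval,
        mode = mode, plantedContacts = matrix(as.integer(plantedContacts),
                                              ncol = 2L),
        jitterSD = jitterSD, seed = as.integer(seed))
}

## ---- chain geometry -------------------------------------------------------

.BOND_BACKBONE <- 0.25   # nm, virtual C-C spacing along the walk
.MIN_NONBONDED <- 0.15   # nm, self-avoidance floor between residues

.unit <- function(v) v / sqrt(sum(v * v))

.randUnit <- function() .unit(stats::rnorm(3))

## perpendicular frame (n, b) for tangent u
.perpFrame <- function(u) {
    v <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    n <- .unit(v - sum(v * u) * u)
    list(n = n, b = .unit(c(u[2] * n[3] - u[3] * n[2],
                            u[3] * n[1] - u[1] * n[3],
                            u[1] * n[2] - u[2] * n[1])))
}

## side-chain offsets from the stereocenter C2, in the local (d, b) frame
## where d is the side direction fixed by the dyad sequence
.sideOffsets <- function(d, b) {
    rbind(N  = 0.25 * d - 0.10 * b,
          O  = 0.23 * d + 0.10 * b,
          CI = 0.40 * d,
          CE = 0.52 * d + 0.12 * b,
          CF = 0.52 * d - 0.12 * b)
}

## up/down side of each residue from the dyad string: meso keeps the side,
## racemo flips it
.sideSigns <- function(dyads) {
    s <- numeric(length(dyads@symbols) + 1L)
    s[1L] <- 1
    for (i in seq_along(dyads@symbols))
        s[i + 1L] <- if (dyads@symbols[i] == "m") s[i] else -s[i]
    s
}

#' Generate self-avoiding coordinates for one chain
#'
#' Builds a compact self-avoiding backbone random walk (fixed 0.25 nm bond
#' between consecutive backbone carbons, tethered so the chain stays within a
#' compact blob) and attaches the five side-chain pseudo-atoms of each
#' residue at fixed local geometry, on the backbone side dictated by the
#' chain's dyad sequence (meso dyad: consecutive side groups on the same
#' side; racemo: alternating). No two atoms of different residues come
#' closer than 0.15 nm.
#'
#' @param chain a [ChainTopology-class].
#' @param seed integer seed; identical seeds give identical coordinates.
#' @param maxRadius tether radius of the backbone walk, nm.
#' @param maxTries bounded number of rebuild attempts before failing.
#' @return nAtoms x 3 coordinate matrix (nm) in topology atom order
#'   (per residue: C1, C2, N, O, CI, CE, CF).
#' @export
generateChainCoordinates <- function(chain, seed, maxRadius = 1.35,
                                     maxTries = 200L) {
    stopifnot(is(chain, "ChainTopology"))
    set.seed(as.integer(seed))
    nres <- nResidues(chain)
    signs <- .sideSigns(chain@dyads)
    for (try in seq_len(maxTries)) {
        xyz <- .tryBuildChain(nres, signs, maxRadius)
        if (!is.null(xyz)) return(xyz)
    }
    stop("could not generate a self-avoiding chain after ", maxTries,
         " attempts; try a different seed")
}

## grow the chain residue by residue; each step proposes walk directions,
## places the residue's 7 atoms and retries on a clash with earlier residues
.tryBuildChain <- function(nres, signs, maxRadius) {
    xyz <- matrix(NA_real_, nres * 7L, 3L)
    prev <- c(0, 0, 0)   # last backbone node of the previous residue
    dir <- .randUnit()
    for (i in seq_len(nres)) {
        placed <- FALSE
        for (attempt in 1:40) {
            d1 <- dir
            # steer back inside the tether when drifting out
            if (sqrt(sum(prev^2)) > maxRadius)
                d1 <- .unit(d1 + 1.2 * .unit(-prev))
            c1 <- if (i == 1L) prev else prev + .BOND_BACKBONE * d1
            d2 <- .unit(d1 + 0.35 * stats::rnorm(3))
            c2 <- c1 + .BOND_BACKBONE * d2
            u <- .unit(c2 - c1)
            fr <- .perpFrame(u)
            off <- .sideOffsets(signs[i] * fr$n, fr$b)
            atoms <- rbind(c1, c2, sweep(off, 2L, c2, "+"))
            ok <- TRUE
            if (i > 1L) {
                old <- xyz[seq_len((i - 1L) * 7L), , drop = FALSE]
                for (r in seq_len(nrow(atoms))) {
                    dd <- sweep(old, 2L, atoms[r, ])
                    if (min(rowSums(dd * dd)) < .MIN_NONBONDED^2) {
                        ok <- FALSE; break
                    }
                }
            }
            if (ok && sqrt(sum(c2^2)) <= maxRadius + 0.5) {
                xyz[(i - 1L) * 7L + 1:7, ] <- atoms
                prev <- c2
                dir <- .unit(d2 + 0.35 * stats::rnorm(3))
                placed <- TRUE
                break
            }
            dir <- .randUnit()
        }
        if (!placed) return(NULL)
    }
    xyz
}

## ---- planted-contact construction ----------------------------------------

## available contact atoms per planted pair, tried in order; each entry
## names the A-side atom, the B-side atom and the class cutoff used
.PLANT_CLASSES <- list(
    list(a = "N",  b = "O",  class = "N(A)-O(B)"),
    list(a = "CE", b = "CE", class = "CE_CF-CE_CF"),
    list(a = "CI", b = "CI", class = "CI-CI"),
    list(a = "CF", b = "CI", class = "CE_CF-CI"),
    list(a = "O",  b = "N",  class = "N(B)-O(A)")
)

.plantMargin <- 0.05

## straight-rod base configuration with planted pairs relocated to a grid of
## well-separated contact sites half way between the rods
.plantedBase <- function(system, pc, box, spec) {
    nres <- nResidues(system)
    at <- atomTable(system)
    nat <- nrow(at)
    xyz <- matrix(0, nat, 3L)
    yA <- 1.0; yB <- box - 1.0; z0 <- 2.0
    for (r in seq_len(nat)) {
        i <- at$residue[r]
        y <- if (at$chain[r] == "A") yA else yB
        x0 <- (i - 1L) * 0.5
        p <- switch(at$name[r],
            C1 = c(x0, y, z0),
            C2 = c(x0 + 0.25, y, z0),
            N  = c(x0 + 0.25, y, z0 + 0.25),
            O  = c(x0 + 0.25, y, z0 - 0.25),
            CI = c(x0 + 0.25, y, z0 + 0.45),
            CE = c(x0 + 0.10, y, z0 + 0.62),
            CF = c(x0 + 0.40, y, z0 + 0.62))
        xyz[r, ] <- p
    }
    pc <- unique(pc)
    nSitesPerRow <- max(1L, floor(box / 1.5))
    if (nrow(pc) > nSitesPerRow^2)
        stop("infeasible planted pattern: more contacts than available ",
             "well-separated sites in this box")
    cutoffs <- stats::setNames(spec@pairs$cutoff, spec@pairs$class)
    usedA <- list(); usedB <- list()
    pairedAtoms <- vector("list", nrow(pc))
    for (p in seq_len(nrow(pc))) {
        i <- pc[p, 1L]; j <- pc[p, 2L]
        keyA <- as.character(i); keyB <- as.character(j)
        choice <- NULL
        for (cl in .PLANT_CLASSES) {
            if (cl$a %in% usedA[[keyA]] || cl$b %in% usedB[[keyB]]) next
            choice <- cl; break
        }
        if (is.null(choice))
            stop("infeasible planted pattern: residue pair (", i, ", ", j,
                 ") exhausts the contact atoms of a residue")
        usedA[[keyA]] <- c(usedA[[keyA]], choice$a)
        usedB[[keyB]] <- c(usedB[[keyB]], choice$b)
        d <- unname(cutoffs[choice$class]) - .plantMargin
        sx <- 0.75 + 1.5 * ((p - 1L) %% nSitesPerRow)
        sz <- 0.75 + 1.5 * ((p - 1L) %/% nSitesPerRow)
        ia <- which(at$chain == "A" & at$residue == i & at$name == choice$a)
        ib <- which(at$chain == "B" & at$residue == j & at$name == choice$b)
        xyz[ia, ] <- c(sx, box / 2 - d / 2, sz)
        xyz[ib, ] <- c(sx, box / 2 + d / 2, sz)
        pairedAtoms[[p]] <- c(ia, ib)
    }
    list(xyz = xyz, pairedAtoms = pairedAtoms)
}

## ---- trajectory generation ------------------------------------------------

#' Generate a synthetic two-chain trajectory
#'
#' Produces a geometric stand-in for an atomistic simulation, with a
#' controlled inter-chain association state:
#' \describe{
#'   \item{separated}{the chains are compact coils placed so that every
#'     inter-chain atom distance exceeds the largest contact cutoff by a wide
#'     margin in every frame.}
#'   \item{touching}{chain B is rigid-shifted toward chain A until the first
#'     inter-chain contact appears.}
#'   \item{aggregated}{chain B is rigid-shifted into chain A until at least
#'     25\% of the residues of each chain carry an inter-chain contact.}
#'   \item{planted}{exactly the requested residue pairs are in contact
#'     (placed 0.05 nm inside their class cutoff) and no other residue pair
#'     is (all other inter-chain distances at least 0.05 nm beyond the
#'     largest cutoff).}
#' }
#' Frames differ by small random jitter that preserves the contact pattern:
#' the two atoms realizing a planted contact share one displacement per
#' frame, and for the other modes each frame's contact pattern is verified
#' and re-jittered if the mode contract would be broken.
#'
#' @param config a [SynthConfig-class].
#' @param system matching [SystemTopology-class]; built from the default
#'   atactic reference sequence when omitted.
#' @param spec the [ContactSpec-class] the contacts must respect
#'   (default [defaultContactSpec()]).
#' @return a [Trajectory-class].
#' @examples
#' cfg <- synthConfig(mode = "planted", nFrames = 2,
#'                    plantedContacts = rbind(c(5, 12)))
#' traj <- generateTrajectory(cfg)
#' @export
generateTrajectory <- function(config, system = NULL,
                               spec = defaultContactSpec()) {
    stopifnot(is(config, "SynthConfig"))
    if (is.null(system)) {
        dy <- generateBernoullianSequence(config@nRes, 0.45,
                                          seed = config@seed)
        system <- buildSystemTopology(dy)
    }
    if (nResidues(system) != config@nRes)
        stop("system topology residue count does not match config")
    set.seed(config@seed)
    box <- rep(config@box, 3L)
    maxCut <- max(spec@pairs$cutoff)
    pairedAtoms <- list()

    if (config@mode == "planted") {
        base <- .plantedBase(system, config@plantedContacts, config@box, spec)
        xyz <- base$xyz
        pairedAtoms <- base$pairedAtoms
    } else {
        xyz <- .placeTwoCoils(system, config, spec, maxCut)
        if (config@mode %in% c("touching", "aggregated"))
            xyz <- .shiftToAssociation(xyz, system, box, spec, config@mode)
    }

    ok <- function(co) .modeContractHolds(co, system, box, spec, config)
    if (!ok(xyz))
        stop("internal error: base configuration violates the ",
             config@mode, " contract")

    frames <- vector("list", config@nFrames)
    for (f in seq_len(config@nFrames)) {
        for (attempt in 1:100) {
            co <- .jitterFrame(xyz, config@jitterSD, pairedAtoms)
            if (ok(co)) break
            co <- NULL
        }
        if (is.null(co))
            stop("could not jitter frame ", f,
                 " without breaking the contact pattern")
        frames[[f]] <- co
    }
    Trajectory(frames,
               times = (seq_len(config@nFrames) - 1L) *
                   config@samplingInterval,
               boxes = box)
}

## truncated gaussian jitter; planted contact pairs move rigidly
.jitterFrame <- function(xyz, sd, pairedAtoms) {
    if (sd <= 0) return(xyz)
    j <- matrix(stats::rnorm(length(xyz), sd = sd), nrow(xyz), 3L)
    j <- pmin(pmax(j, -1.25 * sd), 1.25 * sd)
    for (pa in pairedAtoms) j[pa[2L], ] <- j[pa[1L], ]
    xyz + j
}

.placeTwoCoils <- function(system, config, spec, maxCut) {
    box <- config@box
    for (try in 1:60) {
        sA <- sample.int(2^30, 1L); sB <- sample.int(2^30, 1L)
        cA <- generateChainCoordinates(system@chains[[1L]], sA)
        cB <- generateChainCoordinates(system@chains[[2L]], sB)
        shift <- function(co, target)
            sweep(co, 2L, target - colMeans(co), "+")
        cA <- shift(cA, c(box * 0.25, box / 2, box / 2))
        cB <- shift(cB, c(box * 0.75, box / 2, box / 2))
        xyz <- rbind(cA, cB)
        dmin <- min(.micDistMatrix(cA, cB, rep(box, 3L)))
        if (dmin > maxCut + 0.15) return(xyz)
    }
    stop("could not place separated chains; try a different seed")
}

## rigid-shift chain B toward chain A until the association criterion holds
.shiftToAssociation <- function(xyz, system, box, spec, mode) {
    at <- atomTable(system)
    idxB <- which(at$chain == "B")
    comA <- colMeans(xyz[at$chain == "A", , drop = FALSE])
    comB <- colMeans(xyz[idxB, , drop = FALSE])
    dirAB <- .unit(.mic(comA - comB, box))
    total <- sqrt(sum(.mic(comA - comB, box)^2))
    crit <- function(co) {
        det <- detectContacts(list(coords = co, box = box), system, spec)
        if (mode == "touching") return(nrow(det$contacts) >= 1L)
        nres <- nResidues(system)
        fl <- det$residueFlags
        mean(fl[seq_len(nres)]) >= 0.25 &&
            mean(fl[nres + seq_len(nres)]) >= 0.25
    }
    for (s in seq(0, total, by = 0.05)) {
        co <- xyz
        co[idxB, ] <- sweep(co[idxB, ], 2L, s * dirAB, "+")
        if (crit(co)) return(co)
    }
    stop("rigid shift failed to reach the requested association state; ",
         "try a different seed")
}

.modeContractHolds <- function(coords, system, box, spec, config) {
    det <- detectContacts(list(coords = coords, box = box), system, spec)
    nres <- nResidues(system)
    switch(config@mode,
        separated = nrow(det$contacts) == 0L,
        touching = nrow(det$contacts) >= 1L,
        aggregated = {
            fl <- det$residueFlags
            mean(fl[seq_len(nres)]) >= 0.25 &&
                mean(fl[nres + seq_len(nres)]) >= 0.25
        },
        planted = {
            got <- residueContactPairs(det, system)
            want <- unique(config@plantedContacts)
            identical(
                got[order(got[, 1L], got[, 2L]), , drop = FALSE],
                want[order(want[, 1L], want[, 2L]), , drop = FALSE])
        })
}

#' One-frame fixture reproducing the worked junction example
#'
#' A planted single-frame trajectory realizing the canonical two-junction
#' snapshot: one junction formed by a single residue of chain A with one
#' residue of chain B, the other by two adjacent residues of A with one
#' residue of B, the two A-side junctions separated by several non-contact
#' residues. Junction analysis of this frame yields NR_A = 3, NJ_A = 2,
#' LJ_mean_A = 1.5 and NR_B = 2, NJ_B = 2, LJ_mean_B = 1.
#'
#' @param seed integer seed for the frame jitter.
#' @return list with elements \code{trajectory} ([Trajectory-class]),
#'   \code{system} ([SystemTopology-class]) and \code{contacts} (the planted
#'   residue-pair matrix).
#' @export
twoJunctionFixture <- function(seed = 1L) {
    pc <- rbind(c(5L, 12L), c(12L, 20L), c(13L, 20L))
    system <- buildSystemTopology(pnipamDyadSequences()$isotactic)
    cfg <- synthConfig(mode = "planted", nFrames = 1L,
                       plantedContacts = pc, seed = seed)
    list(trajectory = generateTrajectory(cfg, system),
         system = system, contacts = pc)
}
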