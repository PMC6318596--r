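#' @import methods
NULL

#' DyadSequence: stereochemical dyad string of a vinyl polymer chain
#'
#' An ordered sequence over the alphabet \{\code{"r"}, \code{"m"}\} encoding
#' the relative configuration of consecutive stereocenter pairs along a chain:
#' \code{"m"} for a meso dyad (same relative configuration, isotactic
#' placement), \code{"r"} for a racemo dyad (opposite configuration,
#' syndiotactic placement). A chain of \code{n} residues has \code{n - 1}
#' dyads.
#'
#' @slot symbols character vector of single characters, each "r" or "m".
#'
#' @seealso [DyadSequence()], [mesoFraction()], [pnipamDyadSequences()]
#' @export
setClass("DyadSequence", representation(symbols = "character"))

setValidity("DyadSequence", function(object) {
    s <- object@symbols
    if (length(s) == 0L)
        return("dyad sequence must contain at least one symbol")
    if (any(nchar(s) != 1L) || !all(s %in% c("r", "m")))
        return("dyad symbols must all be 'r' or 'm'")
    TRUE
})

#' ChainTopology: one polymer chain with named pseudo-atoms
#'
#' Describes a single PNIPAM-like chain: per-residue atom records (name, role,
#' mass, van der Waals radius) and the dyad sequence fixing its
#' stereochemistry. Each residue carries two backbone carbons (\code{C1},
#' \code{C2}) and the five side-chain heavy atoms of the isopropylamide group:
#' amide nitrogen \code{N} and carbonyl oxygen \code{O} (polar), the two
#' isopropyl methyl carbons \code{CE} and \code{CF} and the isopropyl methine
#' carbon \code{CI} (hydrophobic).
#'
#' @slot chainId "A" or "B".
#' @slot atoms data.frame with columns \code{residue} (1-based local index),
#'   \code{name}, \code{role} (\code{polar}/\code{hydrophobic}/\code{backbone}),
#'   \code{element}, \code{mass} (amu) and \code{vdw} (nm).
#' @slot dyads [DyadSequence-class] of length \code{nResidues - 1}.
#'
#' @export
setClass("ChainTopology", representation(
    chainId = "character",
    atoms   = "data.frame",
    dyads   = "DyadSequence"
))

setValidity("ChainTopology", function(object) {
    if (!object@chainId %in% c("A", "B"))
        return("chainId must be 'A' or 'B'")
    a <- object@atoms
    need <- c("residue", "name", "role", "element", "mass", "vdw")
    if (!all(need %in% names(a)))
        return(paste("atoms table must have columns:",
                     paste(need, collapse = ", ")))
    nres <- max(a$residue)
    if (!identical(sort(unique(a$residue)), seq_len(nres)))
        return("residue indices must be contiguous 1..n_res")
    if (length(object@dyads@symbols) != nres - 1L)
        return("dyad sequence length must equal n_res - 1")
    for (i in seq_len(nres)) {
        nm <- a$name[a$residue == i]
        if (sum(nm == "N") != 1L || sum(nm == "O") != 1L ||
            sum(nm == "CI") != 1L || sum(nm %in% c("CE", "CF")) != 2L)
            return(sprintf(
                "residue %d must expose exactly one N, one O, one CI and two of {CE, CF}", i))
    }
    if (any(a$mass <= 0) || any(a$vdw <= 0))
        return("atom masses and vdW radii must be positive")
    bad <- (a$name %in% c("N", "O") & a$role != "polar") |
           (a$name %in% c("CE", "CF", "CI") & a$role != "hydrophobic")
    if (any(bad))
        return("N and O must be polar; CE, CF, CI must be hydrophobic")
    TRUE
})

#' SystemTopology: two equal-length chains with global indexing
#'
#' The two-chain system studied throughout the package: chains A and B, each
#' of \code{n_res} residues. Residues are indexed globally 1..\code{2 n_res}
#' (A first, then B: with 30-residue chains, residues 1-30 are chain A and
#' 31-60 chain B); atoms are indexed globally in the same chain order.
#'
#' @slot chains list of two [ChainTopology-class] objects (A then B).
#'
#' @seealso [buildSystemTopology()], [atomTable()]
#' @export
setClass("SystemTopology", representation(chains = "list"))

setValidity("SystemTopology", function(object) {
    ch <- object@chains
    if (length(ch) != 2L ||
        !all(vapply(ch, is, logical(1), "ChainTopology")))
        return("chains must be a list of exactly two ChainTopology objects")
    if (ch[[1]]@chainId != "A" || ch[[2]]@chainId != "B")
        return("chains must be ordered (A, B)")
    if (max(ch[[1]]@atoms$residue) != max(ch[[2]]@atoms$residue))
        return("both chains must have the same number of residues")
    TRUE
})

#' Trajectory: time-ordered coordinate frames in an orthorhombic box
#'
#' Coordinates are in nm, times in ps. Each frame stores one row per atom of
#' the associated topology, in global atom order, plus the orthorhombic box
#' edge lengths (Lx, Ly, Lz).
#'
#' @slot coords list of numeric matrices (nAtoms x 3), one per frame.
#' @slot times numeric vector of frame times (ps), strictly increasing.
#' @slot boxes numeric matrix (nFrames x 3) of box edges (nm).
#'
#' @seealso [readTrajectory()], [writeTrajectory()], [generateTrajectory()]
#' @export
setClass("Trajectory", representation(
    coords = "list",
    times  = "numeric",
    boxes  = "matrix"
))

setValidity("Trajectory", function(object) {
    nf <- length(object@coords)
    if (nf == 0L) return("trajectory must contain at least one frame")
    if (length(object@times) != nf || nrow(object@boxes) != nf)
        return("times and boxes must have one entry per frame")
    if (nf > 1L && any(diff(object@times) <= 0))
        return("frame times must be strictly increasing")
    if (any(object@boxes <= 0))
        return("all box edges must be positive")
    nat <- vapply(object@coords, nrow, integer(1))
    if (any(nat != nat[1L]))
        return("all frames must have the same atom count")
    if (any(vapply(object@coords, ncol, integer(1)) != 3L))
        return("coordinates must be 3-column matrices")
    TRUE
})

#' ContactSpec: atom-class pair list and contact cutoffs
#'
#' The inter-chain contact definition: which named-atom classes are scanned
#' against each other and at which distance (nm) a pair counts as a contact.
#' An inter-chain atom pair is a contact when its minimum-image distance is
#' less than or equal to the class cutoff. The default spec (see
#' [defaultContactSpec()]) uses cutoffs calibrated as the first minima of the
#' corresponding inter-chain radial distribution functions: 0.38 nm for N-O,
#' 0.50 nm for CE_CF-CE_CF, 0.62 nm for CE_CF-CI and 0.73 nm for CI-CI. The
#' N-O class is polar (dipolar/hydrogen-bond proxy); the carbon classes are
#' hydrophobic. Backbone atoms never participate.
#'
#' @slot pairs data.frame with columns \code{class} (label), \code{namesA},
#'   \code{namesB} (lists of atom names on each side), \code{cutoff} (nm) and
#'   \code{polarity} ("polar"/"hydrophobic").
#'
#' @export
setClass("ContactSpec", representation(pairs = "data.frame"))

setValidity("ContactSpec", function(object) {
    p <- object@pairs
    need <- c("class", "namesA", "namesB", "cutoff", "polarity")
    if (!all(need %in% names(p)))
        return(paste("pairs must have columns:", paste(need, collapse = ", ")))
    if (any(p$cutoff <= 0)) return("all cutoffs must be positive")
    if (!all(p$polarity %in% c("polar", "hydrophobic")))
        return("polarity must be 'polar' or 'hydrophobic'")
    TRUE
})
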