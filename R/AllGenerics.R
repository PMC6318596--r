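#' Fraction and percentage of meso dyads
#'
#' @param x a [DyadSequence-class] or a plain character string over
#'   \{"r", "m"\}.
#' @return named list with \code{fraction} (count of "m" over sequence
#'   length) and \code{percent} (the fraction times 100, rounded
#'   half-away-from-zero to the nearest integer, the convention under which
#'   13/29 reports as 45 and 17/29 as 59).
#' @examples
#' mesoFraction(pnipamDyadSequences()$isotactic)$percent  # 59
#' @export
setGeneric("mesoFraction", function(x) standardGeneric("mesoFraction"))

#' Number of residues described by a topology
#' @param x a [ChainTopology-class] or [SystemTopology-class].
#' @return integer; for a system, the per-chain residue count.
#' @export
setGeneric("nResidues", function(x) standardGeneric("nResidues"))

#' Number of atoms described by a topology
#' @param x a [ChainTopology-class] or [SystemTopology-class].
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Flat atom table with global indices
#'
#' @param x a [SystemTopology-class].
#' @return data.frame with one row per atom in global order, columns
#'   \code{atom} (0-based global index), \code{chain}, \code{residue}
#'   (local 1..n_res), \code{residueGlobal} (1..2*n_res), \code{name},
#'   \code{role}, \code{element}, \code{mass}, \code{vdw}.
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))

#' Number of frames in a trajectory
#' @param x a [Trajectory-class].
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' Frame times in ps
#' @param x a [Trajectory-class].
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))

#' Extract a single frame
#' @param x a [Trajectory-class].
#' @param i frame index.
#' @return list with elements \code{time} (ps), \code{coords}
#'   (nAtoms x 3 matrix, nm) and \code{box} (length-3 edge vector, nm).
#' @export
setGeneric("getFrame", function(x, i) standardGeneric("getFrame"))
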