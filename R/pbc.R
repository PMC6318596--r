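#' Minimum-image distance in an orthorhombic box
#'
#' Euclidean distance between two points after wrapping each component
#' difference into (-L/2, L/2], the minimum image convention for an
#' orthorhombic periodic box.
#'
#' @param x1,x2 numeric 3-vectors, nm.
#' @param box length-3 vector of box edge lengths (Lx, Ly, Lz), nm.
#' @return distance in nm.
#' @examples
#' minimumImageDistance(c(0.1, 0, 0), c(8.9, 0, 0), c(9, 9, 9))  # 0.2
#' @export
minimumImageDistance <- function(x1, x2, box) {
    stopifnot(length(x1) == 3L, length(x2) == 3L, length(box) == 3L)
    if (any(box <= 0)) stop("box edges must be positive")
    d <- .mic(x1 - x2, box)
    sqrt(sum(d * d))
}

## wrap component differences into (-L/2, L/2]; works on vectors and
## matrices with columns recycled against box
.mic <- function(d, box) {
    if (is.matrix(d)) {
        for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
    } else {
        d <- d - box * round(d / box)
    }
    d
}

## all minimum-image distances between rows of A (n x 3) and rows of B
## (m x 3): returns n x m matrix. Vectorized per coordinate.
.micDistMatrix <- function(A, B, box) {
    dx <- outer(A[, 1], B[, 1], "-")
    dy <- outer(A[, 2], B[, 2], "-")
    dz <- outer(A[, 3], B[, 3], "-")
    dx <- dx - box[1] * round(dx / box[1])
    dy <- dy - box[2] * round(dy / box[2])
    dz <- dz - box[3] * round(dz / box[3])
    sqrt(dx * dx + dy * dy + dz * dz)
}

#' Make chains whole across periodic boundaries
#'
#' Rebuilds each chain by minimum-image chaining along its atom order: the
#' first atom of each chain anchors the chain, and every subsequent atom is
#' placed at its minimum-image position relative to the previous atom. Size
#' observables (radius of gyration, end-to-end distance, SASA) require whole
#' chains; pairwise contact analysis does not (it uses minimum-image
#' distances directly).
#'
#' @param coords nAtoms x 3 coordinate matrix (nm).
#' @param system a [SystemTopology-class] giving the chain boundaries.
#' @param box length-3 box edge vector (nm).
#' @return coordinate matrix of the same shape with each chain contiguous.
#' @export
unwrapChains <- function(coords, system, box) {
    at <- atomTable(system)
    out <- coords
    for (ch in unique(at$chain)) {
        idx <- which(at$chain == ch)
        for (k in idx[-1L]) {
            step <- .mic(out[k, ] - out[k - 1L, ], box)
            out[k, ] <- out[k - 1L, ] + step
        }
    }
    out
}
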