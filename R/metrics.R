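#' Mass-weighted radius of gyration of a frame
#'
#' Rg = sqrt(sum_i m_i |r_i - r_cm|^2 / sum_i m_i), computed after making
#' the chains whole across periodic boundaries (set \code{unwrap = FALSE}
#' when the coordinates are already whole).
#'
#' @param frame frame list from [getFrame()].
#' @param system a [SystemTopology-class].
#' @param selection optional integer vector of 1-based global atom row
#'   indices; default all atoms.
#' @param unwrap make chains whole first (default TRUE).
#' @return Rg in nm.
#' @export
radiusOfGyration <- function(frame, system, selection = NULL,
                             unwrap = TRUE) {
    at <- atomTable(system)
    co <- frame$coords
    if (unwrap) co <- unwrapChains(co, system, frame$box)
    if (is.null(selection)) selection <- seq_len(nrow(at))
    if (!length(selection)) stop("atom selection is empty")
    co <- co[selection, , drop = FALSE]
    m <- at$mass[selection]
    cm <- colSums(co * m) / sum(m)
    d2 <- rowSums(sweep(co, 2L, cm)^2)
    sqrt(sum(m * d2) / sum(m))
}

#' End-to-end distance of one chain
#'
#' Distance between the first backbone carbon of residue 1 and the last
#' backbone carbon of the final residue, measured on the unwrapped (whole)
#' chain — no minimum-image folding, so an extended chain reports its full
#' extension.
#'
#' @param frame frame list from [getFrame()].
#' @param system a [SystemTopology-class].
#' @param chain "A" or "B".
#' @param unwrap make chains whole first (default TRUE).
#' @return distance in nm.
#' @export
endToEndDistance <- function(frame, system, chain = "A", unwrap = TRUE) {
    at <- atomTable(system)
    co <- frame$coords
    if (unwrap) co <- unwrapChains(co, system, frame$box)
    nres <- nResidues(system)
    i1 <- which(at$chain == chain & at$residue == 1L & at$name == "C1")
    i2 <- which(at$chain == chain & at$residue == nres & at$name == "C2")
    sqrt(sum((co[i1, ] - co[i2, ])^2))
}

#' Average minimum inter-residue distance matrix
#'
#' For every pair of global residues (1..2*n_res; chain A then chain B),
#' the per-frame minimum over all heavy-atom pairs of the minimum-image
#' distance, averaged over the frames of the window. The matrix is
#' symmetric with a zero diagonal; the off-diagonal quadrants hold the
#' inter-chain map, the diagonal blocks the intra-chain maps.
#'
#' @param traj a [Trajectory-class].
#' @param system a [SystemTopology-class].
#' @param window length-2 time window in ps (default: all frames).
#' @return 2*n_res x 2*n_res numeric matrix, nm.
#' @export
minDistanceMatrix <- function(traj, system, window = NULL) {
    stopifnot(is(traj, "Trajectory"))
    tms <- frameTimes(traj)
    if (is.null(window)) window <- range(tms)
    sel <- which(tms >= window[1] & tms <= window[2])
    if (!length(sel)) stop("analysis window contains no frames")
    at <- atomTable(system)
    heavy <- which(at$element != "H")
    rg <- at$residueGlobal[heavy]
    nres2 <- 2L * nResidues(system)
    acc <- matrix(0, nres2, nres2)
    grp <- split(seq_along(heavy), rg)   # residue -> rows of heavy subset
    for (f in sel) {
        fr <- getFrame(traj, f)
        co <- fr$coords[heavy, , drop = FALSE]
        d <- .micDistMatrix(co, co, fr$box)
        # residue-block minimum via two-stage group minima
        m1 <- do.call(rbind, lapply(grp, function(ix)
            suppressWarnings(apply(d[ix, , drop = FALSE], 2L, min))))
        m2 <- do.call(cbind, lapply(grp, function(ix)
            suppressWarnings(apply(m1[, ix, drop = FALSE], 1L, min))))
        acc <- acc + m2
    }
    out <- acc / length(sel)
    diag(out) <- 0
    dimnames(out) <- list(seq_len(nres2), seq_len(nres2))
    out
}
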