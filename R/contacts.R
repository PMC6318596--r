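#' Default inter-chain contact specification
#'
#' The atom-class pair list and cutoff distances used to declare inter-chain
#' contacts, with cutoffs set at the first minima of the corresponding
#' inter-chain radial distribution functions: 0.38 nm for N-O (both
#' directions, the polar/hydrogen-bond proxy class), 0.50 nm for
#' CE_CF-CE_CF, 0.62 nm for CE_CF-CI (both directions) and 0.73 nm for
#' CI-CI (hydrophobic classes). CE and CF, the two isopropyl methyl carbons,
#' are pooled into one class. Backbone atoms are never scanned.
#'
#' @return a [ContactSpec-class].
#' @export
defaultContactSpec <- function() {
    p <- data.frame(
        class = c("N(A)-O(B)", "N(B)-O(A)", "CE_CF-CE_CF",
                  "CI-CI", "CE_CF-CI", "CI-CE_CF"),
        cutoff = c(0.38, 0.38, 0.50, 0.73, 0.62, 0.62),
        polarity = c("polar", "polar", "hydrophobic",
                     "hydrophobic", "hydrophobic", "hydrophobic"),
        stringsAsFactors = FALSE)
    p$namesA <- list("N", "O", c("CE", "CF"), "CI", c("CE", "CF"), "CI")
    p$namesB <- list("O", "N", c("CE", "CF"), "CI", "CI", c("CE", "CF"))
    new("ContactSpec", pairs = p)
}

setMethod("show", "ContactSpec", function(object) {
    p <- object@pairs
    cat("ContactSpec:", nrow(p), "atom-class pairs\n")
    for (k in seq_len(nrow(p)))
        cat(sprintf("  %-12s cutoff %.2f nm  (%s)\n",
                    p$class[k], p$cutoff[k], p$polarity[k]))
})

#' Detect inter-chain contacts in one frame
#'
#' Scans the side-chain atom-class pair list of \code{spec} over all
#' inter-chain atom pairs; a pair is a contact when its minimum-image
#' distance is less than or equal to the class cutoff. Both partner residues
#' of every contact are flagged.
#'
#' @param frame a frame as returned by [getFrame()] (list with
#'   \code{coords} and \code{box}).
#' @param system a [SystemTopology-class].
#' @param spec a [ContactSpec-class].
#' @return list with \code{contacts} (data.frame: \code{atomA}, \code{atomB}
#'   0-based global atom indices, \code{class}, \code{polarity},
#'   \code{distance} nm, \code{residueA}, \code{residueB} local residue
#'   indices) and \code{residueFlags} (logical vector over global residues
#'   1..2*n_res).
#' @export
detectContacts <- function(frame, system, spec = defaultContactSpec()) {
    at <- atomTable(system)
    specNames <- unique(unlist(c(spec@pairs$namesA, spec@pairs$namesB)))
    unknown <- setdiff(specNames, unique(at$name))
    if (length(unknown))
        stop("contact spec references atom name(s) absent from the ",
             "topology: ", paste(unknown, collapse = ", "))
    co <- frame$coords
    box <- frame$box
    nres <- nResidues(system)
    rows <- list()
    for (k in seq_len(nrow(spec@pairs))) {
        ia <- which(at$chain == "A" & at$name %in% spec@pairs$namesA[[k]])
        ib <- which(at$chain == "B" & at$name %in% spec@pairs$namesB[[k]])
        if (!length(ia) || !length(ib)) next
        d <- .micDistMatrix(co[ia, , drop = FALSE], co[ib, , drop = FALSE],
                            box)
        hit <- which(d <= spec@pairs$cutoff[k], arr.ind = TRUE)
        if (nrow(hit)) {
            gA <- ia[hit[, 1L]]; gB <- ib[hit[, 2L]]
            rows[[length(rows) + 1L]] <- data.frame(
                atomA = at$atom[gA], atomB = at$atom[gB],
                class = spec@pairs$class[k],
                polarity = spec@pairs$polarity[k],
                distance = d[hit],
                residueA = at$residue[gA], residueB = at$residue[gB],
                stringsAsFactors = FALSE)
        }
    }
    contacts <- if (length(rows)) do.call(rbind, rows) else
        data.frame(atomA = integer(0), atomB = integer(0),
                   class = character(0), polarity = character(0),
                   distance = numeric(0), residueA = integer(0),
                   residueB = integer(0), stringsAsFactors = FALSE)
    flags <- logical(2L * nres)
    if (nrow(contacts)) {
        flags[unique(contacts$residueA)] <- TRUE
        flags[nres + unique(contacts$residueB)] <- TRUE
    }
    list(contacts = contacts, residueFlags = flags)
}

#' Unique residue pairs in contact
#'
#' @param detection result of [detectContacts()].
#' @param system the matching [SystemTopology-class] (unused beyond
#'   interface symmetry; kept for clarity).
#' @return two-column integer matrix (residue of A, residue of B), one row
#'   per distinct residue pair in contact.
#' @export
residueContactPairs <- function(detection, system) {
    ct <- detection$contacts
    if (!nrow(ct)) return(matrix(integer(0), 0L, 2L))
    u <- unique(ct[, c("residueA", "residueB")])
    m <- as.matrix(u)
    dimnames(m) <- NULL
    matrix(as.integer(m), ncol = 2L)
}

#' Per-frame contact counts and residue flags over a trajectory
#'
#' The per-frame totals count contacting atom pairs (not unique residue
#' pairs): \code{nPolar} is the N-O class total over both directions,
#' \code{nHydrophobic} the sum of the three carbon classes.
#'
#' @param traj a [Trajectory-class].
#' @param system a [SystemTopology-class].
#' @param spec a [ContactSpec-class].
#' @param countBy \code{"atoms"} (default: contacting atom pairs) or
#'   \code{"residues"} (distinct residue pairs in contact).
#' @return list with \code{counts} (data.frame: \code{time}, \code{nPolar},
#'   \code{nHydrophobic}) and \code{residueFlags} (nFrames x 2*n_res logical
#'   matrix).
#' @export
contactTimeSeries <- function(traj, system, spec = defaultContactSpec(),
                              countBy = c("atoms", "residues")) {
    countBy <- match.arg(countBy)
    stopifnot(is(traj, "Trajectory"))
    nf <- nFrames(traj)
    nres <- nResidues(system)
    flags <- matrix(FALSE, nf, 2L * nres)
    np <- nh <- integer(nf)
    for (f in seq_len(nf)) {
        det <- detectContacts(getFrame(traj, f), system, spec)
        ct <- det$contacts
        if (countBy == "residues" && nrow(ct))
            ct <- ct[!duplicated(ct[, c("residueA", "residueB",
                                        "polarity")]), ]
        np[f] <- sum(ct$polarity == "polar")
        nh[f] <- sum(ct$polarity == "hydrophobic")
        flags[f, ] <- det$residueFlags
    }
    list(counts = data.frame(time = frameTimes(traj), nPolar = np,
                             nHydrophobic = nh),
         residueFlags = flags)
}

#' Inter-chain radial distribution function for one atom-class pair
#'
#' Histogram of minimum-image distances between the selected atoms of chain
#' A and of chain B, normalized by the ideal-gas expectation at the pair
#' density, averaged over frames:
#' g(r) = H(r) V / (N_pairs n_frames 4 pi r^2 dr).
#'
#' @param traj a [Trajectory-class].
#' @param system a [SystemTopology-class].
#' @param namesA,namesB atom names selected on chain A / chain B
#'   (e.g. \code{"N"} and \code{"O"}).
#' @param binWidth histogram bin width, nm (default 0.002).
#' @param rMax histogram range, nm; must not exceed the smallest box
#'   half-edge.
#' @return data.frame with \code{r} (bin centers, nm), \code{g} and raw
#'   \code{counts}.
#' @export
radialDistribution <- function(traj, system, namesA, namesB,
                               binWidth = 0.002, rMax = NULL) {
    stopifnot(is(traj, "Trajectory"))
    at <- atomTable(system)
    halfMin <- min(traj@boxes) / 2
    if (is.null(rMax)) rMax <- halfMin
    if (rMax > halfMin + 1e-12)
        stop("rMax must not exceed the smallest box half-edge (",
             format(halfMin), " nm)")
    ia <- which(at$chain == "A" & at$name %in% namesA)
    ib <- which(at$chain == "B" & at$name %in% namesB)
    if (!length(ia) || !length(ib))
        stop("atom selection is empty on one chain")
    breaks <- seq(0, rMax, by = binWidth)
    if (breaks[length(breaks)] < rMax) breaks <- c(breaks, rMax)
    counts <- numeric(length(breaks) - 1L)
    vols <- numeric(nFrames(traj))
    for (f in seq_len(nFrames(traj))) {
        fr <- getFrame(traj, f)
        d <- .micDistMatrix(fr$coords[ia, , drop = FALSE],
                            fr$coords[ib, , drop = FALSE], fr$box)
        h <- graphics::hist(d[d < rMax], breaks = breaks, plot = FALSE)
        counts <- counts + h$counts
        vols[f] <- prod(fr$box)
    }
    mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
    dr <- diff(breaks)
    npairs <- length(ia) * length(ib)
    shell <- 4 * pi * mid^2 * dr
    ideal <- nFrames(traj) * npairs * shell / mean(vols)
    data.frame(r = mid, g = counts / ideal, counts = counts)
}

#' First minimum of a radial distribution function
#'
#' After centered moving-average smoothing, locates the first local minimum
#' that follows the first local maximum of g(r) — the standard definition of
#' a coordination-shell boundary used to calibrate contact cutoffs. Ties are
#' broken toward smaller r.
#'
#' @param g data.frame as returned by [radialDistribution()] (columns
#'   \code{r}, \code{g}).
#' @param smoothingWindow moving-average window, bins (odd; default 5).
#' @return position of the first minimum, nm (a bin center).
#' @export
firstMinimum <- function(g, smoothingWindow = 5L) {
    y <- g$g; r <- g$r
    w <- as.integer(smoothingWindow)
    if (w > 1L) {
        if (w %% 2L == 0L) w <- w + 1L
        y <- as.numeric(stats::filter(y, rep(1 / w, w), sides = 2))
        keep <- !is.na(y)
        y <- y[keep]; r <- r[keep]
    }
    n <- length(y)
    if (n < 3L) stop("g(r) is too short to locate a first minimum")
    maxIdx <- NA_integer_
    for (k in 2:(n - 1L)) {
        if (y[k] >= y[k - 1L] && y[k] > y[k + 1L]) { maxIdx <- k; break }
    }
    if (is.na(maxIdx))
        stop("no interior maximum found in g(r); ",
             "longer sampling may be required")
    for (k in (maxIdx + 1L):(n - 1L)) {
        if (y[k] <= y[k - 1L] && y[k] < y[k + 1L]) return(r[k])
    }
    stop("no first minimum (local minimum followed by a rise) found in ",
         "g(r); longer sampling may be required")
}
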