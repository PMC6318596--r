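#' Junction decomposition of one chain's residue contact flags
#'
#' A junction is a maximal run of consecutive residues that are in
#' inter-chain contact; a single unflagged residue breaks a run (with
#' \code{gap > 0}, runs separated by at most \code{gap} unflagged residues
#' are merged). Reports NJ (number of junctions), LJ_mean (mean number of
#' contacting residues per junction) and NR (total contacting residues);
#' NR = NJ * LJ_mean holds exactly.
#'
#' @param flags logical vector over the chain's residues (index 1..n_res).
#' @param gap maximum number of unflagged residues bridged inside one
#'   junction (default 0: strict adjacency).
#' @return list with \code{NJ}, \code{LJmean} (NA when NJ = 0), \code{NR}
#'   and \code{junctions} (data.frame: \code{start}, \code{end},
#'   \code{length} = contacting residues in the junction).
#' @examples
#' fl <- rep(FALSE, 30); fl[c(5, 12, 13)] <- TRUE
#' junctionsPerFrame(fl)   # NJ 2, LJmean 1.5, NR 3
#' @export
junctionsPerFrame <- function(flags, gap = 0L) {
    stopifnot(is.logical(flags))
    if (!any(flags))
        return(list(NJ = 0L, LJmean = NA_real_, NR = 0L,
                    junctions = data.frame(start = integer(0),
                                           end = integer(0),
                                           length = integer(0))))
    idx <- which(flags)
    brk <- c(0L, which(diff(idx) > gap + 1L), length(idx))
    starts <- ends <- lens <- integer(length(brk) - 1L)
    for (k in seq_len(length(brk) - 1L)) {
        run <- idx[(brk[k] + 1L):brk[k + 1L]]
        starts[k] <- run[1L]; ends[k] <- run[length(run)]
        lens[k] <- length(run)
    }
    list(NJ = length(lens), LJmean = sum(lens) / length(lens),
         NR = sum(lens),
         junctions = data.frame(start = starts, end = ends, length = lens))
}

#' Per-frame, per-chain junction statistics of a trajectory
#'
#' Runs contact detection on every frame and decomposes each chain's
#' residue flags into junctions.
#'
#' @param traj a [Trajectory-class].
#' @param system a [SystemTopology-class].
#' @param spec a [ContactSpec-class].
#' @param gap see [junctionsPerFrame()].
#' @return data.frame with one row per frame and chain: \code{frame},
#'   \code{time} (ps), \code{chain}, \code{NJ}, \code{LJmean}, \code{NR}.
#' @export
junctionTimeSeries <- function(traj, system, spec = defaultContactSpec(),
                               gap = 0L) {
    ts <- contactTimeSeries(traj, system, spec)
    junctionStatsFromFlags(ts$residueFlags, nResidues(system),
                           times = frameTimes(traj), gap = gap)
}

#' Junction statistics from a precomputed residue-flag matrix
#'
#' @param flags nFrames x 2*n_res logical matrix (chain A residues first).
#' @param nRes residues per chain.
#' @param times optional frame times (ps); defaults to 0-based frame index.
#' @param gap see [junctionsPerFrame()].
#' @return as [junctionTimeSeries()].
#' @export
junctionStatsFromFlags <- function(flags, nRes, times = NULL, gap = 0L) {
    nf <- nrow(flags)
    if (is.null(times)) times <- seq_len(nf) - 1
    out <- vector("list", 2L * nf)
    for (f in seq_len(nf)) {
        for (c2 in 1:2) {
            sel <- (c2 - 1L) * nRes + seq_len(nRes)
            j <- junctionsPerFrame(flags[f, sel], gap = gap)
            out[[2L * (f - 1L) + c2]] <- data.frame(
                frame = f, time = times[f], chain = c("A", "B")[c2],
                NJ = j$NJ, LJmean = j$LJmean, NR = j$NR,
                stringsAsFactors = FALSE)
        }
    }
    do.call(rbind, out)
}

#' Trajectory-level junction summary
#'
#' Means and population standard deviations of NR, NJ and LJ_mean per chain
#' over the frames of the analysis window in which that chain has at least
#' one inter-chain contact; contact-free frames are excluded from all three
#' averages. The trajectory-level LJ_mean is by default the unweighted mean
#' of per-frame LJ_mean values; \code{ljWeighting = "junctions"} pools all
#' junctions instead (sum NR / sum NJ over qualifying frames).
#'
#' @param stats data.frame from [junctionTimeSeries()].
#' @param window length-2 numeric (t_start, t_end) in ps; defaults to the
#'   full span of \code{stats}.
#' @param ljWeighting \code{"frames"} or \code{"junctions"}.
#' @return data.frame with one row per chain: means and SDs of NR, NJ,
#'   LJ_mean, \code{nFramesWithContact}, \code{windowStart},
#'   \code{windowEnd} and an \code{empty} flag set when no frame of the
#'   window has a contact for that chain (the statistics are then NA, not
#'   zero).
#' @export
summarizeJunctions <- function(stats, window = NULL,
                               ljWeighting = c("frames", "junctions")) {
    ljWeighting <- match.arg(ljWeighting)
    span <- range(stats$time)
    if (is.null(window)) window <- span
    if (window[1] > window[2] || window[2] < span[1] || window[1] > span[2])
        stop("analysis window [", window[1], ", ", window[2],
             "] lies outside the trajectory span [", span[1], ", ",
             span[2], "]")
    sel <- stats$time >= window[1] & stats$time <= window[2]
    popSD <- function(x) sqrt(mean((x - mean(x))^2))
    rows <- lapply(c("A", "B"), function(ch) {
        s <- stats[sel & stats$chain == ch & stats$NR >= 1L, ]
        if (!nrow(s))
            return(data.frame(chain = ch, meanNR = NA_real_, sdNR = NA_real_,
                              meanNJ = NA_real_, sdNJ = NA_real_,
                              meanLJ = NA_real_, sdLJ = NA_real_,
                              nFramesWithContact = 0L,
                              windowStart = window[1], windowEnd = window[2],
                              empty = TRUE, stringsAsFactors = FALSE))
        lj <- if (ljWeighting == "frames") mean(s$LJmean) else
            sum(s$NR) / sum(s$NJ)
        data.frame(chain = ch,
                   meanNR = mean(s$NR), sdNR = popSD(s$NR),
                   meanNJ = mean(s$NJ), sdNJ = popSD(s$NJ),
                   meanLJ = lj, sdLJ = popSD(s$LJmean),
                   nFramesWithContact = nrow(s),
                   windowStart = window[1], windowEnd = window[2],
                   empty = FALSE, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
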