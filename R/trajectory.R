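#' Construct a Trajectory
#'
#' @param coords list of nAtoms x 3 coordinate matrices (nm), one per frame.
#' @param times numeric frame times (ps), strictly increasing.
#' @param boxes either a length-3 box edge vector reused for every frame or
#'   an nFrames x 3 matrix (nm).
#' @return a [Trajectory-class].
#' @export
Trajectory <- function(coords, times, boxes) {
    if (!is.list(coords)) coords <- list(coords)
    if (!is.matrix(boxes))
        boxes <- matrix(rep(boxes, each = length(coords)), ncol = 3L)
    new("Trajectory", coords = coords, times = as.numeric(times),
        boxes = boxes)
}

#' @rdname nFrames
#' @export
setMethod("nFrames", "Trajectory", function(x) length(x@coords))

#' @rdname frameTimes
#' @export
setMethod("frameTimes", "Trajectory", function(x) x@times)

#' @rdname getFrame
#' @export
setMethod("getFrame", "Trajectory", function(x, i) {
    stopifnot(i >= 1L, i <= nFrames(x))
    list(time = x@times[i], coords = x@coords[[i]], box = x@boxes[i, ])
})

setMethod("show", "Trajectory", function(object) {
    nf <- nFrames(object)
    cat(sprintf(
        "Trajectory: %d frame(s) x %d atoms, t = %.6g..%.6g ps, box %s nm\n",
        nf, nrow(object@coords[[1L]]), object@times[1L], object@times[nf],
        paste(format(object@boxes[1L, ], digits = 4), collapse = " x ")))
})

#' Read a multi-frame GRO or multi-model PDB trajectory
#'
#' Coordinates are returned in nm (PDB angstrom values are divided by 10).
#' Frame order is preserved. The atom count of every frame must match the
#' topology.
#'
#' @param path input file.
#' @param topology the [SystemTopology-class] the frames describe.
#' @param format \code{"gro_multiframe"} or \code{"pdb_multimodel"}.
#' @return a [Trajectory-class].
#' @export
readTrajectory <- function(path, topology,
                           format = c("gro_multiframe", "pdb_multimodel")) {
    format <- match.arg(format)
    if (!file.exists(path)) stop("trajectory file not found: ", path)
    lines <- readLines(path)
    natom <- nAtoms(topology)
    switch(format,
           gro_multiframe = .readGRO(lines, natom),
           pdb_multimodel = .readPDB(lines, natom))
}

.numOrStop <- function(txt, lineno, what) {
    v <- suppressWarnings(as.numeric(txt))
    if (any(is.na(v)))
        stop(sprintf("unparseable %s at line %d", what, lineno))
    v
}

.readGRO <- function(lines, natom) {
    coords <- list(); times <- numeric(0); boxes <- NULL
    i <- 1L; frame <- 0L
    while (i <= length(lines)) {
        if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
        frame <- frame + 1L
        title <- lines[i]
        tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
        t <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else frame - 1
        if (i + 1L > length(lines))
            stop(sprintf("truncated frame %d: missing atom count", frame))
        n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
        if (is.na(n))
            stop(sprintf("unparseable atom count at line %d", i + 1L))
        if (n != natom)
            stop(sprintf(
                "atom count mismatch in frame %d: file has %d, topology has %d",
                frame, n, natom))
        if (i + 1L + n + 1L > length(lines))
            stop(sprintf("truncated frame %d: expected %d atom lines + box",
                         frame, n))
        xyz <- matrix(0, n, 3L)
        for (k in seq_len(n)) {
            ln <- lines[i + 1L + k]
            if (nchar(ln) < 44L)
                stop(sprintf("unparseable atom record at line %d",
                             i + 1L + k))
            xyz[k, ] <- .numOrStop(
                c(substr(ln, 21, 28), substr(ln, 29, 36), substr(ln, 37, 44)),
                i + 1L + k, "coordinates")
        }
        boxline <- i + 1L + n + 1L
        bx <- .numOrStop(strsplit(trimws(lines[boxline]), "\\s+")[[1L]],
                         boxline, "box line")
        if (length(bx) < 3L)
            stop(sprintf("unparseable box line at line %d", boxline))
        if (length(bx) > 3L && any(abs(bx[4:length(bx)]) > 1e-9))
            stop("triclinic boxes are not supported (off-diagonal box ",
                 "components found); only orthorhombic boxes are handled")
        coords[[frame]] <- xyz
        times <- c(times, t)
        boxes <- rbind(boxes, bx[1:3])
        i <- boxline + 1L
    }
    if (frame == 0L) stop("no frames found in GRO file")
    Trajectory(coords, times, boxes)
}

.readPDB <- function(lines, natom) {
    box <- NULL
    cr <- grep("^CRYST1", lines)
    if (length(cr)) {
        ln <- lines[cr[1L]]
        abc <- .numOrStop(c(substr(ln, 7, 15), substr(ln, 16, 24),
                            substr(ln, 25, 33)), cr[1L], "CRYST1 record")
        ang <- suppressWarnings(as.numeric(
            c(substr(ln, 34, 40), substr(ln, 41, 47), substr(ln, 48, 54))))
        if (any(!is.na(ang)) && any(abs(ang - 90) > 1e-6, na.rm = TRUE))
            stop("triclinic boxes are not supported; CRYST1 angles must be 90")
        box <- abc / 10  # angstrom -> nm
    }
    coords <- list(); times <- numeric(0)
    cur <- NULL; frame <- 0L; inModel <- FALSE; t <- NA_real_
    flush <- function() {
        if (is.null(cur)) return()
        if (nrow(cur) != natom)
            stop(sprintf(
                "atom count mismatch in frame %d: file has %d, topology has %d",
                frame, nrow(cur), natom))
        coords[[frame]] <<- cur
        times <<- c(times, if (is.na(t)) frame - 1 else t)
        cur <<- NULL; t <<- NA_real_
    }
    for (i in seq_along(lines)) {
        ln <- lines[i]
        rec <- substr(ln, 1, 6)
        if (startsWith(rec, "MODEL")) {
            frame <- frame + 1L
            cur <- matrix(numeric(0), 0L, 3L)
            inModel <- TRUE
        } else if (startsWith(rec, "REMARK")) {
            tm <- regmatches(ln, regexpr("TIME=\\s*[-0-9.eE+]+", ln))
            if (length(tm)) t <- as.numeric(sub("TIME=\\s*", "", tm))
        } else if (rec == "ATOM  " || rec == "HETATM") {
            if (!inModel) {  # single-model file without MODEL records
                frame <- frame + 1L
                cur <- matrix(numeric(0), 0L, 3L)
                inModel <- TRUE
            }
            if (nchar(ln) < 54L)
                stop(sprintf("unparseable ATOM record at line %d", i))
            xyz <- .numOrStop(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                substr(ln, 47, 54)), i, "ATOM coordinates")
            cur <- rbind(cur, xyz / 10)  # angstrom -> nm
        } else if (startsWith(rec, "ENDMDL")) {
            flush(); inModel <- FALSE
        }
    }
    if (!is.null(cur)) flush()
    if (frame == 0L) stop("no frames found in PDB file")
    if (is.null(box))
        stop("PDB trajectory lacks a CRYST1 record; box is required")
    Trajectory(coords, times, matrix(rep(box, each = frame), ncol = 3L))
}

#' Write a trajectory as multi-frame GRO or multi-model PDB
#'
#' GRO frames carry the time on the title line (\code{t=} tag), fixed-column
#' atom records without velocities, and the three box edge lengths on the box
#' line. PDB output carries one CRYST1 record (edges converted to angstrom)
#' and MODEL/ENDMDL blocks with a \code{REMARK 6 TIME=} line per model.
#'
#' @param traj a [Trajectory-class].
#' @param topology matching [SystemTopology-class] (atom/residue names).
#' @param path output file.
#' @param format \code{"gro_multiframe"} or \code{"pdb_multimodel"}.
#' @return \code{path}, invisibly.
#' @export
writeTrajectory <- function(traj, topology, path,
                            format = c("gro_multiframe", "pdb_multimodel")) {
    format <- match.arg(format)
    stopifnot(is(traj, "Trajectory"))
    if (nFrames(traj) < 1L) stop("refusing to write an empty trajectory")
    at <- atomTable(topology)
    if (nrow(traj@coords[[1L]]) != nrow(at))
        stop("trajectory atom count does not match topology")
    con <- file(path, "w")
    on.exit(close(con))
    if (format == "gro_multiframe") {
        for (f in seq_len(nFrames(traj))) {
            fr <- getFrame(traj, f)
            writeLines(sprintf("PNIPAM two-chain system, t= %.5f", fr$time),
                       con)
            writeLines(sprintf("%5d", nrow(at)), con)
            writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                               at$residueGlobal %% 100000L, "NIP", at$name,
                               (at$atom + 1L) %% 100000L,
                               fr$coords[, 1], fr$coords[, 2], fr$coords[, 3]),
                       con)
            writeLines(sprintf("%10.5f%10.5f%10.5f",
                               fr$box[1], fr$box[2], fr$box[3]), con)
        }
    } else {
        bx <- traj@boxes[1L, ] * 10
        writeLines(sprintf(
            "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
            bx[1], bx[2], bx[3], 90, 90, 90), con)
        for (f in seq_len(nFrames(traj))) {
            fr <- getFrame(traj, f)
            writeLines(sprintf("MODEL     %4d", f), con)
            writeLines(sprintf("REMARK   6 TIME= %.5f PS", fr$time), con)
            xyz <- fr$coords * 10
            writeLines(sprintf(
                "ATOM  %5d %-4s%-4s%1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                (at$atom + 1L) %% 100000L, at$name, "NIP", at$chain,
                at$residueGlobal %% 10000L,
                xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, at$element), con)
            writeLines("ENDMDL", con)
        }
        writeLines("END", con)
    }
    invisible(path)
}
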