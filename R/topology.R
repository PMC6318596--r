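## Heavy-atom pseudo-residue used throughout: two backbone carbons plus the
## five side-chain atoms of the isopropylamide group. Hydrogens are not part
## of the synthetic model; when a topology does carry them they participate
## in SASA (Bondi H radius) but never in contacts.
.RESIDUE_ATOMS <- data.frame(
    name    = c("C1", "C2", "N", "O", "CI", "CE", "CF"),
    role    = c("backbone", "backbone", "polar", "polar",
                "hydrophobic", "hydrophobic", "hydrophobic"),
    element = c("C", "C", "N", "O", "C", "C", "C"),
    stringsAsFactors = FALSE
)

#' Bondi van der Waals radii (nm)
#'
#' Default per-element radii used for Shrake-Rupley SASA and topology
#' construction: C 0.170, N 0.155, O 0.152, H 0.120 nm.
#'
#' @return named numeric vector, nm.
#' @export
bondiRadii <- function() {
    c(C = 0.170, N = 0.155, O = 0.152, H = 0.120)
}

#' Standard atomic masses (amu)
#'
#' @return named numeric vector for the elements used in the heavy-atom
#'   model (C, N, O, H).
#' @export
atomicMasses <- function() {
    c(C = 12.011, N = 14.007, O = 15.999, H = 1.008)
}

## molar mass of the C6H11NO repeat unit, g/mol; chain-end hydrogens ignored
.MONOMER_MW <- 113.16

.buildChainTopology <- function(chainId, dyads, vdwTable, masses) {
    nres <- length(dyads) + 1L
    per <- .RESIDUE_ATOMS
    missingV <- setdiff(unique(per$element), names(vdwTable))
    if (length(missingV))
        stop("no van der Waals radius configured for element(s): ",
             paste(missingV, collapse = ", "))
    missingM <- setdiff(unique(per$element), names(masses))
    if (length(missingM))
        stop("no mass configured for element(s): ",
             paste(missingM, collapse = ", "))
    atoms <- do.call(rbind, lapply(seq_len(nres), function(i) {
        data.frame(residue = i, name = per$name, role = per$role,
                   element = per$element,
                   mass = unname(masses[per$element]),
                   vdw = unname(vdwTable[per$element]),
                   stringsAsFactors = FALSE)
    }))
    rownames(atoms) <- NULL
    new("ChainTopology", chainId = chainId, atoms = atoms, dyads = dyads)
}

#' Build the two-chain system topology
#'
#' Constructs a pair of chains with identical stereochemistry (a "pair of
#' equal stereoisomers") from one dyad sequence. Chain A holds global
#' residues 1..n_res, chain B holds n_res+1..2*n_res, so with the default
#' 30-mers residue 31 is residue 1 of chain B.
#'
#' @param dyads a [DyadSequence-class] (or plain "rm..." string); its length
#'   plus one is the residue count per chain.
#' @param vdwTable named per-element van der Waals radii in nm
#'   (default [bondiRadii()]).
#' @param masses named per-element masses in amu (default [atomicMasses()]).
#' @return a [SystemTopology-class].
#' @examples
#' sys <- buildSystemTopology(pnipamDyadSequences()$atactic)
#' nResidues(sys); nAtoms(sys)
#' @export
buildSystemTopology <- function(dyads, vdwTable = bondiRadii(),
                                masses = atomicMasses()) {
    dyads <- as(dyads, "DyadSequence")
    new("SystemTopology", chains = list(
        .buildChainTopology("A", dyads, vdwTable, masses),
        .buildChainTopology("B", dyads, vdwTable, masses)
    ))
}

#' @rdname nResidues
#' @export
setMethod("nResidues", "ChainTopology", function(x) max(x@atoms$residue))

#' @rdname nResidues
#' @export
setMethod("nResidues", "SystemTopology",
          function(x) nResidues(x@chains[[1L]]))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "ChainTopology", function(x) nrow(x@atoms))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SystemTopology",
          function(x) sum(vapply(x@chains, nAtoms, integer(1))))

#' @rdname atomTable
#' @export
setMethod("atomTable", "SystemTopology", function(x) {
    nres <- nResidues(x)
    tabs <- lapply(seq_along(x@chains), function(k) {
        ch <- x@chains[[k]]
        a <- ch@atoms
        data.frame(chain = ch@chainId,
                   residue = a$residue,
                   residueGlobal = a$residue + (k - 1L) * nres,
                   name = a$name, role = a$role, element = a$element,
                   mass = a$mass, vdw = a$vdw,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, tabs)
    out <- cbind(atom = seq_len(nrow(out)) - 1L, out)
    rownames(out) <- NULL
    out
})

#' Dyad sequences of a system
#' @param system a [SystemTopology-class].
#' @return list of the per-chain [DyadSequence-class] objects (named A, B).
#' @export
systemDyads <- function(system) {
    stopifnot(is(system, "SystemTopology"))
    list(A = system@chains[[1L]]@dyads, B = system@chains[[2L]]@dyads)
}

setMethod("show", "SystemTopology", function(object) {
    mf <- mesoFraction(object@chains[[1L]]@dyads)
    cat(sprintf(paste0(
        "SystemTopology: 2 chains x %d residues (%d atoms), m = %d%%\n"),
        nResidues(object), nAtoms(object), mf$percent))
})

setMethod("show", "ChainTopology", function(object) {
    cat(sprintf("ChainTopology %s: %d residues, %d atoms\n",
                object@chainId, nResidues(object), nAtoms(object)))
})

#' Write a system topology as JSON
#'
#' Serializes the flat atom table plus the dyad strings so that a topology
#' can be exchanged as structured text.
#'
#' @param system a [SystemTopology-class].
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeTopologyJSON <- function(system, path) {
    stopifnot(is(system, "SystemTopology"))
    obj <- list(
        n_res = nResidues(system),
        dyads = lapply(systemDyads(system), as.character),
        atoms = atomTable(system)
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' Read a system topology from JSON
#'
#' @param path file written by [writeTopologyJSON()] (or equivalent).
#' @return a [SystemTopology-class].
#' @export
readTopologyJSON <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    dyads <- DyadSequence(obj$dyads$A)
    a <- obj$atoms
    el <- unique(a[, c("element", "vdw", "mass")])
    vdw <- stats::setNames(el$vdw, el$element)
    ms <- stats::setNames(el$mass, el$element)
    buildSystemTopology(dyads, vdwTable = vdw, masses = ms)
}
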