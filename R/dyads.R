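#' Construct a DyadSequence
#'
#' @param x character: either a single string like \code{"rmmr"} or a
#'   character vector of single symbols.
#' @return a [DyadSequence-class].
#' @examples
#' DyadSequence("rmmr")
#' @export
DyadSequence <- function(x) {
    stopifnot(is.character(x))
    if (length(x) == 1L && nchar(x) > 1L)
        x <- strsplit(x, "", fixed = TRUE)[[1L]]
    new("DyadSequence", symbols = x)
}

#' @describeIn DyadSequence coerce to a plain string.
#' @param object,... standard S4 arguments.
#' @export
setMethod("as.character", "DyadSequence", function(x, ...) {
    paste(x@symbols, collapse = "")
})

#' @export
setMethod("length", "DyadSequence", function(x) length(x@symbols))

setMethod("show", "DyadSequence", function(object) {
    mf <- mesoFraction(object)
    cat(sprintf("DyadSequence of %d dyads (m = %d%%)\n  %s\n",
                length(object@symbols), mf$percent, as.character(object)))
})

## round half away from zero (base round() is banker's rounding)
roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @rdname mesoFraction
#' @export
setMethod("mesoFraction", "DyadSequence", function(x) {
    f <- sum(x@symbols == "m") / length(x@symbols)
    list(fraction = f, percent = as.integer(roundHalfAway(100 * f)))
})

#' @rdname mesoFraction
#' @export
setMethod("mesoFraction", "character", function(x) {
    mesoFraction(DyadSequence(x))
})

#' Reference PNIPAM 30-mer dyad sequences
#'
#' The two 29-dyad stereoisomer sequences used throughout: an atactic chain
#' with 45% meso dyads (the composition obtained with non-stereoselective
#' synthesis) and an isotactic-rich chain with 59% meso dyads.
#'
#' @return named list of two [DyadSequence-class] objects,
#'   \code{atactic} and \code{isotactic}.
#' @examples
#' vapply(pnipamDyadSequences(), function(s) mesoFraction(s)$percent, 0L)
#' @export
pnipamDyadSequences <- function() {
    list(
        atactic   = DyadSequence("rrrmmrmrrrrmmrrmmmmrmmrmrmrrr"),
        isotactic = DyadSequence("rmmrrmrrmmrrmmmmrmmrrmmmrrmmm")
    )
}

#' Generate a Bernoullian dyad sequence
#'
#' Draws the \code{n_res - 1} dyads of a chain independently with
#' P(meso) = \code{pMeso}, the Bernoullian stereochemistry model under which
#' free-radical PNIPAM synthesis is usually described.
#'
#' @param nRes residue count of the chain (>= 2).
#' @param pMeso probability of a meso dyad, in [0, 1].
#' @param seed integer seed; the draw is reproducible for a fixed seed.
#' @return a [DyadSequence-class] of length \code{nRes - 1}.
#' @examples
#' generateBernoullianSequence(30, 0.45, seed = 7)
#' @export
generateBernoullianSequence <- function(nRes, pMeso, seed) {
    if (!is.numeric(nRes) || nRes < 2)
        stop("nRes must be at least 2 (a chain needs >= 1 dyad)")
    if (!is.numeric(pMeso) || pMeso < 0 || pMeso > 1)
        stop("pMeso must be a probability in [0, 1]")
    set.seed(as.integer(seed))
    s <- ifelse(stats::runif(nRes - 1) < pMeso, "m", "r")
    DyadSequence(s)
}

#' Excess meso-dyad count between two stereoisomer systems
#'
#' Counts how many more meso dyads an \code{nChains}-chain ensemble of the
#' first stereoisomer carries than the same ensemble of the second. For the
#' reference pair (59% vs 45% meso, two chains) this is the "extra eight meso
#' dyads" that feeds the dyad-based hydration free-energy estimate.
#'
#' @param seqIso dyad sequence of the first (e.g. isotactic-rich) chain.
#' @param seqAtactic dyad sequence of the second (e.g. atactic) chain.
#' @param nChains number of chains per ensemble (>= 1).
#' @return integer, possibly negative.
#' @examples
#' s <- pnipamDyadSequences()
#' excessMesoCount(s$isotactic, s$atactic, nChains = 2)  # 8
#' @export
excessMesoCount <- function(seqIso, seqAtactic, nChains = 2L) {
    seqIso <- as(seqIso, "DyadSequence")
    seqAtactic <- as(seqAtactic, "DyadSequence")
    if (length(seqIso) != length(seqAtactic))
        stop("dyad sequences must have equal length")
    if (nChains < 1) stop("nChains must be >= 1")
    as.integer(nChains) *
        (sum(seqIso@symbols == "m") - sum(seqAtactic@symbols == "m"))
}

setAs("character", "DyadSequence", function(from) DyadSequence(from))
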