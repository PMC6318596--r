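# Independent oracles and small fixtures shared across tests.

# brute-force minimum-image distance: explicit minimum over all 27
# periodic image translations
bruteMinImage <- function(x1, x2, box) {
  best <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    img <- x2 + c(ix, iy, iz) * box
    best <- min(best, sqrt(sum((x1 - img)^2)))
  }
  best
}

# brute-force contact scan: enumerate every inter-chain atom pair, assign
# its class from the atom-name rule table, and apply distance <= cutoff.
# Written as a flat pair-list computation, independent of the per-class
# matrix scan used by detectContacts().
bruteContacts <- function(coords, box, system, spec = defaultContactSpec()) {
  at <- atomTable(system)
  rule <- data.frame(
    a = c("N", "O", "CE", "CE", "CF", "CF", "CI", "CE", "CF", "CI", "CI"),
    b = c("O", "N", "CE", "CF", "CE", "CF", "CI", "CI", "CI", "CE", "CF"),
    cutoff = c(0.38, 0.38, 0.50, 0.50, 0.50, 0.50, 0.73,
               0.62, 0.62, 0.62, 0.62),
    stringsAsFactors = FALSE)
  ia <- which(at$chain == "A" & at$name %in% c("N", "O", "CE", "CF", "CI"))
  ib <- which(at$chain == "B" & at$name %in% c("N", "O", "CE", "CF", "CI"))
  pairs <- expand.grid(i = ia, j = ib)
  key <- paste(at$name[pairs$i], at$name[pairs$j])
  cut <- rule$cutoff[match(key, paste(rule$a, rule$b))]
  keep <- !is.na(cut)
  pairs <- pairs[keep, ]; cut <- cut[keep]
  d <- vapply(seq_len(nrow(pairs)), function(k) {
    delta <- coords[pairs$i[k], ] - coords[pairs$j[k], ]
    delta <- delta - box * round(delta / box)
    sqrt(sum(delta^2))
  }, numeric(1))
  hit <- d <= cut
  data.frame(i = pairs$i[hit], j = pairs$j[hit], distance = d[hit])
}

# run-length-encoding junction oracle built on base rle()
rleJunctionOracle <- function(flags) {
  r <- rle(as.logical(flags))
  lens <- r$lengths[r$values]
  if (!length(lens)) return(list(NJ = 0L, LJmean = NA_real_, NR = 0L))
  list(NJ = length(lens), LJmean = mean(lens), NR = sum(lens))
}

# small two-chain system for fast tests
tinySystem <- function(nRes = 4L, pMeso = 0.5, seed = 11L) {
  buildSystemTopology(generateBernoullianSequence(nRes, pMeso, seed))
}

# frame constructor for hand-placed coordinates
makeFrame <- function(coords, box) {
  list(time = 0, coords = coords, box = rep(box, length.out = 3L))
}

# coordinates with every atom far from the others, then selected atoms
# moved to prescribed positions
spreadCoords <- function(system, spacing = 2.0) {
  n <- nAtoms(system)
  g <- ceiling(n^(1 / 3))
  idx <- seq_len(n) - 1L
  cbind(idx %% g, (idx %/% g) %% g, idx %/% g^2) * spacing
}
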