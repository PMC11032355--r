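# Shared experiment recipes used by the acceptance-style tests. Each takes a
# base seed so every run derives all randomness from one integer.

# percent 16S divergence of majority representatives vs tree distance
divergenceVsDistance <- function(sim, tree, band = 60L) {
  dm <- ape::cophenetic.phylo(tree)
  gs <- simGenomes(sim)
  ids <- sort(names(gs))
  reps <- vapply(gs[ids], function(g)
    selectRepresentative(rrnaCopies(g)), character(1))
  n <- length(ids)
  x <- numeric(0); y <- numeric(0)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      idy <- if (reps[i] == reps[j]) 100 else
        percentIdentity(globalAlign(reps[i], reps[j], band = band))
      x <- c(x, dm[ids[i], ids[j]])
      y <- c(y, 100 - idy)
    }
  }
  data.frame(x = x, y = y)
}

# count pairs that would be flagged as transfers, evaluating ANI lazily
# (only for pairs that already exceed the identity threshold)
countFlaggablePairs <- function(genomes, idThreshold = 99.9,
                                sepThreshold = 95, band = 60L) {
  ids <- sort(names(genomes))
  reps <- vapply(genomes[ids], function(g)
    selectRepresentative(rrnaCopies(g)), character(1))
  n <- length(ids)
  flags <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      idy <- if (reps[i] == reps[j]) 100 else
        percentIdentity(globalAlign(reps[i], reps[j], band = band))
      if (idy > idThreshold) {
        a <- computeANI(genomes[[ids[i]]], genomes[[ids[j]]])@ani
        if (!is.na(a) && a < sepThreshold) flags <- flags + 1L
      }
    }
  }
  flags
}

# the bacterial genus used for transfer-recovery experiments: rate factor and
# depth are chosen so expected 16S divergence at the ANI-95 boundary
# (genome distance ~0.052 subst/site) is 0.15 * 5.2% ~ 0.78% > 0.1%; in
# count terms that is ~12 expected differences over 1550 bp, so the Poisson
# probability that a natural well-separated pair slips above the 99.9%
# identity threshold (<= 1 difference) is ~7e-5 and no natural pair can be
# flagged
hgtGenusParams <- function() {
  simParams(nSpecies = 30L, treeDepth = 0.15, nGenes = 10L, geneLen = 500L,
            rrnaLen = 1550L, rrnaCopyNumber = 4L, rrnaRateFactor = 0.15)
}

# pick n well-separated (ANI below aniMax) species pairs with no species
# reused, so planted transfers cannot overwrite one another's recipients
pickDisjointSeparatedPairs <- function(aniMat, n, aniMax = 93) {
  cand <- which(upper.tri(aniMat) & aniMat < aniMax, arr.ind = TRUE)
  cand <- cand[sample(nrow(cand)), , drop = FALSE]
  used <- character(0)
  keep <- matrix(0L, 0, 2)
  for (r in seq_len(nrow(cand))) {
    sp <- c(rownames(aniMat)[cand[r, 1]], colnames(aniMat)[cand[r, 2]])
    if (!any(sp %in% used)) {
      keep <- rbind(keep, cand[r, , drop = FALSE])
      used <- c(used, sp)
      if (nrow(keep) == n) break
    }
  }
  if (nrow(keep) < n) stop("not enough disjoint well-separated pairs")
  list(donors = rownames(aniMat)[keep[, 1]],
       recipients = colnames(aniMat)[keep[, 2]])
}

# intraspecific star radiation with a planted three-variant rRNA array under
# gene conversion (the E. coli-like mixture experiment)
mixtureExperiment <- function(seed, nSpecies = 60L, gamma = 15,
                              depth = 0.3) {
  anc <- plantedVariantArray(1550L, c(2L, 2L, 2L), nDiffs = 6L,
                             seed = seed)
  p <- simParams(nSpecies = nSpecies, treeDepth = depth, nGenes = 0L,
                 rrnaLen = 1550L, rrnaCopyNumber = 6L,
                 rrnaRateFactor = 1e-9, conversionRate = gamma,
                 ancestralRrna = anc)
  tr <- ape::stree(nSpecies, "star")
  tr$edge.length <- rep(depth, nSpecies)
  tr$tip.label <- sprintf("s%03d", seq_len(nSpecies))
  sim <- simulateGenus(tr, p, seed = seed + 1L)
  catalog <- buildCatalog(sim, band = 30L)
  profiles <- assignProfiles(sim, catalog, band = 30L)
  list(sim = sim, catalog = catalog, profiles = profiles)
}
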