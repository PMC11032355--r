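.variantGenome <- function(id, copies) {
  new("GenomeRecord", speciesId = id, genes = Biostrings::DNAStringSet(),
      rrnaCopies = Biostrings::DNAStringSet(copies), metadata = list())
}

test_that("catalog construction dereplicates, separates and labels by abundance", {
  set.seed(121)
  A <- randSeq(500)
  B <- plantSubs(A, 5)
  C <- plantSubs(B, 5)
  gs <- list(.variantGenome("g1", rep(A, 4)),
             .variantGenome("g2", c(rep(B, 3), A)),
             .variantGenome("g3", c(rep(C, 2), B)))
  cat3 <- buildCatalog(gs, minSep = 2L)
  expect_equal(length(variantLabels(cat3)), 3L)
  # labels follow descending abundance: A (5), B (4), C (2)
  expect_equal(as.character(variantSequences(cat3)[["A"]]), A)
  expect_equal(as.character(variantSequences(cat3)[["B"]]), B)
  expect_equal(as.character(variantSequences(cat3)[["C"]]), C)
  expect_true(all(cat3@diffMatrix[upper.tri(cat3@diffMatrix)] >= 5))

  # all copies identical everywhere -> catalog of one
  gsame <- list(.variantGenome("g1", rep(A, 3)),
                .variantGenome("g2", rep(A, 2)))
  expect_equal(length(variantLabels(buildCatalog(gsame))), 1L)

  # sequences closer than minSep merge into one variant
  A1 <- plantSubs(A, 1)
  gnear <- list(.variantGenome("g1", c(rep(A, 3), A1)))
  expect_equal(length(variantLabels(buildCatalog(gnear, minSep = 2L))), 1L)
})

test_that("catalog is invariant to genome input order", {
  set.seed(122)
  A <- randSeq(400); B <- plantSubs(A, 6); C <- plantSubs(B, 6)
  gs <- list(.variantGenome("g1", c(rep(A, 3), B)),
             .variantGenome("g2", c(rep(B, 2), C)),
             .variantGenome("g3", rep(C, 3)),
             .variantGenome("g4", rep(A, 2)))
  c1 <- buildCatalog(gs)
  for (perm in list(c(4, 3, 2, 1), c(2, 4, 1, 3))) {
    c2 <- buildCatalog(gs[perm])
    expect_identical(as.character(variantSequences(c1)),
                     as.character(variantSequences(c2)))
  }
})

test_that("profiles assign copies within the radius and conserve copy counts", {
  set.seed(123)
  A <- randSeq(500); B <- plantSubs(A, 6)
  cat2 <- buildCatalog(list(.variantGenome("ref", c(rep(A, 3), rep(B, 2)))))
  A1 <- plantSubs(A, 1)         # within radius 1 of A
  far <- plantSubs(A, 3)        # distance 3 from A, far from B: unassigned
  gs <- list(.variantGenome("g1", c(rep(A, 5), rep(B, 2))),
             .variantGenome("g2", rep(A, 7)),
             .variantGenome("g3", c(A1, far)))
  prof <- assignProfiles(gs, cat2)
  expect_equal(prof$A, c(5L, 7L, 1L))
  expect_equal(prof$B, c(2L, 0L, 0L))
  expect_equal(prof$unassigned, c(0L, 0L, 1L))
  # conservation: assigned + unassigned = intact copies
  nIntact <- vapply(gs, function(g) length(rrnaCopies(g)), integer(1))
  expect_equal(prof$A + prof$B + prof$unassigned, nIntact)
})

test_that("mixture spectrum counts compositions over two-variant genomes", {
  prof <- data.frame(
    genome_id = paste0("g", 1:6),
    A = c(7L, 7L, 7L, 5L, 5L, 0L),
    B = c(0L, 0L, 0L, 2L, 2L, 3L),
    C = c(0L, 0L, 0L, 0L, 0L, 4L),
    unassigned = 0L)
  sp <- mixtureSpectrum(prof, c("A", "B"))
  expect_equal(sum(sp$n_genomes), 5L)  # g6 involves C and is excluded
  expect_equal(sp$n_genomes[sp$composition == "7:0"], 3L)
  expect_equal(sp$n_genomes[sp$composition == "5:2"], 2L)
  expect_error(mixtureSpectrum(prof, c("A", "Z")), "unknown")
})

test_that("conversion on a planted two-variant ancestor explores intermediate mixtures", {
  set.seed(124)
  anc <- plantedVariantArray(600L, c(3L, 3L), nDiffs = 6L, seed = 124)
  p <- simParams(nSpecies = 40L, treeDepth = 0.3, nGenes = 0L,
                 rrnaLen = 600L, rrnaCopyNumber = 6L, rrnaRateFactor = 1e-9,
                 conversionRate = 15, ancestralRrna = anc)
  tr <- ape::stree(40, "star")
  tr$edge.length <- rep(0.3, 40)
  tr$tip.label <- sprintf("s%03d", 1:40)
  sim <- simulateGenus(tr, p, seed = 125)
  cat2 <- buildCatalog(sim, band = 30L)
  prof <- assignProfiles(sim, cat2, band = 30L)
  labs <- variantLabels(cat2)
  expect_equal(length(labs), 2L)
  sp <- mixtureSpectrum(prof, labs)
  # conservation: every genome appears in the two-variant spectrum
  expect_equal(sum(sp$n_genomes), 40L)
  # intermediate (mixed) compositions are reachable alongside pure ones
  mixedComps <- sp$countA > 0 & sp$countB > 0
  expect_true(any(mixedComps))
  expect_true(any(sp$countA == 0 | sp$countB == 0))
})

test_that("dominant variants and the permutation test behave at the extremes", {
  set.seed(126)
  tr <- simulateTree(32, treeDepth = 0.3, seed = 126)
  # all tips one variant: degenerate, p = 1
  prof1 <- data.frame(genome_id = tr$tip.label, A = 7L, B = 0L,
                      unassigned = 0L)
  expect_warning(r1 <- phyloRandomnessTest(tr, prof1, nPerm = 99),
                 "degenerate")
  expect_equal(r1$p, 1)
  # variant confined to one clade: strongly non-random
  sub <- ape::extract.clade(tr, ape::getMRCA(tr, tr$tip.label[1:2]))
  clade <- if (length(sub$tip.label) >= 4 && length(sub$tip.label) <= 16)
    sub$tip.label else tr$tip.label[1:8]
  prof2 <- data.frame(genome_id = tr$tip.label,
                      A = ifelse(tr$tip.label %in% clade, 0L, 7L),
                      B = ifelse(tr$tip.label %in% clade, 7L, 0L),
                      unassigned = 0L)
  r2 <- phyloRandomnessTest(tr, prof2, nPerm = 499, seed = 1)
  expect_lte(r2$p, 0.05)
  expect_false(r2$degenerate)
  # random labels: p is not systematically small
  prof3 <- data.frame(genome_id = tr$tip.label,
                      A = sample(c(0L, 7L), 32, TRUE), unassigned = 0L)
  prof3$B <- 7L - prof3$A
  r3 <- phyloRandomnessTest(tr, prof3, nPerm = 199, seed = 2)
  expect_true(r3$p > 0 && r3$p <= 1)
  # missing tips are reported
  profBad <- data.frame(genome_id = c(tr$tip.label, "zzz"), A = 7L, B = 0L,
                        unassigned = 0L)
  profBad$B[1] <- 7L; profBad$A[1] <- 0L
  expect_error(phyloRandomnessTest(tr, profBad, nPerm = 9), "zzz")
})

test_that("randomized-tie permutation p is calibrated under a random null", {
  set.seed(127)
  tr <- simulateTree(24, treeDepth = 0.3, seed = 127)
  ps <- numeric(60)
  for (r in seq_len(60)) {
    a <- sample(c(0L, 7L), 24, TRUE)
    prof <- data.frame(genome_id = tr$tip.label, A = a, B = 7L - a,
                       unassigned = 0L)
    dom <- dominantVariant(prof)
    if (length(unique(dom)) < 2) { ps[r] <- NA; next }
    ps[r] <- phyloRandomnessTest(tr, prof, nPerm = 199)$p
  }
  ps <- ps[!is.na(ps)]
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("label enrichment uses the exact hypergeometric tail", {
  prof <- data.frame(genome_id = paste0("g", 1:40),
                     A = c(rep(0L, 20), rep(7L, 20)),
                     B = c(rep(7L, 20), rep(0L, 20)),
                     unassigned = 0L)
  labels <- setNames(c(rep("clinical", 20), rep("outbreak", 20)),
                     prof$genome_id)
  r <- labelEnrichment(prof, labels, focalVariant = "A",
                       focalLabel = "outbreak")
  expect_lt(r$p, 1e-4)
  # agreement with direct hypergeometric enumeration
  expect_equal(r$p, sum(dhyper(20:20, 20, 20, 20)), tolerance = 1e-12)
  # independent labels: p well above the perfect-association value
  set.seed(128)
  labInd <- setNames(sample(labels), prof$genome_id)
  r2 <- labelEnrichment(prof, labInd, "A", focalLabel = "outbreak")
  expect_gt(r2$p, 1e-4)
  # single label: degenerate
  labOne <- setNames(rep("clinical", 40), prof$genome_id)
  expect_equal(labelEnrichment(prof, labOne, "A")$p, 1)
  expect_error(labelEnrichment(prof, labels[-1], "A"), "g1")
})
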