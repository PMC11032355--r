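test_that("simulated trees are ultrametric, rescaled and deterministic", {
  tr <- simulateTree(2, treeDepth = 0.25, seed = 1)
  d <- ape::node.depth.edgelength(tr)
  expect_equal(unname(d[1:2]), c(0.25, 0.25), tolerance = 1e-12)

  t1 <- simulateTree(50, treeDepth = 0.3, seed = 99)
  t2 <- simulateTree(50, treeDepth = 0.3, seed = 99)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(ape::Ntip(t1), 50L)
  expect_true(ape::is.ultrametric(t1, option = 2))
  depths <- vapply(1:40, function(s)
    max(ape::node.depth.edgelength(simulateTree(10, treeDepth = 0.3,
                                                seed = s))), numeric(1))
  expect_equal(depths, rep(0.3, 40), tolerance = 1e-12)

  expect_error(simulateTree(1), "nSpecies")
})

test_that("neutral two-species divergence matches the Jukes-Cantor expectation", {
  # two tips at depth T: pairwise distance 2T; expected p = 3/4 (1 - e^(-8T/3))
  T <- 0.15
  ps <- numeric(120)
  set.seed(21)
  for (r in seq_len(120)) {
    tr <- simulateTree(2, treeDepth = T)
    p <- simParams(nSpecies = 2, nGenes = 0L, rrnaLen = 500L,
                   rrnaCopyNumber = 1L, rrnaRateFactor = 1)
    sim <- simulateGenus(tr, p)
    a <- strsplit(as.character(rrnaCopies(simGenomes(sim)[[1]])[[1]]), "")[[1]]
    b <- strsplit(as.character(rrnaCopies(simGenomes(sim)[[2]])[[1]]), "")[[1]]
    ps[r] <- mean(a != b)
  }
  expected <- 0.75 * (1 - exp(-4 * 2 * T / 3))
  se <- sd(ps) / sqrt(length(ps))
  expect_lt(abs(mean(ps) - expected), 4 * se + 1e-4)
})

test_that("rRNA rate factor scales divergence down relative to markers", {
  set.seed(8)
  tr <- simulateTree(2, treeDepth = 0.2)
  p <- simParams(nSpecies = 2, nGenes = 2L, geneLen = 2000L, rrnaLen = 2000L,
                 rrnaCopyNumber = 1L, rrnaRateFactor = 0.05)
  sim <- simulateGenus(tr, p)
  g1 <- simGenomes(sim)[[1]]; g2 <- simGenomes(sim)[[2]]
  pGene <- mean(strsplit(as.character(markerGenes(g1)[[1]]), "")[[1]] !=
                strsplit(as.character(markerGenes(g2)[[1]]), "")[[1]])
  pRrna <- mean(strsplit(as.character(rrnaCopies(g1)[[1]]), "")[[1]] !=
                strsplit(as.character(rrnaCopies(g2)[[1]]), "")[[1]])
  expect_gt(pGene, 5 * pRrna)  # 20x rate difference, loose factor
})

test_that("simulation is byte-deterministic for a fixed seed", {
  tr <- simulateTree(6, treeDepth = 0.1, seed = 4)
  p <- simParams(nSpecies = 6, nGenes = 2L, geneLen = 200L, rrnaLen = 300L,
                 rrnaCopyNumber = 3L, conversionRate = 5, hgtRate = 2)
  s1 <- simulateGenus(tr, p, seed = 11)
  s2 <- simulateGenus(tr, p, seed = 11)
  expect_identical(lapply(simGenomes(s1), function(g)
    as.character(rrnaCopies(g))),
    lapply(simGenomes(s2), function(g) as.character(rrnaCopies(g))))
  expect_identical(eventLog(s1), eventLog(s2))
})

test_that("events never change sequence length or alphabet", {
  tr <- simulateTree(8, treeDepth = 0.2, seed = 12)
  p <- simParams(nSpecies = 8, nGenes = 1L, geneLen = 150L, rrnaLen = 250L,
                 rrnaCopyNumber = 4L, rrnaRateFactor = 0.5,
                 conversionRate = 20, hgtRate = 3)
  sim <- simulateGenus(tr, p, seed = 13)
  expect_gt(nrow(eventLog(sim)), 0)
  for (g in simGenomes(sim)) {
    expect_true(all(Biostrings::width(rrnaCopies(g)) == 250L))
    expect_true(all(Biostrings::width(markerGenes(g)) == 150L))
    expect_false(any(grepl("[^ACGT]",
                           c(as.character(rrnaCopies(g)),
                             as.character(markerGenes(g))))))
  }
})

test_that("strong conversion homogenizes intragenomic copies", {
  # conversion 100x the per-copy substitution rate
  r16 <- 0.1; L <- 400L
  gam <- 100 * r16 * L
  set.seed(31)
  meds <- numeric(5)
  for (r in 1:5) {
    tr <- simulateTree(5, treeDepth = 0.05)
    p <- simParams(nSpecies = 5, nGenes = 0L, rrnaLen = L,
                   rrnaCopyNumber = 4L, rrnaRateFactor = r16,
                   conversionRate = gam)
    sim <- simulateGenus(tr, p)
    meds[r] <- median(unlist(lapply(simGenomes(sim), copyIdentities)))
  }
  expect_true(all(meds >= 99.9))
})

test_that("planted transfers make recipients carry the donor variant and are logged", {
  tr <- simulateTree(10, treeDepth = 0.2, seed = 17)
  p <- simParams(nSpecies = 10, nGenes = 0L, rrnaLen = 300L,
                 rrnaCopyNumber = 3L, rrnaRateFactor = 1)
  sim <- simulateGenus(tr, p, seed = 18)
  sim2 <- plantHgtEvents(sim, donors = c("s001", "s004"),
                         recipients = c("s007", "s009"))
  for (pr in list(c("s001", "s007"), c("s004", "s009"))) {
    donorVar <- selectRepresentative(rrnaCopies(simGenomes(sim2)[[pr[1]]]))
    rec <- as.character(rrnaCopies(simGenomes(sim2)[[pr[2]]]))
    expect_true(all(rec == donorVar))
  }
  ev <- eventLog(sim2)
  planted <- ev[ev$event_type == "hgt", ]
  expect_equal(nrow(planted), 2L)
  expect_setequal(planted$recipient, c("s007", "s009"))
  expect_error(plantHgtEvents(sim, "s001", "s001"), "differ")
})

test_that("stochastic whole-array transfers leave recipients identical to the donor variant", {
  tr <- simulateTree(6, treeDepth = 0.15, seed = 23)
  p <- simParams(nSpecies = 6, nGenes = 0L, rrnaLen = 300L,
                 rrnaCopyNumber = 3L, rrnaRateFactor = 1e-9, hgtRate = 10)
  sim <- simulateGenus(tr, p, seed = 24)
  ev <- eventLog(sim)
  hgt <- ev[ev$event_type == "hgt", ]
  expect_gt(nrow(hgt), 0)
  # with effectively no substitution, the last transfer into each tip
  # lineage leaves all its copies equal to one sequence
  last <- hgt[nrow(hgt), ]
  if (last$recipient %in% names(simGenomes(sim))) {
    cp <- as.character(rrnaCopies(simGenomes(sim)[[last$recipient]]))
    expect_equal(length(unique(cp)), 1L)
  }
  expect_true(all(ev$time >= 0 & ev$time <= 0.15 + 1e-9))
})

test_that("vertebrate mode rejects transfer/conversion and plants the rate ratio", {
  tr <- simulateTree(12, treeDepth = 0.2, seed = 41)
  pOK <- simParams(nSpecies = 12, nGenes = 2L, geneLen = 200L,
                   rrnaLen = 600L, rrnaCopyNumber = 1L)
  expect_error(simulateVertebrateMode(
    tr, simParams(nSpecies = 12, hgtRate = 1)), "invalid parameter")
  expect_error(simulateVertebrateMode(
    tr, simParams(nSpecies = 12, conversionRate = 1)), "invalid parameter")
  sim <- simulateVertebrateMode(tr, pOK, r18 = 0.1, seed = 42)
  pt <- vertebratePairTable(sim)
  expect_equal(nrow(pt), choose(12, 2))
  # mito locus diverges much faster than the 18S analog
  expect_gt(mean(pt$divMito), 4 * mean(pt$div18S))
  # deep tree: mito p-distance plateaus below the 75% JC ceiling
  trDeep <- simulateTree(8, treeDepth = 1.5, seed = 43)
  pDeep <- simParams(nSpecies = 8, nGenes = 0L, rrnaLen = 1000L,
                     rrnaCopyNumber = 1L)
  simDeep <- simulateVertebrateMode(trDeep, pDeep, r18 = 0.1, seed = 44)
  ptDeep <- vertebratePairTable(simDeep, band = 60L)
  expect_lt(max(ptDeep$divMito), 75)
  expect_gt(max(ptDeep$divMito), 50)  # saturating, not merely slow
})

test_that("fixtures round-trip losslessly", {
  tr <- simulateTree(4, treeDepth = 0.1, seed = 51)
  p <- simParams(nSpecies = 4, nGenes = 2L, geneLen = 120L, rrnaLen = 180L,
                 rrnaCopyNumber = 2L, conversionRate = 10)
  sim <- simulateGenus(tr, p, seed = 52)
  out <- file.path(tempdir(), "fixt1")
  paths <- writeFixture(sim, out)
  expect_equal(length(paths), 4L + 2L)  # genomes + tree + events
  back <- readFixture(out)
  expect_equal(sort(speciesId(back)), sort(speciesId(sim)))
  for (id in speciesId(sim)) {
    expect_equal(as.character(rrnaCopies(simGenomes(back)[[id]])),
                 as.character(rrnaCopies(simGenomes(sim)[[id]])),
                 ignore_attr = TRUE)
    expect_equal(as.character(markerGenes(simGenomes(back)[[id]])),
                 as.character(markerGenes(simGenomes(sim)[[id]])),
                 ignore_attr = TRUE)
  }
  expect_equal(nrow(eventLog(back)), nrow(eventLog(sim)))
  unlink(out, recursive = TRUE)
})
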