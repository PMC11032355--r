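.BASES <- c("A", "C", "G", "T")

#' Construct simulator parameters
#'
#' See [SimParams-class] for the meaning of each field. Defaults describe a
#' typical bacterial genus: a 1550-bp rRNA in several copies evolving much
#' slower than the marker genes, with optional gene conversion and
#' inter-lineage rRNA transfer.
#'
#' @param nSpecies number of species (>= 2).
#' @param treeModel tree prior; only `"yule"` is implemented.
#' @param birthRate Yule speciation rate.
#' @param treeDepth root-to-tip length in expected marker substitutions/site.
#' @param nGenes,geneLen marker-gene count (may be 0) and length (bp).
#' @param rrnaLen rRNA copy length (bp).
#' @param rrnaCopyNumber rRNA copies per genome (>= 1).
#' @param rrnaRateFactor rRNA substitution rate relative to markers, (0, 1].
#' @param conversionRate gene-conversion events per copy per unit branch
#'   length.
#' @param hgtRate rRNA transfer events per coexisting lineage pair per unit
#'   time.
#' @param hgtScope `"all_copies"` (whole-array replacement) or `"k_copies"`.
#' @param hgtCopies number of copies replaced under `"k_copies"`.
#' @param ancestralRrna optional `DNAStringSet` of length `rrnaCopyNumber`
#'   planting an ancestral variant polymorphism.
#' @return a validated [SimParams-class] object.
#' @export
simParams <- function(nSpecies = 20L, treeModel = "yule", birthRate = 1,
                      treeDepth = 0.3, nGenes = 10L, geneLen = 500L,
                      rrnaLen = 1550L, rrnaCopyNumber = 4L,
                      rrnaRateFactor = 0.05, conversionRate = 0,
                      hgtRate = 0, hgtScope = "all_copies", hgtCopies = 1L,
                      ancestralRrna = NULL) {
  methods::new("SimParams", nSpecies = as.integer(nSpecies),
               treeModel = treeModel, birthRate = as.numeric(birthRate),
               treeDepth = as.numeric(treeDepth), nGenes = as.integer(nGenes),
               geneLen = as.integer(geneLen), rrnaLen = as.integer(rrnaLen),
               rrnaCopyNumber = as.integer(rrnaCopyNumber),
               rrnaRateFactor = as.numeric(rrnaRateFactor),
               conversionRate = as.numeric(conversionRate),
               hgtRate = as.numeric(hgtRate), hgtScope = hgtScope,
               hgtCopies = as.integer(hgtCopies),
               ancestralRrna = ancestralRrna)
}

#' Simulate an ultrametric Yule species tree
#'
#' A pure-birth tree is drawn and rescaled so that every root-to-tip path
#' equals `treeDepth` (the tree is ultrametric, so mean and individual
#' root-to-tip paths coincide).
#'
#' @param nSpecies number of tips (>= 2).
#' @param birthRate speciation rate (> 0).
#' @param treeDepth root-to-tip path length after rescaling.
#' @param seed optional integer seed for reproducibility.
#' @return an ultrametric `phylo` with tips `s001`, `s002`, ...
#' @examples
#' tr <- simulateTree(10, treeDepth = 0.2, seed = 1)
#' @export
simulateTree <- function(nSpecies, birthRate = 1, treeDepth = 0.3,
                         seed = NULL) {
  if (nSpecies < 2) stop("nSpecies must be >= 2")
  if (birthRate <= 0 || treeDepth <= 0)
    stop("birthRate and treeDepth must be > 0")
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rphylo(as.integer(nSpecies), birth = birthRate, death = 0)
  depth <- max(ape::node.depth.edgelength(tr))
  tr$edge.length <- tr$edge.length * (treeDepth / depth)
  tr$tip.label <- sprintf("s%03d", seq_len(as.integer(nSpecies)))
  tr
}

# Apply a Jukes-Cantor substitution process to an integer-coded sequence:
# sites are hit as a Poisson process at `rate` per site over time `dt`; each
# hit replaces the base by one of the three others, sequentially so that
# multiple hits at one site compose correctly.
.mutateVec <- function(x, rate, dt) {
  lam <- length(x) * rate * dt
  if (lam <= 0) return(x)
  nmut <- stats::rpois(1L, lam)
  if (nmut == 0L) return(x)
  pos <- sample.int(length(x), nmut, replace = TRUE)
  off <- sample.int(3L, nmut, replace = TRUE)
  if (anyDuplicated(pos)) {
    for (k in seq_len(nmut)) {
      p <- pos[k]
      x[p] <- ((x[p] - 1L + off[k]) %% 4L) + 1L
    }
  } else {
    x[pos] <- ((x[pos] - 1L + off) %% 4L) + 1L
  }
  x
}

.advanceLineage <- function(lin, t, r16) {
  dt <- t - lin$lastT
  if (dt > 0) {
    if (length(lin$genes))
      lin$genes <- lapply(lin$genes, .mutateVec, rate = 1, dt = dt)
    lin$rrna <- lapply(lin$rrna, .mutateVec, rate = r16, dt = dt)
    lin$lastT <- t
  }
  lin
}

.intToSeq <- function(x) paste(.BASES[x], collapse = "")
.seqToInt <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], .BASES)
  if (anyNA(v)) stop("ancestral sequences must be over {A, C, G, T}")
  v
}

# majority variant among integer-coded copies; ties by longest then
# lexicographically smallest (mirrors selectRepresentative)
.majorityVariant <- function(copies) {
  keys <- vapply(copies, .intToSeq, character(1))
  tab <- table(keys)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L) {
    cand <- cand[nchar(cand) == max(nchar(cand))]
    cand <- sort(cand)[1L]
  }
  copies[[match(cand, keys)]]
}

.emptyEventLog <- function() {
  data.frame(event_type = character(0), time = numeric(0),
             donor = character(0), recipient = character(0),
             copies_affected = character(0), tract = character(0),
             stringsAsFactors = FALSE)
}

#' Forward-simulate a genus along a species tree
#'
#' Marker genes evolve by Jukes-Cantor substitution at rate 1 per site per
#' unit branch length; each rRNA copy evolves independently at
#' `rrnaRateFactor` times that rate. Intragenomic gene conversion
#' (whole-copy replacement by a uniformly chosen sister copy) and
#' inter-lineage rRNA transfer (the donor's majority variant replaces
#' recipient copies) are drawn as a Gillespie process between speciation
#' times; every event is appended to the ground-truth log.
#'
#' @param tree an ultrametric `phylo` (see [simulateTree()]).
#' @param params a [SimParams-class] object.
#' @param seed optional integer seed; fixed seed + params give
#'   byte-identical output.
#' @return a [GenusSimulation-class].
#' @examples
#' tr <- simulateTree(6, treeDepth = 0.1, seed = 1)
#' sim <- simulateGenus(tr, simParams(nSpecies = 6, nGenes = 2L,
#'                                    geneLen = 200L, rrnaLen = 300L),
#'                      seed = 1)
#' sim
#' @export
simulateGenus <- function(tree, params, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  methods::validObject(params)
  nt <- ape::Ntip(tree)
  if (nt < 2) stop("tree must have >= 2 tips")
  if (!ape::is.ultrametric(tree, option = 2))
    stop("tree must be ultrametric")
  if (!is.null(seed)) set.seed(seed)

  C <- params@rrnaCopyNumber
  r16 <- params@rrnaRateFactor
  gam <- params@conversionRate
  eta <- params@hgtRate

  nodeT <- ape::node.depth.edgelength(tree)
  depth <- max(nodeT)
  root <- nt + 1L
  kids <- split(tree$edge[, 2L], tree$edge[, 1L])

  if (is.null(params@ancestralRrna)) {
    a0 <- sample.int(4L, params@rrnaLen, replace = TRUE)
    ancRrna <- rep(list(a0), C)
  } else {
    ancRrna <- lapply(as.character(params@ancestralRrna), .seqToInt)
  }
  ancestor <- list(
    genes = replicate(params@nGenes,
                      sample.int(4L, params@geneLen, replace = TRUE),
                      simplify = FALSE),
    rrna = ancRrna, lastT = 0)

  lineages <- list()
  for (ch in kids[[as.character(root)]])
    lineages[[as.character(ch)]] <- ancestor

  labelOf <- function(node)
    if (node <= nt) tree$tip.label[node] else paste0("n", node)

  internal <- setdiff(seq.int(nt + 1L, nt + tree$Nnode), root)
  schedule <- internal[order(nodeT[internal])]

  ev <- list()
  tcur <- 0
  for (step in c(schedule, NA_integer_)) {
    tnext <- if (is.na(step)) depth else nodeT[step]
    k <- length(lineages)
    repeat {
      convTotal <- if (C >= 2L) gam * C * k else 0
      hgtTotal <- if (k >= 2L) eta * k * (k - 1) / 2 else 0
      tot <- convTotal + hgtTotal
      if (tot <= 0) break
      tau <- stats::rexp(1L, tot)
      if (tcur + tau >= tnext) break
      tcur <- tcur + tau
      if (stats::runif(1L) * tot < convTotal) {
        li <- sample.int(k, 1L)
        nm <- names(lineages)[li]
        lin <- .advanceLineage(lineages[[nm]], tcur, r16)
        rec <- sample.int(C, 1L)
        don <- sample.int(C - 1L, 1L)
        if (don >= rec) don <- don + 1L
        lin$rrna[[rec]] <- lin$rrna[[don]]
        lineages[[nm]] <- lin
        lab <- labelOf(as.integer(nm))
        ev[[length(ev) + 1L]] <- data.frame(
          event_type = "conversion", time = tcur, donor = lab,
          recipient = lab, copies_affected = as.character(rec),
          tract = "whole_copy", stringsAsFactors = FALSE)
      } else {
        pr <- sample.int(k, 2L)
        dn <- names(lineages)[pr[1L]]
        rn <- names(lineages)[pr[2L]]
        dlin <- .advanceLineage(lineages[[dn]], tcur, r16)
        rlin <- .advanceLineage(lineages[[rn]], tcur, r16)
        donorVar <- .majorityVariant(dlin$rrna)
        idx <- if (params@hgtScope == "all_copies") seq_len(C)
               else sort(sample.int(C, min(params@hgtCopies, C)))
        for (i in idx) rlin$rrna[[i]] <- donorVar
        lineages[[dn]] <- dlin
        lineages[[rn]] <- rlin
        ev[[length(ev) + 1L]] <- data.frame(
          event_type = "hgt", time = tcur,
          donor = labelOf(as.integer(dn)),
          recipient = labelOf(as.integer(rn)),
          copies_affected = paste(idx, collapse = ","),
          tract = "whole_copy", stringsAsFactors = FALSE)
      }
    }
    tcur <- tnext
    if (!is.na(step)) {
      nm <- as.character(step)
      lin <- .advanceLineage(lineages[[nm]], tnext, r16)
      for (ch in kids[[nm]]) lineages[[as.character(ch)]] <- lin
      lineages[[nm]] <- NULL
    }
  }

  genomes <- vector("list", nt)
  for (nm in names(lineages)) {
    node <- as.integer(nm)
    lin <- .advanceLineage(lineages[[nm]], depth, r16)
    sid <- tree$tip.label[node]
    genes <- Biostrings::DNAStringSet(vapply(lin$genes, .intToSeq,
                                             character(1)))
    if (length(genes))
      names(genes) <- sprintf("g%03d", seq_along(genes))
    rr <- Biostrings::DNAStringSet(vapply(lin$rrna, .intToSeq, character(1)))
    names(rr) <- sprintf("rrna%02d", seq_along(rr))
    genomes[[node]] <- methods::new("GenomeRecord", speciesId = sid,
                                    genes = genes, rrnaCopies = rr,
                                    metadata = list(mode = "bacterial"))
  }
  names(genomes) <- tree$tip.label
  events <- if (length(ev)) do.call(rbind, ev) else .emptyEventLog()
  methods::new("GenusSimulation", tree = tree, genomes = genomes,
               events = events, params = params)
}

#' Plant recent whole-array rRNA transfers between named species
#'
#' Applies horizontal transfers at the present (time = tree depth): each
#' recipient's rRNA copies are replaced by the donor's majority variant,
#' emulating a recent transfer that leaves the pair sharing essentially the
#' same 16S sequence while their genomes remain well separated. Events are
#' appended to the ground-truth log.
#'
#' @param sim a [GenusSimulation-class].
#' @param donors,recipients equal-length character vectors of tip labels.
#' @param scope `"all_copies"` or `"k_copies"`.
#' @param k copies replaced per recipient when `scope = "k_copies"`.
#' @return the modified [GenusSimulation-class].
#' @export
plantHgtEvents <- function(sim, donors, recipients, scope = "all_copies",
                           k = 1L) {
  stopifnot(methods::is(sim, "GenusSimulation"),
            length(donors) == length(recipients))
  if (any(donors == recipients)) stop("donor and recipient must differ")
  tips <- sim@tree$tip.label
  bad <- setdiff(c(donors, recipients), tips)
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  depth <- max(ape::node.depth.edgelength(sim@tree))
  ev <- sim@events
  for (i in seq_along(donors)) {
    drec <- sim@genomes[[donors[i]]]
    rrec <- sim@genomes[[recipients[i]]]
    variant <- selectRepresentative(rrnaCopies(drec))
    nC <- length(rrnaCopies(rrec))
    idx <- if (scope == "all_copies") seq_len(nC) else seq_len(min(k, nC))
    rr <- as.character(rrnaCopies(rrec))
    rr[idx] <- as.character(variant)
    newSet <- Biostrings::DNAStringSet(rr)
    names(newSet) <- names(rrnaCopies(rrec))
    rrec@rrnaCopies <- newSet
    sim@genomes[[recipients[i]]] <- rrec
    ev <- rbind(ev, data.frame(
      event_type = "hgt", time = depth, donor = donors[i],
      recipient = recipients[i], copies_affected = paste(idx, collapse = ","),
      tract = "whole_copy", stringsAsFactors = FALSE))
  }
  sim@events <- ev
  sim
}

#' Plant an ancestral intragenomic rRNA variant polymorphism
#'
#' Builds an rRNA copy array whose copies belong to a few well-separated
#' variants: variant 1 is random, and each further variant differs from the
#' previous one at `nDiffs` fresh positions (so consecutive variants differ
#' by `nDiffs` and non-consecutive ones by up to the sum). Used as
#' `ancestralRrna` in [simParams()] to study conversion-driven mixture
#' dynamics (the multi-variant situation observed within E. coli).
#'
#' @param rrnaLen copy length (bp).
#' @param copyCounts integer vector, copies per variant (e.g. `c(3, 2, 2)`
#'   for a 7-copy array over three variants).
#' @param nDiffs substitutions separating consecutive variants.
#' @param seed optional seed.
#' @return a `DNAStringSet` of `sum(copyCounts)` copies; the planted
#'   variant of each copy is recorded in the names (`v1.1`, `v1.2`, ...).
#' @export
plantedVariantArray <- function(rrnaLen = 1550L, copyCounts = c(3L, 2L, 2L),
                                nDiffs = 6L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  rrnaLen <- as.integer(rrnaLen)
  if (any(copyCounts < 1L)) stop("copyCounts must be >= 1")
  nv <- length(copyCounts)
  if (nv * nDiffs > rrnaLen) stop("too many differences for this length")
  base <- sample.int(4L, rrnaLen, replace = TRUE)
  variants <- list(base)
  free <- seq_len(rrnaLen)
  for (v in seq_len(nv - 1L)) {
    pos <- sample(free, nDiffs)
    free <- setdiff(free, pos)
    nxt <- variants[[v]]
    off <- sample.int(3L, nDiffs, replace = TRUE)
    nxt[pos] <- ((nxt[pos] - 1L + off) %% 4L) + 1L
    variants[[v + 1L]] <- nxt
  }
  seqs <- character(0); nms <- character(0)
  for (v in seq_len(nv)) {
    for (k in seq_len(copyCounts[v])) {
      seqs <- c(seqs, .intToSeq(variants[[v]]))
      nms <- c(nms, sprintf("v%d.%d", v, k))
    }
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- nms
  out
}

#' Simulate the vertebrate (no-HGT) control mode
#'
#' Two single-copy loci evolve alongside the marker genes: a slow nuclear
#' "18S analog" (rate factor `r18`) and a fast "mitochondrial 16S analog"
#' (rate factor `rMito`, default 10 x `r18`). Horizontal transfer and gene
#' conversion are the mode's defining exclusions; requesting either is an
#' error.
#'
#' @param tree an ultrametric `phylo`.
#' @param params a [SimParams-class]; its `hgtRate` and `conversionRate`
#'   must be 0, `rrnaLen` sets the locus length and `nGenes`/`geneLen` the
#'   markers.
#' @param r18 18S-analog rate factor (<= 1).
#' @param rMito mitochondrial-analog rate factor (default `10 * r18`).
#' @param seed optional integer seed.
#' @return a [GenusSimulation-class] whose genomes carry the two loci as
#'   rRNA entries named `locus18S` and `locusMito16S`.
#' @export
simulateVertebrateMode <- function(tree, params, r18 = 0.1, rMito = 10 * r18,
                                   seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  methods::validObject(params)
  if (params@hgtRate > 0)
    stop("invalid parameter: vertebrate mode excludes HGT (hgtRate must be 0)")
  if (params@conversionRate > 0)
    stop("invalid parameter: vertebrate mode excludes gene conversion")
  if (r18 <= 0 || r18 > 1) stop("r18 must lie in (0, 1]")
  if (rMito <= 0) stop("rMito must be > 0")
  nt <- ape::Ntip(tree)
  if (nt < 2) stop("tree must have >= 2 tips")
  if (!is.null(seed)) set.seed(seed)

  root <- nt + 1L
  anc <- list(
    genes = replicate(params@nGenes,
                      sample.int(4L, params@geneLen, replace = TRUE),
                      simplify = FALSE),
    s18 = sample.int(4L, params@rrnaLen, replace = TRUE),
    mito = sample.int(4L, params@rrnaLen, replace = TRUE))

  states <- list()
  states[[as.character(root)]] <- anc
  # preorder edge traversal
  ord <- ape::reorder.phylo(tree, "cladewise")
  genomes <- vector("list", nt)
  for (e in seq_len(nrow(ord$edge))) {
    par <- ord$edge[e, 1L]; ch <- ord$edge[e, 2L]
    len <- ord$edge.length[e]
    st <- states[[as.character(par)]]
    st$genes <- lapply(st$genes, .mutateVec, rate = 1, dt = len)
    st$s18 <- .mutateVec(st$s18, rate = r18, dt = len)
    st$mito <- .mutateVec(st$mito, rate = rMito, dt = len)
    if (ch <= nt) {
      sid <- tree$tip.label[ch]
      genes <- Biostrings::DNAStringSet(vapply(st$genes, .intToSeq,
                                               character(1)))
      if (length(genes)) names(genes) <- sprintf("g%03d", seq_along(genes))
      loci <- Biostrings::DNAStringSet(c(.intToSeq(st$s18),
                                         .intToSeq(st$mito)))
      names(loci) <- c("locus18S", "locusMito16S")
      genomes[[ch]] <- methods::new("GenomeRecord", speciesId = sid,
                                    genes = genes, rrnaCopies = loci,
                                    metadata = list(mode = "vertebrate",
                                                    r18 = r18, rMito = rMito))
    } else {
      states[[as.character(ch)]] <- st
    }
  }
  names(genomes) <- tree$tip.label
  methods::new("GenusSimulation", tree = tree, genomes = genomes,
               events = .emptyEventLog(),
               params = params)
}

#' Pairwise divergence of the vertebrate-mode loci
#'
#' For every species pair, reports the tree path distance together with the
#' percent divergence (100 - identity) of the 18S analog and of the
#' mitochondrial analog, the input for slope-ratio and saturation fits.
#'
#' @param sim a vertebrate-mode [GenusSimulation-class].
#' @param scheme alignment scoring scheme.
#' @param band optional alignment band half-width (the simulator introduces
#'   no indels, so a modest band is exact); `NULL` for full DP.
#' @return data.frame with columns `species_a`, `species_b`,
#'   `tree_distance`, `div18S`, `divMito`.
#' @export
vertebratePairTable <- function(sim, scheme = scoringScheme(), band = 25L) {
  stopifnot(methods::is(sim, "GenusSimulation"))
  ids <- sort(speciesId(sim))
  dm <- ape::cophenetic.phylo(sim@tree)
  rows <- list()
  for (i in seq_along(ids)[-length(ids)]) {
    for (j in seq.int(i + 1L, length(ids))) {
      ga <- sim@genomes[[ids[i]]]; gb <- sim@genomes[[ids[j]]]
      d18 <- 100 - percentIdentity(globalAlign(
        rrnaCopies(ga)[["locus18S"]], rrnaCopies(gb)[["locus18S"]],
        scheme, band))
      dmt <- 100 - percentIdentity(globalAlign(
        rrnaCopies(ga)[["locusMito16S"]], rrnaCopies(gb)[["locusMito16S"]],
        scheme, band))
      rows[[length(rows) + 1L]] <- data.frame(
        species_a = ids[i], species_b = ids[j],
        tree_distance = dm[ids[i], ids[j]],
        div18S = d18, divMito = dmt, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated genus to disk as plain-text fixtures
#'
#' One FASTA per genome (headers `>{species}|{locus}|{index}`), the tree in
#' newick, and the event log as TSV. The files round-trip losslessly through
#' [readGenomeFasta()] / [readFixture()].
#'
#' @param sim a [GenusSimulation-class].
#' @param outDir output directory (created if needed).
#' @return invisibly, the named character vector of written paths.
#' @export
writeFixture <- function(sim, outDir) {
  stopifnot(methods::is(sim, "GenusSimulation"))
  if (length(sim@genomes) == 0L) stop("empty genome list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outDir)) stop("cannot create output directory: ", outDir)
  paths <- character(0)
  for (g in sim@genomes) {
    sid <- g@speciesId
    seqs <- c(as.character(g@genes), as.character(g@rrnaCopies))
    locus <- c(rep("gene", length(g@genes)),
               rep("rrna", length(g@rrnaCopies)))
    # vertebrate loci keep their own locus names
    nm <- c(names(g@genes), names(g@rrnaCopies))
    locus[nm %in% "locus18S"] <- "18S"
    locus[nm %in% "locusMito16S"] <- "mito16S"
    idx <- stats::ave(seq_along(locus), locus, FUN = seq_along)
    headers <- sprintf("%s|%s|%d", sid, locus, idx)
    fp <- file.path(outDir, paste0(sid, ".fasta"))
    writeFastaSequences(stats::setNames(seqs, headers), fp)
    paths[sid] <- fp
  }
  tp <- file.path(outDir, "tree.nwk")
  ape::write.tree(sim@tree, file = tp)
  paths["tree"] <- tp
  ep <- file.path(outDir, "events.tsv")
  writeTsv(sim@events, ep)
  paths["events"] <- ep
  invisible(paths)
}
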