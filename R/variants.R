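# distance between two variant sequences: mismatches + gap openings; exact
# equality short-circuits the dynamic program
.variantDist <- function(a, b, scheme, band = NULL) {
  if (a == b) return(0L)
  alignmentDistance(globalAlign(a, b, scheme, band))
}

#' Build a catalog of well-separated intragenomic rRNA variants
#'
#' Intact copies (length >= `minLenFrac` of the expected copy length, no
#' internal N runs) from all genomes are dereplicated; unique sequences are
#' visited in order of descending abundance (lexicographic tie-break) and
#' one founds a new reference variant iff its distance (mismatches + gap
#' openings) to every existing founder is at least `minSep`. Founders are
#' labelled `A`, `B`, `C`, ... in founding order, so labels rank variants
#' by abundance and the catalog is invariant to genome input order.
#'
#' @param genomes list of [GenomeRecord-class] objects (or a
#'   [GenusSimulation-class]).
#' @param minSep minimum separation between reference variants (default 2,
#'   so single sequencing/assembly errors cannot found a variant).
#' @param assignRadius assignment radius recorded for downstream profiling.
#' @param minLenFrac,expectedLen intact-copy filter, see
#'   [selectRepresentative()].
#' @param scheme alignment scoring scheme.
#' @param band optional alignment band half-width.
#' @return a [VariantCatalog-class].
#' @export
buildCatalog <- function(genomes, minSep = 2L, assignRadius = 1L,
                         minLenFrac = 0.8, expectedLen = NULL,
                         scheme = scoringScheme(), band = NULL) {
  if (methods::is(genomes, "GenusSimulation")) genomes <- genomes@genomes
  allCopies <- unlist(lapply(genomes, function(g)
    .intactCopies(g@rrnaCopies, minLenFrac, expectedLen)), use.names = FALSE)
  if (length(allCopies) == 0L) stop("no intact rRNA copies in input")
  tab <- table(allCopies)
  ord <- order(-as.integer(tab), names(tab))
  uniq <- names(tab)[ord]
  founders <- character(0)
  for (s in uniq) {
    if (length(founders) == 0L) {
      founders <- s
      next
    }
    d <- vapply(founders, .variantDist, integer(1), b = s,
                scheme = scheme, band = band)
    if (all(d >= minSep)) founders <- c(founders, s)
  }
  labels <- .variantLabels(length(founders))
  vs <- Biostrings::DNAStringSet(founders)
  names(vs) <- labels
  nf <- length(founders)
  dm <- matrix(0L, nf, nf, dimnames = list(labels, labels))
  if (nf > 1L) {
    for (i in seq_len(nf - 1L)) {
      for (j in seq.int(i + 1L, nf)) {
        dm[i, j] <- dm[j, i] <- .variantDist(founders[i], founders[j],
                                             scheme, band)
      }
    }
  }
  methods::new("VariantCatalog", variants = vs, diffMatrix = dm,
               minSep = as.integer(minSep),
               assignRadius = as.integer(assignRadius))
}

.variantLabels <- function(n) {
  if (n <= 26L) return(LETTERS[seq_len(n)])
  c(LETTERS, paste0(rep(LETTERS, each = 26L), LETTERS))[seq_len(n)]
}

#' Assign each genome's rRNA copies to catalog variants
#'
#' Every intact copy is assigned to its nearest reference variant if within
#' `assignRadius` differences (mismatches + gap openings); ties go to the
#' earlier label; copies matching nothing are counted as unassigned. Per
#' genome, assigned counts plus unassigned equal the intact copy count.
#'
#' @param genomes list of [GenomeRecord-class] (or [GenusSimulation-class]).
#' @param catalog a [VariantCatalog-class].
#' @param assignRadius assignment radius; defaults to the catalog's.
#' @param minLenFrac,expectedLen intact-copy filter.
#' @param scheme alignment scoring scheme.
#' @param band optional alignment band half-width.
#' @return data.frame with `genome_id`, one count column per variant label,
#'   and `unassigned`.
#' @export
assignProfiles <- function(genomes, catalog, assignRadius = NULL,
                           minLenFrac = 0.8, expectedLen = NULL,
                           scheme = scoringScheme(), band = NULL) {
  if (methods::is(genomes, "GenusSimulation")) genomes <- genomes@genomes
  stopifnot(methods::is(catalog, "VariantCatalog"))
  if (length(catalog@variants) == 0L) stop("empty catalog")
  if (is.null(assignRadius)) assignRadius <- catalog@assignRadius
  refs <- as.character(catalog@variants)
  labels <- names(catalog@variants)
  rows <- lapply(genomes, function(g) {
    copies <- .intactCopies(g@rrnaCopies, minLenFrac, expectedLen)
    counts <- stats::setNames(integer(length(labels)), labels)
    un <- 0L
    for (cp in copies) {
      d <- vapply(refs, .variantDist, integer(1), b = cp,
                  scheme = scheme, band = band)
      best <- which.min(d)  # ties -> earlier label
      if (d[best] <= assignRadius) counts[best] <- counts[best] + 1L
      else un <- un + 1L
    }
    cbind(data.frame(genome_id = g@speciesId, stringsAsFactors = FALSE),
          as.data.frame(as.list(counts)), data.frame(unassigned = un))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Composition spectrum of a two-variant mixture
#'
#' Restricted to genomes whose assigned copies involve only the two given
#' variants (and nothing unassigned), counts how many genomes show each
#' composition ratio, e.g. `7:0`, `6:1`, ..., `0:7`.
#'
#' @param profiles profile table from [assignProfiles()].
#' @param pair character(2), the two variant labels.
#' @return data.frame with columns `composition` (e.g. `"5:2"`), `countA`,
#'   `countB`, `n_genomes`.
#' @export
mixtureSpectrum <- function(profiles, pair) {
  stopifnot(length(pair) == 2L)
  if (!all(pair %in% names(profiles)))
    stop("unknown variant label(s): ",
         paste(setdiff(pair, names(profiles)), collapse = ", "))
  others <- setdiff(names(profiles),
                    c("genome_id", "unassigned", pair))
  otherCounts <- if (length(others))
    rowSums(profiles[, others, drop = FALSE]) else 0L
  keep <- otherCounts == 0L & profiles$unassigned == 0L &
    (profiles[[pair[1L]]] + profiles[[pair[2L]]]) > 0L
  sub <- profiles[keep, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(data.frame(composition = character(0), countA = integer(0),
                      countB = integer(0), n_genomes = integer(0),
                      stringsAsFactors = FALSE))
  comp <- paste(sub[[pair[1L]]], sub[[pair[2L]]], sep = ":")
  tab <- table(comp)
  a <- as.integer(sub[[pair[1L]]][match(names(tab), comp)])
  b <- as.integer(sub[[pair[2L]]][match(names(tab), comp)])
  ord <- order(-a, b)
  data.frame(composition = names(tab)[ord], countA = a[ord], countB = b[ord],
             n_genomes = as.integer(tab)[ord], stringsAsFactors = FALSE)
}

#' Dominant variant per genome
#'
#' The argmax of the assigned counts; ties go to the earlier label; genomes
#' with no assigned copies return `NA`.
#'
#' @param profiles profile table from [assignProfiles()].
#' @return named character vector of variant labels.
#' @export
dominantVariant <- function(profiles) {
  labels <- setdiff(names(profiles), c("genome_id", "unassigned"))
  m <- as.matrix(profiles[, labels, drop = FALSE])
  out <- apply(m, 1L, function(r)
    if (sum(r) == 0L) NA_character_ else labels[which.max(r)])
  stats::setNames(out, profiles$genome_id)
}

#' Permutation test for phylogenetic randomness of variant possession
#'
#' The observed statistic is the Fitch parsimony score of the
#' dominant-variant character on the tree; the null distribution comes from
#' permuting the tip labels. Small p means the variants cluster on the
#' phylogeny; a variant scattered at random (the pattern expected under
#' rampant transfer/concerted turnover) gives a non-significant p.
#'
#' Because the parsimony score is a small integer, permutation ties are
#' frequent and the classical `(1 + #\{perm <= obs\}) / (1 + nPerm)` value is
#' conservative (super-uniform). The default `p` therefore breaks ties
#' uniformly at random, which is exactly calibrated under the permutation
#' null; the conservative value is returned alongside as `pConservative`.
#'
#' @param tree `phylo` whose tips include all profiled genomes.
#' @param profiles profile table from [assignProfiles()].
#' @param nPerm number of permutations.
#' @param seed optional seed for the permutations (and the tie-break draw).
#' @return list with `statistic` (observed parsimony score), `p`
#'   (randomized-tie permutation p), `pConservative`, `nPerm`, and
#'   `degenerate` (TRUE when fewer than two variants occur, in which case
#'   `p = 1`).
#' @export
phyloRandomnessTest <- function(tree, profiles, nPerm = 999L, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  dom <- dominantVariant(profiles)
  dom <- dom[!is.na(dom)]
  missing <- setdiff(names(dom), tree$tip.label)
  if (length(missing))
    stop("profiled genomes absent from tree: ",
         paste(missing, collapse = ", "))
  if (length(unique(dom)) < 2L) {
    warning("fewer than two distinct dominant variants; test is degenerate")
    return(list(statistic = NA_real_, p = 1, pConservative = 1,
                nPerm = as.integer(nPerm), degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::keep.tip(tree, names(dom))
  dom <- dom[tr$tip.label]
  perms <- vapply(seq_len(nPerm), function(i) sample(unname(dom)),
                  character(length(dom)))
  m <- cbind(obs = unname(dom), perms)
  rownames(m) <- tr$tip.label
  dat <- phangorn::phyDat(m, type = "USER", levels = sort(unique(dom)))
  scores <- phangorn::parsimony(tr, dat, site = "site")
  # phyDat collapses duplicate site patterns; expand back per column
  idx <- attr(dat, "index")
  scores <- scores[idx]
  obs <- scores[1L]
  null <- scores[-1L]
  pCons <- (1 + sum(null <= obs)) / (1 + nPerm)
  p <- (sum(null < obs) + stats::runif(1L) * (1 + sum(null == obs))) /
    (1 + nPerm)
  list(statistic = obs, p = p, pConservative = pCons,
       nPerm = as.integer(nPerm), degenerate = FALSE)
}

#' Exact enrichment test of a variant against a metadata label
#'
#' Genomes are called enriched when they carry at least `threshold` copies
#' of the focal variant; the 2x2 table (enriched vs focal label) is tested
#' with the one-sided hypergeometric tail (Fisher-style exact test for
#' over-representation of the label among enriched genomes).
#'
#' @param profiles profile table from [assignProfiles()].
#' @param labels named character vector, `genome_id` -> label; must cover
#'   all profiled genomes.
#' @param focalVariant variant label to test.
#' @param focalLabel metadata label of interest; defaults to the most
#'   frequent label among enriched genomes.
#' @param threshold minimum focal-variant copies to call a genome enriched.
#' @return list with `table` (2x2), `p`, `focalLabel`, and `degenerate`
#'   (TRUE with p = 1 when all genomes share one label or no genome is
#'   enriched).
#' @export
labelEnrichment <- function(profiles, labels, focalVariant,
                            focalLabel = NULL, threshold = 2L) {
  if (!focalVariant %in% names(profiles))
    stop("unknown variant label: ", focalVariant)
  missing <- setdiff(profiles$genome_id, names(labels))
  if (length(missing))
    stop("missing metadata labels for: ", paste(missing, collapse = ", "))
  lab <- labels[profiles$genome_id]
  enriched <- profiles[[focalVariant]] >= threshold
  if (length(unique(lab)) < 2L || !any(enriched) || all(enriched)) {
    tb <- table(factor(enriched, levels = c(FALSE, TRUE)), lab)
    return(list(table = tb, p = 1, focalLabel = unique(lab)[1L],
                degenerate = TRUE))
  }
  if (is.null(focalLabel)) {
    tt <- sort(table(lab[enriched]), decreasing = TRUE)
    focalLabel <- names(tt)[1L]
  }
  isFocal <- lab == focalLabel
  N <- length(lab)
  K <- sum(isFocal)
  n <- sum(enriched)
  x <- sum(enriched & isFocal)
  # one-sided upper tail: P(X >= x) under hypergeometric sampling
  p <- stats::phyper(x - 1L, K, N - K, n, lower.tail = FALSE)
  tb <- table(enriched = factor(enriched, levels = c(FALSE, TRUE)),
              label = factor(isFocal, levels = c(FALSE, TRUE),
                             labels = c("other", focalLabel)))
  list(table = tb, p = p, focalLabel = focalLabel, degenerate = FALSE)
}
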