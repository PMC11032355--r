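.asGenomeString <- function(x) {
  if (methods::is(x, "GenomeRecord")) x <- x@genes
  if (methods::is(x, "XStringSet")) x <- as.character(x)
  if (is.character(x)) x <- paste(x, collapse = "")
  if (!is.character(x) || length(x) != 1L)
    stop("cannot interpret input as a genome sequence")
  toupper(x)
}

.kmerTable <- function(seq, k = 9L) {
  n <- nchar(seq) - k + 1L
  if (n < 1L) return(character(0))
  substring(seq, seq_len(n), seq_len(n) + k - 1L)
}

# Seed a fragment on a target via exact 9-mer probes spaced along the
# fragment; returns the modal diagonal offset (>= 2 concordant probes) or NA.
.seedDiagonal <- function(frag, kmerTable, k = 9L, step = 20L) {
  offs <- seq(1L, nchar(frag) - k + 1L, by = step)
  probes <- substring(frag, offs, offs + k - 1L)
  hit <- match(probes, kmerTable)
  ok <- !is.na(hit)
  if (sum(ok) < 2L) return(NA_integer_)
  diag <- hit[ok] - offs[ok]
  tab <- table(diag)
  best <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) < 2L) return(NA_integer_)
  best
}

.fragIdentity <- function(frag, target, kmerTable, scheme, margin = 30L) {
  d <- .seedDiagonal(frag, kmerTable)
  if (!is.na(d)) {
    lo <- max(1L, d + 1L - margin)
    hi <- min(nchar(target), d + nchar(frag) + margin)
    window <- substr(target, lo, hi)
    band <- margin + 10L  # seeded placement: path stays near the diagonal
  } else {
    window <- target  # seed failed: full dynamic program against the genome
    band <- -1L
  }
  res <- .align_affine_cpp(frag, window, scheme@match, scheme@mismatch,
                           scheme@gapOpen, scheme@gapExtend, TRUE, band)
  len <- res$matches + res$mismatches + res$gap_columns
  c(identity = if (len > 0L) 100 * res$matches / len else 0,
    coverage = 100 * (res$matches + res$mismatches) / nchar(frag))
}

#' Fragment-based average nucleotide identity (ANI)
#'
#' The classical fragment formulation: the query genome is chopped into
#' non-overlapping windows of `fragLen` bp; each full-length fragment is
#' placed at its best position on the subject (exact 9-mer seeding with a
#' diagonal vote, falling back to a full dynamic program when seeding
#' fails), and fragments passing the identity and coverage floors are
#' averaged. Both directions are computed and the symmetrized mean is
#' reported; ~95% is the conventional species boundary this formulation was
#' calibrated against.
#'
#' @param genomeA,genomeB genomes as [GenomeRecord-class], `DNAStringSet`,
#'   or character (sequences are concatenated).
#' @param fragLen fragment length in bp (>= 100; default 1000).
#' @param minFragIdentity,minFragCoverage retention floors in percent
#'   (defaults 70/70).
#' @param scheme alignment scoring scheme.
#' @param .kmerA,.kmerB optional precomputed 9-mer tables (see
#'   [aniMatrix()]), an internal cache to avoid rebuilding them per pair.
#' @return an [ANIResult-class].
#' @examples
#' g <- paste(sample(c("A", "C", "G", "T"), 2000, TRUE), collapse = "")
#' computeANI(g, g, fragLen = 500)
#' @export
computeANI <- function(genomeA, genomeB, fragLen = 1000L,
                       minFragIdentity = 70, minFragCoverage = 70,
                       scheme = scoringScheme(),
                       .kmerA = NULL, .kmerB = NULL) {
  a <- .asGenomeString(genomeA)
  b <- .asGenomeString(genomeB)
  fragLen <- as.integer(fragLen)
  if (fragLen < 100L) stop("fragLen must be >= 100")
  if (nchar(a) < fragLen || nchar(b) < fragLen)
    stop("genome shorter than one fragment")
  if (is.null(.kmerA)) .kmerA <- .kmerTable(a)
  if (is.null(.kmerB)) .kmerB <- .kmerTable(b)

  oneWay <- function(q, t, kt) {
    starts <- seq(1L, nchar(q) - fragLen + 1L, by = fragLen)
    ids <- numeric(0); covs <- numeric(0)
    for (s in starts) {
      frag <- substr(q, s, s + fragLen - 1L)
      r <- .fragIdentity(frag, t, kt, scheme)
      ids <- c(ids, r[["identity"]]); covs <- c(covs, r[["coverage"]])
    }
    keep <- ids >= minFragIdentity & covs >= minFragCoverage
    list(ani = if (any(keep)) mean(ids[keep]) else NA_real_,
         identities = ids[keep], coverages = covs[keep],
         allIdentities = ids, nUsed = sum(keep), nTotal = length(starts))
  }
  fw <- oneWay(a, b, .kmerB)
  rv <- oneWay(b, a, .kmerA)
  vals <- c(fw$ani, rv$ani)
  ani <- if (all(is.na(vals))) 0 else mean(vals, na.rm = TRUE)
  methods::new("ANIResult", ani = ani, forward = fw, reverse = rv)
}

#' Symmetric ANI matrix over a set of genomes
#'
#' @param genomes named list of [GenomeRecord-class] objects.
#' @param ... passed to [computeANI()].
#' @return symmetric numeric matrix (percent), diagonal 100.
#' @export
aniMatrix <- function(genomes, ...) {
  ids <- vapply(genomes, function(g) g@speciesId, character(1))
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  if (n < 2L) return(m)
  strs <- lapply(genomes, .asGenomeString)
  kts <- lapply(strs, .kmerTable)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- computeANI(strs[[i]], strs[[j]], ...,
                      .kmerA = kts[[i]], .kmerB = kts[[j]])@ani
      m[i, j] <- m[j, i] <- v
    }
  }
  m
}

#' Single-copy orthologs by complete reciprocal-best-hit cliques
#'
#' For every species pair, best hits are determined by global alignment
#' score; reciprocal best hits form a graph over (species, gene) nodes, and
#' a gene family is retained only if its connected component has exactly one
#' member per species and every pairwise RBH edge is present (a complete
#' single-copy clique).
#'
#' @param seqSets named list (one element per species, >= 2) of named
#'   character vectors or `XStringSet`s of gene sequences.
#' @param scheme alignment scoring scheme.
#' @param seqType `"nt"` or `"aa"` recorded in the resulting table.
#' @return an [SCOTable-class]; rows are named after the first species'
#'   gene ids.
#' @export
findScoRbh <- function(seqSets, scheme = scoringScheme(), seqType = "nt") {
  if (length(seqSets) < 2L) stop("need >= 2 species")
  if (is.null(names(seqSets)) || any(!nzchar(names(seqSets))))
    stop("seqSets must be named by species")
  sets <- lapply(seqSets, function(s) {
    if (methods::is(s, "XStringSet")) s <- as.character(s)
    if (length(s) == 0L) stop("empty proteome/gene set")
    nm <- names(s)
    s <- toupper(s)  # drops attributes, so restore names afterwards
    names(s) <- if (is.null(nm)) sprintf("g%03d", seq_along(s)) else nm
    s
  })
  sp <- names(sets)
  n <- length(sp)
  # best hit index from species x gene -> species y
  best <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      si <- sets[[i]]; sj <- sets[[j]]
      bh <- integer(length(si))
      for (gi in seq_along(si)) {
        sc <- vapply(sj, function(t)
          .align_affine_cpp(si[[gi]], t, scheme@match, scheme@mismatch,
                            scheme@gapOpen, scheme@gapExtend,
                            FALSE, -1L)$score, numeric(1))
        bh[gi] <- which.max(sc)  # ties: first
      }
      best[[paste(i, j)]] <- bh
    }
  }
  # RBH edges between (i, gi) and (j, gj)
  nodeId <- function(i, g) paste0(i, ".", g)
  parent <- new.env(parent = emptyenv())
  findRoot <- function(x) {
    while (!identical(get(x, envir = parent), x)) {
      assign(x, get(get(x, envir = parent), envir = parent), envir = parent)
      x <- get(x, envir = parent)
    }
    x
  }
  for (i in seq_len(n)) for (g in seq_along(sets[[i]]))
    assign(nodeId(i, g), nodeId(i, g), envir = parent)
  edges <- new.env(parent = emptyenv())
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      bij <- best[[paste(i, j)]]; bji <- best[[paste(j, i)]]
      for (gi in seq_along(bij)) {
        gj <- bij[gi]
        if (bji[gj] == gi) {
          a <- nodeId(i, gi); b <- nodeId(j, gj)
          ra <- findRoot(a); rb <- findRoot(b)
          if (!identical(ra, rb)) assign(ra, rb, envir = parent)
          assign(paste(a, b), TRUE, envir = edges)
        }
      }
    }
  }
  # group nodes by component
  comp <- list()
  for (i in seq_len(n)) for (g in seq_along(sets[[i]])) {
    r <- findRoot(nodeId(i, g))
    comp[[r]] <- rbind(comp[[r]], c(i, g))
  }
  keep <- list()
  for (cc in comp) {
    if (nrow(cc) != n) next
    if (anyDuplicated(cc[, 1L])) next
    # all pairwise RBH edges must be present (complete clique)
    complete <- TRUE
    o <- cc[order(cc[, 1L]), , drop = FALSE]
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (!isTRUE(mget(paste(nodeId(o[i, 1L], o[i, 2L]),
                               nodeId(o[j, 1L], o[j, 2L])),
                         envir = edges, ifnotfound = FALSE)[[1L]])) {
          complete <- FALSE
          break
        }
      }
      if (!complete) break
    }
    if (complete) keep[[length(keep) + 1L]] <- o
  }
  if (length(keep) == 0L)
    stop("no complete single-copy ortholog families found")
  rowIds <- vapply(keep, function(o) names(sets[[1L]])[o[1L, 2L]],
                   character(1))
  m <- matrix(NA_character_, length(keep), n,
              dimnames = list(rowIds, sp))
  for (r in seq_along(keep)) {
    o <- keep[[r]]
    for (i in seq_len(n)) m[r, i] <- sets[[o[i, 1L]]][[o[i, 2L]]]
  }
  m <- m[order(rownames(m)), , drop = FALSE]
  methods::new("SCOTable", sequences = m, seqType = seqType)
}

#' SCO table from simulator ground truth
#'
#' In simulated genera orthology is known by construction (genes are
#' positional); this bypasses the reciprocal-best-hit search. The two paths
#' must agree at moderate depth.
#'
#' @param sim a [GenusSimulation-class] (or named list of
#'   [GenomeRecord-class]).
#' @return an [SCOTable-class] of nucleotide sequences.
#' @export
scoTableFromSimulation <- function(sim) {
  genomes <- if (methods::is(sim, "GenusSimulation")) sim@genomes else sim
  ids <- vapply(genomes, function(g) g@speciesId, character(1),
                USE.NAMES = FALSE)
  ng <- unique(vapply(genomes, function(g) length(g@genes), integer(1)))
  if (length(ng) != 1L) stop("gene count differs across genomes")
  if (ng == 0L) stop("no marker genes in this simulation")
  m <- matrix(NA_character_, ng, length(ids),
              dimnames = list(sprintf("g%03d", seq_len(ng)), ids))
  for (i in seq_along(genomes))
    m[, i] <- as.character(genomes[[i]]@genes)
  methods::new("SCOTable", sequences = m, seqType = "nt")
}

#' Concatenated maximum-likelihood distance matrix from an SCO table
#'
#' Each ortholog pair is globally aligned, aligned columns are concatenated,
#' the proportion of differing sites `p` is taken over non-gap columns, and
#' the closed-form ML correction is applied: Jukes-Cantor for nucleotides,
#' Poisson for amino acids. Saturated pairs (p beyond the model domain) are
#' reported as `NA` and listed in the `"saturated"` attribute rather than
#' silently clamped.
#'
#' The default scoring uses stiff gap penalties (open -8, extend -2): with
#' permissive penalties the optimizer converts runs of mismatches into
#' spurious gaps at high divergence, deflating `p` and biasing distances
#' short; stiff penalties keep gaps for genuine indels and make the
#' estimator additive-in-expectation on clock simulations (regression
#' slope ~1 against true path lengths, a tested invariant).
#'
#' @param sco an [SCOTable-class].
#' @param scheme alignment scoring scheme (see Details for the default).
#' @return symmetric numeric matrix of substitutions/site with attribute
#'   `saturated` (two-column matrix of species pairs, possibly empty).
#' @export
concatMlDistance <- function(sco, scheme = scoringScheme(gapOpen = -8,
                                                         gapExtend = -2)) {
  stopifnot(methods::is(sco, "SCOTable"))
  m <- sco@sequences
  sp <- colnames(m)
  n <- length(sp)
  if (n < 2L) stop("need >= 2 species")
  lim <- if (sco@seqType == "nt") 0.75 else 0.95
  corr <- if (sco@seqType == "nt") jcDistance else poissonAaDistance
  out <- matrix(0, n, n, dimnames = list(sp, sp))
  sat <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      diff <- 0L; tot <- 0L
      for (g in seq_len(nrow(m))) {
        r <- .align_affine_cpp(m[g, i], m[g, j], scheme@match,
                               scheme@mismatch, scheme@gapOpen,
                               scheme@gapExtend, FALSE, -1L)
        diff <- diff + r$mismatches
        tot <- tot + r$matches + r$mismatches
      }
      p <- if (tot > 0L) diff / tot else 0
      if (p >= lim) {
        out[i, j] <- out[j, i] <- NA_real_
        sat <- rbind(sat, c(sp[i], sp[j]))
      } else {
        out[i, j] <- out[j, i] <- corr(p)
      }
    }
  }
  attr(out, "saturated") <-
    if (is.null(sat)) matrix(character(0), 0, 2) else sat
  out
}
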