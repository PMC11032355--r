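.intactCopies <- function(copies, minLenFrac = 0.8, expectedLen = NULL) {
  s <- if (methods::is(copies, "XStringSet")) as.character(copies)
       else as.character(copies)
  s <- toupper(s)
  if (length(s) == 0L) return(character(0))
  if (is.null(expectedLen)) expectedLen <- stats::median(nchar(s))
  ok <- nchar(s) >= minLenFrac * expectedLen & !grepl("NN", s, fixed = TRUE)
  s[ok]
}

#' Majority-variant representative of a set of rRNA copies
#'
#' Copies shorter than `minLenFrac` of the expected length (deletion-affected,
#' possibly non-functional) are excluded; the remaining copies are
#' dereplicated and the most abundant exact sequence is returned. Ties break
#' by longest sequence, then lexicographically.
#'
#' @param copies `DNAStringSet` or character vector of copy sequences.
#' @param minLenFrac minimum length as a fraction of the expected length.
#' @param expectedLen expected copy length; defaults to the median length.
#' @return a single sequence string.
#' @export
selectRepresentative <- function(copies, minLenFrac = 0.8,
                                 expectedLen = NULL) {
  s <- .intactCopies(copies, minLenFrac, expectedLen)
  if (length(s) == 0L) stop("no intact rRNA copies to choose from")
  tab <- table(s)
  cand <- names(tab)[tab == max(tab)]
  if (length(cand) > 1L) {
    cand <- cand[nchar(cand) == max(nchar(cand))]
    cand <- sort(cand)
  }
  cand[1L]
}

#' Per-pair 16S-vs-genome divergence table
#'
#' One row per unordered species pair: symmetrized ANI, concatenated-SCO ML
#' distance, and the percent identity of the majority-variant 16S
#' representatives. `rrna_divergence` is `100 - rrna_identity`. The
#' `hgt_flag` column is initialised to `FALSE`; see [detectHgtPairs()].
#'
#' @param genomes named list of [GenomeRecord-class] objects.
#' @param aniMat symmetric ANI matrix (percent) covering all species.
#' @param mlMat symmetric ML distance matrix covering all species.
#' @param scheme alignment scoring scheme.
#' @param band optional alignment band half-width for the 16S alignments.
#' @return data.frame with columns `species_a`, `species_b`, `ani`,
#'   `ml_distance`, `rrna_identity`, `rrna_divergence`, `hgt_flag`.
#' @export
buildPairTable <- function(genomes, aniMat, mlMat,
                           scheme = scoringScheme(), band = NULL) {
  ids <- sort(vapply(genomes, function(g) g@speciesId, character(1)))
  names(genomes) <- vapply(genomes, function(g) g@speciesId, character(1))
  for (nm in c("aniMat", "mlMat")) {
    m <- get(nm)
    missing <- setdiff(ids, rownames(m))
    if (length(missing))
      stop("species absent from ", nm, ": ", paste(missing, collapse = ", "))
  }
  reps <- vapply(genomes[ids], function(g)
    selectRepresentative(g@rrnaCopies), character(1))
  n <- length(ids)
  if (n < 2L) stop("need >= 2 species")
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      idy <- if (reps[i] == reps[j]) 100
             else percentIdentity(globalAlign(reps[i], reps[j], scheme, band))
      k <- k + 1L
      rows[[k]] <- data.frame(
        species_a = ids[i], species_b = ids[j],
        ani = aniMat[ids[i], ids[j]], ml_distance = mlMat[ids[i], ids[j]],
        rrna_identity = idy, rrna_divergence = 100 - idy,
        hgt_flag = FALSE, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Flag candidate 16S horizontal-transfer pairs
#'
#' A pair is flagged when the species share essentially the same 16S
#' sequence (identity above `idThreshold`, default 99.9%) despite being
#' evolutionarily well separated at the genome level (ANI below
#' `separationThreshold`, default the ~95% species boundary).
#'
#' @param pairs pair table from [buildPairTable()].
#' @param idThreshold 16S identity threshold in percent.
#' @param separationThreshold ANI species boundary in percent.
#' @return list with `pairs` (table with `hgt_flag` filled), `flagged`
#'   (flagged subset) and `n` (flag count).
#' @export
detectHgtPairs <- function(pairs, idThreshold = 99.9,
                           separationThreshold = 95) {
  if (idThreshold < 0 || idThreshold > 100 ||
      separationThreshold < 0 || separationThreshold > 100)
    stop("thresholds must lie in [0, 100]")
  need <- c("species_a", "species_b", "ani", "rrna_identity")
  if (!all(need %in% names(pairs))) stop("not a valid pair table")
  pairs$hgt_flag <- pairs$rrna_identity > idThreshold &
    !is.na(pairs$ani) & pairs$ani < separationThreshold
  list(pairs = pairs, flagged = pairs[pairs$hgt_flag, , drop = FALSE],
       n = sum(pairs$hgt_flag))
}

#' Genus summary row (species, transfer pairs, copy number, SCO count)
#'
#' Copy-number quartiles use linear-interpolation quantiles, so medians may
#' be half-integral. Copy counts consider intact copies only (length at
#' least 80% of the expected copy length).
#'
#' @param genusName genus label.
#' @param genomes named list of [GenomeRecord-class] objects.
#' @param pairs flagged pair table (after [detectHgtPairs()]).
#' @param sco optional [SCOTable-class] for the SCO count.
#' @return one-row data.frame: `genus`, `n_species`, `n_hgt_pairs`,
#'   `copy_number_median`, `copy_number_q1`, `copy_number_q3`, `n_sco`.
#' @export
summarizeGenus <- function(genusName, genomes, pairs, sco = NULL) {
  cn <- vapply(genomes, function(g)
    length(.intactCopies(g@rrnaCopies)), integer(1))
  q <- stats::quantile(cn, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  nflag <- if ("hgt_flag" %in% names(pairs)) sum(pairs$hgt_flag) else 0L
  maxPairs <- length(genomes) * (length(genomes) - 1L) / 2L
  if (nflag > maxPairs) stop("more flags than pairs")
  data.frame(genus = genusName, n_species = length(genomes),
             n_hgt_pairs = nflag, copy_number_median = q[2L],
             copy_number_q1 = q[1L], copy_number_q3 = q[3L],
             n_sco = if (is.null(sco)) NA_integer_
                     else nrow(sco@sequences),
             stringsAsFactors = FALSE)
}

#' Cross-genus scan for shared 16S variants
#'
#' Applies the same identity + separation rule across genera: every
#' cross-genus species pair whose 16S representatives exceed `idThreshold`
#' identity is checked by ANI and flagged if below `separationThreshold`.
#' Without inter-genus transfer this is expected to come back empty.
#'
#' @param genera named list (>= 2) of genome lists (each a named list of
#'   [GenomeRecord-class]).
#' @param idThreshold,separationThreshold as in [detectHgtPairs()].
#' @param scheme alignment scoring scheme.
#' @param band optional alignment band for the 16S comparisons.
#' @param ... passed to [computeANI()] for candidate pairs.
#' @return data.frame of flagged cross-genus pairs (possibly 0 rows) with
#'   columns `genus_a`, `species_a`, `genus_b`, `species_b`,
#'   `rrna_identity`, `ani`.
#' @export
intergenusScan <- function(genera, idThreshold = 99.9,
                           separationThreshold = 95,
                           scheme = scoringScheme(), band = NULL, ...) {
  if (length(genera) < 2L) stop("need >= 2 genera")
  if (is.null(names(genera))) names(genera) <- paste0("genus", seq_along(genera))
  reps <- lapply(genera, function(gen)
    vapply(gen, function(g) selectRepresentative(g@rrnaCopies), character(1)))
  out <- list()
  gn <- names(genera)
  for (i in seq_len(length(genera) - 1L)) {
    for (j in seq.int(i + 1L, length(genera))) {
      for (a in seq_along(genera[[i]])) {
        for (b in seq_along(genera[[j]])) {
          ra <- reps[[i]][a]; rb <- reps[[j]][b]
          idy <- if (ra == rb) 100
                 else percentIdentity(globalAlign(ra, rb, scheme, band))
          if (idy > idThreshold) {
            ani <- computeANI(genera[[i]][[a]], genera[[j]][[b]], ...)@ani
            if (!is.na(ani) && ani < separationThreshold) {
              out[[length(out) + 1L]] <- data.frame(
                genus_a = gn[i],
                species_a = genera[[i]][[a]]@speciesId,
                genus_b = gn[j],
                species_b = genera[[j]][[b]]@speciesId,
                rrna_identity = idy, ani = ani, stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(genus_a = character(0), species_a = character(0),
                  genus_b = character(0), species_b = character(0),
                  rrna_identity = numeric(0), ani = numeric(0),
                  stringsAsFactors = FALSE)
}
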