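#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib stasis16S, .registration = TRUE
NULL

#' Scoring scheme for global alignment
#'
#' Affine-gap scoring used by [globalAlign()]. Match reward must be
#' non-negative and gap penalties non-positive.
#'
#' @slot match numeric(1), score added per matching column.
#' @slot mismatch numeric(1), score added per mismatching column.
#' @slot gapOpen numeric(1), penalty (<= 0) charged once per gap opening.
#' @slot gapExtend numeric(1), penalty (<= 0) charged per gap column.
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(match = "numeric", mismatch = "numeric",
                 gapOpen = "numeric", gapExtend = "numeric"),
  validity = function(object) {
    if (length(object@match) != 1L || length(object@mismatch) != 1L ||
        length(object@gapOpen) != 1L || length(object@gapExtend) != 1L)
      return("all scoring parameters must be scalars")
    if (object@match < 0) return("match score must be >= 0")
    if (object@gapOpen > 0 || object@gapExtend > 0)
      return("gap penalties must be <= 0")
    TRUE
  })

#' Result of a pairwise global alignment
#'
#' @slot alignedA,alignedB gapped sequence strings of equal length.
#' @slot matches,mismatches,gapOpenings,gapColumns integer column counts; a
#'   column with a gap in either row counts once in `gapColumns`.
#' @slot score numeric(1) optimal score under the [ScoringScheme-class] used.
#' @exportClass AlignmentResult
setClass("AlignmentResult",
  representation(alignedA = "character", alignedB = "character",
                 matches = "integer", mismatches = "integer",
                 gapOpenings = "integer", gapColumns = "integer",
                 score = "numeric"),
  validity = function(object) {
    if (nchar(object@alignedA) != nchar(object@alignedB))
      return("aligned strings must have equal length")
    if (object@matches + object@mismatches + object@gapColumns !=
        nchar(object@alignedA))
      return("matches + mismatches + gapColumns must equal alignment length")
    if (any(c(object@matches, object@mismatches, object@gapOpenings,
              object@gapColumns) < 0L))
      return("counts must be non-negative")
    TRUE
  })

#' Parameters of the genus-evolution simulator
#'
#' Marker genes evolve by a Jukes-Cantor substitution process at rate 1 per
#' site per unit branch length; every rRNA copy evolves independently at
#' `rrnaRateFactor` times that rate. Gene conversion overwrites a recipient
#' copy with a uniformly chosen sister copy of the same genome at rate
#' `conversionRate` per copy per unit branch length; rRNA horizontal transfer
#' copies the donor's majority variant into a random coexisting lineage at
#' rate `hgtRate` per lineage pair per unit time.
#'
#' @slot nSpecies integer, number of tip species (>= 2).
#' @slot treeModel character, currently only `"yule"`.
#' @slot birthRate numeric speciation rate of the Yule process.
#' @slot treeDepth numeric, root-to-tip path length in expected marker
#'   substitutions per site.
#' @slot nGenes,geneLen integer, marker-gene count (>= 0) and length in bp.
#' @slot rrnaLen integer, rRNA copy length in bp (default 1550).
#' @slot rrnaCopyNumber integer >= 1 rRNA copies per genome.
#' @slot rrnaRateFactor numeric in (0, 1], rRNA rate relative to markers.
#' @slot conversionRate numeric >= 0, gene-conversion rate per copy.
#' @slot hgtRate numeric >= 0, rRNA transfer rate per lineage pair.
#' @slot hgtScope character, `"all_copies"` or `"k_copies"`.
#' @slot hgtCopies integer, copies replaced when `hgtScope = "k_copies"`.
#' @slot ancestralRrna `NULL` or a `DNAStringSet` of `rrnaCopyNumber`
#'   sequences planting an ancestral intragenomic polymorphism.
#' @exportClass SimParams
setClass("SimParams",
  representation(nSpecies = "integer", treeModel = "character",
                 birthRate = "numeric", treeDepth = "numeric",
                 nGenes = "integer", geneLen = "integer", rrnaLen = "integer",
                 rrnaCopyNumber = "integer", rrnaRateFactor = "numeric",
                 conversionRate = "numeric", hgtRate = "numeric",
                 hgtScope = "character", hgtCopies = "integer",
                 ancestralRrna = "ANY"),
  validity = function(object) {
    if (object@nSpecies < 2L) return("nSpecies must be >= 2")
    if (!object@treeModel %in% "yule") return("unknown treeModel")
    if (object@birthRate <= 0 || object@treeDepth <= 0)
      return("birthRate and treeDepth must be > 0")
    if (object@nGenes < 0L || object@geneLen < 1L || object@rrnaLen < 1L)
      return("invalid gene/rRNA dimensions")
    if (object@rrnaCopyNumber < 1L) return("rrnaCopyNumber must be >= 1")
    if (object@rrnaRateFactor <= 0 || object@rrnaRateFactor > 1)
      return("rrnaRateFactor must lie in (0, 1]")
    if (object@conversionRate < 0 || object@hgtRate < 0)
      return("event rates must be >= 0")
    if (!object@hgtScope %in% c("all_copies", "k_copies"))
      return("hgtScope must be 'all_copies' or 'k_copies'")
    if (object@hgtScope == "k_copies" &&
        (object@hgtCopies < 1L || object@hgtCopies > object@rrnaCopyNumber))
      return("hgtCopies must lie in [1, rrnaCopyNumber]")
    if (!is.null(object@ancestralRrna)) {
      if (!methods::is(object@ancestralRrna, "DNAStringSet"))
        return("ancestralRrna must be NULL or a DNAStringSet")
      if (length(object@ancestralRrna) != object@rrnaCopyNumber)
        return("ancestralRrna must supply one sequence per rRNA copy")
    }
    TRUE
  })

#' One simulated or ingested genome
#'
#' @slot speciesId character(1) species/isolate identifier.
#' @slot genes `DNAStringSet` of marker-gene sequences.
#' @slot rrnaCopies `DNAStringSet` of rRNA copy sequences (>= 1).
#' @slot metadata named list of labels (e.g. serotype analogs).
#' @exportClass GenomeRecord
setClass("GenomeRecord",
  representation(speciesId = "character", genes = "ANY",
                 rrnaCopies = "ANY", metadata = "list"),
  validity = function(object) {
    if (length(object@speciesId) != 1L || !nzchar(object@speciesId))
      return("speciesId must be a non-empty string")
    if (!methods::is(object@genes, "DNAStringSet"))
      return("genes must be a DNAStringSet")
    if (!methods::is(object@rrnaCopies, "DNAStringSet"))
      return("rrnaCopies must be a DNAStringSet")
    if (length(object@rrnaCopies) < 1L)
      return("at least one rRNA copy is required")
    TRUE
  })

#' A simulated genus: tree, genomes and ground-truth event log
#'
#' @slot tree an ultrametric `phylo` tree with tip labels matching the
#'   genome `speciesId`s.
#' @slot genomes named list of [GenomeRecord-class] objects.
#' @slot events data.frame ground-truth event log with columns
#'   `event_type`, `time`, `donor`, `recipient`, `copies_affected`, `tract`.
#' @slot params the [SimParams-class] used (or a list in vertebrate mode).
#' @exportClass GenusSimulation
setClass("GenusSimulation",
  representation(tree = "ANY", genomes = "list", events = "data.frame",
                 params = "ANY"),
  validity = function(object) {
    if (!inherits(object@tree, "phylo")) return("tree must be a 'phylo'")
    if (length(object@genomes) < 1L) return("no genomes")
    ids <- vapply(object@genomes, function(g) g@speciesId, character(1))
    if (!setequal(ids, object@tree$tip.label))
      return("genome speciesIds must match tree tip labels")
    need <- c("event_type", "time", "donor", "recipient",
              "copies_affected", "tract")
    if (!all(need %in% names(object@events)))
      return("event log is missing required columns")
    TRUE
  })

#' Fragment-based average nucleotide identity between two genomes
#'
#' @slot ani numeric(1) symmetrized mean ANI (percent).
#' @slot forward,reverse lists with elements `ani`, `identities`,
#'   `coverages`, `nUsed`, `nTotal` for each query direction.
#' @exportClass ANIResult
setClass("ANIResult",
  representation(ani = "numeric", forward = "list", reverse = "list"),
  validity = function(object) {
    for (d in list(object@forward, object@reverse)) {
      if (d$nUsed > d$nTotal) return("nUsed must be <= nTotal")
      if (d$nUsed > 0L &&
          abs(d$ani - mean(d$identities)) > 1e-8)
        return("directional ani must equal the mean retained identity")
    }
    if (object@ani < 0 || object@ani > 100) return("ani must lie in [0, 100]")
    TRUE
  })

#' Complete single-copy ortholog table
#'
#' @slot sequences character matrix, rows = ortholog ids, columns = species;
#'   every cell holds exactly one sequence (no missing entries).
#' @slot seqType `"nt"` or `"aa"`.
#' @exportClass SCOTable
setClass("SCOTable",
  representation(sequences = "matrix", seqType = "character"),
  validity = function(object) {
    if (!is.character(object@sequences)) return("sequences must be character")
    if (anyNA(object@sequences) || any(!nzchar(object@sequences)))
      return("SCO table must be complete: one sequence per species per gene")
    if (!object@seqType %in% c("nt", "aa")) return("seqType must be nt or aa")
    TRUE
  })

#' A fitted divergence-accumulation model
#'
#' @slot model one of `"linear_origin"`, `"quadratic_origin"`,
#'   `"logarithmic"`.
#' @slot coefficients named numeric coefficients.
#' @slot se numeric standard errors of the coefficients.
#' @slot rss numeric(1) residual sum of squares.
#' @slot n integer(1) number of points.
#' @slot fStatistic,pValue nested-model comparison statistics (NA until
#'   [selectModel()] is applied).
#' @slot selected logical(1), set by [selectModel()].
#' @exportClass RateFit
setClass("RateFit",
  representation(model = "character", coefficients = "numeric",
                 se = "numeric", rss = "numeric", n = "integer",
                 fStatistic = "numeric", pValue = "numeric",
                 selected = "logical"),
  validity = function(object) {
    if (!object@model %in% c("linear_origin", "quadratic_origin",
                             "logarithmic"))
      return("unknown model")
    if (object@rss < -1e-12) return("rss must be >= 0")
    if (!is.na(object@pValue) &&
        (object@pValue < 0 || object@pValue > 1))
      return("pValue must lie in [0, 1]")
    TRUE
  })

#' Catalog of well-separated intragenomic rRNA variants
#'
#' @slot variants `DNAStringSet` of reference variants, named by label
#'   (`A`, `B`, ... in descending founding abundance).
#' @slot diffMatrix integer matrix of pairwise mismatches + gap openings
#'   between the reference variants.
#' @slot minSep,assignRadius the thresholds the catalog was built with.
#' @exportClass VariantCatalog
setClass("VariantCatalog",
  representation(variants = "ANY", diffMatrix = "matrix",
                 minSep = "integer", assignRadius = "integer"),
  validity = function(object) {
    if (!methods::is(object@variants, "DNAStringSet"))
      return("variants must be a DNAStringSet")
    if (anyDuplicated(names(object@variants)))
      return("variant labels must be unique")
    n <- length(object@variants)
    if (!all(dim(object@diffMatrix) == c(n, n)))
      return("diffMatrix dimensions must match the number of variants")
    if (n > 1L) {
      off <- object@diffMatrix[upper.tri(object@diffMatrix)]
      if (any(off < object@minSep))
        return("catalog variants must differ by at least minSep")
    }
    TRUE
  })
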