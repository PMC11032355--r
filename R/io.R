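#' Read a FASTA file of nucleotide sequences
#'
#' Accepts wrapped or unwrapped records and mixed case; sequences are folded
#' to upper case, ids (full header lines) preserved.
#'
#' @param path FASTA file path.
#' @return a named `DNAStringSet`.
#' @export
readFastaSequences <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) stop("no FASTA records in ", path)
  Biostrings::DNAStringSet(toupper(as.character(x)))
}

#' Write sequences to FASTA (70-column wrapping)
#'
#' @param seqs named character vector or `XStringSet`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeFastaSequences <- function(seqs, path) {
  if (methods::is(seqs, "XStringSet")) seqs <- as.character(seqs)
  if (length(seqs) == 0L) stop("no sequences to write")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 70L)
    writeLines(substring(s, starts, pmin(starts + 69L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a genome fixture FASTA with structured headers
#'
#' Headers must follow `>{species_id}|{locus_type}|{index}` as written by
#' [writeFixture()]; `gene` entries become marker genes, everything else
#' becomes an rRNA/locus entry.
#'
#' @param path FASTA path.
#' @return a [GenomeRecord-class].
#' @export
readGenomeFasta <- function(path) {
  seqs <- readFastaSequences(path)
  parts <- strsplit(names(seqs), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed header at record ", bad[1L], " in ", path,
         " (expected species|locus|index)")
  sp <- unique(vapply(parts, `[`, character(1), 1L))
  if (length(sp) != 1L)
    stop("multiple species ids in one genome FASTA: ",
         paste(sp, collapse = ", "))
  locus <- vapply(parts, `[`, character(1), 2L)
  genes <- seqs[locus == "gene"]
  if (length(genes)) names(genes) <- sprintf("g%03d", seq_along(genes))
  rr <- seqs[locus != "gene"]
  if (length(rr) == 0L) stop("genome ", sp, " has no rRNA entries")
  names(rr) <- ifelse(locus[locus != "gene"] == "rrna",
                      sprintf("rrna%02d", seq_along(rr)),
                      paste0("locus", locus[locus != "gene"]))
  methods::new("GenomeRecord", speciesId = sp, genes = genes,
               rrnaCopies = rr, metadata = list())
}

#' Read a whole fixture directory back into a simulation object
#'
#' @param dir directory produced by [writeFixture()].
#' @return a [GenusSimulation-class] (params slot is `NULL`).
#' @export
readFixture <- function(dir) {
  if (!dir.exists(dir)) stop("directory not found: ", dir)
  tree <- readNewickTree(file.path(dir, "tree.nwk"))
  fas <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  genomes <- lapply(fas, readGenomeFasta)
  names(genomes) <- vapply(genomes, function(g) g@speciesId, character(1))
  events <- readTsv(file.path(dir, "events.tsv"))
  if (nrow(events) == 0L) events <- .emptyEventLog()
  events$time <- as.numeric(events$time)
  for (cc in c("event_type", "donor", "recipient", "copies_affected",
               "tract"))
    events[[cc]] <- as.character(events[[cc]])
  methods::new("GenusSimulation", tree = tree, genomes = genomes,
               events = events, params = NULL)
}

#' Read a newick tree, requiring branch lengths
#'
#' @param path newick file.
#' @return a `phylo`.
#' @export
readNewickTree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick in ", path)
  if (is.null(tr$edge.length))
    stop("newick tree in ", path, " has no branch lengths (required)")
  tr
}

#' Write/read TSV tables with headers
#'
#' Plain tab-separated tables, never quoted, `NA` written literally.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @return `writeTsv`: invisibly, `path`; `readTsv`: a data.frame.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
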