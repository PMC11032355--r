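# Independent test oracles and sequence helpers. The alignment oracle is a
# self-contained affine-gap dynamic program (score only), vectorised per row
# with a cummax trick for the within-row gap state; it shares no code with
# the package kernel.

randSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Jukes-Cantor mutation of a sequence at expected distance d (sequential
# multi-hit handling, independent of the simulator's implementation).
mutateJC <- function(s, d) {
  x <- strsplit(s, "")[[1]]
  nmut <- rpois(1, length(x) * d)
  B <- c("A", "C", "G", "T")
  for (k in seq_len(nmut)) {
    p <- sample.int(length(x), 1)
    x[p] <- sample(setdiff(B, x[p]), 1)
  }
  paste(x, collapse = "")
}

# plant exactly k substitutions at distinct positions
plantSubs <- function(s, k) {
  x <- strsplit(s, "")[[1]]
  pos <- sample.int(length(x), k)
  B <- c("A", "C", "G", "T")
  for (p in pos) x[p] <- sample(setdiff(B, x[p]), 1)
  paste(x, collapse = "")
}

# Optimal global affine-gap alignment score. States: M (diagonal),
# X (gap in b, consumes a, from the row above), Y (gap in a, consumes b,
# within-row; closed via cummax over max(M, X) + gap chain).
oracleAlignScore <- function(a, b, match = 1, mismatch = -1,
                             go = -2, ge = -0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e18
  Mp <- c(0, rep(NEG, m))
  Xp <- rep(NEG, m + 1)
  Yp <- c(NEG, go + ge * seq_len(m))
  for (i in seq_len(n)) {
    Xc <- pmax(Mp + go + ge, Xp + ge, Yp + go + ge)
    s <- ifelse(A[i] == "N" | B == "N", mismatch,
                ifelse(A[i] == B, match, mismatch))
    Mc <- c(NEG, pmax(Mp[1:m], Xp[1:m], Yp[1:m]) + s)
    f <- pmax(Mc[1:m], Xc[1:m]) + go - ge * (0:(m - 1))
    Yc <- c(NEG, ge * seq_len(m) + cummax(f))
    Mp <- Mc; Xp <- Xc; Yp <- Yc
  }
  max(Mp[m + 1], Xp[m + 1], Yp[m + 1])
}

# quick intragenomic copy identities of one genome record
copyIdentities <- function(g, band = 40L) {
  cp <- as.character(rrnaCopies(g))
  n <- length(cp)
  out <- numeric(0)
  if (n < 2) return(out)
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      out <- c(out, if (cp[i] == cp[j]) 100
               else percentIdentity(globalAlign(cp[i], cp[j], band = band)))
    }
  }
  out
}
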