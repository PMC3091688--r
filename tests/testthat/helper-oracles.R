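# Independent oracles used by the test suite.  These deliberately share no
# code with the package implementation.

# BLOSUM62 is a data set (not an exported object) in Biostrings
B62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Exhaustive affine-gap Smith-Waterman (Gotoh) in plain R.  A gap of
# length k costs open + k * ext, matching the package's convention.
sw_oracle <- function(a, b, submat, open = 11, ext = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in a (consumes b)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[av[i - 1], bv[j - 1]]
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]))
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Global alignment with free end gaps (overlap alignment), returning the
# maximum score; match/mismatch/gap scores given explicitly.
overlap_oracle <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  S <- matrix(0, n + 1, m + 1)  # free leading gaps
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      S[i, j] <- max(S[i - 1, j - 1] + s, S[i - 1, j] + gap, S[i, j - 1] + gap)
    }
  }
  max(S[n + 1, ], S[, m + 1])   # free trailing gaps
}

# Monophyly by exhaustive bipartition enumeration: delete each internal
# edge of the unrooted tree (as a graph) and compare the resulting leaf
# components with the query subset.  Uses igraph, independent of the
# package's prop.part-style traversal.
monophyly_oracle <- function(tree, labels) {
  stopifnot(requireNamespace("igraph", quietly = TRUE))
  n_tip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  target <- sort(match(labels, tree$tip.label))
  if (length(target) %in% c(1L, n_tip)) return(TRUE)
  for (e in seq_len(nrow(tree$edge))) {
    g2 <- igraph::delete_edges(g, e)
    comp <- igraph::components(g2)$membership
    tips1 <- sort(as.integer(names(comp)[comp == 1 &
                                           as.integer(names(comp)) <= n_tip]))
    if (identical(tips1, target) ||
        identical(sort(setdiff(seq_len(n_tip), tips1)), target))
      return(TRUE)
  }
  FALSE
}

# random peptide / dna strings for property tests
random_pep <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                                       n, replace = TRUE), collapse = "")
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
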