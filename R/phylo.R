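# Distance-based phylogenetics: pairwise alignment distances, neighbor
# joining, and unrooted monophyly testing (used for the non-Bohr clade
# check).

#' Pairwise alignment distances for a set of coding sequences
#'
#' Distance between two sequences is `1 - identity` of their pairwise
#' global alignment with free end gaps (match 1, mismatch/internal gap 0 of
#' credit; identity = matches / aligned columns of the overlap region).
#'
#' @param cds_set Named character vector (or [Biostrings::DNAStringSet]) of
#'   at least 3 coding sequences.
#' @return List with `labels` and symmetric matrix `d` (zero diagonal),
#'   class `distance_matrix`.
#' @export
pairwise_distances <- function(cds_set) {
  if (inherits(cds_set, "DNAStringSet")) {
    cds_set <- setNames(as.character(cds_set), names(cds_set))
  }
  if (length(cds_set) < 3L) stop("need at least 3 sequences")
  labels <- names(cds_set)
  if (is.null(labels) || any(!nzchar(labels)) || anyDuplicated(labels))
    stop("sequences must carry unique non-empty labels")
  n <- length(cds_set)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  nmat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                   baseOnly = FALSE)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- Biostrings::pairwiseAlignment(
        Biostrings::DNAString(cds_set[[i]]), Biostrings::DNAString(cds_set[[j]]),
        type = "overlap", substitutionMatrix = nmat,
        gapOpening = 0, gapExtension = 1)
      ncol_aln <- nchar(as.character(Biostrings::pattern(al)))
      id <- if (ncol_aln == 0L) 0 else Biostrings::nmatch(al) / ncol_aln
      d[i, j] <- d[j, i] <- 1 - id
    }
  }
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (Q-criterion agglomeration; engine: [ape::nj]).
#' Negative branch lengths are clamped to zero with a warning.
#'
#' @param d A `distance_matrix` from [pairwise_distances()], or a symmetric
#'   numeric matrix with labelled rows/columns.
#' @return An unrooted [ape::phylo] tree.
#' @export
neighbor_joining <- function(d) {
  m <- if (inherits(d, "distance_matrix")) d$d else d
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("d must be a square matrix")
  if (nrow(m) < 3L) stop("need at least 3 taxa")
  if (max(abs(m - t(m))) > 1e-8) stop("non-symmetric distance matrix")
  if (any(diag(m) != 0)) stop("distance matrix diagonal must be zero")
  tree <- ape::nj(m)
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Test monophyly of a label subset on an unrooted tree
#'
#' In an unrooted tree a leaf set is monophyletic iff some edge bipartitions
#' the leaves into exactly that set and its complement.  Singletons and the
#' full leaf set are trivially monophyletic.
#'
#' @param tree An [ape::phylo] tree.
#' @param labels Character vector of leaf labels.
#' @return List with `monophyletic` (logical) and, when true and supported
#'   by an internal edge, `edge` (row index into `tree$edge`).
#' @export
is_monophyletic <- function(tree, labels) {
  tips <- tree$tip.label
  unknown <- setdiff(labels, tips)
  if (length(unknown) > 0L)
    stop("unknown label(s): ", paste(unknown, collapse = ", "))
  labels <- unique(labels)
  if (length(labels) %in% c(1L, length(tips)))
    return(list(monophyletic = TRUE, edge = NA_integer_))
  n_tip <- length(tips)
  target <- sort(match(labels, tips))
  # descendant tip sets below each edge (child side)
  for (e in seq_len(nrow(tree$edge))) {
    child <- tree$edge[e, 2L]
    below <- tips_below(tree, child, n_tip)
    if (identical(sort(below), target) ||
        identical(sort(setdiff(seq_len(n_tip), below)), target))
      return(list(monophyletic = TRUE, edge = e))
  }
  list(monophyletic = FALSE, edge = NA_integer_)
}

tips_below <- function(tree, node, n_tip) {
  if (node <= n_tip) return(node)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0L) {
    nd <- stack[[1L]]; stack <- stack[-1L]
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    out <- c(out, kids[kids <= n_tip])
    stack <- c(stack, kids[kids > n_tip])
  }
  out
}

#' Write a tree in Newick format
#'
#' @param tree An [ape::phylo] tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Non-Bohr clade check on a CDS set
#'
#' Builds alignment distances and a neighbor-joining tree for a labelled CDS
#' set and tests whether the given subset (e.g. the non-Bohr beta genes)
#' forms a clade.
#'
#' @param cds_set Named character vector of CDS.
#' @param subset Labels whose monophyly is tested.
#' @return List with `tree`, `monophyletic`, `edge`.
#' @export
clade_check <- function(cds_set, subset) {
  d <- pairwise_distances(cds_set)
  tree <- neighbor_joining(d)
  mono <- is_monophyletic(tree, subset)
  list(tree = tree, monophyletic = mono$monophyletic, edge = mono$edge)
}
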