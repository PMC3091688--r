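# Flanking-gene synteny: cluster typing from signature gene sets, shared
# gene presence/absence matrices, and dot-plot/windowed-identity homeology
# comparison.

#' Canonicalize flanking-gene names
#'
#' Case-folds, strips punctuation and whitespace, and maps common synonyms
#' (e.g. `MPG` to DNA-3-methyladenine glycosylase) so that gene lists from
#' different annotation sources compare by content rather than spelling.
#'
#' @param x Character vector of gene names.
#' @return Canonical name vector.
#' @export
canonical_gene_name <- function(x) {
  y <- tolower(x)
  y <- gsub("[^a-z0-9]", "", y)
  syn <- c(mpg = "dna3methyladenineglycosylase",
           c16orf35 = "upf0171proteinc16orf35",
           upf0171 = "upf0171proteinc16orf35",
           dock6 = "dedicatorofcytokinesisprotein6",
           elavl3 = "elavlikeprotein3",
           elavlike3 = "elavlikeprotein3",
           aqp8 = "aquaporin8",
           rhbdf1 = "rhomboidfamilymember1",
           arhgap = "rhogtpaseactivatingprotein")
  hit <- y %in% names(syn)
  y[hit] <- syn[y[hit]]
  y
}

#' Signature gene sets distinguishing the two teleost hemoglobin clusters
#'
#' Teleost genomes carry up to two ancestral hemoglobin cluster types that
#' are distinguishable by their flanking genes: Cluster 1 by UPF0171 protein
#' C16orf35, Rhomboid family member 1, Dedicator of cytokinesis protein 6,
#' ELAV-like protein 3 and DNA-3-methyladenine glycosylase; Cluster 2 by
#' Aquaporin-8 and Rho-GTPase-activating protein.
#'
#' @return List with canonicalized character sets `cluster1` and `cluster2`.
#' @export
signature_sets <- function() {
  sig <- list(
    cluster1 = canonical_gene_name(c(
      "UPF0171 protein C16orf35", "Rhomboid family member 1",
      "Dedicator of cytokinesis protein 6", "ELAV-like protein 3",
      "DNA-3-methyladenine glycosylase")),
    cluster2 = canonical_gene_name(c(
      "Aquaporin-8", "Rho-GTPase-activating protein")))
  stopifnot(length(intersect(sig$cluster1, sig$cluster2)) == 0L)
  sig
}

#' Read a flanking-gene table
#'
#' @param path TSV with columns `species`, `cluster_id`, `gene_name` and
#'   optionally `orientation` (toward/away/unknown relative to the cluster).
#' @return List of flanking-gene sets, one per (species, cluster_id), each a
#'   list with `species`, `cluster_id`, `genes` (data.frame `name`,
#'   `orientation`).
#' @export
read_flank_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("species", "cluster_id", "gene_name")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(x$orientation)) x$orientation <- "unknown"
  key <- paste(x$species, x$cluster_id, sep = "\r")
  lapply(split(x, factor(key, levels = unique(key))), function(d) {
    list(species = d$species[1L], cluster_id = d$cluster_id[1L],
         genes = data.frame(name = d$gene_name,
                            orientation = d$orientation,
                            stringsAsFactors = FALSE))
  })
}

#' Type a hemoglobin cluster from its flanking genes
#'
#' Counts how many Cluster 1 vs Cluster 2 signature genes appear among the
#' canonicalized flanking-gene names; the label goes to the signature set
#' with strictly more hits, with ties (including 0-0) reported as
#' `ambiguous`.  Invariant to gene order and duplicates.
#'
#' @param flank A flanking-gene set (element of [read_flank_tsv()] output)
#'   or a plain character vector of gene names.
#' @param sig Signature sets, see [signature_sets()].
#' @return List with `label` (cluster1/cluster2/ambiguous), `hits_cluster1`,
#'   `hits_cluster2` (canonical signature genes found).
#' @export
classify_cluster <- function(flank, sig = signature_sets()) {
  names_in <- if (is.character(flank)) flank else flank$genes$name
  canon <- unique(canonical_gene_name(names_in))
  h1 <- intersect(sig$cluster1, canon)
  h2 <- intersect(sig$cluster2, canon)
  label <- if (length(h1) > length(h2)) "cluster1"
           else if (length(h2) > length(h1)) "cluster2"
           else "ambiguous"
  list(label = label, hits_cluster1 = h1, hits_cluster2 = h2)
}

#' Presence/absence matrix of flanking genes across clusters
#'
#' @param flanks List of flanking-gene sets (>= 2), as from
#'   [read_flank_tsv()].
#' @return Logical matrix; rows are canonical gene names in first-seen
#'   order, columns are `species:cluster_id`.
#' @export
shared_gene_matrix <- function(flanks) {
  if (length(flanks) < 2L) stop("need at least two flanking-gene sets")
  canon <- lapply(flanks, function(f) unique(canonical_gene_name(f$genes$name)))
  rows <- unique(unlist(canon))
  cols <- vapply(flanks, function(f)
    paste(f$species, f$cluster_id, sep = ":"), character(1))
  m <- vapply(canon, function(g) rows %in% g, logical(length(rows)))
  m <- matrix(m, nrow = length(rows), dimnames = list(rows, cols))
  m
}

#' Exact-word dot plot of two sequences
#'
#' Reports every exact `word`-length match between `a` and `b`, on the
#' forward strand and (separately flagged) against the reverse complement of
#' `b`.  `dotplot(a, b)` is the transpose of `dotplot(b, a)`.
#'
#' @param a,b Nucleotide strings or length-1 [Biostrings::DNAStringSet].
#' @param word Word length (>= 8).
#' @param step Step between sampled word start positions in `a` and `b`.
#' @return A `dotplot` object: list with `hits` (data.frame `x`, `y`,
#'   `strand`; positions of the word starts in `a` and `b`), `word`, `na`,
#'   `nb`.
#' @export
dotplot <- function(a, b, word = 15L, step = 1L) {
  if (word < 8L) stop("word must be >= 8")
  sa <- as_single_sequence(a)$residues
  sb <- as_single_sequence(b)$residues
  na_ <- nchar(sa); nb_ <- nchar(sb)
  empty <- data.frame(x = integer(0), y = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  if (na_ < word || nb_ < word) {
    return(structure(list(hits = empty, word = word, na = na_, nb = nb_),
                     class = "dotplot"))
  }
  pa <- seq.int(1L, na_ - word + 1L, by = step)
  pb <- seq.int(1L, nb_ - word + 1L, by = step)
  wa <- substring(sa, pa, pa + word - 1L)
  wb <- substring(sb, pb, pb + word - 1L)
  lookup <- split(pb, wb)
  match_channel <- function(words_a, strand) {
    found <- lookup[words_a]
    nhit <- lengths(found)
    if (sum(nhit) == 0L) return(empty)
    data.frame(x = rep(pa, nhit), y = unlist(found, use.names = FALSE),
               strand = strand, stringsAsFactors = FALSE)
  }
  fwd <- match_channel(wa, "+")
  # reverse-complement channel: word of a matched against revcomp(b); report
  # y as the forward-strand start of the matching b word.  The reverse
  # complement of a's word at x is the word of revcomp(a) starting at
  # na - x - word + 2.
  rc_a <- revcomp(sa)
  pr <- na_ - pa - word + 2L
  wa_rc <- substring(rc_a, pr, pr + word - 1L)
  rev_ <- match_channel(wa_rc, "-")
  hits <- rbind(fwd, rev_)
  hits <- hits[order(hits$x, hits$y, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  structure(list(hits = hits, word = word, na = na_, nb = nb_),
            class = "dotplot")
}

#' @export
print.dotplot <- function(x, ...) {
  cat(sprintf("<dotplot> %d x %d nt, word=%d: %d forward, %d reverse hit(s)\n",
              x$na, x$nb, x$word, sum(x$hits$strand == "+"),
              sum(x$hits$strand == "-")))
  invisible(x)
}

#' Windowed identity along two collinear sequences
#'
#' Anchors the two sequences on the dominant forward diagonal of their dot
#' plot, then globally aligns corresponding windows and reports the identity
#' (matches / alignment columns) of each.  A sequence against itself gives
#' identity 1 in every window.
#'
#' @param a,b Nucleotide strings or length-1 [Biostrings::DNAStringSet].
#' @param window Window size (bp).
#' @param word Anchor word length passed to [dotplot()].
#' @return Data.frame with `start`, `end` (window in `a`) and `identity`.
#' @export
windowed_identity <- function(a, b, window = 1000L, word = 15L) {
  sa <- as_single_sequence(a)$residues
  sb <- as_single_sequence(b)$residues
  dp <- dotplot(sa, sb, word = word, step = 1L)
  fw <- dp$hits[dp$hits$strand == "+", , drop = FALSE]
  if (nrow(fw) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      identity = numeric(0)))
  }
  diag_ <- fw$x - fw$y
  offset <- as.integer(names(sort(table(diag_), decreasing = TRUE))[1L])
  nmat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = 0,
                                                   baseOnly = FALSE)
  starts <- seq.int(1L, nchar(sa), by = window)
  out <- lapply(starts, function(s) {
    e <- min(nchar(sa), s + window - 1L)
    bs <- s - offset; be <- e - offset
    if (be < 1L || bs > nchar(sb)) return(NULL)
    bs <- max(1L, bs); be <- min(nchar(sb), be)
    if (e - s + 1L < 0.5 * window || be - bs + 1L < 0.5 * window) return(NULL)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(substr(sa, s, e)),
      Biostrings::DNAString(substr(sb, bs, be)),
      type = "global", substitutionMatrix = nmat,
      gapOpening = 4, gapExtension = 1)
    ncol_aln <- nchar(as.character(Biostrings::pattern(al)))
    data.frame(start = s, end = e,
               identity = Biostrings::nmatch(al) / ncol_aln)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               identity = numeric(0)) else out
}
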