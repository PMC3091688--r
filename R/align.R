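#' Optimal local alignment of two residue strings
#'
#' Smith-Waterman local alignment with affine gap penalties (engine:
#' [Biostrings::pairwiseAlignment]).  Peptides are scored with BLOSUM62 and
#' gap open 11 / extend 1 by default; nucleotide alignments use a simple
#' match/mismatch matrix.  A gap of length k costs `gap_open + k *
#' gap_extension`.
#'
#' @param a,b Residue strings (pattern, subject); must be non-empty.
#' @param alphabet `"aa"` or `"dna"`.
#' @param gap_open,gap_extension Affine gap penalties (positive costs).
#' @param match,mismatch Nucleotide scores (ignored for `alphabet = "aa"`).
#' @return List with `score`, the aligned interval pair (`a_start`, `a_end`,
#'   `b_start`, `b_end`, 1-based inclusive), `identity` (matches / aligned
#'   columns, in `[0,1]`) and `n_match`.
#' @export
local_align <- function(a, b, alphabet = c("aa", "dna"),
                        gap_open = 11, gap_extension = 1,
                        match = 2, mismatch = -3) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(a) || !nzchar(b)) stop("empty input to local_align")
  if (alphabet == "aa") {
    mat <- blosum62_matrix()
    pa <- Biostrings::AAString(a)
    pb <- Biostrings::AAString(b)
  } else {
    mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                    mismatch = mismatch,
                                                    baseOnly = FALSE)
    pa <- Biostrings::DNAString(a)
    pb <- Biostrings::DNAString(b)
  }
  al <- Biostrings::pairwiseAlignment(pa, pb, type = "local",
                                      substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extension)
  sc <- Biostrings::score(al)
  if (sc <= 0) {
    return(list(score = 0, a_start = NA_integer_, a_end = NA_integer_,
                b_start = NA_integer_, b_end = NA_integer_,
                identity = 0, n_match = 0L))
  }
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  ncol_aln <- nchar(as.character(pat))
  list(score = sc,
       a_start = Biostrings::start(pat), a_end = Biostrings::end(pat),
       b_start = Biostrings::start(sub), b_end = Biostrings::end(sub),
       identity = Biostrings::nmatch(al) / ncol_aln,
       n_match = Biostrings::nmatch(al))
}

# BLOSUM62 from Biostrings' data set, loaded once per session.
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})
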