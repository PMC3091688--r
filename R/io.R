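#' Read genomic sequence from a FASTA file
#'
#' Residues are uppercased and RNA-style `U` is mapped to `T`.  `N` is a
#' legal residue (assembly gaps); any other character aborts with the
#' offending record and offset.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one entry per record, named by
#'   the first whitespace-delimited token of each header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- Biostrings::readBStringSet(path)
  if (length(raw) == 0L) stop("no records in FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(raw))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) stop("duplicate id in FASTA file: ", dup[1L])
  res <- toupper(as.character(raw))
  res <- gsub("U", "T", res, fixed = TRUE)
  bad <- regexpr("[^ACGTN]", res)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("alphabet violation in record '%s' at position %d (character '%s')",
                 ids[i], bad[i], substr(res[i], bad[i], bad[i])))
  }
  out <- Biostrings::DNAStringSet(res)
  names(out) <- ids
  out
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector or [Biostrings::DNAStringSet].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  Biostrings::writeXStringSet(seqs, filepath = path, width = width)
  invisible(path)
}

GFF3_FEATURE_RANK <- c(gene = 1L, pseudogene = 1L, exon = 2L, CDS = 3L)

#' Write annotation records as GFF3
#'
#' Records are written as 9-column GFF3 with 1-based inclusive coordinates,
#' ordered deterministically by (seq_id, start, feature rank).  Parent/child
#' links are carried in the `ID`/`Parent` attributes.
#'
#' @param records A data.frame with columns `seq_id`, `feature_type` (one of
#'   gene, pseudogene, exon, CDS), `start`, `end`, `strand` (`+`/`-`), `ID`,
#'   and optionally `Parent` plus further attribute columns (e.g. `Name`,
#'   `subunit`, `status`, `bohr_status`, `defects`).
#' @param path Output path.
#' @param seq_lengths Optional named integer vector of sequence lengths used
#'   to validate coordinates.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path, seq_lengths = NULL) {
  header <- "##gff-version 3"
  if (is.null(records) || nrow(records) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  needed <- c("seq_id", "feature_type", "start", "end", "strand", "ID")
  miss <- setdiff(needed, names(records))
  if (length(miss) > 0L) stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(!(records$start >= 1L & records$start <= records$end))
  if (length(bad) > 0L)
    stop("coordinate invariant violated for record ID=", records$ID[bad[1L]])
  if (!is.null(seq_lengths)) {
    lim <- seq_lengths[records$seq_id]
    over <- which(!is.na(lim) & records$end > lim)
    if (length(over) > 0L)
      stop("record ID=", records$ID[over[1L]], " extends past end of ",
           records$seq_id[over[1L]])
  }
  if (!all(records$feature_type %in% names(GFF3_FEATURE_RANK)))
    stop("unsupported feature_type")
  ord <- order(records$seq_id, records$start,
               GFF3_FEATURE_RANK[records$feature_type], records$end)
  records <- records[ord, , drop = FALSE]
  attr_cols <- setdiff(names(records),
                       c("seq_id", "feature_type", "start", "end", "strand"))
  enc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    gsub(",", "%2C", x, fixed = TRUE)
  }
  attrs <- vapply(seq_len(nrow(records)), function(i) {
    kv <- vapply(attr_cols, function(k) {
      v <- records[[k]][i]
      if (is.na(v) || !nzchar(as.character(v))) return(NA_character_)
      paste0(k, "=", enc(as.character(v)))
    }, character(1))
    paste(kv[!is.na(kv)], collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   records$seq_id, "globinscan", records$feature_type,
                   as.integer(records$start), as.integer(records$end),
                   records$strand, attrs)
  writeLines(c(header, lines), path)
  invisible(path)
}

TRUTH_COLUMNS <- c("seq_id", "name", "subunit", "status", "bohr_status",
                   "strand", "exon1_start", "exon1_end", "exon2_start",
                   "exon2_end", "exon3_start", "exon3_end", "defects")

#' Write a synthetic-cluster truth table
#'
#' Tab-separated ground-truth companion to a generated cluster; one row per
#' planted gene.  Missing exons are encoded as `NA` intervals and planted
#' defect labels are comma-joined in `defects` (empty for functional genes).
#'
#' @param truth Truth data.frame as returned by [generate_cluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  miss <- setdiff(TRUTH_COLUMNS, names(truth))
  if (length(miss) > 0L) stop("missing truth column(s): ", paste(miss, collapse = ", "))
  utils::write.table(truth[, TRUTH_COLUMNS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a synthetic-cluster truth table
#'
#' @param path Path to a TSV written by [write_truth_table()].
#' @return Truth data.frame with the planted gene records.
#' @export
read_truth_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  miss <- setdiff(TRUTH_COLUMNS, names(x))
  if (length(miss) > 0L)
    stop("truth table parse error: missing mandatory column '", miss[1L], "'")
  for (k in grep("^exon", TRUTH_COLUMNS, value = TRUE))
    x[[k]] <- suppressWarnings(as.integer(x[[k]]))
  x$defects[is.na(x$defects)] <- ""
  x[, TRUTH_COLUMNS]
}

#' Extract sequences from a GenBank flat file
#'
#' Minimal offline reader for deposited assembly records: pulls the LOCUS
#' name and ORIGIN sequence block of each entry and returns plain sequence.
#' Feature tables are deliberately ignored; annotation is re-derived by the
#' pipeline.
#'
#' @param path Path to a GenBank flat file (possibly multi-record).
#' @return A [Biostrings::DNAStringSet] named by LOCUS.
#' @export
read_genbank_seq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  loci <- grep("^LOCUS", lines)
  if (length(loci) == 0L) stop("no LOCUS records in GenBank file: ", path)
  ends <- c(loci[-1L] - 1L, length(lines))
  seqs <- character(0)
  for (i in seq_along(loci)) {
    block <- lines[loci[i]:ends[i]]
    id <- strsplit(trimws(block[1L]), "\\s+")[[1L]][2L]
    o <- grep("^ORIGIN", block)
    if (length(o) == 0L) stop("record '", id, "' has no ORIGIN block")
    body <- block[(o[1L] + 1L):length(block)]
    body <- body[!grepl("^//", body)]
    s <- toupper(gsub("[^A-Za-z]", "", paste(body, collapse = "")))
    s <- gsub("U", "T", s, fixed = TRUE)
    s <- gsub("[^ACGTN]", "N", s)
    if (!nzchar(s)) stop("record '", id, "' has an empty ORIGIN block")
    seqs[id] <- s
  }
  Biostrings::DNAStringSet(seqs)
}
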