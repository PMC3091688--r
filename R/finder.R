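# Candidate globin gene discovery: translated exon search (seed-and-extend
# at the peptide level), splice-aware chaining into gene models, and
# nucleotide-level boundary refinement.

fwd_to_tx <- function(s, e, strand, L) {
  if (strand == "+") c(s, e) else c(L - e + 1L, L - s + 1L)
}
tx_to_fwd <- fwd_to_tx  # the mapping is an involution

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Find candidate globin exon hits in a genomic sequence
#'
#' Scans both strands by seeding exact peptide k-mers of each exon template
#' against the six-frame translation, then extends each seeded locus with a
#' Smith-Waterman peptide alignment (BLOSUM62, gap open 11 / extend 1).  A
#' locus is reported when its alignment identity reaches `min_identity` and
#' its score reaches `score_frac` times the template self-score.
#' Overlapping hits of the same subunit and exon index keep only the
#' best-scoring template variant.
#'
#' @param seq A single named sequence: length-1 [Biostrings::DNAStringSet],
#'   or a plain string together with `seq_id`.
#' @param ref A `globin_reference`.
#' @param min_identity Minimum alignment identity (fraction).
#' @param score_frac Minimum score as a fraction of the template self-score.
#' @param seq_id Sequence name when `seq` is a bare string.
#' @param kmer Peptide seed length.
#' @return Data.frame of hits sorted by (seq_id, start): `seq_id`, `start`,
#'   `end` (forward-strand 1-based inclusive), `strand`, `subunit`,
#'   `variant`, `exon_index`, `score`, `identity`.
#' @export
find_exon_hits <- function(seq, ref, min_identity = 0.5, score_frac = 0.3,
                           seq_id = NULL, kmer = 5L) {
  sq <- as_single_sequence(seq, seq_id)
  L <- nchar(sq$residues)
  tpl <- ref$templates
  self_scores <- vapply(seq_len(nrow(tpl)), function(i) {
    local_align(tpl$peptide[i], tpl$peptide[i])$score
  }, numeric(1))
  hits <- list()
  for (strand in c("+", "-")) {
    dna <- if (strand == "+") sq$residues else revcomp(sq$residues)
    # frame translations and per-frame k-mer position index
    frames <- lapply(0:2, function(f) translate_cds(dna, phase = f))
    index <- lapply(frames, function(p) {
      np <- nchar(p) - kmer + 1L
      if (np < 1L) return(list())
      kms <- substring(p, seq_len(np), seq_len(np) + kmer - 1L)
      split(seq_len(np), kms)
    })
    for (ti in seq_len(nrow(tpl))) {
      tpep <- tpl$peptide[ti]
      lt_aa <- nchar(tpep)
      lt_nt <- nchar(tpl$cds[ti])
      if (lt_aa < kmer) next
      tk <- substring(tpep, seq_len(lt_aa - kmer + 1L),
                      seq_len(lt_aa - kmer + 1L) + kmer - 1L)
      g0 <- integer(0)  # implied genomic (transcription-strand) start of template
      for (f in 0:2) {
        pos_by_kmer <- index[[f + 1L]][tk]
        for (j in seq_along(tk)) {
          pv <- pos_by_kmer[[j]]
          if (is.null(pv)) next
          g0 <- c(g0, f + (pv - 1L) * 3L + 1L - (j - 1L) * 3L)
        }
      }
      if (length(g0) == 0L) next
      g0 <- sort(g0)
      grp <- cumsum(c(TRUE, diff(g0) > 45L))
      for (cl in split(g0, grp)) {
        center <- as.integer(round(stats::median(cl)))
        ws <- center - 18L                   # 18 is a multiple of 3: same frame
        if (ws < 1L) ws <- ((center - 1L) %% 3L) + 1L  # clamp, same frame
        we <- min(L, ws + lt_nt + 36L - 1L)
        if (we - ws + 1L < 3L * kmer) next
        wpep <- translate_cds(substr(dna, ws, we))
        if (!nzchar(wpep)) next
        al <- local_align(tpep, wpep)
        if (al$score < score_frac * self_scores[ti]) next
        if (al$identity < min_identity) next
        bs <- ws + (al$b_start - 1L) * 3L - (al$a_start - 1L) * 3L
        be <- ws + al$b_end * 3L - 1L + (lt_aa - al$a_end) * 3L
        if (tpl$exon_index[ti] == 3L) be <- be + 3L  # terminal stop codon
        bs <- max(1L, bs); be <- min(L, be)
        f1 <- tx_to_fwd(bs, be, strand, L)
        hits[[length(hits) + 1L]] <- data.frame(
          seq_id = sq$id, start = f1[1L], end = f1[2L], strand = strand,
          subunit = tpl$subunit[ti], variant = tpl$variant[ti],
          exon_index = tpl$exon_index[ti], score = al$score,
          identity = al$identity, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(seq_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      subunit = character(0), variant = character(0),
                      exon_index = integer(0), score = numeric(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, hits)
  h <- dedupe_hits(h)
  h <- h[order(h$seq_id, h$start, h$strand, h$exon_index), , drop = FALSE]
  rownames(h) <- NULL
  h
}

# Keep the best-scoring variant among overlapping hits of the same subunit,
# exon index and strand (ties: leftmost, then '+' strand, then variant name).
dedupe_hits <- function(h) {
  ord <- order(-h$score, h$start, h$strand, h$variant)
  h <- h[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    if (i == nrow(h)) break
    for (j in (i + 1L):nrow(h)) {
      if (!keep[j]) next
      same <- h$subunit[j] == h$subunit[i] && h$exon_index[j] == h$exon_index[i] &&
        h$strand[j] == h$strand[i] && h$seq_id[j] == h$seq_id[i]
      if (same && h$start[j] <= h$end[i] && h$end[j] >= h$start[i]) keep[j] <- FALSE
    }
  }
  h[keep, , drop = FALSE]
}

as_single_sequence <- function(seq, seq_id = NULL) {
  if (inherits(seq, "DNAStringSet")) {
    stopifnot(length(seq) == 1L)
    return(list(id = names(seq)[1L], residues = as.character(seq[[1L]])))
  }
  if (inherits(seq, "DNAString")) {
    return(list(id = if (is.null(seq_id)) "seq" else seq_id,
                residues = as.character(seq)))
  }
  stopifnot(is.character(seq), length(seq) == 1L)
  id <- if (!is.null(seq_id)) seq_id else if (!is.null(names(seq))) names(seq) else "seq"
  list(id = id, residues = toupper(unname(seq)))
}

#' Chain exon hits into candidate gene models
#'
#' Builds maximal-scoring compatible chains: same strand and subunit, exon
#' indices strictly increasing in transcription order, and gap lengths
#' between consecutive exons within intron bounds (a skipped exon admits up
#' to two introns plus the missing exon's length).  Hits are assigned
#' greedily to chains by descending chain score; each hit joins at most one
#' model, and leftover hits overlapping an assigned model are dropped rather
#' than seeding spurious models.  Complete chains (exons 1-2-3) become gene
#' candidates; partial chains become candidates with `missing_exon` defects.
#'
#' @param hits Hit table from [find_exon_hits()] (one sequence).
#' @param seq_length Length of the sequence the hits came from.
#' @param intron_min,intron_max Intron length bounds (bp).
#' @param skip_slack Extra gap slack (bp) allowed when an exon is skipped.
#' @param gap_penalty Chain score penalty per kb of intron gap; a weak
#'   length prior that makes compact (single-gene) chains outscore chains
#'   stretching across neighbouring genes without ever disqualifying a long
#'   intron outright.
#' @return List of unrefined `gene_model` objects sorted by forward start.
#' @export
chain_hits <- function(hits, seq_length, intron_min = 40L, intron_max = 10000L,
                       skip_slack = 400L, gap_penalty = 10) {
  if (nrow(hits) == 0L) return(list())
  if (length(unique(hits$seq_id)) > 1L) stop("hits from multiple sequences")
  L <- as.integer(seq_length)
  h <- hits
  tx <- t(vapply(seq_len(nrow(h)), function(i)
    fwd_to_tx(h$start[i], h$end[i], h$strand[i], L), numeric(2)))
  h$ts <- as.integer(tx[, 1L]); h$te <- as.integer(tx[, 2L])
  h$used <- FALSE
  compatible <- function(i, j) {  # i strictly upstream of j in transcription
    if (h$strand[i] != h$strand[j] || h$subunit[i] != h$subunit[j]) return(FALSE)
    if (h$exon_index[j] <= h$exon_index[i]) return(FALSE)
    gap <- h$ts[j] - h$te[i] - 1L
    nskip <- h$exon_index[j] - h$exon_index[i]
    gap >= intron_min && gap <= nskip * intron_max + (nskip - 1L) * skip_slack
  }
  best_chain <- function(avail) {
    idx <- which(avail)
    if (length(idx) == 0L) return(NULL)
    idx <- idx[order(h$ts[idx])]
    n <- length(idx)
    sc <- h$score[idx]; prev <- rep(0L, n)
    for (jj in seq_len(n)) {
      for (ii in seq_len(max(0L, jj - 1L))) {
        if (!compatible(idx[ii], idx[jj])) next
        gap <- h$ts[idx[jj]] - h$te[idx[ii]] - 1L
        cand <- h$score[idx[jj]] + sc[ii] - gap_penalty * gap / 1000
        if (cand > sc[jj]) {
          sc[jj] <- cand
          prev[jj] <- ii
        }
      }
    }
    jbest <- which.max(sc)
    chain <- integer(0); jj <- jbest
    while (jj != 0L) { chain <- c(idx[jj], chain); jj <- prev[jj] }
    list(members = chain, score = sc[jbest])
  }
  models <- list()
  avail <- rep(TRUE, nrow(h))
  while (any(avail)) {
    bc <- best_chain(avail)
    if (is.null(bc)) break
    mem <- bc$members
    avail[mem] <- FALSE
    span <- range(c(h$start[mem], h$end[mem]))
    # drop leftover same-subunit hits overlapping the claimed span
    ol <- avail & h$subunit == h$subunit[mem[1L]] &
      h$start <= span[2L] & h$end >= span[1L]
    avail[ol] <- FALSE
    mem <- mem[order(h$ts[mem])]
    exons <- data.frame(exon_index = h$exon_index[mem],
                        start = h$start[mem], end = h$end[mem])
    variant <- h$variant[mem[which.max(h$score[mem])]]
    missing <- setdiff(1:3, exons$exon_index)
    models[[length(models) + 1L]] <- structure(list(
      seq_id = h$seq_id[mem[1L]], strand = h$strand[mem[1L]],
      subunit = h$subunit[mem[1L]], variant = variant,
      exons = exons, score = bc$score,
      defects = if (length(missing)) paste0("missing_exon_", missing) else character(0),
      refined = FALSE), class = "gene_model")
  }
  models[order(vapply(models, function(m) min(m$exons$start), numeric(1)))]
}

#' Refine a chained gene model against the genomic sequence
#'
#' Re-aligns each exon's template CDS to the genomic neighbourhood
#' (nucleotide global-local alignment) to fix exon boundaries, then adjusts
#' boundaries within a +/-`refine_window` nt search to place the canonical
#' GT donor / AG acceptor dinucleotides and the start/stop codons wherever
#' doing so does not reduce the identity of the spliced CDS to the template.
#' Splice status, start/stop presence and the defect list (`bad_splice_*`,
#' `no_start`, `no_stop`, `frameshift`, `internal_stop`, `length_violation`,
#' `missing_exon_*`) are recomputed.
#'
#' @param model Unrefined `gene_model` from [chain_hits()].
#' @param seq The genomic sequence the model lives on (same forms as
#'   [find_exon_hits()]).
#' @param ref A `globin_reference`.
#' @param refine_window Boundary search half-width (nt).
#' @return The refined `gene_model`, with `cds`, `protein`, `splice_ok`,
#'   `has_start`, `has_stop`, `introns` and `defects` populated.
#' @export
refine_model <- function(model, seq, ref, refine_window = 12L) {
  sq <- as_single_sequence(seq)
  L <- nchar(sq$residues)
  tdna <- if (model$strand == "+") sq$residues else revcomp(sq$residues)
  tpl <- ref$templates[ref$templates$variant == model$variant, , drop = FALSE]
  cfg <- ref$config
  ex <- model$exons
  ex <- ex[order(ex$exon_index), , drop = FALSE]
  # to transcription coordinates
  txi <- t(vapply(seq_len(nrow(ex)), function(i)
    fwd_to_tx(ex$start[i], ex$end[i], model$strand, L), numeric(2)))
  ex$ts <- as.integer(txi[, 1L]); ex$te <- as.integer(txi[, 2L])
  ex <- ex[order(ex$ts), , drop = FALSE]
  pad <- refine_window + 8L
  nmat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                   baseOnly = FALSE)
  for (i in seq_len(nrow(ex))) {
    tcds <- tpl$cds[tpl$exon_index == ex$exon_index[i]]
    ws <- max(1L, ex$ts[i] - pad); we <- min(L, ex$te[i] + pad)
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(tcds),
      Biostrings::DNAString(substr(tdna, ws, we)),
      type = "global-local", substitutionMatrix = nmat,
      gapOpening = 5, gapExtension = 2)
    ex$ts[i] <- ws + Biostrings::start(Biostrings::subject(al)) - 1L
    ex$te[i] <- ws + Biostrings::end(Biostrings::subject(al)) - 1L
  }
  tmpl_cds_all <- paste(tpl$cds[order(tpl$exon_index)][ex$exon_index], collapse = "")
  spliced <- function(ts, te) {
    paste(substring(tdna, ts, te), collapse = "")
  }
  # positionwise identity of the spliced CDS to the template CDS; boundary
  # errors desynchronise downstream codons, so this is a sharp criterion
  cds_identity <- function(ts, te) {
    s <- spliced(ts, te)
    n <- min(nchar(s), nchar(tmpl_cds_all))
    if (n == 0L) return(0)
    a <- strsplit(substr(s, 1L, n), "")[[1L]]
    b <- strsplit(substr(tmpl_cds_all, 1L, n), "")[[1L]]
    sum(a == b) / max(nchar(s), nchar(tmpl_cds_all))
  }
  w <- as.integer(refine_window)
  adjust_boundary <- function(which_exon, side, want, step = 1L, deltas = -w:w) {
    # try shifting one exon boundary so that `want` (a predicate on the
    # resulting boundary) holds, keeping the shift only if it does not
    # reduce spliced identity
    base_id <- cds_identity(ex$ts, ex$te)
    if (want(ex$ts, ex$te, which_exon)) return(TRUE)
    best <- NULL; best_id <- base_id
    for (d in deltas[order(abs(deltas), deltas)]) {
      if (d == 0L) next
      ts2 <- ex$ts; te2 <- ex$te
      if (side == "end") te2[which_exon] <- te2[which_exon] + d * step
      else ts2[which_exon] <- ts2[which_exon] + d * step
      if (ts2[which_exon] < 1L || te2[which_exon] > L ||
          ts2[which_exon] > te2[which_exon]) next
      if (which_exon > 1L && ts2[which_exon] <= te2[which_exon - 1L]) next
      if (which_exon < nrow(ex) && te2[which_exon] >= ts2[which_exon + 1L]) next
      if (!want(ts2, te2, which_exon)) next
      id2 <- cds_identity(ts2, te2)
      if (id2 >= best_id - 1e-12 && (is.null(best) || id2 > best_id)) {
        best <- list(ts = ts2, te = te2); best_id <- id2
      }
    }
    if (!is.null(best) && best_id >= base_id - 1e-12) {
      ex$ts <<- best$ts; ex$te <<- best$te
      return(TRUE)
    }
    FALSE
  }
  donor_ok <- function(ts, te, i) {
    te[i] + 2L <= L && substr(tdna, te[i] + 1L, te[i] + 2L) == cfg$donor_dinucleotide
  }
  acceptor_ok <- function(ts, te, i) {
    ts[i] - 2L >= 1L && substr(tdna, ts[i] - 2L, ts[i] - 1L) == cfg$acceptor_dinucleotide
  }
  start_ok <- function(ts, te, i) {
    substr(tdna, ts[i], ts[i] + 2L) == "ATG"
  }
  stop_ok <- function(ts, te, i) {
    substr(tdna, te[i] - 2L, te[i]) %in% STOP_CODONS
  }
  n_ex <- nrow(ex)
  splice_ok <- logical(0)
  defects <- grep("^missing_exon", model$defects, value = TRUE)
  if (n_ex > 1L) {
    for (i in seq_len(n_ex - 1L)) {
      d_ok <- adjust_boundary(i, "end", donor_ok)
      a_ok <- adjust_boundary(i + 1L, "start", acceptor_ok)
      splice_ok <- c(splice_ok, donor = d_ok, acceptor = a_ok)
      if (!d_ok) defects <- c(defects, "bad_splice_donor")
      if (!a_ok) defects <- c(defects, "bad_splice_acceptor")
    }
  }
  has_start <- FALSE; has_stop <- FALSE
  if (1L %in% ex$exon_index) {
    i1 <- which(ex$exon_index == 1L)
    has_start <- adjust_boundary(i1, "start", start_ok, step = 3L, deltas = -2:2)
    if (!has_start) defects <- c(defects, "no_start")
  }
  if (3L %in% ex$exon_index) {
    i3 <- which(ex$exon_index == 3L)
    has_stop <- adjust_boundary(i3, "end", stop_ok, step = 3L, deltas = -2:2)
    if (!has_stop) defects <- c(defects, "no_stop")
  }
  # structural defects from refined intervals
  slack <- cfg$exon_size_slack
  for (i in seq_len(n_ex)) {
    tlen <- nchar(tpl$cds[tpl$exon_index == ex$exon_index[i]])
    obs <- ex$te[i] - ex$ts[i] + 1L
    diff <- obs - tlen
    if (diff %% 3L != 0L) {
      defects <- c(defects, "frameshift")
    } else if (abs(diff) / 3L > slack) {
      defects <- c(defects, "length_violation")
    }
  }
  cds <- spliced(ex$ts, ex$te)
  protein <- translate_cds(cds)
  body <- substr(protein, 1L, max(0L, nchar(protein) - 1L))
  if (grepl("*", body, fixed = TRUE)) defects <- c(defects, "internal_stop")
  introns <- if (n_ex > 1L) {
    data.frame(start = ex$te[-n_ex] + 1L, end = ex$ts[-1L] - 1L)
  } else data.frame(start = integer(0), end = integer(0))
  # back to forward coordinates
  fwd <- t(vapply(seq_len(n_ex), function(i)
    tx_to_fwd(ex$ts[i], ex$te[i], model$strand, L), numeric(2)))
  model$exons <- data.frame(exon_index = ex$exon_index,
                            start = as.integer(pmin(fwd[, 1L], fwd[, 2L])),
                            end = as.integer(pmax(fwd[, 1L], fwd[, 2L])))
  if (nrow(introns) > 0L) {
    fin <- t(vapply(seq_len(nrow(introns)), function(i)
      tx_to_fwd(introns$start[i], introns$end[i], model$strand, L), numeric(2)))
    introns <- data.frame(start = as.integer(pmin(fin[, 1L], fin[, 2L])),
                          end = as.integer(pmax(fin[, 1L], fin[, 2L])))
  }
  model$introns <- introns
  model$cds <- cds
  model$protein <- protein
  model$splice_ok <- splice_ok
  model$has_start <- has_start
  model$has_stop <- has_stop
  model$defects <- unique(defects)
  model$refined <- TRUE
  model
}

#' Find, chain and refine globin gene models in one call
#'
#' @inheritParams find_exon_hits
#' @inheritParams chain_hits
#' @inheritParams refine_model
#' @return List of refined `gene_model` objects.
#' @export
find_genes <- function(seq, ref, min_identity = 0.5, score_frac = 0.3,
                       intron_min = 40L, intron_max = 10000L,
                       refine_window = 12L, seq_id = NULL) {
  sq <- as_single_sequence(seq, seq_id)
  hits <- find_exon_hits(sq$residues, ref, min_identity = min_identity,
                         score_frac = score_frac, seq_id = sq$id)
  models <- chain_hits(hits, nchar(sq$residues), intron_min = intron_min,
                       intron_max = intron_max)
  lapply(models, refine_model, seq = sq$residues, ref = ref,
         refine_window = refine_window)
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s [%s] exons=%d span=%d-%d defects=%s\n",
              x$seq_id, x$subunit, x$strand, nrow(x$exons),
              min(x$exons$start), max(x$exons$end),
              if (length(x$defects)) paste(x$defects, collapse = ",") else "none"))
  invisible(x)
}
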