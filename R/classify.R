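# Rule-based classification: putatively functional vs pseudogene, and
# Bohr vs non-Bohr beta hemoglobin hallmark detection.

#' Strip a terminal stop from a protein string
#' @param protein Amino-acid string (may end in `*`).
#' @return The protein without its terminal stop symbol.
#' @keywords internal
strip_stop <- function(protein) sub("\\*$", "", protein)

#' Classify a gene model as putatively functional or pseudogene
#'
#' Applies the three functionality criteria: (1) the model has exactly three
#' exons and two introns; (2) the exons are of appropriate sizes — canonical
#' GT/AG splice junctions, start and stop codons present in place, each exon
#' peptide within its template length tolerance, no internal stops or
#' frameshifts; (3) the predicted protein is 143 residues for an alpha chain
#' or 147/148 for a beta chain.  Any failure makes the gene a pseudogene,
#' with `failed_criteria` and the model's defect labels preserved for audit.
#'
#' @param model A refined `gene_model` (see [refine_model()]).
#' @param cfg A `classifier_config`.
#' @return A `classified_gene`: list with `model`, `status`
#'   (functional/pseudogene), `failed_criteria`, `bohr_status` (set by
#'   [classify_bohr()]), `hallmarks_met`, `name`.
#' @export
classify_functionality <- function(model, cfg = classifier_config()) {
  if (!isTRUE(model$refined)) stop("refine first: model has not been refined")
  failed <- character(0)
  n_ex <- nrow(model$exons)
  if (n_ex != cfg$required_exon_count) failed <- c(failed, "exon_count")
  structural <- c("bad_splice_donor", "bad_splice_acceptor", "no_start",
                  "no_stop", "internal_stop", "frameshift", "length_violation")
  if (any(model$defects %in% structural) ||
      (length(model$splice_ok) > 0L && !all(model$splice_ok)) ||
      !isTRUE(model$has_start) || !isTRUE(model$has_stop))
    failed <- c(failed, "splice_and_termini")
  plen <- nchar(strip_stop(model$protein))
  len_ok <- if (model$subunit == "alpha") plen == cfg$alpha_protein_length
            else plen %in% cfg$beta_protein_lengths
  if (!len_ok) failed <- c(failed, "protein_length")
  status <- if (length(failed) == 0L && length(model$defects) == 0L)
    "functional" else "pseudogene"
  if (status == "pseudogene" && length(failed) == 0L) {
    # defects present but no criterion tripped cannot happen by construction;
    # guard against future defect labels
    failed <- "splice_and_termini"
  }
  structure(list(model = model, status = status, failed_criteria = failed,
                 bohr_status = "not_applicable",
                 hallmarks_met = character(0), name = NA_character_),
            class = "classified_gene")
}

#' Diagnose the Bohr status of a classified beta hemoglobin gene
#'
#' A putatively functional beta gene is a non-Bohr hemoglobin iff all three
#' hallmarks hold: chain length 147 residues (counting the initiator
#' methionine), C-terminal phenylalanine, and alanine at position 93.
#' Alpha genes and pseudogenes are `not_applicable`.
#'
#' @param gene A `classified_gene`.
#' @param cfg A `classifier_config`.
#' @return The gene with `bohr_status` and `hallmarks_met` filled in.
#' @export
classify_bohr <- function(gene, cfg = classifier_config()) {
  if (gene$model$subunit != "beta" || gene$status != "functional") {
    gene$bohr_status <- "not_applicable"
    gene$hallmarks_met <- character(0)
    return(gene)
  }
  p <- strip_stop(gene$model$protein)
  met <- character(0)
  if (nchar(p) == cfg$nonbohr_protein_length) met <- c(met, "length_147")
  if (substr(p, nchar(p), nchar(p)) == cfg$nonbohr_cterm_residue)
    met <- c(met, "cterm_phe")
  pos <- if (cfg$nonbohr_position_includes_met) cfg$nonbohr_position
         else cfg$nonbohr_position + 1L
  if (pos <= nchar(p) && substr(p, pos, pos) == cfg$nonbohr_position_residue)
    met <- c(met, "ala_93")
  gene$hallmarks_met <- met
  gene$bohr_status <- if (length(met) == 3L) "non_bohr" else "bohr"
  gene
}

#' Classify a list of refined gene models
#'
#' Runs [classify_functionality()] then [classify_bohr()] on each model.
#'
#' @param models List of refined `gene_model` objects.
#' @param cfg A `classifier_config`.
#' @return List of `classified_gene` objects.
#' @export
classify_genes <- function(models, cfg = classifier_config()) {
  lapply(models, function(m) classify_bohr(classify_functionality(m, cfg), cfg))
}

CATEGORY_LEVELS <- data.frame(
  subunit = c("alpha", "beta", "beta", "alpha", "beta"),
  status = c("functional", "functional", "functional", "pseudogene", "pseudogene"),
  bohr_status = c("not_applicable", "bohr", "non_bohr", "not_applicable",
                  "not_applicable"),
  stringsAsFactors = FALSE)

#' Summarise classified genes into a count table
#'
#' Counts by (subunit, status, Bohr status), per sequence and in total, in a
#' fixed category order; invariant under permutation of the input.
#'
#' @param genes List of `classified_gene` objects.
#' @return List with `per_sequence` and `total` count data.frames.
#' @export
summarize_counts <- function(genes) {
  if (length(genes) == 0L) {
    tot <- cbind(CATEGORY_LEVELS, n = 0L)
    return(list(per_sequence = cbind(seq_id = character(0),
                                     CATEGORY_LEVELS[0, ], n = integer(0)),
                total = tot))
  }
  df <- data.frame(
    seq_id = vapply(genes, function(g) g$model$seq_id, character(1)),
    subunit = vapply(genes, function(g) g$model$subunit, character(1)),
    status = vapply(genes, function(g) g$status, character(1)),
    bohr_status = vapply(genes, function(g) g$bohr_status, character(1)),
    stringsAsFactors = FALSE)
  count_for <- function(d) {
    n <- vapply(seq_len(nrow(CATEGORY_LEVELS)), function(i) {
      sum(d$subunit == CATEGORY_LEVELS$subunit[i] &
          d$status == CATEGORY_LEVELS$status[i] &
          d$bohr_status == CATEGORY_LEVELS$bohr_status[i])
    }, integer(1))
    cbind(CATEGORY_LEVELS, n = n)
  }
  per_seq <- do.call(rbind, lapply(sort(unique(df$seq_id)), function(s) {
    cbind(seq_id = s, count_for(df[df$seq_id == s, , drop = FALSE]))
  }))
  rownames(per_seq) <- NULL
  list(per_sequence = per_seq, total = count_for(df))
}

#' @export
print.classified_gene <- function(x, ...) {
  cat(sprintf("<classified_gene> %s %s %s %s%s\n",
              ifelse(is.na(x$name), "(unnamed)", x$name), x$model$subunit,
              x$status, x$bohr_status,
              if (length(x$failed_criteria))
                paste0(" failed=", paste(x$failed_criteria, collapse = ","))
              else ""))
  invisible(x)
}
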