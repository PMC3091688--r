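#' Classifier rule constants
#'
#' Central container for every structural rule used to separate putatively
#' functional hemoglobin genes from pseudogenes and to diagnose non-Bohr
#' beta hemoglobins:
#' vertebrate globin genes carry 3 exons and 2 introns; a functional alpha
#' chain translates to 143 amino acids and a functional beta chain to 147 or
#' 148 (counts include the initiator methionine; the terminal stop is never
#' counted); the non-Bohr beta hemoglobin is diagnosed by 147 residues, a
#' C-terminal phenylalanine (replacing the Bohr-effect histidine) and an
#' alanine at position 93; splice junctions must carry the canonical GT
#' donor and AG acceptor dinucleotides.
#'
#' @param required_exon_count,required_intron_count Gene structure rule.
#' @param alpha_protein_length Functional alpha chain length (aa).
#' @param beta_protein_lengths Admissible functional beta chain lengths (aa).
#' @param nonbohr_protein_length Non-Bohr beta hallmark 1: chain length (aa),
#'   counting the initiator methionine.
#' @param nonbohr_cterm_residue Hallmark 2: C-terminal residue (Phe).
#' @param nonbohr_position Hallmark 3 position (1-based).
#' @param nonbohr_position_residue Hallmark 3 residue (Ala).
#' @param nonbohr_position_includes_met Whether `nonbohr_position` counts the
#'   initiator methionine as position 1 (the chain-length hallmark is stated
#'   that way, and the same convention is applied here; switchable because
#'   the numbering convention for position 93 is not stated explicitly).
#' @param donor_dinucleotide,acceptor_dinucleotide Canonical splice
#'   dinucleotides on the transcribed strand.
#' @param exon_size_slack Permitted deviation (residues) of an observed exon
#'   peptide length from its template length before the exon is considered
#'   the wrong size.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(required_exon_count = 3L,
                              required_intron_count = 2L,
                              alpha_protein_length = 143L,
                              beta_protein_lengths = c(147L, 148L),
                              nonbohr_protein_length = 147L,
                              nonbohr_cterm_residue = "F",
                              nonbohr_position = 93L,
                              nonbohr_position_residue = "A",
                              nonbohr_position_includes_met = TRUE,
                              donor_dinucleotide = "GT",
                              acceptor_dinucleotide = "AG",
                              exon_size_slack = 2L) {
  cfg <- list(required_exon_count = as.integer(required_exon_count),
              required_intron_count = as.integer(required_intron_count),
              alpha_protein_length = as.integer(alpha_protein_length),
              beta_protein_lengths = as.integer(beta_protein_lengths),
              nonbohr_protein_length = as.integer(nonbohr_protein_length),
              nonbohr_cterm_residue = nonbohr_cterm_residue,
              nonbohr_position = as.integer(nonbohr_position),
              nonbohr_position_residue = nonbohr_position_residue,
              nonbohr_position_includes_met = isTRUE(nonbohr_position_includes_met),
              donor_dinucleotide = donor_dinucleotide,
              acceptor_dinucleotide = acceptor_dinucleotide,
              exon_size_slack = as.integer(exon_size_slack))
  class(cfg) <- "classifier_config"
  validate_classifier_config(cfg)
  cfg
}

#' Validate classifier rule constants
#'
#' @param cfg A `classifier_config`.
#' @return `cfg`, invisibly; aborts on an invariant violation.
#' @export
validate_classifier_config <- function(cfg) {
  lens <- c(cfg$required_exon_count, cfg$required_intron_count,
            cfg$alpha_protein_length, cfg$beta_protein_lengths,
            cfg$nonbohr_protein_length, cfg$nonbohr_position)
  if (any(lens <= 0L)) stop("config invariant violation: lengths must be positive")
  if (!cfg$nonbohr_protein_length %in% cfg$beta_protein_lengths)
    stop("config invariant violation: nonbohr_protein_length not in beta_protein_lengths")
  if (cfg$nonbohr_position >= cfg$nonbohr_protein_length)
    stop("config invariant violation: nonbohr_position must be < nonbohr_protein_length")
  if (cfg$required_intron_count != cfg$required_exon_count - 1L)
    stop("config invariant violation: intron count must be exon count - 1")
  invisible(cfg)
}

#' Translate a coding sequence under the standard genetic code
#'
#' Stop codons are rendered as `*` and retained (defect detection needs
#' internal stops); codons containing `N` render as `X`; a trailing partial
#' codon is ignored.
#'
#' @param cds Nucleotide string over A/C/G/T/N.
#' @param phase Number of leading nucleotides (0-2) to skip before the first
#'   complete codon.
#' @return Amino-acid string.
#' @export
translate_cds <- function(cds, phase = 0L) {
  stopifnot(length(cds) == 1L, phase %in% 0:2)
  s <- substr(cds, phase + 1L, nchar(cds))
  n <- nchar(s) - nchar(s) %% 3L
  if (n < 3L) return("")
  starts <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(s, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

TEMPLATE_VARIANTS <- c("alpha", "beta_bohr", "beta_nonbohr")

#' Assemble and validate a globin reference
#'
#' @param templates Data.frame with columns `variant` (alpha, beta_bohr,
#'   beta_nonbohr), `subunit`, `exon_index`, `peptide`, `cds`, `phase`.
#'   Exon 3 CDS includes the terminal stop codon; its peptide does not.
#' @param config A `classifier_config`.
#' @return An object of class `globin_reference`.
#' @export
globin_reference <- function(templates, config = classifier_config()) {
  ref <- list(templates = templates, config = config)
  class(ref) <- "globin_reference"
  validate_reference(ref)
  ref
}

#' Validate a globin reference bundle
#'
#' Checks that each template variant has exactly exons 1-3, that CDS lengths
#' are consistent with peptide lengths and phase, and that each exon CDS
#' translates to its stated peptide (exon 3 additionally ends with a stop).
#'
#' @param ref A `globin_reference`.
#' @return `ref`, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_reference <- function(ref) {
  tpl <- ref$templates
  validate_classifier_config(ref$config)
  for (v in unique(tpl$variant)) {
    idx <- sort(tpl$exon_index[tpl$variant == v])
    if (!identical(idx, 1:3))
      stop("incomplete template set for variant '", v, "'")
  }
  for (i in seq_len(nrow(tpl))) {
    tr <- translate_cds(tpl$cds[i], tpl$phase[i])
    want <- if (tpl$exon_index[i] == 3L) paste0(tpl$peptide[i], "*") else tpl$peptide[i]
    if (!identical(tr, want))
      stop("template inconsistency: variant '", tpl$variant[i], "' exon ",
           tpl$exon_index[i], " CDS does not translate to its peptide")
  }
  invisible(ref)
}

#' Load a globin reference bundle from disk
#'
#' A bundle directory holds `exon_peptides.fasta`, `exon_cds.fasta` (records
#' named `<variant>_exon<k>`) and `config.yaml` mirroring the
#' [classifier_config()] fields.
#'
#' @param path Bundle directory.
#' @return A `globin_reference`.
#' @export
load_reference <- function(path) {
  pep_f <- file.path(path, "exon_peptides.fasta")
  cds_f <- file.path(path, "exon_cds.fasta")
  cfg_f <- file.path(path, "config.yaml")
  for (f in c(pep_f, cds_f, cfg_f)) if (!file.exists(f)) stop("missing bundle file: ", f)
  pep <- Biostrings::readBStringSet(pep_f)
  cds <- Biostrings::readBStringSet(cds_f)
  ids <- names(pep)
  if (!setequal(ids, names(cds))) stop("peptide/CDS record names do not match")
  m <- regmatches(ids, regexec("^(.*)_exon([123])$", ids))
  if (any(lengths(m) != 3L)) stop("malformed template record name")
  raw <- yaml::read_yaml(cfg_f)
  cfg <- do.call(classifier_config, raw)
  variant <- vapply(m, `[`, "", 2L)
  templates <- data.frame(
    variant = variant,
    subunit = ifelse(grepl("^alpha", variant), "alpha", "beta"),
    exon_index = as.integer(vapply(m, `[`, "", 3L)),
    peptide = as.character(pep),
    cds = toupper(as.character(cds[ids])),
    phase = 0L,
    stringsAsFactors = FALSE)
  templates <- templates[order(templates$variant, templates$exon_index), ,
                         drop = FALSE]
  rownames(templates) <- NULL
  globin_reference(templates, cfg)
}

#' Write a globin reference bundle to disk
#'
#' @param ref A `globin_reference`.
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  ids <- sprintf("%s_exon%d", ref$templates$variant, ref$templates$exon_index)
  pep <- Biostrings::BStringSet(setNames(ref$templates$peptide, ids))
  cds <- Biostrings::DNAStringSet(setNames(ref$templates$cds, ids))
  Biostrings::writeXStringSet(pep, file.path(path, "exon_peptides.fasta"))
  Biostrings::writeXStringSet(cds, file.path(path, "exon_cds.fasta"))
  cfg <- unclass(ref$config)
  yaml::write_yaml(cfg, file.path(path, "config.yaml"))
  invisible(path)
}

#' Packaged synthetic reference bundle
#'
#' Loads the synthetic exon-template bundle shipped with the package
#' (generated by [make_templates()]; labelled synthetic because it is not
#' derived from published salmon clone sequences).
#'
#' @return A `globin_reference`.
#' @export
default_reference <- function() {
  load_reference(system.file("extdata", "synthetic_reference",
                             package = "globinscan", mustWork = TRUE))
}
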