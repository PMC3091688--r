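# Synthetic globin cluster generator: alternating tail-to-tail alpha/beta
# three-exon genes with canonical GT..AG introns, configurable divergence,
# planted pseudogenization defects and non-Bohr variants, plus exact truth
# tables.  Rule-critical sites (start/stop codons, splice dinucleotides,
# non-Bohr hallmark codons) are shielded from background divergence so the
# planted status of a gene is never silently flipped.

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]
SUPPORTED_DEFECTS <- c("missing_exon", "bad_splice_donor", "bad_splice_acceptor",
                       "internal_stop", "frameshift", "no_start", "no_stop",
                       "length_violation")

# codon split points (aa per exon) for each template variant
EXON_AA_SPLITS <- list(alpha = c(31L, 71L, 41L),
                       beta_bohr = c(31L, 74L, 43L),
                       beta_nonbohr = c(31L, 74L, 42L))

rand_dna <- function(n, gc = 0.5) {
  if (n <= 0L) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

codons_of <- function(cds) {
  n <- nchar(cds) %/% 3L
  substring(cds, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# sample a codon for each residue of a peptide (start residue forced to ATG
# when it opens the chain)
pep_to_codons <- function(pep, force_start = TRUE) {
  code <- Biostrings::GENETIC_CODE
  by_aa <- split(names(code), unname(code))
  aa <- strsplit(pep, "")[[1L]]
  cods <- vapply(aa, function(a) {
    ch <- by_aa[[a]]
    if (length(ch) == 1L) ch else sample(ch, 1L)
  }, character(1), USE.NAMES = FALSE)
  if (force_start && aa[1L] == "M") cods[1L] <- "ATG"
  cods
}

#' Generate an internally consistent synthetic globin reference
#'
#' Builds random but structurally faithful three-exon templates: an alpha
#' chain of 143 residues, a Bohr beta chain of 148 residues ending in
#' histidine, and a non-Bohr beta chain derived from the Bohr chain (one
#' residue shorter at 147, C-terminal phenylalanine, alanine at position 93,
#' plus a few lineage substitutions).  Exon boundaries fall at codon
#' boundaries (phase 0) and the exon-3 CDS carries the terminal stop codon.
#' Deterministic per seed.
#'
#' @param seed Integer seed.
#' @return A `globin_reference`.
#' @export
make_templates <- function(seed = 1L) {
  set.seed(as.integer(seed))
  alpha_pep <- paste0("M", paste(sample(AA20, 142L, replace = TRUE), collapse = ""))
  beta_pep <- paste0("M", paste(sample(AA20, 146L, replace = TRUE), collapse = ""), "H")
  nb <- strsplit(beta_pep, "")[[1L]][-120L]
  nb[93L] <- "A"
  nb[147L] <- "F"
  subs_at <- sample(setdiff(5:140, 93L), 6L)
  nb[subs_at] <- sample(AA20, 6L, replace = TRUE)
  nonbohr_pep <- paste(nb, collapse = "")

  alpha_cod <- pep_to_codons(alpha_pep)
  beta_cod <- pep_to_codons(beta_pep)
  # reuse Bohr codons where the non-Bohr residue is unchanged, so the two
  # beta lineages stay close at the nucleotide level
  nb_aa <- strsplit(nonbohr_pep, "")[[1L]]
  beta_aa <- strsplit(beta_pep, "")[[1L]]
  src <- c(1:119, 121:148)  # Bohr position supplying each non-Bohr position
  nonbohr_cod <- vapply(seq_along(nb_aa), function(i) {
    if (nb_aa[i] == beta_aa[src[i]]) beta_cod[src[i]]
    else pep_to_codons(nb_aa[i], force_start = FALSE)
  }, character(1))

  rows <- list()
  peps <- list(alpha = alpha_pep, beta_bohr = beta_pep, beta_nonbohr = nonbohr_pep)
  cods <- list(alpha = alpha_cod, beta_bohr = beta_cod, beta_nonbohr = nonbohr_cod)
  for (v in TEMPLATE_VARIANTS) {
    split_aa <- EXON_AA_SPLITS[[v]]
    bounds <- cumsum(split_aa)
    starts <- c(1L, bounds[-3L] + 1L)
    for (k in 1:3) {
      pep_k <- substr(peps[[v]], starts[k], bounds[k])
      cds_k <- paste(cods[[v]][starts[k]:bounds[k]], collapse = "")
      if (k == 3L) cds_k <- paste0(cds_k, "TAA")
      rows[[length(rows) + 1L]] <- data.frame(
        variant = v, subunit = ifelse(v == "alpha", "alpha", "beta"),
        exon_index = k, peptide = pep_k, cds = cds_k, phase = 0L,
        stringsAsFactors = FALSE)
    }
  }
  globin_reference(do.call(rbind, rows), classifier_config())
}

# codon-wise substitution at per-base probability p, never creating a stop
# codon from a non-stop codon; shielded codon indices are untouched
mutate_cds <- function(cds, p, shield = integer(0)) {
  if (p <= 0) return(cds)
  codons <- codons_of(cds)
  for (i in setdiff(seq_along(codons), shield)) {
    cd <- strsplit(codons[i], "")[[1L]]
    hit <- which(stats::runif(3L) < p)
    if (length(hit) == 0L) next
    for (k in hit) cd[k] <- sample(setdiff(DNA_BASES, cd[k]), 1L)
    newc <- paste(cd, collapse = "")
    if (!(codons[i] %in% STOP_CODONS)) {
      tries <- 0L
      while (newc %in% STOP_CODONS && tries < 12L) {
        k <- hit[1L]
        cd[k] <- sample(setdiff(DNA_BASES, cd[k]), 1L)
        newc <- paste(cd, collapse = "")
        tries <- tries + 1L
      }
      if (newc %in% STOP_CODONS) newc <- codons[i]
    }
    codons[i] <- newc
  }
  paste(codons, collapse = "")
}

#' Simulation configuration for synthetic clusters
#'
#' Defaults mirror the composition of the chromosome-6 salmon hemoglobin
#' cluster: 6 functional alpha genes, 6 functional beta genes of which 2 are
#' non-Bohr, 2 alpha pseudogenes and 3 beta pseudogenes, alternating
#' beta/alpha along the cluster with alpha transcribed on the negative
#' strand and beta on the positive strand (tail-to-tail).
#'
#' @param seed Integer seed; one global random stream per run.
#' @param n_alpha_functional,n_beta_bohr,n_beta_nonbohr Functional gene
#'   counts.
#' @param pseudogene_plan Data.frame with columns `subunit` and `defect`
#'   (one row per planted pseudogene; defects from the supported
#'   vocabulary: missing_exon, bad_splice_donor, bad_splice_acceptor,
#'   internal_stop, frameshift, no_start, no_stop, length_violation).
#' @param template_divergence Per-site substitution probability applied to
#'   each gene copy (rule-critical sites shielded), in `[0, 0.2]`.
#' @param intron_length_range,intergenic_length_range Length bounds (bp).
#' @param gc_content GC fraction of intron interiors and intergenic spacer.
#' @param strand_model `"canonical"` (alpha `-`, beta `+`) or a character
#'   vector of strands, one per gene in cluster order.
#' @return A `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_alpha_functional = 6L,
                              n_beta_bohr = 4L,
                              n_beta_nonbohr = 2L,
                              pseudogene_plan = data.frame(
                                subunit = c("alpha", "alpha", "beta", "beta", "beta"),
                                defect = c("internal_stop", "missing_exon",
                                           "frameshift", "bad_splice_donor",
                                           "internal_stop"),
                                stringsAsFactors = FALSE),
                              template_divergence = 0.05,
                              intron_length_range = c(150L, 500L),
                              intergenic_length_range = c(2500L, 4500L),
                              gc_content = 0.42,
                              strand_model = "canonical") {
  cfg <- list(seed = as.integer(seed),
              n_alpha_functional = as.integer(n_alpha_functional),
              n_beta_bohr = as.integer(n_beta_bohr),
              n_beta_nonbohr = as.integer(n_beta_nonbohr),
              pseudogene_plan = pseudogene_plan,
              template_divergence = template_divergence,
              intron_length_range = as.integer(intron_length_range),
              intergenic_length_range = as.integer(intergenic_length_range),
              gc_content = gc_content,
              strand_model = strand_model)
  stopifnot(cfg$n_alpha_functional >= 0L, cfg$n_beta_bohr >= 0L,
            cfg$n_beta_nonbohr >= 0L,
            template_divergence >= 0, template_divergence <= 0.2,
            diff(cfg$intron_length_range) >= 0,
            cfg$intron_length_range[1L] >= 10L,
            diff(cfg$intergenic_length_range) >= 0,
            gc_content > 0, gc_content < 1)
  if (nrow(cfg$pseudogene_plan) > 0L) {
    bad <- setdiff(cfg$pseudogene_plan$defect, SUPPORTED_DEFECTS)
    if (length(bad) > 0L)
      stop("unsupported defect(s) in pseudogene_plan: ", paste(bad, collapse = ", "))
    stopifnot(all(cfg$pseudogene_plan$subunit %in% c("alpha", "beta")))
  }
  class(cfg) <- "simulation_config"
  cfg
}

# build one gene construct (pieces in transcription order) with planted
# defect; returns exon strings, intron strings and local exon intervals
build_gene_construct <- function(variant, ref, cfg, defect = NA_character_) {
  tpl <- ref$templates[ref$templates$variant == variant, , drop = FALSE]
  tpl <- tpl[order(tpl$exon_index), , drop = FALSE]
  cds_full <- paste(tpl$cds, collapse = "")
  n_cod <- nchar(cds_full) %/% 3L
  shield <- c(1L, n_cod)                    # start codon, stop codon
  if (tpl$subunit[1L] == "beta") shield <- c(shield, 93L, n_cod - 1L)
  cds_mut <- mutate_cds(cds_full, cfg$template_divergence, shield)
  lens <- nchar(tpl$cds)
  ends <- cumsum(lens)
  exon <- substring(cds_mut, c(1L, ends[-3L] + 1L), ends)
  ilen <- sample(seq.int(cfg$intron_length_range[1L],
                         cfg$intron_length_range[2L]), 2L, replace = TRUE)
  intron <- vapply(ilen, function(n)
    paste0("GT", rand_dna(n - 4L, cfg$gc_content), "AG"), character(1))
  exon_present <- c(TRUE, TRUE, TRUE)
  c2 <- (lens[1L] %/% 3L)                    # codons before exon 2
  n2 <- lens[2L] %/% 3L
  if (!is.na(defect)) {
    switch(defect,
      missing_exon = {
        exon_present[2L] <- FALSE
      },
      bad_splice_donor = {
        substr(intron[1L], 1L, 2L) <- "AT"
      },
      bad_splice_acceptor = {
        n <- nchar(intron[2L])
        substr(intron[2L], n - 1L, n) <- "AA"
      },
      internal_stop = {
        j <- sample(5:(n2 - 5L), 1L)
        substr(exon[2L], 3L * j - 2L, 3L * j) <- "TAA"
      },
      frameshift = {
        j <- sample(6:(n2 - 10L), 1L)
        exon[2L] <- paste0(substr(exon[2L], 1L, 3L * j - 1L),
                           substr(exon[2L], 3L * j + 1L, nchar(exon[2L])))
      },
      no_start = {
        substr(exon[1L], 1L, 3L) <- "ATA"
      },
      no_stop = {
        n <- nchar(exon[3L])
        substr(exon[3L], n - 2L, n) <- "CAA"
      },
      length_violation = {
        j <- sample(6:(n2 - 10L), 1L)
        ins <- paste(sample(setdiff(names(Biostrings::GENETIC_CODE)[
          !Biostrings::GENETIC_CODE %in% "*" &
          !grepl("[^ACGT]", names(Biostrings::GENETIC_CODE))], STOP_CODONS),
          3L, replace = TRUE), collapse = "")
        exon[2L] <- paste0(substr(exon[2L], 1L, 3L * j),
                           ins,
                           substr(exon[2L], 3L * j + 1L, nchar(exon[2L])))
      },
      stop("unsupported defect: ", defect))
  }
  # assemble pieces and local (transcription-orientation) exon intervals
  pieces <- character(0)
  local_iv <- matrix(NA_integer_, nrow = 3L, ncol = 2L)
  pos <- 0L
  add <- function(s) { pieces <<- c(pieces, s); pos <<- pos + nchar(s); invisible(NULL) }
  for (k in 1:3) {
    if (exon_present[k]) {
      local_iv[k, ] <- c(pos + 1L, pos + nchar(exon[k]))
      add(exon[k])
    }
    if (k < 3L) add(intron[k])
  }
  list(seqs = paste(pieces, collapse = ""), local_iv = local_iv,
       exon_present = exon_present,
       cds = paste(exon[exon_present], collapse = ""))
}

#' Generate a synthetic hemoglobin cluster with exact truth
#'
#' Places genes 5'->3' in alternating subunit order (pseudogenes first
#' within each subunit, then Bohr, then non-Bohr beta genes), separated by
#' random intergenic spacer.  Each functional gene is a template copy
#' mutated at `template_divergence` away from rule-critical sites; each
#' pseudogene additionally carries exactly its planted defect.  A soundness
#' self-check re-derives every planted gene's spliced CDS from the emitted
#' sequence before returning.
#'
#' @param cfg A `simulation_config`.
#' @param ref A `globin_reference`, e.g. from [make_templates()].
#' @return List with `seq` (length-1 [Biostrings::DNAStringSet]) and
#'   `truth` (data.frame, one row per planted gene; see
#'   [write_truth_table()] for columns).
#' @export
generate_cluster <- function(cfg = simulation_config(), ref = make_templates(cfg$seed)) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  plan <- cfg$pseudogene_plan
  entry_block <- function(variant, status, defects, n = length(defects)) {
    if (n == 0L) return(NULL)
    data.frame(variant = variant, status = status,
               defect = if (length(defects)) defects else NA_character_,
               stringsAsFactors = FALSE)
  }
  entries <- list(
    alpha = rbind(
      entry_block("alpha", "pseudogene", plan$defect[plan$subunit == "alpha"]),
      entry_block("alpha", "functional", rep(NA_character_, cfg$n_alpha_functional))),
    beta = rbind(
      entry_block("beta_bohr", "pseudogene", plan$defect[plan$subunit == "beta"]),
      entry_block("beta_bohr", "functional", rep(NA_character_, cfg$n_beta_bohr)),
      entry_block("beta_nonbohr", "functional", rep(NA_character_, cfg$n_beta_nonbohr))))
  n_a <- if (is.null(entries$alpha)) 0L else nrow(entries$alpha)
  n_b <- if (is.null(entries$beta)) 0L else nrow(entries$beta)
  first <- if (n_b >= n_a) "beta" else "alpha"
  second <- setdiff(c("alpha", "beta"), first)
  order_sub <- character(0)
  counts <- c(alpha = n_a, beta = n_b)
  taken <- c(alpha = 0L, beta = 0L)
  cur <- first
  while (sum(taken) < n_a + n_b) {
    if (taken[[cur]] < counts[[cur]]) {
      order_sub <- c(order_sub, cur)
      taken[[cur]] <- taken[[cur]] + 1L
    }
    nxt <- setdiff(c("alpha", "beta"), cur)
    cur <- if (taken[[nxt]] < counts[[nxt]]) nxt else cur
  }
  idx <- c(alpha = 0L, beta = 0L)
  gene_rows <- lapply(order_sub, function(su) {
    idx[[su]] <<- idx[[su]] + 1L
    entries[[su]][idx[[su]], , drop = FALSE]
  })
  n_genes <- length(gene_rows)
  strands <- if (identical(cfg$strand_model, "canonical")) {
    ifelse(order_sub == "alpha", "-", "+")
  } else {
    stopifnot(length(cfg$strand_model) == n_genes,
              all(cfg$strand_model %in% c("+", "-")))
    cfg$strand_model
  }
  seq_id <- sprintf("simcluster_seed%d", cfg$seed)
  parts <- character(0)
  offset <- 0L
  truth <- list()
  add_part <- function(s) { parts <<- c(parts, s); offset <<- offset + nchar(s); invisible(NULL) }
  spacer <- function() rand_dna(sample(seq.int(cfg$intergenic_length_range[1L],
                                               cfg$intergenic_length_range[2L]), 1L),
                                cfg$gc_content)
  add_part(spacer())
  for (i in seq_len(n_genes)) {
    row <- gene_rows[[i]]
    g <- build_gene_construct(row$variant, ref, cfg, row$defect)
    Lc <- nchar(g$seqs)
    placed <- if (strands[i] == "+") g$seqs else revcomp(g$seqs)
    iv <- matrix(NA_integer_, 3L, 2L)
    for (k in 1:3) {
      if (!g$exon_present[k]) next
      ls <- g$local_iv[k, 1L]; le <- g$local_iv[k, 2L]
      iv[k, ] <- if (strands[i] == "+") c(offset + ls, offset + le)
                 else c(offset + Lc - le + 1L, offset + Lc - ls + 1L)
    }
    su <- if (row$variant == "alpha") "alpha" else "beta"
    bohr <- if (row$status != "functional") "not_applicable"
            else if (row$variant == "beta_nonbohr") "non_bohr"
            else if (su == "beta") "bohr" else "not_applicable"
    defect_label <- if (is.na(row$defect)) "" else {
      if (row$defect == "missing_exon") "missing_exon_2" else row$defect
    }
    truth[[i]] <- data.frame(
      seq_id = seq_id, name = sprintf("g%02d", i), subunit = su,
      status = row$status, bohr_status = bohr, strand = strands[i],
      exon1_start = iv[1L, 1L], exon1_end = iv[1L, 2L],
      exon2_start = iv[2L, 1L], exon2_end = iv[2L, 2L],
      exon3_start = iv[3L, 1L], exon3_end = iv[3L, 2L],
      defects = defect_label, cds = g$cds, variant = row$variant,
      stringsAsFactors = FALSE)
    add_part(placed)
    add_part(spacer())
  }
  residues <- paste(parts, collapse = "")
  truth <- do.call(rbind, truth)
  if (is.null(truth)) {
    truth <- data.frame(seq_id = character(0), name = character(0),
                        subunit = character(0), status = character(0),
                        bohr_status = character(0), strand = character(0),
                        exon1_start = integer(0), exon1_end = integer(0),
                        exon2_start = integer(0), exon2_end = integer(0),
                        exon3_start = integer(0), exon3_end = integer(0),
                        defects = character(0), cds = character(0),
                        variant = character(0), stringsAsFactors = FALSE)
  }
  check_truth_soundness(residues, truth)
  seqs <- Biostrings::DNAStringSet(setNames(residues, seq_id))
  list(seq = seqs, truth = truth)
}

# re-derive each planted gene's spliced CDS from the emitted sequence and
# compare with the recorded construct; run at generation time
check_truth_soundness <- function(residues, truth) {
  for (i in seq_len(nrow(truth))) {
    iv <- matrix(c(truth$exon1_start[i], truth$exon1_end[i],
                   truth$exon2_start[i], truth$exon2_end[i],
                   truth$exon3_start[i], truth$exon3_end[i]),
                 ncol = 2L, byrow = TRUE)
    present <- which(!is.na(iv[, 1L]))
    present <- present[order(iv[present, 1L])]   # ascending forward order
    segs <- vapply(present, function(k)
      substr(residues, iv[k, 1L], iv[k, 2L]), character(1))
    spliced <- paste(segs, collapse = "")
    if (truth$strand[i] == "-") spliced <- revcomp(spliced)
    if (!identical(spliced, truth$cds[i]))
      stop("soundness self-check failed for planted gene ", truth$name[i])
    if (truth$status[i] == "functional") {
      p <- translate_cds(spliced)
      if (substr(p, 1L, 1L) != "M" || substr(p, nchar(p), nchar(p)) != "*" ||
          grepl("*", substr(p, 1L, nchar(p) - 1L), fixed = TRUE))
        stop("soundness self-check failed: functional gene ", truth$name[i],
             " does not translate cleanly")
    }
  }
  invisible(TRUE)
}

#' Generate a pair of homeologous clusters
#'
#' Generates one cluster, then an independently mutated copy at the stated
#' divergence: functional exons are mutated codon-aware with rule-critical
#' sites shielded, pseudogene exons are left untouched (their planted defect
#' must survive verbatim), and non-coding sequence is substituted per base
#' away from splice dinucleotides.  Gene structure and truth coordinates are
#' identical between the two copies.
#'
#' @param cfg A `simulation_config`.
#' @param divergence Per-site substitution probability for the copy
#'   (`<= 0.2`).
#' @param ref A `globin_reference`.
#' @return List with `seq_a`, `seq_b` (each length-1 DNAStringSet),
#'   `truth_a`, `truth_b`.
#' @export
generate_homeolog_pair <- function(cfg = simulation_config(), divergence = 0.04,
                                   ref = make_templates(cfg$seed)) {
  stopifnot(divergence >= 0, divergence <= 0.2)
  gen <- generate_cluster(cfg, ref)
  residues <- as.character(gen$seq[[1L]])
  truth <- gen$truth
  L <- nchar(residues)
  s <- strsplit(residues, "")[[1L]]
  protect <- logical(L)
  for (i in seq_len(nrow(truth))) {
    iv <- matrix(c(truth$exon1_start[i], truth$exon1_end[i],
                   truth$exon2_start[i], truth$exon2_end[i],
                   truth$exon3_start[i], truth$exon3_end[i]),
                 ncol = 2L, byrow = TRUE)
    present <- which(!is.na(iv[, 1L]))
    for (k in present) protect[iv[k, 1L]:iv[k, 2L]] <- TRUE
    # splice dinucleotides flanking each exon (within the gene span)
    span <- range(iv[present, ], na.rm = TRUE)
    for (k in present) {
      lo <- iv[k, 1L]; hi <- iv[k, 2L]
      for (pp in c(lo - 2L, lo - 1L, hi + 1L, hi + 2L))
        if (pp >= span[1L] && pp <= span[2L]) protect[pp] <- TRUE
    }
  }
  idx <- which(!protect)
  hit <- idx[stats::runif(length(idx)) < divergence]
  if (length(hit) > 0L) {
    s[hit] <- vapply(s[hit], function(b)
      if (b %in% DNA_BASES) sample(setdiff(DNA_BASES, b), 1L) else b,
      character(1), USE.NAMES = FALSE)
  }
  residues_b <- paste(s, collapse = "")
  # functional exons: codon-aware mutation written back in place
  truth_b <- truth
  for (i in seq_len(nrow(truth))) {
    if (truth$status[i] != "functional") next
    iv <- matrix(c(truth$exon1_start[i], truth$exon1_end[i],
                   truth$exon2_start[i], truth$exon2_end[i],
                   truth$exon3_start[i], truth$exon3_end[i]),
                 ncol = 2L, byrow = TRUE)
    asc <- order(iv[, 1L])                 # ascending forward order
    segs <- vapply(asc, function(k)
      substr(residues_b, iv[k, 1L], iv[k, 2L]), character(1))
    cds <- paste(segs, collapse = "")
    if (truth$strand[i] == "-") cds <- revcomp(cds)
    n_cod <- nchar(cds) %/% 3L
    shield <- c(1L, n_cod)
    if (truth$subunit[i] == "beta") shield <- c(shield, 93L, n_cod - 1L)
    cds2 <- mutate_cds(cds, divergence, shield)
    fwd <- if (truth$strand[i] == "-") revcomp(cds2) else cds2
    pos <- 1L
    for (k in asc) {
      w <- iv[k, 2L] - iv[k, 1L] + 1L
      substr(residues_b, iv[k, 1L], iv[k, 2L]) <- substr(fwd, pos, pos + w - 1L)
      pos <- pos + w
    }
    truth_b$cds[i] <- cds2
  }
  check_truth_soundness(residues_b, truth_b)
  ids <- paste0(names(gen$seq), c("_a", "_b"))
  list(seq_a = Biostrings::DNAStringSet(setNames(as.character(gen$seq[[1L]]), ids[1L])),
       seq_b = Biostrings::DNAStringSet(setNames(residues_b, ids[2L])),
       truth_a = truth, truth_b = truth_b)
}

#' Generate a two-lineage CDS set with a planted clade
#'
#' Draws independent copies of the non-Bohr and Bohr beta template CDS, each
#' mutated at the given divergence (start/stop codons shielded, no new
#' stops), labelled `nonBohr1..n` and `bohr1..m`.  The non-Bohr copies form
#' a planted clade against the Bohr background.
#'
#' @param seed Integer seed.
#' @param n_nonbohr,n_bohr Lineage sizes.
#' @param divergence Per-site substitution probability within each lineage.
#' @param ref A `globin_reference`.
#' @return Named character vector of CDS.
#' @export
generate_lineage_cds <- function(seed = 1L, n_nonbohr = 6L, n_bohr = 8L,
                                 divergence = 0.02, ref = make_templates(seed)) {
  set.seed(as.integer(seed) + 7L)
  tpl <- ref$templates
  cds_of <- function(variant) {
    rows <- tpl[tpl$variant == variant, , drop = FALSE]
    paste(rows$cds[order(rows$exon_index)], collapse = "")
  }
  out <- character(0)
  nb <- cds_of("beta_nonbohr"); bb <- cds_of("beta_bohr")
  for (i in seq_len(n_nonbohr)) {
    n_cod <- nchar(nb) %/% 3L
    out[paste0("nonBohr", i)] <- mutate_cds(nb, divergence, c(1L, n_cod))
  }
  for (i in seq_len(n_bohr)) {
    n_cod <- nchar(bb) %/% 3L
    out[paste0("bohr", i)] <- mutate_cds(bb, divergence, c(1L, n_cod))
  }
  out
}
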