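# lightweight fabricated models for rule-path tests
fake_model <- function(subunit = "beta", protein = NULL, n_exons = 3L,
                       defects = character(0), splice_ok = c(TRUE, TRUE),
                       has_start = TRUE, has_stop = TRUE, strand = "+",
                       start = 1000L, seq_id = "s") {
  if (is.null(protein))
    protein <- paste0("M", strrep("A", 146L), "*")
  exons <- data.frame(exon_index = seq_len(n_exons),
                      start = start + (seq_len(n_exons) - 1L) * 400L,
                      end = start + (seq_len(n_exons) - 1L) * 400L + 100L)
  structure(list(seq_id = seq_id, strand = strand, subunit = subunit,
                 variant = ifelse(subunit == "alpha", "alpha", "beta_bohr"),
                 exons = exons, introns = NULL, cds = "", protein = protein,
                 splice_ok = splice_ok, has_start = has_start,
                 has_stop = has_stop, defects = defects, refined = TRUE,
                 score = 500),
            class = "gene_model")
}

beta_prot <- function(len, cterm, pos93 = "A") {
  p <- strsplit(paste0("M", strrep("L", len - 1L)), "")[[1]]
  p[93] <- pos93
  p[len] <- cterm
  paste0(paste(p, collapse = ""), "*")
}

test_that("each functionality criterion trips independently", {
  cfg <- classifier_config()
  # intact alpha of 143 aa -> functional
  a_ok <- classify_functionality(
    fake_model("alpha", paste0("M", strrep("G", 142L), "*")), cfg)
  expect_equal(a_ok$status, "functional")
  expect_length(a_ok$failed_criteria, 0L)
  # intact beta of 148 aa -> functional
  b_ok <- classify_functionality(fake_model("beta", beta_prot(148L, "H")), cfg)
  expect_equal(b_ok$status, "functional")
  # criterion 1: two exons
  c1 <- classify_functionality(
    fake_model("beta", n_exons = 2L, defects = "missing_exon_3",
               splice_ok = TRUE), cfg)
  expect_equal(c1$status, "pseudogene")
  expect_true("exon_count" %in% c1$failed_criteria)
  # criterion 2: internal stop
  c2 <- classify_functionality(
    fake_model("beta", paste0("M", strrep("L", 60L), "*", strrep("L", 86L), "*"),
               defects = "internal_stop"), cfg)
  expect_equal(c2$status, "pseudogene")
  expect_true("splice_and_termini" %in% c2$failed_criteria)
  expect_true("internal_stop" %in% c2$model$defects)
  # criterion 2: bad splice
  c2b <- classify_functionality(
    fake_model("beta", beta_prot(148L, "H"), defects = "bad_splice_donor",
               splice_ok = c(FALSE, TRUE)), cfg)
  expect_true("splice_and_termini" %in% c2b$failed_criteria)
  # criterion 3: wrong protein length only
  c3 <- classify_functionality(fake_model("beta", beta_prot(150L, "H")), cfg)
  expect_equal(c3$failed_criteria, "protein_length")
  c3a <- classify_functionality(
    fake_model("alpha", paste0("M", strrep("G", 140L), "*")), cfg)
  expect_equal(c3a$failed_criteria, "protein_length")
})

test_that("unrefined models are rejected", {
  m <- fake_model()
  m$refined <- FALSE
  expect_error(classify_functionality(m), "refine first")
})

test_that("adding a defect never rescues a gene (monotonicity)", {
  cfg <- classifier_config()
  base <- fake_model("beta", beta_prot(147L, "F"))
  expect_equal(classify_functionality(base, cfg)$status, "functional")
  for (d in c("internal_stop", "frameshift", "no_start", "no_stop",
              "length_violation", "bad_splice_acceptor")) {
    m <- base
    m$defects <- d
    expect_equal(classify_functionality(m, cfg)$status, "pseudogene",
                 info = d)
  }
})

test_that("Bohr hallmarks are conjunctive", {
  cfg <- classifier_config()
  cls <- function(m) classify_bohr(classify_functionality(m, cfg), cfg)
  nb <- cls(fake_model("beta", beta_prot(147L, "F", "A")))
  expect_equal(nb$bohr_status, "non_bohr")
  expect_setequal(nb$hallmarks_met, c("length_147", "cterm_phe", "ala_93"))
  # 148 aa ending in histidine: hallmarks 1 and 2 fail -> Bohr
  b <- cls(fake_model("beta", beta_prot(148L, "H", "A")))
  expect_equal(b$bohr_status, "bohr")
  expect_equal(b$hallmarks_met, "ala_93")
  # 147 aa but position 93 not alanine -> Bohr, not an error
  b93 <- cls(fake_model("beta", beta_prot(147L, "F", "S")))
  expect_equal(b93$bohr_status, "bohr")
  # alpha genes are out of the rule's domain
  a <- cls(fake_model("alpha", paste0("M", strrep("G", 142L), "*")))
  expect_equal(a$bohr_status, "not_applicable")
  # pseudogenes too
  ps <- cls(fake_model("beta", beta_prot(147L, "F"), defects = "internal_stop"))
  expect_equal(ps$bohr_status, "not_applicable")
})

test_that("position 93 convention is switchable", {
  cfg <- classifier_config(nonbohr_position_includes_met = FALSE)
  p <- strsplit(beta_prot(147L, "F", "S"), "")[[1]]
  p[94] <- "A"      # alanine at mature-chain position 93
  m <- fake_model("beta", paste(p, collapse = ""))
  g <- classify_bohr(classify_functionality(m, cfg), cfg)
  expect_equal(g$bohr_status, "non_bohr")
})

test_that("count tables are deterministic and permutation-invariant", {
  genes <- classify_genes(list(
    fake_model("alpha", paste0("M", strrep("G", 142L), "*")),
    fake_model("beta", beta_prot(148L, "H")),
    fake_model("beta", beta_prot(147L, "F")),
    fake_model("beta", beta_prot(147L, "F"), defects = "frameshift")))
  tab <- summarize_counts(genes)$total
  expect_equal(tab$n, c(1L, 1L, 1L, 0L, 1L))
  set.seed(2)
  for (i in 1:3) {
    tab2 <- summarize_counts(sample(genes))$total
    expect_identical(tab2, tab)
  }
  empty <- summarize_counts(list())$total
  expect_true(all(empty$n == 0L))
})
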