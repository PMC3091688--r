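ref_f <- make_templates(101)

test_that("a planted exact exon copy is found with identity 1 on both strands", {
  tpl <- ref_f$templates
  e2 <- tpl$cds[tpl$variant == "beta_bohr" & tpl$exon_index == 2L]
  set.seed(8)
  seqs <- paste0(random_dna(500), e2, random_dna(500))
  hits <- find_exon_hits(seqs, ref_f, seq_id = "plant")
  h2 <- hits[hits$exon_index == 2L & hits$subunit == "beta", ]
  expect_equal(nrow(h2), 1L)
  expect_equal(h2$identity, 1)
  expect_equal(h2$strand, "+")
  expect_equal(c(h2$start, h2$end), c(501L, 500L + nchar(e2)))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seqs)))
  hits_rc <- find_exon_hits(rc, ref_f, seq_id = "plant_rc")
  h2rc <- hits_rc[hits_rc$exon_index == 2L & hits_rc$subunit == "beta", ]
  expect_equal(nrow(h2rc), 1L)
  expect_equal(h2rc$strand, "-")
  expect_equal(h2rc$score, h2$score)
  expect_equal(h2rc$identity, 1)
})

test_that("a diverged exon copy is recovered and scores match the oracle", {
  tpl <- ref_f$templates
  e2 <- tpl$cds[tpl$variant == "beta_bohr" & tpl$exon_index == 2L]
  pep <- tpl$peptide[tpl$variant == "beta_bohr" & tpl$exon_index == 2L]
  set.seed(12)
  mut <- globinscan:::mutate_cds(e2, 0.1)
  seqs <- paste0(random_dna(400), mut, random_dna(400))
  hits <- find_exon_hits(seqs, ref_f, min_identity = 0.5, seq_id = "div")
  h2 <- hits[hits$exon_index == 2L & hits$subunit == "beta", ]
  expect_equal(nrow(h2), 1L)
  expect_gt(h2$identity, 0.75)
  oracle <- sw_oracle(pep, translate_cds(mut), B62)
  expect_equal(h2$score, oracle)
})

test_that("hits chain into gene models respecting intron bounds", {
  mk_hit <- function(start, end, strand, subunit, idx, score) {
    data.frame(seq_id = "s", start = start, end = end, strand = strand,
               subunit = subunit, variant = ifelse(subunit == "alpha", "alpha",
                                                   "beta_bohr"),
               exon_index = idx, score = score, identity = 0.95,
               stringsAsFactors = FALSE)
  }
  # three ordered hits with 200-bp gaps -> one complete model
  h <- rbind(mk_hit(1000, 1092, "+", "beta", 1L, 150),
             mk_hit(1293, 1514, "+", "beta", 2L, 350),
             mk_hit(1715, 1846, "+", "beta", 3L, 250))
  m <- chain_hits(h, 5000L)
  expect_length(m, 1L)
  expect_equal(nrow(m[[1]]$exons), 3L)
  expect_length(m[[1]]$defects, 0L)

  # exons 1 and 3 only, compatible spacing -> missing_exon model
  m2 <- chain_hits(h[c(1, 3), ], 5000L)
  expect_length(m2, 1L)
  expect_equal(m2[[1]]$defects, "missing_exon_2")

  # two complete interleaved chains on opposite strands -> two models
  # alpha hits on '-' run right-to-left: exon 1 is rightmost on forward coords
  h3 <- rbind(h, mk_hit(1800, 1925, "-", "alpha", 1L, 150),
              mk_hit(1395, 1607, "-", "alpha", 2L, 350),
              mk_hit(1100, 1192, "-", "alpha", 3L, 200))
  m3 <- chain_hits(h3, 5000L)
  expect_length(m3, 2L)
  expect_setequal(vapply(m3, function(m) m$strand, character(1)), c("+", "-"))
  expect_true(all(vapply(m3, function(m) nrow(m$exons), integer(1)) == 3L))

  # gap beyond intron_max is not chained
  h4 <- rbind(mk_hit(1000, 1092, "+", "beta", 1L, 150),
              mk_hit(15000, 15221, "+", "beta", 2L, 350))
  m4 <- chain_hits(h4, 20000L, intron_max = 10000L)
  expect_true(all(vapply(m4, function(m) nrow(m$exons), integer(1)) == 1L))
})

test_that("the finder is strand-symmetric end to end", {
  cfg <- small_config(seed = 21)
  gen <- generate_cluster(cfg, make_templates(21))
  fwd <- find_genes(gen$seq, make_templates(21))
  rc <- Biostrings::reverseComplement(gen$seq[[1]])
  rev <- find_genes(as.character(rc), make_templates(21), seq_id = "rc")
  expect_equal(length(fwd), length(rev))
  key <- function(m) paste(m$subunit, nrow(m$exons),
                           paste(sort(m$defects), collapse = "+"))
  expect_setequal(vapply(fwd, key, character(1)), vapply(rev, key, character(1)))
  expect_setequal(vapply(fwd, function(m) m$strand, character(1)),
                  vapply(rev, function(m) setdiff(c("+", "-"), m$strand),
                         character(1)))
})

test_that("no models arise in pure intergenic spacer", {
  for (seed in 1:5) {
    cfg <- simulation_config(seed = seed, n_alpha_functional = 0L,
                             n_beta_bohr = 0L, n_beta_nonbohr = 0L,
                             pseudogene_plan = data.frame(subunit = character(0),
                                                          defect = character(0)))
    gen <- generate_cluster(cfg, make_templates(seed))
    expect_equal(nrow(gen$truth), 0L)
    models <- find_genes(gen$seq, make_templates(seed))
    expect_length(models, 0L)
  }
})
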