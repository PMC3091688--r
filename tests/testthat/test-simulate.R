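test_that("templates are structurally faithful and deterministic", {
  ref <- make_templates(17)
  tpl <- ref$templates
  pep_len <- function(v) sum(nchar(tpl$peptide[tpl$variant == v]))
  expect_equal(pep_len("alpha"), 143L)
  expect_equal(pep_len("beta_bohr"), 148L)
  expect_equal(pep_len("beta_nonbohr"), 147L)
  # non-Bohr hallmarks on the template protein itself
  nb <- paste(tpl$peptide[tpl$variant == "beta_nonbohr"][
    order(tpl$exon_index[tpl$variant == "beta_nonbohr"])], collapse = "")
  expect_equal(substr(nb, 147, 147), "F")
  expect_equal(substr(nb, 93, 93), "A")
  expect_equal(nchar(nb), 147L)
  # Bohr template keeps its C-terminal histidine
  bb <- paste(tpl$peptide[tpl$variant == "beta_bohr"][
    order(tpl$exon_index[tpl$variant == "beta_bohr"])], collapse = "")
  expect_equal(substr(bb, 148, 148), "H")
  expect_identical(make_templates(17), ref)
  expect_false(identical(make_templates(18)$templates$cds, tpl$cds))
})

test_that("generation is byte-deterministic per seed", {
  cfg <- small_config(seed = 4)
  g1 <- generate_cluster(cfg, make_templates(4))
  g2 <- generate_cluster(cfg, make_templates(4))
  expect_identical(as.character(g1$seq), as.character(g2$seq))
  expect_identical(g1$truth, g2$truth)
})

test_that("a zero-gene config yields pure spacer and empty truth", {
  cfg <- simulation_config(seed = 2, n_alpha_functional = 0L,
                           n_beta_bohr = 0L, n_beta_nonbohr = 0L,
                           pseudogene_plan = data.frame(subunit = character(0),
                                                        defect = character(0)))
  gen <- generate_cluster(cfg, make_templates(2))
  expect_equal(nrow(gen$truth), 0L)
  expect_gt(Biostrings::width(gen$seq), 0L)
})

test_that("the chromosome-6-like default composition is emitted in order", {
  gen <- generate_cluster(simulation_config(seed = 6), make_templates(6))
  tr <- gen$truth
  expect_equal(nrow(tr), 17L)
  expect_equal(sum(tr$subunit == "alpha" & tr$status == "functional"), 6L)
  expect_equal(sum(tr$subunit == "beta" & tr$status == "functional"), 6L)
  expect_equal(sum(tr$bohr_status == "non_bohr"), 2L)
  expect_equal(sum(tr$subunit == "alpha" & tr$status == "pseudogene"), 2L)
  expect_equal(sum(tr$subunit == "beta" & tr$status == "pseudogene"), 3L)
  # strictly alternating subunits, tail-to-tail strands
  expect_true(all(tr$subunit[-1] != tr$subunit[-17]))
  expect_true(all(tr$strand[tr$subunit == "alpha"] == "-"))
  expect_true(all(tr$strand[tr$subunit == "beta"] == "+"))
  # genes sorted 5'->3'
  starts <- pmin(tr$exon1_start, tr$exon3_start, na.rm = TRUE)
  expect_true(all(diff(starts) > 0))
})

test_that("unsupported defects are rejected", {
  expect_error(simulation_config(pseudogene_plan = data.frame(
    subunit = "beta", defect = "inversion")), "unsupported defect")
})

test_that("zero divergence, defect-free clusters are recovered verbatim", {
  cfg <- small_config(seed = 13, template_divergence = 0)
  ref <- make_templates(13)
  gen <- generate_cluster(cfg, ref)
  res <- annotate_cluster(gen$seq, ref = ref)
  cmp <- compare_to_truth(res$genes, gen$truth)
  expect_true(cmp$all_match)
  expect_equal(cmp$n_spurious, 0L)
  # with zero divergence, recovered exon intervals equal the planted ones
  tr <- gen$truth
  for (i in seq_len(nrow(tr))) {
    g <- res$genes[[i]]
    ex <- g$model$exons[order(g$model$exons$exon_index), ]
    expect_equal(ex$start, c(tr$exon1_start[i], tr$exon2_start[i],
                             tr$exon3_start[i]))
    expect_equal(ex$end, c(tr$exon1_end[i], tr$exon2_end[i], tr$exon3_end[i]))
    expect_equal(g$model$strand, tr$strand[i])
  }
})

test_that("every supported defect is producible and detected", {
  plan <- data.frame(
    subunit = rep(c("alpha", "beta"), each = 4L),
    defect = c("missing_exon", "bad_splice_donor", "internal_stop", "no_start",
               "bad_splice_acceptor", "frameshift", "no_stop",
               "length_violation"),
    stringsAsFactors = FALSE)
  cfg <- simulation_config(seed = 33, n_alpha_functional = 1L,
                           n_beta_bohr = 1L, n_beta_nonbohr = 0L,
                           pseudogene_plan = plan,
                           intergenic_length_range = c(800L, 1500L))
  ref <- make_templates(33)
  gen <- generate_cluster(cfg, ref)
  expect_equal(sum(gen$truth$status == "pseudogene"), 8L)
  res <- annotate_cluster(gen$seq, ref = ref)
  cmp <- compare_to_truth(res$genes, gen$truth)
  expect_true(cmp$all_match)
})

test_that("homeolog pairs keep structure and diverge as configured", {
  cfg <- small_config(seed = 8)
  hp0 <- generate_homeolog_pair(cfg, divergence = 0, ref = make_templates(8))
  expect_equal(as.character(hp0$seq_a[[1]]), as.character(hp0$seq_b[[1]]))

  hp <- generate_homeolog_pair(cfg, divergence = 0.05, ref = make_templates(8))
  expect_equal(nrow(hp$truth_a), nrow(hp$truth_b))
  expect_equal(hp$truth_a[, c("name", "subunit", "status", "strand")],
               hp$truth_b[, c("name", "subunit", "status", "strand")])
  a <- strsplit(as.character(hp$seq_a[[1]]), "")[[1]]
  b <- strsplit(as.character(hp$seq_b[[1]]), "")[[1]]
  expect_equal(mean(a != b), 0.05, tolerance = 0.15)
})

test_that("lineage CDS sets carry the planted two-lineage structure", {
  cds <- generate_lineage_cds(seed = 44, n_nonbohr = 3L, n_bohr = 4L,
                              divergence = 0.02)
  expect_length(cds, 7L)
  expect_equal(sum(startsWith(names(cds), "nonBohr")), 3L)
  d <- pairwise_distances(cds)
  within_nb <- d$d[1:3, 1:3][upper.tri(matrix(0, 3, 3))]
  between <- d$d[1:3, 4:7]
  expect_lt(max(within_nb), min(between))
})
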