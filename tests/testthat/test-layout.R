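fake_gene <- function(subunit, strand, start, status = "functional",
                      bohr = NULL, seq_id = "ctg") {
  if (is.null(bohr))
    bohr <- if (subunit == "beta" && status == "functional") "bohr"
            else "not_applicable"
  model <- structure(list(
    seq_id = seq_id, strand = strand, subunit = subunit, variant = subunit,
    exons = data.frame(exon_index = 1:3,
                       start = start + c(0L, 300L, 700L),
                       end = start + c(100L, 500L, 900L)),
    protein = "", splice_ok = c(TRUE, TRUE), has_start = TRUE,
    has_stop = TRUE, defects = character(0), refined = TRUE),
    class = "gene_model")
  structure(list(model = model, status = status,
                 failed_criteria = character(0), bohr_status = bohr,
                 hallmarks_met = character(0), name = NA_character_),
            class = "classified_gene")
}

alternating_cluster <- function(n = 6L, seq_id = "ctg") {
  genes <- list()
  pos <- 1000L
  for (i in seq_len(n)) {
    su <- if (i %% 2 == 1L) "beta" else "alpha"
    st <- if (su == "alpha") "-" else "+"
    genes[[i]] <- fake_gene(su, st, pos, seq_id = seq_id)
    pos <- pos + 4000L
  }
  genes
}

test_that("a canonical alternating tail-to-tail cluster has no violations", {
  rep <- build_layout(alternating_cluster(8L))
  expect_length(rep$strand_violations, 0L)
  expect_equal(nrow(rep$alternation_violations), 0L)
  # beta(+) followed by alpha(-) is a tail-to-tail pair
  expect_equal(rep$orientation_motif_count, 4L)
})

test_that("strand and alternation disruptions are reported", {
  genes <- alternating_cluster(6L)
  genes[[3]]$model$strand <- "-"              # a beta gene on the minus strand
  rep <- build_layout(genes)
  expect_equal(rep$strand_violations, 3L)

  genes2 <- alternating_cluster(6L)
  genes2[[4]] <- fake_gene("beta", "+", 1000L + 3L * 4000L)  # adjacent betas
  rep2 <- build_layout(genes2)
  expect_equal(nrow(rep2$alternation_violations), 2L)  # pairs (3,4) and (4,5)
  expect_true(all(c(3L, 4L) %in% rep2$alternation_violations$upstream))
})

test_that("pseudogenes participate in alternation unless excluded", {
  genes <- alternating_cluster(5L)
  genes[[3]]$status <- "pseudogene"
  genes[[3]]$bohr_status <- "not_applicable"
  rep_in <- build_layout(genes, include_pseudogenes = TRUE)
  expect_length(rep_in$ordered_genes, 5L)
  rep_out <- build_layout(genes, include_pseudogenes = FALSE)
  expect_length(rep_out$ordered_genes, 4L)
  # removing the middle beta creates an adjacent alpha-alpha pair
  expect_equal(nrow(rep_out$alternation_violations), 1L)
})

test_that("genes from multiple sequences are rejected", {
  genes <- c(alternating_cluster(2L, seq_id = "a"),
             alternating_cluster(2L, seq_id = "b"))
  expect_error(build_layout(genes), "multiple sequences")
})

test_that("names follow the Ssa<Chr><subunit><k> scheme", {
  genes <- list(fake_gene("beta", "+", 1000L),
                fake_gene("alpha", "-", 5000L),
                fake_gene("beta", "+", 9000L, status = "pseudogene"),
                fake_gene("alpha", "-", 13000L),
                fake_gene("beta", "+", 17000L, status = "pseudogene"),
                fake_gene("beta", "+", 21000L, status = "pseudogene"))
  named <- assign_names(build_layout(genes), "Chr6")
  got <- vapply(named, function(g) g$name, character(1))
  expect_equal(got, c("SsaChr6\u03b21", "SsaChr6\u03b11", "SsaChr6\u03b2\u03c81",
                      "SsaChr6\u03b12", "SsaChr6\u03b2\u03c82",
                      "SsaChr6\u03b2\u03c83"))
  expect_false(anyDuplicated(got) > 0)
  # renaming the same report reproduces identical names
  named2 <- assign_names(build_layout(genes), "Chr6")
  expect_equal(vapply(named2, function(g) g$name, character(1)), got)
})

test_that("empty reports name nothing and label reuse is caught", {
  expect_equal(assign_names(build_layout(list()), "Chr3"), list())
  reg <- new.env()
  genes <- alternating_cluster(2L)
  assign_names(build_layout(genes), "Chr3", registry = reg)
  expect_error(assign_names(build_layout(genes), "Chr3", registry = reg),
               "already used")
})

test_that("violation counts are invariant under reverse complement", {
  genes <- alternating_cluster(7L)
  genes[[2]]$model$strand <- "+"   # one alpha strand violation
  rep_f <- build_layout(genes)
  # mirror the cluster: positions and strands flip
  total <- 40000L
  mirrored <- lapply(genes, function(g) {
    m <- g$model
    e <- m$exons
    new_start <- total - e$end
    new_end <- total - e$start
    m$exons <- data.frame(exon_index = e$exon_index,
                          start = rev(new_start), end = rev(new_end))
    m$strand <- setdiff(c("+", "-"), m$strand)
    g$model <- m
    g
  })
  rep_r <- build_layout(mirrored)
  expect_equal(length(rep_r$strand_violations), length(rep_f$strand_violations))
  expect_equal(nrow(rep_r$alternation_violations),
               nrow(rep_f$alternation_violations))
  expect_equal(rep_r$orientation_motif_count, rep_f$orientation_motif_count)
})
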