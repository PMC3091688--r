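test_that("cluster typing matches the teleost signature gene sets", {
  salmon <- c("C16orf35", "Rhomboid family member 1", "DOCK6",
              "ELAV-like protein 3", "MPG")
  res <- classify_cluster(salmon)
  expect_equal(res$label, "cluster1")
  expect_length(res$hits_cluster1, 5L)
  expect_length(res$hits_cluster2, 0L)

  # a second cluster carrying Rho-GTPase-activating protein but no
  # Aquaporin-8, plus a stray Rhomboid copy: 1-1 tie -> ambiguous
  tetraodon2 <- c("Rho-GTPase-activating protein", "Rhomboid family member 1",
                  "unrelated gene A", "unrelated gene B")
  res2 <- classify_cluster(tetraodon2)
  expect_equal(res2$label, "ambiguous")
  expect_equal(res2$hits_cluster1, canonical_gene_name("Rhomboid family member 1"))
  expect_equal(res2$hits_cluster2,
               canonical_gene_name("Rho-GTPase-activating protein"))

  empty <- classify_cluster(character(0))
  expect_equal(empty$label, "ambiguous")
  expect_length(empty$hits_cluster1, 0L)
})

test_that("cluster typing ignores order, case and duplicates", {
  base <- c("Aquaporin-8", "Rho-GTPase-activating protein", "somegene")
  res <- classify_cluster(base)
  expect_equal(res$label, "cluster2")
  shuffled <- classify_cluster(rev(c(toupper(base), base)))
  expect_equal(shuffled$label, res$label)
  expect_setequal(shuffled$hits_cluster2, res$hits_cluster2)
})

test_that("shared-gene matrices reflect set overlap structure", {
  f <- function(sp, cl, genes) list(species = sp, cluster_id = cl,
                                    genes = data.frame(name = genes))
  same <- shared_gene_matrix(list(f("a", "1", c("x", "y")),
                                  f("b", "1", c("y", "x"))))
  expect_true(all(same))
  expect_equal(dim(same), c(2L, 2L))

  disj <- shared_gene_matrix(list(f("a", "1", c("x", "y")),
                                  f("b", "1", c("u", "v"))))
  expect_equal(sum(disj), 4L)
  expect_true(all(disj[1:2, 1]) && all(!disj[1:2, 2]))

  expect_error(shared_gene_matrix(list(f("a", "1", "x"))), "at least two")
})

test_that("flank tables round-trip through the TSV reader", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("species\tcluster_id\tgene_name\torientation",
               "salmon\tChr6\tMPG\ttoward",
               "salmon\tChr6\tC16orf35\taway",
               "medaka\tchr19\tAquaporin-8\tunknown"), f)
  flanks <- read_flank_tsv(f)
  expect_length(flanks, 2L)
  expect_equal(flanks[[1]]$species, "salmon")
  expect_equal(classify_cluster(flanks[[2]])$label, "cluster2")
  expect_error(read_flank_tsv({
    f2 <- withr::local_tempfile(fileext = ".tsv")
    writeLines("species\tgene_name\na\tb", f2); f2
  }), "missing column")
})

test_that("dot plots satisfy self, reverse-complement and transpose laws", {
  set.seed(41)
  a <- random_dna(300)
  b <- paste0(random_dna(60), substr(a, 101, 220), random_dna(60))

  dp_self <- dotplot(a, a, word = 12L)
  diag_hits <- dp_self$hits[dp_self$hits$strand == "+", ]
  expect_true(all(seq_len(300 - 12 + 1) %in% diag_hits$x[diag_hits$x == diag_hits$y]))

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(a)))
  dp_rc <- dotplot(a, rc, word = 12L)
  minus <- dp_rc$hits[dp_rc$hits$strand == "-", ]
  expect_gt(nrow(minus), 250L)
  expect_true(all(minus$y == 300 - minus$x - 12 + 2))

  ab <- dotplot(a, b, word = 12L)$hits
  ba <- dotplot(b, a, word = 12L)$hits
  expect_identical(sort(paste(ab$x, ab$y, ab$strand)),
                   sort(paste(ba$y, ba$x, ba$strand)))

  short <- dotplot("ACGTACGTAC", a, word = 12L)
  expect_equal(nrow(short$hits), 0L)
  expect_error(dotplot(a, b, word = 4L), "word must be")
})

test_that("windowed identity is 1 against itself and tracks divergence", {
  set.seed(42)
  a <- random_dna(5000)
  self <- windowed_identity(a, a, window = 500L)
  expect_gt(nrow(self), 5L)
  expect_true(all(self$identity == 1))

  av <- strsplit(a, "")[[1]]
  hit <- runif(5000) < 0.05
  av[hit] <- vapply(av[hit], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), "x")
  b <- paste(av, collapse = "")
  wi <- windowed_identity(a, b, window = 500L)
  expect_equal(median(wi$identity), 0.95, tolerance = 0.02)
})
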