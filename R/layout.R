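# Cluster layout: gene order, tail-to-tail orientation, alternation of the
# alpha/beta subunits, and paper-style gene naming.

#' Build a cluster layout report
#'
#' Orders classified genes 5'->3' on forward coordinates and scores the
#' expected organisation of a teleost hemoglobin cluster: alpha genes
#' transcribed on the negative strand, beta genes on the positive strand,
#' subunits alternating along the cluster, adjacent genes tail-to-tail
#' (3' ends facing, i.e. upstream gene on `+`, downstream on `-`).
#'
#' @param genes List of `classified_gene` objects from one sequence.
#' @param include_pseudogenes Include pseudogenes in the ordered list and
#'   alternation check (the alternating pattern holds across pseudogenes in
#'   the salmon clusters, so they participate by default).
#' @return A `cluster_report`: list with `seq_id`, `ordered_genes`,
#'   `cluster_orientation` (`forward`/`reverse`: which global orientation
#'   the strand-expectation model fits best; contig orientation is
#'   arbitrary in an assembly),
#'   `strand_violations` (indices into `ordered_genes`),
#'   `alternation_violations` (data.frame of adjacent same-subunit pairs),
#'   and `orientation_motif_count` (number of tail-to-tail adjacent pairs).
#' @export
build_layout <- function(genes, include_pseudogenes = TRUE) {
  if (length(genes) == 0L) {
    return(structure(list(seq_id = NA_character_, ordered_genes = list(),
                          cluster_orientation = "forward",
                          strand_violations = integer(0),
                          alternation_violations = data.frame(upstream = integer(0),
                                                              downstream = integer(0)),
                          orientation_motif_count = 0L),
                     class = "cluster_report"))
  }
  seq_ids <- unique(vapply(genes, function(g) g$model$seq_id, character(1)))
  if (length(seq_ids) > 1L)
    stop("genes from multiple sequences: ", paste(seq_ids, collapse = ", "))
  if (!include_pseudogenes)
    genes <- Filter(function(g) g$status == "functional", genes)
  starts <- vapply(genes, function(g) min(g$model$exons$start), numeric(1))
  genes <- genes[order(starts)]
  sub <- vapply(genes, function(g) g$model$subunit, character(1))
  strand <- vapply(genes, function(g) g$model$strand, character(1))
  # the global orientation of an assembled contig is arbitrary, so the
  # expectation model (alpha -, beta +) is applied up to cluster
  # orientation: violations are scored under whichever orientation fits the
  # majority of genes
  expected <- ifelse(sub == "alpha", "-", "+")
  viol_fwd <- which(strand != expected)
  viol_rev <- which(strand == expected)
  if (length(viol_rev) < length(viol_fwd)) {
    strand_viol <- viol_rev
    orientation <- "reverse"
  } else {
    strand_viol <- viol_fwd
    orientation <- "forward"
  }
  n <- length(genes)
  alt <- data.frame(upstream = integer(0), downstream = integer(0))
  motif <- 0L
  if (n > 1L) {
    same <- which(sub[-n] == sub[-1L])
    alt <- data.frame(upstream = same, downstream = same + 1L)
    motif <- sum(strand[-n] == "+" & strand[-1L] == "-")
  }
  structure(list(seq_id = seq_ids, ordered_genes = genes,
                 cluster_orientation = orientation,
                 strand_violations = strand_viol,
                 alternation_violations = alt,
                 orientation_motif_count = as.integer(motif)),
            class = "cluster_report")
}

#' Assign paper-style gene names along a cluster
#'
#' Functional genes are named `Ssa<label><subunit><k>` and pseudogenes
#' `Ssa<label><subunit>ψ<k>`, with the Greek subunit letter
#' (α/β) and `k` counting 5'->3' within each subunit; functional
#' genes and pseudogenes carry independent counters.
#'
#' @param report A `cluster_report` from [build_layout()].
#' @param chromosome_label Chromosome label, e.g. `"Chr6"`.
#' @param registry Optional environment used to detect reuse of a
#'   chromosome label across calls (collisions abort).
#' @return The ordered list of `classified_gene` objects with `name` set.
#' @export
assign_names <- function(report, chromosome_label, registry = NULL) {
  if (!is.null(registry)) {
    if (isTRUE(registry[[chromosome_label]]))
      stop("chromosome label already used: ", chromosome_label)
    registry[[chromosome_label]] <- TRUE
  }
  genes <- report$ordered_genes
  if (length(genes) == 0L) return(list())
  greek <- c(alpha = "\u03b1", beta = "\u03b2")
  counters <- new.env()
  for (i in seq_along(genes)) {
    g <- genes[[i]]
    key <- paste0(g$model$subunit, "_", g$status)
    k <- (if (is.null(counters[[key]])) 0L else counters[[key]]) + 1L
    counters[[key]] <- k
    psi <- if (g$status == "pseudogene") "\u03c8" else ""
    genes[[i]]$name <- paste0("Ssa", chromosome_label,
                              greek[[g$model$subunit]], psi, k)
  }
  genes
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %s: %d genes, %d strand violation(s), %d alternation violation(s), %d tail-to-tail pair(s)\n",
              x$seq_id, length(x$ordered_genes), length(x$strand_violations),
              nrow(x$alternation_violations), x$orientation_motif_count))
  invisible(x)
}

#' Render a cluster report as a data.frame
#'
#' @param report A `cluster_report` (genes ideally named via
#'   [assign_names()]).
#' @return Data.frame with one row per gene in cluster order.
#' @export
layout_table <- function(report) {
  genes <- report$ordered_genes
  if (length(genes) == 0L) {
    return(data.frame(name = character(0), subunit = character(0),
                      status = character(0), bohr_status = character(0),
                      strand = character(0), start = integer(0),
                      end = integer(0), defects = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    name = vapply(genes, function(g) g$name, character(1)),
    subunit = vapply(genes, function(g) g$model$subunit, character(1)),
    status = vapply(genes, function(g) g$status, character(1)),
    bohr_status = vapply(genes, function(g) g$bohr_status, character(1)),
    strand = vapply(genes, function(g) g$model$strand, character(1)),
    start = vapply(genes, function(g) min(g$model$exons$start), integer(1)),
    end = vapply(genes, function(g) max(g$model$exons$end), integer(1)),
    defects = vapply(genes, function(g)
      paste(g$model$defects, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
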