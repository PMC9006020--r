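# Two-topology log-likelihood comparison at gene and site granularity:
# the diagnostic for genes (or gene segments) whose signal favors an
# alternative placement of a clade, e.g. putative endosymbiotic-transfer
# chimeras.

#' Per-gene log-likelihood difference between two topologies
#'
#' For every gene, computes lnL under topology `t1` and `t2` (restricted
#' to the gene's taxa) and the difference `delta = lnL(T1) - lnL(T2)`,
#' normalized by the gene's alignment length (all columns, including
#' gap-bearing ones). In the default "per-gene-optimized" mode branch
#' lengths (and the gamma shape, when `k >= 2`) are optimized
#' independently under each topology; in "fixed-branch-lengths" mode the
#' supplied branch lengths are used as-is, which makes per-gene values
#' additive over concatenation. Genes overlapping fewer than 4 leaves are
#' skipped with a notice. Negative normalized values indicate a
#' preference for `t2`.
#'
#' @param genes A `gene_set`.
#' @param t1,t2 `phylo` topologies sharing one leaf set (branch lengths
#'   required in fixed mode; used as starting values otherwise).
#' @param model An [aa_model()].
#' @param mode "per-gene-optimized" (default) or "fixed-branch-lengths".
#' @return Object of class `delta_lnl_report`: data.frame with gene,
#'   length, lnl1, lnl2, delta, norm_delta, sorted by norm_delta
#'   ascending (T2-preferring genes first). Skipped genes are recorded in
#'   `attr(, "skipped")`.
#' @export
per_gene_delta_lnl <- function(genes, t1, t2, model,
                               mode = c("per-gene-optimized",
                                        "fixed-branch-lengths")) {
  mode <- match.arg(mode)
  genes <- gene_set(genes)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("t1 and t2 must share the same leaf set")
  rows <- list()
  skipped <- character(0)
  for (g in genes) {
    taxa <- intersect(aln_taxa(g), t1$tip.label)
    if (length(taxa) < 4) {
      message("gene '", g$name, "' overlaps fewer than 4 leaves; skipped")
      skipped <- c(skipped, g$name)
      next
    }
    r1 <- ape::keep.tip(t1, taxa)
    r2 <- ape::keep.tip(t2, taxa)
    L <- aln_length(g)
    if (mode == "fixed-branch-lengths") {
      l1 <- site_log_likelihoods(g, r1, model)$total
      l2 <- site_log_likelihoods(g, r2, model)$total
    } else {
      l1 <- optimize_parameters(g, r1, model)$logLik
      l2 <- optimize_parameters(g, r2, model)$logLik
    }
    rows[[length(rows) + 1]] <- data.frame(
      gene = g$name, length = L, lnl1 = l1, lnl2 = l2,
      delta = l1 - l2, norm_delta = (l1 - l2) / L,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no gene overlapped the trees in >= 4 leaves")
  rep <- do.call(rbind, rows)
  rep <- rep[order(rep$norm_delta, rep$gene), , drop = FALSE]
  rownames(rep) <- NULL
  attr(rep, "skipped") <- skipped
  class(rep) <- c("delta_lnl_report", "data.frame")
  rep
}

#' Site-wise log-likelihood difference between two topologies
#'
#' Returns the vector `l_s(T1) - l_s(T2)` over all alignment columns.
#' Branch lengths are, by default, optimized once per topology on the
#' whole alignment and then held fixed during the scan, so the site
#' values sum to the alignment-level delta-lnL. The cumulative sum (for
#' scan plots) is attached as `attr(, "cumulative")`.
#'
#' @param aln Alignment.
#' @param t1,t2 `phylo` topologies sharing one leaf set.
#' @param model An [aa_model()].
#' @param optimize "branches" (default: per-alignment branch-length
#'   optima per tree) or "none" (use the supplied branch lengths).
#' @return Numeric vector of per-site lnL differences with attribute
#'   `cumulative`.
#' @export
per_site_delta_lnl <- function(aln, t1, t2, model,
                               optimize = c("branches", "none")) {
  optimize <- match.arg(optimize)
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("t1 and t2 must share the same leaf set")
  taxa <- intersect(aln_taxa(aln), t1$tip.label)
  if (length(taxa) < 4) stop("alignment overlaps fewer than 4 leaves")
  r1 <- ape::keep.tip(t1, taxa)
  r2 <- ape::keep.tip(t2, taxa)
  if (optimize == "branches") {
    r1 <- optimize_branch_lengths(aln, r1, model)$tree
    r2 <- optimize_branch_lengths(aln, r2, model)$tree
  }
  s1 <- site_log_likelihoods(aln, r1, model)$site
  s2 <- site_log_likelihoods(aln, r2, model)$site
  d <- s1 - s2
  attr(d, "cumulative") <- cumsum(d)
  d
}

#' Rank a per-gene report and flag outlier genes
#'
#' Stable sort by normalized delta-lnL ascending (T2-preferring genes
#' first; ties broken by gene name), extraction of the top N, and
#' z-score flagging of genes whose normalized delta-lnL is unusually far
#' from the across-gene mean.
#'
#' @param report A `delta_lnl_report` from [per_gene_delta_lnl()].
#' @param top_n How many top (most T2-preferring) genes to extract
#'   (larger than the gene count simply returns the full table).
#' @param z_threshold Absolute z-score above which a gene is flagged.
#' @return List with `table` (ranked report with `rank`, `z`, `flagged`
#'   columns) and `top` (the first `top_n` rows).
#' @export
rank_and_flag <- function(report, top_n = 10, z_threshold = 3) {
  stopifnot(is.data.frame(report), nrow(report) >= 1)
  tab <- as.data.frame(report)
  tab <- tab[order(tab$norm_delta, tab$gene), , drop = FALSE]
  tab$rank <- seq_len(nrow(tab))
  s <- sd(tab$norm_delta)
  tab$z <- if (is.na(s) || s == 0) 0 else
    (tab$norm_delta - mean(tab$norm_delta)) / s
  tab$flagged <- abs(tab$z) >= z_threshold
  rownames(tab) <- NULL
  list(table = tab, top = head(tab, min(top_n, nrow(tab))))
}

#' Write a per-gene delta-lnL report as TSV
#'
#' @param report A `delta_lnl_report`.
#' @param path Output path.
#' @export
write_delta_report <- function(report, path) {
  write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
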