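# Supermatrix construction: concatenation of per-gene alignments with
# 1-based inclusive partition ranges (RAxML-style), per-taxon coverage,
# and taxon-deletion that leaves columns untouched.

#' Concatenate gene alignments into a supermatrix
#'
#' Builds one row per taxon in the union of gene taxa (or in a supplied
#' `taxon_universe`); taxa absent from a gene are padded with '-' across
#' that gene's partition. Partitions are recorded in input gene order as
#' 1-based inclusive ranges.
#'
#' @param genes A `gene_set` (or list of `gene_alignment`s).
#' @param taxon_universe Optional character vector; must contain every
#'   taxon occurring in the genes.
#' @return An object of class `supermatrix` with fields `seq` (character
#'   matrix), `partitions` (data.frame gene/start/end), `coverage`
#'   (named percentages in [0, 100]).
#' @export
#' @examples
#' g1 <- gene_alignment("g1", c(A = "MKL", B = "MKI", C = "MRL", D = "MRI"))
#' g2 <- gene_alignment("g2", c(A = "ACDEF", B = "ACDEY", C = "ACNEF", D = "ACNEY"))
#' sm <- concatenate(gene_set(list(g1, g2)))
#' sm$partitions
concatenate <- function(genes, taxon_universe = NULL) {
  genes <- gene_set(genes)
  if (length(genes) < 1) stop("empty gene set")
  all_taxa <- unique(unlist(lapply(genes, aln_taxa)))
  if (!is.null(taxon_universe)) {
    extra <- setdiff(all_taxa, taxon_universe)
    if (length(extra) > 0)
      stop("taxon present in genes but not in the supplied universe: ",
           extra[1])
    taxa <- taxon_universe
  } else taxa <- sort(all_taxa)
  lens <- vapply(genes, aln_length, numeric(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1
  L <- ends[length(ends)]
  seq <- matrix("-", nrow = length(taxa), ncol = L,
                dimnames = list(taxa, NULL))
  for (i in seq_along(genes)) {
    m <- genes[[i]]$seq
    seq[rownames(m), starts[i]:ends[i]] <- m
  }
  partitions <- data.frame(gene = names(genes), start = unname(starts),
                           end = unname(ends), stringsAsFactors = FALSE)
  structure(list(seq = seq, partitions = partitions,
                 coverage = compute_coverage(seq)),
            class = "supermatrix")
}

compute_coverage <- function(seq) {
  miss <- matrix(seq %in% MISSING_CHARS, nrow = nrow(seq))
  cov <- 100 * (1 - rowSums(miss) / ncol(seq))
  names(cov) <- rownames(seq)
  cov
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d positions, %d gene partitions\n",
              nrow(x$seq), ncol(x$seq), nrow(x$partitions)))
  cat(sprintf("Coverage: %.1f-%.1f%% (median %.1f%%)\n",
              min(x$coverage), max(x$coverage),
              stats::median(x$coverage)))
  invisible(x)
}

#' Per-taxon coverage report
#'
#' @param sm A `supermatrix`.
#' @return Data frame with `taxon`, `coverage` (percent of non-missing
#'   cells), and one logical presence column per gene (a taxon is present
#'   in a gene if it has at least one unambiguous residue in the gene's
#'   partition).
#' @export
coverage_table <- function(sm) {
  stopifnot(inherits(sm, "supermatrix"))
  out <- data.frame(taxon = rownames(sm$seq),
                    coverage = unname(sm$coverage),
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(sm$partitions))) {
    cols <- sm$partitions$start[i]:sm$partitions$end[i]
    part <- sm$seq[, cols, drop = FALSE]
    out[[sm$partitions$gene[i]]] <-
      rowSums(matrix(!(part %in% MISSING_CHARS), nrow = nrow(part))) > 0
  }
  out
}

#' Remove taxa from a supermatrix
#'
#' Rows are dropped; columns and partitions are unchanged (constant or
#' all-missing columns are deliberately retained) and coverage is
#' recomputed.
#'
#' @param sm A `supermatrix`.
#' @param remove Character vector of taxon labels to delete (may be
#'   empty, in which case the supermatrix is returned unchanged).
#' @return A `supermatrix` on the surviving taxa (at least 4 required).
#' @export
subset_taxa <- function(sm, remove) {
  stopifnot(inherits(sm, "supermatrix"))
  if (length(remove) == 0) return(sm)
  unknown <- setdiff(remove, rownames(sm$seq))
  if (length(unknown) > 0)
    stop("unknown taxon in removal list: ", unknown[1])
  keep <- setdiff(rownames(sm$seq), remove)
  if (length(keep) < 4)
    stop(sprintf("taxon removal would leave %d taxa; at least 4 are required",
                 length(keep)))
  seq <- sm$seq[keep, , drop = FALSE]
  structure(list(seq = seq, partitions = sm$partitions,
                 coverage = compute_coverage(seq)),
            class = "supermatrix")
}

#' Split a supermatrix back into its gene alignments
#'
#' Inverse of [concatenate()]: cuts the matrix at the recorded partition
#' boundaries and, for each gene, drops taxa that are entirely missing in
#' that partition (the padding added during concatenation).
#'
#' @param sm A `supermatrix`.
#' @param drop_empty_taxa Drop all-missing rows per gene (default TRUE).
#' @return A `gene_set`.
#' @export
split_genes <- function(sm, drop_empty_taxa = TRUE) {
  stopifnot(inherits(sm, "supermatrix"))
  genes <- lapply(seq_len(nrow(sm$partitions)), function(i) {
    cols <- sm$partitions$start[i]:sm$partitions$end[i]
    m <- sm$seq[, cols, drop = FALSE]
    if (drop_empty_taxa) {
      present <- rowSums(matrix(!(m %in% MISSING_CHARS), nrow = nrow(m))) > 0
      m <- m[present, , drop = FALSE]
    }
    gene_alignment(sm$partitions$gene[i], m)
  })
  gene_set(genes)
}

#' Extract one gene's columns from a supermatrix as a gene set subset
#'
#' @param sm A `supermatrix`.
#' @param sites Integer vector of column indices to keep (1-based).
#' @return Character matrix of the selected columns.
#' @export
subset_sites <- function(sm, sites) {
  m <- as_seq_matrix(sm)
  stopifnot(all(sites >= 1), all(sites <= ncol(m)))
  m[, sites, drop = FALSE]
}

#' Write a supermatrix and its partition file
#'
#' Writes the concatenated alignment as FASTA and, optionally, a
#' RAxML-style partition file with lines like `LG, g1 = 1-303`.
#'
#' @param sm A `supermatrix`.
#' @param fasta Path for the FASTA output.
#' @param partitions Optional path for the partition file.
#' @param model_label Model label used in the partition file.
#' @export
write_supermatrix <- function(sm, fasta, partitions = NULL,
                              model_label = "LG") {
  stopifnot(inherits(sm, "supermatrix"))
  write_fasta(sm, fasta)
  if (!is.null(partitions)) {
    lines <- sprintf("%s, %s = %d-%d", model_label, sm$partitions$gene,
                     sm$partitions$start, sm$partitions$end)
    writeLines(lines, partitions)
  }
  invisible(fasta)
}
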