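# Aligned protein data containers. A gene alignment is stored as a
# character matrix (rows = taxa, columns = positions); '-', '?', 'X' and
# the other ambiguity letters are treated as fully missing throughout.

#' Construct a single-gene alignment
#'
#' @param name Gene identifier.
#' @param seqs Either a named character vector of equal-length sequence
#'   strings, or a character matrix (one character per cell) with taxon
#'   rownames.
#' @return An object of class `gene_alignment` with fields `name` and
#'   `seq` (character matrix, taxa x positions).
#' @export
#' @examples
#' g <- gene_alignment("g1", c(A = "MKL-", B = "MKLV"))
#' aln_length(g)
gene_alignment <- function(name, seqs) {
  if (is.matrix(seqs)) {
    m <- seqs
  } else {
    if (is.null(names(seqs)) || any(names(seqs) == ""))
      stop("sequences must be named by taxon")
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1)
      stop(sprintf(
        "ragged alignment in gene '%s': row '%s' has length %d, expected %d",
        name, names(seqs)[which(lens != lens[1])[1]],
        lens[lens != lens[1]][1], lens[1]))
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
  }
  if (is.null(rownames(m))) stop("alignment matrix must have taxon rownames")
  if (anyDuplicated(rownames(m)))
    stop(sprintf("duplicate taxon label '%s' in gene '%s'",
                 rownames(m)[duplicated(rownames(m))][1], name))
  if (ncol(m) < 1) stop(sprintf("gene '%s' has zero alignment columns", name))
  m[] <- toupper(m)
  bad <- setdiff(unique(as.vector(m)), c(AA_STATES, MISSING_CHARS))
  if (length(bad) > 0)
    stop(sprintf("invalid characters in gene '%s': %s", name,
                 paste(bad, collapse = " ")))
  structure(list(name = name, seq = m), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("Gene alignment '%s': %d taxa x %d positions\n",
              x$name, nrow(x$seq), ncol(x$seq)))
  invisible(x)
}

#' Alignment length (number of columns)
#' @param x A `gene_alignment`, `supermatrix`, or character matrix.
#' @export
aln_length <- function(x) ncol(as_seq_matrix(x))

#' Taxon labels of an alignment
#' @param x A `gene_alignment`, `supermatrix`, or character matrix.
#' @export
aln_taxa <- function(x) rownames(as_seq_matrix(x))

# Coerce the accepted alignment representations to a character matrix.
as_seq_matrix <- function(x) {
  if (inherits(x, "gene_alignment")) return(x$seq)
  if (inherits(x, "supermatrix")) return(x$seq)
  if (is.matrix(x) && is.character(x)) return(x)
  if (is.character(x) && !is.null(names(x)))
    return(gene_alignment("aln", x)$seq)
  stop("cannot interpret object of class ", paste(class(x), collapse = "/"),
       " as an alignment")
}

#' Bundle gene alignments into a named set
#'
#' @param genes List of `gene_alignment` objects (or a single one).
#' @return Named list of class `gene_set`.
#' @export
gene_set <- function(genes) {
  if (inherits(genes, "gene_alignment")) genes <- list(genes)
  if (inherits(genes, "gene_set")) return(genes)
  stopifnot(is.list(genes))
  if (length(genes) < 1) stop("empty gene set")
  ok <- vapply(genes, inherits, logical(1), "gene_alignment")
  if (!all(ok)) stop("all elements must be gene_alignment objects")
  nm <- vapply(genes, `[[`, character(1), "name")
  if (anyDuplicated(nm))
    stop("duplicate gene names: ", paste(unique(nm[duplicated(nm)]), collapse = ", "))
  structure(setNames(genes, nm), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  lens <- vapply(x, aln_length, numeric(1))
  cat(sprintf("Gene set: %d genes, %d-%d positions each, %d taxa total\n",
              length(x), min(lens), max(lens),
              length(unique(unlist(lapply(x, aln_taxa))))))
  invisible(x)
}

#' @export
`[.gene_set` <- function(x, i) {
  structure(NextMethod(), class = "gene_set")
}

#' Load aligned FASTA files as a gene set
#'
#' Each file becomes one gene; the gene name is the file name without its
#' extension. Sequences are upper-cased and validated against the amino
#' acid alphabet plus the missing/ambiguity characters. Ragged rows,
#' duplicate labels within a file, and empty files are errors.
#'
#' @param paths Character vector of FASTA file paths.
#' @return A `gene_set`.
#' @export
load_gene_alignments <- function(paths) {
  stopifnot(length(paths) >= 1)
  genes <- lapply(paths, function(p) {
    if (!file.exists(p)) stop("file not found: ", p)
    nm <- sub("\\.[^.]*$", "", basename(p))
    recs <- read_fasta_file(p)
    if (length(recs) == 0) stop("empty FASTA file: ", p)
    if (anyDuplicated(names(recs)))
      stop(sprintf("duplicate taxon label '%s' in file %s",
                   names(recs)[duplicated(names(recs))][1], p))
    lens <- nchar(recs)
    if (length(unique(lens)) != 1) {
      i <- which(lens != lens[1])[1]
      stop(sprintf("ragged alignment in file %s: row '%s' has length %d, expected %d",
                   p, names(recs)[i], lens[i], lens[1]))
    }
    gene_alignment(nm, recs)
  })
  gene_set(genes)
}

# Minimal FASTA reader returning a named character vector of sequences.
read_fasta_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(character(0))
  hdr <- grepl("^>", lines)
  if (!hdr[1]) stop("not a FASTA file (no leading '>'): ", path)
  id <- cumsum(hdr)
  labs <- sub("^>\\s*", "", lines[hdr])
  labs <- sub("\\s.*$", "", labs)
  seqs <- vapply(split(lines[!hdr], id[!hdr]), paste0, character(1), collapse = "")
  out <- character(sum(hdr))
  names(out) <- labs
  out[as.integer(names(seqs))] <- seqs
  names(out) <- labs
  out
}

#' Write an alignment to FASTA
#'
#' @param x Alignment (gene alignment, supermatrix, or character matrix).
#' @param path Output file path.
#' @param width Line width for sequence wrapping.
#' @export
write_fasta <- function(x, path, width = 60) {
  m <- as_seq_matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m))) {
    s <- paste0(m[i, ], collapse = "")
    chunks <- substring(s, seq(1, nchar(s), width),
                        pmin(seq(1, nchar(s), width) + width - 1, nchar(s)))
    writeLines(c(paste0(">", rownames(m)[i]), chunks), con)
  }
  invisible(path)
}

# Integer-encode an alignment: 1..20 for amino acids (AA_STATES order),
# NA for missing/ambiguous characters.
encode_states <- function(x) {
  m <- as_seq_matrix(x)
  s <- match(m, AA_STATES)
  dim(s) <- dim(m)
  rownames(s) <- rownames(m)
  s
}

# Collapse identical columns into site patterns. Returns the pattern
# matrix (taxa x n_patterns), pattern weights, and the site -> pattern map.
compress_patterns <- function(states) {
  n <- nrow(states)
  s0 <- states
  s0[is.na(s0)] <- 0L
  key <- s0[1, ]
  if (n > 1) for (i in 2:n) key <- paste(key, s0[i, ], sep = ".")
  idx <- match(key, unique(key))
  first <- which(!duplicated(key))
  list(pat = states[, first, drop = FALSE],
       w = as.numeric(tabulate(idx, nbins = length(first))),
       site_index = idx)
}
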