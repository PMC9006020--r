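# Constraint-based screening of single-gene alignments: build a quick
# gene tree, bootstrap it, and flag bipartitions that are both strongly
# supported and incompatible with any well-established clade.

#' Define clade constraints for gene screening
#'
#' @param clades Named list of taxon-label vectors (each >= 2 members),
#'   e.g. the major eukaryotic assemblages.
#' @param tau Support threshold in (0, 1] above which a conflicting
#'   bipartition triggers exclusion (default 0.95).
#' @return Object of class `clade_constraints`.
#' @export
clade_constraints <- function(clades, tau = 0.95) {
  stopifnot(is.list(clades), length(clades) >= 1)
  if (is.null(names(clades)) || any(names(clades) == ""))
    stop("clades must be named")
  sizes <- vapply(clades, length, integer(1))
  if (any(sizes < 2)) stop("each clade must have >= 2 members")
  if (!is.numeric(tau) || tau <= 0 || tau > 1)
    stop("tau must be in (0, 1]")
  structure(list(clades = clades, tau = tau), class = "clade_constraints")
}

#' Read clade constraints from a YAML config file
#'
#' Expected structure: a top-level `tau` scalar and a `clades` map from
#' clade label to a list of taxon labels.
#'
#' @param path YAML file path.
#' @return A [clade_constraints()] object.
#' @export
read_clade_constraints <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$clades)) stop("config must contain a 'clades' map")
  clade_constraints(lapply(cfg$clades, as.character),
                    tau = cfg$tau %||% 0.95)
}

#' Screen one gene alignment against clade constraints
#'
#' Builds a quick gene tree (NJ on pairwise ML distances under a
#' Poisson + gamma model, refined by NNI under LG + gamma), bootstraps it
#' (site resampling, quick trees), and collects every bipartition whose
#' bootstrap frequency reaches `tau` and which is incompatible with any
#' constraint clade restricted to the gene's taxa. The verdict is
#' "exclude" iff at least one such bipartition exists. Genes overlapping
#' the constraint universe in fewer than 4 taxa are reported
#' "unscreenable" rather than raising an error.
#'
#' @param g A `gene_alignment`.
#' @param constraints A [clade_constraints()] object.
#' @param engine List of quick-tree settings: `n_boot` (bootstrap
#'   replicates, default 100), `model` (an [aa_model()], default
#'   LG + G4), `dist_model` (distance model, default Poisson + G4),
#'   `control` (a [search_control()], default [fast_search()]).
#' @param seed Integer base seed; replicate r uses `seed + r`.
#' @return List with `gene`, `status` ("screened"/"unscreenable"),
#'   `verdict` ("keep"/"exclude"/NA), and `conflicts` (data.frame with
#'   clade, split, support).
#' @export
screen_gene <- function(g, constraints, engine = list(), seed = 1) {
  stopifnot(inherits(g, "gene_alignment"),
            inherits(constraints, "clade_constraints"))
  n_boot <- engine$n_boot %||% 100
  model <- engine$model %||% aa_model("LG", k = 4, alpha = 1)
  dist_model <- engine$dist_model %||% aa_model("Poisson", k = 4, alpha = 1)
  control <- engine$control %||% fast_search()
  taxa <- aln_taxa(g)
  universe <- unique(unlist(constraints$clades))
  empty_report <- data.frame(clade = character(0), split = character(0),
                             support = numeric(0), stringsAsFactors = FALSE)
  if (length(intersect(taxa, universe)) < 4 || length(taxa) < 4) {
    return(list(gene = g$name, status = "unscreenable", verdict = NA,
                conflicts = empty_report))
  }
  quick_tree <- function(aln, sd) {
    start <- ape::nj(ml_pairwise_distances(aln, dist_model))
    ml_tree_search(aln, model, start = start, seed = sd,
                   control = control)$tree
  }
  # bootstrap frequency of every bipartition seen in replicate trees
  key_tab <- new.env(parent = emptyenv())
  side_tab <- new.env(parent = emptyenv())
  for (r in seq_len(n_boot)) {
    rep_aln <- bootstrap_alignment(g, seed = seed + r)
    bs <- bipartition_set(quick_tree(rep_aln, seed + r))
    for (i in seq_along(bs$keys)) {
      key <- bs$keys[i]
      key_tab[[key]] <- (key_tab[[key]] %||% 0) + 1
      side_tab[[key]] <- bs$sides[[i]]
    }
  }
  conflicts <- empty_report
  for (key in ls(key_tab)) {
    supp <- key_tab[[key]] / n_boot
    if (supp < constraints$tau) next
    side <- side_tab[[key]]
    for (cl_name in names(constraints$clades)) {
      cl <- intersect(constraints$clades[[cl_name]], taxa)
      if (length(cl) < 2 || length(setdiff(taxa, cl)) < 2) next
      if (split_conflicts_clade(side, cl, taxa)) {
        conflicts <- rbind(conflicts, data.frame(
          clade = cl_name, split = paste(side, collapse = ","),
          support = supp, stringsAsFactors = FALSE))
      }
    }
  }
  list(gene = g$name, status = "screened",
       verdict = if (nrow(conflicts) > 0) "exclude" else "keep",
       conflicts = conflicts)
}

#' Screen a whole gene set
#'
#' Applies [screen_gene()] to every gene; per-gene seeds are offset by
#' 1000 so single genes can be re-screened in isolation.
#'
#' @inheritParams screen_gene
#' @param genes A `gene_set`.
#' @return List with `verdicts` (data.frame gene/status/verdict),
#'   `reports` (per-gene conflict tables), and `keep` (a `gene_set` of
#'   the retained genes).
#' @export
screen_genes <- function(genes, constraints, engine = list(), seed = 1) {
  genes <- gene_set(genes)
  res <- lapply(seq_along(genes), function(i)
    screen_gene(genes[[i]], constraints, engine, seed = seed + 1000 * (i - 1)))
  verdicts <- data.frame(
    gene = vapply(res, `[[`, character(1), "gene"),
    status = vapply(res, `[[`, character(1), "status"),
    verdict = vapply(res, function(r) as.character(r$verdict %||% NA),
                     character(1)),
    stringsAsFactors = FALSE)
  keep_idx <- which(verdicts$verdict %in% "keep" |
                      verdicts$status == "unscreenable")
  list(verdicts = verdicts,
       reports = setNames(lapply(res, `[[`, "conflicts"), verdicts$gene),
       keep = if (length(keep_idx) > 0) genes[keep_idx] else NULL)
}
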