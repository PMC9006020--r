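# Perturbation designs over the likelihood engine: nonparametric
# bootstrap, fast-evolving-position-removal (FPR) series, random-gene-
# sampling (RGS) series, and taxon-deletion experiments.
#
# Seed schedule (all seeds are plain integer offsets from the base seed,
# so any single replicate can be reproduced in isolation):
#   bootstrap_support: replicate i          -> seed + i
#   fpr_series:        fraction index i     -> seed + 10000 * (i - 1)
#   rgs_series:        size i, replicate j  -> seed + 10000*(i-1) + 100*(j-1)
#                      (gene draw at that seed; bootstraps at +1 .. +n_boot)
#   taxon_deletion:    scheme index i       -> seed + 1000000 * (i - 1)

#' Felsenstein bootstrap resampling of alignment columns
#'
#' Draws L columns uniformly with replacement; deterministic per seed.
#'
#' @param aln Alignment (gene alignment, supermatrix, character matrix).
#' @param seed Integer seed.
#' @return Object of the same kind as the input with resampled columns
#'   (partitions/coverage of a supermatrix are not carried over; the
#'   result is a plain alignment of class `gene_alignment`).
#' @export
bootstrap_alignment <- function(aln, seed) {
  m <- as_seq_matrix(aln)
  idx <- with_seed(seed, sample.int(ncol(m), ncol(m), replace = TRUE))
  nm <- if (inherits(aln, "gene_alignment")) aln$name else "bootstrap"
  gene_alignment(nm, m[, idx, drop = FALSE])
}

#' Bootstrap clade support
#'
#' For each replicate: resample columns, run [ml_tree_search()], and
#' record which monitored clades appear as bipartitions. Replicate i uses
#' seed `seed + i`, so runs are reproducible replicate by replicate.
#' Clades that are not evaluable on the alignment's taxa (fewer than two
#' members or complement members) get `NA` support.
#'
#' @param aln Alignment.
#' @param model An [aa_model()].
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param clades Named list of taxon-label vectors to monitor.
#' @param seed Integer base seed.
#' @param control [search_control()] settings (default [fast_search()]).
#' @param start Starting tree for the replicate searches: "nj" (default,
#'   independent neighbor-joining start per replicate) or a `phylo`
#'   guide tree, typically the full-data ML tree (the rapid-bootstrap
#'   convention; useful when hill climbing from NJ is prone to local
#'   optima).
#' @return List with `support` (named percentages, NA if not evaluable),
#'   `table` (clade x replicate presence as 0/100), `trees` (replicate
#'   trees).
#' @export
bootstrap_support <- function(aln, model, n_reps = 100, clades, seed = 1,
                              control = fast_search(), start = "nj") {
  stopifnot(n_reps >= 1, is.list(clades), length(clades) >= 1,
            !is.null(names(clades)))
  taxa <- aln_taxa(aln)
  evaluable <- vapply(clades, function(cl) {
    cl <- intersect(cl, taxa)
    length(cl) >= 2 && length(setdiff(taxa, cl)) >= 2
  }, logical(1))
  trees <- vector("list", n_reps)
  pres <- matrix(NA_real_, n_reps, length(clades),
                 dimnames = list(NULL, names(clades)))
  for (i in seq_len(n_reps)) {
    rep_aln <- bootstrap_alignment(aln, seed = seed + i)
    trees[[i]] <- ml_tree_search(rep_aln, model, start = start,
                                 seed = seed + i,
                                 control = control)$tree
    keys <- bipartition_set(trees[[i]])$keys
    for (j in which(evaluable)) {
      cl <- intersect(clades[[j]], taxa)
      pres[i, j] <- 100 * (canonical_split_key(cl, taxa) %in% keys)
    }
  }
  support <- colMeans(pres)
  tab <- data.frame(
    clade = rep(names(clades), each = n_reps),
    replicate = rep(seq_len(n_reps), length(clades)),
    support = as.vector(pres),
    stringsAsFactors = FALSE)
  list(support = support, table = tab, trees = trees)
}

#' Plan for a fast-evolving-position-removal (FPR) series
#'
#' @param fractions Strictly increasing removal fractions in [0, 1);
#'   default `c(0, 0.2, 0.4, 0.6, 0.8)`.
#' @param n_boot Bootstrap replicates per fraction.
#' @param rank_tree,rank_model Optional tree/model used only for the site
#'   -rate ranking (the ranking model needs `k >= 2`); defaults to the
#'   tree/model of the series itself.
#' @param ranking Optional precomputed site ranking (column indices,
#'   fastest first), e.g. a [estimate_site_rates()] ranking computed on a
#'   richer taxon set before taxon deletion. Overrides
#'   `rank_tree`/`rank_model`.
#' @param control [search_control()] for the bootstrap searches.
#' @return Object of class `fpr_plan`.
#' @export
fpr_plan <- function(fractions = c(0, 0.2, 0.4, 0.6, 0.8), n_boot = 100,
                     rank_tree = NULL, rank_model = NULL, ranking = NULL,
                     control = fast_search()) {
  stopifnot(is.numeric(fractions), length(fractions) >= 1)
  if (any(fractions < 0 | fractions >= 1))
    stop("removal fractions must lie in [0, 1)")
  if (any(diff(fractions) <= 0))
    stop("removal fractions must be strictly increasing")
  structure(list(fractions = fractions, n_boot = n_boot,
                 rank_tree = rank_tree, rank_model = rank_model,
                 ranking = ranking, control = control),
            class = "fpr_plan")
}

#' Fast-evolving-position-removal support series
#'
#' Ranks all sites once by posterior-mean rate over the supplied tree,
#' then, for each removal fraction f, deletes the `round(f * L)` fastest
#' sites (ties broken toward the lower column index) and runs a bootstrap
#' support analysis on the truncated alignment. Removal sets are nested
#' across fractions. The f = 0 row reproduces [bootstrap_support()] on
#' the full alignment bit for bit (same seeds).
#'
#' @param aln Alignment.
#' @param tree Guide tree (typically the ML tree) used for site-rate
#'   ranking.
#' @param model Analysis model for the bootstrap searches.
#' @param plan An [fpr_plan()].
#' @param clades Named list of monitored clades.
#' @param seed Integer base seed.
#' @return A `support_series` data.frame with columns scheme, axis,
#'   condition (fraction), clade, replicate, support.
#' @export
fpr_series <- function(aln, tree, model, plan = fpr_plan(), clades,
                       seed = 1) {
  stopifnot(inherits(plan, "fpr_plan"))
  m <- as_seq_matrix(aln)
  L <- ncol(m)
  if (!is.null(plan$ranking)) {
    ranking <- plan$ranking
    if (length(ranking) != L)
      stop("precomputed ranking length does not match the alignment")
  } else {
    rank_model <- plan$rank_model %||% model
    if (rank_model$k < 2)
      stop("site-rate ranking requires a model with k >= 2 ",
           "(supply plan$rank_model)")
    rank_tree <- plan$rank_tree %||% tree
    ranking <- estimate_site_rates(m, rank_tree, rank_model)$ranking
  }
  out <- list()
  for (i in seq_along(plan$fractions)) {
    f <- plan$fractions[i]
    n_rm <- round(f * L)
    keep <- if (n_rm > 0) sort(setdiff(seq_len(L), ranking[seq_len(n_rm)]))
            else seq_len(L)
    bs <- bootstrap_support(m[, keep, drop = FALSE], model,
                            n_reps = plan$n_boot, clades = clades,
                            seed = seed + 10000 * (i - 1),
                            control = plan$control)
    tab <- bs$table
    tab$condition <- f
    out[[i]] <- tab
  }
  res <- do.call(rbind, out)
  res <- data.frame(scheme = "baseline", axis = "fpr",
                    condition = res$condition, clade = res$clade,
                    replicate = res$replicate, support = res$support,
                    stringsAsFactors = FALSE)
  class(res) <- c("support_series", "data.frame")
  res
}

#' Plan for a random-gene-sampling (RGS) series
#'
#' @param sizes Gene-subsample sizes (without replacement).
#' @param reps Replicate count per size (recycled if scalar); defaults to
#'   the classic 50/50/10/10 design for sizes 50/100/150/200.
#' @param n_boot Bootstrap replicates per subsampled concatenation.
#' @param control [search_control()] for the bootstrap searches.
#' @return Object of class `rgs_plan`.
#' @export
rgs_plan <- function(sizes = c(50, 100, 150, 200),
                     reps = c(50, 50, 10, 10), n_boot = 100,
                     control = fast_search()) {
  reps <- rep_len(reps, length(sizes))
  stopifnot(all(sizes >= 1), all(reps >= 1))
  structure(list(sizes = sizes, reps = reps, n_boot = n_boot,
                 control = control),
            class = "rgs_plan")
}

#' Random-gene-sampling support series
#'
#' For each subsample size and replicate, draws that many genes without
#' replacement (keeping input gene order), concatenates them, and records
#' bootstrap clade support. The replicate-level support values form the
#' box-plot-ready distribution per size.
#'
#' @param genes A `gene_set`.
#' @param model Analysis model.
#' @param plan An [rgs_plan()].
#' @param clades Named list of monitored clades.
#' @param seed Integer base seed.
#' @return A `support_series` data.frame (condition = gene count,
#'   replicate = subsample replicate, support = bootstrap %).
#' @export
rgs_series <- function(genes, model, plan = rgs_plan(), clades, seed = 1) {
  stopifnot(inherits(plan, "rgs_plan"))
  genes <- gene_set(genes)
  if (any(plan$sizes > length(genes)))
    stop("subsample size exceeds the number of genes")
  out <- list()
  draws <- list()
  for (i in seq_along(plan$sizes)) {
    size <- plan$sizes[i]
    for (j in seq_len(plan$reps[i])) {
      s_ij <- seed + 10000 * (i - 1) + 100 * (j - 1)
      pick <- sort(with_seed(s_ij,
                             sample.int(length(genes), size,
                                        replace = FALSE)))
      draws[[length(draws) + 1]] <- data.frame(
        condition = size, replicate = j, gene = names(genes)[pick],
        stringsAsFactors = FALSE)
      sub <- concatenate(genes[pick])
      bs <- bootstrap_support(sub, model, n_reps = plan$n_boot,
                              clades = clades, seed = s_ij,
                              control = plan$control)
      out[[length(out) + 1]] <- data.frame(
        scheme = "baseline", axis = "rgs", condition = size,
        clade = names(bs$support), replicate = j,
        support = unname(bs$support), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "draws") <- do.call(rbind, draws)
  class(res) <- c("support_series", "data.frame")
  res
}

#' Plain bootstrap plan (for taxon-deletion baselines)
#'
#' @param n_reps Bootstrap replicates.
#' @param control [search_control()] settings.
#' @export
boot_plan <- function(n_reps = 100, control = fast_search()) {
  structure(list(n_reps = n_reps, control = control), class = "boot_plan")
}

#' Taxon-deletion experiment series
#'
#' For each named removal scheme, deletes the listed taxa from every
#' gene, re-runs the downstream design (plain bootstrap, FPR, or RGS) on
#' the reduced data, and labels the resulting rows by scheme. Monitored
#' clades are restricted to the surviving taxa; a clade whose restriction
#' (or its complement) drops below two members is reported with `NA`
#' support ("not evaluable") rather than 0. An empty scheme reproduces
#' the baseline run. Genes left with fewer than 4 taxa are dropped from
#' that scheme's gene set.
#'
#' @param genes A `gene_set`.
#' @param model Analysis model.
#' @param schemes Named list of taxon-label vectors to remove (may
#'   include `character(0)` for a baseline).
#' @param downstream A [boot_plan()], [fpr_plan()], or [rgs_plan()].
#' @param clades Named list of monitored clades.
#' @param seed Integer base seed; scheme i runs at
#'   `seed + 1e6 * (i - 1)`.
#' @return A `support_series` data.frame with the scheme column filled.
#' @export
taxon_deletion_series <- function(genes, model, schemes, downstream,
                                  clades, seed = 1) {
  genes <- gene_set(genes)
  stopifnot(is.list(schemes), !is.null(names(schemes)))
  out <- list()
  for (i in seq_along(schemes)) {
    rm_taxa <- schemes[[i]]
    sub_genes <- lapply(genes, function(g) {
      keep <- setdiff(aln_taxa(g), rm_taxa)
      if (length(keep) < 4) return(NULL)
      gene_alignment(g$name, g$seq[keep, , drop = FALSE])
    })
    sub_genes <- sub_genes[!vapply(sub_genes, is.null, logical(1))]
    if (length(sub_genes) == 0)
      stop("scheme '", names(schemes)[i], "' leaves no usable genes")
    sub_genes <- gene_set(unname(sub_genes))
    s_i <- seed + 1000000 * (i - 1)
    res <- if (inherits(downstream, "rgs_plan")) {
      rgs_series(sub_genes, model, downstream, clades, seed = s_i)
    } else if (inherits(downstream, "fpr_plan")) {
      sm <- concatenate(sub_genes)
      rank_model <- downstream$rank_model %||% model
      guide <- if (!is.null(downstream$rank_tree)) {
        ape::keep.tip(downstream$rank_tree,
                      intersect(downstream$rank_tree$tip.label,
                                rownames(sm$seq)))
      } else {
        ml_tree_search(sm, rank_model, control = downstream$control)$tree
      }
      plan_i <- downstream
      plan_i$rank_tree <- NULL
      fpr_series(sm, guide, model, plan_i, clades, seed = s_i)
    } else if (inherits(downstream, "boot_plan")) {
      sm <- concatenate(sub_genes)
      bs <- bootstrap_support(sm, model, n_reps = downstream$n_reps,
                              clades = clades, seed = s_i,
                              control = downstream$control)
      tab <- bs$table
      data.frame(scheme = "baseline", axis = "bootstrap", condition = 0,
                 clade = tab$clade, replicate = tab$replicate,
                 support = tab$support, stringsAsFactors = FALSE)
    } else stop("unsupported downstream plan of class ",
                paste(class(downstream), collapse = "/"))
    res$scheme <- names(schemes)[i]
    out[[i]] <- as.data.frame(res)
  }
  res <- do.call(rbind, out)
  class(res) <- c("support_series", "data.frame")
  res
}

#' Summarize a support series (mean support per cell)
#'
#' @param x A `support_series` data.frame.
#' @return Data frame with one row per (scheme, condition, clade) and the
#'   mean support over replicates (NA replicates propagate as NA).
#' @export
support_summary <- function(x) {
  stopifnot(is.data.frame(x))
  agg <- stats::aggregate(support ~ scheme + axis + condition + clade,
                          data = x, FUN = mean, na.action = NULL)
  agg[order(agg$scheme, agg$condition, agg$clade), , drop = FALSE]
}

#' Write a support series as TSV
#'
#' @param x A `support_series` data.frame.
#' @param path Output path.
#' @export
write_support_series <- function(x, path) {
  write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
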