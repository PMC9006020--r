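# Synthetic-data generation with known ground truth: sequence evolution
# along a tree under a reversible amino-acid model with discrete-gamma
# site rates, long-branch-attraction geometries with breaker taxa,
# chimeric (two-history) genes, and coverage-profile missingness.

#' Simulate an alignment along a tree
#'
#' The root state of every column is drawn from the model's stationary
#' frequencies; states evolve along branches with transition matrices
#' `P(t r_s)` where the per-site gamma category (hence rate `r_s`) is
#' drawn once per site. Deterministic for a fixed seed.
#'
#' @param tree `phylo` with branch lengths (rooted or unrooted).
#' @param model An [aa_model()].
#' @param n_sites Number of columns (>= 1).
#' @param seed Integer seed.
#' @param name Gene name for the returned alignment.
#' @return List with `alignment` (a `gene_alignment`) and `truth` (list
#'   with per-site `categories`, true relative `rates`, and the `tree`).
#' @export
simulate_alignment <- function(tree, model, n_sites, seed, name = "sim") {
  stopifnot(inherits(tree, "phylo"), inherits(model, "aa_model"),
            n_sites >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and >= 0")
  tr <- stats::reorder(tree, "postorder")
  ntip <- length(tr$tip.label)
  M <- ntip + tr$Nnode
  E <- tr$edge
  root <- E[nrow(E), 1]
  k <- model$k
  out <- with_seed(seed, {
    cats <- sample.int(k, n_sites, replace = TRUE)
    node_state <- vector("list", M)
    node_state[[root]] <- sample.int(20, n_sites, replace = TRUE,
                                     prob = model$freq)
    for (e in rev(seq_len(nrow(E)))) {   # preorder
      p <- E[e, 1]; ch <- E[e, 2]
      ps <- node_state[[p]]
      cs <- integer(n_sites)
      for (m in seq_len(k)) {
        in_cat <- which(cats == m)
        if (length(in_cat) == 0) next
        P <- transition_matrix(model, tr$edge.length[e], model$rates[m])
        for (a in unique(ps[in_cat])) {
          idx <- in_cat[ps[in_cat] == a]
          cs[idx] <- sample.int(20, length(idx), replace = TRUE,
                                prob = P[a, ])
        }
      }
      node_state[[ch]] <- cs
    }
    list(node_state = node_state, cats = cats)
  })
  seqm <- matrix("", ntip, n_sites, dimnames = list(tr$tip.label, NULL))
  for (i in seq_len(ntip)) seqm[i, ] <- AA_STATES[out$node_state[[i]]]
  list(alignment = gene_alignment(name, seqm),
       truth = list(categories = out$cats, rates = model$rates[out$cats],
                    tree = tree))
}

#' Simulate a set of genes on one tree
#'
#' Convenience wrapper: gene i is simulated with seed `seed + i`.
#'
#' @inheritParams simulate_alignment
#' @param n_genes Number of genes.
#' @param gene_length Columns per gene (scalar or vector recycled).
#' @param prefix Gene-name prefix.
#' @return List with `genes` (a `gene_set`) and `truth` (per-gene list).
#' @export
simulate_genes <- function(tree, model, n_genes, gene_length, seed,
                           prefix = "g") {
  lens <- rep_len(gene_length, n_genes)
  sims <- lapply(seq_len(n_genes), function(i)
    simulate_alignment(tree, model, lens[i], seed = seed + i,
                       name = sprintf("%s%03d", prefix, i)))
  list(genes = gene_set(lapply(sims, `[[`, "alignment")),
       truth = lapply(sims, `[[`, "truth"))
}

#' Long-branch-attraction scenario specification
#'
#' Describes the classic geometry: two long terminal branches on opposite
#' sides of a short internal branch, each paired with a short-branch
#' "breaker" sister, plus one outgroup-like taxon per side. Sequences are
#' simulated under strong gamma rate heterogeneity (small alpha); the
#' intended analysis mis-specification that elicits the artefactual
#' long-branch clade is a rate-homogeneous (k = 1) inference model.
#'
#' @param lambda_long Length of the two long terminal branches.
#' @param lambda_int Length of the short internal branch separating them.
#' @param lambda_breaker Terminal branch length of the breaker taxa.
#' @param lambda_stem Stem length of each (long, breaker) cherry.
#' @param lambda_out Terminal branch length of the two outer taxa.
#' @param alpha Gamma shape used for simulation (strong heterogeneity).
#' @param k Gamma categories of the simulation model.
#' @param model_name Substitution model for simulation.
#' @param n_sites Columns per gene.
#' @param n_genes Number of genes.
#' @param seed Integer seed.
#' @return Object of class `lba_scenario`.
#' @export
lba_scenario <- function(lambda_long = 1.5, lambda_int = 0.02,
                         lambda_breaker = 0.1, lambda_stem = 0.15,
                         lambda_out = 1.5, alpha = 0.3, k = 4,
                         model_name = "LG", n_sites = 5000, n_genes = 1,
                         seed = 1) {
  stopifnot(lambda_long > 0, lambda_int >= 0, alpha > 0, n_sites >= 1)
  structure(as.list(environment()), class = "lba_scenario")
}

#' Simulate a long-branch-attraction test case
#'
#' Simulates genes on the true tree
#' `((longA,breakA),outA,((longB,breakB),outB))` with the long branches
#' `longA`/`longB` separated by the short internal branch. The returned
#' clade definitions name the true cherries, the artefactual long-branch
#' pair, and the breaker taxa whose deletion exposes the artefact under a
#' rate-homogeneous analysis.
#'
#' @param spec An [lba_scenario()].
#' @return List with `genes`, `tree` (true tree), `model` (simulation
#'   model), `clades` (true_a, true_b, artefact), `breakers`, `truth`.
#' @export
simulate_lba_case <- function(spec = lba_scenario()) {
  stopifnot(inherits(spec, "lba_scenario"))
  nwk <- sprintf(
    "((longA:%g,breakA:%g):%g,outA:%g,((longB:%g,breakB:%g):%g,outB:%g):%g);",
    spec$lambda_long, spec$lambda_breaker, spec$lambda_stem,
    spec$lambda_out, spec$lambda_long, spec$lambda_breaker,
    spec$lambda_stem, spec$lambda_out, spec$lambda_int)
  tree <- ape::read.tree(text = nwk)
  need <- c("longA", "longB")
  if (!all(need %in% tree$tip.label))
    stop("designated long-branch leaves are missing from the base tree")
  model <- aa_model(spec$model_name, k = spec$k, alpha = spec$alpha)
  sims <- simulate_genes(tree, model, spec$n_genes, spec$n_sites,
                         seed = spec$seed, prefix = "lba")
  list(genes = sims$genes, tree = tree, model = model,
       clades = list(true_a = c("longA", "breakA"),
                     true_b = c("longB", "breakB"),
                     artefact = c("longA", "longB")),
       breakers = c("breakA", "breakB"),
       truth = sims$truth)
}

#' Simulate a chimeric (two-history) gene
#'
#' A fraction `c` of the columns (`ceiling(c * length)`) evolves on the
#' donor tree, the rest on the host tree. The "contiguous" layout puts
#' the donor block at the end of the gene; "interleaved" spreads donor
#' columns evenly across it. Segment coordinates tiling 1..length are
#' recorded in the ground truth.
#'
#' @param host_tree,donor_tree `phylo` trees sharing one leaf set.
#' @param length Gene length (columns).
#' @param fraction Chimeric fraction c in [0, 1].
#' @param layout "contiguous" or "interleaved".
#' @param model An [aa_model()].
#' @param seed Integer seed (host columns at `seed`, donor at
#'   `seed + 1`).
#' @param name Gene name.
#' @return List with `alignment` and `truth` (per-site `source` factor,
#'   `segments` data.frame with start/end/source, donor site indices).
#' @export
simulate_chimeric_gene <- function(host_tree, donor_tree, length,
                                   fraction, layout = c("contiguous",
                                                        "interleaved"),
                                   model, seed, name = "chimera") {
  layout <- match.arg(layout)
  if (!setequal(host_tree$tip.label, donor_tree$tip.label))
    stop("host and donor trees must share the same leaf set")
  stopifnot(fraction >= 0, fraction <= 1, length >= 1)
  n_donor <- ceiling(fraction * length)
  donor_idx <- if (n_donor == 0) integer(0)
  else if (layout == "contiguous") (length - n_donor + 1):length
  else {
    idx <- unique(round(seq(1, length, length.out = n_donor)))
    extra <- setdiff(seq_len(length), idx)
    sort(c(idx, extra[seq_len(n_donor - base::length(idx))]))
  }
  source <- rep("host", length)
  source[donor_idx] <- "donor"
  taxa <- sort(host_tree$tip.label)
  seqm <- matrix("", base::length(taxa), length,
                 dimnames = list(taxa, NULL))
  host_n <- length - n_donor
  truth_host <- NULL
  truth_donor <- NULL
  if (host_n > 0) {
    h <- simulate_alignment(host_tree, model, host_n, seed = seed)
    seqm[, which(source == "host")] <- h$alignment$seq[taxa, , drop = FALSE]
    truth_host <- h$truth
  }
  if (n_donor > 0) {
    d <- simulate_alignment(donor_tree, model, n_donor, seed = seed + 1)
    seqm[, donor_idx] <- d$alignment$seq[taxa, , drop = FALSE]
    truth_donor <- d$truth
  }
  runs <- rle(source)
  ends <- cumsum(runs$lengths)
  segments <- data.frame(start = ends - runs$lengths + 1, end = ends,
                         source = runs$values, stringsAsFactors = FALSE)
  list(alignment = gene_alignment(name, seqm),
       truth = list(source = source, segments = segments,
                    donor_sites = donor_idx,
                    host = truth_host, donor = truth_donor))
}

#' Chimeric-gene (endosymbiotic-transfer) scenario specification
#'
#' Two 11-taxon topologies identical except for the position of the
#' taxon `M`: the host tree attaches M next to the outgroup pair across
#' a very short internal edge (`host_edge`; the vertical placement is
#' nearly unsupported), the donor tree attaches M as sister to the
#' `R1`/`R2` pair across a modest internal edge (`donor_edge`). Three
#' further decoy pairs (`G`, `X`, `Y`) sit within two short hops of M's
#' host position, so a noise-placed M has many near-equivalent landing
#' spots besides the donor stem. M's terminal branch (`m_branch`) is
#' long, which attenuates every per-gene placement signal relative to
#' sampling noise while leaving the concatenated signal decisive — the
#' regime in which transferred segments are individually undetectable
#' but jointly visible. Chimeric genes evolve a fraction `fraction` of
#' their columns on the donor tree.
#'
#' @param n_genes Number of genes.
#' @param gene_length Columns per gene.
#' @param fraction Chimeric fraction per gene (recycled vector; use 0 for
#'   pure host genes and 1 for pure donor genes).
#' @param layout "contiguous" or "interleaved" donor segments.
#' @param donor_edge Internal branch subtending the donor clade
#'   \{M, R1, R2\} in the donor tree.
#' @param host_edge Internal branch subtending M's (weak) host placement.
#' @param m_branch Terminal branch length of M.
#' @param alpha,k,model_name Simulation model settings.
#' @param seed Integer seed.
#' @return Object of class `chimera_scenario`.
#' @export
chimera_scenario <- function(n_genes = 100, gene_length = 100,
                             fraction = 0.3, layout = "contiguous",
                             donor_edge = 0.025, host_edge = 0.001,
                             m_branch = 0.5, alpha = 0.8, k = 4,
                             model_name = "LG", seed = 1) {
  stopifnot(all(fraction >= 0), all(fraction <= 1), donor_edge > 0,
            host_edge >= 0, m_branch > 0)
  structure(as.list(environment()), class = "chimera_scenario")
}

#' Simulate a chimeric-gene study
#'
#' Generates `n_genes` genes under a [chimera_scenario()]: gene i is a
#' chimera with its own fraction (recycled from `spec$fraction`),
#' simulated at seed `spec$seed + 10 * i`.
#'
#' @param spec A [chimera_scenario()].
#' @return List with `genes` (a `gene_set`), `host_tree`, `donor_tree`,
#'   `model`, `donor_clade` (taxon labels), and per-gene `truth`.
#' @export
simulate_chimera_study <- function(spec = chimera_scenario()) {
  stopifnot(inherits(spec, "chimera_scenario"))
  # Host: M next to the O pair, one weak edge (host_edge) from the
  # R-pair stem; decoy pairs G, X, Y have long stems within two cheap
  # hops so spurious single-gene placements of M spread across them.
  # Donor: M moves onto the R-pair stem across donor_edge; the backbone
  # is otherwise identical (M's host attachment edge is absorbed into
  # the O stem).
  host <- ape::read.tree(text = sprintf(
    paste0("((O1:0.15,O2:0.15):0.05,M:%g,((R1:0.15,R2:0.15):0.05,",
           "((G1:0.15,G2:0.15):0.12,((X1:0.15,X2:0.15):0.12,",
           "(Y1:0.15,Y2:0.15):0.12):0.01):0.01):%g);"),
    spec$m_branch, spec$host_edge))
  donor <- ape::read.tree(text = sprintf(
    paste0("(((R1:0.15,R2:0.15):0.05,M:%g):%g,",
           "((G1:0.15,G2:0.15):0.12,((X1:0.15,X2:0.15):0.12,",
           "(Y1:0.15,Y2:0.15):0.12):0.01):0.01,(O1:0.15,O2:0.15):%g);"),
    spec$m_branch, spec$donor_edge, 0.05 + spec$host_edge))
  model <- aa_model(spec$model_name, k = spec$k, alpha = spec$alpha)
  fracs <- rep_len(spec$fraction, spec$n_genes)
  sims <- lapply(seq_len(spec$n_genes), function(i)
    simulate_chimeric_gene(host, donor, spec$gene_length, fracs[i],
                           layout = spec$layout, model = model,
                           seed = spec$seed + 10 * i,
                           name = sprintf("g%03d", i)))
  list(genes = gene_set(lapply(sims, `[[`, "alignment")),
       host_tree = host, donor_tree = donor, model = model,
       donor_clade = c("M", "R1", "R2"),
       truth = lapply(sims, `[[`, "truth"))
}

#' Apply per-taxon, per-gene missingness
#'
#' Each (taxon, gene) pair is independently retained with the taxon's
#' profile probability; masks leaving fewer than 4 taxa in a gene are
#' redrawn, so every emitted gene keeps at least 4 taxa.
#'
#' @param genes A `gene_set`.
#' @param profile Either a single retention probability or a named
#'   vector of per-taxon probabilities (taxa absent from the profile
#'   default to 1).
#' @param seed Integer base seed (gene i is masked at `seed + i`).
#' @return A `gene_set` with taxa dropped per gene.
#' @export
apply_missingness <- function(genes, profile, seed) {
  genes <- gene_set(genes)
  stopifnot(is.numeric(profile), all(profile >= 0), all(profile <= 1))
  out <- lapply(seq_along(genes), function(i) {
    g <- genes[[i]]
    taxa <- aln_taxa(g)
    p <- if (length(profile) == 1 && is.null(names(profile)))
      rep(profile, length(taxa))
    else {
      pv <- profile[taxa]
      pv[is.na(pv)] <- 1
      unname(pv)
    }
    keep <- with_seed(seed + i, {
      for (try in 1:1000) {
        mask <- runif(length(taxa)) < p
        if (sum(mask) >= 4) break
      }
      if (sum(mask) < 4) mask[order(-p)[1:4]] <- TRUE
      mask
    })
    gene_alignment(g$name, g$seq[taxa[keep], , drop = FALSE])
  })
  gene_set(out)
}

#' Read a simulation scenario from a YAML config file
#'
#' The file must contain a `type` field ("lba" or "chimera"); remaining
#' top-level fields are passed to the matching scenario constructor.
#'
#' @param path YAML file path.
#' @return A scenario object.
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  type <- cfg$type %||% stop("scenario config must contain a 'type' field")
  cfg$type <- NULL
  switch(type,
         lba = do.call(lba_scenario, cfg),
         chimera = do.call(chimera_scenario, cfg),
         stop("unknown scenario type: ", type))
}
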