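# Shared fixtures: tiny alignments, trees, and fast models built in code.

aa20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Four 4-taxon gene alignments with distinct, easily checked content.
tiny_gene <- function(name = "g1", L = 6, taxa = c("A", "B", "C", "D"),
                      seed = 1) {
  m <- with_seed_local(seed, matrix(sample(aa20, length(taxa) * L,
                                           replace = TRUE),
                                    nrow = length(taxa),
                                    dimnames = list(taxa, NULL)))
  gene_alignment(name, m)
}

# testthat helpers run before the package namespace utilities are
# attached, so keep an independent seed guard here.
with_seed_local <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

# A small fixed quartet tree; bl = terminal lengths A,B,C,D + internal.
quartet_tree <- function(bl = c(0.2, 0.3, 0.15, 0.25, 0.1)) {
  ape::read.tree(text = sprintf(
    "((A:%g,B:%g):%g,C:%g,D:%g);", bl[1], bl[2], bl[5], bl[3], bl[4]))
}

# Independent brute-force likelihood for a quartet: enumerate both
# internal states, transition matrices via Matrix::expm (not the
# package's eigendecomposition path).
brute_quartet_lnl <- function(aln, tree, model) {
  seqm <- if (inherits(aln, "gene_alignment")) aln$seq else aln
  states <- match(seqm, aa20)
  dim(states) <- dim(seqm)
  rownames(states) <- rownames(seqm)
  tr <- ape::unroot(tree)
  stopifnot(length(tr$tip.label) == 4)
  # identify internal edge structure: root trifurcation (x) -- y
  E <- tr$edge
  ntip <- 4
  inner_edge <- which(E[, 2] > ntip)
  y <- E[inner_edge, 2]
  x <- E[inner_edge, 1]
  t_xy <- tr$edge.length[inner_edge]
  x_tips <- E[E[, 1] == x & E[, 2] <= ntip, 2]
  y_tips <- E[E[, 1] == y & E[, 2] <= ntip, 2]
  bl <- function(node) tr$edge.length[E[, 2] == node]
  pexp <- function(t, r) {
    P <- as.matrix(Matrix::expm(model$Q * t * r))
    P
  }
  L <- ncol(states)
  site_l <- numeric(L)
  for (s in seq_len(L)) {
    tot <- 0
    for (m in seq_len(model$k)) {
      r <- model$rates[m]
      Pxy <- pexp(t_xy, r)
      Ptip <- lapply(seq_len(ntip), function(i) pexp(bl(i), r))
      tipvec <- function(node, state_at_parent) {
        obs <- states[tr$tip.label[node], s]
        if (is.na(obs)) 1 else Ptip[[node]][state_at_parent, obs]
      }
      acc <- 0
      for (i in 1:20) for (j in 1:20) {
        term <- model$freq[i] * Pxy[i, j]
        for (tp in x_tips) term <- term * tipvec(tp, i)
        for (tp in y_tips) term <- term * tipvec(tp, j)
        acc <- acc + term
      }
      tot <- tot + acc / model$k
    }
    site_l[s] <- log(tot)
  }
  list(site = site_l, total = sum(site_l))
}
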