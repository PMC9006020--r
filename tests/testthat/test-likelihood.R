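# Pruning likelihoods, optimization, and site rates.

test_that("pruning matches brute-force state enumeration on a quartet", {
  mod <- aa_model("LG", k = 4, alpha = 0.5)
  tr <- quartet_tree()
  sim <- simulate_alignment(tr, mod, 6, seed = 3)
  aln <- sim$alignment
  aln$seq[2, 3] <- "-"   # include a missing cell
  mine <- site_log_likelihoods(aln, tr, mod)
  oracle <- brute_quartet_lnl(aln, tr, mod)
  expect_equal(mine$site, oracle$site, tolerance = 1e-9)
})

test_that("two identical residues at zero distance give lnL = log(1/20)", {
  mod <- aa_model("Poisson", k = 1)
  tr <- ape::read.tree(text = "(A:0,B:0);")
  aln <- gene_alignment("g", c(A = "A", B = "A"))
  expect_equal(site_log_likelihoods(aln, tr, mod)$total, log(1 / 20),
               tolerance = 1e-12)
})

test_that("all-missing columns contribute zero log-likelihood", {
  mod <- aa_model("LG", k = 2, alpha = 1)
  tr <- quartet_tree()
  aln <- gene_alignment("g", c(A = "M-", B = "M-", C = "M-", D = "M-"))
  ll <- site_log_likelihoods(aln, tr, mod)
  expect_equal(ll$site[2], 0)
  expect_lt(ll$site[1], 0)
})

test_that("total lnL is invariant to rooting and the site sum is exact", {
  mod <- aa_model("LG", k = 4, alpha = 0.8)
  tr <- with_seed_local(5, ape::rtree(7))
  tr$edge.length <- with_seed_local(6, runif(nrow(tr$edge), 0.05, 0.5))
  sim <- simulate_alignment(tr, mod, 40, seed = 8)
  unrooted <- site_log_likelihoods(sim$alignment, ape::unroot(tr), mod)
  rooted <- site_log_likelihoods(sim$alignment, tr, mod)
  reroot <- site_log_likelihoods(sim$alignment,
                                 ape::root(ape::unroot(tr), "t3",
                                           resolve.root = TRUE), mod)
  expect_equal(unrooted$total, rooted$total, tolerance = 1e-9)
  expect_equal(unrooted$total, reroot$total, tolerance = 1e-9)
  expect_identical(sum(unrooted$site), unrooted$total)
})

test_that("pruning agrees with an independent implementation (phangorn)", {
  mod <- aa_model("LG", k = 4, alpha = 0.6)
  tr <- with_seed_local(11, ape::unroot(ape::rtree(8)))
  tr$edge.length <- with_seed_local(12, runif(nrow(tr$edge), 0.05, 0.6))
  sim <- simulate_alignment(tr, mod, 120, seed = 13)
  mine <- site_log_likelihoods(sim$alignment, tr, mod)$total
  fit <- phangorn::pml(tr, phangorn::phyDat(sim$alignment$seq, type = "AA"),
                       model = "LG", k = 4, shape = 0.6)
  expect_equal(mine, as.numeric(stats::logLik(fit)), tolerance = 1e-6)
})

test_that("a leaf without a sequence row is reported by name", {
  mod <- aa_model("Poisson", k = 1)
  aln <- gene_alignment("g", c(A = "MK", B = "ML", C = "MR"))
  expect_error(site_log_likelihoods(aln, quartet_tree(), mod),
               "leaf without a sequence row: D")
})

test_that("two-sequence branch estimate matches a dense grid oracle", {
  mod <- aa_model("LG", k = 4, alpha = 0.7)
  tr <- ape::read.tree(text = "(A:0.3,B:0.3);")
  sim <- simulate_alignment(ape::read.tree(text = "(A:0.25,B:0.25);"),
                            mod, 500, seed = 21)
  fit <- optimize_branch_lengths(sim$alignment, tr, mod)
  t_hat <- sum(fit$tree$edge.length)
  # oracle: coarse grid then local refinement on the same likelihood
  f <- function(t) site_log_likelihoods(
    sim$alignment, ape::read.tree(text = sprintf("(A:%.10f,B:0);", t)),
    mod)$total
  grid <- seq(0.05, 2, by = 0.01)
  t0 <- grid[which.max(vapply(grid, f, numeric(1)))]
  fine <- seq(t0 - 0.01, t0 + 0.01, by = 1e-4)
  t_star <- fine[which.max(vapply(fine, f, numeric(1)))]
  expect_equal(t_hat, t_star, tolerance = 1e-3)
})

test_that("branch optimization never decreases the log-likelihood", {
  mod <- aa_model("LG", k = 2, alpha = 1)
  for (seed in c(2, 3)) {
    tr <- with_seed_local(seed, ape::unroot(ape::rtree(6)))
    tr$edge.length <- with_seed_local(seed + 10,
                                      runif(nrow(tr$edge), 0.05, 0.5))
    sim <- simulate_alignment(tr, mod, 80, seed = seed + 20)
    start <- tr
    start$edge.length <- rep(0.3, nrow(tr$edge))
    before <- site_log_likelihoods(sim$alignment, start, mod)$total
    fit <- optimize_branch_lengths(sim$alignment, start, mod)
    expect_gte(fit$logLik, before)
    after <- site_log_likelihoods(sim$alignment, fit$tree, mod)$total
    expect_equal(fit$logLik, after, tolerance = 1e-6)
  }
})

test_that("identical sequences drive branch lengths to the lower bound", {
  mod <- aa_model("Poisson", k = 1)
  aln <- gene_alignment("g", c(A = "MKLVAC", B = "MKLVAC", C = "MKLVAC",
                               D = "MKLVAC"))
  fit <- optimize_branch_lengths(aln, quartet_tree(), mod)
  expect_true(all(fit$tree$edge.length <= 1e-4))
})

test_that("k = 1 parameter fits report alpha as not applicable", {
  mod <- aa_model("LG", k = 1)
  sim <- simulate_alignment(quartet_tree(), mod, 60, seed = 4)
  fit <- optimize_parameters(sim$alignment, quartet_tree(), mod)
  expect_true(is.na(fit$alpha))
})

test_that("empirical +F frequencies equal alignment proportions", {
  g <- tiny_gene("g", L = 50, seed = 31)
  m <- aa_model("LG", k = 1, freq_mode = "empirical", alignment = g,
                pseudo_freq = 0)
  counts <- table(factor(g$seq, levels = aa20))
  expect_equal(unname(m$freq), as.numeric(counts / sum(counts)))
})

test_that("site rates: ties, ordering, bounds, and the k = 1 error", {
  mod <- aa_model("LG", k = 4, alpha = 0.5)
  tr <- with_seed_local(41, ape::unroot(ape::rtree(12)))
  tr$edge.length <- with_seed_local(42, runif(nrow(tr$edge), 0.1, 0.4))
  sim <- simulate_alignment(tr, mod, 30, seed = 43)
  aln <- sim$alignment
  aln$seq[, 2] <- aln$seq[, 1]            # duplicate column
  aln$seq[, 3] <- "A"                     # constant column
  aln$seq[, 4] <- c("A", "R", "N", "D", "C", "Q",
                    rep("E", 6))          # 7 distinct residues
  sr <- estimate_site_rates(aln, tr, mod)
  expect_equal(sr$rates[1], sr$rates[2])
  expect_lt(sr$rates[3], sr$rates[4])
  expect_gt(mean(sr$rates), 0)
  expect_lte(mean(sr$rates), max(mod$rates))
  # invariant columns never outrank the fastest variable column
  expect_gt(max(sr$rates), sr$rates[3])
  # tie-break: among equal rates the smaller column index ranks first
  r12 <- sr$ranking[sr$ranking %in% c(1, 2)]
  expect_equal(r12, c(1, 2))
  expect_error(estimate_site_rates(aln, tr, aa_model("LG", k = 1)),
               "k must be >= 2")
})

test_that("tree search solves the 5-taxon case exhaustively", {
  mod <- aa_model("LG", k = 2, alpha = 0.9)
  true_tr <- ape::read.tree(
    text = "((A:0.2,B:0.2):0.15,C:0.3,(D:0.2,E:0.25):0.1);")
  sim <- simulate_alignment(true_tr, mod, 300, seed = 51)
  res <- ml_tree_search(sim$alignment, mod)
  best <- -Inf
  topos <- phangorn::allTrees(5, tip.label = true_tr$tip.label)
  for (i in seq_along(topos)) {
    tt <- topos[[i]]   # [[ restores tip labels on compressed multiPhylo
    tt$edge.length <- rep(0.2, nrow(tt$edge))
    best <- max(best, optimize_branch_lengths(sim$alignment, tt,
                                              mod)$logLik)
  }
  expect_equal(res$logLik, best, tolerance = 1e-3)
})
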