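# Synthetic-data generator: determinism, closed-form checks,
# stationarity, chimera bookkeeping, missingness profiles.

test_that("simulation honours size, alphabet, and the seed", {
  tr <- quartet_tree()
  mod <- aa_model("LG", k = 4, alpha = 0.5)
  s1 <- simulate_alignment(tr, mod, 25, seed = 7)
  s2 <- simulate_alignment(tr, mod, 25, seed = 7)
  s3 <- simulate_alignment(tr, mod, 25, seed = 8)
  expect_equal(dim(s1$alignment$seq), c(4, 25))
  expect_true(all(s1$alignment$seq %in% aa20))
  expect_identical(s1$alignment$seq, s2$alignment$seq)
  expect_false(identical(s1$alignment$seq, s3$alignment$seq))
  expect_length(s1$truth$rates, 25)
  expect_true(all(s1$truth$rates > 0))
})

test_that("pairwise identity matches the 20-state Jukes-Cantor solution", {
  mod <- aa_model("Poisson", k = 1)
  for (t in c(0.2, 1)) {
    tr <- ape::read.tree(text = sprintf("(A:%g,B:0);", t))
    n <- 50000
    sim <- simulate_alignment(tr, mod, n, seed = 17)
    p_ident <- mean(sim$alignment$seq["A", ] == sim$alignment$seq["B", ])
    p_theory <- 1 / 20 + (19 / 20) * exp(-20 * t / 19)
    sigma <- sqrt(p_theory * (1 - p_theory) / n)
    expect_lt(abs(p_ident - p_theory), 3 * sigma)
  }
})

test_that("simulated states are stationary at the model frequencies", {
  mod <- aa_model("LG", k = 1)
  tr <- ape::read.tree(text = "(A:10,B:10);")
  sim <- simulate_alignment(tr, mod, 100000, seed = 23)
  obs <- table(factor(sim$alignment$seq["A", ], levels = aa20))
  chi <- suppressWarnings(
    stats::chisq.test(as.numeric(obs), p = unname(mod$freq)))
  expect_gt(chi$p.value, 0.001)
})

test_that("chimeric genes tile their segments and honour the endpoints", {
  cs <- chimera_scenario(seed = 5)
  st <- simulate_chimera_study(chimera_scenario(n_genes = 2, seed = 5))
  mod <- st$model
  pure_host <- simulate_chimeric_gene(st$host_tree, st$donor_tree, 50, 0,
                                      model = mod, seed = 3)
  pure_donor <- simulate_chimeric_gene(st$host_tree, st$donor_tree, 50, 1,
                                       model = mod, seed = 3)
  expect_true(all(pure_host$truth$source == "host"))
  expect_true(all(pure_donor$truth$source == "donor"))
  for (layout in c("contiguous", "interleaved")) {
    ch <- simulate_chimeric_gene(st$host_tree, st$donor_tree, 101, 0.3,
                                 layout = layout, model = mod, seed = 9)
    seg <- ch$truth$segments
    expect_equal(seg$start[1], 1)
    expect_equal(seg$end[nrow(seg)], 101)
    expect_true(all(seg$start[-1] == seg$end[-nrow(seg)] + 1))
    expect_equal(sum(ch$truth$source == "donor"), ceiling(0.3 * 101))
    expect_length(ch$truth$donor_sites, ceiling(0.3 * 101))
  }
  # contiguous layout: donor block at the end of the gene
  ch <- simulate_chimeric_gene(st$host_tree, st$donor_tree, 100, 0.25,
                               model = mod, seed = 9)
  expect_equal(ch$truth$donor_sites, 76:100)
  expect_error(
    simulate_chimeric_gene(st$host_tree, ape::rtree(4), 10, 0.5,
                           model = mod, seed = 1),
    "same leaf set")
})

test_that("the LBA scenario builds the advertised geometry", {
  lba <- simulate_lba_case(lba_scenario(n_sites = 50, seed = 2))
  expect_setequal(lba$tree$tip.label,
                  c("longA", "breakA", "outA", "longB", "breakB", "outB"))
  expect_setequal(lba$breakers, c("breakA", "breakB"))
  keys <- bipartition_set(lba$tree)$keys
  expect_true(phylosieve:::canonical_split_key(
    lba$clades$true_a, lba$tree$tip.label) %in% keys)
  expect_false(phylosieve:::canonical_split_key(
    lba$clades$artefact, lba$tree$tip.label) %in% keys)
  # long terminals sit on opposite sides of the short internal branch
  expect_equal(aln_length(lba$genes[[1]]), 50)
})

test_that("a long internal branch leaves no artefact even when mis-specified", {
  # strong-signal control: with a long internal branch the
  # rate-homogeneous analysis still recovers the true tree
  lba <- simulate_lba_case(lba_scenario(lambda_int = 0.5, n_sites = 2000,
                                        seed = 7))
  fit <- ml_tree_search(concatenate(lba$genes), aa_model("LG", k = 1),
                        control = fast_search())
  expect_equal(robinson_foulds(fit$tree, lba$tree), 0)
})

test_that("scenario YAML configs round-trip through read_scenario", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("type: lba", "lambda_int: 0.4", "n_sites: 123", "seed: 9"),
             path)
  sc <- read_scenario(path)
  expect_s3_class(sc, "lba_scenario")
  expect_equal(sc$lambda_int, 0.4)
  expect_equal(sc$n_sites, 123)
  writeLines(c("type: chimera", "n_genes: 7"), path)
  expect_equal(read_scenario(path)$n_genes, 7)
  writeLines(c("type: nope"), path)
  expect_error(read_scenario(path), "unknown scenario type")
})

test_that("missingness profiles hit their target rates and the 4-taxon floor", {
  tr <- with_seed_local(3, ape::rtree(8))
  tr$edge.length <- rep(0.2, nrow(tr$edge))
  mod <- aa_model("Poisson", k = 1)
  genes <- simulate_genes(tr, mod, 200, 10, seed = 1)$genes
  prof <- setNames(rep(1, 8), tr$tip.label)
  expect_identical(
    lapply(apply_missingness(genes, prof, seed = 5), aln_taxa),
    lapply(genes, aln_taxa))
  prof["t1"] <- 0.5
  masked <- apply_missingness(genes, prof, seed = 5)
  frac <- mean(vapply(masked, function(g) "t1" %in% aln_taxa(g),
                      logical(1)))
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 200))
  # forced minimum: extreme profile still leaves >= 4 taxa per gene
  harsh <- apply_missingness(genes[1:20], setNames(rep(0.2, 8),
                                                   tr$tip.label), seed = 2)
  expect_true(all(vapply(harsh, function(g) nrow(g$seq), integer(1)) >= 4))
})
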