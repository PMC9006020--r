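# Bootstrap, FPR, RGS, and taxon-deletion plumbing.

small_gene_fixture <- function() {
  tr <- ape::read.tree(
    text = "((A:0.2,B:0.2):0.15,C:0.3,(D:0.25,(E:0.2,F:0.2):0.15):0.1);")
  mod <- aa_model("Poisson", k = 1)
  list(tree = tr, model = mod,
       genes = simulate_genes(tr, mod, 6, 40, seed = 70)$genes)
}

test_that("bootstrap replicates are deterministic and full width", {
  g <- tiny_gene("g", L = 17, seed = 2)
  b1 <- bootstrap_alignment(g, seed = 4)
  b2 <- bootstrap_alignment(g, seed = 4)
  b3 <- bootstrap_alignment(g, seed = 5)
  expect_identical(b1$seq, b2$seq)
  expect_false(identical(b1$seq, b3$seq))
  expect_equal(ncol(b1$seq), 17)
})

test_that("column resampling is uniform-multinomial across replicates", {
  g <- gene_alignment("g", c(A = "ARN", B = "ARN", C = "ARN", D = "ARN"))
  g$seq[1, ] <- c("A", "R", "N")   # distinguishable columns
  n_rep <- 10000
  counts <- integer(3)
  for (i in seq_len(n_rep)) {
    b <- bootstrap_alignment(g, seed = i)
    counts <- counts + tabulate(match(b$seq[1, ], c("A", "R", "N")), 3)
  }
  n_draw <- 3 * n_rep
  sigma <- sqrt(n_draw * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n_draw / 3) < 3 * sigma))
})

test_that("saturated signal gives 100% support and absent clades 0%", {
  fx <- small_gene_fixture()
  sm <- concatenate(fx$genes)   # 240 positions of strong signal
  bs <- bootstrap_support(sm, fx$model, n_reps = 10,
                          clades = list(ab = c("A", "B"),
                                        ef = c("E", "F"),
                                        wrong = c("A", "C")),
                          seed = 1)
  expect_equal(unname(bs$support["ab"]), 100)
  expect_equal(unname(bs$support["ef"]), 100)
  expect_equal(unname(bs$support["wrong"]), 0)
  # bit-for-bit reproducibility under a fixed seed
  bs2 <- bootstrap_support(sm, fx$model, n_reps = 10,
                           clades = list(ab = c("A", "B"),
                                         ef = c("E", "F"),
                                         wrong = c("A", "C")),
                           seed = 1)
  expect_identical(bs$support, bs2$support)
  expect_identical(bs$table, bs2$table)
})

test_that("the f = 0 FPR row reproduces plain bootstrap support bitwise", {
  fx <- small_gene_fixture()
  sm <- concatenate(fx$genes)
  rank_mod <- aa_model("LG", k = 4, alpha = 1)
  clades <- list(ab = c("A", "B"), ef = c("E", "F"))
  plan <- fpr_plan(fractions = c(0, 0.25), n_boot = 5,
                   rank_model = rank_mod)
  ser <- fpr_series(sm, fx$tree, fx$model, plan, clades, seed = 11)
  bs <- bootstrap_support(sm, fx$model, n_reps = 5, clades = clades,
                          seed = 11)
  f0 <- ser[ser$condition == 0, ]
  expect_identical(
    unname(vapply(split(f0$support, f0$clade), mean, numeric(1))),
    unname(bs$support[sort(names(bs$support))]))
})

test_that("FPR removal sets are nested and fractions validated", {
  fx <- small_gene_fixture()
  sm <- concatenate(fx$genes)
  rank_mod <- aa_model("LG", k = 4, alpha = 1)
  sr <- estimate_site_rates(sm, fx$tree, rank_mod)
  L <- ncol(sm$seq)
  rm2 <- sr$ranking[seq_len(round(0.2 * L))]
  rm4 <- sr$ranking[seq_len(round(0.4 * L))]
  rm6 <- sr$ranking[seq_len(round(0.6 * L))]
  expect_true(all(rm2 %in% rm4) && all(rm4 %in% rm6))
  expect_error(fpr_plan(fractions = c(0, 1)), "\\[0, 1\\)")
  expect_error(fpr_plan(fractions = c(0.4, 0.2)), "increasing")
  expect_error(
    fpr_series(sm, fx$tree, fx$model, fpr_plan(fractions = 0),
               list(ab = c("A", "B")), seed = 1),
    "k >= 2")
})

test_that("RGS emits the planned replicate structure and records draws", {
  fx <- small_gene_fixture()
  clades <- list(ab = c("A", "B"))
  plan <- rgs_plan(sizes = c(3, 5), reps = c(4, 2), n_boot = 3)
  ser <- rgs_series(fx$genes, fx$model, plan, clades, seed = 31)
  expect_equal(nrow(ser), 6)
  expect_equal(sum(ser$condition == 3), 4)
  expect_equal(sum(ser$condition == 5), 2)
  draws <- attr(ser, "draws")
  expect_equal(nrow(draws), 4 * 3 + 2 * 5)
  expect_error(rgs_series(fx$genes, fx$model,
                          rgs_plan(sizes = 10, reps = 1),
                          clades, seed = 1),
               "exceeds")
})

test_that("degenerate full-size RGS equals the plain bootstrap", {
  fx <- small_gene_fixture()
  clades <- list(ab = c("A", "B"), ef = c("E", "F"))
  plan <- rgs_plan(sizes = length(fx$genes), reps = 1, n_boot = 4)
  ser <- rgs_series(fx$genes, fx$model, plan, clades, seed = 50)
  bs <- bootstrap_support(concatenate(fx$genes), fx$model, n_reps = 4,
                          clades = clades, seed = 50)
  expect_equal(setNames(ser$support, ser$clade)[names(bs$support)],
               bs$support)
})

test_that("RGS gene inclusion is uniform (chi-squared on draw counts)", {
  fx <- small_gene_fixture()
  plan <- rgs_plan(sizes = 3, reps = 200, n_boot = 1,
                   control = fast_search())
  ser <- rgs_series(fx$genes, fx$model, plan,
                    list(ab = c("A", "B")), seed = 77)
  counts <- table(attr(ser, "draws")$gene)
  expect_length(counts, 6)
  chi <- stats::chisq.test(as.numeric(counts))
  expect_gt(chi$p.value, 0.001)
})

test_that("taxon deletion schemes label, restrict, and propagate", {
  fx <- small_gene_fixture()
  clades <- list(ab = c("A", "B"), ef = c("E", "F"))
  schemes <- list(baseline = character(0), drop_ef = c("E", "F"))
  ser <- taxon_deletion_series(fx$genes, fx$model, schemes,
                               boot_plan(n_reps = 4), clades, seed = 3)
  expect_setequal(unique(ser$scheme), c("baseline", "drop_ef"))
  # empty scheme reproduces the plain bootstrap run
  bs <- bootstrap_support(concatenate(fx$genes), fx$model, n_reps = 4,
                          clades = clades, seed = 3)
  base <- ser[ser$scheme == "baseline", ]
  expect_equal(
    unname(vapply(split(base$support, base$clade), mean, numeric(1))),
    unname(bs$support[sort(names(bs$support))]))
  # removing a monitored clade's members yields NA ("not evaluable")
  dropped <- ser[ser$scheme == "drop_ef" & ser$clade == "ef", ]
  expect_true(all(is.na(dropped$support)))
  kept <- ser[ser$scheme == "drop_ef" & ser$clade == "ab", ]
  expect_true(all(!is.na(kept$support)))
})

test_that("deleting breaker taxa exposes the long-branch artefact", {
  # a milder long branch than the FPR fixture: with breakers present the
  # attraction is only partial, so their deletion shows a clear rise
  lba <- simulate_lba_case(lba_scenario(lambda_long = 1, lambda_breaker = 0.05,
                                        lambda_out = 0.3, n_sites = 2000,
                                        seed = 100))
  k1 <- aa_model("LG", k = 1)
  ser <- taxon_deletion_series(
    lba$genes, k1,
    schemes = list(baseline = character(0), no_breakers = lba$breakers),
    downstream = boot_plan(n_reps = 10),
    clades = list(artefact = lba$clades$artefact), seed = 4)
  agg <- support_summary(ser)
  base <- agg$support[agg$scheme == "baseline"]
  nobrk <- agg$support[agg$scheme == "no_breakers"]
  expect_gt(nobrk, base)
  expect_gte(nobrk, 90)   # the quartet artefact is essentially certain
})

test_that("support summaries aggregate and series write as TSV", {
  fx <- small_gene_fixture()
  clades <- list(ab = c("A", "B"))
  ser <- fpr_series(concatenate(fx$genes), fx$tree, fx$model,
                    fpr_plan(fractions = c(0, 0.5), n_boot = 2,
                             rank_model = aa_model("LG", k = 4, alpha = 1)),
                    clades, seed = 2)
  agg <- support_summary(ser)
  expect_equal(nrow(agg), 2)
  expect_true(all(agg$support >= 0 & agg$support <= 100))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_support_series(ser, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(ser))
})
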