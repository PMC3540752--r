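test_that("every generator is deterministic given the master seed", {
  p <- sim_params(seed = 5, n_genes = 300L,
                  planted_modules = list(list(size = 12L, bias = "male",
                                              multiplier = 6)))
  b1 <- simulate_bundle(p)
  b2 <- simulate_bundle(p)
  expect_identical(b1$network$links, b2$network$links)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$expression$values, b2$expression$values)
  expect_identical(b1$groups$groups, b2$groups$groups)
  expect_identical(b1$annotations, b2$annotations)

  b3 <- simulate_bundle(sim_params(seed = 6, n_genes = 300L,
                                   planted_modules = p$planted_modules))
  expect_false(identical(b1$network$links, b3$network$links))
})

test_that("the realized network matches its degree targets", {
  nt <- simulate_network(sim_params(seed = 42))
  d <- degrees(nt$network)
  expect_lt(abs(mean(d) - 6) / 6, 0.15)
  fit <- degree_loglog_fit(d)
  expect_lt(abs(fit$slope - (-2.3)), 0.6)
  expect_lt(fit$slope, 0)

  # independent brute-force histogram regression gives the same slope
  tab <- table(d[d > 0])
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab))
  oracle <- stats::lm(y ~ x, weights = as.numeric(tab))
  expect_equal(fit$slope, unname(stats::coef(oracle)[2]),
               tolerance = 1e-12)
})

test_that("planted modules appear as dense, high-confidence subgraphs", {
  nt <- simulate_network(sim_params(seed = 11))
  truth <- nt$truth
  links <- nt$network$links
  for (mi in 1:3) {
    members <- truth$gene[!is.na(truth$module) & truth$module == mi]
    intra <- links$gene_a %in% members & links$gene_b %in% members
    # each member has expected within-module degree ~ multiplier = 8
    expect_gt(2 * sum(intra) / length(members), 5)
    expect_gt(max(links$confidence[intra]), 0.99)
  }
  # bias totals follow the biased fraction, split between the sexes
  expect_equal(sum(truth$bias != "unbiased"), 400L)
  expect_equal(sum(truth$bias == "male"), 200L)
})

test_that("expression carries the planted sex effects on the log2 scale", {
  p <- sim_params(seed = 9, n_genes = 500L, planted_modules = list())
  nt <- simulate_network(p)
  ex <- simulate_expression(p, nt$truth)
  expect_true(all(ex$values > 0))
  expect_equal(ncol(ex$values), 6L)
  expect_equal(ex$sample_meta$sex, rep(c("male", "female"), each = 3))
  logged <- log2(ex$values)
  diff <- rowMeans(logged[, 1:3]) - rowMeans(logged[, 4:6])
  m <- nt$truth$bias == "male"
  f <- nt$truth$bias == "female"
  expect_gt(mean(diff[m]), 1.5)
  expect_lt(mean(diff[f]), -1.5)
  expect_lt(abs(mean(diff[nt$truth$bias == "unbiased"])), 0.3)
  expect_error(sim_params(reps_per_sex = 1L))
})

test_that("ortholog concordance interpolates between pure and random groups", {
  p1 <- sim_params(seed = 13, concordance = 1)
  t1 <- simulate_network(p1)$truth
  g1 <- simulate_orthologs(p1, t1)
  lab <- stats::setNames(t1$bias, t1$gene)
  pure <- vapply(g1$groups, function(m) length(unique(lab[m])) == 1L,
                 logical(1))
  expect_true(all(pure))

  p0 <- sim_params(seed = 13, concordance = 0)
  g0 <- simulate_orthologs(p0, t1)
  pure0 <- vapply(g0$groups, function(m) length(unique(lab[m])) == 1L,
                  logical(1))
  # analytic expectation for independent draws: sum over labels of
  # (label frequency)^k, averaged over the group sizes
  freq <- table(t1$bias) / nrow(t1)
  expected <- mean(vapply(p0$ortholog_group_sizes,
                          function(k) sum(freq^k), numeric(1)))
  se <- sqrt(expected * (1 - expected) / length(g0$groups))
  expect_lt(abs(mean(pure0) - expected), 4 * se + 0.05)
})

test_that("annotations paint modules up to the requested noise level", {
  p <- sim_params(seed = 21, annotation_noise = 0)
  truth <- simulate_network(p)$truth
  annot <- simulate_annotations(p, truth)
  members <- truth$gene[!is.na(truth$module) & truth$module == 1L]
  covered <- annot$gene[annot$term == "MOD01_01"]
  expect_setequal(covered, members)
  expect_equal(sum(grepl("^MOD01", unique(annot$term))),
               p$terms_per_module)
})

test_that("a written bundle round-trips through the package readers", {
  p <- sim_params(seed = 3, n_genes = 250L,
                  planted_modules = list(list(size = 10L, bias = "male",
                                              multiplier = 5)),
                  ortholog_group_sizes = c(2L, 3L, 2L))
  b <- simulate_bundle(p)
  dir <- withr::local_tempdir()
  write_bundle(b, dir)
  net <- read_network(file.path(dir, "network.tsv"), cutoff = 0)
  expect_identical(net$links[, c("gene_a", "gene_b")],
                   b$network$links[, c("gene_a", "gene_b")])
  vals <- read_expression(file.path(dir, "expression.tsv"))
  expect_equal(vals, b$expression$values, tolerance = 1e-10)
  meta <- read_sample_meta(file.path(dir, "samples.tsv"))
  expect_equal(meta$sex, b$expression$sample_meta$sex)
  groups <- load_groups(file.path(dir, "groups.tsv"), rownames(vals))
  expect_identical(groups$groups[order(names(groups$groups))],
                   b$groups$groups[order(names(b$groups$groups))])
  chrom <- read_chromosome_table(file.path(dir, "chromosomes.tsv"))
  expect_identical(chrom, b$chromosomes)
})
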