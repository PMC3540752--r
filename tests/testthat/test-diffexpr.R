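test_that("d0 = 0 reproduces the classical Welch test exactly", {
  set.seed(11)
  male <- matrix(2^stats::rnorm(30, 8, 1), nrow = 10)
  female <- matrix(2^stats::rnorm(30, 8, 1.5), nrow = 10)
  tx <- toy_expression(male, female)
  de <- moderated_welch(tx$values, tx$meta, d0 = 0)
  logged <- log2(pmax(tx$values, 1))
  for (i in seq_len(10)) {
    oracle <- welch_oracle(logged[i, 1:3], logged[i, 4:6])
    expect_equal(de$t_mod[i], oracle$t, tolerance = 1e-10)
    expect_equal(de$df[i], oracle$df, tolerance = 1e-10)
    expect_equal(de$p[i], oracle$p, tolerance = 1e-10)
  }
})

test_that("d0 = Inf gives the fully pooled equal-variance-scale limit", {
  set.seed(12)
  male <- matrix(2^stats::rnorm(60, 8, 1), nrow = 20)
  female <- matrix(2^stats::rnorm(60, 8, 1), nrow = 20)
  tx <- toy_expression(male, female)
  de <- moderated_welch(tx$values, tx$meta, d0 = Inf)
  s0 <- attr(de, "s0")
  logged <- log2(pmax(tx$values, 1))
  diff <- rowMeans(logged[, 1:3]) - rowMeans(logged[, 4:6])
  expected_t <- diff / sqrt(s0[["male"]] / 3 + s0[["female"]] / 3)
  expect_equal(de$t_mod, unname(expected_t), tolerance = 1e-12)
  expect_true(all(is.infinite(de$df)))
  # large finite d0 approaches the same statistic
  de_big <- moderated_welch(tx$values, tx$meta, d0 = 1e8)
  expect_equal(de_big$t_mod, de$t_mod, tolerance = 1e-4)
})

test_that("identical constant groups give t = 0 and p = 1", {
  vals <- matrix(5, nrow = 3, ncol = 6,
                 dimnames = list(c("g1", "g2", "g3"),
                                 c("m1", "m2", "m3", "f1", "f2", "f3")))
  meta <- data.frame(sample = colnames(vals),
                     sex = rep(c("male", "female"), each = 3),
                     tissue = "t", stage = "s", replicate = rep(1:3, 2))
  de <- moderated_welch(vals, meta, d0 = 0)
  expect_true(all(de$t_mod == 0))
  expect_true(all(de$p == 1))
  expect_true(all(de$direction == "none"))
})

test_that("swapping sex labels flips every statistic's sign exactly", {
  b <- default_bundle()
  de <- default_de()
  meta_sw <- b$expression$sample_meta
  meta_sw$sex <- ifelse(meta_sw$sex == "male", "female", "male")
  de_sw <- moderated_welch(b$expression$values, meta_sw,
                           d0 = attr(de, "d0"))
  expect_equal(de_sw$t_mod, -de$t_mod, tolerance = 1e-12)
  expect_equal(de_sw$log2fc, -de$log2fc, tolerance = 1e-12)
})

test_that("a missing or under-replicated sex is an error", {
  vals <- matrix(2, nrow = 2, ncol = 3,
                 dimnames = list(c("a", "b"), c("m1", "m2", "f1")))
  meta <- data.frame(sample = colnames(vals),
                     sex = c("male", "male", "female"),
                     tissue = "t", stage = "s", replicate = c(1, 2, 1))
  expect_error(moderated_welch(vals, meta), "at least 2 female")
  expect_error(moderated_welch(vals[, 1:2], meta[1:2, ]), "no female")
})

test_that("bh_fdr matches hand-computed step-up values on forced examples", {
  expect_equal(bh_fdr(0.05), 0.05)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
  set.seed(21)
  for (i in 1:20) {
    p <- stats::runif(sample(3:40, 1))
    expect_equal(bh_fdr(p), bh_stepup_oracle(p), tolerance = 1e-12)
  }
})

test_that("classify_bias applies threshold semantics and flags zero fold changes", {
  de <- data.frame(gene = c("g1", "g2", "g3", "g4"),
                   t_mod = c(3, 2, -2.5, 1), df = 4,
                   p = c(0.001, 0.02, 0.01, 0.5),
                   fdr = c(0.09, 0.11, 0.05, 0.8),
                   log2fc = c(1.2, 3, -0.8, 0.1),
                   direction = c("male", "male", "female", "male"))
  bias <- classify_bias(de)
  expect_equal(bias$label, c("male", "unbiased", "female", "unbiased"))
  expect_equal(attr(bias, "fdr_cutoff"), 0.1)
  expect_equal(formals(classify_bias)$fdr_cutoff, 0.1)

  de$log2fc[1] <- 0
  expect_warning(bias <- classify_bias(de), "zero fold change")
  expect_equal(bias$label[1], "unbiased")
})

test_that("a null expression matrix yields almost no biased calls", {
  p0 <- sim_params(seed = 17, biased_fraction = 0, planted_modules = list())
  nt <- simulate_network(p0)
  ex <- simulate_expression(p0, nt$truth)
  de <- moderated_welch(ex$values, ex$sample_meta)
  bias <- classify_bias(de)
  expect_lte(sum(bias$label != "unbiased"), 5L)
})

test_that("strongly sex-biased genes are recovered at the study effect size", {
  bias <- default_bias()
  b <- default_bundle()
  lab <- bias_labels(bias)
  truth <- stats::setNames(b$truth$bias, b$truth$gene)
  affected <- names(truth)[truth != "unbiased"]
  recall <- mean(lab[affected] == truth[affected])
  expect_gte(recall, 0.8)
})

test_that("log_fold_change is the log2 ratio of floored group means", {
  vals <- matrix(c(8, 3, 8, 3, 8, 3,   # male samples
                   2, 12, 2, 12, 2, 12), nrow = 2,
                 dimnames = list(c("up", "down"),
                                 c("m1", "m2", "m3", "f1", "f2", "f3")))
  meta <- data.frame(sample = colnames(vals),
                     sex = rep(c("male", "female"), each = 3),
                     tissue = "t", stage = "s", replicate = rep(1:3, 2))
  lfc <- log_fold_change(vals, meta)
  expect_equal(unname(lfc["up"]), 2)
  expect_equal(unname(lfc["down"]), -2)
  same <- vals; same[, 4:6] <- same[, 1:3]
  expect_equal(unname(log_fold_change(same, meta)), c(0, 0))
})
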