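# Shared fixtures, built in code. Expensive objects are memoised per test
# run so several test files can reuse the same default synthetic bundle.

sbn_cache <- new.env(parent = emptyenv())

# The documented default study bundle (see the methods vignette): master
# seed 42 is the fixed seed used throughout the recovery tests.
default_bundle <- function() {
  if (is.null(sbn_cache$bundle)) {
    sbn_cache$bundle <- simulate_bundle(sim_params(seed = 42))
  }
  sbn_cache$bundle
}

default_de <- function() {
  if (is.null(sbn_cache$de)) {
    b <- default_bundle()
    sbn_cache$de <- moderated_welch(b$expression$values,
                                    b$expression$sample_meta)
  }
  sbn_cache$de
}

default_bias <- function() {
  if (is.null(sbn_cache$bias)) {
    sbn_cache$bias <- classify_bias(default_de())
  }
  sbn_cache$bias
}

# small networks built from explicit edge lists
make_net <- function(pairs, confidence = 0.9, genes = character()) {
  df <- data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2],
                   confidence = confidence, stringsAsFactors = FALSE)
  fcnet(df, genes = genes)
}

clique_pairs <- function(ids) t(utils::combn(ids, 2))

# Erdos-Renyi network over n genes with link probability p
er_net <- function(n, p, seed, prefix = "e") {
  set.seed(seed)
  ids <- sprintf("%s%04d", prefix, seq_len(n))
  prs <- t(utils::combn(ids, 2))
  keep <- stats::runif(nrow(prs)) < p
  make_net(prs[keep, , drop = FALSE],
           confidence = stats::runif(sum(keep), 0.3, 1), genes = ids)
}

# adjusted Rand index between a clustering and true labels, restricted to
# the genes under evaluation
ari_against_truth <- function(clustering, genes_eval, truth_labels) {
  mm <- cluster_membership(clustering)
  common <- intersect(names(mm), genes_eval)
  mclust::adjustedRandIndex(mm[common], truth_labels[common])
}

# brute-force Benjamini-Hochberg step-up, straight from the definition:
# fdr_i = min over { j : p_j >= p_i } of m * p_j / rank_j, clipped at 1
bh_stepup_oracle <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  vapply(seq_len(m), function(i) {
    cand <- p >= p[i] | seq_len(m) == i
    min(1, min(m * p[cand] / r[cand]))
  }, numeric(1))
}

# classical Welch test closed form (the d0 = 0 oracle)
welch_oracle <- function(xm, xf) {
  nm <- length(xm); nf <- length(xf)
  vm <- stats::var(xm) / nm
  vf <- stats::var(xf) / nf
  t <- (mean(xm) - mean(xf)) / sqrt(vm + vf)
  df <- (vm + vf)^2 / (vm^2 / (nm - 1) + vf^2 / (nf - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# exhaustive hypergeometric upper tail by direct summation of the pmf
hyper_tail_oracle <- function(k, n, K, N) {
  j <- k:min(n, K)
  if (length(j) == 0 || k > min(n, K)) return(0)
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# tiny expression matrix with explicit per-group values
toy_expression <- function(male, female, genes = NULL) {
  stopifnot(nrow(male) == nrow(female))
  if (is.null(genes)) genes <- sprintf("g%02d", seq_len(nrow(male)))
  vals <- cbind(male, female)
  colnames(vals) <- c(paste0("m", seq_len(ncol(male))),
                      paste0("f", seq_len(ncol(female))))
  rownames(vals) <- genes
  meta <- data.frame(
    sample = colnames(vals),
    sex = rep(c("male", "female"), c(ncol(male), ncol(female))),
    tissue = "gonad", stage = "adult",
    replicate = c(seq_len(ncol(male)), seq_len(ncol(female))),
    stringsAsFactors = FALSE)
  list(values = vals, meta = meta)
}
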