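#' Spearman rank correlation with mid-ranks and an exact small-sample p
#'
#' Computes the correlation as the Pearson correlation of mid-ranks (ties get
#' average ranks). For `n <= 9` the two-sided p-value is exact, obtained by
#' enumerating all permutations of one variable; for larger samples it uses
#' the t approximation with `n - 2` degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, at least 3.
#' @return List with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`). A constant input yields `rho = NA` with a warning.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("need at least 3 observations")
  if (anyNA(x) || anyNA(y)) stop("missing values are not supported")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("constant input: Spearman correlation undefined")
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= 9L) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    obs <- abs(sum(rxc * ryc))
    # inner product with every permutation of the centered y-ranks
    stat <- abs(matrix(ryc[perms], nrow = nrow(perms)) %*% rxc)
    p <- sum(stat >= obs - 1e-9) / nrow(perms)
    method <- "exact"
  } else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
    method <- "t-approximation"
  }
  list(rho = rho, p = min(p, 1), n = n, method = method)
}

# all n! permutations of 1..n as a matrix (rows), n <= 9
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Correlation between differential-expression FDR and node degree
#'
#' For each bias category, computes the Spearman correlation between the
#' per-gene FDR of the sex-bias test and the gene's network degree,
#' restricted to the category's genes that are present in the network. A
#' positive correlation means that stronger sex bias (lower FDR) goes with
#' lower connectivity, i.e. sex-biased genes tend not to be hubs.
#'
#' @param de a `de_result` from [moderated_welch()].
#' @param degree_table named integer vector from [degrees()].
#' @param bias a `bias_table` or named label vector.
#' @param categories labels to analyse (default male, female, unbiased).
#' @param min_n categories with fewer genes are skipped with a warning.
#' @return data.frame with columns `category`, `rho`, `p`, `n`.
#' @export
bias_degree_correlation <- function(de, degree_table, bias,
                                    categories = c("male", "female",
                                                   "unbiased"),
                                    min_n = 3L) {
  labels <- bias_labels(bias)
  fdr <- stats::setNames(de$fdr, de$gene)
  rows <- lapply(categories, function(cat) {
    genes <- names(labels)[labels == cat]
    genes <- intersect(intersect(genes, names(fdr)), names(degree_table))
    if (length(genes) < min_n) {
      warning(sprintf("category '%s' has %d gene(s) in the network; skipped",
                      cat, length(genes)))
      return(NULL)
    }
    res <- spearman_cor(fdr[genes], as.numeric(degree_table[genes]))
    data.frame(category = cat, rho = res$rho, p = res$p, n = res$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(category = character(), rho = numeric(),
                      p = numeric(), n = integer(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Rank sex-biased hub genes by combined bias and connectivity rank
#'
#' Each gene is ranked once by increasing FDR (rank 1 = most sex-biased) and
#' once by decreasing degree (rank 1 = most connected), using mid-ranks for
#' ties; genes are then re-ranked by the sum of the two ranks, so the top of
#' the list holds the most sex-biased hubs. Rank-sum ties are broken by
#' smaller FDR, then lexicographic gene id, making the ordering fully
#' deterministic.
#'
#' @param de a `de_result`.
#' @param degree_table named integer vector from [degrees()].
#' @param top_n number of top-ranked genes to return (default 20).
#' @return data.frame with columns `gene`, `fdr`, `degree`, `bias_rank`,
#'   `degree_rank`, `rank_sum`, `final_rank`, ordered by `final_rank`.
#' @export
rank_hubs <- function(de, degree_table, top_n = 20L) {
  genes <- intersect(de$gene, names(degree_table))
  if (length(genes) == 0L) {
    stop("no genes shared between the DE result and the degree table")
  }
  fdr <- stats::setNames(de$fdr, de$gene)[genes]
  deg <- as.numeric(degree_table[genes])
  bias_rank <- rank(fdr)
  degree_rank <- rank(-deg)
  rank_sum <- bias_rank + degree_rank
  ord <- order(rank_sum, fdr, genes)
  out <- data.frame(gene = genes, fdr = unname(fdr), degree = deg,
                    bias_rank = unname(bias_rank),
                    degree_rank = unname(degree_rank),
                    rank_sum = unname(rank_sum),
                    stringsAsFactors = FALSE)[ord, , drop = FALSE]
  out$final_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, top_n)
}
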