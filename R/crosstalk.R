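#' Build a gene-group partition for crosstalk analysis
#'
#' Assigns every gene of the network exactly one group label, by default its
#' sex-bias label. When a chromosome-class table is supplied, Z-linked genes
#' get a composite `<bias>_Z` label so Z-chromosome bias groups are analysed
#' as separate strata (avian dosage compensation is incomplete, so Z genes
#' must not be mixed with autosomal ones).
#'
#' @param bias a `bias_table` or named character vector of bias labels.
#' @param network an [fcnet]; the partition covers exactly its genes.
#' @param chromosome optional named character vector gene -> class
#'   (`"Z"`, `"autosome"`, `"unknown"`), as from [read_chromosome_table()].
#' @param default_label label used for network genes absent from `bias`.
#' @return Named character vector mapping every network gene to a label.
#' @export
make_partition <- function(bias, network, chromosome = NULL,
                           default_label = "unbiased") {
  labels <- bias_labels(bias)
  part <- stats::setNames(rep(default_label, length(network$genes)),
                          network$genes)
  known <- intersect(names(labels), network$genes)
  part[known] <- labels[known]
  if (!is.null(chromosome)) {
    z_genes <- names(chromosome)[chromosome == "Z"]
    z_genes <- intersect(z_genes, network$genes)
    part[z_genes] <- paste0(part[z_genes], "_Z")
  }
  part
}

as_partition <- function(partition, network) {
  if (is.data.frame(partition)) {
    stopifnot(all(c("gene", "label") %in% names(partition)))
    partition <- stats::setNames(as.character(partition$label),
                                 partition$gene)
  }
  if (is.null(names(partition))) stop("partition must be a named vector")
  missing <- setdiff(network$genes, names(partition))
  if (length(missing) > 0L) {
    stop(sprintf("partition must label every network gene; %d missing (e.g. %s)",
                 length(missing), missing[1L]))
  }
  partition[network$genes]
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

count_pairs <- function(links, partition, levels) {
  la <- partition[links$gene_a]
  lb <- partition[links$gene_b]
  tab <- table(factor(pair_key(la, lb), levels = levels))
  as.integer(tab)
}

#' Count links between two gene groups
#'
#' For distinct labels, the number of links with one endpoint in each group;
#' for a label paired with itself, each within-group link is counted once.
#'
#' @param network an [fcnet].
#' @param label_a,label_b group labels.
#' @param partition named character vector gene -> label covering the
#'   network genes (see [make_partition()]).
#' @return Integer link count.
#' @export
count_links <- function(network, label_a, label_b, partition) {
  partition <- as_partition(partition, network)
  if (!label_a %in% partition || !label_b %in% partition) {
    stop("unknown group label: ",
         paste(setdiff(c(label_a, label_b), partition), collapse = ", "))
  }
  count_pairs(network$links, partition, pair_key(label_a, label_b))
}

#' Degree-preserving network randomization
#'
#' Rewires the network by repeated pairwise edge swaps, each of which keeps
#' every gene's degree unchanged; swaps that would create a self-loop or a
#' duplicate link are rejected. The result is a draw from the
#' configuration-model null with exactly the original degree sequence.
#'
#' @param network an [fcnet] with at least 2 links.
#' @param seed integer seed making the randomization reproducible; `NULL`
#'   continues the current RNG stream.
#' @param swaps_per_link number of attempted swaps per link (default 10,
#'   ample burn-in for networks of the sizes handled here).
#' @return A randomized [fcnet] over the same genes with the same degree
#'   sequence.
#' @export
randomize_network <- function(network, seed = NULL, swaps_per_link = 10) {
  stopifnot(inherits(network, "fcnet"))
  if (nrow(network$links) < 2L) stop("need at least 2 links to randomize")
  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(network)
  rg <- igraph::rewire(
    g, igraph::keeping_degseq(loops = FALSE,
                              niter = swaps_per_link *
                                igraph::ecount(g)))
  out <- fcnet_from_igraph(rg, cutoff_applied = network$cutoff_applied)
  # exact invariant of the swap construction
  if (!identical(degrees(out)[network$genes], degrees(network))) {
    stop("internal error: randomization changed the degree sequence")
  }
  out
}

#' Crosstalk between gene groups under a degree-preserving null
#'
#' Compares, for every unordered pair of group labels (including each group
#' with itself), the observed number of links between the groups to its
#' distribution over `n_rand` degree-preserving randomizations of the
#' network. Reports the z-score `(observed - null mean) / null sd`, a
#' two-sided p-value from the normal approximation, an add-one empirical
#' two-sided p-value, and Benjamini-Hochberg FDRs across all pairs tested.
#' Self-pair rows measure within-group cohesion.
#'
#' Degenerate nulls are handled explicitly: when the null sd is 0 and the
#' observed count equals the null mean the pair gets `z = 0, p = 1`; when
#' the null sd is 0 but the observed count differs, `z` is undefined (`NA`)
#' and the pair is excluded from the FDR family.
#'
#' @param network an [fcnet].
#' @param partition named character vector (or data.frame `gene`,`label`)
#'   assigning every network gene one group label.
#' @param n_rand number of randomizations (default 100).
#' @param seed integer seed for the randomization stream.
#' @param swaps_per_link attempted swaps per link in each randomization.
#' @return data.frame of class `crosstalk_result` with columns `label_a`,
#'   `label_b`, `observed`, `null_mean`, `null_sd`, `z`, `p_normal`,
#'   `p_empirical`, `fdr`, `sign`.
#' @export
crosstalk <- function(network, partition, n_rand = 100, seed = 1,
                      swaps_per_link = 10) {
  stopifnot(inherits(network, "fcnet"))
  if (n_rand < 2L) stop("n_rand must be at least 2")
  partition <- as_partition(partition, network)
  labs <- sort(unique(partition))
  if (length(labs) < 2L) {
    stop("partition must contain at least 2 distinct labels")
  }
  pairs <- expand.grid(i = seq_along(labs), j = seq_along(labs))
  pairs <- pairs[pairs$i <= pairs$j, , drop = FALSE]
  label_a <- labs[pairs$i]
  label_b <- labs[pairs$j]
  levels <- pair_key(label_a, label_b)

  observed <- count_pairs(network$links, partition, levels)
  ref_deg <- degrees(network)

  if (!is.null(seed)) set.seed(seed)
  g <- as_igraph(network)
  niter <- swaps_per_link * igraph::ecount(g)
  null_counts <- matrix(0L, nrow = n_rand, ncol = length(levels))
  for (r in seq_len(n_rand)) {
    rg <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE,
                                                   niter = niter))
    stopifnot(all(igraph::degree(rg)[network$genes] == ref_deg))
    edges <- igraph::as_data_frame(rg, what = "edges")
    null_counts[r, ] <- count_pairs(
      data.frame(gene_a = edges$from, gene_b = edges$to,
                 stringsAsFactors = FALSE),
      partition, levels)
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, stats::sd)

  z <- ifelse(null_sd > 0, (observed - null_mean) / null_sd,
              ifelse(observed == null_mean, 0, NA_real_))
  p_normal <- ifelse(is.na(z), NA_real_, 2 * stats::pnorm(-abs(z)))
  p_normal[!is.na(z) & z == 0] <- 1
  p_empirical <- vapply(seq_along(levels), function(i) {
    dev <- abs(null_counts[, i] - null_mean[i])
    (1 + sum(dev >= abs(observed[i] - null_mean[i]))) / (n_rand + 1)
  }, numeric(1))
  fdr <- rep(NA_real_, length(levels))
  ok <- !is.na(z)
  if (any(ok)) fdr[ok] <- bh_fdr(p_normal[ok])
  sign <- ifelse(is.na(z) | z == 0, "none",
                 ifelse(z > 0, "enriched", "depleted"))
  out <- data.frame(label_a = label_a, label_b = label_b,
                    observed = observed, null_mean = null_mean,
                    null_sd = null_sd, z = z, p_normal = p_normal,
                    p_empirical = p_empirical, fdr = fdr, sign = sign,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_rand") <- n_rand
  attr(out, "swaps_per_link") <- swaps_per_link
  class(out) <- c("crosstalk_result", "data.frame")
  out
}

#' Graph-ready edge table of significant crosstalk
#'
#' Convenience view of a crosstalk result for plotting a group-level graph:
#' one edge per label pair with its z-score, significance flag and sign,
#' mirroring the usual crosstalk summary figure.
#'
#' @param result a `crosstalk_result`.
#' @param fdr_cutoff FDR below which an edge is flagged significant.
#' @return data.frame with columns `from`, `to`, `z`, `fdr`, `sign`,
#'   `significant`.
#' @export
crosstalk_edges <- function(result, fdr_cutoff = 0.05) {
  stopifnot(inherits(result, "crosstalk_result"))
  data.frame(from = result$label_a, to = result$label_b, z = result$z,
             fdr = result$fdr, sign = result$sign,
             significant = !is.na(result$fdr) & result$fdr < fdr_cutoff,
             stringsAsFactors = FALSE)
}
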