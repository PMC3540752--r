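#' Upper-tail hypergeometric probability
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`: drawing `n` objects
#' without replacement from `N` of which `K` are marked, the probability of
#' seeing at least `k` marked ones.
#'
#' @param k observed count(s) of marked objects (vectorized).
#' @param n draw size(s).
#' @param K number of marked objects in the population.
#' @param N population size.
#' @return Numeric vector of tail probabilities.
#' @export
hypergeom_tail <- function(k, n, K, N) {
  if (length(K) != 1L || length(N) != 1L) {
    stop("K and N must be scalars")
  }
  bad <- k < 0 | n < k | N < n | K < 0 | K > N
  if (any(bad)) stop("impossible hypergeometric parameters")
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Build a sex-biased subnetwork by hypergeometric neighbor recruitment
#'
#' The subnetwork seeds are the genes of the requested bias present in the
#' network. Every other network gene is then tested for a surplus of links
#' to the seed set with the hypergeometric test (`k` = links to seeds, `n` =
#' degree, `K` = number of seeds, `N` = network size); genes whose
#' Bonferroni-corrected p-value falls below the cutoff are recruited, and
#' the induced subgraph on seeds plus recruits is returned. The Bonferroni
#' factor is the number of genes tested. The default cutoff of 0.10 (10%)
#' matches the usual working threshold for this construction.
#'
#' A gene of the opposite bias can legitimately be recruited when its links
#' concentrate on the seed set - such genes are part of the same functional
#' module despite their opposite expression bias.
#'
#' @param network an [fcnet].
#' @param bias a `bias_table` or named label vector.
#' @param sex `"male"` or `"female"`: which bias group seeds the subnetwork.
#' @param bonferroni_cutoff corrected-p threshold for recruitment.
#' @return Object of class `subnetwork`: list with `network` (induced
#'   [fcnet]), `seed_genes`, `recruited_genes`, `n_tested`,
#'   `bonferroni_cutoff`, `sex` and `parent_n_genes`.
#' @export
build_subnetwork <- function(network, bias, sex,
                             bonferroni_cutoff = 0.1) {
  stopifnot(inherits(network, "fcnet"))
  if (!sex %in% c("male", "female")) stop("sex must be 'male' or 'female'")
  labels <- bias_labels(bias)
  seed <- intersect(names(labels)[labels == sex], network$genes)
  if (length(seed) == 0L) {
    stop("no ", sex, "-biased genes present in the network")
  }
  others <- setdiff(network$genes, seed)
  deg <- degrees(network)
  # links-to-seed count per gene
  links <- network$links
  a_in <- links$gene_a %in% seed
  b_in <- links$gene_b %in% seed
  touched <- c(links$gene_b[a_in], links$gene_a[b_in])
  k <- stats::setNames(integer(length(network$genes)), network$genes)
  if (length(touched) > 0L) {
    tab <- table(touched)
    k[names(tab)] <- as.integer(tab)
  }
  recruited <- character(0)
  if (length(others) > 0L) {
    p <- hypergeom_tail(k[others], deg[others], K = length(seed),
                        N = length(network$genes))
    p_corr <- pmin(1, p * length(others))
    recruited <- others[p_corr < bonferroni_cutoff]
  }
  structure(
    list(network = induced_network(network, c(seed, recruited)),
         seed_genes = sort(seed),
         recruited_genes = sort(recruited),
         n_tested = length(others),
         bonferroni_cutoff = bonferroni_cutoff,
         sex = sex,
         parent_n_genes = length(network$genes)),
    class = "subnetwork"
  )
}

#' @export
print.subnetwork <- function(x, ...) {
  cat(sprintf(
    "subnetwork (%s): %d seed + %d recruited genes, %d links\n",
    x$sex, length(x$seed_genes), length(x$recruited_genes),
    nrow(x$network$links)))
  invisible(x)
}

subnetwork_net <- function(x) {
  if (inherits(x, "subnetwork")) return(x$network)
  if (inherits(x, "fcnet")) return(x)
  stop("expected a subnetwork or fcnet")
}

new_clustering <- function(member_list, genes, method, params,
                           converged = TRUE, n_iter = NA_integer_) {
  # order clusters by their smallest member id, members sorted
  member_list <- lapply(member_list, sort)
  ord <- order(vapply(member_list, `[`, character(1), 1L))
  member_list <- member_list[ord]
  sizes <- vapply(member_list, length, integer(1))
  structure(
    list(clusters = unname(member_list[sizes >= 2L]),
         singletons = sort(unlist(member_list[sizes == 1L],
                                  use.names = FALSE)),
         genes = sort(genes),
         method = method, params = params,
         converged = converged, n_iter = n_iter),
    class = "gene_clustering"
  )
}

#' @export
print.gene_clustering <- function(x, ...) {
  cat(sprintf("%s clustering: %d cluster(s) of size >= 2, %d singleton(s)\n",
              x$method, length(x$clusters), length(x$singletons)))
  if (length(x$clusters) > 0L) {
    cat("cluster sizes:",
        paste(vapply(x$clusters, length, integer(1)), collapse = ", "),
        "\n")
  }
  invisible(x)
}

#' Cluster membership as a named vector
#'
#' @param clustering a `gene_clustering`.
#' @param include_singletons whether singletons get their own cluster ids.
#' @return Named integer vector gene -> cluster id.
#' @export
cluster_membership <- function(clustering, include_singletons = TRUE) {
  ids <- integer(0)
  genes <- character(0)
  for (i in seq_along(clustering$clusters)) {
    genes <- c(genes, clustering$clusters[[i]])
    ids <- c(ids, rep(i, length(clustering$clusters[[i]])))
  }
  if (include_singletons && length(clustering$singletons) > 0L) {
    genes <- c(genes, clustering$singletons)
    ids <- c(ids, length(clustering$clusters) +
               seq_along(clustering$singletons))
  }
  stats::setNames(ids, genes)
}

#' Markov clustering (MCL) of a subnetwork
#'
#' Runs the Markov Cluster algorithm on the link-confidence matrix with
#' self-loops of weight 1: the column-stochastic transition matrix is
#' alternately expanded (matrix squaring) and inflated (entrywise power
#' followed by column renormalization), with entries below a pruning
#' threshold dropped, until the matrix change falls below a tolerance. The
#' final nonzero pattern partitions the genes into attractor systems, read
#' out as connected components; overlaps (a gene attracted to several
#' systems) are resolved by the component structure, whose clusters are
#' indexed by their lexicographically smallest member. The default
#' inflation of 3.5 is the standard setting for this analysis; larger
#' inflation gives finer clusters.
#'
#' @param x a `subnetwork` or [fcnet].
#' @param inflation inflation exponent, must exceed 1 (default 3.5).
#' @param pruning entries below this value are zeroed each iteration.
#' @param tol convergence threshold on the maximum entry change.
#' @param max_iter iteration cap; hitting it returns the current
#'   interpretation with `converged = FALSE` and a warning.
#' @return A `gene_clustering` (clusters of size >= 2 in `$clusters`,
#'   singletons in `$singletons`).
#' @export
mcl_cluster <- function(x, inflation = 3.5, pruning = 1e-5, tol = 1e-8,
                        max_iter = 200L) {
  if (inflation <= 1) stop("inflation must be greater than 1")
  net <- subnetwork_net(x)
  genes <- net$genes
  n <- length(genes)
  if (n == 0L) stop("empty subnetwork")
  A <- matrix(0, n, n, dimnames = list(genes, genes))
  if (nrow(net$links) > 0L) {
    ia <- match(net$links$gene_a, genes)
    ib <- match(net$links$gene_b, genes)
    A[cbind(ia, ib)] <- net$links$confidence
    A[cbind(ib, ia)] <- net$links$confidence
  }
  diag(A) <- 1
  normalize <- function(M) {
    cs <- colSums(M)
    dead <- cs == 0
    if (any(dead)) {
      M[cbind(which(dead), which(dead))] <- 1
      cs[dead] <- 1
    }
    sweep(M, 2L, cs, "/")
  }
  M <- normalize(A)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    M_old <- M
    M <- M %*% M            # expansion
    M <- M^inflation        # inflation
    M[M < pruning] <- 0
    M <- normalize(M)
    if (max(abs(M - M_old)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iter,
            " iterations; returning current interpretation")
  }
  supp <- (M > 0) | (t(M) > 0)
  comp <- igraph::components(
    igraph::graph_from_adjacency_matrix(supp, mode = "undirected"))
  member_list <- split(genes, comp$membership)
  new_clustering(member_list, genes, method = "mcl",
                 params = list(inflation = inflation, pruning = pruning,
                               tol = tol),
                 converged = converged, n_iter = iter)
}

#' Shared-neighbor agglomerative clustering
#'
#' Clusters of strongly mutually linked genes are grown from pairwise link
#' affinities defined as the Jaccard index of the two endpoints' closed
#' neighborhoods (neighbor sets including the endpoints themselves);
#' non-adjacent gene pairs have affinity 0. Starting from singletons, the
#' pair of clusters with the highest affinity is merged greedily, with the
#' affinity between clusters recomputed as the mean pairwise member
#' affinity, until no inter-cluster affinity exceeds the threshold `theta`.
#' Ties are broken towards the lexicographically smallest pair of cluster
#' representatives, so the procedure is fully deterministic. The method
#' follows the shared-neighbor clustering principle of MGclus and is
#' labelled `"mgclus_like"` in outputs.
#'
#' The default `theta` was calibrated on synthetic planted-module
#' benchmarks (see the package vignette); raise it for tighter clusters.
#'
#' @param x a `subnetwork` or [fcnet].
#' @param theta stopping threshold on inter-cluster affinity, in (0, 1).
#' @return A `gene_clustering`.
#' @export
sharedneighbor_cluster <- function(x, theta = 0.02) {
  if (theta <= 0 || theta >= 1) stop("theta must lie in (0, 1)")
  net <- subnetwork_net(x)
  genes <- net$genes
  n <- length(genes)
  if (n == 0L) stop("empty subnetwork")
  adj <- matrix(FALSE, n, n, dimnames = list(genes, genes))
  if (nrow(net$links) > 0L) {
    ia <- match(net$links$gene_a, genes)
    ib <- match(net$links$gene_b, genes)
    adj[cbind(ia, ib)] <- TRUE
    adj[cbind(ib, ia)] <- TRUE
  }
  closed <- adj
  diag(closed) <- TRUE
  common <- crossprod(closed * 1)          # closed-neighborhood overlaps
  sizes_nb <- diag(common)
  union_sz <- outer(sizes_nb, sizes_nb, "+") - common
  aff <- ifelse(adj & union_sz > 0, common / union_sz, 0)
  diag(aff) <- 0

  members <- as.list(seq_len(n))
  S <- aff                     # S[i, j] = sum of member-pair affinities
  csize <- rep(1L, n)
  active <- rep(TRUE, n)
  reps <- genes                # smallest member id per cluster
  repeat {
    idx <- which(active)
    if (length(idx) < 2L) break
    C <- S[idx, idx, drop = FALSE] /
      outer(csize[idx], csize[idx])
    diag(C) <- -Inf
    best <- max(C)
    if (best <= theta) break
    hits <- which(C >= best - 1e-12, arr.ind = TRUE)
    hits <- hits[hits[, 1L] < hits[, 2L], , drop = FALSE]
    # deterministic tie-break: smallest representative pair
    key_a <- pmin(reps[idx[hits[, 1L]]], reps[idx[hits[, 2L]]])
    key_b <- pmax(reps[idx[hits[, 1L]]], reps[idx[hits[, 2L]]])
    pick <- order(key_a, key_b)[1L]
    i <- idx[hits[pick, 1L]]
    j <- idx[hits[pick, 2L]]
    members[[i]] <- c(members[[i]], members[[j]])
    S[i, ] <- S[i, ] + S[j, ]
    S[, i] <- S[, i] + S[, j]
    S[i, i] <- 0
    csize[i] <- csize[i] + csize[j]
    reps[i] <- min(reps[i], reps[j])
    active[j] <- FALSE
  }
  member_list <- lapply(members[active], function(ix) genes[ix])
  new_clustering(member_list, genes, method = "mgclus_like",
                 params = list(theta = theta))
}

#' Gene Ontology term enrichment of a gene cluster
#'
#' Per term with at least one annotated cluster gene, the upper-tail
#' hypergeometric probability of the observed number of annotated cluster
#' genes given the background annotation frequency. A term counts as
#' enriched when its p-value falls below `p_cutoff` and at least
#' `min_genes` (default 2) cluster genes carry it, so single-gene hits can
#' never drive a cluster's significance.
#'
#' @param cluster character vector of gene ids (subset of `background`).
#' @param background character vector of background gene ids.
#' @param annot annotation data.frame with columns `gene`, `term`.
#' @param p_cutoff per-term p-value threshold (uncorrected; downstream
#'   randomization calibrates the counts).
#' @param min_genes minimum annotated cluster genes for a term to qualify.
#' @return data.frame with columns `term`, `k`, `K`, `p` (enriched terms
#'   only, sorted by p).
#' @export
go_enrichment <- function(cluster, background, annot, p_cutoff = 0.05,
                          min_genes = 2L) {
  stopifnot(all(c("gene", "term") %in% names(annot)))
  if (!all(cluster %in% background)) {
    stop("cluster must be a subset of the background")
  }
  ann_bg <- annot[annot$gene %in% background, , drop = FALSE]
  ann_bg <- unique(ann_bg[, c("gene", "term")])
  if (nrow(ann_bg) == 0L) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  K_tab <- table(ann_bg$term)
  in_cl <- ann_bg$gene %in% cluster
  if (!any(in_cl)) {
    return(data.frame(term = character(), k = integer(), K = integer(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  k_tab <- table(ann_bg$term[in_cl])
  terms <- names(k_tab)
  k <- as.integer(k_tab)
  K <- as.integer(K_tab[terms])
  p <- vapply(seq_along(terms), function(i) {
    hypergeom_tail(k[i], length(cluster), K = K[i],
                   N = length(background))
  }, numeric(1))
  keep <- p < p_cutoff & k >= min_genes
  out <- data.frame(term = terms[keep], k = k[keep], K = K[keep],
                    p = p[keep], stringsAsFactors = FALSE)
  out[order(out$p, out$term), , drop = FALSE]
}

#' Clustering significance against size-matched random modules
#'
#' Evaluates whether a clustering carries more functional signal than
#' chance: for each cluster size `n`, a null distribution of
#' enriched-term counts is built from `n_rand` uniform draws of `n` genes
#' from the parental subnetwork, and the clustering-level z-score compares
#' the observed average number of enriched terms per cluster with the
#' distribution of the same average over the random draws. A z above 2
#' corresponds to roughly p < 0.05.
#'
#' @param clustering a `gene_clustering` (clusters of size >= 2 are
#'   evaluated).
#' @param subnetwork the parental `subnetwork` (or [fcnet]) the clustering
#'   was computed on; its genes are the sampling pool and enrichment
#'   background.
#' @param annot annotation data.frame (`gene`, `term`).
#' @param n_rand number of random modules per cluster size (default 500).
#' @param seed integer seed.
#' @return Object of class `clustering_significance`: list with
#'   `n_clusters`, `n_significant` (clusters with >= 1 enriched term),
#'   `avg_enriched`, `random_avg`, `random_sd`, `z` and `per_cluster`
#'   (data.frame `cluster`, `size`, `enriched_terms`).
#' @export
clustering_significance <- function(clustering, subnetwork, annot,
                                    n_rand = 500, seed = 1) {
  stopifnot(inherits(clustering, "gene_clustering"))
  if (n_rand < 50L) stop("n_rand must be at least 50")
  bg <- subnetwork_net(subnetwork)$genes
  clusters <- clustering$clusters
  if (length(clusters) == 0L) stop("clustering has no clusters of size >= 2")
  sizes <- vapply(clusters, length, integer(1))
  if (max(sizes) > length(bg)) {
    stop("cluster larger than the parental subnetwork")
  }
  obs <- vapply(clusters, function(cl) {
    nrow(go_enrichment(cl, bg, annot))
  }, numeric(1))
  usize <- sort(unique(sizes))
  if (!is.null(seed)) set.seed(seed)
  null_counts <- matrix(0, nrow = n_rand, ncol = length(usize),
                        dimnames = list(NULL, as.character(usize)))
  for (r in seq_len(n_rand)) {
    for (s in seq_along(usize)) {
      draw <- sample(bg, usize[s])
      null_counts[r, s] <- nrow(go_enrichment(draw, bg, annot))
    }
  }
  size_col <- match(sizes, usize)
  null_avgs <- rowMeans(null_counts[, size_col, drop = FALSE])
  random_sd <- stats::sd(null_avgs)
  z <- if (random_sd > 0) (mean(obs) - mean(null_avgs)) / random_sd else {
    warning("degenerate null (zero spread); z undefined")
    NA_real_
  }
  structure(
    list(n_clusters = length(clusters),
         n_significant = sum(obs >= 1),
         avg_enriched = mean(obs),
         random_avg = mean(null_avgs),
         random_sd = random_sd,
         z = z,
         per_cluster = data.frame(cluster = seq_along(clusters),
                                  size = sizes, enriched_terms = obs,
                                  row.names = NULL)),
    class = "clustering_significance"
  )
}

#' @export
print.clustering_significance <- function(x, ...) {
  cat(sprintf(
    "clusters: %d, significant: %d, avg enriched terms: %.2f (random %.2f), z = %.2f\n",
    x$n_clusters, x$n_significant, x$avg_enriched, x$random_avg, x$z))
  invisible(x)
}

jaccard_sets <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(1)   # two empty sets are identical
  length(intersect(a, b)) / u
}

jaccard_matrix <- function(sets1, sets2) {
  out <- matrix(0, length(sets1), length(sets2),
                dimnames = list(names(sets1), names(sets2)))
  for (i in seq_along(sets1)) {
    for (j in seq_along(sets2)) {
      out[i, j] <- jaccard_sets(sets1[[i]], sets2[[j]])
    }
  }
  out
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage hierarchical clustering rendered as an ultrametric
#' phylogeny (leaf-to-ancestor height equals half the average-linkage merge
#' distance). Ties in the merge order are resolved by [stats::hclust()]'s
#' deterministic ordering.
#'
#' @param d symmetric distance matrix with labelled rows/columns.
#' @return List with `phylo` ([ape::as.phylo] tree) and `newick` string.
#' @export
upgma_tree <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  phy <- ape::as.phylo(hc)
  list(phylo = phy, newick = ape::write.tree(phy))
}

#' Compare two clusterings of the same subnetwork
#'
#' Computes the pairwise Jaccard matrix between the clusters of the two
#' clusterings (by member genes, and optionally by enriched GO term sets),
#' each cluster's best-counterpart overlap fraction in the other
#' clustering, and a UPGMA tree over the union of all clusters built from
#' `1 - Jaccard` distances (emitted in Newick). Overlap trees make it easy
#' to see which modules the two methods agree on.
#'
#' @param c1,c2 `gene_clustering` objects with nonempty `$clusters`.
#' @param annot optional annotation data.frame (`gene`, `term`); when given,
#'   term-based Jaccard and tree are computed from each cluster's enriched
#'   terms.
#' @param background background gene set for term enrichment; defaults to
#'   the union of both clusterings' genes.
#' @return List of class `cluster_comparison` with `jaccard_genes`,
#'   `best_overlap` (data.frame), `tree_genes` (Newick), and when `annot`
#'   is supplied also `jaccard_terms` and `tree_terms`.
#' @export
compare_clusterings <- function(c1, c2, annot = NULL, background = NULL) {
  stopifnot(inherits(c1, "gene_clustering"),
            inherits(c2, "gene_clustering"))
  if (length(c1$clusters) == 0L || length(c2$clusters) == 0L) {
    stop("both clusterings must contain at least one cluster")
  }
  name_of <- function(cl, tag) {
    stats::setNames(cl$clusters,
                    paste0(tag, "_", seq_along(cl$clusters)))
  }
  tag1 <- c1$method
  tag2 <- if (identical(c2$method, c1$method))
    paste0(c2$method, "2") else c2$method
  s1 <- name_of(c1, tag1)
  s2 <- name_of(c2, tag2)
  jg <- jaccard_matrix(s1, s2)
  best1 <- vapply(seq_along(s1), function(i) {
    max(vapply(s2, function(b)
      length(intersect(s1[[i]], b)) / length(s1[[i]]), numeric(1)))
  }, numeric(1))
  best2 <- vapply(seq_along(s2), function(j) {
    max(vapply(s1, function(a)
      length(intersect(s2[[j]], a)) / length(s2[[j]]), numeric(1)))
  }, numeric(1))
  best <- data.frame(
    cluster = c(names(s1), names(s2)),
    method = c(rep(tag1, length(s1)), rep(tag2, length(s2))),
    size = c(vapply(s1, length, integer(1)),
             vapply(s2, length, integer(1))),
    best_overlap = c(best1, best2),
    stringsAsFactors = FALSE, row.names = NULL)
  all_sets <- c(s1, s2)
  tree_genes <- upgma_tree(1 - jaccard_matrix(all_sets, all_sets))
  out <- list(jaccard_genes = jg, best_overlap = best,
              tree_genes = tree_genes$newick,
              upgma_genes = tree_genes$phylo)
  if (!is.null(annot)) {
    if (is.null(background)) {
      background <- union(c1$genes, c2$genes)
    }
    term_sets <- lapply(all_sets, function(cl) {
      go_enrichment(intersect(cl, background), background, annot)$term
    })
    jt_all <- jaccard_matrix(term_sets, term_sets)
    out$jaccard_terms <- jt_all[names(s1), names(s2), drop = FALSE]
    tree_terms <- upgma_tree(1 - jt_all)
    out$tree_terms <- tree_terms$newick
    out$upgma_terms <- tree_terms$phylo
  }
  class(out) <- "cluster_comparison"
  out
}

#' @export
print.cluster_comparison <- function(x, ...) {
  cat(sprintf("cluster comparison: %d x %d clusters\n",
              nrow(x$jaccard_genes), ncol(x$jaccard_genes)))
  cat(sprintf("mean best-counterpart overlap: %.2f\n",
              mean(x$best_overlap$best_overlap)))
  invisible(x)
}
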