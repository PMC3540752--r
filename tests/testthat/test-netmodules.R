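test_that("hypergeom_tail matches enumeration and handles boundary cases", {
  expect_equal(hypergeom_tail(0, 3, 4, 10), 1)
  expect_equal(hypergeom_tail(3, 3, 4, 10), 4 / 120)
  expect_equal(hypergeom_tail(5, 5, 5, 5), 1)
  expect_error(hypergeom_tail(4, 3, 4, 10), "impossible")
  expect_error(hypergeom_tail(1, 5, 11, 10), "impossible")

  # enumeration oracle on a spread of parameter tuples
  set.seed(2)
  for (i in 1:200) {
    N <- sample(2:25, 1)
    K <- sample(0:N, 1)
    n <- sample(0:N, 1)
    k <- sample(0:n, 1)
    expect_equal(hypergeom_tail(k, n, K, N), hyper_tail_oracle(k, n, K, N),
                 tolerance = 1e-12)
  }
})

test_that("subnetwork recruitment follows the corrected hypergeometric test", {
  # eight male seeds forming a clique; one female gene linked only to
  # seeds (recruited); one unbiased gene with a single stray link (not)
  seeds <- sprintf("m%d", 1:8)
  extra_genes <- sprintf("x%02d", 1:40)
  prs <- rbind(clique_pairs(seeds),
               cbind("fem", seeds),               # all links to seeds
               cbind("lone", seeds[1]),           # one link to seeds
               cbind(extra_genes[-40], extra_genes[-1]))  # background path
  net <- make_net(prs)
  bias <- stats::setNames(
    c(rep("male", 8), "female", rep("unbiased", 41)),
    c(seeds, "fem", "lone", extra_genes))
  sub <- build_subnetwork(net, bias, "male")
  expect_true("fem" %in% sub$recruited_genes)
  expect_false("lone" %in% sub$recruited_genes)
  expect_setequal(sub$seed_genes, seeds)
  expect_true(all(sub$network$genes %in% c(seeds, sub$recruited_genes)))
  expect_equal(formals(build_subnetwork)$bonferroni_cutoff, 0.1)

  # a gene with no links to the seed set can never be recruited
  expect_false(any(degrees(net)[sub$recruited_genes] == 0))
  expect_error(build_subnetwork(net, bias, "other"), "male")
  expect_error(
    build_subnetwork(net, stats::setNames("unbiased", "m1"), "female"),
    "no female")
})

test_that("subnetwork recruitment is monotone in the Bonferroni cutoff", {
  b <- default_bundle()
  bias <- default_bias()
  r1 <- build_subnetwork(b$network, bias, "male",
                         bonferroni_cutoff = 0.01)$recruited_genes
  r2 <- build_subnetwork(b$network, bias, "male",
                         bonferroni_cutoff = 0.5)$recruited_genes
  expect_true(all(r1 %in% r2))
})

test_that("MCL separates disconnected cliques and honours its default inflation", {
  tri <- make_net(rbind(clique_pairs(c("a", "b", "c")),
                        clique_pairs(c("d", "e", "f"))), confidence = 0.8)
  cl <- mcl_cluster(tri)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[1]], c("a", "b", "c"))
  expect_setequal(cl$clusters[[2]], c("d", "e", "f"))
  expect_equal(formals(mcl_cluster)$inflation, 3.5)
  expect_error(mcl_cluster(tri, inflation = 1), "inflation")
})

test_that("MCL agrees with a step-by-step transcription on the bridged cliques", {
  g1 <- sprintf("a%d", 1:5)
  g2 <- sprintf("b%d", 1:5)
  prs <- rbind(clique_pairs(g1), clique_pairs(g2), c("a1", "b1"))
  net <- make_net(prs, confidence = 0.8)
  cl <- mcl_cluster(net)
  expect_equal(length(cl$clusters), 2L)
  expect_setequal(cl$clusters[[1]], g1)
  expect_setequal(cl$clusters[[2]], g2)

  # independent plain transcription of the iteration on the 10x10 matrix
  genes <- net$genes
  A <- matrix(0, 10, 10, dimnames = list(genes, genes))
  for (r in seq_len(nrow(net$links))) {
    A[net$links$gene_a[r], net$links$gene_b[r]] <- net$links$confidence[r]
    A[net$links$gene_b[r], net$links$gene_a[r]] <- net$links$confidence[r]
  }
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (i in 1:200) {
    M_prev <- M
    M <- M %*% M
    M <- M^3.5
    M[M < 1e-5] <- 0
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - M_prev)) < 1e-8) break
  }
  comp <- igraph::components(igraph::graph_from_adjacency_matrix(
    (M > 0) | (t(M) > 0), mode = "undirected"))
  oracle <- lapply(split(genes, comp$membership), sort)
  expect_setequal(lapply(cl$clusters, sort), unname(oracle))
})

test_that("MCL output is a partition and is stable under gene relabeling", {
  net <- default_bundle()$network
  sub <- induced_network(net, net$genes[1:120])
  cl <- mcl_cluster(sub)
  all_members <- c(unlist(cl$clusters), cl$singletons)
  expect_setequal(all_members, sub$genes)
  expect_equal(anyDuplicated(all_members), 0L)

  # relabel genes by a fixed permutation: same partition up to names
  map <- stats::setNames(sprintf("zz%03d", seq_along(sub$genes)),
                         sub$genes)
  relinks <- sub$links
  relinks$gene_a <- unname(map[relinks$gene_a])
  relinks$gene_b <- unname(map[relinks$gene_b])
  cl2 <- mcl_cluster(fcnet(relinks, genes = unname(map)))
  back <- lapply(cl2$clusters, function(cl_genes)
    sort(names(map)[match(cl_genes, map)]))
  expect_setequal(back, lapply(cl$clusters, sort))
})

test_that("shared-neighbor clustering separates cliques and excludes pendants", {
  two <- make_net(rbind(clique_pairs(sprintf("a%d", 1:5)),
                        clique_pairs(sprintf("b%d", 1:4))))
  for (theta in c(0.1, 0.5, 0.9)) {
    cl <- sharedneighbor_cluster(two, theta = theta)
    expect_equal(length(cl$clusters), 2L)
    expect_setequal(cl$clusters[[1]], sprintf("a%d", 1:5))
  }

  # pendant on a 5-clique: affinity to its anchor is 2/(size+1) = 1/3,
  # below theta = 0.5, so the pendant stays out
  pend <- make_net(rbind(clique_pairs(sprintf("c%d", 1:5)),
                         c("c1", "p")))
  cl <- sharedneighbor_cluster(pend, theta = 0.5)
  expect_setequal(cl$clusters[[1]], sprintf("c%d", 1:5))
  expect_equal(cl$singletons, "p")
})

test_that("both clusterers recover planted modules in the default bundle", {
  b <- default_bundle()
  bias <- default_bias()
  sub <- build_subnetwork(b$network, bias, "male")
  module_genes <- b$truth$gene[!is.na(b$truth$module) &
                                 b$truth$module %in% c(1L, 2L)]
  truth <- stats::setNames(b$truth$module, b$truth$gene)
  expect_gte(ari_against_truth(mcl_cluster(sub), module_genes, truth), 0.8)
  expect_gte(ari_against_truth(sharedneighbor_cluster(sub), module_genes,
                               truth), 0.9)
})

test_that("go_enrichment requires two carriers and the hypergeometric tail", {
  bg <- sprintf("g%03d", 1:100)
  annot <- data.frame(gene = c(bg[1:5], bg[6]),
                      term = c(rep("T1", 5), "T2"))
  # cluster of 5, all carrying T1; T2 carried by a single cluster gene
  cluster <- c(bg[1:5], bg[6])[1:5]
  res <- go_enrichment(cluster, bg, annot)
  expect_equal(res$term, "T1")
  expect_equal(res$p, 1 / choose(100, 5), tolerance = 1e-12)
  single <- go_enrichment(bg[6], bg, annot)  # one gene can never enrich
  expect_equal(nrow(single), 0L)
  none <- go_enrichment(cluster, bg,
                        data.frame(gene = character(),
                                   term = character()))
  expect_equal(nrow(none), 0L)
  expect_error(go_enrichment("zzz", bg, annot), "subset")
})

test_that("clustering significance separates planted from uniform annotation", {
  b <- default_bundle()
  bias <- default_bias()
  sub <- build_subnetwork(b$network, bias, "male")
  modlist <- lapply(1:2, function(i)
    intersect(b$truth$gene[!is.na(b$truth$module) & b$truth$module == i],
              sub$network$genes))
  truth_cl <- structure(
    list(clusters = modlist, singletons = character(0),
         genes = sub$network$genes, method = "truth", params = list(),
         converged = TRUE, n_iter = 1L),
    class = "gene_clustering")
  sig <- clustering_significance(truth_cl, sub, b$annotations,
                                 n_rand = 200, seed = 1)
  expect_gt(sig$z, 2)
  expect_equal(sig$n_clusters, 2L)
  expect_equal(sig$n_significant, 2L)
  expect_equal(formals(clustering_significance)$n_rand, 500)

  # annotation with no relation to the clustering: |z| < 2 in most seeds
  set.seed(8)
  unet <- er_net(80, 0.08, seed = 12, prefix = "u")
  genes <- unet$genes
  annot <- data.frame(gene = sample(genes, 160, replace = TRUE),
                      term = sample(sprintf("T%02d", 1:10), 160,
                                    replace = TRUE))
  part_cl <- structure(
    list(clusters = list(genes[1:10], genes[11:25], genes[26:33]),
         singletons = genes[34:80], genes = genes, method = "arbitrary",
         params = list(), converged = TRUE, n_iter = 1L),
    class = "gene_clustering")
  zs <- vapply(1:25, function(s)
    clustering_significance(part_cl, unet, annot, n_rand = 60,
                            seed = s)$z, numeric(1))
  expect_gte(mean(abs(zs) < 2), 0.8)
})

test_that("compare_clusterings computes Jaccard overlap and UPGMA trees", {
  mk <- function(clusters, method) structure(
    list(clusters = clusters, singletons = character(0),
         genes = sort(unlist(clusters)), method = method, params = list(),
         converged = TRUE, n_iter = 1L), class = "gene_clustering")
  c1 <- mk(list(c("a", "b", "c"), c("d", "e")), "mcl")
  cmp_same <- compare_clusterings(c1, mk(c1$clusters, "mgclus_like"))
  expect_equal(diag(cmp_same$jaccard_genes), c(1, 1),
               ignore_attr = TRUE)
  expect_true(all(cmp_same$best_overlap$best_overlap == 1))

  c2 <- mk(list(c("b", "c", "d"), c("e", "a")), "mgclus_like")
  cmp <- compare_clusterings(c1, c2)
  expect_equal(cmp$jaccard_genes["mcl_1", "mgclus_like_1"], 0.5)
  expect_match(cmp$tree_genes, "^\\(")
})

test_that("UPGMA reproduces hand-computed heights and is ultrametric", {
  d <- matrix(c(0, 0.2, 0.6,
                0.2, 0, 0.8,
                0.6, 0.8, 0), 3, 3,
              dimnames = list(c("c1", "c2", "c3"), c("c1", "c2", "c3")))
  tree <- upgma_tree(d)
  # c1 and c2 join at height 0.1; c3 joins at mean(0.6, 0.8)/2 = 0.35
  depths <- ape::node.depth.edgelength(tree$phylo)
  total <- max(depths)
  expect_equal(total, 0.35, tolerance = 1e-12)
  internal <- sort(total - depths[-(1:3)])  # heights of root and join node
  expect_equal(internal, c(0.1, 0.35), tolerance = 1e-12)
  expect_true(ape::is.ultrametric(tree$phylo))

  # ultrametric on random distance matrices too
  set.seed(6)
  for (i in 1:5) {
    n <- sample(4:8, 1)
    m <- matrix(stats::runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(sprintf("x%d", 1:n), sprintf("x%d", 1:n))
    expect_true(ape::is.ultrametric(upgma_tree(m)$phylo))
  }
})
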