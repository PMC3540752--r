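#' Parameters of the synthetic study generator
#'
#' Bundles every knob of the synthetic data generator. The defaults emulate
#' a moderately sex-biased tissue profiled on a small replicated microarray
#' design over a scale-free functional-coupling network: 2000 genes, three
#' replicate pools per sex, a log2 effect of 2.5 for biased genes, 20% of
#' genes biased, and three planted 30-gene modules (two male, one female)
#' whose members receive on average `multiplier = 8` additional
#' within-module links each, making them clear communities against the
#' sparse background.
#'
#' @param n_genes number of genes.
#' @param degree_exponent target power-law exponent of the degree
#'   distribution.
#' @param mean_degree target mean degree of the background network.
#' @param planted_modules list of modules, each a list with `size`, `bias`
#'   (`"male"`, `"female"` or `"unbiased"`) and `multiplier` (expected
#'   number of planted within-module links per member). Modules are laid
#'   out as a scaffold core of two hub members coupled to every member at
#'   maximum confidence, plus stochastic member-member links filling the
#'   expected within-module degree up to the multiplier.
#' @param effect_size_delta log2 expression shift added to the favored sex
#'   of a biased gene.
#' @param reps_per_sex replicate pools per sex (default 3).
#' @param variance_shape,variance_scale inverse-gamma hyperparameters of the
#'   per-gene log2 expression variance (defaults give mean variance 0.5).
#' @param biased_fraction fraction of genes with a true sex bias (split
#'   equally between the sexes, planted-module members included).
#' @param ortholog_group_sizes integer vector of inparalog group sizes.
#' @param concordance probability that an ortholog group is drawn entirely
#'   from genes of one true bias label.
#' @param z_fraction fraction of genes tagged as Z-chromosome.
#' @param annotation_terms number of background annotation terms.
#' @param terms_per_module number of private annotation terms painted on
#'   each planted module; real ontologies annotate a pathway with many
#'   correlated terms, so module clusters show several enriched terms.
#' @param annotation_noise fraction of each planted module left unpainted
#'   by each of its private annotation terms.
#' @param seed master seed; per-stage seeds are derived from it.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_genes = 2000L,
                       degree_exponent = 2.3,
                       mean_degree = 6,
                       planted_modules = list(
                         list(size = 30L, bias = "male", multiplier = 8),
                         list(size = 30L, bias = "male", multiplier = 8),
                         list(size = 30L, bias = "female", multiplier = 8)),
                       effect_size_delta = 2.5,
                       reps_per_sex = 3L,
                       variance_shape = 4,
                       variance_scale = 1.5,
                       biased_fraction = 0.2,
                       ortholog_group_sizes = rep(c(2L, 3L, 4L),
                                                  c(20L, 12L, 8L)),
                       concordance = 0.9,
                       z_fraction = 0.1,
                       annotation_terms = 40L,
                       terms_per_module = 5L,
                       annotation_noise = 0.1,
                       seed = 1L) {
  p <- list(n_genes = as.integer(n_genes),
            degree_exponent = degree_exponent,
            mean_degree = mean_degree,
            planted_modules = planted_modules,
            effect_size_delta = effect_size_delta,
            reps_per_sex = as.integer(reps_per_sex),
            variance_shape = variance_shape,
            variance_scale = variance_scale,
            biased_fraction = biased_fraction,
            ortholog_group_sizes = as.integer(ortholog_group_sizes),
            concordance = concordance,
            z_fraction = z_fraction,
            annotation_terms = as.integer(annotation_terms),
            terms_per_module = as.integer(terms_per_module),
            annotation_noise = annotation_noise,
            seed = as.integer(seed))
  stopifnot(p$n_genes >= 10L, p$mean_degree > 0,
            p$degree_exponent > 1,
            p$reps_per_sex >= 2L,
            p$biased_fraction >= 0, p$biased_fraction <= 1,
            p$concordance >= 0, p$concordance <= 1,
            p$z_fraction >= 0, p$z_fraction <= 1,
            p$annotation_noise >= 0, p$annotation_noise <= 1,
            p$terms_per_module >= 1L,
            all(p$ortholog_group_sizes >= 2L))
  for (m in p$planted_modules) {
    stopifnot(m$size >= 2L, m$bias %in% c("male", "female", "unbiased"),
              m$multiplier >= 0)
  }
  class(p) <- "sim_params"
  p
}

# Deterministic per-stage seed derivation from the master seed; kept below
# 2^31 so it is a valid R integer seed.
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) * 7919 + stage * 104729) %% 2147483647)
}

#' Simulate a scale-free network with planted modules
#'
#' Draws a power-law degree sequence (exponent `degree_exponent`, scaled to
#' `mean_degree`, capped at `n_genes - 1`), realizes it with a
#' configuration model, and simplifies the result (self-loops and
#' multi-edges removed). Planted-module members then receive additional
#' within-module links: a two-hub scaffold at confidence 1 (the strongly
#' supported core of a complex or pathway) plus random member pairs at
#' background confidence, together giving each member an expected
#' within-module degree of `multiplier`. Background link confidences are
#' drawn uniformly from (0.25, 1], i.e. above the usual working cutoff.
#'
#' Ground-truth bias labels are assigned so that `biased_fraction` of genes
#' are biased in total, split equally between the sexes; planted-module
#' members inherit their module's bias and count towards the totals.
#'
#' @param params a [sim_params] object.
#' @return List with `network` (an [fcnet]) and `truth` (data.frame `gene`,
#'   `bias`, `module`, `chromosome_class`).
#' @export
simulate_network <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 1L))
  n <- params$n_genes
  genes <- sprintf("g%04d", seq_len(n))

  kmax <- n - 1L
  ks <- seq_len(kmax)
  w <- ks^(-params$degree_exponent)
  # tune the minimum degree so the expected degree of the truncated power
  # law matches mean_degree (rescaling draws instead would distort the
  # power-law shape)
  mean_for_kmin <- rev(cumsum(rev(ks * w))) / rev(cumsum(rev(w)))
  kmin <- which.min(abs(mean_for_kmin - params$mean_degree))
  kk <- kmin:kmax
  d <- sample(kk, n, replace = TRUE,
              prob = kk^(-params$degree_exponent))
  if (sum(d) %% 2L == 1L) d[which.max(d)] <- d[which.max(d)] + 1L
  g <- igraph::sample_degseq(d, method = "configuration")
  g <- igraph::simplify(g)
  edges <- igraph::as_edgelist(g, names = FALSE)

  # disjoint planted modules
  sizes <- vapply(params$planted_modules, function(m) as.integer(m$size),
                  integer(1))
  if (sum(sizes) > n) stop("planted modules exceed the gene count")
  pool <- sample(n)
  module_of <- rep(NA_integer_, n)
  offset <- 0L
  extra <- list()
  for (mi in seq_along(params$planted_modules)) {
    m <- params$planted_modules[[mi]]
    idx <- sort(pool[offset + seq_len(sizes[mi])])
    offset <- offset + sizes[mi]
    module_of[idx] <- mi
    # scaffold core: two hub members coupled to every other member at
    # maximum confidence, emulating the strongly supported core of a
    # complex or pathway
    n_hub <- min(2L, sizes[mi] - 1L)
    hubs <- sample(idx, n_hub)
    scaffold <- cbind(rep(hubs, each = sizes[mi]),
                      rep(idx, times = n_hub))
    scaffold <- scaffold[scaffold[, 1L] != scaffold[, 2L], , drop = FALSE]
    scaffold <- cbind(pmin(scaffold[, 1L], scaffold[, 2L]),
                      pmax(scaffold[, 1L], scaffold[, 2L]))
    scaffold <- scaffold[!duplicated(scaffold), , drop = FALSE]
    extra[[length(extra) + 1L]] <- cbind(scaffold, 2)  # marker: conf 1
    # stochastic member-member links bringing the expected within-module
    # degree up to the multiplier
    p_extra <- max(0, (m$multiplier - n_hub) / max(1L, sizes[mi] - 1L -
                                                     n_hub))
    periph <- setdiff(idx, hubs)
    if (length(periph) >= 2L && p_extra > 0) {
      prs <- utils::combn(periph, 2L)
      keep <- stats::runif(ncol(prs)) < min(1, p_extra)
      if (any(keep)) {
        extra[[length(extra) + 1L]] <- cbind(t(prs[, keep, drop = FALSE]),
                                             1)
      }
    }
  }
  edges <- cbind(edges, 0)  # third column: 2 = scaffold, else stochastic
  if (length(extra) > 0L) {
    edges <- rbind(edges, do.call(rbind, extra))
  }
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  # scaffold links win duplicate resolution so they keep confidence 1
  ord <- order(paste(a, b), -edges[, 3L])
  a <- a[ord]
  b <- b[ord]
  kind <- edges[ord, 3L]
  dup <- duplicated(paste(a, b))
  a <- a[!dup]
  b <- b[!dup]
  kind <- kind[!dup]
  conf <- stats::runif(length(a), min = 0.25, max = 1)
  conf[kind == 2] <- 1
  net <- fcnet(data.frame(gene_a = genes[a], gene_b = genes[b],
                          confidence = conf, stringsAsFactors = FALSE),
               genes = genes, cutoff_applied = 0.25)

  # ground-truth bias labels
  bias <- rep("unbiased", n)
  for (mi in seq_along(params$planted_modules)) {
    bias[which(module_of == mi)] <- params$planted_modules[[mi]]$bias
  }
  target_total <- round(params$biased_fraction * n)
  target_sex <- c(male = round(target_total / 2),
                  female = target_total - round(target_total / 2))
  for (sex in c("male", "female")) {
    have <- sum(bias == sex)
    need <- target_sex[[sex]] - have
    if (need > 0) {
      free <- which(bias == "unbiased" & is.na(module_of))
      bias[sample(free, min(need, length(free)))] <- sex
    }
  }
  chrom <- ifelse(stats::runif(n) < params$z_fraction, "Z", "autosome")
  truth <- data.frame(gene = genes, bias = bias, module = module_of,
                      chromosome_class = chrom, stringsAsFactors = FALSE)
  list(network = net, truth = truth)
}

#' Simulate a MAS5-scale expression matrix from ground truth
#'
#' Per gene, a log2 baseline ~ Normal(8, 1) and a variance drawn from an
#' inverse-gamma prior; male-biased genes gain `effect_size_delta` log2
#' units in male samples and female-biased genes in female samples. One
#' condition (adult gonad by default) with `reps_per_sex` replicate pools
#' per sex is emitted; intensities are `2^log2value`, hence positive.
#'
#' @param params a [sim_params].
#' @param truth truth data.frame from [simulate_network()].
#' @param tissue,stage condition labels recorded in the sample metadata.
#' @return List with `values` (matrix genes x samples) and `sample_meta`.
#' @export
simulate_expression <- function(params, truth, tissue = "gonad",
                                stage = "adult") {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 2L))
  n <- nrow(truth)
  reps <- params$reps_per_sex
  if (reps < 2L) stop("reps_per_sex must be at least 2")
  sigma2 <- 1 / stats::rgamma(n, shape = params$variance_shape,
                              rate = params$variance_scale)
  baseline <- stats::rnorm(n, mean = 8, sd = 1)
  sex <- rep(c("male", "female"), each = reps)
  samples <- paste0(substr(sex, 1, 1), rep(seq_len(reps), times = 2L))
  shift <- outer(ifelse(truth$bias == "male", params$effect_size_delta, 0),
                 as.numeric(sex == "male")) +
    outer(ifelse(truth$bias == "female", params$effect_size_delta, 0),
          as.numeric(sex == "female"))
  noise <- matrix(stats::rnorm(n * length(sex), sd = sqrt(sigma2)),
                  nrow = n)
  logvals <- baseline + shift + noise
  values <- 2^logvals
  dimnames(values) <- list(truth$gene, samples)
  meta <- data.frame(sample = samples, sex = sex, tissue = tissue,
                     stage = stage, replicate = rep(seq_len(reps), 2L),
                     stringsAsFactors = FALSE)
  list(values = values, sample_meta = meta)
}

#' Simulate inparalog groups with tunable bias concordance
#'
#' With probability `concordance` a group is drawn entirely from genes of
#' one true bias label (the label itself sampled with probability
#' proportional to the label's gene frequency); otherwise its members are
#' drawn independently and uniformly from all genes.
#'
#' @param params a [sim_params].
#' @param truth truth data.frame from [simulate_network()].
#' @return An `ortholog_groups` object (see [load_groups()]).
#' @export
simulate_orthologs <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 3L))
  genes <- truth$gene
  by_label <- split(genes, truth$bias)
  groups <- list()
  for (i in seq_along(params$ortholog_group_sizes)) {
    k <- params$ortholog_group_sizes[i]
    concordant <- stats::runif(1) < params$concordance
    if (concordant) {
      lab <- truth$bias[sample(length(genes), 1L)]
      pool <- by_label[[lab]]
      if (length(pool) < k) pool <- genes  # degenerate label pool
      members <- sample(pool, k)
    } else {
      members <- sample(genes, k)
    }
    groups[[sprintf("og%03d", i)]] <- sort(members)
  }
  structure(list(groups = groups, n_total = length(groups),
                 n_dropped = 0L),
            class = "ortholog_groups")
}

#' Simulate gene annotations with module-private terms
#'
#' Every planted module gets `terms_per_module` private terms, each painted
#' independently on a fraction `1 - annotation_noise` of its members;
#' `annotation_terms` background terms are each assigned to a uniformly
#' drawn gene set of size 5-30.
#'
#' @param params a [sim_params].
#' @param truth truth data.frame from [simulate_network()].
#' @return Annotation data.frame with columns `gene`, `term`.
#' @export
simulate_annotations <- function(params, truth) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(derive_seed(params$seed, 4L))
  rows <- list()
  for (mi in seq_along(params$planted_modules)) {
    members <- truth$gene[!is.na(truth$module) & truth$module == mi]
    n_paint <- max(0L, ceiling((1 - params$annotation_noise) *
                                 length(members)))
    if (n_paint > 0L) {
      for (tm in seq_len(params$terms_per_module)) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = sample(members, n_paint),
          term = sprintf("MOD%02d_%02d", mi, tm), stringsAsFactors = FALSE)
      }
    }
  }
  for (t in seq_len(params$annotation_terms)) {
    size <- sample(5:30, 1L)
    rows[[length(rows) + 1L]] <- data.frame(
      gene = sample(truth$gene, size),
      term = sprintf("T%03d", t), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$gene, out$term), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate the complete input bundle
#'
#' Runs all generators with per-stage seeds derived from the master seed
#' and returns every input the pipeline consumes plus the ground truth.
#'
#' @param params a [sim_params].
#' @return List of class `sim_bundle` with `params`, `network`, `truth`,
#'   `expression` (list `values`, `sample_meta`), `groups`, `annotations`
#'   and `chromosomes` (named vector).
#' @export
simulate_bundle <- function(params = sim_params()) {
  nt <- simulate_network(params)
  expr <- simulate_expression(params, nt$truth)
  groups <- simulate_orthologs(params, nt$truth)
  annot <- simulate_annotations(params, nt$truth)
  structure(
    list(params = params,
         network = nt$network,
         truth = nt$truth,
         expression = expr,
         groups = groups,
         annotations = annot,
         chromosomes = stats::setNames(nt$truth$chromosome_class,
                                       nt$truth$gene)),
    class = "sim_bundle"
  )
}

#' Write a simulated bundle to a directory of TSV files
#'
#' Emits `network.tsv`, `expression.tsv`, `samples.tsv`, `groups.tsv`,
#' `chromosomes.tsv`, `annotations.tsv` and `truth.tsv`, all in the formats
#' the package readers consume, so a written bundle round-trips through
#' [read_network()], [read_expression()], [read_sample_meta()],
#' [load_groups()] and [read_chromosome_table()].
#'
#' @param bundle a `sim_bundle` from [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  write_network(bundle$network, file.path(dir, "network.tsv"))
  expr <- data.frame(gene = rownames(bundle$expression$values),
                     bundle$expression$values, check.names = FALSE,
                     stringsAsFactors = FALSE)
  wt(expr, "expression.tsv")
  wt(bundle$expression$sample_meta, "samples.tsv")
  gdf <- data.frame(
    group_id = rep(names(bundle$groups$groups),
                   vapply(bundle$groups$groups, length, integer(1))),
    gene_id = unlist(bundle$groups$groups, use.names = FALSE),
    stringsAsFactors = FALSE)
  wt(gdf, "groups.tsv")
  wt(data.frame(gene_id = names(bundle$chromosomes),
                class = unname(bundle$chromosomes),
                stringsAsFactors = FALSE), "chromosomes.tsv")
  wt(bundle$annotations, "annotations.tsv")
  wt(bundle$truth, "truth.tsv")
  invisible(dir)
}
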