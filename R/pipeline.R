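#' Pipeline configuration
#'
#' Collects the input locations (file paths or in-memory objects) and every
#' analysis parameter, all defaulting to the package's standard working
#' values: confidence cutoff 0.25, bias FDR cutoff 0.1, 100 crosstalk
#' randomizations, 1000 inparalog resampling replicates, 500 random modules
#' per cluster size, Bonferroni recruitment cutoff 0.1, MCL inflation 3.5
#' and 20 top hubs.
#'
#' @param network path to a network TSV or an [fcnet].
#' @param expression path to an expression TSV or a genes x samples matrix.
#' @param sample_meta path to a sample metadata TSV or a data.frame.
#' @param groups optional path to a groups TSV or `ortholog_groups` object.
#' @param chromosomes optional path to a chromosome TSV or named vector.
#' @param annotations optional path to an annotation TSV or data.frame.
#' @param out_dir output directory for all result tables.
#' @param confidence_cutoff link confidence cutoff.
#' @param fdr_cutoff bias-call FDR cutoff.
#' @param n_rand_crosstalk crosstalk randomizations.
#' @param n_rep_paralogs inparalog resampling replicates.
#' @param n_rand_modules random modules per cluster size.
#' @param bonferroni_cutoff subnetwork recruitment cutoff.
#' @param inflation MCL inflation.
#' @param theta shared-neighbor clustering threshold.
#' @param top_n_hubs hub list length.
#' @param min_biased minimum number of biased genes in the network for a
#'   condition to enter crosstalk/module analysis.
#' @param seed master seed; all stochastic stages derive their seeds from
#'   it deterministically.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(network, expression, sample_meta,
                            groups = NULL, chromosomes = NULL,
                            annotations = NULL,
                            out_dir = "sexbiasnet_results",
                            confidence_cutoff = 0.25,
                            fdr_cutoff = 0.1,
                            n_rand_crosstalk = 100,
                            n_rep_paralogs = 1000,
                            n_rand_modules = 500,
                            bonferroni_cutoff = 0.1,
                            inflation = 3.5,
                            theta = 0.02,
                            top_n_hubs = 20L,
                            min_biased = 10L,
                            seed = 1L) {
  structure(
    list(network = network, expression = expression,
         sample_meta = sample_meta, groups = groups,
         chromosomes = chromosomes, annotations = annotations,
         out_dir = out_dir,
         confidence_cutoff = confidence_cutoff,
         fdr_cutoff = fdr_cutoff,
         n_rand_crosstalk = n_rand_crosstalk,
         n_rep_paralogs = n_rep_paralogs,
         n_rand_modules = n_rand_modules,
         bonferroni_cutoff = bonferroni_cutoff,
         inflation = inflation, theta = theta,
         top_n_hubs = as.integer(top_n_hubs),
         min_biased = as.integer(min_biased),
         seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

load_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Run the full sex-bias network analysis
#'
#' Executes, per tissue/stage condition found in the sample metadata:
#' differential expression (moderated Welch test), bias classification,
#' crosstalk between bias groups (stratified by Z chromosome when a
#' chromosome table is supplied), degree-bias correlation and hub ranking,
#' inparalog concordance testing (when groups are supplied), and sex-biased
#' module discovery with both clusterers (plus GO significance when
#' annotations are supplied). All result tables are written as TSV under
#' `config$out_dir`, together with a JSON run manifest recording every
#' parameter, derived seed and output file, which suffices to reproduce
#' the run. Conditions with too few biased genes in the network skip
#' crosstalk and module discovery with an explicit notice, as such
#' conditions carry no analysable sex-bias signal.
#'
#' Any stage failure aborts the run with a stage-named error and removes
#' the partially written outputs.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with per-condition results and the manifest.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  network <- load_input(config$network, read_network,
                        cutoff = config$confidence_cutoff)
  values <- load_input(config$expression, read_expression)
  meta <- load_input(config$sample_meta, read_sample_meta)
  chromosomes <- if (!is.null(config$chromosomes))
    load_input(config$chromosomes, read_chromosome_table) else NULL
  annotations <- if (!is.null(config$annotations))
    load_input(config$annotations, utils::read.delim,
               stringsAsFactors = FALSE) else NULL

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, file) {
    path <- file.path(config$out_dir, file)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <<- c(written, path)
    path
  }
  notices <- character(0)
  results <- list()
  conds <- unique(meta[, c("tissue", "stage")])

  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  for (ci in seq_len(nrow(conds))) {
    condition <- list(tissue = conds$tissue[ci], stage = conds$stage[ci])
    tag <- paste(condition$tissue, condition$stage, sep = "_")
    res <- list(condition = condition)

    de <- run_stage(paste0("diffexpr:", tag),
                    moderated_welch(values, meta, condition = condition))
    bias <- classify_bias(de, fdr_cutoff = config$fdr_cutoff)
    res$de <- de
    res$bias <- bias
    emit(cbind(de, label = bias$label), paste0("de_", tag, ".tsv"))

    deg <- degrees(network)
    labels <- bias_labels(bias)
    net_labels <- labels[intersect(names(labels), network$genes)]
    n_biased <- sum(net_labels %in% c("male", "female"))

    res$hubs <- run_stage(paste0("hubs:", tag), {
      corr <- suppressWarnings(
        bias_degree_correlation(de, deg, bias))
      hubs <- rank_hubs(de, deg, top_n = config$top_n_hubs)
      emit(corr, paste0("bias_degree_correlation_", tag, ".tsv"))
      emit(hubs, paste0("hubs_", tag, ".tsv"))
      list(correlation = corr, ranking = hubs)
    })

    if (!is.null(config$groups)) {
      res$paralogs <- run_stage(paste0("paralogs:", tag), {
        groups <- load_input(config$groups, load_groups,
                             expression_genes = rownames(values))
        cls <- classify_groups(groups, bias)
        null <- resample_null(groups, bias,
                              n_rep = config$n_rep_paralogs,
                              seed = derive_seed(config$seed, 20L + ci))
        emit(null, paste0("paralogs_", tag, ".tsv"))
        list(classification = cls, null = null)
      })
    }

    if (n_biased < config$min_biased) {
      msg <- sprintf(
        "condition %s: only %d biased gene(s) in the network; crosstalk and module discovery skipped",
        tag, n_biased)
      message(msg)
      notices <- c(notices, msg)
      results[[tag]] <- res
      next
    }

    res$crosstalk <- run_stage(paste0("crosstalk:", tag), {
      part <- make_partition(bias, network, chromosome = chromosomes)
      ct <- crosstalk(network, part, n_rand = config$n_rand_crosstalk,
                      seed = derive_seed(config$seed, 40L + ci))
      emit(ct, paste0("crosstalk_", tag, ".tsv"))
      emit(crosstalk_edges(ct), paste0("crosstalk_edges_", tag, ".tsv"))
      ct
    })

    res$modules <- list()
    for (sex in c("male", "female")) {
      if (sum(net_labels == sex) < config$min_biased) {
        msg <- sprintf("condition %s: too few %s-biased genes for modules",
                       tag, sex)
        message(msg)
        notices <- c(notices, msg)
        next
      }
      res$modules[[sex]] <- run_stage(paste0("netmodules:", tag, ":", sex), {
        sub <- build_subnetwork(network, bias, sex,
                                bonferroni_cutoff = config$bonferroni_cutoff)
        mcl <- mcl_cluster(sub, inflation = config$inflation)
        sn <- sharedneighbor_cluster(sub, theta = config$theta)
        memb <- function(cl, method) {
          mm <- cluster_membership(cl)
          data.frame(cluster_id = paste0(method, "_", unname(mm)),
                     gene = names(mm),
                     bias = unname(labels[names(mm)]),
                     stringsAsFactors = FALSE)
        }
        emit(rbind(memb(mcl, "mcl"), memb(sn, "mgclus_like")),
             paste0("modules_", tag, "_", sex, ".tsv"))
        out <- list(subnetwork = sub, mcl = mcl, sharedneighbor = sn)
        if (!is.null(annotations) && length(mcl$clusters) > 0L &&
            length(sn$clusters) > 0L) {
          sig <- lapply(
            stats::setNames(list(mcl, sn), c("mcl", "mgclus_like")),
            clustering_significance, subnetwork = sub,
            annot = annotations, n_rand = config$n_rand_modules,
            seed = derive_seed(config$seed, 60L + ci))
          sig_df <- do.call(rbind, lapply(names(sig), function(mth) {
            s <- sig[[mth]]
            data.frame(method = mth, clusters = s$n_clusters,
                       significant = s$n_significant,
                       avg_sig_terms = s$avg_enriched,
                       random_avg_sig_terms = s$random_avg,
                       z = s$z, stringsAsFactors = FALSE)
          }))
          emit(sig_df, paste0("module_significance_", tag, "_", sex,
                              ".tsv"))
          cmp <- compare_clusterings(mcl, sn, annot = annotations,
                                     background = sub$network$genes)
          tree_path <- file.path(config$out_dir,
                                 paste0("upgma_", tag, "_", sex, ".nwk"))
          writeLines(c(cmp$tree_genes, cmp$tree_terms), tree_path)
          written <- c(written, tree_path)
          out$significance <- sig
          out$comparison <- cmp
        }
        out
      })
    }
    results[[tag]] <- res
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("sexbiasnet")),
    r_version = R.version.string,
    parameters = config[!(names(config) %in%
                            c("network", "expression", "sample_meta",
                              "groups", "chromosomes", "annotations"))],
    inputs = lapply(config[c("network", "expression", "sample_meta",
                             "groups", "chromosomes", "annotations")],
                    function(x) if (is.character(x)) x else class(x)[1L]),
    master_seed = config$seed,
    derived_seeds = list(
      paralogs = derive_seed(config$seed, 21L),
      crosstalk = derive_seed(config$seed, 41L),
      modules = derive_seed(config$seed, 61L)),
    conditions = paste(conds$tissue, conds$stage, sep = "_"),
    notices = notices,
    outputs = basename(written))
  manifest_path <- file.path(config$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, force = TRUE)
  invisible(list(results = results, manifest = manifest,
                 manifest_path = manifest_path))
}
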