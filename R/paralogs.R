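#' Load inparalog groups from a TSV of (group_id, gene_id) pairs
#'
#' Groups are filtered to members with expression data; groups that drop
#' below 2 members are excluded and counted. This mirrors the usual setting
#' where ortholog groups come pre-extracted from an InParanoid-style
#' database and only group membership is used.
#'
#' @param path path to a TSV with header columns `group_id`, `gene_id`.
#' @param expression_genes character vector of genes with expression data.
#' @return Object of class `ortholog_groups`: list with `groups` (named list
#'   of member gene vectors, every group of size >= 2), `n_total` groups in
#'   the file and `n_dropped` groups lost to the expression filter.
#' @export
load_groups <- function(path, expression_genes) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0L) stop("empty ortholog group file: ", path)
  if (!all(c("group_id", "gene_id") %in% names(df))) {
    stop("group file must have columns group_id, gene_id")
  }
  all_groups <- split(df$gene_id, df$group_id)
  all_groups <- lapply(all_groups, unique)
  filtered <- lapply(all_groups, intersect, y = expression_genes)
  keep <- vapply(filtered, length, integer(1)) >= 2L
  structure(
    list(groups = filtered[keep],
         n_total = length(all_groups),
         n_dropped = sum(!keep)),
    class = "ortholog_groups"
  )
}

#' @export
print.ortholog_groups <- function(x, ...) {
  cat(sprintf("ortholog_groups: %d group(s) retained, %d dropped of %d\n",
              length(x$groups), x$n_dropped, x$n_total))
  invisible(x)
}

as_ortholog_groups <- function(groups) {
  if (inherits(groups, "ortholog_groups")) return(groups)
  stopifnot(is.list(groups))
  structure(list(groups = groups, n_total = length(groups), n_dropped = 0L),
            class = "ortholog_groups")
}

classify_one_group <- function(members, labels) {
  lab <- labels[members]
  if (anyNA(lab)) {
    stop("gene(s) without a bias label: ",
         paste(members[is.na(lab)], collapse = ", "))
  }
  u <- unique(lab)
  if (length(u) == 1L) {
    switch(u, male = "all_male", female = "all_female",
           unbiased = "all_unbiased",
           stop("unexpected bias label: ", u))
  } else {
    "mixed"
  }
}

#' Classify inparalog groups by sex-bias concordance
#'
#' Each group is labelled `all_male`, `all_female` or `all_unbiased` when
#' every member shares that bias, and `mixed` otherwise. Mixed groups that
#' contain at least one male-biased and one female-biased member are counted
#' separately (`mixed_mf`) - these are candidates for subfunctionalization
#' driven by sex differentiation.
#'
#' @param groups an `ortholog_groups` object (or plain named list of member
#'   vectors).
#' @param bias a `bias_table` or named label vector covering all members.
#' @return Object of class `group_classification`: list with `counts` (named
#'   integer vector over the four categories), `mixed_mf`, and `per_group`
#'   (data.frame `group`, `class`, `has_male_and_female`).
#' @export
classify_groups <- function(groups, bias) {
  groups <- as_ortholog_groups(groups)
  labels <- bias_labels(bias)
  cls <- vapply(groups$groups, classify_one_group, character(1),
                labels = labels)
  has_mf <- vapply(groups$groups, function(m) {
    lab <- labels[m]
    any(lab == "male") && any(lab == "female")
  }, logical(1))
  counts <- vapply(c("all_male", "all_female", "all_unbiased", "mixed"),
                   function(k) sum(cls == k), integer(1))
  structure(
    list(counts = counts,
         mixed_mf = sum(has_mf),
         per_group = data.frame(group = names(groups$groups), class = cls,
                                has_male_and_female = has_mf,
                                stringsAsFactors = FALSE,
                                row.names = NULL)),
    class = "group_classification"
  )
}

#' @export
print.group_classification <- function(x, ...) {
  cat("inparalog group classification:\n")
  print(x$counts)
  cat(sprintf("mixed groups with both male- and female-biased members: %d\n",
              x$mixed_mf))
  invisible(x)
}

#' Resampling null for inparalog bias concordance
#'
#' Tests whether the observed numbers of concordant (and mixed) inparalog
#' groups could arise by chance. Each replicate redraws, for every group,
#' the same number of genes uniformly without replacement from the complete
#' expression universe, re-classifies the pseudo-groups and tallies category
#' counts. The empirical p-value per category is one-sided in the direction
#' of the observed deviation, with an add-one correction so it never equals
#' zero: `(1 + #{null >= observed}) / (n_rep + 1)` when the observed count
#' exceeds the null mean (direction `+`), and with `<=` otherwise
#' (direction `-`).
#'
#' @param groups an `ortholog_groups` object.
#' @param bias a `bias_table` or named label vector; its genes define the
#'   default sampling universe.
#' @param n_rep number of resampling replicates (default 1000).
#' @param seed integer seed.
#' @param universe optional character vector to sample from; defaults to all
#'   genes with a bias label (i.e. the complete expression dataset).
#' @return data.frame of class `resample_null` with columns `category`,
#'   `observed`, `null_mean`, `null_sd`, `p`, `direction`; categories are
#'   `all_male`, `all_female`, `all_unbiased`, `mixed`, `mixed_mf` and
#'   `same_bias` (groups whose members all share one *biased* label, i.e.
#'   all-male plus all-female - the headline concordance statistic).
#' @export
resample_null <- function(groups, bias, n_rep = 1000, seed = 1,
                          universe = NULL) {
  groups <- as_ortholog_groups(groups)
  if (n_rep < 100L) stop("n_rep must be at least 100")
  labels <- bias_labels(bias)
  if (is.null(universe)) universe <- names(labels)
  if (!all(universe %in% names(labels))) {
    stop("every universe gene must carry a bias label")
  }
  sizes <- vapply(groups$groups, length, integer(1))
  if (length(sizes) == 0L) stop("no groups to test")
  if (max(sizes) > length(universe)) {
    stop("sampling universe is smaller than the largest group")
  }
  obs_cls <- classify_groups(groups, labels)
  categories <- c("all_male", "all_female", "all_unbiased", "mixed",
                  "mixed_mf", "same_bias")
  observed <- c(obs_cls$counts, mixed_mf = obs_cls$mixed_mf,
                same_bias = unname(obs_cls$counts["all_male"] +
                                     obs_cls$counts["all_female"]))[categories]

  if (!is.null(seed)) set.seed(seed)
  null_counts <- matrix(0L, nrow = n_rep, ncol = length(categories),
                        dimnames = list(NULL, categories))
  for (r in seq_len(n_rep)) {
    tallies <- c(all_male = 0L, all_female = 0L, all_unbiased = 0L,
                 mixed = 0L, mixed_mf = 0L, same_bias = 0L)
    for (k in sizes) {
      lab <- labels[sample(universe, k)]
      u <- unique(lab)
      if (length(u) == 1L) {
        key <- switch(u, male = "all_male", female = "all_female",
                      unbiased = "all_unbiased")
        tallies[key] <- tallies[key] + 1L
        if (u != "unbiased") tallies["same_bias"] <- tallies["same_bias"] + 1L
      } else {
        tallies["mixed"] <- tallies["mixed"] + 1L
        if (any(lab == "male") && any(lab == "female")) {
          tallies["mixed_mf"] <- tallies["mixed_mf"] + 1L
        }
      }
    }
    null_counts[r, ] <- tallies
  }
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, stats::sd)
  direction <- ifelse(observed > null_mean, "+", "-")
  p <- vapply(seq_along(categories), function(i) {
    if (direction[i] == "+") {
      (1 + sum(null_counts[, i] >= observed[i])) / (n_rep + 1)
    } else {
      (1 + sum(null_counts[, i] <= observed[i])) / (n_rep + 1)
    }
  }, numeric(1))
  out <- data.frame(category = categories, observed = unname(observed),
                    null_mean = unname(null_mean),
                    null_sd = unname(null_sd), p = p,
                    direction = unname(direction),
                    stringsAsFactors = FALSE)
  attr(out, "n_rep") <- n_rep
  class(out) <- c("resample_null", "data.frame")
  out
}

#' Link sharing between two genes (duplicate pair report)
#'
#' Compares the network neighborhoods of two genes (typically a duplicate
#' pair) at a given confidence cutoff, excluding the pair link itself:
#' reports the fraction of each gene's links not shared with the other and
#' the number of shared links.
#'
#' @param network an [fcnet].
#' @param gene_a,gene_b gene ids present in the network.
#' @param cutoff optional confidence cutoff; only links with confidence
#'   strictly above it are considered (default: all links of the network).
#' @return List with `shared` (count), `frac_a_unshared`, `frac_b_unshared`,
#'   `n_a`, `n_b` (neighborhood sizes). Fractions are `NaN` for a gene with
#'   no qualifying links.
#' @export
shared_links <- function(network, gene_a, gene_b, cutoff = NULL) {
  stopifnot(inherits(network, "fcnet"))
  absent <- setdiff(c(gene_a, gene_b), network$genes)
  if (length(absent) > 0L) {
    stop("gene(s) absent from network: ", paste(absent, collapse = ", "))
  }
  links <- network$links
  if (!is.null(cutoff)) links <- links[links$confidence > cutoff, ,
                                       drop = FALSE]
  nbrs <- function(g) {
    setdiff(unique(c(links$gene_b[links$gene_a == g],
                     links$gene_a[links$gene_b == g])),
            c(gene_a, gene_b))
  }
  na <- nbrs(gene_a)
  nb <- nbrs(gene_b)
  shared <- length(intersect(na, nb))
  list(shared = shared,
       frac_a_unshared = if (length(na) > 0) 1 - shared / length(na) else NaN,
       frac_b_unshared = if (length(nb) > 0) 1 - shared / length(nb) else NaN,
       n_a = length(na), n_b = length(nb))
}
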