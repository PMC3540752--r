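#' Construct a functional-coupling network object
#'
#' An `fcnet` holds an undirected, simple, weighted gene network: a link table
#' with one row per unordered gene pair and a per-link confidence in (0, 1],
#' plus the set of genes (which may include isolated genes). Links are stored
#' in canonical order (`gene_a <= gene_b` lexicographically, rows sorted) so
#' that written files diff reproducibly.
#'
#' @param links data.frame with columns `gene_a`, `gene_b`, `confidence` and
#'   optionally `category` (one of `"metabolic"`, `"signaling"`, `"combined"`,
#'   `"total"`).
#' @param genes character vector of gene ids; endpoints of `links` are added
#'   automatically. Gene ids are opaque, case-sensitive strings.
#' @param cutoff_applied confidence cutoff that was applied to produce this
#'   network, recorded for provenance (`NA` if unknown).
#' @return An object of class `fcnet` with elements `links`, `genes`,
#'   `cutoff_applied`.
#' @export
fcnet <- function(links, genes = character(), cutoff_applied = NA_real_) {
  stopifnot(is.data.frame(links))
  required <- c("gene_a", "gene_b", "confidence")
  if (!all(required %in% names(links))) {
    stop("links must have columns gene_a, gene_b, confidence")
  }
  links$gene_a <- as.character(links$gene_a)
  links$gene_b <- as.character(links$gene_b)
  if (!"category" %in% names(links)) {
    links$category <- rep(NA_character_, nrow(links))
  }
  links <- links[, c("gene_a", "gene_b", "confidence", "category")]
  if (any(links$gene_a == links$gene_b)) {
    stop("self-links are not allowed in an fcnet")
  }
  bad <- !is.finite(links$confidence) | links$confidence <= 0 |
    links$confidence > 1
  if (any(bad)) {
    stop("link confidence must lie in (0, 1]; offending rows: ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  # canonical unordered order
  swap <- links$gene_a > links$gene_b
  if (any(swap)) {
    tmp <- links$gene_a[swap]
    links$gene_a[swap] <- links$gene_b[swap]
    links$gene_b[swap] <- tmp
  }
  key <- paste(links$gene_a, links$gene_b, links$category, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate links for the same gene pair")
  links <- links[order(links$gene_a, links$gene_b), , drop = FALSE]
  rownames(links) <- NULL
  genes <- sort(unique(c(as.character(genes), links$gene_a, links$gene_b)))
  if (any(!nzchar(genes))) stop("gene ids must be nonempty strings")
  structure(
    list(links = links, genes = genes, cutoff_applied = cutoff_applied),
    class = "fcnet"
  )
}

#' @export
print.fcnet <- function(x, ...) {
  cat(sprintf("fcnet: %d genes, %d links", length(x$genes), nrow(x$links)))
  if (!is.na(x$cutoff_applied)) {
    cat(sprintf(" (confidence > %g)", x$cutoff_applied))
  }
  cat("\n")
  invisible(x)
}

#' Read a functional-coupling network from a TSV edge list
#'
#' The file must be tab-separated with a header line naming at least
#' `gene_a`, `gene_b` and `confidence`, and optionally `category`. Lines
#' starting with `#` are treated as comments. Duplicate unordered pairs are
#' collapsed keeping the maximum confidence; self-links are dropped with a
#' warning; links are retained when `confidence > cutoff`.
#'
#' The default cutoff of 0.25 is the working confidence threshold used for
#' FunCoup-style networks, a tradeoff between accuracy and coverage.
#'
#' @param path path to the TSV file.
#' @param cutoff confidence cutoff in `[0, 1)`; only links with confidence
#'   strictly above it are kept.
#' @param category optional link category to keep (e.g. `"metabolic"`); needs
#'   a `category` column in the file.
#' @return An [fcnet] object with `cutoff_applied` recorded.
#' @export
read_network <- function(path, cutoff = 0.25, category = NULL) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L || cutoff < 0 ||
      cutoff >= 1) {
    stop("cutoff must be a single number in [0, 1)")
  }
  raw <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  required <- c("gene_a", "gene_b", "confidence")
  if (!all(required %in% names(raw))) {
    stop("network file must have header columns gene_a, gene_b, confidence: ",
         path)
  }
  conf <- suppressWarnings(as.numeric(raw$confidence))
  bad <- is.na(conf) | !nzchar(raw$gene_a) | !nzchar(raw$gene_b)
  if (any(bad)) {
    stop(sprintf("malformed network line(s) %s in %s",
                 paste(utils::head(which(bad) + 1L, 5L), collapse = ", "),
                 path))
  }
  out_of_range <- conf <= 0 | conf > 1
  if (any(out_of_range)) {
    stop(sprintf("confidence outside (0, 1] on line(s) %s in %s",
                 paste(utils::head(which(out_of_range) + 1L, 5L),
                       collapse = ", "),
                 path))
  }
  df <- data.frame(gene_a = raw$gene_a, gene_b = raw$gene_b,
                   confidence = conf, stringsAsFactors = FALSE)
  df$category <- if ("category" %in% names(raw)) raw$category else
    NA_character_
  if (!is.null(category)) {
    if (all(is.na(df$category))) {
      stop("category filter requested but file has no category column")
    }
    df <- df[!is.na(df$category) & df$category == category, , drop = FALSE]
  }
  self <- df$gene_a == df$gene_b
  if (any(self)) {
    warning(sprintf("dropped %d self-link(s) while reading %s", sum(self),
                    path))
    df <- df[!self, , drop = FALSE]
  }
  # collapse duplicate unordered pairs, keeping maximum confidence
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  df$gene_a <- a
  df$gene_b <- b
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    ord <- order(key, -df$confidence)
    df <- df[ord, , drop = FALSE]
    df <- df[!duplicated(paste(df$gene_a, df$gene_b, sep = "\r")), ,
             drop = FALSE]
  }
  df <- df[df$confidence > cutoff, , drop = FALSE]
  fcnet(df, cutoff_applied = cutoff)
}

#' Write a network as a canonical sorted TSV edge list
#'
#' Links are written in lexicographic pair order so repeated writes of the
#' same network are byte-identical.
#'
#' @param network an [fcnet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "fcnet"))
  links <- network$links
  if (all(is.na(links$category))) links$category <- NULL
  utils::write.table(links, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Node degrees of a network
#'
#' @param network an [fcnet].
#' @return Named integer vector mapping every gene in the network (including
#'   isolated genes, with degree 0) to its number of incident links.
#' @export
degrees <- function(network) {
  stopifnot(inherits(network, "fcnet"))
  d <- integer(length(network$genes))
  names(d) <- network$genes
  if (nrow(network$links) > 0L) {
    tab <- table(c(network$links$gene_a, network$links$gene_b))
    d[names(tab)] <- as.integer(tab)
  }
  d
}

#' Log-log power-law diagnostic of a degree distribution
#'
#' Fits least squares to log10(frequency) versus log10(degree) over the
#' observed nonzero degrees. For a scale-free network the points fall on a
#' line whose slope estimates minus the power-law exponent.
#'
#' By default each point is weighted by its frequency, so every gene
#' contributes equally: the sparse far tail, where each degree is observed
#' only once or twice and log-frequencies are dominated by counting noise,
#' would otherwise flatten the fitted slope badly. An unweighted fit and a
#' minimum-frequency trim are available for diagnostic use.
#'
#' @param degree_table named integer vector as returned by [degrees()].
#' @param min_freq minimum frequency for a degree to enter the fit
#'   (default 1, i.e. all observed degrees).
#' @param weighted weight points by their frequency (default `TRUE`).
#' @return List of class `loglog_fit` with `slope`, `intercept`, `r_squared`
#'   and `n_degrees` (number of distinct degrees used).
#' @export
degree_loglog_fit <- function(degree_table, min_freq = 1L,
                              weighted = TRUE) {
  k <- degree_table[degree_table > 0]
  tab <- table(k)
  tab <- tab[tab >= min_freq]
  kk <- as.numeric(names(tab))
  freq <- as.numeric(tab)
  if (length(kk) < 3L) {
    stop("degenerate input: need at least 3 distinct nonzero degrees")
  }
  x <- log10(kk)
  y <- log10(freq)
  fit <- if (weighted) stats::lm(y ~ x, weights = freq) else
    stats::lm(y ~ x)
  # exactly collinear input is legitimate here; silence the perfect-fit note
  r2 <- suppressWarnings(summary(fit)$r.squared)
  structure(
    list(slope = unname(stats::coef(fit)[2L]),
         intercept = unname(stats::coef(fit)[1L]),
         r_squared = r2,
         n_degrees = length(kk)),
    class = "loglog_fit"
  )
}

#' @export
print.loglog_fit <- function(x, ...) {
  cat(sprintf(
    "log-log degree fit: slope %.3f, intercept %.3f, r^2 %.3f (%d degrees)\n",
    x$slope, x$intercept, x$r_squared, x$n_degrees))
  invisible(x)
}

#' Convert an fcnet to an igraph graph
#'
#' @param network an [fcnet].
#' @return An undirected [igraph::igraph] graph with a `confidence` edge
#'   attribute; isolated genes are kept as vertices.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "fcnet"))
  igraph::graph_from_data_frame(
    network$links, directed = FALSE,
    vertices = data.frame(name = network$genes, stringsAsFactors = FALSE)
  )
}

# igraph -> fcnet, preserving the vertex (gene) set. Edge rewiring can drop
# or invalidate edge attributes; link identity, not confidence, is what
# downstream consumers of a rewired network use, so missing confidences are
# replaced by 1.
fcnet_from_igraph <- function(g, cutoff_applied = NA_real_) {
  df <- igraph::as_data_frame(g, what = "edges")
  names(df)[1:2] <- c("gene_a", "gene_b")
  if (!"confidence" %in% names(df)) {
    df$confidence <- rep(1, nrow(df))
  } else {
    df$confidence[!is.finite(df$confidence)] <- 1
  }
  fcnet(df, genes = igraph::V(g)$name, cutoff_applied = cutoff_applied)
}

#' Read a gene-to-chromosome-class side table
#'
#' Expects a TSV with header columns `gene_id` and `class`, where class is
#' one of `Z`, `autosome`, `unknown`. The avian Z chromosome must be treated
#' separately from autosomes in crosstalk analyses because incomplete dosage
#' compensation inflates male expression of Z-linked genes.
#'
#' @param path path to the TSV file.
#' @return Named character vector mapping gene id to chromosome class.
#' @export
read_chromosome_table <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "class") %in% names(df))) {
    stop("chromosome table must have columns gene_id, class")
  }
  ok <- df$class %in% c("Z", "autosome", "unknown")
  if (!all(ok)) {
    stop("chromosome class must be one of Z, autosome, unknown; got: ",
         paste(unique(df$class[!ok]), collapse = ", "))
  }
  stats::setNames(df$class, df$gene_id)
}

#' Induced subgraph of a network on a gene set
#'
#' @param network an [fcnet].
#' @param genes character vector of gene ids to keep (genes absent from the
#'   network are ignored).
#' @return An [fcnet] on `genes` with all links whose two endpoints are kept.
#' @export
induced_network <- function(network, genes) {
  stopifnot(inherits(network, "fcnet"))
  keep <- intersect(network$genes, genes)
  links <- network$links
  links <- links[links$gene_a %in% keep & links$gene_b %in% keep, ,
                 drop = FALSE]
  fcnet(links, genes = keep, cutoff_applied = network$cutoff_applied)
}
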