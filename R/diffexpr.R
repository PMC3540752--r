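#' Read an expression matrix from TSV
#'
#' First column is the gene id, remaining columns are samples. Values are
#' positive MAS5-style intensities.
#'
#' @param path path to the TSV file.
#' @return Numeric matrix genes x samples with gene ids as row names.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes)) stop("duplicate gene ids in expression matrix")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (any(!is.finite(m)) || any(m <= 0)) {
    stop("expression intensities must be finite and positive")
  }
  m
}

#' Read a sample-metadata table
#'
#' Expects columns `sample`, `sex`, `tissue`, `stage`, `replicate`; `sex`
#' must be `male` or `female`.
#'
#' @param path path to the TSV file.
#' @return data.frame of per-sample metadata.
#' @export
read_sample_meta <- function(path) {
  df <- utils::read.delim(path, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample", "sex", "tissue", "stage", "replicate")
  if (!all(need %in% names(df))) {
    stop("sample metadata must have columns ", paste(need, collapse = ", "))
  }
  if (!all(df$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  df
}

# Solve trigamma(y) = x by Newton iteration (monotone decreasing trigamma).
trigamma_inverse <- function(x) {
  if (x <= 0) stop("trigamma_inverse needs a positive argument")
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:75) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

# Method-of-moments estimate of the variance-shrinkage prior df d0.
# Under a scaled inverse-chi-square prior for per-gene variances, the excess
# spread of log sample variances over trigamma(df/2) estimates
# trigamma(d0/2). Estimated per sex and averaged on the trigamma scale.
estimate_d0 <- function(var_list, df_list) {
  excess <- mapply(function(s2, d) {
    s2 <- s2[is.finite(s2) & s2 > 0]
    if (length(s2) < 10L || d < 1) return(NA_real_)
    stats::var(log(s2)) - trigamma(d / 2)
  }, var_list, df_list)
  excess <- excess[is.finite(excess)]
  if (length(excess) == 0L) return(Inf)
  e <- mean(excess)
  if (e <= trigamma(500)) return(Inf)
  2 * trigamma_inverse(e)
}

# Moment-matched prior scale s0^2 on the log-variance scale. Under a scaled
# inverse-chi-square variance prior, E log s^2 = log s0^2 + digamma(d/2) -
# log(d/2) - digamma(d0/2) + log(d0/2); inverting this gives an estimate of
# s0^2 consistent with the trigamma-based d0 fit (the arithmetic mean of
# sample variances would overshoot the prior scale by d0/(d0-2)).
estimate_s0 <- function(s2, d, d0) {
  pos <- s2[is.finite(s2) & s2 > 0]
  if (length(pos) == 0L) return(mean(s2))
  adj <- if (is.finite(d0) && d0 > 0) digamma(d0 / 2) - log(d0 / 2) else 0
  exp(mean(log(pos)) - digamma(d / 2) + log(d / 2) + adj)
}

select_condition <- function(sample_meta, condition) {
  if (is.null(condition)) return(sample_meta)
  keep <- rep(TRUE, nrow(sample_meta))
  for (field in intersect(names(condition), c("tissue", "stage"))) {
    keep <- keep & sample_meta[[field]] == condition[[field]]
  }
  out <- sample_meta[keep, , drop = FALSE]
  if (nrow(out) == 0L) stop("no samples match the requested condition")
  out
}

#' Moderated Welch test for sex-biased expression
#'
#' Tests, per gene, whether the mean log2 intensity differs between male and
#' female samples of one tissue/stage condition. With only a few replicates
#' per sex, per-gene variance estimates are unstable, so each sex's per-gene
#' variance is shrunk towards the mean variance of that sex across all genes:
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d_g s_g^2) / (d_0 + d_g)}
#' with \eqn{d_g = n_g - 1} and \eqn{s_0^2} a prior variance scale for the
#' group, fitted across all genes. The statistic is the Welch ratio on
#' shrunk variances,
#' \deqn{t = (\bar m_M - \bar m_F) / \sqrt{\tilde s^2_M/n_M +
#'   \tilde s^2_F/n_F},}
#' and the two-sided p-value uses a Satterthwaite approximation in which each
#' group's variance carries \eqn{d_0 + d_g} degrees of freedom. The prior
#' degrees of freedom \eqn{d_0} default to a method-of-moments fit of the
#' across-gene distribution of log sample variances; `d0 = 0` recovers the
#' classical Welch test and `d0 = Inf` the fully pooled equal-variance-scale
#' limit (both exposed for testing).
#'
#' Intensities are floored at 1 and log2-transformed internally. Positive
#' statistics and log fold changes mean male-biased expression.
#'
#' @param values positive intensity matrix, genes x samples.
#' @param sample_meta data.frame as from [read_sample_meta()]; `sample`
#'   entries must match the column names of `values`.
#' @param condition optional list with `tissue` and/or `stage` selecting one
#'   condition; default uses all samples.
#' @param d0 variance-shrinkage prior degrees of freedom; `NULL` (default)
#'   estimates it from the data, `0` disables shrinkage, `Inf` pools fully.
#' @return data.frame of class `de_result` with columns `gene`, `t_mod`,
#'   `df`, `p`, `fdr`, `log2fc` (difference of mean log2 intensities, male
#'   minus female) and `direction`; attributes record `d0`, the per-sex
#'   pooled variances and the condition tested.
#' @export
moderated_welch <- function(values, sample_meta, condition = NULL,
                            d0 = NULL) {
  stopifnot(is.matrix(values))
  meta <- select_condition(sample_meta, condition)
  missing_cols <- setdiff(meta$sample, colnames(values))
  if (length(missing_cols) > 0L) {
    stop("samples absent from expression matrix: ",
         paste(missing_cols, collapse = ", "))
  }
  groups <- split(meta$sample, meta$sex)
  for (sex in c("male", "female")) {
    if (is.null(groups[[sex]])) {
      stop("no ", sex, " samples in the selected condition")
    }
    if (length(groups[[sex]]) < 2L) {
      stop("need at least 2 ", sex, " samples, got ",
           length(groups[[sex]]))
    }
  }
  logged <- log2(pmax(values, 1))
  mM <- rowMeans(logged[, groups$male, drop = FALSE])
  mF <- rowMeans(logged[, groups$female, drop = FALSE])
  nM <- length(groups$male)
  nF <- length(groups$female)
  s2M <- rowSums((logged[, groups$male, drop = FALSE] - mM)^2) / (nM - 1)
  s2F <- rowSums((logged[, groups$female, drop = FALSE] - mF)^2) / (nF - 1)
  dM <- nM - 1
  dF <- nF - 1
  if (is.null(d0)) {
    d0 <- estimate_d0(list(s2M, s2F), list(dM, dF))
  }
  if (d0 < 0) stop("d0 must be nonnegative")
  s0M <- estimate_s0(s2M, dM, d0)
  s0F <- estimate_s0(s2F, dF, d0)
  if (is.infinite(d0)) {
    stM <- rep(s0M, length(s2M))
    stF <- rep(s0F, length(s2F))
    dfM_eff <- Inf
    dfF_eff <- Inf
  } else if (d0 == 0) {
    stM <- s2M
    stF <- s2F
    dfM_eff <- dM
    dfF_eff <- dF
  } else {
    stM <- (d0 * s0M + dM * s2M) / (d0 + dM)
    stF <- (d0 * s0F + dF * s2F) / (d0 + dF)
    dfM_eff <- d0 + dM
    dfF_eff <- d0 + dF
  }
  vM <- stM / nM
  vF <- stF / nF
  v <- vM + vF
  diff <- mM - mF
  t_mod <- ifelse(v > 0, diff / sqrt(v),
                  ifelse(diff == 0, 0, sign(diff) * Inf))
  if (is.infinite(dfM_eff)) {
    df_sat <- rep(Inf, length(v))
  } else {
    df_sat <- ifelse(v > 0,
                     v^2 / (vM^2 / dfM_eff + vF^2 / dfF_eff),
                     dM + dF)
  }
  p <- 2 * stats::pt(-abs(t_mod), df = df_sat)
  p[v == 0 & diff == 0] <- 1
  log2fc <- diff
  out <- data.frame(
    gene = rownames(values),
    t_mod = unname(t_mod),
    df = unname(df_sat),
    p = unname(p),
    fdr = bh_fdr(unname(p)),
    log2fc = unname(log2fc),
    direction = ifelse(log2fc > 0, "male",
                       ifelse(log2fc < 0, "female", "none")),
    stringsAsFactors = FALSE
  )
  attr(out, "d0") <- d0
  attr(out, "s0") <- c(male = s0M, female = s0F)
  attr(out, "n") <- c(male = nM, female = nF)
  attr(out, "condition") <- condition
  class(out) <- c("de_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment: `fdr_i` is the smallest value of `m * p_j / rank_j`
#' over all `p_j >= p_i`, clipped at 1, returned in input order.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of FDR values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) stop("empty p-value vector")
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Classify genes into sex-bias categories
#'
#' A gene is male-biased when its FDR falls below the cutoff and its log2
#' fold change is positive (male over female), female-biased when negative,
#' and unbiased otherwise. The default cutoff of 0.1 is the standard working
#' threshold for this analysis.
#'
#' @param de a `de_result` from [moderated_welch()].
#' @param fdr_cutoff FDR threshold below which a gene is called biased.
#' @return data.frame of class `bias_table` with columns `gene`, `label`,
#'   `fdr`, `log2fc`; the cutoff is stored in the `fdr_cutoff` attribute.
#' @export
classify_bias <- function(de, fdr_cutoff = 0.1) {
  stopifnot(is.data.frame(de),
            all(c("gene", "fdr", "log2fc") %in% names(de)))
  label <- rep("unbiased", nrow(de))
  label[de$fdr < fdr_cutoff & de$log2fc > 0] <- "male"
  label[de$fdr < fdr_cutoff & de$log2fc < 0] <- "female"
  odd <- de$fdr < fdr_cutoff & de$log2fc == 0
  if (any(odd)) {
    warning(sprintf(
      "%d gene(s) below the FDR cutoff with exactly zero fold change were classified unbiased",
      sum(odd)))
  }
  out <- data.frame(gene = de$gene, label = label, fdr = de$fdr,
                    log2fc = de$log2fc, stringsAsFactors = FALSE)
  attr(out, "fdr_cutoff") <- fdr_cutoff
  class(out) <- c("bias_table", "data.frame")
  out
}

#' Extract bias labels as a named vector
#'
#' @param bias a `bias_table` from [classify_bias()], or an already-named
#'   character vector (returned unchanged).
#' @return Named character vector mapping gene id to bias label.
#' @export
bias_labels <- function(bias) {
  if (is.character(bias) && !is.null(names(bias))) return(bias)
  stopifnot(is.data.frame(bias), all(c("gene", "label") %in% names(bias)))
  stats::setNames(bias$label, bias$gene)
}

#' Log2 fold change of male over female mean intensity
#'
#' Computed on floored (at 1) raw intensities as
#' `log2(mean male) - log2(mean female)`, the classical fold-change measure
#' of sex bias used as an alternative to the moderated test statistic.
#'
#' @inheritParams moderated_welch
#' @return Named numeric vector of per-gene log2 ratios.
#' @export
log_fold_change <- function(values, sample_meta, condition = NULL) {
  stopifnot(is.matrix(values))
  meta <- select_condition(sample_meta, condition)
  groups <- split(meta$sample, meta$sex)
  if (is.null(groups$male) || is.null(groups$female)) {
    stop("both sexes must be present in the selected condition")
  }
  floored <- pmax(values, 1)
  log2(rowMeans(floored[, groups$male, drop = FALSE])) -
    log2(rowMeans(floored[, groups$female, drop = FALSE]))
}
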