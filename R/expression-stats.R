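# qPCR expression statistics: delta-delta-Ct relative expression against
# the arithmetic mean of two reference genes, per-gene tests against the
# control sample with joint Benjamini-Hochberg correction, effect-size
# flagging, Pearson correlation clustering and jackknife bias-corrected
# mutual information with top-fraction pair selection.

#' Relative expression by the delta-delta-Ct method
#'
#' Per replicate, `dCt = Ct_gene - mean(Ct of the reference genes)` within
#' the same sample and replicate; the per-replicate log2 relative
#' expression is `-(dCt - mean control dCt) * log2(efficiency)`. With the
#' default amplification efficiency of 2 this is the classical `-ddCt`
#' log2 fold change. The control-sample mean log2 relative expression is
#' zero for every gene by construction.
#'
#' @param ct a `ct_table` (see [read_ct_table()] / [ct_table()]).
#' @param efficiency amplification efficiency (default 2).
#' @return object of class `rel_expr`: a data frame with columns `gene`,
#'   `sample`, `replicate`, `delta_ct`, `log2_rel`, carrying the control
#'   sample, reference genes and sample order as attributes.
#' @export
relative_expression <- function(ct, efficiency = 2) {
  stopifnot(inherits(ct, "ct_table"))
  dat <- ct$data
  refs <- dat[dat$gene %in% ct$reference_genes, , drop = FALSE]
  ref_mean <- stats::aggregate(ct ~ sample + replicate, data = refs,
                               FUN = mean)
  names(ref_mean)[names(ref_mean) == "ct"] <- "ref_ct"
  merged <- merge(dat, ref_mean, by = c("sample", "replicate"),
                  sort = FALSE)
  merged$delta_ct <- merged$ct - merged$ref_ct
  ctrl <- merged[merged$sample == ct$control_sample, , drop = FALSE]
  ctrl_mean <- tapply(ctrl$delta_ct, ctrl$gene, mean)
  merged$log2_rel <- -(merged$delta_ct - ctrl_mean[merged$gene]) *
    log2(efficiency)
  out <- merged[, c("gene", "sample", "replicate", "delta_ct", "log2_rel")]
  out <- out[order(match(out$gene, ct$genes), match(out$sample, ct$samples),
                   out$replicate), ]
  rownames(out) <- NULL
  structure(out, class = c("rel_expr", "data.frame"),
            control_sample = ct$control_sample,
            reference_genes = ct$reference_genes,
            samples = ct$samples,
            genes = ct$genes)
}

#' Per-gene mean expression profiles
#'
#' Mean log2 relative expression per gene and sample, excluding the
#' reference genes.
#'
#' @param rel a `rel_expr`.
#' @return matrix genes x samples (sample order as measured).
#' @export
rel_expr_profiles <- function(rel) {
  genes <- setdiff(attr(rel, "genes"), attr(rel, "reference_genes"))
  samples <- attr(rel, "samples")
  m <- matrix(NA_real_, length(genes), length(samples),
              dimnames = list(genes, samples))
  agg <- stats::aggregate(log2_rel ~ gene + sample, data = rel, FUN = mean)
  for (i in seq_len(nrow(agg))) {
    if (agg$gene[i] %in% genes) m[agg$gene[i], agg$sample[i]] <- agg$log2_rel[i]
  }
  m
}

#' Test each gene and sample against the control
#'
#' Two-sided t-tests on per-replicate log2 relative expression, each
#' non-control sample against the control sample; Student's (pooled
#' variance) or Welch's flavor. Reference genes are excluded.
#'
#' @param rel a `rel_expr`.
#' @param method `"student"` or `"welch"`.
#' @return data frame with `gene`, `sample`, `mean_log2fc`, `p`.
#' @export
test_vs_control <- function(rel, method = c("student", "welch")) {
  method <- match.arg(method)
  control <- attr(rel, "control_sample")
  genes <- setdiff(attr(rel, "genes"), attr(rel, "reference_genes"))
  samples <- setdiff(attr(rel, "samples"), control)
  rows <- list()
  for (g in genes) {
    ctrl <- rel$log2_rel[rel$gene == g & rel$sample == control]
    for (s in samples) {
      x <- rel$log2_rel[rel$gene == g & rel$sample == s]
      if (length(x) < 2L || length(ctrl) < 2L) {
        stop("need at least 2 replicates per group (gene ", g,
             ", sample ", s, ")", call. = FALSE)
      }
      tt <- stats::t.test(x, ctrl, var.equal = (method == "student"))
      rows[[length(rows) + 1L]] <- data.frame(gene = g, sample = s,
                                              mean_log2fc = mean(x),
                                              p = tt$p.value,
                                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Benjamini-Hochberg adjustment over all pooled comparisons
#'
#' Standard step-up FDR adjustment applied jointly to the p-values of all
#' genes and comparisons of a dataset.
#'
#' @param p numeric vector of raw p-values.
#' @return adjusted p-values (same order).
#' @export
adjust_bh <- function(p) stats::p.adjust(p, method = "BH")

#' Flag test results by significance and effect size
#'
#' Adds BH-adjusted p-values (pooled across all rows) and the flags
#' `sig05` (adjusted p < 0.05), `sig01` (adjusted p < 0.01),
#' `large_effect` (|mean log2FC| strictly greater than `lfc_threshold`)
#' and `highlighted` (`sig05` and `large_effect`), the combination marked
#' with a red asterisk in expression figures.
#'
#' @param tests data frame from [test_vs_control()].
#' @param alpha_levels two significance levels (default 0.05 and 0.01).
#' @param lfc_threshold log2 fold-change magnitude threshold (default 2;
#'   the comparison is strict, so exactly 2 is not flagged).
#' @return the input with columns `p_adj`, `sig05`, `sig01`,
#'   `large_effect`, `highlighted` appended.
#' @export
flag_results <- function(tests, alpha_levels = c(0.05, 0.01),
                         lfc_threshold = 2) {
  tests$p_adj <- adjust_bh(tests$p)
  tests$sig05 <- tests$p_adj < alpha_levels[1]
  tests$sig01 <- tests$p_adj < alpha_levels[2]
  tests$large_effect <- abs(tests$mean_log2fc) > lfc_threshold
  tests$highlighted <- tests$sig05 & tests$large_effect
  tests
}

#' Pearson correlation and complete-linkage clustering of gene profiles
#'
#' Correlation of per-gene mean log2 relative expression across samples;
#' pairwise two-sided p-values from the t distribution of r; distance
#' `1 - r` (maximal positive correlation becomes distance 0, maximal
#' negative correlation distance 2); complete-linkage dendrogram.
#'
#' @param x a `rel_expr` or a genes x samples profile matrix.
#' @return list with `r` (correlation matrix), `p` (p-value matrix,
#'   `NA` diagonal), `dist` (`dist` of 1 - r), `hclust` and `order`.
#' @export
pearson_cluster <- function(x) {
  profiles <- if (inherits(x, "rel_expr")) rel_expr_profiles(x) else x
  r <- stats::cor(t(profiles))
  n <- ncol(profiles)
  g <- nrow(profiles)
  p <- matrix(NA_real_, g, g, dimnames = dimnames(r))
  for (i in seq_len(g)) for (j in seq_len(g)) {
    if (i == j) next
    tt <- stats::cor.test(profiles[i, ], profiles[j, ])
    p[i, j] <- tt$p.value
  }
  d <- stats::as.dist(1 - r)
  hc <- stats::hclust(d, method = "complete")
  list(r = r, p = p, dist = d, hclust = hc, order = hc$order)
}

# mutual information (nats) of a 2-d contingency table
mi_from_table <- function(tab) {
  n <- sum(tab)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  expected <- outer(px, py)
  idx <- p > 0
  sum(p[idx] * log(p[idx] / expected[idx]))
}

#' Jackknife bias-corrected mutual information of two profiles
#'
#' Mutual information estimated on an equal-frequency binned contingency
#' table with `ceiling(sqrt(n))` bins per margin, bias-corrected by the
#' delete-one jackknife `BCMI = n * MI - (n - 1) * mean(MI_(-i))`. The
#' bin assignment is computed once on the full data and held fixed while
#' jackknifing the counts (re-binning each leave-one-out subset makes the
#' estimator unusably noisy at small n).
#'
#' @param x,y numeric vectors of equal length.
#' @param bins number of bins per margin (default `ceiling(sqrt(n))`).
#' @return the BCMI estimate (nats).
#' @export
bcmi <- function(x, y, bins = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, n >= 4L)
  if (is.null(bins)) bins <- ceiling(sqrt(n))
  bx <- ceiling(bins * rank(x, ties.method = "first") / n)
  by <- ceiling(bins * rank(y, ties.method = "first") / n)
  tab <- matrix(0L, bins, bins)
  for (i in seq_len(n)) tab[bx[i], by[i]] <- tab[bx[i], by[i]] + 1L
  full <- mi_from_table(tab)
  loo <- vapply(seq_len(n), function(i) {
    t2 <- tab
    t2[bx[i], by[i]] <- t2[bx[i], by[i]] - 1L
    mi_from_table(t2)
  }, numeric(1))
  n * full - (n - 1) * mean(loo)
}

#' Pairwise BCMI matrix of gene profiles
#'
#' @param x a `rel_expr` or a genes x samples profile matrix.
#' @param bins bins per margin (default `ceiling(sqrt(n_samples))`).
#' @return symmetric matrix of BCMI values; the diagonal holds each
#'   gene's self-BCMI (the maximal entry of its row).
#' @export
bcmi_matrix <- function(x, bins = NULL) {
  profiles <- if (inherits(x, "rel_expr")) rel_expr_profiles(x) else x
  g <- nrow(profiles)
  m <- matrix(0, g, g, dimnames = list(rownames(profiles),
                                       rownames(profiles)))
  for (i in seq_len(g)) {
    m[i, i] <- bcmi(profiles[i, ], profiles[i, ], bins)
    if (i < g) for (j in (i + 1L):g) {
      m[i, j] <- m[j, i] <- bcmi(profiles[i, ], profiles[j, ], bins)
    }
  }
  m
}

#' Top fraction of gene pairs by association strength
#'
#' Ranks the `choose(G, 2)` off-diagonal pairs of a symmetric association
#' matrix in decreasing order (ties broken by id pair) and returns the
#' top `floor(fraction * n_pairs)` pairs — e.g. 7 of the 153 pairs of 18
#' genes at the default 5%.
#'
#' @param m symmetric matrix with dimnames.
#' @param fraction fraction of pairs to keep (default 0.05).
#' @return data frame with `gene1`, `gene2`, `value`, strongest first.
#' @export
top_pairs <- function(m, fraction = 0.05) {
  ids <- rownames(m)
  idx <- which(upper.tri(m), arr.ind = TRUE)
  pairs <- data.frame(gene1 = ids[idx[, 1]], gene2 = ids[idx[, 2]],
                      value = m[idx], stringsAsFactors = FALSE)
  n_top <- floor(fraction * nrow(pairs))
  pairs <- pairs[order(-pairs$value, pairs$gene1, pairs$gene2), ]
  rownames(pairs) <- NULL
  utils::head(pairs, n_top)
}
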