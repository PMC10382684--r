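## Two-sample KS p-value. Exact (permutation/psmirnov, ties respected) when
## both sides are small, asymptotic otherwise: tiny responder arms (down to
## 3 samples in PDX cohorts) make the asymptotic tail unreliable.
ksPvalue <- function(x, y, exactMax = 10L) {
  exact <- length(x) <= exactMax && length(y) <= exactMax
  suppressWarnings(stats::ks.test(x, y, exact = exact))$p.value
}

#' Supervised domain-adaptation KS filter
#'
#' For each gene, tests equality of the class-conditional expression
#' distributions between domains with two two-sample Kolmogorov-Smirnov
#' tests: source-vs-target within the sensitive class (`Y = 1`) and within
#' the resistant class (`Y = 0`). Under the default `ksRule = "both"` a
#' gene passes the filter only when both p-values are at least `alpha` —
#' the stricter reading of "similar conditional distributions", matching
#' the two class-wise sup-norm distances. Large `alpha` (0.6-0.9) keeps
#' only genes whose conditional laws are statistically indistinguishable
#' across domains.
#'
#' Exact p-values are used whenever both sides of a test have at most
#' `exactMax` samples (ties handled by the exact conditional distribution),
#' asymptotic p-values otherwise.
#'
#' @param source,target [DomainDataset-class] objects sharing the same gene
#'   set and order; each must contain at least one sample of each class.
#' @param alpha pass threshold in (0, 1): a gene needs KS p >= alpha.
#' @param ksRule `"both"` (default), `"either"` (one class-conditional test
#'   suffices), or `"pooled"` (one KS test ignoring the label).
#' @param exactMax per-side sample cap for exact p-value computation.
#' @return data.frame with columns `gene_id`, `ks_p_y1`, `ks_p_y0`,
#'   `passed_da`.
#' @seealso [selectFeatures()] for the full pipeline.
#' @export
ksDomainFilter <- function(source, target, alpha,
                           ksRule = c("both", "either", "pooled"),
                           exactMax = 10L) {
  ksRule <- match.arg(ksRule)
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!identical(rownames(source), rownames(target)))
    stop("source and target must share the same genes in the same order")
  xs <- exprMatrix(source); ys <- responseLabels(source)
  xt <- exprMatrix(target); yt <- responseLabels(target)
  for (cls in c(1L, 0L)) {
    if (!any(ys == cls))
      stop("source domain has no samples of class ", cls)
    if (!any(yt == cls))
      stop("target domain has no samples of class ", cls)
  }
  n <- nrow(xs)
  p1 <- p0 <- numeric(n)
  if (ksRule == "pooled") {
    for (i in seq_len(n))
      p1[i] <- p0[i] <- ksPvalue(xs[i, ], xt[i, ], exactMax)
    passed <- p1 >= alpha
  } else {
    s1 <- ys == 1L; s0 <- !s1
    t1 <- yt == 1L; t0 <- !t1
    for (i in seq_len(n)) {
      p1[i] <- ksPvalue(xs[i, s1], xt[i, t1], exactMax)
      p0[i] <- ksPvalue(xs[i, s0], xt[i, t0], exactMax)
    }
    passed <- if (ksRule == "both") p1 >= alpha & p0 >= alpha
              else p1 >= alpha | p0 >= alpha
  }
  data.frame(gene_id = rownames(xs), ks_p_y1 = p1, ks_p_y0 = p0,
             passed_da = passed, stringsAsFactors = FALSE)
}

#' Differential-expression prioritisation with an FDR cap
#'
#' Ranks candidate genes by differential expression between sensitive and
#' resistant samples of the source domain: a Welch two-sample t-test per
#' gene, Benjamini-Hochberg adjustment across the candidate set, and
#' retention of at most `maxGenes` genes with the smallest FDR (ties broken
#' by smaller raw p-value, then gene identifier, for determinism).
#'
#' @param source a [DomainDataset-class]; both classes need >= 2 samples.
#' @param candidateGenes character vector, a subset of the source genes.
#' @param maxGenes cap on the number of genes kept (default 1000).
#' @return data.frame with columns `gene_id`, `t_stat`, `p_value`, `fdr`,
#'   ordered by FDR (at most `maxGenes` rows).
#' @export
deRank <- function(source, candidateGenes, maxGenes = 1000L) {
  x <- exprMatrix(source)
  missing <- setdiff(candidateGenes, rownames(x))
  if (length(missing))
    stop("candidate genes absent from the source data: ",
         paste(utils::head(missing, 5), collapse = ", "))
  y <- responseLabels(source)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each class needs at least 2 source samples for the t-test")
  x <- x[candidateGenes, , drop = FALSE]
  welch <- welchRows(x[, y == 1L, drop = FALSE], x[, y == 0L, drop = FALSE])
  fdr <- stats::p.adjust(welch$p, method = "BH")
  ord <- order(fdr, welch$p, candidateGenes)
  keep <- utils::head(ord, maxGenes)
  data.frame(gene_id = candidateGenes[keep], t_stat = welch$t[keep],
             p_value = welch$p[keep], fdr = fdr[keep],
             stringsAsFactors = FALSE)
}

## Row-wise Welch t-test (class 1 minus class 0). Degenerate rows (both
## groups constant): equal means -> t = 0, p = 1; unequal -> t = +-Inf, p = 0.
welchRows <- function(x1, x0) {
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v0 <- rowSums((x0 - m0)^2) / (n0 - 1)
  se2 <- v1 / n1 + v0 / n0
  t <- (m1 - m0) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m0)
    t[eq] <- 0; p[eq] <- 1
    ne <- zero & (m1 != m0)
    t[ne] <- sign(m1[ne] - m0[ne]) * Inf; p[ne] <- 0
  }
  list(t = t, p = p)
}

#' BW ratio: between- to within-group sum of squares
#'
#' For one gene, the ratio of the between-group sum of squares
#' `sum_k n_k (xbar_k - xbar)^2` to the within-group sum of squares
#' `sum_k sum_{i in k} (x_i - xbar_k)^2`, where the two groups are the
#' sensitive and resistant samples. Large values mean strong class
#' separation. Degenerate cases preserve a total order: `0/0` returns 0
#' (uninformative gene, ranked last) and a positive numerator over a zero
#' denominator returns `Inf` (perfectly separating gene, ranked first).
#'
#' @param values numeric vector, one expression value per sample.
#' @param labels 0/1 vector of the same length; both groups non-empty.
#' @return non-negative number (possibly `Inf`).
#' @examples
#' bwRatio(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0))  # 3.375
#' @export
bwRatio <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  g1 <- values[labels == 1]; g0 <- values[labels == 0]
  if (length(g1) == 0L || length(g0) == 0L)
    stop("both groups must be non-empty")
  grand <- mean(values)
  between <- length(g1) * (mean(g1) - grand)^2 +
    length(g0) * (mean(g0) - grand)^2
  within <- sum((g1 - mean(g1))^2) + sum((g0 - mean(g0))^2)
  if (within == 0) {
    if (between == 0) 0 else Inf
  } else between / within
}

## Vectorised BW ratio over gene rows
bwRatioRows <- function(x, y) {
  x1 <- x[, y == 1L, drop = FALSE]; x0 <- x[, y == 0L, drop = FALSE]
  n1 <- ncol(x1); n0 <- ncol(x0)
  m1 <- rowMeans(x1); m0 <- rowMeans(x0)
  grand <- rowMeans(x)
  between <- n1 * (m1 - grand)^2 + n0 * (m0 - grand)^2
  within <- rowSums((x1 - m1)^2) + rowSums((x0 - m0)^2)
  out <- ifelse(within == 0, ifelse(between == 0, 0, Inf), between / within)
  names(out) <- rownames(x)
  out
}

#' Three-stage feature selection across domains
#'
#' Composes the selection pipeline: (1) the supervised
#' domain-adaptation KS filter at level `alpha` (skipped when
#' `useDA = FALSE`, the ablation mode), (2) differential-expression
#' prioritisation of the survivors capped at `maxGenes` genes by FDR, and
#' (3) ordering of the retained genes by decreasing BW ratio. The result is
#' deterministic for fixed inputs and invariant to sample or gene
#' permutations.
#'
#' @inheritParams ksDomainFilter
#' @param maxGenes cap passed to [deRank()] (default 1000).
#' @param useDA apply the DA filter (`TRUE`) or run the ablation without it.
#' @return a [FeatureRanking-class].
#' @examples
#' sim <- generateDomainPair(syntheticConfig(
#'   n_source = 60, n_target = 60, n_invariant_informative = 5,
#'   n_invariant_null = 5, n_shifted = 10, seed = 7))
#' fr <- selectFeatures(sim$source, sim$target, alpha = 0.7, maxGenes = 10)
#' rankedGenes(fr)
#' @export
selectFeatures <- function(source, target, alpha = 0.7, maxGenes = 1000L,
                           useDA = TRUE,
                           ksRule = c("both", "either", "pooled"),
                           exactMax = 10L) {
  ksRule <- match.arg(ksRule)
  ks <- ksDomainFilter(source, target, alpha = alpha, ksRule = ksRule,
                       exactMax = exactMax)
  survivors <- if (useDA) ks$gene_id[ks$passed_da] else ks$gene_id
  if (useDA && length(survivors) == 0L)
    stop("no genes passed the DA filter at alpha = ", alpha,
         "; consider a lower alpha")
  de <- deRank(source, survivors, maxGenes = maxGenes)
  bw <- bwRatioRows(exprMatrix(source)[de$gene_id, , drop = FALSE],
                    responseLabels(source))
  ord <- order(-bw, de$fdr, de$gene_id)
  genes <- de$gene_id[ord]
  tab <- S4Vectors::DataFrame(
    gene_id = ks$gene_id, ks_p_y1 = ks$ks_p_y1, ks_p_y0 = ks$ks_p_y0,
    passed_da = ks$passed_da,
    t_stat = NA_real_, p_value = NA_real_, fdr = NA_real_, bw = NA_real_,
    rank = NA_integer_)
  idx <- match(de$gene_id, tab$gene_id)
  tab$t_stat[idx] <- de$t_stat
  tab$p_value[idx] <- de$p_value
  tab$fdr[idx] <- de$fdr
  tab$bw[idx] <- as.numeric(bw)
  tab$rank[match(genes, tab$gene_id)] <- seq_along(genes)
  new("FeatureRanking", table = tab, genes = genes, alpha = alpha,
      useDA = useDA)
}

#' Export a feature ranking as a data.frame / TSV
#'
#' @param x a [FeatureRanking-class].
#' @param path optional file path; when given, the table is written as
#'   tab-separated text.
#' @return the per-gene table as a base data.frame (invisibly when `path`
#'   is given).
#' @export
featureRankingTable <- function(x, path = NULL) {
  stopifnot(is(x, "FeatureRanking"))
  df <- as.data.frame(x@table)
  if (!is.null(path)) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(df))
  }
  df
}
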