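#' Two-domain expression dataset with binary drug response
#'
#' A `DomainDataset` couples a genes-by-samples expression matrix with binary
#' drug-response labels (1 = sensitive/responder, 0 = resistant) and a domain
#' tag: `"source"` for the training domain (drug-screened cell lines) or
#' `"target"` for the test domain (patient tumours or PDXs). It extends
#' [SummarizedExperiment::SummarizedExperiment] so the usual subsetting and
#' assay accessors apply; the labels live in `colData(x)$response`.
#'
#' @param expr numeric genes-by-samples matrix with unique gene identifiers
#'   as row names and sample identifiers as column names.
#' @param response binary vector (0/1), one value per sample, in column
#'   order. A named vector is checked against the sample identifiers.
#' @param domain `"source"` or `"target"`.
#' @param drug drug name (free text; used in reports).
#' @return a `DomainDataset`.
#' @seealso [generateDomainPair()] for simulated pairs,
#'   [readExpressionMatrix()] for loading expression text files.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
#' ds <- DomainDataset(m, c(1, 0, 1, 0), domain = "source", drug = "erlotinib")
#' responseLabels(ds)
#' @aliases responseLabels domainTag drugName exprMatrix
#' @export DomainDataset
#' @exportClass DomainDataset
DomainDataset <- function(expr, response, domain = c("source", "target"),
                          drug = "unknown") {
  domain <- match.arg(domain)
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("'expr' must be a numeric matrix (genes x samples)")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("'expr' must carry gene row names and sample column names")
  if (!is.null(names(response))) {
    if (!setequal(names(response), colnames(expr)))
      stop("names of 'response' do not match the sample identifiers")
    response <- response[colnames(expr)]
  }
  response <- as.integer(response)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(expr = expr),
    colData = S4Vectors::DataFrame(response = response,
                                   row.names = colnames(expr)))
  S4Vectors::metadata(se)$domain <- domain
  S4Vectors::metadata(se)$drug <- drug
  new("DomainDataset", se)
}

setClass("DomainDataset", contains = "SummarizedExperiment")

setValidity("DomainDataset", function(object) {
  msg <- character()
  if (!"expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'expr' is missing")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene identifiers")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample identifiers")
  cd <- SummarizedExperiment::colData(object)
  if (!"response" %in% colnames(cd)) {
    msg <- c(msg, "colData column 'response' is missing")
  } else if (!all(cd$response %in% c(0L, 1L))) {
    msg <- c(msg, "response labels must all be 0 or 1")
  }
  dom <- S4Vectors::metadata(object)$domain
  if (is.null(dom) || !dom %in% c("source", "target"))
    msg <- c(msg, "metadata 'domain' must be \"source\" or \"target\"")
  if (length(msg)) msg else TRUE
})

#' @rdname DomainDataset-class
#' @export
setMethod("responseLabels", "DomainDataset", function(x)
  stats::setNames(SummarizedExperiment::colData(x)$response, colnames(x)))

#' @rdname DomainDataset-class
#' @export
setMethod("domainTag", "DomainDataset", function(x)
  S4Vectors::metadata(x)$domain)

#' @rdname DomainDataset-class
#' @export
setMethod("drugName", "DomainDataset", function(x)
  S4Vectors::metadata(x)$drug)

#' @rdname DomainDataset-class
#' @export
setMethod("exprMatrix", "DomainDataset", function(x)
  SummarizedExperiment::assay(x, "expr"))

setMethod("show", "DomainDataset", function(object) {
  y <- SummarizedExperiment::colData(object)$response
  cat(sprintf("DomainDataset (%s domain, drug: %s)\n",
              domainTag(object), drugName(object)))
  cat(sprintf("  %d genes x %d samples; %d sensitive / %d resistant\n",
              nrow(object), ncol(object), sum(y == 1L), sum(y == 0L)))
})

#' Ranked gene list produced by the feature-selection pipeline
#'
#' Holds the per-gene statistics of the three selection stages — the
#' class-conditional Kolmogorov-Smirnov domain filter, the Welch
#' t-test/Benjamini-Hochberg differential-expression prioritisation, and the
#' BW (between- to within-group sum of squares) ratio — together with the
#' final ordering. `rankedGenes(x)` returns the selected genes sorted by BW
#' ratio, best first.
#'
#' @slot table a [S4Vectors::DataFrame] with one row per candidate gene and
#'   columns `gene_id`, `ks_p_y1`, `ks_p_y0`, `passed_da`, `t_stat`,
#'   `p_value`, `fdr`, `bw`, `rank` (`NA` for genes not in the final list).
#' @slot genes character: the final ordered gene list (length <= `maxGenes`).
#' @slot alpha the KS pass threshold used (p-values must be >= alpha).
#' @slot useDA whether the domain-adaptation filter was applied.
#' @seealso [selectFeatures()]
#' @exportClass FeatureRanking
setClass("FeatureRanking",
         representation(table = "DataFrame", genes = "character",
                        alpha = "numeric", useDA = "logical"))

setValidity("FeatureRanking", function(object) {
  msg <- character()
  tab <- object@table
  need <- c("gene_id", "ks_p_y1", "ks_p_y0", "passed_da",
            "t_stat", "p_value", "fdr", "bw", "rank")
  if (!all(need %in% colnames(tab)))
    msg <- c(msg, paste("table lacks columns:",
                        paste(setdiff(need, colnames(tab)), collapse = ", ")))
  else {
    pv <- c(tab$ks_p_y1, tab$ks_p_y0, tab$p_value, tab$fdr)
    pv <- pv[!is.na(pv)]
    if (length(pv) && (min(pv) < 0 || max(pv) > 1))
      msg <- c(msg, "p-values outside [0, 1]")
    if (!all(object@genes %in% tab$gene_id))
      msg <- c(msg, "ranked genes missing from the table")
  }
  if (length(object@alpha) != 1 || object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be a single value in (0, 1)")
  if (length(msg)) msg else TRUE
})

#' @rdname FeatureRanking-class
#' @export
setMethod("rankedGenes", "FeatureRanking", function(x) x@genes)

setMethod("show", "FeatureRanking", function(object) {
  tab <- object@table
  cat("FeatureRanking\n")
  if (object@useDA)
    cat(sprintf("  DA filter: alpha = %.2f, %d / %d genes passed\n",
                object@alpha, sum(tab$passed_da), nrow(tab)))
  else
    cat("  DA filter: disabled (ablation mode)\n")
  cat(sprintf("  final ranking: %d genes (BW-ratio order)\n",
              length(object@genes)))
  if (length(object@genes))
    cat("  top genes:", paste(utils::head(object@genes, 5), collapse = ", "),
        "\n")
})

#' Trained predictors
#'
#' `LogitDA` is a logistic ridge regression fitted on the top-p genes of a
#' [FeatureRanking-class], with the penalty constant lambda and the gene
#' count p tuned by repeated stratified cross-validation scored by AUC.
#' `KNNDA` is a K-nearest-neighbour classifier under the distance
#' 1 - Spearman's rho, storing the full source data restricted to the top-p
#' genes as its reference set. Both extend the virtual class
#' `TrainedPredictor` and support [predictProb()].
#'
#' @slot genes ordered character vector of the genes used by the model.
#' @slot cvScore mean cross-validated AUC of the winning configuration.
#' @slot cvSE standard error of the CV AUC over repeats.
#' @slot gridTable data.frame of all configurations scored during tuning.
#' @slot seed integer seed that fixed the CV fold assignments.
#' @aliases TrainedPredictor-class
#' @exportClass TrainedPredictor
#' @exportClass LogitDA
#' @exportClass KNNDA
#' @name TrainedPredictor
NULL

setClass("TrainedPredictor",
         representation("VIRTUAL", genes = "character", cvScore = "numeric",
                        cvSE = "numeric", gridTable = "data.frame",
                        seed = "integer"))

#' @rdname TrainedPredictor
#' @slot lambda ridge penalty constant (on the mean log-likelihood scale).
#' @slot intercept fitted (unpenalised) intercept.
#' @slot coefficients fitted gene coefficients, named by gene.
setClass("LogitDA", contains = "TrainedPredictor",
         representation(lambda = "numeric", intercept = "numeric",
                        coefficients = "numeric"))

#' @rdname TrainedPredictor
#' @slot k number of neighbours.
#' @slot refExpr reference genes-by-samples matrix (source domain, top-p genes).
#' @slot refLabels reference binary labels.
setClass("KNNDA", contains = "TrainedPredictor",
         representation(k = "integer", refExpr = "matrix",
                        refLabels = "integer"))

setValidity("LogitDA", function(object) {
  msg <- character()
  if (object@lambda <= 0) msg <- c(msg, "lambda must be > 0")
  if (length(object@coefficients) != length(object@genes))
    msg <- c(msg, "one coefficient per gene required")
  if (length(object@cvScore) &&
      (object@cvScore < 0 || object@cvScore > 1))
    msg <- c(msg, "cvScore must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setValidity("KNNDA", function(object) {
  msg <- character()
  if (object@k < 1L || object@k %% 2L == 0L)
    msg <- c(msg, "K must be odd and >= 1")
  if (nrow(object@refExpr) != length(object@genes))
    msg <- c(msg, "reference matrix rows must match the gene list")
  if (ncol(object@refExpr) != length(object@refLabels))
    msg <- c(msg, "one reference label per reference sample required")
  if (length(msg)) msg else TRUE
})

setMethod("show", "LogitDA", function(object) {
  cat(sprintf("LogitDA: p = %d genes, lambda = %.4g, CV AUC = %.3f (s.e. %.3f)\n",
              length(object@genes), object@lambda, object@cvScore,
              object@cvSE))
})

setMethod("show", "KNNDA", function(object) {
  cat(sprintf("KNNDA: p = %d genes, K = %d, CV AUC = %.3f (s.e. %.3f)\n",
              length(object@genes), object@k, object@cvScore, object@cvSE))
})

#' Class-prior-shift cutoff adjustment
#'
#' Stores the responder/non-responder counts of both domains, the implied
#' odds ratio `r = (NS_S/NR_S) / (NS_T/NR_T)`, and the adjusted
#' prediction-probability cutoff `r/(1+r)`. `r = 1` (equal responder odds in
#' both domains) gives the conventional cutoff 0.5.
#'
#' @slot nsSource,nrSource,nsTarget,nrTarget responder (NS) and
#'   non-responder (NR) counts in each domain.
#' @slot r domain odds ratio.
#' @slot cutoff adjusted cutoff `r/(1+r)`, stored at full precision.
#' @seealso [cutoffAdjustment()], [oddsRatio()], [adjustedCutoff()]
#' @exportClass CutoffAdjustment
setClass("CutoffAdjustment",
         representation(nsSource = "integer", nrSource = "integer",
                        nsTarget = "integer", nrTarget = "integer",
                        r = "numeric", cutoff = "numeric"))

setValidity("CutoffAdjustment", function(object) {
  msg <- character()
  cnt <- c(object@nsSource, object@nrSource, object@nsTarget, object@nrTarget)
  if (any(cnt <= 0L))
    msg <- c(msg, "all four class counts must be positive")
  if (object@r <= 0) msg <- c(msg, "r must be positive")
  if (abs(object@cutoff - object@r / (1 + object@r)) > 1e-12)
    msg <- c(msg, "cutoff must equal r/(1+r)")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CutoffAdjustment", function(object) {
  cat(sprintf(
    "CutoffAdjustment: r = %.4g (source %d/%d vs target %d/%d), cutoff = %.2f\n",
    object@r, object@nsSource, object@nrSource, object@nsTarget,
    object@nrTarget, object@cutoff))
})
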