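#' @import methods
NULL

#' Predicted response probabilities for new samples
#'
#' Scores target-domain samples with a trained predictor. For a
#' [LogitDA-class] model this is the logistic probability
#' `plogis(b0 + x'b)`; for a [KNNDA-class] model it is the fraction of the
#' K nearest reference samples (Spearman distance) labelled sensitive.
#'
#' @param object a trained predictor ([LogitDA-class] or [KNNDA-class]).
#' @param newdata a genes-by-samples numeric matrix with gene identifiers as
#'   row names, or a [DomainDataset-class]. Every gene used by the model must
#'   be present; missing genes raise an error listing them.
#' @return numeric vector of scores in `[0, 1]`, named by sample.
#' @export
setGeneric("predictProb", function(object, newdata) standardGeneric("predictProb"))

#' @rdname DomainDataset-class
#' @param x,object a `DomainDataset`.
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' @rdname DomainDataset-class
#' @export
setGeneric("domainTag", function(x) standardGeneric("domainTag"))

#' @rdname DomainDataset-class
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))

#' @rdname DomainDataset-class
#' @export
setGeneric("exprMatrix", function(x) standardGeneric("exprMatrix"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankedGenes", function(x) standardGeneric("rankedGenes"))
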