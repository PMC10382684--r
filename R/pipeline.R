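#' Run the full translation pipeline end to end
#'
#' Orchestrates gene intersection, optional harmonisation, three-stage
#' feature selection, predictor training, target-domain scoring, cutoff
#' selection, and evaluation. With `adjustCutoff = TRUE` (LogitDA only —
#' the odds-ratio correction presumes a continuous probability, not a
#' majority vote) the decision threshold is `r/(1+r)` with `r` estimated
#' from the two domains' labels; otherwise 0.5. All randomness flows from
#' `config$seed`, so a rerun with the same inputs is bit-identical.
#'
#' @param source,target [DomainDataset-class] objects.
#' @param alpha KS pass threshold for the DA filter (default 0.7, the
#'   recommended operating point).
#' @param method `"logitda"` or `"knnda"`.
#' @param useDA `FALSE` runs the ablation: DE/FDR + BW selection only.
#' @param harmonize `"none"` (default; see the vignette) or
#'   `"location_scale"`.
#' @param adjustCutoff use the class-prior-shift cutoff `r/(1+r)`.
#' @param maxGenes DE-stage cap on retained genes.
#' @param config a [trainingConfig()].
#' @return list with `ranking`, `model`, `scores`, `cutoff` (a
#'   [CutoffAdjustment-class] or numeric 0.5), `report` (see
#'   [evaluateScores()]), and `log` (gene counts surviving each stage).
#' @examples
#' sim <- generateDomainPair(syntheticConfig(
#'   n_source = 80, n_target = 80, n_invariant_informative = 10,
#'   n_invariant_null = 10, n_shifted = 30, seed = 3))
#' run <- runPipeline(sim$source, sim$target,
#'                    config = trainingConfig(p_grid = 10, repeats = 2,
#'                                            lambda_fixed = 0.1))
#' run$report$auc
#' @export
runPipeline <- function(source, target, alpha = 0.7,
                        method = c("logitda", "knnda"), useDA = TRUE,
                        harmonize = c("none", "location_scale"),
                        adjustCutoff = FALSE, maxGenes = 1000L,
                        config = trainingConfig()) {
  method <- match.arg(method)
  harmonize <- match.arg(harmonize)
  if (adjustCutoff && method == "knnda")
    stop("the odds-ratio cutoff adjustment applies to probability ",
         "classifiers only, not to KNN majority votes")
  both <- suppressMessages(
    intersectGenes(exprMatrix(source), exprMatrix(target)))
  harm <- harmonizeDomains(both$a, both$b, method = harmonize)
  src <- DomainDataset(harm$source, responseLabels(source),
                       domain = "source", drug = drugName(source))
  tgt <- DomainDataset(harm$target, responseLabels(target),
                       domain = "target", drug = drugName(target))
  ranking <- selectFeatures(src, tgt, alpha = alpha, maxGenes = maxGenes,
                            useDA = useDA)
  model <- if (method == "logitda") trainLogitDA(src, ranking, config)
           else trainKNNDA(src, ranking, config)
  scores <- predictProb(model, tgt)
  cutoff <- if (adjustCutoff) cutoffAdjustment(src, tgt) else 0.5
  cutVal <- if (is(cutoff, "CutoffAdjustment")) cutoff@cutoff else cutoff
  report <- evaluateScores(scores, responseLabels(tgt), cutoff = cutVal)
  log <- list(genes_common = nrow(both$a),
              genes_passed_da = sum(ranking@table$passed_da),
              genes_ranked = length(rankedGenes(ranking)),
              genes_in_model = length(model@genes),
              alpha = alpha, use_da = useDA, method = method,
              harmonize = harmonize, seed = config$seed)
  list(ranking = ranking, model = model, scores = scores, cutoff = cutoff,
       report = report, log = log)
}

#' Paired with-DA versus without-DA comparison
#'
#' Runs the pipeline twice per seed on the same data — once with the
#' domain-adaptation filter and once without (ablation) — using identical
#' CV fold assignments in both arms, and reports the paired per-seed
#' target-AUC difference with its mean and standard error.
#'
#' @inheritParams runPipeline
#' @param seeds integer vector of CV seeds (one pipeline pair per seed).
#' @return list with `per_seed` (data.frame: seed, auc_da, auc_noda, diff)
#'   and `summary` (mean and s.e. of the paired difference).
#' @export
ablationCompare <- function(source, target, alpha = 0.7,
                            method = c("logitda", "knnda"),
                            harmonize = c("none", "location_scale"),
                            maxGenes = 1000L, seeds = 1:10,
                            config = trainingConfig()) {
  method <- match.arg(method)
  harmonize <- match.arg(harmonize)
  rows <- lapply(seeds, function(s) {
    cf <- config; cf$seed <- as.integer(s)
    withDA <- runPipeline(source, target, alpha = alpha, method = method,
                          useDA = TRUE, harmonize = harmonize,
                          maxGenes = maxGenes, config = cf)
    noDA <- runPipeline(source, target, alpha = alpha, method = method,
                        useDA = FALSE, harmonize = harmonize,
                        maxGenes = maxGenes, config = cf)
    data.frame(seed = s, auc_da = withDA$report$auc,
               auc_noda = noDA$report$auc,
               diff = withDA$report$auc - noDA$report$auc)
  })
  perSeed <- do.call(rbind, rows)
  summ <- if (nrow(perSeed) >= 2L) repeatSummary(perSeed$diff)
          else c(mean = mean(perSeed$diff), se = NA_real_)
  list(per_seed = perSeed, summary = summ)
}

#' Responder/non-responder counts of the ten studied drug cohorts
#'
#' Training (cell-line) and test (patient/PDX) responder (NS) and
#' non-responder (NR) counts for the ten drug cohorts used in the worked
#' examples, shipped as plain text under `inst/extdata`. These counts are
#' the only ingredient of the cutoff adjustment, so the full set of
#' adjusted cutoffs can be reproduced without any expression data.
#'
#' @return data.frame with columns `drug`, `cohort`, `ns_train`,
#'   `nr_train`, `ns_test`, `nr_test`.
#' @examples
#' counts <- drugResponseCounts()
#' r <- (counts$ns_train / counts$nr_train) / (counts$ns_test / counts$nr_test)
#' round(r / (1 + r), 2)
#' @export
drugResponseCounts <- function() {
  path <- system.file("extdata", "drug_response_counts.tsv",
                      package = "drtrans", mustWork = TRUE)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}
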