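#' Training configuration for LogitDA / KNNDA
#'
#' Bundles the hyperparameter grids and cross-validation settings of the
#' training protocols. The default gene-count grid is 50 to 200 in steps of
#' 10, 220 to 400 in steps of 20, and 500 to 1000 in steps of 100; the
#' neighbour grid is the odd numbers 3 to 29 (odd K avoids half-vote ties).
#'
#' @param p_grid increasing integer vector of candidate gene counts.
#' @param folds number of CV folds (default 5).
#' @param repeats number of CV repeats (default 10).
#' @param seed integer seed fixing all fold assignments.
#' @param k_grid odd integer candidate neighbour counts for KNNDA.
#' @param lambda_fixed optional single positive value: skip the two-stage
#'   lambda search and score this penalty directly (useful for scaled-down
#'   simulation studies).
#' @param pool pool out-of-fold scores per repeat, see [cvAUC()].
#' @return a validated list of class `trainingConfig`.
#' @export
trainingConfig <- function(p_grid = c(seq(50L, 200L, 10L),
                                      seq(220L, 400L, 20L),
                                      seq(500L, 1000L, 100L)),
                           folds = 5L, repeats = 10L, seed = 1L,
                           k_grid = seq(3L, 29L, 2L),
                           lambda_fixed = NULL, pool = TRUE) {
  p_grid <- sort(unique(as.integer(p_grid)))
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(p_grid) == 0L || any(p_grid < 1L))
    stop("'p_grid' must be a non-empty vector of positive integers")
  if (folds < 2L) stop("'folds' must be at least 2")
  if (repeats < 1L) stop("'repeats' must be at least 1")
  if (length(k_grid) == 0L || any(k_grid %% 2L == 0L))
    stop("'k_grid' must be non-empty odd integers")
  if (!is.null(lambda_fixed) &&
      (!is.numeric(lambda_fixed) || length(lambda_fixed) != 1L ||
       lambda_fixed <= 0))
    stop("'lambda_fixed' must be a single positive number")
  structure(list(p_grid = p_grid, folds = as.integer(folds),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 k_grid = k_grid, lambda_fixed = lambda_fixed,
                 pool = isTRUE(pool)),
            class = "trainingConfig")
}

## top-p design matrix (samples x genes) in ranking order
topGeneMatrix <- function(source, genes) {
  t(exprMatrix(source)[genes, , drop = FALSE])
}

clipPGrid <- function(p_grid, nGenes) {
  pg <- p_grid[p_grid <= nGenes]
  if (length(pg) == 0L)
    stop("all entries of 'p_grid' exceed the ", nGenes,
         " available ranked genes")
  pg
}

#' Train a LogitDA predictor
#'
#' For every candidate gene count p in `config$p_grid` (clipped to the
#' ranking length), takes the top-p genes of the ranking, tunes the ridge
#' penalty by [tuneLambdaTwoStage()], and scores the configuration by mean
#' CV AUC. The (p, lambda) pair with the highest score wins — ties go to
#' the smaller p (parsimony), then the smaller lambda — and the final model
#' is refitted on all source samples.
#'
#' @param source the source-domain [DomainDataset-class].
#' @param ranking a [FeatureRanking-class] from [selectFeatures()].
#' @param config a [trainingConfig()].
#' @return a [LogitDA-class] predictor.
#' @export
trainLogitDA <- function(source, ranking, config = trainingConfig()) {
  stopifnot(is(ranking, "FeatureRanking"), inherits(config, "trainingConfig"))
  genes <- rankedGenes(ranking)
  pg <- clipPGrid(config$p_grid, length(genes))
  X <- topGeneMatrix(source, genes)
  y <- as.integer(responseLabels(source))
  rows <- lapply(pg, function(p) {
    Xp <- X[, seq_len(p), drop = FALSE]
    if (is.null(config$lambda_fixed)) {
      tuned <- tuneLambdaTwoStage(Xp, y, folds = config$folds,
                                  repeats = config$repeats,
                                  seed = config$seed, pool = config$pool)
      data.frame(p = p, lambda = tuned$lambda, cv_auc = tuned$cv_score,
                 cv_se = tuned$cv_se)
    } else {
      cv <- cvAUC(Xp, y, ridgeFactory(config$lambda_fixed),
                  folds = config$folds, repeats = config$repeats,
                  seed = config$seed, pool = config$pool)
      data.frame(p = p, lambda = config$lambda_fixed, cv_auc = cv$mean,
                 cv_se = cv$se)
    }
  })
  grid <- do.call(rbind, rows)
  best <- grid[order(-grid$cv_auc, grid$p, grid$lambda)[1L], ]
  gsel <- genes[seq_len(best$p)]
  fit <- fitLogisticRidge(X[, seq_len(best$p), drop = FALSE], y, best$lambda)
  new("LogitDA", genes = gsel, lambda = best$lambda,
      intercept = fit$intercept,
      coefficients = stats::setNames(fit$coefficients, gsel),
      cvScore = best$cv_auc, cvSE = best$cv_se, gridTable = grid,
      seed = config$seed)
}

#' Spearman-correlation distance between two expression profiles
#'
#' `1 - rho`, where rho is Spearman's rank correlation (average ranks for
#' ties). Ranges over `[0, 2]`: 0 for identical orderings, 2 for exactly
#' reversed ones. Euclidean distance performs poorly on expression profiles
#' across platforms; rank correlation is scale-free.
#'
#' @param u,v numeric vectors of equal length >= 2, neither constant.
#' @return distance in `[0, 2]`.
#' @examples
#' spearmanDistance(c(1, 2, 3, 4), c(1, 3, 2, 4))  # 0.2
#' @export
spearmanDistance <- function(u, v) {
  stopifnot(length(u) == length(v), length(u) >= 2L)
  if (stats::sd(u) == 0 || stats::sd(v) == 0)
    stop("Spearman's rho is undefined for a constant vector")
  1 - stats::cor(u, v, method = "spearman")
}

## KNN vote-fraction scores. refX/queryX are samples x genes; neighbour
## distance is 1 - Spearman rho; distance ties break by reference sample
## order for determinism.
knnScores <- function(refX, refY, queryX, k) {
  if (ncol(refX) < 2L) stop("KNN needs at least 2 genes")
  constRow <- function(m) apply(m, 1L, function(r) stats::sd(r) == 0)
  if (any(constRow(refX)) || any(constRow(queryX)))
    stop("Spearman's rho is undefined for constant expression profiles")
  rk <- function(m) t(apply(m, 1L, rank))
  rho <- stats::cor(t(rk(queryX)), t(rk(refX)))   # n_query x n_ref
  d <- 1 - rho
  apply(d, 1L, function(di) {
    nb <- order(di, seq_along(di))[seq_len(k)]
    mean(refY[nb])
  })
}

## factory with a fixed neighbour count
knnFactory <- function(k) {
  force(k)
  function(Xtr, ytr) function(Xte) knnScores(Xtr, ytr, Xte, k)
}

#' Train a KNNDA predictor
#'
#' For every candidate gene count p and neighbour count K, scores a
#' Spearman-distance KNN classifier (a sample's score is the fraction of
#' its K nearest training neighbours labelled sensitive) by repeated
#' stratified CV AUC. The best (p, K) wins — ties go to the smaller K, then
#' the smaller p — and the final predictor stores all source samples
#' restricted to the top-p genes as its reference set. K values exceeding
#' the smallest training-fold size are skipped with a warning.
#'
#' @inheritParams trainLogitDA
#' @return a [KNNDA-class] predictor.
#' @export
trainKNNDA <- function(source, ranking, config = trainingConfig()) {
  stopifnot(is(ranking, "FeatureRanking"), inherits(config, "trainingConfig"))
  genes <- rankedGenes(ranking)
  pg <- clipPGrid(config$p_grid, length(genes))
  X <- topGeneMatrix(source, genes)
  y <- as.integer(responseLabels(source))
  minTrain <- nrow(X) - ceiling(nrow(X) / config$folds)
  kg <- config$k_grid[config$k_grid <= minTrain]
  if (length(kg) < length(config$k_grid))
    warning("skipping K > ", minTrain,
            " (smallest training-fold size): ",
            paste(setdiff(config$k_grid, kg), collapse = ", "))
  if (length(kg) == 0L)
    stop("every K in 'k_grid' exceeds the training-fold size")
  rows <- list()
  for (p in pg) {
    Xp <- X[, seq_len(p), drop = FALSE]
    for (k in kg) {
      cv <- cvAUC(Xp, y, knnFactory(k), folds = config$folds,
                  repeats = config$repeats, seed = config$seed,
                  pool = config$pool)
      rows[[length(rows) + 1L]] <-
        data.frame(p = p, k = k, cv_auc = cv$mean, cv_se = cv$se)
    }
  }
  grid <- do.call(rbind, rows)
  best <- grid[order(-grid$cv_auc, grid$k, grid$p)[1L], ]
  gsel <- genes[seq_len(best$p)]
  new("KNNDA", genes = gsel, k = as.integer(best$k),
      refExpr = exprMatrix(source)[gsel, , drop = FALSE],
      refLabels = y, cvScore = best$cv_auc, cvSE = best$cv_se,
      gridTable = grid, seed = config$seed)
}

## shared gene lookup for prediction methods
alignGenes <- function(object, newdata) {
  if (is(newdata, "DomainDataset")) newdata <- exprMatrix(newdata)
  stopifnot(is.matrix(newdata))
  missing <- setdiff(object@genes, rownames(newdata))
  if (length(missing))
    stop("genes used by the model are missing from the new data: ",
         paste(utils::head(missing, 10), collapse = ", "),
         if (length(missing) > 10) sprintf(" (and %d more)",
                                           length(missing) - 10) else "")
  newdata[object@genes, , drop = FALSE]
}

#' @rdname predictProb
#' @export
setMethod("predictProb", "LogitDA", function(object, newdata) {
  x <- alignGenes(object, newdata)
  drop(stats::plogis(object@intercept +
                       crossprod(x, object@coefficients)))
})

#' @rdname predictProb
#' @export
setMethod("predictProb", "KNNDA", function(object, newdata) {
  x <- alignGenes(object, newdata)
  scores <- knnScores(t(object@refExpr), object@refLabels, t(x), object@k)
  stats::setNames(scores, colnames(x))
})
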