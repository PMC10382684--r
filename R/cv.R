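## Run code under a temporary RNG state so seeded internals do not disturb
## the caller's random stream.
withLocalSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

## Stratified fold assignment: within each class, a random permutation is
## dealt into folds round-robin, so every fold keeps both classes whenever
## each class has >= folds samples.
stratifiedFolds <- function(y, folds) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx[sample.int(length(idx))]] <-
      rep_len(seq_len(folds), length(idx))
  }
  fold
}

#' Repeated stratified cross-validated AUC
#'
#' Scores a model-building recipe by K-fold cross-validation repeated with
#' different fold assignments. Folds are stratified by class (responder
#' counts as low as a few dozen would otherwise produce single-class
#' folds). Per repeat, the out-of-fold scores of all samples are pooled
#' into one AUC (set `pool = FALSE` to average per-fold AUCs instead); the
#' mean and standard error over repeats are returned. Fold assignments come
#' from a seeded generator, so results are bit-reproducible for a fixed
#' `seed`.
#'
#' @param X numeric samples-by-genes matrix.
#' @param y 0/1 response vector; each class needs at least `folds` samples.
#' @param modelFactory function `(Xtrain, ytrain)` returning a scoring
#'   function `(Xtest) -> numeric scores`.
#' @param folds number of folds (default 5).
#' @param repeats number of repeats with fresh fold assignments (default 10).
#' @param seed integer; repeat `i` uses seed `seed + i - 1`.
#' @param pool pool out-of-fold scores per repeat (default) or average
#'   per-fold AUCs.
#' @return list with `mean`, `se`, and `perRepeat` AUC vector.
#' @export
cvAUC <- function(X, y, modelFactory, folds = 5L, repeats = 10L, seed = 1L,
                  pool = TRUE) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (min(table(factor(y, levels = c(0L, 1L)))) < folds)
    stop("each class needs at least ", folds,
         " samples for ", folds, "-fold CV; use fewer folds")
  perRepeat <- numeric(repeats)
  for (r in seq_len(repeats)) {
    fold <- withLocalSeed(seed + r - 1L, stratifiedFolds(y, folds))
    if (pool) {
      scores <- numeric(length(y))
      for (f in seq_len(folds)) {
        te <- fold == f
        predictor <- modelFactory(X[!te, , drop = FALSE], y[!te])
        scores[te] <- predictor(X[te, , drop = FALSE])
      }
      perRepeat[r] <- rocAUC(scores, y)
    } else {
      aucs <- numeric(folds)
      for (f in seq_len(folds)) {
        te <- fold == f
        predictor <- modelFactory(X[!te, , drop = FALSE], y[!te])
        aucs[f] <- rocAUC(predictor(X[te, , drop = FALSE]), y[te])
      }
      perRepeat[r] <- mean(aucs)
    }
  }
  summ <- repeatSummary(perRepeat)
  list(mean = summ[["mean"]], se = summ[["se"]], perRepeat = perRepeat)
}

## model factory for a fixed ridge penalty
ridgeFactory <- function(lambda) {
  force(lambda)
  function(Xtr, ytr) {
    fit <- fitLogisticRidge(Xtr, ytr, lambda)
    function(Xte) drop(stats::plogis(fit$intercept +
                                       Xte %*% fit$coefficients))
  }
}

#' Two-stage grid search for the ridge penalty
#'
#' Stage 1 scans `lambda = 10^a` over the 11 exponents `a = -3, -2.7, ...,
#' 0` by repeated cross-validated AUC; writing `a1` for the best exponent,
#' stage 2 rescans the 11 exponents `a1 - 0.05, a1 - 0.04, ..., a1 + 0.05`.
#' The final lambda is the stage-2 grid point with the highest mean CV AUC;
#' score ties go to the smaller lambda. Both stages reuse the same seed, so
#' every lambda is compared on identical fold assignments.
#'
#' @inheritParams cvAUC
#' @return list with `lambda`, `exponent`, `cv_score`, `cv_se`, and `table`
#'   (a data.frame of every grid point scored, with a `stage` column).
#' @export
tuneLambdaTwoStage <- function(X, y, folds = 5L, repeats = 10L, seed = 1L,
                               pool = TRUE) {
  scan <- function(exponents, stage) {
    res <- lapply(exponents, function(a) {
      cv <- cvAUC(X, y, ridgeFactory(10^a), folds = folds,
                  repeats = repeats, seed = seed, pool = pool)
      data.frame(stage = stage, exponent = a, lambda = 10^a,
                 cv_auc = cv$mean, cv_se = cv$se)
    })
    do.call(rbind, res)
  }
  stage1 <- scan(stage1Exponents(), 1L)
  a1 <- with(stage1, exponent[order(-cv_auc, lambda)][1L])
  stage2 <- scan(stage2Exponents(a1), 2L)
  best <- with(stage2, order(-cv_auc, lambda))[1L]
  list(lambda = stage2$lambda[best], exponent = stage2$exponent[best],
       cv_score = stage2$cv_auc[best], cv_se = stage2$cv_se[best],
       table = rbind(stage1, stage2))
}

## exponent grids of the two-stage search (11 points each)
stage1Exponents <- function() round(seq(-3, 0, by = 0.3), 10)
stage2Exponents <- function(a1) round(seq(a1 - 0.05, a1 + 0.05, by = 0.01), 10)
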