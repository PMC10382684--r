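test_that("ridge limits behave: heavy penalty shrinks to the prevalence", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3)
  y <- rbinom(100, 1, 0.3)
  fit <- fitLogisticRidge(X, y, lambda = 1e8)
  expect_lt(max(abs(fit$coefficients)), 1e-6)
  expect_equal(fit$intercept, qlogis(mean(y)), tolerance = 1e-3)
})

test_that("ridge keeps separable data finite with perfect training AUC", {
  X <- matrix(c(-3, -2, -1, 1, 2, 3), ncol = 1)
  y <- c(0, 0, 0, 1, 1, 1)
  fit <- fitLogisticRidge(X, y, lambda = 0.1)
  expect_true(all(is.finite(c(fit$intercept, fit$coefficients))))
  scores <- plogis(fit$intercept + X %*% fit$coefficients)
  expect_equal(rocAUC(scores, y), 1.0)
})

test_that("near-unpenalised ridge recovers known coefficients", {
  set.seed(42)
  n <- 5000; p <- 5
  beta <- c(1, -0.8, 0.5, 0, 0.3)
  X <- matrix(rnorm(n * p), n, p)
  y <- rbinom(n, 1, plogis(0.2 + X %*% beta))
  fit <- fitLogisticRidge(X, y, lambda = 1e-6)
  ml <- glm(y ~ X, family = binomial)
  se <- summary(ml)$coefficients[-1, "Std. Error"]
  expect_lt(max(abs(fit$coefficients - coef(ml)[-1])), 1e-3)  # matches MLE
  expect_true(all(abs(fit$coefficients - beta) < 3 * se))     # recovers truth
})

test_that("ridge solution agrees with glmnet and is a local optimum", {
  set.seed(43)
  X <- matrix(rnorm(600), 120, 5)
  y <- rbinom(120, 1, plogis(X[, 1] - X[, 2]))
  lam <- 0.05
  fit <- fitLogisticRidge(X, y, lambda = lam)
  # glmnet penalises lambda/2 * ||beta||^2 on the mean log-likelihood scale
  gn <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                       lambda = 2 * lam, standardize = FALSE,
                       thresh = 1e-14)
  expect_equal(unname(fit$coefficients), as.numeric(gn$beta),
               tolerance = 1e-4)
  expect_equal(fit$intercept, as.numeric(gn$a0), tolerance = 1e-4)

  obj0 <- drtrans:::ridgeObjective(X, y, fit$intercept, fit$coefficients, lam)
  set.seed(44)
  for (i in 1:1000) {
    d <- rnorm(6); d <- 1e-3 * d / sqrt(sum(d^2))
    expect_lte(obj0, drtrans:::ridgeObjective(X, y, fit$intercept + d[1],
                                              fit$coefficients + d[-1], lam))
  }
})

test_that("cross-validated AUC is null-centred, sharp, and deterministic", {
  aucs <- sapply(1:50, function(s) {
    set.seed(s)
    X <- matrix(rnorm(200 * 5), 200, 5)
    y <- rbinom(200, 1, 0.5)
    cvAUC(X, y, drtrans:::ridgeFactory(0.1), folds = 5, repeats = 2,
          seed = s)$mean
  })
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)

  set.seed(45)
  y <- rbinom(100, 1, 0.5)
  X <- cbind(y + rnorm(100, sd = 1e-6), matrix(rnorm(200), 100, 2))
  perfect <- cvAUC(X, y, drtrans:::ridgeFactory(0.01), repeats = 2, seed = 9)
  expect_equal(perfect$mean, 1.0)

  a <- cvAUC(X, y, drtrans:::ridgeFactory(0.1), repeats = 3, seed = 7)
  b <- cvAUC(X, y, drtrans:::ridgeFactory(0.1), repeats = 3, seed = 7)
  expect_identical(a$perRepeat, b$perRepeat)

  expect_error(cvAUC(X, c(rep(1, 3), rep(0, 97)),
                     drtrans:::ridgeFactory(0.1), folds = 5, seed = 1),
               "fewer folds")
})

test_that("two-stage lambda search scans 11 + 11 points around the peak", {
  set.seed(46)
  X <- matrix(rnorm(80 * 3), 80, 3)
  y <- rbinom(80, 1, plogis(X[, 1]))
  tuned <- tuneLambdaTwoStage(X, y, repeats = 2, seed = 3)
  expect_equal(sum(tuned$table$stage == 1), 11)
  expect_equal(sum(tuned$table$stage == 2), 11)
  a1 <- with(tuned$table[tuned$table$stage == 1, ],
             exponent[which.max(cv_auc)])
  expect_gte(tuned$lambda, 10^(a1 - 0.05) - 1e-12)
  expect_lte(tuned$lambda, 10^(a1 + 0.05) + 1e-12)
})

test_that("LogitDA training selects the informative gene count", {
  sim <- generateDomainPair(syntheticConfig(n_source = 200, n_target = 50,
    n_invariant_informative = 60, n_invariant_null = 140, n_shifted = 0,
    effect_size = 0.5, seed = 2))
  fr <- selectFeatures(sim$source, sim$target, alpha = 0.7, useDA = FALSE)
  m <- trainLogitDA(sim$source, fr,
                    trainingConfig(p_grid = c(20, 60, 140), repeats = 2,
                                   lambda_fixed = 0.1, seed = 2))
  expect_equal(length(m@genes), 60)
  expect_equal(m@cvScore, max(m@gridTable$cv_auc))

  single <- trainLogitDA(sim$source, fr,
                         trainingConfig(p_grid = 10, repeats = 2,
                                        lambda_fixed = 0.5, seed = 2))
  expect_equal(length(single@genes), 10)
  expect_equal(single@lambda, 0.5)
  expect_error(trainLogitDA(sim$source, fr,
                            trainingConfig(p_grid = 10000, repeats = 2,
                                           lambda_fixed = 0.5)),
               "exceed")
})

test_that("Spearman distance matches hand computations", {
  expect_equal(spearmanDistance(c(2, 5, 9, 11), c(2, 5, 9, 11)), 0)
  expect_equal(spearmanDistance(1:5, 5:1), 2)
  expect_equal(spearmanDistance(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.2)
  expect_error(spearmanDistance(c(1, 1, 1), c(1, 2, 3)), "constant")
})

test_that("KNN neighbour sets match a brute-force all-pairs sort", {
  set.seed(47)
  for (trial in 1:5) {
    nref <- sample(10:30, 1)
    refX <- matrix(rnorm(nref * 8), nref, 8)
    refY <- rbinom(nref, 1, 0.5)
    q <- rnorm(8)
    for (k in c(1, 3, 7)) {
      nb <- bruteNeighbors(refX, q, k)
      score <- drtrans:::knnScores(refX, refY, matrix(q, 1), k)
      expect_equal(score, mean(refY[nb]))
    }
  }
})

test_that("KNNDA training separates clustered classes and is deterministic", {
  set.seed(48)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  # class-specific profile shapes (Spearman distance ignores level shifts)
  x <- matrix(rnorm(10 * n, sd = 0.5), 10, n) +
    outer(seq(-2, 2, length.out = 10), ifelse(y == 1, 1, -1))
  dimnames(x) <- list(sprintf("G%02d", 1:10), sprintf("CL%03d", 1:n))
  src <- DomainDataset(x, y, domain = "source")
  fr <- selectFeatures(src,
                       DomainDataset(x, y, domain = "target"),
                       alpha = 0.6, maxGenes = 10)
  cfg <- trainingConfig(p_grid = c(5, 10), repeats = 2,
                        k_grid = c(3, 5, 7), seed = 5)
  m1 <- trainKNNDA(src, fr, cfg)
  expect_gte(min(m1@gridTable$cv_auc), 0.95)
  m2 <- trainKNNDA(src, fr, cfg)
  expect_identical(c(length(m1@genes), m1@k), c(length(m2@genes), m2@k))
  expect_identical(m1@gridTable, m2@gridTable)
})

test_that("a duplicated sample's nearest neighbour is itself", {
  set.seed(49)
  ref <- matrix(rnorm(5 * 6), 5, 6)
  refY <- c(1L, 0L, 1L, 0L, 1L)
  score <- drtrans:::knnScores(ref, refY, ref[2, , drop = FALSE], k = 1)
  expect_equal(score, 0)  # duplicate of sample 2, labelled 0
})

test_that("prediction contracts hold for both model kinds", {
  genes <- c("G1", "G2")
  m <- new("LogitDA", genes = genes, lambda = 1, intercept = 0,
           coefficients = setNames(c(0, 0), genes), cvScore = 0.5,
           cvSE = 0, gridTable = data.frame(), seed = 1L)
  tgt <- matrix(rnorm(6), 2, 3, dimnames = list(genes, paste0("PT", 1:3)))
  expect_equal(unname(predictProb(m, tgt)), rep(0.5, 3))

  m@coefficients["G1"] <- 2
  lo <- predictProb(m, tgt)
  hi <- tgt; hi["G1", ] <- hi["G1", ] + 1
  expect_true(all(predictProb(m, hi) > lo))  # monotone in a +ve coefficient

  expect_error(predictProb(m, tgt[1, , drop = FALSE]), "G2")

  set.seed(50)
  ref <- matrix(rnorm(40), 4, 10,
                dimnames = list(paste0("G", 1:4), paste0("CL", 1:10)))
  km <- new("KNNDA", genes = rownames(ref), k = 5L, refExpr = ref,
            refLabels = rep(c(1L, 0L), 5), cvScore = 0.5, cvSE = 0,
            gridTable = data.frame(), seed = 1L)
  sc <- predictProb(km, matrix(rnorm(8), 4, 2,
                               dimnames = list(rownames(ref), c("A", "B"))))
  expect_true(all(sc %in% ((0:5) / 5)))  # vote fractions only
})

test_that("training on permuted labels yields near-chance target AUC", {
  aucs <- sapply(1:20, function(s) {
    sim <- generateDomainPair(syntheticConfig(n_source = 150, n_target = 100,
      n_invariant_informative = 10, n_invariant_null = 0, n_shifted = 0,
      effect_size = 1, seed = 600 + s))
    set.seed(s)
    yPerm <- sample(responseLabels(sim$source))
    srcPerm <- DomainDataset(exprMatrix(sim$source), unname(yPerm),
                             domain = "source")
    fit <- fitLogisticRidge(t(exprMatrix(srcPerm)), responseLabels(srcPerm),
                            0.1)
    scores <- plogis(fit$intercept +
                       t(exprMatrix(sim$target)) %*% fit$coefficients)
    rocAUC(scores, responseLabels(sim$target))
  })
  expect_gte(mean(aucs), 0.42)
  expect_lte(mean(aucs), 0.58)
})
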