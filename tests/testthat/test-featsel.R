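makeKSPair <- function(xs, ys, xt, yt) {
  list(source = makeDomain(xs, ys, "source"),
       target = makeDomain(xt, yt, "target"))
}

test_that("identical class-conditional samples pass the KS filter", {
  vals <- c(1.5, 2.5, 3.5, 9, 10, 11)
  y <- c(1, 1, 1, 0, 0, 0)
  pair <- makeKSPair(rbind(G1 = vals), y, rbind(G1 = vals), y)
  ks <- ksDomainFilter(pair$source, pair$target, alpha = 0.9)
  expect_equal(ks$ks_p_y1, 1)
  expect_equal(ks$ks_p_y0, 1)
  expect_true(ks$passed_da)
})

test_that("disjoint-support KS p-value matches exact enumeration", {
  xs <- rbind(G1 = c(1, 2, 3, 4, 50, 60, 70))
  ys <- c(1, 1, 1, 1, 0, 0, 0)
  xt <- rbind(G1 = c(10, 11, 12, 13, 50.5, 61, 71))
  yt <- c(1, 1, 1, 1, 0, 0, 0)
  pair <- makeKSPair(xs, ys, xt, yt)
  ks <- ksDomainFilter(pair$source, pair$target, alpha = 0.5)
  # class-1 samples {1,2,3,4} vs {10,11,12,13}: D = 1
  expect_equal(ks$ks_p_y1, bruteKSp(c(1, 2, 3, 4), c(10, 11, 12, 13)))
  expect_equal(ks$ks_p_y1, 2 / choose(8, 4))
})

test_that("small-sample KS p-values equal the enumeration oracle", {
  set.seed(31)
  for (case in 1:25) {
    n1 <- sample(3:8, 1); n2 <- sample(3:8, 1)
    if (case %% 2 == 0) {  # discrete values force ties
      x <- sample(1:4, n1, replace = TRUE) + 0
      y <- sample(1:4, n2, replace = TRUE) + 0
    } else {
      x <- rnorm(n1); y <- rnorm(n2, mean = 0.5)
    }
    expect_equal(drtrans:::ksPvalue(x, y), bruteKSp(x, y),
                 tolerance = 1e-10,
                 info = sprintf("case %d (n1=%d, n2=%d)", case, n1, n2))
  }
})

test_that("DA passing sets are nested as alpha grows", {
  set.seed(32)
  sim <- generateDomainPair(syntheticConfig(n_source = 60, n_target = 60,
    n_invariant_informative = 30, n_invariant_null = 30, n_shifted = 40,
    seed = 32))
  alphas <- c(0.6, 0.7, 0.8, 0.9)
  sets <- lapply(alphas, function(a) {
    ks <- ksDomainFilter(sim$source, sim$target, alpha = a)
    ks$gene_id[ks$passed_da]
  })
  for (i in 2:4)
    expect_true(all(sets[[i]] %in% sets[[i - 1]]))
})

test_that("KS filter rejects degenerate class structure loudly", {
  xs <- rbind(G1 = rnorm(4))
  pair <- makeKSPair(xs, c(1, 1, 1, 1), rbind(G1 = rnorm(4)), c(1, 0, 1, 0))
  expect_error(
    ksDomainFilter(makeDomain(xs, c(1, 1, 1, 1)), pair$target, alpha = 0.5),
    "source.*class 0")
})

test_that("differential-expression ranking rewards a dominating gene", {
  set.seed(33)
  n <- 40
  y <- rep(c(1, 0), each = 20)
  x <- matrix(rnorm(50 * n), 50, n,
              dimnames = list(sprintf("G%02d", 1:50), paste0("S", 1:n)))
  x["G07", y == 1] <- x["G07", y == 1] + 10
  src <- makeDomain(x, y)
  de <- deRank(src, rownames(x))
  expect_identical(de$gene_id[1], "G07")
  expect_equal(nrow(de), 50)          # cap of 1000 not binding
  de5 <- deRank(src, rownames(x)[1:5], maxGenes = 1000)
  expect_equal(nrow(de5), 5)
})

test_that("BH adjustment matches the hand-computed step-up ladder", {
  # raw p {0.01,...,0.05}, m = 5: p_(i) * 5/i = 0.05 for every i
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.04, 0.05), method = "BH"),
               rep(0.05, 5))
  # deRank orders by this FDR with raw-p tie-breaks; spot-check wiring
  set.seed(34)
  y <- rep(c(1, 0), each = 10)
  x <- matrix(rnorm(60), 3, 20,
              dimnames = list(c("GA", "GB", "GC"), paste0("S", 1:20)))
  de <- deRank(makeDomain(x, y), c("GA", "GB", "GC"))
  welch <- sapply(c("GA", "GB", "GC"),
                  function(g) t.test(x[g, y == 1], x[g, y == 0])$p.value)
  expect_equal(de$fdr[order(de$gene_id)],
               unname(p.adjust(welch, "BH")), tolerance = 1e-12)
})

test_that("BW ratio matches the definition and its degenerate rules", {
  expect_equal(bwRatio(c(1, 2, 3, 4, 5, 6), c(1, 1, 1, 0, 0, 0)), 3.375)
  expect_equal(bwRatio(c(2, 2, 2, 2), c(1, 1, 0, 0)), 0)          # 0/0
  expect_identical(bwRatio(c(1, 1, 3, 3), c(1, 1, 0, 0)), Inf)    # x/0
  expect_error(bwRatio(c(1, 2), c(1, 1)), "non-empty")
})

test_that("BW ratio equals a naive double-loop oracle on random input", {
  set.seed(35)
  for (i in 1:1000) {
    n <- sample(4:12, 1)
    y <- c(1, 0, rbinom(n - 2, 1, 0.5))
    x <- round(rnorm(n), 2)
    expect_equal(bwRatio(x, y), naiveBW(x, y), tolerance = 1e-12)
  }
})

test_that("selection recovers invariant informative genes", {
  sim <- generateDomainPair(syntheticConfig(
    n_source = 200, n_target = 200, n_invariant_informative = 50,
    n_invariant_null = 0, n_shifted = 500, seed = 1))
  fr <- selectFeatures(sim$source, sim$target, alpha = 0.7)
  top <- utils::head(rankedGenes(fr), 50)
  expect_gte(mean(sim$truth$roles[top] == "invariant_informative"), 0.8)

  # ablation removes the filter: strictly more genes become eligible
  frNo <- selectFeatures(sim$source, sim$target, alpha = 0.7, useDA = FALSE)
  expect_gt(length(rankedGenes(frNo)), length(rankedGenes(fr)))

  fr10 <- selectFeatures(sim$source, sim$target, alpha = 0.7, maxGenes = 10)
  expect_equal(length(rankedGenes(fr10)),
               min(10L, length(rankedGenes(fr))))
})

test_that("selection is invariant to sample and gene permutations", {
  sim <- generateDomainPair(syntheticConfig(n_source = 50, n_target = 50,
    n_invariant_informative = 10, n_invariant_null = 10, n_shifted = 20,
    seed = 36))
  fr <- selectFeatures(sim$source, sim$target, alpha = 0.6, maxGenes = 15)
  set.seed(37)
  gp <- sample(nrow(sim$source))
  sp <- sample(ncol(sim$source)); tp <- sample(ncol(sim$target))
  permute <- function(ds, gp, sp, domain) {
    DomainDataset(exprMatrix(ds)[gp, sp], responseLabels(ds)[sp],
                  domain = domain)
  }
  frP <- selectFeatures(permute(sim$source, gp, sp, "source"),
                        permute(sim$target, gp, tp, "target"),
                        alpha = 0.6, maxGenes = 15)
  expect_identical(rankedGenes(frP), rankedGenes(fr))
})

test_that("null panels keep the BH false-discovery fraction nominal", {
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    sim <- generateDomainPair(syntheticConfig(n_source = 40, n_target = 10,
      n_invariant_informative = 0, n_invariant_null = 50, n_shifted = 0,
      effect_size = 0, seed = 400 + s))
    de <- deRank(sim$source, rownames(sim$source))
    hits <- hits + sum(de$fdr < 0.05)
    total <- total + nrow(de)
  }
  se <- sqrt(0.05 * 0.95 / total)
  expect_lte(hits / total, 0.05 + 3 * se)
})
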