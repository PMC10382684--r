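#' Standardise each gene to mean zero and unit scale
#'
#' Centres and scales every gene row by its sample mean and sample standard
#' deviation (denominator n-1). Genes with zero variance become all-zero
#' rows rather than NaN, so downstream matrices stay finite; such genes can
#' never rank in differential expression anyway.
#'
#' @param expr numeric genes-by-samples matrix (>= 2 samples).
#' @return matrix of the same shape; each non-constant row has mean 0 and
#'   sample s.d. 1.
#' @export
standardizeGenes <- function(expr) {
  if (ncol(expr) < 2L)
    stop("standardisation needs at least 2 samples per gene")
  mu <- rowMeans(expr)
  sdv <- apply(expr, 1L, stats::sd)
  ctr <- expr - mu
  sdv[sdv == 0] <- Inf   # constant rows -> all zeros
  ctr / sdv
}

#' Normalise samples by a housekeeping gene
#'
#' Subtracts the housekeeping gene's value from every gene in the same
#' sample (division on the raw scale; expression is expected log-scale).
#' The housekeeping row itself becomes identically zero, so applying the
#' transform twice equals applying it once.
#'
#' @param expr numeric genes-by-samples matrix.
#' @param hkGene housekeeping gene identifier, e.g. `"GAPDH"`; must be a
#'   row of `expr`. If absent, the error lists close matches.
#' @return matrix of the same shape.
#' @export
normalizeHousekeeping <- function(expr, hkGene = "GAPDH") {
  if (!hkGene %in% rownames(expr)) {
    near <- utils::head(agrep(hkGene, rownames(expr), value = TRUE,
                              ignore.case = TRUE, max.distance = 0.2), 5)
    stop("housekeeping gene '", hkGene, "' not found",
         if (length(near)) paste0("; near matches: ",
                                  paste(near, collapse = ", ")) else "")
  }
  sweep(expr, 2L, expr[hkGene, ], "-")
}

#' Restrict two expression matrices to their common genes
#'
#' Keeps only genes present in both matrices, in the same order in both
#' (the order of appearance in `a`). The intersection size is reported via
#' `message()` for audit logs.
#'
#' @param a,b numeric genes-by-samples matrices with gene row names.
#' @return list with elements `a` and `b`, both restricted to the common
#'   genes.
#' @export
intersectGenes <- function(a, b) {
  common <- intersect(rownames(a), rownames(b))
  if (length(common) == 0L)
    stop("no genes in common between the two matrices")
  message(sprintf("intersectGenes: %d genes in common (of %d and %d)",
                  length(common), nrow(a), nrow(b)))
  list(a = a[common, , drop = FALSE], b = b[common, , drop = FALSE])
}

#' Harmonise source and target expression matrices
#'
#' Cross-platform location-scale matching: every gene is centred and scaled
#' within each domain, so per-domain per-gene means (0) and scales (1)
#' agree across domains afterwards. `method = "none"` passes pre-harmonised
#' inputs through untouched. Empirical-Bayes batch correction (ComBat) is
#' deliberately out of scope; use the sva package upstream if needed.
#'
#' @param source,target numeric genes-by-samples matrices with identical
#'   gene sets in identical order (run [intersectGenes()] first).
#' @param method `"location_scale"` (default) or `"none"`.
#' @return list with harmonised `source` and `target` matrices.
#' @export
harmonizeDomains <- function(source, target,
                             method = c("location_scale", "none")) {
  method <- match.arg(method)
  if (!identical(rownames(source), rownames(target)))
    stop("gene sets/order differ between domains; run intersectGenes() first")
  if (method == "none") return(list(source = source, target = target))
  list(source = standardizeGenes(source), target = standardizeGenes(target))
}

#' Assemble and pre-process a source/target dataset pair
#'
#' Convenience wrapper over the single-step functions: optional
#' housekeeping normalisation of either domain, per-gene standardisation,
#' gene intersection, harmonisation, and construction of the two
#' [DomainDataset-class] objects.
#'
#' @param sourceExpr,targetExpr genes-by-samples matrices.
#' @param sourceResponse,targetResponse named or ordered 0/1 vectors.
#' @param drug drug name carried through to reports.
#' @param hkGene housekeeping gene for normalisation, or `NULL` to skip.
#' @param hkDomains which domains receive housekeeping normalisation.
#' @param harmonize harmonisation method, see [harmonizeDomains()].
#' @return list with `source` and `target` [DomainDataset-class] objects.
#' @export
preprocessDomains <- function(sourceExpr, sourceResponse,
                              targetExpr, targetResponse,
                              drug = "unknown", hkGene = NULL,
                              hkDomains = c("source", "target"),
                              harmonize = c("location_scale", "none")) {
  harmonize <- match.arg(harmonize)
  sourceExpr <- standardizeGenes(sourceExpr)
  targetExpr <- standardizeGenes(targetExpr)
  if (!is.null(hkGene)) {
    if ("source" %in% hkDomains)
      sourceExpr <- normalizeHousekeeping(sourceExpr, hkGene)
    if ("target" %in% hkDomains)
      targetExpr <- normalizeHousekeeping(targetExpr, hkGene)
  }
  both <- intersectGenes(sourceExpr, targetExpr)
  harm <- harmonizeDomains(both$a, both$b, method = harmonize)
  list(source = DomainDataset(harm$source, sourceResponse,
                              domain = "source", drug = drug),
       target = DomainDataset(harm$target, targetResponse,
                              domain = "target", drug = drug))
}
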