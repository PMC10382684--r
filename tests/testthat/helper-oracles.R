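# Independent brute-force oracles used to validate the fast implementations.

## Exact two-sample KS p-value by enumeration of all class-preserving
## splits of the pooled sample (feasible for n1 + n2 <= 16).
bruteKSp <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  Dof <- function(a, b) {
    u <- sort(unique(c(a, b)))
    max(abs(stats::ecdf(a)(u) - stats::ecdf(b)(u)))
  }
  d0 <- Dof(x, y)
  idx <- utils::combn(length(z), n1)
  hits <- 0L
  for (j in seq_len(ncol(idx))) {
    a <- z[idx[, j]]; b <- z[-idx[, j]]
    if (Dof(a, b) >= d0 - 1e-12) hits <- hits + 1L
  }
  hits / ncol(idx)
}

## Literal double-loop transcription of the BW-ratio definition.
naiveBW <- function(x, y) {
  xbar <- mean(x)
  num <- 0; den <- 0
  for (i in seq_along(x)) {
    for (k in c(0, 1)) {
      if (y[i] == k) {
        xk <- mean(x[y == k])
        num <- num + (xk - xbar)^2
        den <- den + (x[i] - xk)^2
      }
    }
  }
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

## AUC by exhaustive positive-negative pair counting.
bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg)
    tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

## Neighbour sets by scalar Spearman distances and a full sort.
bruteNeighbors <- function(refX, query, k) {
  d <- apply(refX, 1L, function(r) spearmanDistance(query, r))
  order(d, seq_along(d))[seq_len(k)]
}

## Tiny DomainDataset builder with automatic identifiers.
makeDomain <- function(x, y, domain = "source", drug = "testdrug") {
  if (is.null(rownames(x)))
    rownames(x) <- sprintf("G%03d", seq_len(nrow(x)))
  if (is.null(colnames(x)))
    colnames(x) <- sprintf("%s%03d", if (domain == "source") "CL" else "PT",
                           seq_len(ncol(x)))
  DomainDataset(x, y, domain = domain, drug = drug)
}
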