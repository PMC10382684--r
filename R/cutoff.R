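#' Domain odds ratio of responder proportions
#'
#' `r = (NS_S / NR_S) / (NS_T / NR_T)`: the responder odds of the source
#' domain over the responder odds of the target domain, from empirical
#' label counts. `r = 1` means identical class balance across domains; a
#' source-trained predictor's probabilities are then directly portable
#' (cutoff 0.5). All four counts must be positive — a zero count leaves the
#' odds ratio, and with it the adjusted cutoff, undefined.
#'
#' @param sourceLabels,targetLabels 0/1 label vectors (or
#'   [DomainDataset-class] objects, whose labels are extracted).
#' @return positive number `r`.
#' @examples
#' oddsRatio(rep(c(1, 0), c(275, 575)), rep(c(1, 0), c(60, 6)))  # ~0.0478
#' @export
oddsRatio <- function(sourceLabels, targetLabels) {
  lab <- function(x) if (is(x, "DomainDataset")) responseLabels(x) else x
  s <- as.integer(lab(sourceLabels)); t <- as.integer(lab(targetLabels))
  ns_s <- sum(s == 1L); nr_s <- sum(s == 0L)
  ns_t <- sum(t == 1L); nr_t <- sum(t == 0L)
  if (min(ns_s, nr_s, ns_t, nr_t) == 0L)
    stop("all four class counts must be positive: the odds-ratio cutoff ",
         "adjustment requires responders and non-responders in both domains")
  (ns_s / nr_s) / (ns_t / nr_t)
}

#' Adjusted prediction-probability cutoff r/(r+1)
#'
#' When the responder odds differ between domains by a factor `r`, a
#' source-trained probability applied to target samples should be
#' thresholded at `r/(1+r)` instead of 0.5: probabilities are overestimated
#' for `r > 1` and underestimated for `r < 1`, and the adjusted cutoff
#' compensates exactly under the domain-invariance condition. The value is
#' returned at full precision (round only for display); it is strictly
#' increasing in `r` and equals 0.5 iff `r = 1`.
#'
#' @param r positive odds ratio, see [oddsRatio()].
#' @return cutoff in (0, 1).
#' @examples
#' adjustedCutoff(1)                    # 0.5
#' round(adjustedCutoff(0.0478), 2)     # 0.05
#' @export
adjustedCutoff <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r <= 0)
    stop("'r' must be a single positive finite number")
  r / (1 + r)
}

#' Build a CutoffAdjustment from two domains' labels
#'
#' Convenience constructor combining [oddsRatio()] and [adjustedCutoff()].
#' The target responder proportion is taken from the supplied target labels
#' (the test data themselves); pass synthetic counts to use an external
#' prior instead.
#'
#' @inheritParams oddsRatio
#' @return a [CutoffAdjustment-class].
#' @export
cutoffAdjustment <- function(sourceLabels, targetLabels) {
  lab <- function(x) if (is(x, "DomainDataset")) responseLabels(x) else x
  s <- as.integer(lab(sourceLabels)); t <- as.integer(lab(targetLabels))
  r <- oddsRatio(s, t)
  new("CutoffAdjustment",
      nsSource = sum(s == 1L), nrSource = sum(s == 0L),
      nsTarget = sum(t == 1L), nrTarget = sum(t == 0L),
      r = r, cutoff = adjustedCutoff(r))
}

#' Classify probability scores at a cutoff
#'
#' Labels a sample sensitive (1) iff its score strictly exceeds the cutoff;
#' a score exactly at the cutoff is classed 0, keeping the conventional
#' behaviour at 0.5.
#'
#' @param scores numeric vector of probabilities in `[0, 1]`.
#' @param cutoff single value strictly inside (0, 1); typically
#'   [adjustedCutoff()] output or 0.5.
#' @return integer 0/1 vector.
#' @export
classifyWithCutoff <- function(scores, cutoff) {
  if (!is.numeric(cutoff) || length(cutoff) != 1L ||
      cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must be a single value in (0, 1)")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("'scores' must be probabilities in [0, 1]")
  out <- as.integer(scores > cutoff)
  names(out) <- names(scores)
  out
}
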