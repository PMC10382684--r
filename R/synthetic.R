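#' Configuration for the two-domain expression simulator
#'
#' Defines a ground-truthed pair of source (cell-line-like) and target
#' (tumour-like) datasets with three gene roles:
#'
#' * *invariant informative* genes carry a class-mean shift of
#'   `effect_size` standard deviations (signs alternating over genes) with
#'   the same conditional law given the label in both domains — the genes
#'   the domain-adaptation filter should keep;
#' * *invariant null* genes are pure noise in both domains;
#' * *shifted* genes violate domain invariance: in the source they carry a
#'   spurious class effect of `spurious_effect` s.d. (default
#'   `effect_size`, so they look exactly as informative as the true
#'   markers), while in the target their mean is offset by `shift_size`
#'   s.d. and carries no class signal. These are the negative-transfer
#'   genes the filter should reject.
#'
#' Responder labels are Bernoulli with per-domain proportions `pi_source`
#' and `pi_target`, so the implied domain odds ratio
#' `r = (pi_s/(1-pi_s)) / (pi_t/(1-pi_t))` is directly controllable.
#'
#' @param n_source,n_target samples per domain.
#' @param pi_source,pi_target responder proportions in (0, 1).
#' @param n_invariant_informative,n_invariant_null,n_shifted gene counts.
#' @param effect_size class mean shift of informative genes, in s.d. units.
#' @param spurious_effect source-only class effect of shifted genes, in
#'   s.d. units; 0 makes shifted genes plain nuisance offsets.
#' @param shift_size target-domain mean offset of shifted genes (s.d. units).
#' @param var_inflation multiplies the target s.d. of shifted genes.
#' @param noise_sd residual standard deviation of every gene.
#' @param heavy_tails use scaled t(3) noise instead of Gaussian, to stress
#'   the KS filter.
#' @param seed integer seed; generation is deterministic given the config.
#' @return a validated list of class `syntheticConfig`.
#' @seealso [generateDomainPair()]
#' @export
syntheticConfig <- function(n_source = 200L, n_target = 200L,
                            pi_source = 0.5, pi_target = 0.5,
                            n_invariant_informative = 50L,
                            n_invariant_null = 100L,
                            n_shifted = 500L,
                            effect_size = 1, spurious_effect = effect_size,
                            shift_size = 3, var_inflation = 1,
                            noise_sd = 1, heavy_tails = FALSE, seed = 1L) {
  stopifnot(n_source >= 2L, n_target >= 2L)
  if (pi_source <= 0 || pi_source >= 1 || pi_target <= 0 || pi_target >= 1)
    stop("responder proportions must lie strictly inside (0, 1)")
  counts <- c(n_invariant_informative, n_invariant_null, n_shifted)
  if (any(counts < 0L) || sum(counts) < 1L)
    stop("gene counts must be non-negative with a positive total")
  if (noise_sd <= 0) stop("'noise_sd' must be positive")
  structure(list(n_source = as.integer(n_source),
                 n_target = as.integer(n_target),
                 pi_source = pi_source, pi_target = pi_target,
                 n_invariant_informative = as.integer(n_invariant_informative),
                 n_invariant_null = as.integer(n_invariant_null),
                 n_shifted = as.integer(n_shifted),
                 effect_size = effect_size,
                 spurious_effect = spurious_effect,
                 shift_size = shift_size, var_inflation = var_inflation,
                 noise_sd = noise_sd, heavy_tails = isTRUE(heavy_tails),
                 seed = as.integer(seed)),
            class = "syntheticConfig")
}

#' Generate a ground-truthed source/target dataset pair
#'
#' Draws the two domains described by a [syntheticConfig()]: Bernoulli
#' labels per domain (re-drawn until both classes are present, so every
#' downstream operation is well defined), class-conditionally Gaussian
#' (optionally t(3)) expression values per gene role, and a ground-truth
#' record of every gene's role, its class effect, and the implied odds
#' ratio. Deterministic for a fixed config.
#'
#' @param config a [syntheticConfig()].
#' @return list with `source` and `target` ([DomainDataset-class]) and
#'   `truth` (list: `roles` named character vector, `true_beta` named
#'   numeric vector of class effects, `r_true`, `cutoff_true`).
#' @examples
#' sim <- generateDomainPair(syntheticConfig(n_source = 50, n_target = 50,
#'   n_invariant_informative = 5, n_invariant_null = 5, n_shifted = 5))
#' table(sim$truth$roles)
#' @export
generateDomainPair <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "syntheticConfig"))
  cf <- config
  nGenes <- cf$n_invariant_informative + cf$n_invariant_null + cf$n_shifted
  geneIds <- sprintf("G%04d", seq_len(nGenes))
  roles <- rep(c("invariant_informative", "invariant_null", "shifted"),
               c(cf$n_invariant_informative, cf$n_invariant_null,
                 cf$n_shifted))
  names(roles) <- geneIds
  ## alternating signs avoid an all-positive degenerate logit
  sgn <- function(k) if (k == 0L) numeric(0) else rep_len(c(1, -1), k)
  beta <- numeric(nGenes)
  beta[roles == "invariant_informative"] <-
    cf$effect_size * sgn(cf$n_invariant_informative)
  spur <- numeric(nGenes)
  spur[roles == "shifted"] <- cf$spurious_effect * sgn(cf$n_shifted)
  names(beta) <- geneIds

  out <- withLocalSeed(cf$seed, {
    drawLabels <- function(n, pi) {
      repeat {
        y <- stats::rbinom(n, 1L, pi)
        if (any(y == 1L) && any(y == 0L)) return(y)
      }
    }
    noise <- function(nGenes, nSamp) {
      if (cf$heavy_tails)
        matrix(stats::rt(nGenes * nSamp, df = 3) / sqrt(3), nGenes, nSamp)
      else matrix(stats::rnorm(nGenes * nSamp), nGenes, nSamp)
    }
    ys <- drawLabels(cf$n_source, cf$pi_source)
    yt <- drawLabels(cf$n_target, cf$pi_target)
    ## source: true effects plus spurious source-only effects of shifted genes
    meanS <- outer(beta + spur, as.numeric(ys))
    xs <- meanS + cf$noise_sd * noise(nGenes, cf$n_source)
    ## target: true effects only; shifted genes offset and class-free
    meanT <- outer(beta, as.numeric(yt))
    meanT[roles == "shifted", ] <- cf$shift_size * cf$noise_sd
    sdT <- rep(cf$noise_sd, nGenes)
    sdT[roles == "shifted"] <- cf$noise_sd * cf$var_inflation
    xt <- meanT + sdT * noise(nGenes, cf$n_target)
    list(xs = xs, ys = ys, xt = xt, yt = yt)
  })
  dimnames(out$xs) <- list(geneIds, sprintf("CL%04d", seq_len(cf$n_source)))
  dimnames(out$xt) <- list(geneIds, sprintf("PT%04d", seq_len(cf$n_target)))
  rTrue <- (cf$pi_source / (1 - cf$pi_source)) /
    (cf$pi_target / (1 - cf$pi_target))
  list(source = DomainDataset(out$xs, out$ys, domain = "source",
                              drug = "simulated"),
       target = DomainDataset(out$xt, out$yt, domain = "target",
                              drug = "simulated"),
       truth = list(roles = roles, true_beta = beta, r_true = rTrue,
                    cutoff_true = rTrue / (1 + rTrue)))
}
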