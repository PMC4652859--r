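# Shannon entropy, mutual information, and symmetric uncertainty computed
# from exact enumerated distributions.  Entropies are in nats unless another
# base is requested; symmetric uncertainty is base-invariant.

#' Shannon entropy of a probability table
#'
#' `-sum p log(p)` with the convention `0 log 0 = 0`.
#'
#' @param p numeric probabilities (must be nonnegative and sum to 1 within
#'   1e-8), or a marginal table from [marginal()] (its `p` column is used).
#' @param base logarithm base; default `exp(1)` for nats.
#' @return scalar entropy.
#' @export
entropy <- function(p, base = exp(1)) {
  if (is.data.frame(p)) p <- p$p
  if (any(p < -1e-12)) .stopf("probabilities must be nonnegative")
  p <- pmax(p, 0)
  if (abs(sum(p) - 1) > 1e-8)
    .stopf("probability table is unnormalized (sum = %.10g)", sum(p))
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(base)
}

.component_entropy <- function(dist, comp, base = exp(1)) {
  entropy(marginal(dist, comp)$p, base)
}

#' Mutual information between two components
#'
#' `I(i, j) = H(i) + H(j) - H(i, j)` from the exact marginals; tiny negative
#' rounding (within 1e-12) is clipped to zero.
#'
#' @param dist an `aim_dist`.
#' @param i,j two distinct component names.
#' @param base logarithm base; default nats.
#' @return scalar mutual information.
#' @export
mutual_information <- function(dist, i, j, base = exp(1)) {
  stopifnot(inherits(dist, "aim_dist"))
  if (identical(i, j)) .stopf("mutual information needs two distinct components")
  mi <- .component_entropy(dist, i, base) + .component_entropy(dist, j, base) -
    entropy(marginal(dist, c(i, j))$p, base)
  if (mi < 0 && mi > -1e-12) mi <- 0
  mi
}

#' Symmetric uncertainty between two components
#'
#' Mutual information normalised by the mean marginal entropy:
#' `SU = 2 I(i, j) / (H(i) + H(j))`, dimensionless in `[0, 1]` and invariant
#' to the logarithm base.
#'
#' @inheritParams mutual_information
#' @return scalar symmetric uncertainty.
#' @export
symmetric_uncertainty <- function(dist, i, j) {
  stopifnot(inherits(dist, "aim_dist"))
  hi <- .component_entropy(dist, i)
  hj <- .component_entropy(dist, j)
  if (hi + hj <= 0)
    .stopf("both components are deterministic; symmetric uncertainty is undefined")
  2 * mutual_information(dist, i, j) / (hi + hj)
}

#' Pairwise information summary for two components
#'
#' @inheritParams mutual_information
#' @return a `pair_info` list with the marginal entropies `H_i`, `H_j`, the
#'   mutual information `I_ij` (all in the requested base, recorded in
#'   `base`), and the base-invariant symmetric uncertainty `SU_ij`.
#' @export
pair_info <- function(dist, i, j, base = exp(1)) {
  structure(list(i = i, j = j,
                 H_i = .component_entropy(dist, i, base),
                 H_j = .component_entropy(dist, j, base),
                 I_ij = mutual_information(dist, i, j, base),
                 SU_ij = symmetric_uncertainty(dist, i, j),
                 base = base),
            class = "pair_info")
}

#' @export
print.pair_info <- function(x, ...) {
  unit <- if (isTRUE(all.equal(x$base, exp(1)))) "nats"
          else if (isTRUE(all.equal(x$base, 2))) "bits"
          else sprintf("log base %g", x$base)
  cat(sprintf("Pair information %s / %s (%s)\n", x$i, x$j, unit))
  cat(sprintf("  H_i = %.6g, H_j = %.6g, I = %.6g, SU = %.6g\n",
              x$H_i, x$H_j, x$I_ij, x$SU_ij))
  invisible(x)
}
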