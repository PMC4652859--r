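# Marginal and conditional tables over exact enumerated distributions.

# Interpret a state value for one component: -1/+1, 0/1, "down"/"up", or the
# component's own state labels.
.as_spin <- function(value, comp_row) {
  if (is.numeric(value)) {
    if (value %in% c(-1, 1)) return(value)
    .stopf("spin values must be -1 or +1 (got %g)", value)
  }
  v <- as.character(value)
  if (v %in% c("down", comp_row$down_label)) return(-1)
  if (v %in% c("up", comp_row$up_label)) return(1)
  .stopf("unknown state '%s' for component '%s'", v, comp_row$name)
}

# logical mask of configurations matching a named assignment
.assignment_mask <- function(dist, given) {
  mask <- rep(TRUE, nrow(dist$spins))
  if (is.null(given) || length(given) == 0L) return(mask)
  if (is.null(names(given))) .stopf("assignments must be named by component")
  idx <- .comp_index(dist, names(given))
  for (k in seq_along(idx)) {
    s <- .as_spin(given[[k]], dist$components[idx[k], ])
    mask <- mask & dist$spins[, idx[k]] == s
  }
  mask
}

# probability table over a component subset from masked joint probabilities
.subset_table <- function(dist, subset, p) {
  idx <- .comp_index(dist, subset)
  k <- length(idx)
  # rows of .spin_grid(k) are exactly the binary codes 0 .. 2^k - 1 with the
  # first component as the least significant bit
  G <- .spin_grid(k)
  code <- as.vector(((dist$spins[, idx, drop = FALSE] + 1) / 2) %*%
                      2^(seq_len(k) - 1L))
  pm <- vapply(seq_len(2^k) - 1L, function(cd) sum(p[code == cd]), numeric(1))
  out <- as.data.frame(G)
  names(out) <- subset
  out$p <- pm
  attr(out, "beta") <- dist$beta
  class(out) <- c("aim_marginal", "data.frame")
  out
}

#' Marginal distribution over a subset of components
#'
#' Sums the exact joint probabilities over all components outside `subset`.
#'
#' @param dist an `aim_dist` from [enumerate_distribution()].
#' @param subset non-empty character vector of component names.
#' @return data frame with one spin column (-1/+1) per requested component and
#'   a probability column `p`; rows cover all `2^k` joint states.
#' @export
marginal <- function(dist, subset) {
  stopifnot(inherits(dist, "aim_dist"))
  if (length(subset) == 0L) .stopf("subset must name at least one component")
  .subset_table(dist, subset, dist$p)
}

#' Conditional distribution over a subset of components
#'
#' Restricts the joint distribution to the configurations matching `given`
#' (a named assignment of other components), renormalises, and marginalises
#' onto `subset`.  An empty `given` reduces to [marginal()].
#'
#' @inheritParams marginal
#' @param given named vector/list of states for the conditioning components
#'   (values -1/+1, "down"/"up", or the components' own labels); must be
#'   disjoint from `subset`.
#' @return data frame as in [marginal()]; probabilities sum to 1.
#' @export
conditional <- function(dist, subset, given = NULL) {
  stopifnot(inherits(dist, "aim_dist"))
  if (length(given) && length(intersect(subset, names(given))))
    .stopf("conditioning components must be disjoint from the subset")
  mask <- .assignment_mask(dist, given)
  pc <- sum(dist$p[mask])
  if (pc <= 0)
    .stopf("conditioning event has zero probability")
  p <- dist$p
  p[!mask] <- 0
  .subset_table(dist, subset, p / pc)
}

# the four ligand/site marginal cells p(L = sl, A = sa), optionally within a
# conditioning mask; returned as named vector c(uu, ud, du, dd)
.pair_cells <- function(dist, a, b, mask = NULL) {
  ia <- .comp_index(dist, a); ib <- .comp_index(dist, b)
  sa <- dist$spins[, ia]; sb <- dist$spins[, ib]
  p <- dist$p
  if (!is.null(mask)) p <- p * mask
  c(uu = sum(p[sa == 1 & sb == 1]),
    ud = sum(p[sa == 1 & sb == -1]),
    du = sum(p[sa == -1 & sb == 1]),
    dd = sum(p[sa == -1 & sb == -1]))
}
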