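# Internal numerical helpers.  Everything downstream of enumeration works in
# the log domain so that energies up to several hundred 1/beta units stay
# finite.

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(cosh(x)), stable for large |x|
.log_cosh <- function(x) {
  ax <- abs(x)
  ax + log1p(exp(-2 * ax)) - log(2)
}

# elementwise log(exp(la) + exp(lb))
.log_add <- function(la, lb) {
  m <- pmax(la, lb)
  m + log1p(exp(-abs(la - lb)))
}

# log of the channel factor: log[(cosh(2b(u1+u2)) + cosh(2b uc)) /
#                                (cosh(2b(u1-u2)) + cosh(2b uc))]
# Vectorised over all arguments.
.log_channel_factor <- function(u_lc, u_ca, u_conf_c, beta) {
  lc_conf <- .log_cosh(2 * beta * u_conf_c)
  .log_add(.log_cosh(2 * beta * (u_lc + u_ca)), lc_conf) -
    .log_add(.log_cosh(2 * beta * (u_lc - u_ca)), lc_conf)
}

# All 2^n spin configurations as a numeric matrix of -1/+1 rows; the first
# component varies fastest.  This ordering is the package-wide convention.
.spin_grid <- function(n) {
  g <- as.matrix(expand.grid(rep(list(c(-1, 1)), n), KEEP.OUT.ATTRS = FALSE))
  dimnames(g) <- NULL
  storage.mode(g) <- "double"
  g
}

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

.check_finite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("%s must be finite", what)
  invisible(x)
}
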