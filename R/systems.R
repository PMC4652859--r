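#' Declare the components of a two-state system
#'
#' Builds the component table shared by [ising_system()] and
#' [general_system()].  Every component has exactly two states; throughout the
#' package the down state (spin -1) is the off/unbound state and the up state
#' (spin +1) is the on/bound state.
#'
#' @param names character vector of unique component names.
#' @param roles optional character vector (recycled or named by component) of
#'   roles among `"ligand"`, `"site"`, `"channel"`, `"other"`.
#' @param down_label,up_label state labels, e.g. `"off"`/`"on"` or
#'   `"unbound"`/`"bound"`; recycled across components.
#' @return a data frame with columns `name`, `down_label`, `up_label`, `role`.
#' @export
aim_components <- function(names, roles = "other",
                           down_label = "down", up_label = "up") {
  if (is.data.frame(names)) {
    df <- names
    if (!all(c("name", "down_label", "up_label", "role") %in% names(df)))
      .stopf("component data frame needs columns name, down_label, up_label, role")
    names <- df$name
  } else {
    if (!is.character(names) || length(names) < 1L)
      .stopf("component names must be a non-empty character vector")
    if (!is.null(names(roles))) {
      r <- rep("other", length(names))
      names(r) <- names
      bad <- setdiff(names(roles), names)
      if (length(bad))
        .stopf("role given for unknown component '%s'", bad[1L])
      r[names(roles)] <- roles
      roles <- r
    }
    df <- data.frame(name = names,
                     down_label = rep_len(down_label, length(names)),
                     up_label = rep_len(up_label, length(names)),
                     role = rep_len(roles, length(names)),
                     stringsAsFactors = FALSE)
  }
  if (anyDuplicated(df$name))
    .stopf("component names must be unique (duplicated: '%s')",
           df$name[duplicated(df$name)][1L])
  ok <- df$role %in% c("ligand", "site", "channel", "other")
  if (!all(ok)) .stopf("unknown role '%s'", df$role[!ok][1L])
  rownames(df) <- NULL
  df
}

# normalise a couplings argument (NULL, named vector "A:B", or data frame
# i/j/value) into a dense symmetric matrix with zero diagonal
.parse_couplings <- function(couplings, comp_names) {
  n <- length(comp_names)
  J <- matrix(0, n, n, dimnames = list(comp_names, comp_names))
  if (is.null(couplings) || length(couplings) == 0L) return(J)
  if (is.matrix(couplings)) {
    if (!identical(dim(couplings), c(n, n)))
      .stopf("coupling matrix must be %d x %d", n, n)
    if (max(abs(couplings - t(couplings))) > 0)
      .stopf("coupling matrix must be symmetric")
    if (any(diag(couplings) != 0)) .stopf("self-couplings are not allowed")
    J[] <- couplings
    return(J)
  }
  if (is.data.frame(couplings)) {
    pairs <- cbind(as.character(couplings[[1L]]), as.character(couplings[[2L]]))
    vals <- couplings[[3L]]
  } else {
    if (is.null(names(couplings)))
      .stopf("couplings must be named like 'A:B' or given as a data frame")
    pairs <- do.call(rbind, strsplit(names(couplings), ":", fixed = TRUE))
    if (ncol(pairs) != 2L) .stopf("coupling names must be 'i:j' pairs")
    vals <- as.numeric(couplings)
  }
  for (k in seq_len(nrow(pairs))) {
    i <- pairs[k, 1L]; j <- pairs[k, 2L]
    if (!i %in% comp_names) .stopf("coupling refers to unknown component '%s'", i)
    if (!j %in% comp_names) .stopf("coupling refers to unknown component '%s'", j)
    if (i == j) .stopf("self-coupling on '%s' is not allowed", i)
    J[i, j] <- J[i, j] + vals[k]
    J[j, i] <- J[i, j]
  }
  J
}

#' Construct an Ising system
#'
#' An Ising system assigns each two-state component a scalar conformational
#' energy `u_conf` (the up state has energy `+u_conf`, the down state
#' `-u_conf`) and each unordered pair a scalar coupling `u_int` contributing
#' `u_int * s_i * s_j` to the total energy.  All energies are in units of
#' 1/beta; absent pairs have coupling 0.
#'
#' @param components character vector of names, or a component data frame from
#'   [aim_components()].
#' @param conf_energy numeric conformational energies, recycled to the number
#'   of components; may be named by component.
#' @param couplings pairwise couplings: a named numeric vector with names
#'   `"i:j"`, a data frame with columns (i, j, value), or a full symmetric
#'   matrix.
#' @param beta inverse temperature (> 0); defaults to 1 so that energies are
#'   read directly in thermal units.
#' @param roles,down_label,up_label passed to [aim_components()] when
#'   `components` is a character vector.
#' @return an object of class `aim_ising`.
#' @examples
#' sys <- ising_system(c("L", "R"), conf_energy = 0, couplings = c("L:R" = -1))
#' allosteric_efficacy(sys, "L", "R")
#' @export
ising_system <- function(components, conf_energy = 0, couplings = NULL,
                         beta = 1, roles = "other",
                         down_label = "down", up_label = "up") {
  comps <- aim_components(components, roles, down_label, up_label)
  n <- nrow(comps)
  if (!is.null(names(conf_energy))) {
    ce <- rep(0, n); names(ce) <- comps$name
    bad <- setdiff(names(conf_energy), comps$name)
    if (length(bad)) .stopf("conf_energy for unknown component '%s'", bad[1L])
    ce[names(conf_energy)] <- conf_energy
    conf_energy <- ce
  } else {
    conf_energy <- rep_len(as.numeric(conf_energy), n)
    names(conf_energy) <- comps$name
  }
  .check_finite(conf_energy, "conformational energies")
  J <- .parse_couplings(couplings, comps$name)
  .check_finite(J, "couplings")
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    .stopf("beta must be a single positive number")
  structure(list(components = comps, conf = conf_energy, J = J, beta = beta),
            class = c("aim_ising", "aim_system"))
}

#' Construct a general (non-Ising) two-state system
#'
#' The general model assigns each component two independent conformational
#' energies, one per state, and each interacting pair a full 2 x 2 interaction
#' table.  It is the superset of the Ising model obtained when the Ising
#' energy symmetries are not imposed.
#'
#' @param components as in [ising_system()].
#' @param conf_energy_table numeric matrix with one row per component and
#'   columns `down`, `up` (rows may be named by component).
#' @param interaction_tables named list `"i:j"` of 2 x 2 matrices; rows index
#'   the state of `i` (down, up), columns the state of `j`.
#' @param beta inverse temperature (> 0).
#' @param roles,down_label,up_label passed to [aim_components()].
#' @return an object of class `aim_general`.
#' @export
general_system <- function(components, conf_energy_table,
                           interaction_tables = NULL, beta = 1,
                           roles = "other",
                           down_label = "down", up_label = "up") {
  comps <- aim_components(components, roles, down_label, up_label)
  n <- nrow(comps)
  ct <- as.matrix(conf_energy_table)
  if (nrow(ct) != n || ncol(ct) != 2L)
    .stopf("conf_energy_table must be %d x 2 (columns down, up)", n)
  if (!is.null(rownames(ct)) && !identical(rownames(ct), comps$name)) {
    if (!setequal(rownames(ct), comps$name))
      .stopf("conf_energy_table rows do not match component names")
    ct <- ct[comps$name, , drop = FALSE]
  }
  dimnames(ct) <- list(comps$name, c("down", "up"))
  .check_finite(ct, "conformational energy table")

  tabs <- list()
  if (!is.null(interaction_tables) && length(interaction_tables)) {
    if (is.null(names(interaction_tables)))
      .stopf("interaction_tables must be a named list with names 'i:j'")
    for (nm in names(interaction_tables)) {
      pr <- strsplit(nm, ":", fixed = TRUE)[[1L]]
      if (length(pr) != 2L) .stopf("interaction name '%s' is not 'i:j'", nm)
      i <- match(pr[1L], comps$name); j <- match(pr[2L], comps$name)
      if (is.na(i)) .stopf("interaction refers to unknown component '%s'", pr[1L])
      if (is.na(j)) .stopf("interaction refers to unknown component '%s'", pr[2L])
      if (i == j) .stopf("self-interaction on '%s' is not allowed", pr[1L])
      tb <- as.matrix(interaction_tables[[nm]])
      if (!identical(dim(tb), c(2L, 2L)))
        .stopf("interaction table '%s' must be 2 x 2", nm)
      .check_finite(tb, sprintf("interaction table '%s'", nm))
      if (j < i) { tb <- t(tb); tmp <- i; i <- j; j <- tmp }  # canonical order
      key <- paste(comps$name[i], comps$name[j], sep = ":")
      dimnames(tb) <- list(c("down", "up"), c("down", "up"))
      if (!is.null(tabs[[key]])) .stopf("duplicate interaction '%s'", key)
      tabs[[key]] <- tb
    }
  }
  if (!is.numeric(beta) || length(beta) != 1L || !is.finite(beta) || beta <= 0)
    .stopf("beta must be a single positive number")
  structure(list(components = comps, conf_table = ct, int_tables = tabs,
                 beta = beta),
            class = c("aim_general", "aim_system"))
}

#' @export
print.aim_ising <- function(x, ...) {
  cat(sprintf("Ising system: %d components, beta = %g\n", nrow(x$components),
              x$beta))
  cat("  components:", paste(x$components$name, collapse = ", "), "\n")
  e <- which(upper.tri(x$J) & x$J != 0, arr.ind = TRUE)
  if (nrow(e)) {
    lab <- apply(e, 1L, function(k)
      sprintf("%s:%s = %g", x$components$name[k[1L]], x$components$name[k[2L]],
              x$J[k[1L], k[2L]]))
    cat("  couplings:", paste(lab, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.aim_general <- function(x, ...) {
  cat(sprintf("General two-state system: %d components, %d interaction tables, beta = %g\n",
              nrow(x$components), length(x$int_tables), x$beta))
  cat("  components:", paste(x$components$name, collapse = ", "), "\n")
  invisible(x)
}

#' Component names of a system or distribution
#' @param x an `aim_system` or `aim_dist` object.
#' @return character vector of component names.
#' @export
component_names <- function(x) x$components$name

#' Number of components
#' @param x an `aim_system` or `aim_dist` object.
#' @export
n_components <- function(x) nrow(x$components)

.comp_index <- function(x, comp) {
  i <- match(comp, x$components$name)
  if (anyNA(i)) .stopf("unknown component '%s'", comp[which(is.na(i))[1L]])
  i
}

#' Potential energy of one configuration
#'
#' For an Ising system the energy is `sum_i u_conf_i s_i +
#' sum_{i<j} u_int_ij s_i s_j`; for a general system it is the sum of the
#' per-state conformational entries plus the selected interaction-table cells.
#'
#' @param system an `aim_ising` or `aim_general` object.
#' @param config numeric vector of spins (-1/+1), one per component.
#' @return scalar energy in 1/beta units.
#' @export
state_energy <- function(system, config) {
  n <- n_components(system)
  if (length(config) != n)
    .stopf("configuration has %d spins but the system has %d components",
           length(config), n)
  if (!all(config %in% c(-1, 1))) .stopf("spins must be -1 or +1")
  drop(.config_energies(system, matrix(config, nrow = 1L)))
}

# vectorised energy over rows of a spin matrix
.config_energies <- function(system, S) UseMethod(".config_energies")

.config_energies.aim_ising <- function(system, S) {
  as.vector(S %*% system$conf) + 0.5 * rowSums((S %*% system$J) * S)
}

.config_energies.aim_general <- function(system, S) {
  idx <- (S + 3) / 2  # 1 = down, 2 = up
  n <- ncol(S)
  U <- numeric(nrow(S))
  for (i in seq_len(n)) U <- U + system$conf_table[i, idx[, i]]
  nm <- component_names(system)
  for (key in names(system$int_tables)) {
    pr <- strsplit(key, ":", fixed = TRUE)[[1L]]
    i <- match(pr[1L], nm); j <- match(pr[2L], nm)
    tb <- system$int_tables[[key]]
    U <- U + tb[cbind(idx[, i], idx[, j])]
  }
  U
}

#' Express an Ising system as a general two-state system
#'
#' Expands the scalar Ising parameters into per-state tables obeying the Ising
#' symmetries: `U_conf(up) = +u_conf`, `U_conf(down) = -u_conf`;
#' `U_int(up,up) = U_int(down,down) = +u_int` and the mixed cells `-u_int`.
#' The enumerated distribution of the result is identical to the source's.
#'
#' @param system an `aim_ising` object.
#' @return an `aim_general` object.
#' @export
ising_to_general <- function(system) {
  stopifnot(inherits(system, "aim_ising"))
  ct <- cbind(down = -system$conf, up = system$conf)
  nm <- component_names(system)
  tabs <- list()
  e <- which(upper.tri(system$J) & system$J != 0, arr.ind = TRUE)
  for (k in seq_len(nrow(e))) {
    u <- system$J[e[k, 1L], e[k, 2L]]
    tabs[[paste(nm[e[k, 1L]], nm[e[k, 2L]], sep = ":")]] <-
      matrix(c(u, -u, -u, u), 2L, 2L)
  }
  general_system(system$components, ct, tabs, beta = system$beta)
}

#' Fold a physical (zero-when-unbound) ligand into Ising form
#'
#' Under the physical convention a ligand interacts only in its bound (up)
#' state: the pair term is `u_int (s_L + 1)/2 * s_j`.  Expanding that product
#' shows the same distribution is produced by an Ising system in which each
#' neighbour `j` of the ligand has conformational energy
#' `u_conf_j + u_int/2` and coupling `u_int/2`.  This function performs that
#' reparameterisation, treating the couplings of `ligand` in `system` as the
#' physical bound-state interaction energies.
#'
#' @param system an `aim_ising` object whose ligand couplings are physical
#'   bound-state interactions.
#' @param ligand name of the ligand component.
#' @return an `aim_ising` object with the equivalent symmetric parameters.
#' @export
ligandize <- function(system, ligand) {
  stopifnot(inherits(system, "aim_ising"))
  li <- .comp_index(system, ligand)
  out <- system
  for (j in seq_len(n_components(system))) {
    if (j == li) next
    u <- system$J[li, j]
    if (u == 0) next
    out$conf[j] <- out$conf[j] + u / 2
    out$J[li, j] <- u / 2
    out$J[j, li] <- u / 2
  }
  out
}

#' Zero all interactions involving a ligand's unbound state
#'
#' Applies the physical ligand convention to a general system: every
#' interaction-table cell in which `ligand` is in its down (unbound) state is
#' set to 0.
#'
#' @param system an `aim_general` object.
#' @param ligand name of the ligand component.
#' @return the modified `aim_general` object.
#' @export
zero_unbound_ligand <- function(system, ligand) {
  stopifnot(inherits(system, "aim_general"))
  li <- .comp_index(system, ligand)
  nm <- component_names(system)
  for (key in names(system$int_tables)) {
    pr <- strsplit(key, ":", fixed = TRUE)[[1L]]
    if (pr[1L] == nm[li]) system$int_tables[[key]]["down", ] <- 0
    if (pr[2L] == nm[li]) system$int_tables[[key]][, "down"] <- 0
  }
  system
}

#' Exact Boltzmann distribution by full state enumeration
#'
#' Enumerates all `2^n` configurations, accumulates Boltzmann weights in the
#' log domain, and returns exact probabilities together with the log partition
#' function.  Probabilities sum to 1 within 1e-12.
#'
#' @param system an `aim_ising` or `aim_general` object.
#' @param cap refuse systems with more components than this (default 22,
#'   about 4 million states); guards against accidental exponential blow-up.
#' @return an object of class `aim_dist` with elements `components`, `spins`
#'   (a `2^n` x `n` matrix of -1/+1 rows, first component varying fastest),
#'   `p`, `log_p`, `log_z`, and `beta`.
#' @export
enumerate_distribution <- function(system,
                                   cap = getOption("aim.enum_cap", 22L)) {
  stopifnot(inherits(system, "aim_system"))
  n <- n_components(system)
  if (n > cap)
    .stopf("system has %d components; exact enumeration is capped at %d", n, cap)
  S <- .spin_grid(n)
  lw <- -system$beta * .config_energies(system, S)
  lz <- .logsumexp(lw)
  lp <- lw - lz
  structure(list(components = system$components, spins = S, p = exp(lp),
                 log_p = lp, log_z = lz, beta = system$beta),
            class = "aim_dist")
}

#' @export
print.aim_dist <- function(x, ...) {
  cat(sprintf("Exact distribution over %d components (%d states), log Z = %.6g\n",
              nrow(x$components), length(x$p), x$log_z))
  invisible(x)
}
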