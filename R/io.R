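# Model-file reading/writing and result serialisation.  Models travel as
# schema-checked JSON (energies stored in 1/beta units with beta alongside);
# tables travel as TSV with a commented metadata header.

.json_err <- function(path_str, fmt, ...) {
  stop(sprintf("model validation error at %s: %s", path_str,
               sprintf(fmt, ...)), call. = FALSE)
}

.check_fields <- function(obj, allowed, where) {
  extra <- setdiff(names(obj), allowed)
  if (length(extra))
    .json_err(paste0(where, ".", extra[1L]), "unknown field")
}

#' Read a model file
#'
#' Parses and validates a JSON model description and returns the
#' corresponding system.  The format is
#' `{"beta": number, "components": [{"name", "down_label", "up_label",
#' "role", "conf_energy" | "conf_energy_table"}, ...],
#' "interactions": [{"pair": [name, name], "value" | "table"}, ...]}`:
#' scalar `conf_energy`/`value` entries declare an Ising system, two-entry
#' `conf_energy_table` (down, up) and 2 x 2 `table` rows-by-first-component
#' entries declare a general system.  Unknown fields and unknown component
#' names are rejected with the offending JSON path.
#'
#' @param path file path.
#' @return an `aim_ising` or `aim_general` system.
#' @export
read_model <- function(path) {
  if (!file.exists(path)) .stopf("model file '%s' does not exist", path)
  m <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  .check_fields(m, c("beta", "components", "interactions"), "$")
  if (is.null(m$components) || !length(m$components))
    .json_err("$.components", "at least one component is required")
  beta <- if (is.null(m$beta)) 1 else as.numeric(m$beta)

  is_general <- NULL
  names_ <- character(); down <- character(); up <- character()
  roles <- character(); conf_s <- numeric(); conf_t <- list()
  for (ci in seq_along(m$components)) {
    comp <- m$components[[ci]]
    where <- sprintf("$.components[%d]", ci)
    .check_fields(comp, c("name", "down_label", "up_label", "role",
                          "conf_energy", "conf_energy_table"), where)
    if (is.null(comp$name)) .json_err(where, "missing name")
    has_s <- !is.null(comp[["conf_energy", exact = TRUE]])
    has_t <- !is.null(comp[["conf_energy_table", exact = TRUE]])
    if (has_s == has_t)
      .json_err(where, "exactly one of conf_energy and conf_energy_table is required")
    kind <- has_t
    if (is.null(is_general)) is_general <- kind
    else if (!identical(is_general, kind))
      .json_err(where, "components mix scalar and per-state conformational energies")
    names_ <- c(names_, comp$name)
    down <- c(down, comp$down_label %||% "down")
    up <- c(up, comp$up_label %||% "up")
    roles <- c(roles, comp$role %||% "other")
    if (has_s) conf_s <- c(conf_s, as.numeric(comp$conf_energy))
    else {
      v <- as.numeric(unlist(comp$conf_energy_table))
      if (length(v) != 2L)
        .json_err(paste0(where, ".conf_energy_table"),
                  "expected two entries (down, up)")
      conf_t[[length(conf_t) + 1L]] <- v
    }
  }
  comps <- data.frame(name = names_, down_label = down, up_label = up,
                      role = roles, stringsAsFactors = FALSE)

  vals <- numeric(); val_names <- character(); tabs <- list()
  for (ii in seq_along(m$interactions)) {
    it <- m$interactions[[ii]]
    where <- sprintf("$.interactions[%d]", ii)
    .check_fields(it, c("pair", "value", "table"), where)
    pr <- unlist(it$pair)
    if (length(pr) != 2L) .json_err(paste0(where, ".pair"),
                                    "expected two component names")
    for (p in pr)
      if (!p %in% names_)
        .json_err(paste0(where, ".pair"), "unknown component '%s'", p)
    has_v <- !is.null(it$value); has_t <- !is.null(it$table)
    if (has_v == has_t)
      .json_err(where, "exactly one of value and table is required")
    if (has_t != is_general)
      .json_err(where, "interaction form does not match the component energy form")
    key <- paste(pr, collapse = ":")
    if (has_v) {
      vals <- c(vals, as.numeric(it$value)); val_names <- c(val_names, key)
    } else {
      tb <- matrix(as.numeric(unlist(it$table)), 2L, 2L, byrow = TRUE)
      tabs[[key]] <- tb
    }
  }

  if (is_general) {
    ct <- do.call(rbind, conf_t)
    general_system(comps, ct, tabs, beta = beta)
  } else {
    cp <- if (length(vals)) stats::setNames(vals, val_names) else NULL
    ising_system(comps, conf_energy = conf_s, couplings = cp, beta = beta)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model file
#'
#' Serialises a system to the canonical JSON model format (see
#' [read_model()]).  Writing and re-reading reproduces the system exactly.
#'
#' @param system an `aim_ising` or `aim_general` system.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_model <- function(system, path) {
  stopifnot(inherits(system, "aim_system"))
  comps <- lapply(seq_len(n_components(system)), function(i) {
    row <- system$components[i, ]
    c(list(name = row$name, down_label = row$down_label,
           up_label = row$up_label, role = row$role),
      if (inherits(system, "aim_ising"))
        list(conf_energy = unname(system$conf[i]))
      else
        list(conf_energy_table = unname(system$conf_table[i, ])))
  })
  if (inherits(system, "aim_ising")) {
    e <- which(upper.tri(system$J) & system$J != 0, arr.ind = TRUE)
    inter <- lapply(seq_len(nrow(e)), function(k) {
      i <- e[k, 1L]; j <- e[k, 2L]
      list(pair = component_names(system)[c(i, j)],
           value = system$J[i, j])
    })
  } else {
    inter <- lapply(names(system$int_tables), function(key) {
      tb <- system$int_tables[[key]]
      list(pair = strsplit(key, ":", fixed = TRUE)[[1L]],
           table = list(unname(tb[1L, ]), unname(tb[2L, ])))
    })
  }
  jsonlite::write_json(list(beta = system$beta, components = comps,
                            interactions = inter),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write a result table or report
#'
#' Writes either TSV (with a `#`-prefixed metadata header recording the
#' package version and any supplied fields such as seed, beta, and
#' tolerances; numbers at 12 significant digits) or JSON (metadata and data
#' at full precision).  Output is deterministic: the same inputs produce
#' byte-identical files.
#'
#' @param x a data frame, or a list/report coercible to one.
#' @param path output file path.
#' @param format `"tsv"` or `"json"`.
#' @param meta named list of metadata values for the header.
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path, format = c("tsv", "json"), meta = list()) {
  format <- match.arg(format)
  meta <- c(list(package = "aim",
                 version = as.character(utils::packageVersion("aim"))),
            meta)
  if (inherits(x, "efficacy_report") || inherits(x, "pair_info"))
    x <- as.data.frame(unclass(x)[!vapply(unclass(x), is.null, logical(1))])
  if (format == "json") {
    jsonlite::write_json(list(metadata = meta, data = x), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    return(invisible(path))
  }
  stopifnot(is.data.frame(x))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(meta))
    writeLines(sprintf("# %s: %s", nm, paste(meta[[nm]], collapse = ", ")),
               con)
  fmt <- vapply(x, is.numeric, logical(1))
  y <- x
  for (cc in which(fmt)) y[[cc]] <- sprintf("%.12g", x[[cc]])
  utils::write.table(y, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
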