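# Structured model-spec format: one YAML document with `metabolites`,
# `reactions` and `reference_state`. Infinite equilibrium constants are
# written as the YAML .inf scalar.

#' Write a network + reference state to a model-spec YAML file
#'
#' @param network a \linkS4class{MetabolicNetwork}.
#' @param ref a \linkS4class{ReferenceState}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelSpec <- function(network, ref, path) {
  spec <- list(
    metabolites = lapply(seq_len(nrow(network@metabolites)), function(i)
      list(id = network@metabolites$id[i],
           internal = network@metabolites$internal[i])),
    reactions = lapply(unname(network@reactions), function(rx)
      list(id = rx$id, stoichiometry = as.list(rx$stoich),
           reversible = rx$reversible, mechanism = rx$mechanism)),
    reference_state = list(
      concentrations = as.list(ref@concentrations),
      boundary_concentrations = as.list(ref@boundaryConcentrations),
      fluxes = as.list(ref@fluxes),
      keq = as.list(ref@keq),
      doubling_time_min = ref@doublingTime))
  yaml::write_yaml(spec, path, precision = 15L)
  invisible(path)
}

#' Read a model-spec YAML/JSON file
#'
#' @param path path to a file written by \code{\link{writeModelSpec}} (YAML;
#'   JSON is a subset of YAML and is accepted too).
#' @return list with elements \code{network} (\linkS4class{MetabolicNetwork})
#'   and \code{ref} (\linkS4class{ReferenceState}).
#' @export
readModelSpec <- function(path) {
  if (!file.exists(path)) stop("model spec file not found: ", path)
  spec <- yaml::read_yaml(path)
  mets <- data.frame(
    id = vapply(spec$metabolites, `[[`, character(1), "id"),
    internal = vapply(spec$metabolites, `[[`, logical(1), "internal"))
  rxns <- lapply(spec$reactions, function(rx)
    list(id = rx$id, stoich = unlist(rx$stoichiometry),
         reversible = isTRUE(rx$reversible),
         mechanism = if (is.null(rx$mechanism)) "convenience" else rx$mechanism))
  network <- MetabolicNetwork(mets, rxns)
  rs <- spec$reference_state
  ref <- ReferenceState(
    concentrations = unlist(rs$concentrations),
    boundaryConcentrations = if (length(rs$boundary_concentrations))
      unlist(rs$boundary_concentrations) else numeric(),
    fluxes = unlist(rs$fluxes),
    keq = vapply(rs$keq, function(x) if (is.character(x)) Inf else as.numeric(x),
                 numeric(1), USE.NAMES = TRUE),
    doublingTime = rs$doubling_time_min)
  names(ref@keq) <- names(rs$keq)
  list(network = network, ref = ref)
}

#' Write a ParameterTable as wide CSV
#'
#' One row per parameter set; columns \code{KM__<reaction>__<metabolite>},
#' \code{VMAX__<reaction>}, plus \code{label} when the table is labelled.
#'
#' @param table a \linkS4class{ParameterTable}.
#' @param path output CSV path.
#' @return \code{path}, invisibly.
#' @export
writeParameterTable <- function(table, path) {
  df <- as.data.frame(table@values)
  if (!all(is.na(table@label))) df$label <- table@label
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a ParameterTable from CSV
#'
#' @param path CSV path written by \code{\link{writeParameterTable}}.
#' @return a \linkS4class{ParameterTable}.
#' @export
readParameterTable <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- if ("label" %in% names(df)) as.integer(df$label) else
    rep(NA_integer_, nrow(df))
  df$label <- NULL
  ParameterTable(as.matrix(df), label = lab)
}

#' Count kinetic parameters in a deposited parameter-table manifest
#'
#' Accounting helper for externally deposited training tables: given the
#' column names of a wide parameter table, reports the total number of
#' kinetic parameters and the number of concentration-associated (Km)
#' features that remain after eliminating the Vmax scaling coefficients.
#'
#' @param columnNames character vector of parameter column names; Km columns
#'   are identified by a \code{KM} token, Vmax columns by a \code{VMAX}/
#'   \code{vmax} token (case-insensitive), any label column is ignored.
#' @return list with \code{total} and \code{kmFeatures}.
#' @export
countKineticParameters <- function(columnNames) {
  cols <- setdiff(columnNames, c("label", "Label"))
  isKm <- grepl("(^|_)k_?m(_|$)", cols, ignore.case = TRUE) |
    startsWith(cols, "KM__")
  list(total = length(cols), kmFeatures = sum(isKm))
}
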