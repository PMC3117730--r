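#' Thermodynamic audit of a network's parameters
#'
#' One-call pipeline: prune to the closed subsystem, extract the cycle
#' basis, evaluate the Wegscheider residual and entropy production rate of
#' every cycle under the network's current parameters, and summarise.
#'
#' @param network a `reaction_network`.
#' @param annotations a [pruning_annotations()] object.
#' @param volume system volume forwarded to [entropy_production_audit()].
#' @param tol zero-classification tolerance on the log-residual scale.
#' @return a `thermo_audit` list: `N0`, `M0`, `rank`, `M2`, the per-cycle
#'   `audit` tibble, `n_satisfied`, and `verdict` (`"feasible"`,
#'   `"infeasible"`, or `"no thermodynamic constraints"` when `M2 = 0`).
#' @export
audit_network <- function(network, annotations = pruning_annotations(),
                          volume = 1, tol = 1e-9) {
  closed <- prune_to_closed(network, annotations)
  basis <- cycle_basis(closed)
  audit <- entropy_production_audit(basis, network, volume = volume, tol = tol)
  verdict <- if (basis$M2 == 0L) "no thermodynamic constraints"
  else if (all(audit$satisfied)) "feasible" else "infeasible"
  structure(
    list(N0 = length(closed$species_ids), M0 = length(closed$reaction_ids),
         rank = basis$rank_M1, M2 = basis$M2,
         audit = audit, n_satisfied = sum(audit$satisfied),
         verdict = verdict, closed = closed, basis = basis),
    class = "thermo_audit"
  )
}

#' @export
print.thermo_audit <- function(x, ...) {
  cat("<thermo_audit> N0 = ", x$N0, ", M0 = ", x$M0, ", rank = ", x$rank,
      ", M2 = ", x$M2, "\n", sep = "")
  if (x$M2 > 0L) {
    cat("  Wegscheider conditions satisfied: ", x$n_satisfied, "/", x$M2, "\n", sep = "")
    signs <- table(factor(x$audit$sign, levels = c("negative", "zero", "positive")))
    cat("  entropy production signs: ",
        paste(names(signs), signs, sep = "=", collapse = ", "), "\n", sep = "")
  }
  cat("  verdict: ", x$verdict, "\n", sep = "")
  invisible(x)
}

# ---- YAML run configuration -------------------------------------------------

parse_annotations <- function(x) {
  if (is.null(x)) return(pruning_annotations())
  ov <- logical(0)
  if (!is.null(x$elementary_override))
    ov <- stats::setNames(as.logical(unlist(x$elementary_override)),
                          names(x$elementary_override))
  pruning_annotations(
    partially_modeled = as.character(x$partially_modeled %||% character(0)),
    thermodynamically_dependent =
      as.character(x$thermodynamically_dependent %||% character(0)),
    elementary_override = ov
  )
}

parse_constraints <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(cn) {
    log_linear_constraint(
      kind = cn$kind,
      coefficients = stats::setNames(as.numeric(unlist(cn$coefficients)),
                                     names(cn$coefficients)),
      rhs = if (identical(cn$rhs, "zero")) "zero" else as.numeric(cn$rhs %||% 0)
    )
  })
}

parse_designs <- function(x) {
  if (is.null(x)) return(list())
  lapply(x, function(d) {
    experiment_design(
      experiment_id = d$id,
      observation_times = as.numeric(unlist(d$observation_times)),
      observed_species = as.character(unlist(d$observed_species)),
      initial_overrides = stats::setNames(
        as.numeric(unlist(d$initial_overrides)), names(d$initial_overrides)),
      clamp_overrides = stats::setNames(
        as.numeric(unlist(d$clamp_overrides)), names(d$clamp_overrides))
    )
  })
}

#' Read a YAML run configuration
#'
#' Sections (all optional): `annotations` (pruning), `constraints` (extra
#' log-linear constraints), `experiments` (designs), `sa` (annealing
#' settings), `volume`, `seed`.
#'
#' @param path YAML file path.
#' @return list with parsed `annotations`, `constraints`, `designs`, `sa`,
#'   `volume`, `seed`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  sa_args <- raw$sa %||% list()
  if (!is.null(raw$seed) && is.null(sa_args$seed)) sa_args$seed <- raw$seed
  list(
    annotations = parse_annotations(raw$annotations),
    constraints = parse_constraints(raw$constraints),
    designs = parse_designs(raw$experiments),
    sa = do.call(sa_config, sa_args),
    volume = raw$volume %||% 1,
    seed = raw$seed %||% 1L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
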