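#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a calibration result
#'
#' One row per kinetic parameter: reference value, calibrated value, and the
#' log-scale shift applied by the calibration.
#'
#' @param x a `calibration_result`.
#' @param ... ignored.
#' @return a tibble.
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) {
  pt <- parameter_table(x$network)
  ref <- x$reparam$reference[pt$id]
  tibble::tibble(
    id = pt$id, reaction_id = pt$reaction_id, role = pt$role,
    fixed_zero = pt$fixed_zero,
    reference = ifelse(pt$fixed_zero, 0, exp(ref)),
    estimate = pt$value,
    log_shift = ifelse(pt$fixed_zero, 0, log(pt$value) - ref)
  )
}

#' One-row summary of a calibration result
#'
#' @param x a `calibration_result`.
#' @param ... ignored.
#' @return a tibble with the reduced dimension, costs, cost reduction,
#'   cycle count and the feasibility verdict of the calibrated model.
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    d = x$reparam$d,
    n_parameters = length(x$reparam$param_ids),
    M2 = x$basis$M2,
    initial_cost = x$initial_cost,
    final_cost = x$final_cost,
    cost_reduction = 1 - x$final_cost / x$initial_cost,
    n_evaluations = x$n_evaluations,
    feasible = if (nrow(x$audit) == 0L) TRUE else x$feasible,
    no_thermo = x$no_thermo,
    seed = x$seed
  )
}

#' Tidy a thermodynamic audit
#'
#' @param x a `thermo_audit`.
#' @param ... ignored.
#' @return the per-cycle audit tibble (residual, entropy production rate,
#'   sign, satisfied).
#' @method tidy thermo_audit
#' @export
tidy.thermo_audit <- function(x, ...) x$audit

#' @method glance thermo_audit
#' @export
glance.thermo_audit <- function(x, ...) {
  tibble::tibble(N0 = x$N0, M0 = x$M0, rank = x$rank, M2 = x$M2,
                 n_satisfied = x$n_satisfied,
                 n_negative = sum(x$audit$sign == "negative"),
                 n_positive = sum(x$audit$sign == "positive"),
                 verdict = x$verdict)
}

#' Plot the annealing cost trace
#'
#' Best-so-far least-squares cost against iteration, on a log cost scale.
#'
#' @param object a `calibration_result`.
#' @param ... ignored.
#' @return a ggplot object.
#' @method autoplot calibration_result
#' @export
autoplot.calibration_result <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$cost_trace),
                       cost = object$cost_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$cost)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "SA iteration", y = "best cost so far",
                  title = "Simulated annealing cost trace")
}

#' Plot simulated trajectories
#'
#' Concentration against time, one line per species, faceted by experiment;
#' optionally overlays observed data points.
#'
#' @param traj trajectory tibble from [simulate_network()].
#' @param data optional measurement tibble to overlay.
#' @return a ggplot object.
#' @export
plot_trajectories <- function(traj, data = NULL) {
  p <- ggplot2::ggplot(traj, ggplot2::aes(x = .data$time, y = .data$concentration,
                                          colour = .data$species_id)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~experiment_id) +
    ggplot2::labs(x = "time", y = "concentration", colour = "species")
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      mapping = ggplot2::aes(x = .data$time, y = .data$value,
                             colour = .data$species_id))
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
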