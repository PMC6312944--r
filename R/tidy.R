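#' Tidy a simulation result into its event log
#'
#' @param x A `hospital_sim`.
#' @param ... Unused.
#' @return The event log as a tibble (`step`, `patient_id`, `kind`, `from`,
#'   `to`).
#' @export
tidy.hospital_sim <- function(x, ...) {
  x$events
}

#' One-row summary of a simulation run
#'
#' @param x A `hospital_sim`.
#' @param ... Unused.
#' @return A one-row tibble: `steps_run`, `n_arrived`, `n_admitted`,
#'   `n_discharged`, `n_events`, `mean_occupancy` (hospital-wide mean of
#'   per-step total occupancy) and `seed`.
#' @export
glance.hospital_sim <- function(x, ...) {
  total_occ <- if (nrow(x$occupancy) > 0) {
    per_step <- tapply(x$occupancy$occupancy, x$occupancy$step, sum)
    mean(per_step)
  } else {
    NA_real_
  }
  tibble::tibble(
    steps_run = x$steps_run,
    n_arrived = x$totals[["arrived"]],
    n_admitted = x$totals[["admitted"]],
    n_discharged = x$totals[["discharged"]],
    n_events = nrow(x$events),
    mean_occupancy = total_occ,
    seed = as.integer(x$seed)
  )
}

#' Tidy a flow network into its edge list
#'
#' @param x A `flow_network`.
#' @param ... Unused.
#' @return Edge tibble (`from`, `to`, `count`).
#' @export
tidy.flow_network <- function(x, ...) {
  x$edges
}

#' Tidy an analysis report into per-node network statistics
#'
#' @param x A `flow_analysis`.
#' @param ... Unused.
#' @return The node-statistics tibble (see [network_statistics()]).
#' @export
tidy.flow_analysis <- function(x, ...) {
  x$network_stats
}

#' One-row summary of an analysis report
#'
#' @param x A `flow_analysis`.
#' @param ... Unused.
#' @return The basic-statistics tibble with the censored count appended.
#' @export
glance.flow_analysis <- function(x, ...) {
  dplyr::mutate(x$basic, n_censored = x$waiting$n_censored)
}
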