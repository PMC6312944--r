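#' Per-patient waiting times and target performance
#'
#' A patient's waiting time is the step of its first exit from the entry
#' ward (a `TRANSFER`, `DISCHARGE` or `DIVERT` out of it) minus its arrival
#' step, matching the arrival-to-departure semantics of the UK 4-hour A&E
#' target. Patients still in the entry ward or its queue when the run ends
#' are censored: they are excluded from the percentage and reported as a
#' count.
#'
#' @param result A `hospital_sim` from [run_simulation()] or a reconstructed
#'   result from [read_events()] analysis.
#' @param target Waiting-time target in steps; defaults to the config value.
#' @return A list with `waits` (tibble: `patient_id`, `arrival_step`,
#'   `exit_step`, `wait`, `within_target`), `pct_within_target` (`NA` when
#'   no waits were measured), `n_measured` and `n_censored`.
#' @export
waiting_times <- function(result,
                          target = result$config$settings$waiting_time_target) {
  ev <- result$events
  entry <- entry_ward(result$config)
  arrivals <- ev[ev$kind == "ARRIVAL", c("patient_id", "step")]
  names(arrivals) <- c("patient_id", "arrival_step")
  exits <- ev[ev$from == entry & ev$kind %in% c("TRANSFER", "DISCHARGE", "DIVERT"),
              c("patient_id", "step")]
  exits <- exits[!duplicated(exits$patient_id), ]
  names(exits) <- c("patient_id", "exit_step")
  waits <- dplyr::inner_join(arrivals, exits, by = "patient_id")
  waits <- dplyr::mutate(
    waits,
    wait = .data$exit_step - .data$arrival_step,
    within_target = .data$wait <= target
  )
  n_measured <- nrow(waits)
  list(
    waits = tibble::as_tibble(waits),
    pct_within_target = if (n_measured > 0) {
      100 * sum(waits$within_target) / n_measured
    } else {
      NA_real_
    },
    n_measured = n_measured,
    n_censored = nrow(arrivals) - n_measured
  )
}

#' Ward occupancy and utilisation over time
#'
#' @param result A `hospital_sim`.
#' @return A tibble with `step`, `ward`, `occupancy`, `capacity` and
#'   `utilisation` (`occupancy / capacity`; `NA` for zero-capacity wards).
#' @export
occupancy_series <- function(result) {
  cap <- setNames(result$config$wards$capacity, result$config$wards$id)
  dplyr::mutate(
    result$occupancy,
    capacity = unname(cap[.data$ward]),
    utilisation = ifelse(.data$capacity > 0,
                         .data$occupancy / .data$capacity, NA_real_)
  )
}

entry_ward <- function(config) config$wards$id[config$wards$is_entry][1]

#' Build the realised patient-flow network
#'
#' Counts every recorded bed movement as one directed edge increment:
#' entry admissions (`EXTERNAL` to the entry ward), inter-ward transfers,
#' overflow diversions, boarding returns, and discharges (ward to
#' `DISCHARGE`). Arrivals join the outside queue and are not movements.
#'
#' @param result A `hospital_sim`.
#' @return An object of class `flow_network`: list with `nodes` (character)
#'   and `edges` (tibble: `from`, `to`, `count`).
#' @export
build_flow_network <- function(result) {
  ev <- result$events
  moves <- ev[ev$kind %in% c("ADMIT", "TRANSFER", "DIVERT", "RETURN",
                             "DISCHARGE"), ]
  edges <- dplyr::count(moves, .data$from, .data$to, name = "count")
  nodes <- unique(c(EXTERNAL_NODE, result$config$wards$id, DISCHARGE_NODE,
                    edges$from, edges$to))
  structure(list(nodes = nodes, edges = tibble::as_tibble(edges)),
            class = "flow_network")
}

#' @export
print.flow_network <- function(x, ...) {
  cat(sprintf("<flow_network> %d nodes, %d edges, %d movements\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$count)))
  invisible(x)
}

#' Node-level network statistics of a flow network
#'
#' Computes, per node: unweighted and flow-weighted in- and out-degree,
#' normalised directed betweenness, and normalised directed harmonic
#' closeness. Shortest paths are taken on the unweighted edge-presence
#' graph (an edge exists when any patient made that movement). Betweenness
#' of a node v is the mean, over ordered pairs (s, t) of other nodes with
#' at least one directed path, of the fraction of shortest s-t paths
#' passing through v — so a pure relay on a directed line scores 1.
#' Harmonic closeness of v is the mean of 1/d(v, t) over all other nodes t
#' (0 for unreachable t), which stays well-defined on the disconnected
#' graphs realised flows often produce. Both lie in [0, 1].
#'
#' @param net A `flow_network` (or any data frame of `from`, `to`, `count`
#'   edges).
#' @return A tibble with columns `node`, `in_degree`, `out_degree`,
#'   `in_degree_weighted`, `out_degree_weighted`, `betweenness`,
#'   `closeness`.
#' @export
network_statistics <- function(net) {
  edges <- if (inherits(net, "flow_network")) net$edges else tibble::as_tibble(net)
  nodes <- if (inherits(net, "flow_network")) {
    net$nodes
  } else {
    unique(c(edges$from, edges$to))
  }
  if (length(nodes) == 0) {
    stop("no flow recorded", call. = FALSE)
  }
  n <- length(nodes)
  in_deg <- setNames(numeric(n), nodes)
  out_deg <- in_deg
  in_w <- in_deg
  out_w <- in_deg
  if (nrow(edges) > 0) {
    it <- tapply(edges$count, edges$to, length)
    in_deg[names(it)] <- it
    ot <- tapply(edges$count, edges$from, length)
    out_deg[names(ot)] <- ot
    iw <- tapply(edges$count, edges$to, sum)
    in_w[names(iw)] <- iw
    ow <- tapply(edges$count, edges$from, sum)
    out_w[names(ow)] <- ow
  }

  g <- igraph::graph_from_data_frame(
    edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = nodes)
  )
  if (n > 2 && nrow(edges) > 0) {
    btw_raw <- igraph::betweenness(g, directed = TRUE, normalized = FALSE)
    d <- igraph::distances(g, mode = "out")
    reachable <- is.finite(d) & !diag(TRUE, n)
    # ordered reachable pairs (s, t) excluding each node v
    pair_counts <- vapply(seq_len(n), function(v) {
      sum(reachable[-v, -v, drop = FALSE])
    }, numeric(1))
    btw <- ifelse(pair_counts > 0, btw_raw[nodes] / pair_counts, 0)
  } else {
    btw <- numeric(n)
    d <- igraph::distances(g, mode = "out")
  }
  if (n > 1) {
    inv <- 1 / d
    diag(inv) <- 0
    clo <- rowSums(inv)[nodes] / (n - 1)
  } else {
    clo <- numeric(n)
  }

  tibble::tibble(
    node = nodes,
    in_degree = unname(in_deg[nodes]),
    out_degree = unname(out_deg[nodes]),
    in_degree_weighted = unname(in_w[nodes]),
    out_degree_weighted = unname(out_w[nodes]),
    betweenness = unname(btw),
    closeness = unname(clo)
  )
}

#' Summarise completed patient journeys
#'
#' A journey is the ordered sequence of required wards a discharged patient
#' actually visited — boarding wards entered through overflow diversion are
#' excluded, because the patient was never treated there. Journey duration
#' is discharge step minus arrival step. Patients still in hospital at the
#' end of the run are censored and excluded.
#'
#' @param result A `hospital_sim`.
#' @return A list with `journeys` (tibble: `journey` — wards joined by
#'   `" -> "` — `length`, `count`, `min_duration`, `median_duration`,
#'   `max_duration`, sorted by descending count), `path_lengths` (tibble:
#'   `length`, `count`) and `n_censored`.
#' @export
journey_summary <- function(result) {
  ev <- result$events
  discharged <- ev$patient_id[ev$kind == "DISCHARGE"]
  arr <- setNames(ev$step[ev$kind == "ARRIVAL"], ev$patient_id[ev$kind == "ARRIVAL"])
  dis <- setNames(ev$step[ev$kind == "DISCHARGE"],
                  ev$patient_id[ev$kind == "DISCHARGE"])
  # required wards actually entered: entry admission + transfers + returns
  moves <- ev[ev$kind %in% c("ADMIT", "TRANSFER", "RETURN"), ]
  per_patient <- split(moves$to, moves$patient_id)
  if (length(discharged) == 0) {
    return(list(
      journeys = tibble::tibble(journey = character(), length = integer(),
                                count = integer(), min_duration = numeric(),
                                median_duration = numeric(),
                                max_duration = numeric()),
      path_lengths = tibble::tibble(length = integer(), count = integer()),
      n_censored = result$totals[["arrived"]]
    ))
  }
  tab <- tibble::tibble(
    patient_id = discharged,
    journey = vapply(as.character(discharged), function(pid) {
      paste(per_patient[[pid]], collapse = " -> ")
    }, character(1), USE.NAMES = FALSE),
    length = vapply(as.character(discharged), function(pid) {
      length(per_patient[[pid]])
    }, integer(1), USE.NAMES = FALSE),
    duration = unname(dis[as.character(discharged)] -
                        arr[as.character(discharged)])
  )
  journeys <- tab |>
    dplyr::group_by(.data$journey, .data$length) |>
    dplyr::summarise(
      count = dplyr::n(),
      min_duration = min(.data$duration),
      median_duration = median(.data$duration),
      max_duration = max(.data$duration),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$journey)
  path_lengths <- dplyr::count(tab, .data$length, name = "count")
  list(
    journeys = journeys,
    path_lengths = path_lengths,
    n_censored = result$totals[["arrived"]] - length(discharged)
  )
}

#' Headline statistics of a run
#'
#' Operating cost is `steps_run * sum(resources * resource_unit_cost +
#' capacity * bed_unit_cost)` over wards: both beds and resources are paid
#' for whether used or not.
#'
#' @param result A `hospital_sim`.
#' @return A one-row tibble: `operating_cost`, `pct_within_target`,
#'   `n_patients`, `n_discharged`, `n_unique_journeys`.
#' @export
basic_statistics <- function(result) {
  s <- result$config$settings
  w <- result$config$wards
  cost <- result$steps_run *
    sum(w$resources * s$resource_unit_cost + w$capacity * s$bed_unit_cost)
  wt <- waiting_times(result)
  js <- journey_summary(result)
  tibble::tibble(
    operating_cost = cost,
    pct_within_target = wt$pct_within_target,
    n_patients = result$totals[["arrived"]],
    n_discharged = result$totals[["discharged"]],
    n_unique_journeys = nrow(js$journeys)
  )
}

#' Full post-run analysis
#'
#' Bundles every analysis the package offers for one completed run: basic
#' statistics, waiting-time distribution and target performance, occupancy
#' series, the realised flow network with node statistics, and journey
#' summaries.
#'
#' @param result A `hospital_sim`.
#' @param target Waiting-time target override (steps).
#' @return An object of class `flow_analysis`.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$settings$max_steps <- 48
#' rep <- analyze(run_simulation(cfg, seed = 1))
#' rep$basic
analyze <- function(result,
                    target = result$config$settings$waiting_time_target) {
  wt <- waiting_times(result, target)
  js <- journey_summary(result)
  net <- build_flow_network(result)
  netstats <- if (nrow(net$edges) > 0) network_statistics(net) else NULL
  structure(
    list(
      basic = basic_statistics(result),
      waiting = wt,
      occupancy = occupancy_series(result),
      network = net,
      network_stats = netstats,
      journeys = js,
      target = target,
      steps_run = result$steps_run
    ),
    class = "flow_analysis"
  )
}

#' @export
print.flow_analysis <- function(x, ...) {
  b <- x$basic
  cat("<flow_analysis>\n")
  cat(sprintf("  patients: %d arrived, %d discharged, %d unique journeys\n",
              b$n_patients, b$n_discharged, b$n_unique_journeys))
  pct <- if (is.na(b$pct_within_target)) "n/a" else sprintf("%.1f%%", b$pct_within_target)
  cat(sprintf("  within %d-step waiting target: %s (%d censored)\n",
              as.integer(x$target), pct, x$waiting$n_censored))
  cat(sprintf("  operating cost: %s over %d steps\n",
              format(b$operating_cost, big.mark = ","), x$steps_run))
  invisible(x)
}
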