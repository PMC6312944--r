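#' Run the patient-flow simulation
#'
#' Advances a stochastic discrete-event simulation of the configured
#' hospital step by step. Within every step six sub-phases execute in a
#' fixed order:
#' \enumerate{
#'   \item arrivals join the entry ward's (unbounded) queue;
#'   \item treatment: each ward divides its resource pool among admitted
#'     patients under its resource policy; needs decrease by the
#'     allocation, length-of-stay counters by one step (boarding patients
#'     receive neither);
#'   \item completion: patients with no remaining need and no remaining
#'     stay either queue for the next required ward (staying in their
#'     current bed until admitted) or are discharged, freeing the bed;
#'   \item queue admissions: wards admit from their queues into free beds
#'     under their queue policies; sweeps repeat until no bed can be
#'     filled, so beds freed by a transfer are refilled the same step;
#'   \item overflow: wards at capacity with a waiting queue divert
#'     completed-but-blocked occupants to overflow-enabled wards
#'     (boarding), immediately reusing the freed bed;
#'   \item occupancy and queue-length snapshots are recorded.
#' }
#' The run stops at `max_steps`, or earlier once `max_patients` have
#' arrived and every patient in the system has been discharged. Identical
#' `(config, seed)` pairs produce identical results.
#'
#' @param config A validated `hospital_config`.
#' @param seed Integer random seed; defaults to the seed in the config.
#' @return An object of class `hospital_sim`: a list with `config`, `seed`,
#'   `events` (tibble: `step`, `patient_id`, `kind`, `from`, `to`),
#'   `occupancy` and `queue_lengths` (tibbles: `step`, `ward`, value),
#'   `patients` (tibble with pathway/requirement list-columns and
#'   `discharge_step`), `steps_run` and `totals`
#'   (`arrived`, `admitted`, `discharged`).
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$settings$max_steps <- 48
#' sim <- run_simulation(cfg, seed = 1)
#' sim$totals
run_simulation <- function(config, seed = config$settings$seed) {
  stop_if_invalid(config)
  with_sim_seed(seed, {
    st <- new_sim_state(config)
    max_steps <- config$settings$max_steps
    max_pat <- config$settings$max_patients
    step <- 0L
    while (step < max_steps) {
      step <- step + 1L
      advance_step(st, step)
      if (is.finite(max_pat) && st$arrived >= max_pat &&
          st$discharged >= st$arrived) {
        break
      }
    }
    build_result(st, config, seed, steps_run = step)
  })
}

# -- mutable run state -------------------------------------------------------

new_sim_state <- function(config) {
  st <- new.env(parent = emptyenv())
  w <- config$wards
  st$ward_ids <- w$id
  st$entry <- w$id[w$is_entry][1]
  st$cap <- setNames(w$capacity, w$id)
  st$res <- setNames(w$resources, w$id)
  st$qpol <- setNames(w$queue_policy, w$id)
  st$rpol <- setNames(w$resource_policy, w$id)
  st$overflow_ok <- setNames(w$allow_overflow, w$id)
  st$los_lambda_vec <- w$los_lambda
  st$need_lambda_vec <- w$need_lambda
  st$graph <- config$graph
  st$settings <- config$settings

  st$occupants <- setNames(lapply(w$id, function(x) integer()), w$id)
  st$queues <- setNames(lapply(w$id, function(x) integer()), w$id)

  # per-patient parallel vectors, grown in chunks
  st$n_pat <- 0L
  st$cap_pat <- 0L
  st$arrival <- integer()
  st$path_pos <- integer()
  st$n_path <- integer()
  st$diverted <- logical()
  st$pending <- logical()       # queued for the next required ward
  st$qstep <- integer()
  st$loc <- character()         # ward id, "ENTRY_QUEUE" or "DISCHARGED"
  st$dstep <- integer()
  st$cur_los <- numeric()
  st$cur_need <- numeric()
  st$pathway <- list()
  st$los_req <- list()
  st$need_req <- list()

  st$arrived <- 0L
  st$admitted <- 0L
  st$discharged <- 0L

  # event log, grown in chunks
  st$n_ev <- 0L
  st$cap_ev <- 0L
  st$ev_step <- integer()
  st$ev_id <- integer()
  st$ev_kind <- character()
  st$ev_from <- character()
  st$ev_to <- character()

  n_steps <- if (is.finite(config$settings$max_steps)) {
    as.integer(config$settings$max_steps)
  } else {
    1024L
  }
  st$occ_mat <- matrix(0L, nrow = n_steps, ncol = length(w$id),
                       dimnames = list(NULL, w$id))
  st$qlen_mat <- st$occ_mat
  st
}

grow_patients <- function(st, extra) {
  need <- st$n_pat + extra
  if (need <= st$cap_pat) return(invisible(NULL))
  new_cap <- max(need, st$cap_pat * 2L, 256L)
  pad_i <- integer(new_cap - st$cap_pat)
  pad_l <- logical(new_cap - st$cap_pat)
  pad_n <- numeric(new_cap - st$cap_pat)
  st$arrival <- c(st$arrival, pad_i)
  st$path_pos <- c(st$path_pos, pad_i)
  st$n_path <- c(st$n_path, pad_i)
  st$diverted <- c(st$diverted, pad_l)
  st$pending <- c(st$pending, pad_l)
  st$qstep <- c(st$qstep, pad_i)
  st$loc <- c(st$loc, character(new_cap - st$cap_pat))
  st$dstep <- c(st$dstep, rep(NA_integer_, new_cap - st$cap_pat))
  st$cur_los <- c(st$cur_los, pad_n)
  st$cur_need <- c(st$cur_need, pad_n)
  length(st$pathway) <- new_cap
  length(st$los_req) <- new_cap
  length(st$need_req) <- new_cap
  st$cap_pat <- new_cap
  invisible(NULL)
}

record_event <- function(st, step, id, kind, from, to) {
  n <- st$n_ev + 1L
  if (n > st$cap_ev) {
    new_cap <- max(n, st$cap_ev * 2L, 1024L)
    pad <- new_cap - st$cap_ev
    st$ev_step <- c(st$ev_step, integer(pad))
    st$ev_id <- c(st$ev_id, integer(pad))
    st$ev_kind <- c(st$ev_kind, character(pad))
    st$ev_from <- c(st$ev_from, character(pad))
    st$ev_to <- c(st$ev_to, character(pad))
    st$cap_ev <- new_cap
  }
  st$ev_step[n] <- step
  st$ev_id[n] <- id
  st$ev_kind[n] <- kind
  st$ev_from[n] <- from
  st$ev_to[n] <- to
  st$n_ev <- n
  invisible(NULL)
}

# -- one simulation step -----------------------------------------------------

advance_step <- function(st, step) {
  phase_arrivals(st, step)
  phase_treatment(st)
  phase_completion(st, step)
  phase_admissions(st, step)
  phase_overflow(st, step)
  phase_snapshot(st, step)
  invisible(NULL)
}

phase_arrivals <- function(st, step) {
  max_pat <- st$settings$max_patients
  room <- if (is.finite(max_pat)) max(0, max_pat - st$arrived) else Inf
  if (room <= 0) return(invisible(NULL))
  n_arr <- min(sample_arrivals(st$settings), room)
  if (n_arr <= 0) return(invisible(NULL))
  grow_patients(st, n_arr)
  for (k in seq_len(n_arr)) {
    id <- st$n_pat + 1L
    st$n_pat <- id
    path <- generate_pathway(st$graph, st$entry, st$settings$max_pathway_length)
    idx <- match(path, st$ward_ids)
    st$pathway[[id]] <- path
    st$los_req[[id]] <- as.numeric(pmax(1, rpois(length(path),
                                                 st$los_lambda_vec[idx])))
    st$need_req[[id]] <- as.numeric(rpois(length(path), st$need_lambda_vec[idx]))
    st$arrival[id] <- step
    st$path_pos[id] <- 1L
    st$n_path[id] <- length(path)
    st$diverted[id] <- FALSE
    st$pending[id] <- FALSE
    st$qstep[id] <- step
    st$loc[id] <- "ENTRY_QUEUE"
    st$queues[[st$entry]] <- c(st$queues[[st$entry]], id)
    st$arrived <- st$arrived + 1L
    record_event(st, step, id, "ARRIVAL", EXTERNAL_NODE, st$entry)
  }
  invisible(NULL)
}

phase_treatment <- function(st) {
  for (w in st$ward_ids) {
    occ <- st$occupants[[w]]
    if (length(occ) == 0) next
    active <- occ[!st$diverted[occ]]
    if (length(active) == 0) next
    needs <- st$cur_need[active]
    total <- st$res[[w]]
    alloc <- if (total > 0 && any(needs > 0)) {
      fn <- get_policy("resource", st$rpol[[w]])
      fn(needs, active, total)
    } else {
      numeric(length(active))
    }
    st$cur_need[active] <- pmax(0, needs - alloc)
    st$cur_los[active] <- pmax(0, st$cur_los[active] - 1)
  }
  invisible(NULL)
}

phase_completion <- function(st, step) {
  for (w in st$ward_ids) {
    occ <- st$occupants[[w]]
    if (length(occ) == 0) next
    done <- occ[!st$diverted[occ] & !st$pending[occ] &
                st$cur_need[occ] <= 1e-9 & st$cur_los[occ] <= 0]
    for (id in done) {
      if (st$path_pos[id] >= st$n_path[id]) {
        discharge_patient(st, id, w, step)
      } else {
        nxt <- st$pathway[[id]][st$path_pos[id] + 1L]
        st$pending[id] <- TRUE
        st$qstep[id] <- step
        st$queues[[nxt]] <- c(st$queues[[nxt]], id)
      }
    }
  }
  invisible(NULL)
}

discharge_patient <- function(st, id, ward, step) {
  st$occupants[[ward]] <- setdiff(st$occupants[[ward]], id)
  st$loc[id] <- "DISCHARGED"
  st$dstep[id] <- step
  st$discharged <- st$discharged + 1L
  record_event(st, step, id, "DISCHARGE", ward, DISCHARGE_NODE)
  invisible(NULL)
}

# Admission order within a queue under the ward's queue policy. Preset
# policies are applied directly on the state vectors; registered custom
# policies go through the tibble contract of order_queue().
ordered_queue_ids <- function(st, w) {
  q <- st$queues[[w]]
  if (length(q) <= 1) return(q)
  # need at the destination = need_required for ward w on each patient's path
  pos <- ifelse(st$loc[q] == "ENTRY_QUEUE", st$path_pos[q], st$path_pos[q] + 1L)
  need <- vapply(seq_along(q), function(k) st$need_req[[q[k]]][pos[k]],
                 numeric(1))
  pol <- st$qpol[[w]]
  if (pol == "chronological") {
    q[order(st$qstep[q], q)]
  } else if (pol == "high_need_first") {
    q[order(-need, st$qstep[q], q)]
  } else if (pol == "low_need_first") {
    q[order(need, st$qstep[q], q)]
  } else {
    entries <- tibble::tibble(patient_id = q, queue_entry_step = st$qstep[q],
                              need_at_destination = need)
    order_queue(entries, pol)$patient_id
  }
}

# Admit one patient into ward w; emits ADMIT (from the outside queue),
# RETURN (boarding patient rejoining its path) or TRANSFER (ward to ward).
admit_patient <- function(st, id, w, step) {
  from <- st$loc[id]
  if (from == "ENTRY_QUEUE") {
    record_event(st, step, id, "ADMIT", EXTERNAL_NODE, w)
    st$admitted <- st$admitted + 1L
  } else if (st$diverted[id]) {
    st$occupants[[from]] <- setdiff(st$occupants[[from]], id)
    st$diverted[id] <- FALSE
    st$path_pos[id] <- st$path_pos[id] + 1L
    record_event(st, step, id, "RETURN", from, w)
  } else {
    st$occupants[[from]] <- setdiff(st$occupants[[from]], id)
    st$path_pos[id] <- st$path_pos[id] + 1L
    record_event(st, step, id, "TRANSFER", from, w)
  }
  st$queues[[w]] <- setdiff(st$queues[[w]], id)
  st$pending[id] <- FALSE
  st$loc[id] <- w
  pos <- st$path_pos[id]
  st$cur_los[id] <- st$los_req[[id]][pos]
  st$cur_need[id] <- st$need_req[[id]][pos]
  st$occupants[[w]] <- c(st$occupants[[w]], id)
  invisible(NULL)
}

phase_admissions <- function(st, step) {
  repeat {
    admitted_any <- FALSE
    for (w in st$ward_ids) {
      free <- st$cap[[w]] - length(st$occupants[[w]])
      if (free <= 0 || length(st$queues[[w]]) == 0) next
      ord <- ordered_queue_ids(st, w)
      take <- head(ord, free)
      for (id in take) admit_patient(st, id, w, step)
      if (length(take) > 0) admitted_any <- TRUE
    }
    if (!admitted_any) break
  }
  invisible(NULL)
}

phase_overflow <- function(st, step) {
  for (w in st$ward_ids) {
    repeat {
      if (length(st$occupants[[w]]) < st$cap[[w]] ||
          length(st$queues[[w]]) == 0) {
        break
      }
      occ <- st$occupants[[w]]
      blocked <- occ[st$pending[occ] & !st$diverted[occ]]
      if (length(blocked) == 0) break
      b <- blocked[order(st$qstep[blocked], blocked)][1]
      # destination: first overflow-enabled ward with a free bed that is
      # neither the current ward nor the patient's own next required ward
      required_next <- st$pathway[[b]][st$path_pos[b] + 1L]
      dest <- NA_character_
      for (v in st$ward_ids) {
        if (v != w && v != required_next && st$overflow_ok[[v]] &&
            length(st$occupants[[v]]) < st$cap[[v]]) {
          dest <- v
          break
        }
      }
      if (is.na(dest)) break
      st$occupants[[w]] <- setdiff(st$occupants[[w]], b)
      st$occupants[[dest]] <- c(st$occupants[[dest]], b)
      st$diverted[b] <- TRUE
      st$loc[b] <- dest
      record_event(st, step, b, "DIVERT", w, dest)
      # the freed bed is immediately offered to w's queue
      if (length(st$queues[[w]]) > 0) {
        ord <- ordered_queue_ids(st, w)
        admit_patient(st, ord[1], w, step)
      }
    }
  }
  invisible(NULL)
}

phase_snapshot <- function(st, step) {
  if (step > nrow(st$occ_mat)) {
    st$occ_mat <- rbind(st$occ_mat, matrix(0L, 1024L, ncol(st$occ_mat)))
    st$qlen_mat <- rbind(st$qlen_mat, matrix(0L, 1024L, ncol(st$qlen_mat)))
  }
  st$occ_mat[step, ] <- lengths(st$occupants)[st$ward_ids]
  st$qlen_mat[step, ] <- lengths(st$queues)[st$ward_ids]
  invisible(NULL)
}

# -- result assembly ---------------------------------------------------------

build_result <- function(st, config, seed, steps_run) {
  n <- st$n_pat
  idx <- seq_len(n)
  events <- tibble::tibble(
    step = st$ev_step[seq_len(st$n_ev)],
    patient_id = st$ev_id[seq_len(st$n_ev)],
    kind = st$ev_kind[seq_len(st$n_ev)],
    from = st$ev_from[seq_len(st$n_ev)],
    to = st$ev_to[seq_len(st$n_ev)]
  )
  occ_long <- function(m) {
    if (steps_run == 0) {
      return(tibble::tibble(step = integer(), ward = character(),
                            value = integer()))
    }
    m <- m[seq_len(steps_run), , drop = FALSE]
    tibble::tibble(
      step = rep(seq_len(steps_run), times = ncol(m)),
      ward = rep(colnames(m), each = steps_run),
      value = as.integer(m)
    )
  }
  occupancy <- dplyr::rename(occ_long(st$occ_mat), occupancy = "value")
  queue_lengths <- dplyr::rename(occ_long(st$qlen_mat), queue_length = "value")
  patients <- tibble::tibble(
    id = idx,
    arrival_step = st$arrival[idx],
    discharge_step = st$dstep[idx],
    location = st$loc[idx],
    diverted = st$diverted[idx],
    path_length = st$n_path[idx],
    pathway = st$pathway[idx],
    los_required = st$los_req[idx],
    need_required = st$need_req[idx]
  )
  structure(
    list(
      config = config,
      seed = seed,
      events = events,
      occupancy = occupancy,
      queue_lengths = queue_lengths,
      patients = patients,
      steps_run = as.integer(steps_run),
      totals = c(arrived = st$arrived, admitted = st$admitted,
                 discharged = st$discharged)
    ),
    class = "hospital_sim"
  )
}

#' @export
print.hospital_sim <- function(x, ...) {
  t <- x$totals
  cat(sprintf("<hospital_sim> %d steps, seed %s\n", x$steps_run,
              format(x$seed)))
  cat(sprintf("  arrived %d | admitted %d | discharged %d | events %d\n",
              t[["arrived"]], t[["admitted"]], t[["discharged"]],
              nrow(x$events)))
  invisible(x)
}
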