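#' Ward management policies
#'
#' Each ward makes two per-step decisions through named policies: which
#' queued patient to admit into a free bed (queue policy) and how to divide
#' its per-step resource pool among admitted patients (resource policy).
#' Three presets of each ship with the package; arbitrary policies can be
#' plugged in through [register_policy()].
#'
#' @name policies
NULL

.policy_registry <- new.env(parent = emptyenv())
.policy_registry$queue <- list()
.policy_registry$resource <- list()

#' Register a custom policy
#'
#' Queue policies receive a tibble of queue entries (`patient_id`,
#' `queue_entry_step`, `need_at_destination`) and must return the same rows
#' in admission order. Resource policies receive `(needs, ids, total)` —
#' remaining needs, patient ids for tie-breaking, and the resource pool —
#' and must return per-patient allocations that never exceed need and sum
#' to at most `total`.
#'
#' @param kind `"queue"` or `"resource"`.
#' @param name Policy name used in configuration files; must be new.
#' @param fn The policy function.
#' @return `name`, invisibly.
#' @export
#' @examples
#' register_policy("queue", "reverse_id",
#'                 function(entries) entries[order(-entries$patient_id), ])
#' "reverse_id" %in% list_policies("queue")
register_policy <- function(kind, name, fn) {
  kind <- match.arg(kind, c("queue", "resource"))
  if (name %in% names(.policy_registry[[kind]])) {
    stop(sprintf("a %s policy named '%s' is already registered", kind, name),
         call. = FALSE)
  }
  stopifnot(is.function(fn))
  .policy_registry[[kind]][[name]] <- fn
  invisible(name)
}

#' List registered policy names
#' @param kind `"queue"` or `"resource"`.
#' @return Character vector of policy names.
#' @rdname register_policy
#' @export
list_policies <- function(kind) {
  kind <- match.arg(kind, c("queue", "resource"))
  names(.policy_registry[[kind]])
}

get_policy <- function(kind, name) {
  fn <- .policy_registry[[kind]][[name]]
  if (is.null(fn)) {
    stop(sprintf("unknown %s policy '%s'; registered: %s", kind, name,
                 paste(list_policies(kind), collapse = ", ")), call. = FALSE)
  }
  fn
}

#' Order a ward admission queue
#'
#' Sorts queue entries into the order the ward will admit them.
#' `chronological` is first-come-first-served on `queue_entry_step`;
#' `high_need_first` (`low_need_first`) sorts by descending (ascending)
#' resource need at the destination ward. All policies break ties by
#' `(queue_entry_step, patient_id)` ascending, so the result is a
#' deterministic permutation of the input.
#'
#' @param entries A data frame with columns `patient_id`,
#'   `queue_entry_step`, `need_at_destination`.
#' @param policy Queue policy name (preset or registered).
#' @return The entries as a tibble, in admission order.
#' @export
#' @examples
#' q <- tibble::tibble(patient_id = 1:2, queue_entry_step = 0:1,
#'                     need_at_destination = c(5, 9))
#' order_queue(q, "high_need_first")$patient_id  # 2 then 1
order_queue <- function(entries, policy = "chronological") {
  entries <- tibble::as_tibble(entries)
  fn <- get_policy("queue", policy)
  out <- tibble::as_tibble(fn(entries))
  if (nrow(out) != nrow(entries) ||
      !setequal(out$patient_id, entries$patient_id)) {
    stop(sprintf("queue policy '%s' did not return a permutation of its input",
                 policy), call. = FALSE)
  }
  out
}

#' Divide a ward's resource pool among admitted patients
#'
#' Allocates at most `total` resource units to patients with the given
#' remaining needs. No patient ever receives more than its need. `even`
#' water-fills: the pool is split equally among patients with unmet need,
#' capped at need, and any surplus is redistributed until the pool or all
#' needs are exhausted. `high_need` (`low_need`) serves patients in
#' descending (ascending) order of need, each up to its full need, until
#' the pool runs out. Ties are broken by patient id. Allocations are
#' real-valued.
#'
#' @param needs Named numeric vector, or a numeric vector with `ids` given:
#'   remaining resource need per patient.
#' @param total Resource pool for the step (non-negative).
#' @param policy Resource policy name (preset or registered).
#' @param ids Patient identifiers for tie-breaking; defaults to
#'   `names(needs)` or the element index.
#' @return Numeric vector of allocations, same order and names as `needs`.
#' @export
#' @examples
#' allocate_resources(c(a = 5, b = 2), total = 10)          # c(5, 2)
#' allocate_resources(c(a = 5, b = 5), 4, policy = "high_need")  # c(4, 0)
allocate_resources <- function(needs, total, policy = "even", ids = NULL) {
  if (is.null(ids)) ids <- names(needs) %||% seq_along(needs)
  needs_v <- as.numeric(needs)
  if (total < 0 || any(needs_v < 0) || anyNA(needs_v)) {
    stop("allocate_resources: needs and total must be non-negative",
         call. = FALSE)
  }
  fn <- get_policy("resource", policy)
  alloc <- fn(needs_v, ids, total)
  names(alloc) <- names(needs)
  alloc
}

# -- preset implementations --------------------------------------------------

queue_chronological <- function(entries) {
  entries[order(entries$queue_entry_step, entries$patient_id), ]
}

queue_high_need_first <- function(entries) {
  entries[order(-entries$need_at_destination, entries$queue_entry_step,
                entries$patient_id), ]
}

queue_low_need_first <- function(entries) {
  entries[order(entries$need_at_destination, entries$queue_entry_step,
                entries$patient_id), ]
}

# Iterative water-filling: split the remaining pool equally over patients
# with unmet need, cap at need, redistribute the surplus.
resource_even <- function(needs, ids, total) {
  alloc <- numeric(length(needs))
  pool <- total
  repeat {
    active <- which(needs - alloc > 1e-12)
    if (length(active) == 0 || pool <= 1e-12) break
    share <- pool / length(active)
    give <- pmin(share, needs[active] - alloc[active])
    alloc[active] <- alloc[active] + give
    pool <- pool - sum(give)
    if (all(needs[active] - alloc[active] > 1e-12)) break  # nobody capped
  }
  alloc
}

resource_greedy <- function(decreasing) {
  force(decreasing)
  function(needs, ids, total) {
    alloc <- numeric(length(needs))
    key <- if (decreasing) -needs else needs
    ord <- order(key, rank(ids, ties.method = "first"))
    pool <- total
    for (i in ord) {
      if (pool <= 0) break
      alloc[i] <- min(needs[i], pool)
      pool <- pool - alloc[i]
    }
    alloc
  }
}

register_presets <- function() {
  if (!"chronological" %in% list_policies("queue")) {
    register_policy("queue", "chronological", queue_chronological)
    register_policy("queue", "high_need_first", queue_high_need_first)
    register_policy("queue", "low_need_first", queue_low_need_first)
    register_policy("resource", "even", resource_even)
    register_policy("resource", "high_need", resource_greedy(TRUE))
    register_policy("resource", "low_need", resource_greedy(FALSE))
  }
  invisible(NULL)
}

.onLoad <- function(libname, pkgname) {
  register_presets()
}
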