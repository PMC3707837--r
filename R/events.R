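## Event scheduling: trigger tracking, persistence, priorities, random
## tie-breaking, delayed execution with trigger-time snapshots.
##
## At a given time point the executable events are the union of two sets:
## events whose triggers switched false -> true now (without delay), and
## previously triggered events whose delay reaches the current time.  One
## event of highest priority is chosen (uniformly at random among ties),
## executed, and all triggers and priorities are re-evaluated, because
## the assignments of one event may change the priority or even the
## trigger condition of the others.  The loop ends when no active event
## remains.

.empty_fired <- data.frame(time = numeric(0), event = character(0),
                           stringsAsFactors = FALSE)

#' Create the event bookkeeping context for a model
#'
#' One state record per event: previous trigger value, active flag
#' (membership in the active set), trigger-time snapshot, and the ordered
#' list of pending delayed executions.
#'
#' @param events list of event specifications (from an `sbml_model`).
#' @return Object of class `event_context`.
#' @export
event_context <- function(events) {
  ctx <- new.env(parent = emptyenv())
  ctx$events <- events
  ctx$states <- lapply(events, function(ev)
    list(prev = NA, active = FALSE, snapshot = NULL, pending = list()))
  names(ctx$states) <- vapply(events, `[[`, character(1), "id")
  class(ctx) <- "event_context"
  ctx
}

#' Deep-copy the mutable state of an event context
#' @param ctx an [event_context()].
#' @return An opaque snapshot for [ctx_restore()].
#' @export
ctx_snapshot <- function(ctx) ctx$states

#' Restore event-context state saved by [ctx_snapshot()]
#'
#' Used by the integrator when a step is rewound for event localization:
#' trigger memory and pending executions must roll back together with the
#' state vector.
#'
#' @param ctx an [event_context()].
#' @param snap snapshot from [ctx_snapshot()].
#' @return `ctx`, invisibly.
#' @export
ctx_restore <- function(ctx, snap) {
  ctx$states <- snap
  invisible(ctx)
}

#' Initialize trigger memory at the simulation start
#'
#' Level 3 triggers carry an explicit initial value (an initially-true
#' trigger with `initialValue="true"` is not a transition).  For Level 1/2
#' events the trigger's value before t0 is taken to be its value at t0,
#' so initially-true triggers never fire at t0 either.
#'
#' @param ctx an [event_context()].
#' @param evalf function(tree) evaluating an expression at the initial
#'   state.
#' @return `ctx`, invisibly.
#' @export
init_triggers <- function(ctx, evalf) {
  for (i in seq_along(ctx$events)) {
    ev <- ctx$events[[i]]
    tiv <- ev$trigger_initial_value
    ctx$states[[i]]$prev <- if (is.na(tiv)) {
      isTRUE(evalf(ev$trigger))
    } else {
      isTRUE(tiv)
    }
  }
  invisible(ctx)
}

#' Update trigger transitions at a time point
#'
#' A false-to-true transition activates the event (immediate) or
#' schedules a pending execution at `t + delay` (the delay expression is
#' evaluated at trigger time, since it may differ between firings); a
#' trigger-time snapshot of the state is taken when the event uses
#' trigger-time values.  Active nonpersistent events whose trigger has
#' fallen false are deactivated; pending executions are cancelled only
#' for nonpersistent events that do not use trigger-time values.
#'
#' @param ctx an [event_context()].
#' @param Q named numeric state vector (snapshot source).
#' @param t current time.
#' @param evalf function(tree) evaluating an expression at `(Q, t)`.
#' @return `ctx`, invisibly.
#' @export
update_triggers <- function(ctx, Q, t, evalf) {
  for (i in seq_along(ctx$events)) {
    ev <- ctx$events[[i]]
    st <- ctx$states[[i]]
    cur <- evalf(ev$trigger)
    if (!is.logical(cur))
      stop("trigger of event '", ev$id, "' is not boolean", call. = FALSE)
    cur <- isTRUE(cur)
    prev <- st$prev
    if (is.na(prev)) prev <- cur

    if (!prev && cur) {
      if (!is.null(ctx$transitions))
        ctx$transitions <- ctx$transitions + 1L
      if (!is.null(ev$delay)) {
        dt <- evalf(ev$delay)
        if (!is.numeric(dt) || is.na(dt) || dt < 0)
          stop("delay of event '", ev$id, "' is not a nonnegative number",
               call. = FALSE)
        entry <- list(time = t + dt,
                      snapshot = if (isTRUE(ev$use_trigger_time_values)) Q
                                 else NULL)
        ## keep pending executions sorted ascending by execution time
        pend <- st$pending
        pos <- length(pend) + 1L
        for (k in seq_along(pend))
          if (pend[[k]]$time > entry$time) { pos <- k; break }
        st$pending <- append(pend, list(entry), after = pos - 1L)
      } else {
        st$active <- TRUE
        st$snapshot <- if (isTRUE(ev$use_trigger_time_values)) Q else NULL
      }
    }
    if (!cur) {
      if (st$active && !isTRUE(ev$persistent)) {
        st$active <- FALSE
        st$snapshot <- NULL
      }
      if (length(st$pending) > 0L && !isTRUE(ev$persistent) &&
          !isTRUE(ev$use_trigger_time_values))
        st$pending <- list()
    }
    st$prev <- cur
    ctx$states[[i]] <- st
  }
  invisible(ctx)
}

#' Choose the next event for execution
#'
#' Among the candidates, events with a defined priority compete first:
#' one of those with maximal evaluated priority is chosen, uniformly at
#' random among ties.  Events without a priority form one tie class
#' ranked below every prioritized event, again chosen uniformly.
#'
#' @param candidates integer vector of candidate indices.
#' @param priorities numeric vector aligned with `candidates`; `NA` for
#'   events without a priority.
#' @return One element of `candidates`.
#' @export
choose_event <- function(candidates, priorities) {
  stopifnot(length(candidates) >= 1L,
            length(priorities) == length(candidates))
  with_p <- which(!is.na(priorities))
  ties <- if (length(with_p) > 0L) {
    mx <- max(priorities[with_p])
    with_p[priorities[with_p] == mx]
  } else {
    seq_along(candidates)
  }
  if (length(ties) == 1L) return(candidates[ties])
  candidates[ties[sample.int(length(ties), 1L)]]
}

#' Execute one event's assignments atomically
#'
#' All right-hand sides are evaluated against `values_source` (the
#' current state, or the trigger-time snapshot) before any write, so
#' swapping assignments behave simultaneously.  Species assignments are
#' interpreted in the species' own units: a concentration value is
#' converted to an amount using the current compartment size, so an
#' assignment that halves a compartment leaves amounts untouched while
#' concentrations double.
#'
#' @param event event specification.
#' @param Q named numeric state vector to be updated.
#' @param values_source state vector the right-hand sides read from.
#' @param t current time.
#' @param evalf function(tree, Q, t) evaluating an expression.
#' @param species named list of species specifications (for unit
#'   handling); may be empty.
#' @return The updated state vector.
#' @export
execute_event <- function(event, Q, values_source, t, evalf,
                          species = list()) {
  n <- length(event$assignments)
  if (n == 0L) return(Q)
  vals <- vector("list", n)
  for (k in seq_len(n))
    vals[[k]] <- evalf(event$assignments[[k]]$math, values_source, t)
  for (k in seq_len(n)) {
    var <- event$assignments[[k]]$variable
    v <- vals[[k]]
    sp <- species[[var]]
    if (!is.null(sp) && !isTRUE(sp$has_only_substance_units))
      v <- v * Q[[sp$compartment]]   # concentration -> amount
    Q[[var]] <- v
  }
  Q
}

#' Process all events due at a time point
#'
#' The scheduler loop: refresh trigger transitions, collect the active
#' set (immediate activations plus pending delayed executions whose time
#' has come), drop nonpersistent events whose trigger fell false, choose
#' one event of highest priority, execute it, re-apply assignment rules,
#' and repeat — triggers and priorities are re-evaluated every iteration
#' because executions may influence them.  Terminates when the active set
#' is empty; a cycle guard caps the number of executions at one time
#' point.
#'
#' @param ctx an [event_context()].
#' @param Q named numeric state vector.
#' @param t current time.
#' @param evalf function(tree, Q, t) evaluating an expression.
#' @param apply_rules_fn function(Q, t) re-applying assignment rules
#'   after each execution (identity by default).
#' @param species named list of species specifications for assignment
#'   unit handling.
#' @param cap maximum number of executions at one time point before a
#'   cycle error is raised.
#' @return List with `Q` (updated state), `fired` (list with vectors
#'   `time` and `event`), `n_fired`, and `transitions` (count of rising
#'   trigger edges seen).
#' @export
process_events <- function(ctx, Q, t, evalf,
                           apply_rules_fn = function(Q, t) Q,
                           species = list(), cap = 10000L) {
  fired_t <- numeric(0)
  fired_id <- character(0)
  count <- 0L
  tiny <- 1e-12 * (1 + abs(t))
  ctx$transitions <- 0L   # rising-edge counter (event-time localization)
  evalf1 <- function(tree) evalf(tree, Q, t)

  repeat {
    update_triggers(ctx, Q, t, evalf1)

    cand <- integer(0)
    cand_pending <- logical(0)
    for (i in seq_along(ctx$events)) {
      st <- ctx$states[[i]]
      if (st$active) {
        cand <- c(cand, i); cand_pending <- c(cand_pending, FALSE)
      } else if (length(st$pending) > 0L &&
                 st$pending[[1L]]$time <= t + tiny) {
        cand <- c(cand, i); cand_pending <- c(cand_pending, TRUE)
      }
    }
    if (length(cand) == 0L) break

    prios <- vapply(cand, function(i) {
      p <- ctx$events[[i]]$priority
      if (is.null(p)) NA_real_ else as.numeric(evalf(p, Q, t))
    }, numeric(1))
    pick <- choose_event(cand, prios)
    is_pending <- cand_pending[match(pick, cand)]
    ev <- ctx$events[[pick]]
    st <- ctx$states[[pick]]

    if (is_pending) {
      entry <- st$pending[[1L]]
      st$pending <- st$pending[-1L]
      source_Q <- if (!is.null(entry$snapshot)) entry$snapshot else Q
    } else {
      source_Q <- if (!is.null(st$snapshot)) st$snapshot else Q
      st$active <- FALSE
      st$snapshot <- NULL
    }
    ctx$states[[pick]] <- st

    Q <- execute_event(ev, Q, source_Q, t, evalf, species)
    Q <- apply_rules_fn(Q, t)
    evalf1 <- function(tree) evalf(tree, Q, t)

    fired_t <- c(fired_t, t)
    fired_id <- c(fired_id, ev$id)
    count <- count + 1L
    if (count > cap)
      stop("event cycle: more than ", cap,
           " executions at t = ", format(t), " (events: ",
           paste(unique(fired_id), collapse = ", "), ")", call. = FALSE)
  }
  list(Q = Q, fired = list(time = fired_t, event = fired_id),
       n_fired = count, transitions = ctx$transitions)
}
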