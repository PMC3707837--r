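## Top-level simulation driver: connects the SBML interpreter to the
## generic solvers through the system interface.

#' Wrap an SBML interpreter as an integrable system
#'
#' Implements the system interface consumed by [integrate_system()]:
#' state size and identifiers, derivative computation, rule application,
#' event processing (with snapshot/rewind support for step refinement),
#' and per-step commit hooks (history recording, constraint checks,
#' algebraic-rule residual tracking).
#'
#' @param sim an [sbml_interpreter()] that has been initialized with
#'   [sim_initialize()].
#' @param Q0 initial state from [sim_initialize()] (after t0 event
#'   processing).
#' @param constraint_listener optional function(time, message).
#' @return An object of class `ode_system`.
#' @export
as_ode_system <- function(sim, Q0, constraint_listener = NULL) {
  acc <- new.env(parent = emptyenv())
  acc$constraints <- list()
  acc$max_residual <- 0
  acc$step_times <- numeric(0)
  acc$n_steps <- 0L

  sys <- list(
    ids = sim$index$ids,
    state0 = Q0,
    t0 = sim$t0,
    deriv = function(Q, t) compute_derivatives(sim, Q, t),
    apply_rules_at = function(Q, t) apply_rules(sim, Q, t),
    post_step = function(Q, t) {
      res <- sim_process_events(sim, Q, t)
      ## refine not only when executions changed Q but also when a
      ## trigger transition occurred: delay scheduling and trigger-time
      ## snapshots depend on the localized trigger time itself
      changed <- (res$n_fired > 0L && any(res$Q != Q)) ||
        res$transitions > 0L
      list(Q = res$Q, changed = changed, fired = res$fired)
    },
    snapshot = function() ctx_snapshot(sim$ectx),
    restore = function(s) ctx_restore(sim$ectx, s),
    on_commit = function(Q, t) {
      history_append(sim$history, t, Q)
      viol <- check_constraints(sim, Q, t, constraint_listener)
      if (nrow(viol) > 0L)
        acc$constraints[[length(acc$constraints) + 1L]] <- viol
      resid <- algebraic_residuals(sim, Q, t)
      if (length(resid) > 0L)
        acc$max_residual <- max(acc$max_residual, max(abs(resid)))
      acc$n_steps <- acc$n_steps + 1L
      acc$step_times[acc$n_steps] <- t   # amortized append
    },
    autonomous = isTRUE(sim$autonomous),
    accumulator = acc)
  class(sys) <- "ode_system"
  sys
}

#' Simulate an SBML model
#'
#' End-to-end driver: read (if needed) and validate the model, convert
#' algebraic rules, initialize the state (initial values, initial
#' assignments, assignment rules, t0 event processing), integrate with
#' the configured solver, and assemble the output table.
#'
#' @param model an `sbml_model`, a file path, or SBML XML text.
#' @param t0 start time (default 0, the SBML convention; arbitrary
#'   starts are accepted).
#' @param t_end end time.
#' @param config a [solver_config()]; individual settings can also be
#'   overridden through `...` (passed to [solver_config()]).
#' @param report `"native"` reports each species in the quantity kind of
#'   its initial specification (amount or concentration);
#'   `"amount"`/`"concentration"` force one view for all non-substance
#'   species.
#' @param constraint_listener optional function(time, message) notified
#'   on every constraint violation (violations never stop the
#'   simulation).
#' @param ... settings forwarded to [solver_config()] when `config` is
#'   not given.
#' @return Object of class `sbml_simulation`: list with `table` (a
#'   [result_table] on the output grid), `events` (data frame of
#'   firings), `constraints` (data frame of violations),
#'   `max_algebraic_residual`, and `settings`.
#' @export
simulate_sbml <- function(model, t_end, t0 = 0, config = NULL,
                          report = c("native", "amount", "concentration"),
                          constraint_listener = NULL, ...) {
  report <- match.arg(report)
  if (is.character(model)) model <- read_sbml(model)$model
  if (inherits(model, "sbml_interpreter")) {
    sim <- model
  } else {
    sim <- sbml_interpreter(model)
  }
  if (is.null(config)) config <- solver_config(...)
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  Q0 <- sim_initialize(sim, t0)
  ev0 <- sim_process_events(sim, Q0, t0)
  Q0 <- ev0$Q
  history_append(sim$history, t0, Q0)
  ev0_fired <- data.frame(time = ev0$fired$time, event = ev0$fired$event,
                          stringsAsFactors = FALSE)

  sys <- as_ode_system(sim, Q0, constraint_listener)
  viol0 <- check_constraints(sim, Q0, t0, constraint_listener)

  tab <- integrate_system(sys, config, t0 = t0, tT = t_end)
  fired <- rbind(ev0_fired, attr(tab, "fired"))

  values <- tab$values
  if (report != "amount") {
    for (sp in sim$model$species) {
      conc_view <- if (report == "concentration") {
        !isTRUE(sp$has_only_substance_units)
      } else {
        !isTRUE(sp$has_only_substance_units) &&
          identical(sp$initial_is_amount, FALSE)
      }
      if (conc_view)
        values[, sp$id] <- values[, sp$id] / values[, sp$compartment]
    }
  }
  out_tab <- result_table(tab$times, values,
                          fired = fired, n_steps = attr(tab, "n_steps"))

  acc <- sys$accumulator
  constraints <- if (length(acc$constraints) > 0L || nrow(viol0) > 0L)
    do.call(rbind, c(list(viol0), acc$constraints))
  else data.frame(time = numeric(0), message = character(0),
                  stringsAsFactors = FALSE)

  structure(list(table = out_tab, events = fired,
                 constraints = constraints,
                 max_algebraic_residual = acc$max_residual,
                 step_times = acc$step_times,
                 interpreter = sim,
                 settings = config),
            class = "sbml_simulation")
}

#' @export
print.sbml_simulation <- function(x, ...) {
  cat("<sbml_simulation: ", length(x$table$times), " output points, ",
      nrow(x$events), " event firing(s), ",
      nrow(x$constraints), " constraint violation(s)>\n", sep = "")
  invisible(x)
}
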