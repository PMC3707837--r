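## The SBML interpreter: builds the unified syntax graph for a model,
## initializes the state vector, and computes derivatives
## Qdot = g(Q, t) + N v(Q, t), with rules, constraints, and events
## evaluated against the shared graph.
##
## Species state is stored as AMOUNT internally.  Kinetic laws (and any
## other expression) see a species as amount / compartment size whenever
## hasOnlySubstanceUnits is false, and writes to such species
## (assignment rules, event assignments) are interpreted as
## concentrations and converted back.  This keeps the stoichiometric
## update additive even when compartment sizes change.

#' Build an SBML interpreter
#'
#' Converts algebraic rules to assignment rules, interns every
#' mathematical expression of the model into one shared syntax graph,
#' indexes the state vector, and topologically sorts the assignment
#' rules.
#'
#' @param model an `sbml_model` (validated; call [validate_model()]
#'   first for a full violation report).
#' @return An object of class `sbml_interpreter`.
#' @export
sbml_interpreter <- function(model) {
  viol <- validate_model(model)
  if (length(viol) > 0L)
    stop("model is invalid:\n  ", paste(viol, collapse = "\n  "),
         call. = FALSE)
  model <- convert_algebraic_rules(model)

  sim <- new.env(parent = emptyenv())
  sim$model <- model
  sim$index <- build_state_index(model)
  sim$graph <- syntax_graph()
  g <- sim$graph

  ## species evaluated as concentration: amount / compartment size
  cd <- character(0)
  for (sp in model$species)
    if (!isTRUE(sp$has_only_substance_units))
      cd[[sp$id]] <- sp$compartment
  sim$conc_div <- if (length(cd) > 0L) as.list(cd) else NULL

  ## --- merge all mathematics into the single syntax graph -------------
  sim$kin_nodes <- lapply(model$reactions, function(rx)
    if (is.null(rx$kinetic_law)) NULL else intern(rx$kinetic_law, g))
  sim$stoich <- lapply(model$reactions, function(rx) {
    prep <- function(refs, sign) lapply(refs, function(ref) {
      sp <- model$species[[ref$species]]
      list(species = ref$species, sign = sign,
           skip = is.null(sp) || isTRUE(sp$boundary_condition) ||
                  isTRUE(sp$constant),
           value = ref$stoichiometry,
           node = if (is.null(ref$stoich_math)) NULL
                  else intern(ref$stoich_math, g),
           gov = if (!is.null(ref$stoich_id) && !is.na(ref$stoich_id))
                   ref$stoich_id else NULL)
    })
    c(prep(rx$reactants, -1), prep(rx$products, +1))
  })

  asn <- list()
  sim$rate_rules <- list()
  for (r in model$rules) {
    if (r$kind == "assignment") {
      asn[[length(asn) + 1L]] <- list(variable = r$variable,
                                      node = intern(r$math, g))
    } else if (r$kind == "rate") {
      sim$rate_rules[[length(sim$rate_rules) + 1L]] <-
        list(variable = r$variable, node = intern(r$math, g))
    }
  }
  sim$assignment_rules <- topo_sort_rules(asn)
  sim$algebraic_nodes <- lapply(model$algebraic_originals %||% list(),
                                intern, graph = g)
  sim$initial_assignments <- lapply(model$initial_assignments,
    function(ia) list(variable = ia$variable, node = intern(ia$math, g)))
  sim$event_nodes <- lapply(model$events, function(ev) list(
    trigger = intern(ev$trigger, g),
    priority = if (is.null(ev$priority)) NULL else intern(ev$priority, g),
    delay = if (is.null(ev$delay)) NULL else intern(ev$delay, g),
    assignments = lapply(ev$assignments, function(a)
      list(variable = a$variable, math = intern(a$math, g)))))
  sim$constraint_nodes <- lapply(model$constraints, function(cn)
    list(node = intern(cn$math, g), message = cn$message))

  ## events operate on the interned nodes
  ev_interned <- model$events
  for (i in seq_along(ev_interned)) {
    ev_interned[[i]]$trigger <- sim$event_nodes[[i]]$trigger
    ev_interned[[i]]$priority <- sim$event_nodes[[i]]$priority
    ev_interned[[i]]$delay <- sim$event_nodes[[i]]$delay
    ev_interned[[i]]$assignments <- lapply(
      sim$event_nodes[[i]]$assignments, function(a)
        list(variable = a$variable, math = a$math))
  }
  sim$events <- ev_interned
  sim$ectx <- event_context(ev_interned)

  sim$t0 <- 0
  sim$history <- NULL
  sim$has_delay <- length(grep("^d\\(", ls(g$store, all.names = TRUE))) > 0L
  sim$zero_dQ <- stats::setNames(numeric(length(sim$index$ids)),
                                 sim$index$ids)

  ## is the derivative field explicitly time-dependent?  (lets the
  ## Rosenbrock stepper skip the df/dt finite difference)
  depends_on_time <- function(node) {
    if (is.null(node)) return(FALSE)
    if (node$kind %in% c("time", "delay")) return(TRUE)
    if (!is.null(node$args))
      return(any(vapply(node$args, depends_on_time, logical(1))))
    FALSE
  }
  deriv_nodes <- c(sim$kin_nodes,
                   lapply(sim$rate_rules, `[[`, "node"),
                   lapply(sim$assignment_rules, `[[`, "node"),
                   unlist(lapply(sim$stoich, function(refs)
                     lapply(refs, `[[`, "node")), recursive = FALSE))
  sim$autonomous <- !any(vapply(deriv_nodes, depends_on_time, logical(1)))
  class(sim) <- "sbml_interpreter"
  sim
}

#' @export
print.sbml_interpreter <- function(x, ...) {
  cat("<sbml_interpreter: ", length(x$index$ids), " state quantities, ",
      graph_size(x$graph), " graph nodes>\n", sep = "")
  invisible(x)
}

.empty_violations <- data.frame(time = numeric(0), message = character(0),
                                stringsAsFactors = FALSE)

## dependency-ordered assignment rules (rule variables only)
topo_sort_rules <- function(rules) {
  n <- length(rules)
  if (n <= 1L) return(rules)
  vars <- vapply(rules, `[[`, character(1), "variable")
  deps <- lapply(rules, function(r) {
    ## symbols of an interned node
    syms <- node_symbols(r$node)
    which(vars %in% syms)
  })
  order <- integer(0)
  state <- integer(n)  # 0 unvisited, 1 in progress, 2 done
  visit <- function(i) {
    if (state[i] == 2L) return(invisible())
    if (state[i] == 1L)
      stop("circular dependency among assignment rules (variables: ",
           paste(vars, collapse = ", "), ")", call. = FALSE)
    state[i] <<- 1L
    for (j in deps[[i]]) visit(j)
    state[i] <<- 2L
    order <<- c(order, i)
  }
  for (i in seq_len(n)) visit(i)
  rules[order]
}

node_symbols <- function(node) {
  kind <- node$kind
  if (kind == "symbol") return(node$id)
  if (!is.null(node$args))
    return(unique(unlist(lapply(node$args, node_symbols))))
  character(0)
}

## single expression evaluation at (Q, t) in a fresh epoch
sim_eval <- function(sim, node, Q, t) {
  graph_new_epoch(sim$graph)
  eval_cached(node, sim$graph, sim_ctx(sim, Q, t))
}

## evaluation context over the named state vector (all symbols resolve
## after validation, so the list conversion of eval_ast is not needed)
sim_ctx <- function(sim, Q, t) {
  list(Q = Q, t = t, t0 = sim$t0, conc_div = sim$conc_div,
       history = sim$history, bindings = NULL)
}

## write a value to a quantity, honoring species concentration units
sim_write <- function(sim, Q, var, value) {
  sp <- sim$model$species[[var]]
  if (!is.null(sp) && !isTRUE(sp$has_only_substance_units))
    value <- value * Q[[sp$compartment]]
  Q[[var]] <- value
  Q
}

#' Apply all assignment rules (including converted algebraic rules)
#'
#' Rules are evaluated in dependency order (topological sort), so a
#' single pass reaches the fixed point; chained rules give the same
#' result regardless of their document order.
#'
#' @param sim an [sbml_interpreter()].
#' @param Q named numeric state vector.
#' @param t time.
#' @return The updated state vector.
#' @export
apply_rules <- function(sim, Q, t) {
  for (r in sim$assignment_rules) {
    graph_new_epoch(sim$graph)
    v <- eval_cached(r$node, sim$graph, sim_ctx(sim, Q, t))
    Q <- sim_write(sim, Q, r$variable, v)
  }
  Q
}

#' Compute the derivative vector Qdot at a state
#'
#' Starts from the null vector, writes the rate rules g(Q, t) into their
#' dimensions, then adds, for every reaction channel, the product of each
#' participant's stoichiometry and the reaction velocity.  Stoichiometries
#' given by expressions (StoichiometryMath) or governed by an assignable
#' species-reference identifier are re-evaluated at every call.  Boundary
#' and constant species receive no reaction contribution.
#'
#' @param sim an [sbml_interpreter()].
#' @param Q named numeric state vector (assignment rules already
#'   applied).
#' @param t time.
#' @return Named numeric derivative vector aligned with the state index.
#' @export
compute_derivatives <- function(sim, Q, t) {
  dQ <- sim$zero_dQ
  if (is.null(dQ) || length(dQ) != length(Q))
    dQ <- stats::setNames(numeric(length(Q)), names(Q))
  graph_new_epoch(sim$graph)
  ctx <- sim_ctx(sim, Q, t)
  g <- sim$graph

  for (r in sim$rate_rules) {
    v <- eval_cached(r$node, g, ctx)
    var <- r$variable
    sp <- sim$model$species[[var]]
    if (!is.null(sp) && !isTRUE(sp$has_only_substance_units))
      v <- v * Q[[sp$compartment]]  # concentration rate -> amount rate
    dQ[[var]] <- v
  }

  for (j in seq_along(sim$kin_nodes)) {
    kn <- sim$kin_nodes[[j]]
    if (is.null(kn)) next
    v <- eval_cached(kn, g, ctx)
    if (!is.finite(v))
      stop("non-finite velocity in reaction '",
           sim$model$reactions[[j]]$id, "' at t = ", format(t),
           call. = FALSE)
    for (ref in sim$stoich[[j]]) {
      if (ref$skip) next
      n <- if (!is.null(ref$gov)) Q[[ref$gov]]
           else if (!is.null(ref$node)) eval_cached(ref$node, g, ctx)
           else ref$value
      dQ[[ref$species]] <- dQ[[ref$species]] + ref$sign * n * v
    }
  }
  dQ
}

#' Check all constraints at a state
#'
#' Every constraint expression is evaluated; each one that is false
#' produces one notification (time, message) routed to `listener`.  A
#' violated constraint never stops the simulation.
#'
#' @param sim an [sbml_interpreter()].
#' @param Q named numeric state vector.
#' @param t time.
#' @param listener function(time, message), called once per violation;
#'   defaults to a logged message.
#' @return Data frame of violations with columns `time`, `message`.
#' @export
check_constraints <- function(sim, Q, t, listener = NULL) {
  if (length(sim$constraint_nodes) == 0L) return(.empty_violations)
  graph_new_epoch(sim$graph)
  ctx <- sim_ctx(sim, Q, t)
  times <- numeric(0); msgs <- character(0)
  for (cn in sim$constraint_nodes) {
    ok <- eval_cached(cn$node, sim$graph, ctx)
    if (!isTRUE(ok)) {
      times <- c(times, t); msgs <- c(msgs, cn$message)
      if (!is.null(listener)) listener(t, cn$message)
    }
  }
  data.frame(time = times, message = msgs, stringsAsFactors = FALSE)
}

## residuals of the original algebraic expressions (should stay ~ 0)
algebraic_residuals <- function(sim, Q, t) {
  if (length(sim$algebraic_nodes) == 0L) return(numeric(0))
  graph_new_epoch(sim$graph)
  ctx <- sim_ctx(sim, Q, t)
  vapply(sim$algebraic_nodes, function(nd)
    as.numeric(eval_cached(nd, sim$graph, ctx)), numeric(1))
}

#' Initialize the state vector at the simulation start
#'
#' Order: (1) raw initial values from the model; (2) initial assignments
#' and assignment rules (including converted algebraic rules) iterated to
#' a fixed point; (3) species initial concentrations converted to amounts
#' with the compartment sizes that result from step 2.  Event trigger
#' memory is then initialized.
#'
#' @param sim an [sbml_interpreter()].
#' @param t0 start time (default 0; arbitrary start times are allowed).
#' @return The initial state vector (named, species as amounts).
#' @export
sim_initialize <- function(sim, t0 = 0) {
  sim$t0 <- t0
  model <- sim$model
  ids <- sim$index$ids
  Q <- stats::setNames(rep(NA_real_, length(ids)), ids)

  for (cp in model$compartments)
    Q[[cp$id]] <- if (is.na(cp$size)) 1 else cp$size
  conc0 <- character(0)  # species whose raw initial value is a concentration
  for (sp in model$species) {
    if (is.na(sp$initial_value)) { Q[[sp$id]] <- 0; next }
    if (sp$initial_is_amount) {
      Q[[sp$id]] <- sp$initial_value
    } else {
      conc0 <- c(conc0, sp$id)
      Q[[sp$id]] <- sp$initial_value * Q[[sp$compartment]]
    }
  }
  for (p in model$parameters)
    Q[[p$id]] <- if (is.na(p$value)) 0 else p$value
  for (s in model$stoich_ids)
    Q[[s$id]] <- s$value

  ## quantities written by initial assignments or assignment rules keep
  ## those values; stored initial concentrations track compartment sizes
  written <- c(vapply(sim$initial_assignments, `[[`, character(1),
                      "variable"),
               vapply(sim$assignment_rules, `[[`, character(1),
                      "variable"))
  conc0 <- setdiff(conc0, written)
  conc_vals <- vapply(conc0, function(id)
    model$species[[id]]$initial_value, numeric(1))

  reconcile <- function(Q) {
    for (k in seq_along(conc0)) {
      id <- conc0[k]
      Q[[id]] <- conc_vals[[k]] * Q[[model$species[[id]]$compartment]]
    }
    Q
  }

  max_pass <- length(sim$initial_assignments) +
    length(sim$assignment_rules) + 2L
  for (pass in seq_len(max_pass)) {
    Qold <- Q
    Q <- reconcile(Q)
    for (ia in sim$initial_assignments) {
      graph_new_epoch(sim$graph)
      v <- eval_cached(ia$node, sim$graph, sim_ctx(sim, Q, t0))
      Q <- sim_write(sim, Q, ia$variable, v)
    }
    Q <- apply_rules(sim, Q, t0)
    if (isTRUE(all.equal(Qold, Q, tolerance = 0))) break
    if (pass == max_pass)
      stop("initial assignments and rules did not reach a fixed point ",
           "(circular dependency?)", call. = FALSE)
  }

  bad <- names(Q)[!is.finite(Q)]
  if (length(bad) > 0L)
    stop("no resolvable initial value for: ",
         paste(bad, collapse = ", "), call. = FALSE)

  sim$history <- history_buffer(t0, Q)
  init_triggers(sim$ectx, function(node) {
    graph_new_epoch(sim$graph)
    eval_cached(node, sim$graph, sim_ctx(sim, Q, t0))
  })
  Q
}

## evaluator bundle handed to the event scheduler; reuses the evaluation
## epoch (and its node cache) while the state is unchanged
sim_evalf <- function(sim) {
  last_Q <- NULL
  last_t <- NULL
  ctx <- NULL
  function(node, Q, t) {
    if (is.null(ctx) || !identical(Q, last_Q) || !identical(t, last_t)) {
      graph_new_epoch(sim$graph)
      ctx <<- sim_ctx(sim, Q, t)
      last_Q <<- Q
      last_t <<- t
    }
    eval_cached(node, sim$graph, ctx)
  }
}

#' Process events at the current time for an interpreter
#'
#' Thin wrapper connecting the event scheduler to the interpreter's
#' graph, rules, and species unit handling.
#'
#' @param sim an [sbml_interpreter()].
#' @param Q named numeric state vector.
#' @param t time.
#' @return List with `Q` and `fired` (see [process_events()]).
#' @export
sim_process_events <- function(sim, Q, t) {
  if (length(sim$events) == 0L)
    return(list(Q = Q, fired = list(time = numeric(0),
                                    event = character(0)),
                n_fired = 0L, transitions = 0L))
  process_events(sim$ectx, Q, t, sim_evalf(sim),
                 apply_rules_fn = function(Q, t) apply_rules(sim, Q, t),
                 species = sim$model$species)
}
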