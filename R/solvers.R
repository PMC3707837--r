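## Numerical integration, strictly separated from the system definition:
## any object satisfying the small system interface below can be driven
## by every solver.  The adaptive Rosenbrock method refines its step size
## when rule/event processing changes the state after an accepted step
## (h := h/10, recompute from the pre-step state), so event times are
## localized to within the minimum step size h_min.

#' Solver configuration
#'
#' @param solver one of `"rosenbrock"` (adaptive, default), `"rk4"`,
#'   `"euler"` (fixed step).
#' @param atol absolute error tolerance (default `1e-12`).
#' @param rtol relative error tolerance (default `1e-6`).
#' @param h_min minimum step size; default `1e-10` times the simulated
#'   span.  Bounds the precision of event-time localization.
#' @param h_max maximum step size; default one twentieth of the span
#'   (also bounds the dense-output interpolation error).
#' @param output_steps number of equidistant output intervals.
#' @param internal_steps sub-steps per output interval for the
#'   fixed-step solvers.
#' @param seed integer seed for the event tie-breaking RNG, or `NULL`.
#' @param max_step_attempts guard on the total number of step attempts.
#' @return List of class `solver_config`.
#' @export
solver_config <- function(solver = c("rosenbrock", "rk4", "euler"),
                          atol = 1e-12, rtol = 1e-6,
                          h_min = NULL, h_max = NULL,
                          output_steps = 100L, internal_steps = 1L,
                          seed = NULL, max_step_attempts = 5e6) {
  solver <- match.arg(solver)
  stopifnot(atol > 0, rtol > 0, output_steps >= 1L, internal_steps >= 1L)
  structure(list(solver = solver, atol = atol, rtol = rtol,
                 h_min = h_min, h_max = h_max,
                 output_steps = as.integer(output_steps),
                 internal_steps = as.integer(internal_steps),
                 seed = seed, max_step_attempts = max_step_attempts),
            class = "solver_config")
}

## extract the derivative function from a system or bare function
sys_fun <- function(system) {
  if (is.function(system)) return(system)
  f <- system$deriv
  ar <- system$apply_rules_at
  if (is.null(ar)) return(f)
  function(Q, t) f(ar(Q, t), t)
}

#' Construct a plain mathematical ODE system
#'
#' Wraps a derivative function in the system interface, with no rules,
#' events, or SBML structure — used for testing solvers in isolation and
#' for custom differential equations.
#'
#' @param deriv function(Q, t) returning the derivative vector.
#' @param Q0 named numeric initial state.
#' @param t0 start time.
#' @return An object of class `ode_system`.
#' @export
math_system <- function(deriv, Q0, t0 = 0) {
  structure(list(ids = names(Q0), state0 = Q0, t0 = t0,
                 deriv = deriv, apply_rules_at = NULL, post_step = NULL,
                 snapshot = NULL, restore = NULL, on_commit = NULL),
            class = "ode_system")
}

#' One explicit Euler step
#'
#' @param system an `ode_system` or a derivative function(Q, t).
#' @param Q named numeric state.
#' @param t time.
#' @param h step size (> 0).
#' @return A step outcome: list with `accepted`, `t_new`, `Q_new`,
#'   `h_used`, `h_next`, `error_estimate`.
#' @export
euler_step <- function(system, Q, t, h) {
  if (h <= 0) stop("step size must be positive", call. = FALSE)
  f <- sys_fun(system)
  Q_new <- Q + h * f(Q, t)
  list(accepted = TRUE, t_new = t + h, Q_new = Q_new, h_used = h,
       h_next = h, error_estimate = 0)
}

#' One classical fourth-order Runge-Kutta step
#'
#' @inheritParams euler_step
#' @return A step outcome (see [euler_step()]).
#' @export
rk4_step <- function(system, Q, t, h) {
  if (h <= 0) stop("step size must be positive", call. = FALSE)
  f <- sys_fun(system)
  k1 <- f(Q, t)
  k2 <- f(Q + h / 2 * k1, t + h / 2)
  k3 <- f(Q + h / 2 * k2, t + h / 2)
  k4 <- f(Q + h * k3, t + h)
  Q_new <- Q + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  list(accepted = TRUE, t_new = t + h, Q_new = Q_new, h_used = h,
       h_next = h, error_estimate = 0)
}

## forward-difference Jacobian of f at (Q, t)
fd_jacobian <- function(f, Q, t, f0) {
  n <- length(Q)
  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    dy <- sqrt(.Machine$double.eps) * max(abs(Q[[i]]), 1e-6)
    Qp <- Q
    Qp[[i]] <- Qp[[i]] + dy
    J[, i] <- (f(Qp, t) - f0) / dy
  }
  J
}

## Shampine's parameterization of the 4th-order Rosenbrock method with
## embedded 3rd-order error estimate
.ros <- list(
  gam = 0.5,
  a21 = 2, a31 = 48 / 25, a32 = 6 / 25,
  c21 = -8, c31 = 372 / 25, c32 = 12 / 5,
  c41 = -112 / 125, c42 = -54 / 125, c43 = -2 / 5,
  b1 = 19 / 9, b2 = 1 / 2, b3 = 25 / 108, b4 = 125 / 108,
  e1 = 17 / 54, e2 = 7 / 36, e3 = 0, e4 = 125 / 108,
  c1x = 1 / 2, c2x = -3 / 2, c3x = 121 / 50, c4x = 29 / 250,
  a2x = 1, a3x = 3 / 5)

#' One adaptive fourth-order Rosenbrock step
#'
#' Linearly implicit stiff integrator: four stages sharing one LU
#' factorization of `I/(gamma h) - J`, with the Jacobian `J` obtained by
#' forward finite differences and an embedded third-order solution for
#' error estimation.  The step is accepted when the scaled error norm is
#' at most 1; the outcome carries the controller's proposed next step
#' size in either case.
#'
#' @inheritParams euler_step
#' @param config a [solver_config()] (tolerances).
#' @param cache optional environment reused across attempts: when a step
#'   is retried from the identical `(Q, t)` (error-control rejection or
#'   event-localization rewind), the derivative, Jacobian and time
#'   derivative from the first attempt are reused.
#' @return A step outcome (see [euler_step()]); `accepted` may be
#'   `FALSE`, in which case `h_next` holds the reduced step to retry.
#' @export
rosenbrock_step <- function(system, Q, t, h, config = solver_config(),
                            cache = NULL) {
  if (h <= 0) stop("step size must be positive", call. = FALSE)
  f <- sys_fun(system)
  r <- .ros
  n <- length(Q)
  if (!is.null(cache) && identical(cache$Q, Q) && identical(cache$t, t)) {
    f0 <- cache$f0
    J <- cache$J
    dfdt <- cache$dfdt
  } else {
    f0 <- f(Q, t)
    J <- fd_jacobian(f, Q, t, f0)
    if (!is.function(system) && isTRUE(system$autonomous)) {
      dfdt <- numeric(n)
    } else {
      dt <- sqrt(.Machine$double.eps) * max(abs(t), abs(h), 1e-6)
      dfdt <- (f(Q, t + dt) - f0) / dt
    }
    if (!is.null(cache)) {
      cache$Q <- Q; cache$t <- t
      cache$f0 <- f0; cache$J <- J; cache$dfdt <- dfdt
    }
  }

  A <- diag(1 / (r$gam * h), n) - J
  lu <- tryCatch(solve(A), error = function(e) NULL)
  if (is.null(lu)) {
    return(list(accepted = FALSE, t_new = t, Q_new = Q, h_used = h,
                h_next = h / 2, error_estimate = Inf))
  }
  g1 <- drop(lu %*% (f0 + h * r$c1x * dfdt))
  f2 <- f(Q + r$a21 * g1, t + r$a2x * h)
  g2 <- drop(lu %*% (f2 + h * r$c2x * dfdt + r$c21 * g1 / h))
  y3 <- Q + r$a31 * g1 + r$a32 * g2
  f3 <- f(y3, t + r$a3x * h)
  g3 <- drop(lu %*% (f3 + h * r$c3x * dfdt +
                       (r$c31 * g1 + r$c32 * g2) / h))
  g4 <- drop(lu %*% (f3 + h * r$c4x * dfdt +
                       (r$c41 * g1 + r$c42 * g2 + r$c43 * g3) / h))
  Q_new <- Q + r$b1 * g1 + r$b2 * g2 + r$b3 * g3 + r$b4 * g4
  err <- r$e1 * g1 + r$e2 * g2 + r$e3 * g3 + r$e4 * g4

  sk <- config$atol + config$rtol * pmax(abs(Q), abs(Q_new))
  errnorm <- sqrt(mean((err / sk)^2))
  if (!is.finite(errnorm)) errnorm <- Inf

  if (errnorm <= 1) {
    fac <- if (errnorm == 0) 5 else min(5, max(0.2, 0.9 * errnorm^-0.25))
    list(accepted = TRUE, t_new = t + h, Q_new = Q_new, h_used = h,
         h_next = h * fac, error_estimate = errnorm)
  } else {
    fac <- min(0.5, max(0.1, 0.9 * errnorm^(-1 / 3)))
    list(accepted = FALSE, t_new = t, Q_new = Q, h_used = h,
         h_next = h * fac, error_estimate = errnorm)
  }
}

## cubic Hermite interpolation between accepted steps (dense output)
hermite <- function(t0, Q0, d0, t1, Q1, d1, tq) {
  hh <- t1 - t0
  if (hh <= 0) return(Q1)
  s <- (tq - t0) / hh
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * Q0 + h10 * hh * d0 + h01 * Q1 + h11 * hh * d1
}

#' Integrate a system over a time interval
#'
#' Main loop: advance by solver steps; after each accepted step apply the
#' system's assignment rules and process its events.  If that changes the
#' state, the step is rewound to the pre-step state and retried with
#' h := h/10, until the processing no longer changes the state or h
#' reaches `h_min` — so the precision of event timing is set by `h_min`.
#' Output is interpolated (cubic Hermite from endpoint derivatives) onto
#' an equidistant grid of `output_steps + 1` points; interpolation never
#' alters the accepted-step sequence.
#'
#' @param system an `ode_system` (see [math_system()] and
#'   [as_ode_system()]).
#' @param config a [solver_config()].
#' @param t0,tT integration interval (`t0 < tT`).
#' @return A [result_table] (attribute `fired` holds the event log,
#'   attribute `n_steps` the number of accepted steps).
#' @export
integrate_system <- function(system, config = solver_config(),
                             t0 = system$t0 %||% 0, tT) {
  stopifnot(t0 < tT)
  span <- tT - t0
  h_min <- config$h_min %||% (1e-10 * span)
  h_max <- config$h_max %||% (span / 20)
  if (h_min >= h_max) stop("h_min must be smaller than h_max",
                           call. = FALSE)
  nout <- config$output_steps
  grid <- t0 + span * (0:nout) / nout
  ids <- system$ids
  values <- matrix(NA_real_, nrow = nout + 1L, ncol = length(ids),
                   dimnames = list(NULL, ids))
  apply_rules_at <- system$apply_rules_at %||% function(Q, t) Q

  Q <- system$state0
  t <- t0
  values[1L, ] <- Q
  fired_all <- list()
  tiny <- 1e-12 * (1 + abs(tT))
  gi <- 2L               # next grid row to fill
  n_acc <- 0L

  f <- sys_fun(system)
  fixed <- config$solver %in% c("euler", "rk4")
  stepper <- switch(config$solver,
    euler = function(Q, t, h) euler_step(system, Q, t, h),
    rk4 = function(Q, t, h) rk4_step(system, Q, t, h),
    rosenbrock = local({
      cache <- new.env(parent = emptyenv())
      function(Q, t, h) rosenbrock_step(system, Q, t, h, config, cache)
    }))

  commit_grid <- function(t_prev, Q_prev, t_new, Q_base, Q_final) {
    d_prev <- NULL
    d_base <- NULL
    while (gi <= nout + 1L && grid[gi] <= t_new + tiny) {
      tg <- grid[gi]
      row <- if (tg >= t_new - tiny) {
        Q_final
      } else {
        ## dense output: cubic Hermite from endpoint derivatives,
        ## computed only when a grid point falls inside the step
        if (is.null(d_prev)) {
          d_prev <- f(Q_prev, t_prev)
          d_base <- f(Q_base, t_new)
        }
        qi <- hermite(t_prev, Q_prev, d_prev, t_new, Q_base, d_base, tg)
        apply_rules_at(stats::setNames(qi, ids), tg)
      }
      values[gi, ] <<- row
      gi <<- gi + 1L
    }
  }

  h <- if (fixed) span / nout / config$internal_steps else
    min(h_max, span / 100)
  attempts <- 0L

  while (t < tT - tiny) {
    if (!fixed) h <- min(h, h_max, tT - t)
    attempts <- attempts + 1L
    if (attempts > config$max_step_attempts)
      stop("integration exceeded the step-attempt budget at t = ",
           format(t), call. = FALSE)

    out <- stepper(Q, t, h)
    if (!out$accepted) {
      if (h <= h_min * (1 + 1e-9))
        stop("step size underflow (h_min = ", format(h_min),
             ") during error control at t = ", format(t), call. = FALSE)
      h <- max(out$h_next, h_min)
      next
    }
    t_new <- out$t_new
    Q_base <- apply_rules_at(out$Q_new, t_new)

    changed <- FALSE
    fired <- NULL
    if (!is.null(system$post_step)) {
      snap <- if (!is.null(system$snapshot)) system$snapshot() else NULL
      res <- system$post_step(Q_base, t_new)
      changed <- isTRUE(res$changed)
      if (changed && !fixed && h > h_min * (1 + 1e-9)) {
        ## state changed by events: rewind and retry with h/10 (Figure-4
        ## refinement); precision of event timing is set by h_min
        if (!is.null(system$restore)) system$restore(snap)
        h <- max(h / 10, h_min)
        next
      }
      fired <- res$fired
      Q_final <- res$Q
    } else {
      Q_final <- Q_base
    }

    commit_grid(t, Q, t_new, Q_base, Q_final)
    if (!is.null(fired) && length(fired$time) > 0L)
      fired_all[[length(fired_all) + 1L]] <- fired
    if (!is.null(system$on_commit)) system$on_commit(Q_final, t_new)

    Q <- Q_final
    t <- t_new
    n_acc <- n_acc + 1L
    if (!fixed) h <- min(max(out$h_next, h_min), h_max)
  }

  ## numerical end-of-interval guard: fill any remaining rows
  while (gi <= nout + 1L) {
    values[gi, ] <- Q
    gi <- gi + 1L
  }

  fired <- data.frame(
    time = unlist(lapply(fired_all, `[[`, "time")) %||% numeric(0),
    event = unlist(lapply(fired_all, `[[`, "event")) %||% character(0),
    stringsAsFactors = FALSE)
  result_table(grid, values, fired = fired, n_steps = n_acc)
}
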