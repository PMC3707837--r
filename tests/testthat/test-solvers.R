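# Numerical solvers and the event-localizing integration loop.

decay <- function(Q, t) -Q

test_that("Euler steps match the forward-difference definition", {
  out <- euler_step(decay, c(S = 1), 0, 0.1)
  expect_equal(out$Q_new[["S"]], 0.9)
  expect_true(out$accepted)

  zero <- function(Q, t) 0 * Q
  expect_equal(euler_step(zero, c(S = 2), 0, 0.5)$Q_new[["S"]], 2)

  # first-order global accuracy at small steps
  Q <- c(S = 1); t <- 0; h <- 1e-4
  for (i in 1:10000) { Q <- euler_step(decay, Q, t, h)$Q_new; t <- t + h }
  expect_lt(abs(Q[["S"]] - exp(-1)), 1e-4)
})

test_that("one classical Runge-Kutta step reproduces the exponential to O(h^5)", {
  out <- rk4_step(decay, c(S = 1), 0, 0.1)
  # for y' = -y one RK4 step is the degree-4 Taylor polynomial of e^{-h}
  h <- 0.1
  taylor4 <- 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24
  expect_equal(out$Q_new[["S"]], taylor4, tolerance = 1e-12)
  expect_lt(abs(out$Q_new[["S"]] - exp(-h)), 1e-7)   # O(h^5) agreement
  # h -> 0 limit: state unchanged
  out0 <- rk4_step(decay, c(S = 1), 0, 1e-12)
  expect_equal(out0$Q_new[["S"]], 1, tolerance = 1e-10)
})

test_that("refinement studies recover convergence orders 1 and 4", {
  run_fixed <- function(stepper, h) {
    Q <- c(S = 1); t <- 0
    for (i in seq_len(round(1 / h))) {
      Q <- stepper(decay, Q, t, h)$Q_new
      t <- t + h
    }
    abs(Q[["S"]] - exp(-1))
  }
  hs <- 1 / c(10, 20, 40, 80, 160)
  err_e <- vapply(hs, function(h) run_fixed(euler_step, h), numeric(1))
  err_r <- vapply(hs, function(h) run_fixed(rk4_step, h), numeric(1))
  slope_e <- unname(stats::coef(stats::lm(log(err_e) ~ log(hs)))[2])
  slope_r <- unname(stats::coef(stats::lm(log(err_r) ~ log(hs)))[2])
  expect_gt(slope_e, 0.9); expect_lt(slope_e, 1.1)
  expect_gt(slope_r, 3.8); expect_lt(slope_r, 4.2)
})

test_that("Rosenbrock tracks the exponential within tolerance", {
  cfg <- solver_config("rosenbrock", atol = 1e-12, rtol = 1e-6)
  tab <- integrate_system(math_system(decay, c(S = 1)), cfg, 0, 1)
  err <- abs(result_column(tab, "S") - exp(-tab$times))
  expect_lt(max(err / (1e-12 + 1e-6 * exp(-tab$times)) ), 1)
})

test_that("Rosenbrock accepts a constant system immediately and grows h", {
  zero <- function(Q, t) 0 * Q
  out <- rosenbrock_step(zero, c(S = 1), 0, 0.01, solver_config())
  expect_true(out$accepted)
  expect_gt(out$h_next, 0.01)   # controller proposes growth
})

test_that("step sizes shrink in the fast transient and recover later", {
  # stiff two-species system with an initial boundary layer
  fs <- function(Q, t)
    c(a = -800 * (Q[["a"]] - cos(Q[["b"]])), b = -Q[["b"]])
  cfg <- solver_config("rosenbrock", output_steps = 50L)
  sys <- math_system(fs, c(a = 0, b = 1))
  acc <- new.env(); acc$h <- numeric(0)
  sys$on_commit <- function(Q, t) acc$h <- c(acc$h, t)
  tab <- integrate_system(sys, cfg, 0, 5)
  steps <- diff(acc$h)
  early <- stats::median(steps[seq_len(5)])
  late <- stats::median(steps[seq(length(steps) - 5, length(steps))])
  expect_gt(late, 5 * early)   # monotone step-size recovery
})

test_that("any object satisfying the system interface runs on all solvers", {
  # a pure-math two-state oscillatorish system, no SBML anywhere
  f <- function(Q, t) c(x = Q[["y"]], y = -Q[["x"]])
  for (sv in c("euler", "rk4", "rosenbrock")) {
    cfg <- solver_config(sv, output_steps = 200L,
                         internal_steps = if (sv == "euler") 20L else 5L)
    tab <- integrate_system(math_system(f, c(x = 1, y = 0)), cfg, 0, 3.14)
    expect_equal(result_column(tab, "x")[201], cos(3.14),
                 tolerance = if (sv == "euler") 0.05 else 1e-4)
  }
})

test_that("without events or rules the grid is pure sampling of the solution", {
  m <- generate_fixture("exp_decay")$model
  cfg1 <- solver_config("rosenbrock", output_steps = 100L, seed = 1L)
  cfg2 <- solver_config("rosenbrock", output_steps = 50L, seed = 1L)
  r1 <- simulate_sbml(m, t_end = 1, config = cfg1)
  r2 <- simulate_sbml(m, t_end = 1, config = cfg2)
  # halving the output grid leaves the accepted-step sequence unchanged
  expect_identical(r1$step_times, r2$step_times)
  # and the coarse grid values equal the fine grid at shared times
  expect_equal(result_column(r2$table, "S"),
               result_column(r1$table, "S")[seq(1, 101, by = 2)],
               tolerance = 1e-12)
})

test_that("trigger crossings are localized to within h_min", {
  set.seed(12)
  for (rep in 1:10) {
    k <- stats::runif(1, 0.4, 2)
    thr <- stats::runif(1, 0.2, 0.8)
    t_true <- log(1 / thr) / k
    m <- sbml_model(
      compartments = list(c = mk_comp("c")),
      species = list(S1 = mk_species("S1", amount = 1)),
      parameters = list(P = mk_param("P", 0)),
      reactions = list(mk_reaction(
        "deg", list(mk_ref("S1")), list(),
        op_("times", num_(k), sym_("S1")))),
      events = list(mk_event("hit", op_("leq", sym_("S1"), num_(thr)),
                             list(mk_assign("P", num_(1))))))
    cfg <- solver_config("rosenbrock", h_min = 1e-7, rtol = 1e-10,
                         atol = 1e-14, output_steps = 20L, seed = 1L)
    res <- simulate_sbml(m, t_end = t_true * 1.5, config = cfg)
    expect_identical(nrow(res$events), 1L)
    expect_lt(abs(res$events$time - t_true), 1e-7 + 2e-8)
  }
})

test_that("step-size underflow raises a minimum-step error naming the time", {
  blow <- function(Q, t) c(S = 1e12 * Q[["S"]]^2)
  cfg <- solver_config("rosenbrock", h_min = 1e-4, rtol = 1e-10)
  expect_error(
    integrate_system(math_system(blow, c(S = 1)), cfg, 0, 10),
    "underflow|minimum|step")
})
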