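# Event scheduler: triggers, persistence, priorities, tie-breaking,
# delays, snapshots, atomic execution.

# direct evaluator over plain trees for scheduler-only tests
tree_evalf <- function(tree, Q, t) eval_ast(tree, Q, t)

test_that("rising trigger edges activate; initially-true triggers do not fire", {
  ev <- mk_event("e", op_("geq", ast_time(), num_(5)),
                 list(mk_assign("p", num_(1))))
  ctx <- event_context(list(ev))
  init_triggers(ctx, function(tr) eval_ast(tr, c(p = 0), t = 0))
  e1 <- function(tr) eval_ast(tr, c(p = 0), t = 4)
  update_triggers(ctx, c(p = 0), 4, e1)
  expect_false(ctx$states[[1]]$active)
  e2 <- function(tr) eval_ast(tr, c(p = 0), t = 5.2)
  update_triggers(ctx, c(p = 0), 5.2, e2)
  expect_true(ctx$states[[1]]$active)

  # trigger true at t0 with trigger_initial_value TRUE: no transition
  ev2 <- mk_event("e2", op_("geq", ast_time(), num_(0)),
                  list(mk_assign("p", num_(1))),
                  trigger_initial_value = TRUE)
  ctx2 <- event_context(list(ev2))
  init_triggers(ctx2, function(tr) eval_ast(tr, c(p = 0), t = 0))
  res <- process_events(ctx2, c(p = 0), 0, tree_evalf)
  expect_identical(res$n_fired, 0L)

  # with trigger_initial_value FALSE the same situation is a transition
  ev3 <- mk_event("e3", op_("geq", ast_time(), num_(0)),
                  list(mk_assign("p", num_(1))),
                  trigger_initial_value = FALSE)
  ctx3 <- event_context(list(ev3))
  init_triggers(ctx3, function(tr) eval_ast(tr, c(p = 0), t = 0))
  res3 <- process_events(ctx3, c(p = 0), 0, tree_evalf)
  expect_identical(res3$n_fired, 1L)
  expect_equal(res3$Q[["p"]], 1)
})

test_that("delayed triggers schedule pending executions with snapshots", {
  ev <- mk_event("d", op_("geq", ast_time(), num_(1)),
                 list(mk_assign("p", sym_("S"))),
                 delay = num_(2), use_trigger_time_values = TRUE)
  ctx <- event_context(list(ev))
  init_triggers(ctx, function(tr) eval_ast(tr, c(S = 7, p = 0), t = 0))
  update_triggers(ctx, c(S = 7, p = 0), 0,
                  function(tr) eval_ast(tr, c(S = 7, p = 0), 0))
  Qtrig <- c(S = 7, p = 0)
  update_triggers(ctx, Qtrig, 1, function(tr) eval_ast(tr, Qtrig, 1))
  pend <- ctx$states[[1]]$pending
  expect_length(pend, 1L)
  expect_equal(pend[[1]]$time, 3)          # execution at t + delay
  expect_equal(pend[[1]]$snapshot[["S"]], 7)

  # not due before its time
  res <- process_events(ctx, c(S = 1, p = 0), 2, tree_evalf)
  expect_identical(res$n_fired, 0L)
  # due at t = 3: assignment reads the trigger-time snapshot
  res <- process_events(ctx, c(S = 1, p = 0), 3, tree_evalf)
  expect_identical(res$n_fired, 1L)
  expect_equal(res$Q[["p"]], 7)
})

test_that("multiple pending executions stay sorted by execution time", {
  # delay expression varies between firings: delay = 5 - t
  ev <- mk_event("v", op_("geq", sym_("g"), num_(1)),
                 list(mk_assign("p", num_(1))),
                 delay = op_("minus", num_(5), ast_time()))
  ctx <- event_context(list(ev))
  init_triggers(ctx, function(tr) eval_ast(tr, c(g = 0, p = 0), t = 0))
  update_triggers(ctx, c(g = 0, p = 0), 0,
                  function(tr) eval_ast(tr, c(g = 0, p = 0), 0))
  # firings at t = 1 (exec 5) and t = 4.8 (exec 5.0), trigger released
  # in between; both pending executions must be kept in time order
  update_triggers(ctx, c(g = 1, p = 0), 1,
                  function(tr) eval_ast(tr, c(g = 1, p = 0), 1))
  update_triggers(ctx, c(g = 0, p = 0), 2,
                  function(tr) eval_ast(tr, c(g = 0, p = 0), 2))
  update_triggers(ctx, c(g = 1, p = 0), 4.8,
                  function(tr) eval_ast(tr, c(g = 1, p = 0), 4.8))
  times <- vapply(ctx$states[[1]]$pending, `[[`, numeric(1), "time")
  expect_length(times, 2L)
  expect_identical(times, sort(times))
})

test_that("choose_event honors strict maxima and ranks unset priorities last", {
  expect_identical(choose_event(1:2, c(2, 1)), 1L)
  expect_identical(choose_event(5L, NA_real_), 5L)
  # unset priorities lose against any defined priority
  expect_identical(choose_event(1:3, c(NA, 0.5, NA)), 2L)
})

test_that("tie-breaking among equal priorities is uniform", {
  set.seed(7)
  picks <- replicate(2000, choose_event(1:2, c(3, 3)))
  freq <- mean(picks == 1L)
  expect_gte(freq, 0.45)
  expect_lte(freq, 0.55)
})

test_that("assignments execute simultaneously (swap semantics)", {
  ev <- mk_event("swap", ast_bool(TRUE),
                 list(mk_assign("S1", sym_("S2")),
                      mk_assign("S2", sym_("S1"))))
  Q <- c(S1 = 1, S2 = 2)
  Q2 <- execute_event(ev, Q, Q, 0, tree_evalf)
  expect_equal(unname(Q2), c(2, 1))

  # zero assignments: state untouched
  ev0 <- mk_event("nop", ast_bool(TRUE), list())
  expect_identical(execute_event(ev0, Q, Q, 0, tree_evalf), Q)
})

test_that("halving a compartment preserves amounts and doubles concentrations", {
  m <- sbml_model(
    compartments = list(c = mk_comp("c", size = 2, constant = FALSE)),
    species = list(X = mk_species("X", conc = 3, hosu = FALSE,
                                  boundary = TRUE)),
    events = list(mk_event("halve", op_("geq", ast_time(), num_(1)),
                           list(mk_assign("c", op_("times", num_(0.5),
                                                   sym_("c")))))))
  res <- simulate_sbml(m, t_end = 2, config = solver_config(
    solver = "rosenbrock", output_steps = 20L, seed = 1L),
    report = "amount")
  amt <- result_column(res$table, "X")
  expect_equal(max(abs(amt - 6)), 0)        # amount 3 x 2 stays put
  sizes <- result_column(res$table, "c")
  conc <- amt / sizes
  expect_equal(conc[1], 3)
  expect_equal(conc[length(conc)], 6)       # concentration doubled
})

test_that("an event can enable another event within the same time step", {
  # A sets k; B triggers on k and fires at the same instant, after A
  mA <- mk_event("A", op_("geq", ast_time(), num_(1)),
                 list(mk_assign("k", num_(2))))
  mB <- mk_event("B", op_("geq", sym_("k"), num_(1)),
                 list(mk_assign("w", num_(1))))
  m <- sbml_model(parameters = list(k = mk_param("k", 0),
                                    w = mk_param("w", 0)),
                  events = list(mA, mB))
  res <- simulate_sbml(m, t_end = 2, config = solver_config(
    solver = "rosenbrock", output_steps = 20L, seed = 1L))
  expect_setequal(res$events$event, c("A", "B"))
  expect_equal(diff(res$events$time), 0)    # same time point
  expect_equal(result_column(res$table, "w")[21], 1)
})

test_that("a nonpersistent event cancelled by another never executes", {
  res <- run_fixture("event_nonpersistent_cascade", seed = 11L)
  w1 <- result_column(res$table, "w1")
  w2 <- result_column(res$table, "w2")
  fired_one <- xor(max(w1) > 0.5, max(w2) > 0.5)  # exactly one of the two
  expect_true(fired_one)
  expect_identical(nrow(res$events), 1L)

  # over several seeds, still always exactly one
  for (s in 2:6) {
    r <- run_fixture("event_nonpersistent_cascade", seed = s)
    expect_identical(nrow(r$events), 1L)
  }
})

test_that("a persistent event, once active, is only removed by execution", {
  # trigger rises then falls before the scheduler runs again: the
  # persistent event must still execute; the nonpersistent one must not
  mk <- function(id, persistent) mk_event(
    id, op_("and", op_("geq", ast_time(), num_(1)),
            op_("eq", sym_("gate"), num_(0))),
    list(mk_assign(paste0("w_", id), num_(1))), persistent = persistent)
  ctx <- event_context(list(mk("p", TRUE), mk("n", FALSE)))
  Q0 <- c(gate = 0, w_p = 0, w_n = 0)
  init_triggers(ctx, function(tr) eval_ast(tr, Q0, t = 0))
  update_triggers(ctx, Q0, 0, function(tr) eval_ast(tr, Q0, 0))
  update_triggers(ctx, Q0, 1.5, function(tr) eval_ast(tr, Q0, 1.5))
  expect_true(ctx$states[[1]]$active && ctx$states[[2]]$active)
  # gate closes: triggers fall false before execution
  Q1 <- c(gate = 1, w_p = 0, w_n = 0)
  res <- process_events(ctx, Q1, 1.5, tree_evalf)
  expect_identical(res$fired$event, "p")
  expect_equal(res$Q[["w_p"]], 1)
  expect_equal(res$Q[["w_n"]], 0)
})

test_that("event processing terminates with a cycle error on endless loops", {
  # two events that keep re-enabling each other at one time point
  e1 <- mk_event("e1", op_("eq", sym_("x"), num_(0)),
                 list(mk_assign("x", num_(1))))
  e2 <- mk_event("e2", op_("eq", sym_("x"), num_(1)),
                 list(mk_assign("x", num_(0))))
  ctx <- event_context(list(e1, e2))
  Q <- c(x = 1)
  init_triggers(ctx, function(tr) eval_ast(tr, Q, t = 0))
  update_triggers(ctx, Q, 0, function(tr) eval_ast(tr, Q, 0))
  expect_error(process_events(ctx, c(x = 0), 1, tree_evalf, cap = 50L),
               "cycle")
})

test_that("simulation with events is deterministic under a fixed seed", {
  r1 <- run_fixture("event_priorities_tie", seed = 5L)
  r2 <- run_fixture("event_priorities_tie", seed = 5L)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$table$values, r2$table$values)
})
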