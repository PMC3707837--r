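# Interpreter dynamics: initialization order, derivative computation,
# rule application, constraints, conservation.

test_that("initialization applies raw values, initial assignments, then rules", {
  # assignment rule P := 2 * S1 with S1 initially 4
  m <- sbml_model(
    compartments = list(c = mk_comp("c")),
    species = list(S1 = mk_species("S1", amount = 4, boundary = TRUE)),
    parameters = list(P = mk_param("P", 0)),
    rules = list(mk_rule("assignment", "P",
                         op_("times", num_(2), sym_("S1")))))
  sim <- sbml_interpreter(m)
  Q0 <- sim_initialize(sim)
  expect_equal(Q0[["P"]], 8)

  # converted algebraic rule is processed during initialization
  m2 <- sbml_model(
    parameters = list(A = mk_param("A", 1, constant = TRUE),
                      B = mk_param("B", 2, constant = TRUE),
                      T = mk_param("T", 0)),
    rules = list(mk_rule("algebraic", NULL,
                         op_("minus", op_("plus", sym_("A"), sym_("B")),
                             sym_("T")))))
  sim2 <- sbml_interpreter(m2)
  Q02 <- sim_initialize(sim2)
  expect_equal(Q02[["T"]], 3)
  expect_equal(algebraic_residuals(sim2, Q02, 0), 0)
})

test_that("circular assignment rules are reported as a cycle", {
  m <- sbml_model(
    parameters = list(a = mk_param("a"), b = mk_param("b")),
    rules = list(
      mk_rule("assignment", "a", op_("plus", sym_("b"), num_(1))),
      mk_rule("assignment", "b", op_("plus", sym_("a"), num_(1)))))
  expect_error(sbml_interpreter(m), "circular")
})

test_that("derivatives follow N v for a single reaction", {
  # A -> B, v = k [A], k = 2, amount A = 3, compartment size 1
  m <- sbml_model(
    compartments = list(c = mk_comp("c")),
    species = list(A = mk_species("A", amount = 3, hosu = FALSE),
                   B = mk_species("B", amount = 0, hosu = FALSE)),
    reactions = list(mk_reaction(
      "r", list(mk_ref("A")), list(mk_ref("B")),
      op_("times", num_(2), sym_("A")))))
  sim <- sbml_interpreter(m)
  Q0 <- sim_initialize(sim)
  dQ <- compute_derivatives(sim, Q0, 0)
  expect_equal(dQ[["A"]], -6)
  expect_equal(dQ[["B"]], 6)
  expect_equal(dQ[["c"]], 0)
})

test_that("rate rules fill exactly their dimensions; others stay zero", {
  m <- sbml_model(
    parameters = list(P = mk_param("P", 0), Qp = mk_param("Qp", 1)),
    rules = list(mk_rule("rate", "P", num_(1))))
  sim <- sbml_interpreter(m)
  Q0 <- sim_initialize(sim)
  dQ <- compute_derivatives(sim, Q0, 0)
  expect_equal(dQ[["P"]], 1)
  expect_equal(dQ[["Qp"]], 0)
})

test_that("derivatives match a dense stoichiometric-matrix oracle", {
  set.seed(99)
  for (rep in 1:25) {
    net <- random_mass_action()
    sim <- sbml_interpreter(net$model)
    Q0 <- sim_initialize(sim)
    dQ <- compute_derivatives(sim, Q0, 0)
    expected <- net$oracle(net$amounts)
    expect_lt(max(abs(dQ[net$sp_ids] - expected[net$sp_ids])), 1e-12)
  }
})

test_that("boundary species get no reaction contribution", {
  m <- sbml_model(
    compartments = list(c = mk_comp("c")),
    species = list(A = mk_species("A", amount = 5, boundary = TRUE),
                   B = mk_species("B", amount = 0)),
    reactions = list(mk_reaction(
      "r", list(mk_ref("A")), list(mk_ref("B")),
      op_("times", num_(1), sym_("A")))))
  sim <- sbml_interpreter(m)
  Q0 <- sim_initialize(sim)
  dQ <- compute_derivatives(sim, Q0, 0)
  expect_equal(dQ[["A"]], 0)
  expect_equal(dQ[["B"]], 5)
})

test_that("chained assignment rules are independent of document order", {
  # a := b + 1, b := t  (dependent rule listed first)
  m <- sbml_model(
    parameters = list(a = mk_param("a"), b = mk_param("b")),
    rules = list(
      mk_rule("assignment", "a", op_("plus", sym_("b"), num_(1))),
      mk_rule("assignment", "b", ast_time())))
  sim <- sbml_interpreter(m)
  Q <- sim_initialize(sim)
  Q <- apply_rules(sim, Q, 2)
  expect_equal(Q[["b"]], 2)
  expect_equal(Q[["a"]], 3)

  # reversed document order gives the same fixed point
  m$rules <- rev(m$rules)
  sim2 <- sbml_interpreter(m)
  Q2 <- apply_rules(sim2, sim_initialize(sim2), 2)
  expect_equal(Q2[["a"]], 3)

  # no rules: identity
  m0 <- sbml_model(parameters = list(p = mk_param("p", 4)))
  sim0 <- sbml_interpreter(m0)
  Q0 <- sim_initialize(sim0)
  expect_identical(apply_rules(sim0, Q0, 1), Q0)
})

test_that("constraint violations are reported once per accepted step, never fatal", {
  seen <- new.env(); seen$n <- 0L
  res <- run_fixture("constraint_violation")
  # violations recorded only after S1 crosses 0.5
  t_onset <- log(2) / 0.7
  expect_gt(nrow(res$constraints), 0L)
  expect_true(all(res$constraints$time >= t_onset - 1e-6))
  expect_match(res$constraints$message[1], "below one half")
  # one notification per accepted step inside the violated interval
  viol_steps <- res$step_times[res$step_times >= min(res$constraints$time)]
  expect_identical(nrow(res$constraints), length(viol_steps))
})

test_that("a closed reversible isomerization conserves total mass", {
  kin <- op_("minus", op_("times", num_(0.8), sym_("A")),
             op_("times", num_(0.3), sym_("B")))
  m <- sbml_model(
    compartments = list(c = mk_comp("c")),
    species = list(A = mk_species("A", amount = 2),
                   B = mk_species("B", amount = 0.5)),
    reactions = list(mk_reaction("iso", list(mk_ref("A")),
                                 list(mk_ref("B")), kin)))
  for (sv in c("euler", "rk4", "rosenbrock")) {
    res <- simulate_sbml(m, t_end = 50, config = solver_config(
      solver = sv, output_steps = 200L, seed = 1L))
    tot <- result_column(res$table, "A") + result_column(res$table, "B")
    expect_lt(max(abs(tot - 2.5)) / 2.5, 1e-8)
  }
})

test_that("time-varying stoichiometry is re-evaluated each step", {
  for (nm in c("variable_stoichiometry", "stoich_reference_l3")) {
    res <- run_fixture(nm)
    tt <- res$table$times
    expect_lt(max(abs(result_column(res$table, "B") - (2 * tt + tt^2))),
              1e-4)
  }
})
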