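# Hash-consed syntax graph: sharing, caching, function binding, history.

fig1_kinetics <- function() {
  # nu_R1 = kp1*F16BP - km1*DHAP*GA3P ; nu_R2 = kp2*DHAP - km2*GA3P
  v1 <- op_("minus",
            op_("times", sym_("kp1"), sym_("F16BP")),
            op_("times", sym_("km1"), sym_("DHAP"), sym_("GA3P")))
  v2 <- op_("minus",
            op_("times", sym_("kp2"), sym_("DHAP")),
            op_("times", sym_("km2"), sym_("GA3P")))
  list(v1 = v1, v2 = v2)
}

test_that("interning is idempotent and shares equivalent subexpressions", {
  g <- syntax_graph()
  tr <- op_("plus", sym_("a"), op_("times", sym_("a"), num_(2)))
  n1 <- intern(tr, g)
  size1 <- graph_size(g)
  n2 <- intern(tr, g)
  expect_identical(n1, n2)          # same environment, zero growth
  expect_identical(graph_size(g), size1)

  # a+b and b+a are distinct (syntactic equality, no normalization)
  ga <- intern(op_("plus", sym_("a"), sym_("b")), g)
  gb <- intern(op_("plus", sym_("b"), sym_("a")), g)
  expect_false(identical(ga, gb))
})

test_that("shared species nodes of the reversible kinetics gain multiple parents", {
  g <- syntax_graph()
  k <- fig1_kinetics()
  intern(k$v1, g)
  intern(k$v2, g)
  dhap <- graph_lookup(sym_("DHAP"), g)
  ga3p <- graph_lookup(sym_("GA3P"), g)
  expect_gte(node_parent_count(dhap), 2)
  expect_gte(node_parent_count(ga3p), 2)
})

test_that("graph node count equals the number of distinct subtrees (oracle)", {
  set.seed(101)
  for (rep in 1:10) {
    pool <- list(op_("times", sym_("s1"), sym_("s2")),
                 op_("plus", sym_("s3"), num_(1)))
    trees <- lapply(1:10, function(i)
      random_tree(3, c("s1", "s2", "s3"), pool))
    g <- syntax_graph()
    for (tr in trees) intern(tr, g)
    expect_identical(graph_size(g), ast_distinct_subtrees(trees))
  }
})

test_that("cached evaluation equals evaluation of the un-merged trees", {
  set.seed(202)
  syms <- c("x", "y", "z")
  for (rep in 1:40) {
    trees <- lapply(1:4, function(i) random_tree(3, syms))
    g <- syntax_graph()
    nodes <- lapply(trees, intern, graph = g)
    for (state in 1:5) {
      Q <- stats::setNames(round(stats::runif(3, 0.1, 3), 4), syms)
      graph_new_epoch(g)
      for (i in seq_along(trees)) {
        cached <- evaluate(nodes[[i]], g, Q, t = 0)
        plain <- eval_ast(trees[[i]], Q, t = 0)
        expect_equal(cached, plain, tolerance = 1e-12)
      }
    }
  }
})

test_that("within one epoch every shared node is computed exactly once", {
  g <- syntax_graph()
  k <- fig1_kinetics()
  n1 <- intern(k$v1, g)
  n2 <- intern(k$v2, g)
  Q <- c(kp1 = 1, km1 = 0.5, kp2 = 3, km2 = 0.5,
         F16BP = 4, DHAP = 2, GA3P = 1)
  graph_new_epoch(g, count = TRUE)
  evaluate(n1, g, Q, t = 0)
  evaluate(n2, g, Q, t = 0)
  evaluate(n1, g, Q, t = 0)  # re-evaluation hits the cache
  counts <- graph_eval_counts(g)
  expect_true(all(counts == 1L))
  # and the shared nodes were indeed evaluated (present in the counter)
  expect_true(graph_lookup(sym_("DHAP"), g)$key %in% names(counts))
})

test_that("function binding substitutes capture-safely", {
  f <- list(id = "f", params = "x",
            body = op_("power", sym_("x"), num_(2)))
  out <- bind_function(f, list(sym_("S1")))
  expect_identical(ast_key(out), ast_key(op_("power", sym_("S1"), num_(2))))

  # same parameter name in two functions, no cross-capture
  g1 <- list(id = "g1", params = "x",
             body = op_("plus", sym_("x"), sym_("c")))
  g2 <- list(id = "g2", params = "x",
             body = op_("times", sym_("x"), sym_("c")))
  tab <- list(g1 = g1, g2 = g2)
  b1 <- bind_function(g1, list(sym_("u")), tab)
  b2 <- bind_function(g2, list(sym_("v")), tab)
  Q <- c(u = 3, v = 4, c = 10)
  expect_equal(eval_ast(b1, Q), 13)
  expect_equal(eval_ast(b2, Q), 40)

  # argument order matters: f2(a,b) vs f2(b,a)
  f2 <- list(id = "f2", params = c("x", "y"),
             body = op_("divide", sym_("x"), sym_("y")))
  ab <- bind_function(f2, list(sym_("a"), sym_("b")))
  ba <- bind_function(f2, list(sym_("b"), sym_("a")))
  Q <- c(a = 8, b = 2)
  expect_equal(eval_ast(ab, Q), 4)
  expect_equal(eval_ast(ba, Q), 0.25)
  g <- syntax_graph()
  expect_false(identical(intern(ab, g), intern(ba, g)))
})

test_that("arity mismatches and recursive definitions are rejected", {
  f <- list(id = "f", params = c("x", "y"),
            body = op_("plus", sym_("x"), sym_("y")))
  expect_error(bind_function(f, list(sym_("a"))), "argument")
  rec <- list(id = "r", params = "x",
              body = ast_call("r", list(sym_("x"))))
  expect_error(bind_function(rec, list(num_(1))), "recursive")
})

test_that("history buffer clamps and interpolates linearly", {
  h <- history_buffer(0, c(S = 1))
  history_append(h, 1, c(S = 3))
  history_append(h, 2, c(S = 5))
  expect_equal(history_state(h, -1)$Q[["S"]], 1)     # pre-t0 clamp
  expect_equal(history_state(h, 0.5)$Q[["S"]], 2)    # linear
  expect_equal(history_state(h, 1.75)$Q[["S"]], 4.5)
  expect_equal(history_state(h, 99)$Q[["S"]], 5)     # clamp to latest
  expect_error(history_append(h, 1.5, c(S = 0)), "non-decreasing")
})

test_that("delay expressions read the interpolated historical state", {
  g <- syntax_graph()
  node <- intern(ast_delay(sym_("S"), num_(1)), g)
  h <- history_buffer(0, c(S = 10))
  history_append(h, 2, c(S = 20))
  graph_new_epoch(g)
  # t = 1: query at t - tau = 0 -> initial value
  expect_equal(evaluate(node, g, c(S = 99), t = 1, history = h), 10)
  graph_new_epoch(g)
  # t = 3: query at 2 -> latest record
  expect_equal(evaluate(node, g, c(S = 99), t = 3, history = h), 20)
  graph_new_epoch(g)
  # t = 2.5: query at 1.5, linear between (0, 10) and (2, 20)
  expect_equal(evaluate(node, g, c(S = 99), t = 2.5, history = h), 17.5)
})
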