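# Algebraic rules: bipartite construction, Hopcroft-Karp matching,
# overdetermination, and rearrangement into assignment rules.

conservation_model <- function() {
  # reaction A -> B with kinetic law, algebraic rule A + B - T = 0,
  # free (non-constant) parameter T
  sbml_model(
    compartments = list(c = mk_comp("c")),
    species = list(A = mk_species("A", amount = 1),
                   B = mk_species("B", amount = 0)),
    parameters = list(T = mk_param("T", 0, constant = FALSE)),
    reactions = list(mk_reaction(
      "r", list(mk_ref("A")), list(mk_ref("B")),
      op_("times", num_(0.5), sym_("A")))),
    rules = list(mk_rule("algebraic", NULL,
                         op_("minus", op_("plus", sym_("A"), sym_("B")),
                             sym_("T")))))
}

test_that("the bipartite graph follows the specification construction", {
  g <- build_bipartite(conservation_model())
  expect_length(g$adj, 2L)                    # reaction + algebraic rule
  expect_setequal(g$vars, c("A", "B", "T"))   # constant compartment excluded
  alg <- which(g$eq_type == "algebraic")
  expect_setequal(g$vars[g$adj[[alg]]], c("A", "B", "T"))
  rx <- which(g$eq_type == "reaction")
  expect_setequal(g$vars[g$adj[[rx]]], c("A", "B"))
})

test_that("constant quantities are not variable vertices", {
  m <- conservation_model()
  m$parameters$T$constant <- TRUE
  g <- build_bipartite(m)
  expect_false("T" %in% g$vars)
})

test_that("models without algebraic rules are never overdetermined", {
  m <- conservation_model()
  m$rules <- list()
  g <- build_bipartite(m)
  matching <- hopcroft_karp(g)
  expect_false(check_overdetermined(matching, g))
})

test_that("Hopcroft-Karp finds perfect and path matchings", {
  complete33 <- adj_as_graph(rep(list(1:3), 3), 3)
  expect_identical(sum(!is.na(hopcroft_karp(complete33)$eq_to_var)), 3L)

  # two equations sharing one variable: matching size 1, overdetermined
  path <- adj_as_graph(list(1L, 1L), 1)
  matching <- hopcroft_karp(path)
  expect_identical(sum(!is.na(matching$eq_to_var)), 1L)
  expect_true(check_overdetermined(matching, path))
})

test_that("matching cardinality equals brute force on random graphs", {
  set.seed(33)
  for (rep in 1:200) {
    ne <- sample(1:6, 1); nv <- sample(1:6, 1)
    adj <- random_bipartite(ne, nv)
    g <- adj_as_graph(adj, nv)
    hk <- hopcroft_karp(g)
    card <- sum(!is.na(hk$eq_to_var))
    expect_identical(card, brute_max_matching(g$adj, nv))
    expect_identical(check_overdetermined(hk, g), card < ne)
  }
})

test_that("matching cardinality is invariant under vertex permutation", {
  set.seed(44)
  for (rep in 1:25) {
    adj <- random_bipartite(4, 5)
    g <- adj_as_graph(adj, 5)
    base <- sum(!is.na(hopcroft_karp(g)$eq_to_var))
    perm <- sample(5)
    adj2 <- lapply(adj[sample(4)], function(vs) sort(match(vs, perm)))
    g2 <- adj_as_graph(adj2, 5)
    expect_identical(sum(!is.na(hopcroft_karp(g2)$eq_to_var)), base)
  }
})

test_that("linear algebraic rules rearrange to assignment rules", {
  r <- mk_rule("algebraic", NULL,
               op_("minus", op_("plus", sym_("A"), sym_("B")), sym_("T")))
  a <- rearrange(r, "T")
  expect_identical(a$kind, "assignment")
  expect_identical(a$variable, "T")
  expect_equal(eval_ast(a$math, Q = c(A = 1.5, B = 2.5)), 4)

  x5 <- rearrange(mk_rule("algebraic", NULL,
                          op_("minus", sym_("x"), num_(5))), "x")
  expect_equal(eval_ast(x5$math), 5)

  kx <- rearrange(mk_rule("algebraic", NULL,
                          op_("minus", op_("times", sym_("k"), sym_("x")),
                              op_("times", sym_("S1"), sym_("S2")))), "x")
  expect_equal(eval_ast(kx$math, Q = c(k = 2, S1 = 3, S2 = 4)), 6)
})

test_that("nonlinear occurrences of the target are rejected", {
  sq <- mk_rule("algebraic", NULL,
                op_("minus", op_("power", sym_("x"), num_(2)), num_(4)))
  expect_error(rearrange(sq, "x"), "linear")
  xx <- mk_rule("algebraic", NULL,
                op_("minus", op_("times", sym_("x"), sym_("x")), num_(1)))
  expect_error(rearrange(xx, "x"), "linear")
})

test_that("overdetermined models are rejected with a clear error", {
  m <- sbml_model(
    parameters = list(x = mk_param("x", 0, constant = FALSE)),
    rules = list(
      mk_rule("algebraic", NULL, op_("minus", sym_("x"), num_(5))),
      mk_rule("algebraic", NULL, op_("minus", sym_("x"), num_(6)))))
  expect_error(convert_algebraic_rules(m), "overdetermined")
})

test_that("converted rules keep the original expression at residual zero", {
  m <- convert_algebraic_rules(conservation_model())
  kinds <- vapply(m$rules, `[[`, character(1), "kind")
  expect_false("algebraic" %in% kinds)
  tgt <- vapply(m$rules, `[[`, character(1), "variable")
  expect_true("T" %in% tgt)
  expect_length(m$algebraic_originals, 1L)

  # full simulation: |A + B - T| below tolerance at every output point
  sim <- run_fixture("algebraic_conservation")
  tab <- sim$table
  resid <- abs(result_column(tab, "A") + result_column(tab, "B") -
                 result_column(tab, "T"))
  expect_lt(max(resid), 1e-9)
})
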