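## Programmatic generator of small SBML fixture models, one per
## supported construct family.  Each fixture carries serialized SBML
## text (so the XML reader is exercised on real documents), the parsed
## model, an expected-behavior descriptor (analytic solution, conserved
## quantity, expected firing count, ...), and recommended solver
## settings.

sbml_l3 <- function(model_id, body) {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
    "level=\"3\" version=\"1\">\n",
    "<model id=\"", model_id, "\" timeUnits=\"second\">\n",
    body, "</model>\n</sbml>\n")
}

sbml_l2 <- function(model_id, body) {
  paste0(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level2/version4\" ",
    "level=\"2\" version=\"4\">\n",
    "<model id=\"", model_id, "\">\n", body, "</model>\n</sbml>\n")
}

mml <- function(inner) {
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         inner, "</math>")
}

## one-compartment scaffold used by several fixtures
.x_comp <- paste0(
  "<listOfCompartments>\n",
  "<compartment id=\"c\" size=\"1\" spatialDimensions=\"3\" ",
  "constant=\"true\"/>\n</listOfCompartments>\n")

x_species <- function(id, amount, hosu = "true", boundary = "false",
                      constant = "false", comp = "c") {
  paste0("<species id=\"", id, "\" compartment=\"", comp,
         "\" initialAmount=\"", amount,
         "\" hasOnlySubstanceUnits=\"", hosu,
         "\" boundaryCondition=\"", boundary,
         "\" constant=\"", constant, "\"/>\n")
}

x_param <- function(id, value, constant = "true") {
  paste0("<parameter id=\"", id, "\" value=\"", value,
         "\" constant=\"", constant, "\"/>\n")
}

x_reaction <- function(id, reactants, products, math_inner,
                       locals = character(0)) {
  ref <- function(sp) paste0(
    "<speciesReference species=\"", sp,
    "\" stoichiometry=\"1\" constant=\"true\"/>\n")
  loc <- if (length(locals) > 0L) paste0(
    "<listOfLocalParameters>\n",
    paste0("<localParameter id=\"", names(locals), "\" value=\"",
           unname(locals), "\"/>\n", collapse = ""),
    "</listOfLocalParameters>\n") else ""
  paste0(
    "<reaction id=\"", id, "\" reversible=\"true\" fast=\"false\">\n",
    if (length(reactants) > 0L)
      paste0("<listOfReactants>\n", paste0(vapply(reactants, ref,
        character(1)), collapse = ""), "</listOfReactants>\n") else "",
    if (length(products) > 0L)
      paste0("<listOfProducts>\n", paste0(vapply(products, ref,
        character(1)), collapse = ""), "</listOfProducts>\n") else "",
    "<kineticLaw>", mml(math_inner), loc, "</kineticLaw>\n",
    "</reaction>\n")
}

x_event <- function(id, trigger_inner, assignments,
                    priority_inner = NULL, delay_inner = NULL,
                    persistent = "true", initial_value = "true",
                    utt = "false") {
  asgn <- paste0(vapply(names(assignments), function(v) paste0(
    "<eventAssignment variable=\"", v, "\">",
    mml(assignments[[v]]), "</eventAssignment>\n"), character(1)),
    collapse = "")
  paste0(
    "<event id=\"", id, "\" useValuesFromTriggerTime=\"", utt, "\">\n",
    "<trigger persistent=\"", persistent, "\" initialValue=\"",
    initial_value, "\">", mml(trigger_inner), "</trigger>\n",
    if (!is.null(priority_inner))
      paste0("<priority>", mml(priority_inner), "</priority>\n") else "",
    if (!is.null(delay_inner))
      paste0("<delay>", mml(delay_inner), "</delay>\n") else "",
    "<listOfEventAssignments>\n", asgn, "</listOfEventAssignments>\n",
    "</event>\n")
}

.time_ci <- paste0("<csymbol encoding=\"text\" definitionURL=",
                   "\"http://www.sbml.org/sbml/symbols/time\">t</csymbol>")

## ---------------------------------------------------------------------------
## the registry

fixture_builders <- function() list(

  exp_decay = function() {
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n", x_species("S", 10), "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("k", 0.7), "</listOfParameters>\n",
      "<listOfReactions>\n",
      x_reaction("deg", "S", character(0),
                 "<apply><times/><ci>k</ci><ci>S</ci></apply>"),
      "</listOfReactions>\n")
    list(sbml = sbml_l3("exp_decay", body),
         expected = list(type = "analytic", id = "S",
                         fn = function(t) 10 * exp(-0.7 * t)),
         settings = list(t_end = 1, output_steps = 200L,
                         solver = "all"))
  },

  reversible_mass_action = function() {
    ## the two-reaction glycolysis fragment:
    ## R1: F16BP <=> DHAP + GA3P, R2: DHAP <=> GA3P (mass action)
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n",
      x_species("F16BP", 10, hosu = "false"),
      x_species("DHAP", 2, hosu = "false"),
      x_species("GA3P", 1, hosu = "false"),
      "</listOfSpecies>\n",
      "<listOfReactions>\n",
      x_reaction("R1", "F16BP", c("DHAP", "GA3P"),
                 paste0("<apply><minus/>",
                        "<apply><times/><ci>kp1</ci><ci>F16BP</ci></apply>",
                        "<apply><times/><ci>km1</ci><ci>DHAP</ci>",
                        "<ci>GA3P</ci></apply></apply>"),
                 locals = c(kp1 = 1, km1 = 0.5)),
      x_reaction("R2", "DHAP", "GA3P",
                 paste0("<apply><minus/>",
                        "<apply><times/><ci>kp2</ci><ci>DHAP</ci></apply>",
                        "<apply><times/><ci>km2</ci><ci>GA3P</ci>",
                        "</apply></apply>"),
                 locals = c(kp2 = 3, km2 = 0.5)),
      "</listOfReactions>\n")
    list(sbml = sbml_l3("reversible_mass_action", body),
         expected = list(type = "conserved",
                         weights = c(F16BP = 2, DHAP = 1, GA3P = 1),
                         total = 2 * 10 + 2 + 1),
         settings = list(t_end = 50, output_steps = 200L,
                         solver = "all"))
  },

  rate_rule_only = function() {
    body <- paste0(
      "<listOfParameters>\n", x_param("P", 0, "false"),
      "</listOfParameters>\n",
      "<listOfRules>\n",
      "<rateRule variable=\"P\">", mml("<cn type=\"integer\">1</cn>"),
      "</rateRule>\n</listOfRules>\n")
    list(sbml = sbml_l3("rate_rule_only", body),
         expected = list(type = "analytic", id = "P",
                         fn = function(t) t),
         settings = list(t_end = 5, output_steps = 100L, solver = "all"))
  },

  assignment_chain = function() {
    ## document order deliberately places the dependent rule first
    body <- paste0(
      "<listOfParameters>\n",
      x_param("a", 0, "false"), x_param("b", 0, "false"),
      "</listOfParameters>\n",
      "<listOfRules>\n",
      "<assignmentRule variable=\"a\">",
      mml(paste0("<apply><plus/><ci>b</ci>",
                 "<cn type=\"integer\">1</cn></apply>")),
      "</assignmentRule>\n",
      "<assignmentRule variable=\"b\">", mml(.time_ci),
      "</assignmentRule>\n",
      "</listOfRules>\n")
    list(sbml = sbml_l3("assignment_chain", body),
         expected = list(type = "analytic_multi",
                         fns = list(a = function(t) t + 1,
                                    b = function(t) t)),
         settings = list(t_end = 4, output_steps = 100L, solver = "all"))
  },

  algebraic_conservation = function() {
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n",
      x_species("A", 1), x_species("B", 0),
      "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("T", 0, "false"),
      "</listOfParameters>\n",
      "<listOfReactions>\n",
      x_reaction("iso", "A", "B",
                 paste0("<apply><minus/>",
                        "<apply><times/><ci>k1</ci><ci>A</ci></apply>",
                        "<apply><times/><ci>k2</ci><ci>B</ci></apply>",
                        "</apply>"),
                 locals = c(k1 = 0.5, k2 = 0.3)),
      "</listOfReactions>\n",
      "<listOfRules>\n<algebraicRule>",
      mml(paste0("<apply><minus/><apply><plus/><ci>A</ci><ci>B</ci>",
                 "</apply><ci>T</ci></apply>")),
      "</algebraicRule>\n</listOfRules>\n")
    list(sbml = sbml_l3("algebraic_conservation", body),
         expected = list(type = "algebraic_residual", target = "T",
                         weights = c(A = 1, B = 1)),
         settings = list(t_end = 10, output_steps = 100L,
                         solver = "all"))
  },

  event_threshold = function() {
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n", x_species("S1", 1), "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("k", 0.7), x_param("P", 0, "false"),
      "</listOfParameters>\n",
      "<listOfReactions>\n",
      x_reaction("deg", "S1", character(0),
                 "<apply><times/><ci>k</ci><ci>S1</ci></apply>"),
      "</listOfReactions>\n",
      "<listOfEvents>\n",
      x_event("hit", paste0("<apply><leq/><ci>S1</ci>",
                            "<cn>0.5</cn></apply>"),
              list(P = "<cn type=\"integer\">1</cn>")),
      "</listOfEvents>\n")
    list(sbml = sbml_l3("event_threshold", body),
         expected = list(type = "event_time", event = "hit",
                         t_true = log(2) / 0.7),
         ## tight tolerances: the trigger-time error is bounded by the
         ## trajectory error plus the localization bound h_min
         settings = list(t_end = 2, output_steps = 100L,
                         solver = "rosenbrock", h_min = 1e-8,
                         rtol = 1e-10, atol = 1e-14))
  },

  event_priorities_tie = function() {
    guard <- function(v) paste0(
      "<piecewise><piece><cn type=\"integer\">", v,
      "</cn><apply><eq/><ci>winner</ci><cn type=\"integer\">0</cn>",
      "</apply></piece><otherwise><ci>winner</ci></otherwise>",
      "</piecewise>")
    trig <- paste0("<apply><geq/>", .time_ci,
                   "<cn type=\"integer\">1</cn></apply>")
    body <- paste0(
      "<listOfParameters>\n", x_param("winner", 0, "false"),
      "</listOfParameters>\n",
      "<listOfEvents>\n",
      x_event("e1", trig, list(winner = guard(1)),
              priority_inner = "<cn type=\"integer\">5</cn>"),
      x_event("e2", trig, list(winner = guard(2)),
              priority_inner = "<cn type=\"integer\">5</cn>"),
      "</listOfEvents>\n")
    list(sbml = sbml_l3("event_priorities_tie", body),
         expected = list(type = "tie", outcomes = c(1, 2),
                         id = "winner"),
         settings = list(t_end = 2, output_steps = 50L,
                         solver = "rosenbrock"))
  },

  event_nonpersistent_cascade = function() {
    trig <- function() paste0(
      "<apply><and/><apply><geq/>", .time_ci,
      "<cn type=\"integer\">1</cn></apply>",
      "<apply><eq/><ci>flag</ci><cn type=\"integer\">0</cn></apply>",
      "</apply>")
    body <- paste0(
      "<listOfParameters>\n",
      x_param("flag", 0, "false"), x_param("w1", 0, "false"),
      x_param("w2", 0, "false"),
      "</listOfParameters>\n",
      "<listOfEvents>\n",
      x_event("e1", trig(),
              list(flag = "<cn type=\"integer\">1</cn>",
                   w1 = "<cn type=\"integer\">1</cn>"),
              persistent = "false"),
      x_event("e2", trig(),
              list(flag = "<cn type=\"integer\">1</cn>",
                   w2 = "<cn type=\"integer\">1</cn>"),
              persistent = "false"),
      "</listOfEvents>\n")
    list(sbml = sbml_l3("event_nonpersistent_cascade", body),
         expected = list(type = "cascade_one_of", ids = c("w1", "w2")),
         settings = list(t_end = 2, output_steps = 50L,
                         solver = "rosenbrock"))
  },

  event_delayed_snapshot = function() {
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n", x_species("S1", 1), "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("k", 0.7), x_param("P", 0, "false"),
      "</listOfParameters>\n",
      "<listOfReactions>\n",
      x_reaction("deg", "S1", character(0),
                 "<apply><times/><ci>k</ci><ci>S1</ci></apply>"),
      "</listOfReactions>\n",
      "<listOfEvents>\n",
      x_event("snap", paste0("<apply><geq/>", .time_ci,
                             "<cn type=\"integer\">1</cn></apply>"),
              list(P = "<ci>S1</ci>"),
              delay_inner = "<cn>0.5</cn>", utt = "true"),
      "</listOfEvents>\n")
    list(sbml = sbml_l3("event_delayed_snapshot", body),
         expected = list(type = "delayed_snapshot", id = "P",
                         value = exp(-0.7), exec_time = 1.5),
         settings = list(t_end = 3, output_steps = 100L,
                         solver = "rosenbrock"))
  },

  delay_function_dde = function() {
    ## k tau = 0.25 < 1/e keeps the delayed decay monotone and positive,
    ## so a relative comparison against the reference is well defined
    body <- paste0(
      "<listOfParameters>\n",
      x_param("S", 1, "false"), x_param("k", 0.5),
      "</listOfParameters>\n",
      "<listOfRules>\n<rateRule variable=\"S\">",
      mml(paste0(
        "<apply><minus/><apply><times/><ci>k</ci>",
        "<apply><csymbol encoding=\"text\" definitionURL=",
        "\"http://www.sbml.org/sbml/symbols/delay\">delay</csymbol>",
        "<ci>S</ci><cn>0.5</cn></apply></apply></apply>")),
      "</rateRule>\n</listOfRules>\n")
    list(sbml = sbml_l3("delay_function_dde", body),
         expected = list(type = "dde", id = "S", k = 0.5, tau = 0.5,
                         y0 = 1),
         settings = list(t_end = 5, output_steps = 200L,
                         solver = "rosenbrock", h_max = 0.02))
  },

  variable_stoichiometry = function() {
    ## Level 2 StoichiometryMath: product stoichiometry 1 + t, constant
    ## source flux k = 2, so B(t) = 2 t + t^2
    body <- paste0(
      "<listOfCompartments>\n",
      "<compartment id=\"c\" size=\"1\"/>\n</listOfCompartments>\n",
      "<listOfSpecies>\n",
      "<species id=\"A\" compartment=\"c\" initialAmount=\"10\" ",
      "hasOnlySubstanceUnits=\"true\" boundaryCondition=\"true\"/>\n",
      "<species id=\"B\" compartment=\"c\" initialAmount=\"0\" ",
      "hasOnlySubstanceUnits=\"true\"/>\n",
      "</listOfSpecies>\n",
      "<listOfParameters>\n",
      "<parameter id=\"k\" value=\"2\"/>\n</listOfParameters>\n",
      "<listOfReactions>\n<reaction id=\"gen\" reversible=\"false\">\n",
      "<listOfReactants><speciesReference species=\"A\"/>",
      "</listOfReactants>\n",
      "<listOfProducts><speciesReference species=\"B\">",
      "<stoichiometryMath>",
      mml(paste0("<apply><plus/><cn type=\"integer\">1</cn>", .time_ci,
                 "</apply>")),
      "</stoichiometryMath></speciesReference></listOfProducts>\n",
      "<kineticLaw>", mml("<ci>k</ci>"), "</kineticLaw>\n",
      "</reaction>\n</listOfReactions>\n")
    list(sbml = sbml_l2("variable_stoichiometry", body),
         expected = list(type = "analytic", id = "B",
                         fn = function(t) 2 * t + t^2),
         settings = list(t_end = 3, output_steps = 100L,
                         solver = "all"))
  },

  stoich_reference_l3 = function() {
    ## Level 3 assignable species reference: stoichiometry governed by an
    ## assignment rule (sB := 1 + t), same dynamics as the Level 2 case
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n",
      x_species("A", 10, boundary = "true"), x_species("B", 0),
      "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("k", 2), "</listOfParameters>\n",
      "<listOfReactions>\n",
      "<reaction id=\"gen\" reversible=\"false\" fast=\"false\">\n",
      "<listOfReactants><speciesReference species=\"A\" ",
      "stoichiometry=\"1\" constant=\"true\"/></listOfReactants>\n",
      "<listOfProducts><speciesReference id=\"sB\" species=\"B\" ",
      "stoichiometry=\"1\" constant=\"false\"/></listOfProducts>\n",
      "<kineticLaw>", mml("<ci>k</ci>"), "</kineticLaw>\n",
      "</reaction>\n</listOfReactions>\n",
      "<listOfRules>\n<assignmentRule variable=\"sB\">",
      mml(paste0("<apply><plus/><cn type=\"integer\">1</cn>", .time_ci,
                 "</apply>")),
      "</assignmentRule>\n</listOfRules>\n")
    list(sbml = sbml_l3("stoich_reference_l3", body),
         expected = list(type = "analytic", id = "B",
                         fn = function(t) 2 * t + t^2),
         settings = list(t_end = 3, output_steps = 100L,
                         solver = "all"))
  },

  function_def_nested = function() {
    ## f(x) = x^2, g(x, y) = f(x) + 2 f(y); rule P := g(t, 2) = t^2 + 8
    body <- paste0(
      "<listOfFunctionDefinitions>\n",
      "<functionDefinition id=\"f\">",
      mml(paste0("<lambda><bvar><ci>x</ci></bvar>",
                 "<apply><power/><ci>x</ci><cn type=\"integer\">2</cn>",
                 "</apply></lambda>")),
      "</functionDefinition>\n",
      "<functionDefinition id=\"g\">",
      mml(paste0(
        "<lambda><bvar><ci>x</ci></bvar><bvar><ci>y</ci></bvar>",
        "<apply><plus/><apply><ci>f</ci><ci>x</ci></apply>",
        "<apply><times/><cn type=\"integer\">2</cn>",
        "<apply><ci>f</ci><ci>y</ci></apply></apply></apply></lambda>")),
      "</functionDefinition>\n",
      "</listOfFunctionDefinitions>\n",
      "<listOfParameters>\n", x_param("P", 0, "false"),
      "</listOfParameters>\n",
      "<listOfRules>\n<assignmentRule variable=\"P\">",
      mml(paste0("<apply><ci>g</ci>", .time_ci,
                 "<cn type=\"integer\">2</cn></apply>")),
      "</assignmentRule>\n</listOfRules>\n")
    list(sbml = sbml_l3("function_def_nested", body),
         expected = list(type = "analytic", id = "P",
                         fn = function(t) t^2 + 8),
         settings = list(t_end = 3, output_steps = 100L,
                         solver = "all"))
  },

  constraint_violation = function() {
    body <- paste0(
      .x_comp,
      "<listOfSpecies>\n", x_species("S1", 1), "</listOfSpecies>\n",
      "<listOfParameters>\n", x_param("k", 0.7),
      "</listOfParameters>\n",
      "<listOfReactions>\n",
      x_reaction("deg", "S1", character(0),
                 "<apply><times/><ci>k</ci><ci>S1</ci></apply>"),
      "</listOfReactions>\n",
      "<listOfConstraints>\n<constraint>",
      mml("<apply><geq/><ci>S1</ci><cn>0.5</cn></apply>"),
      "<message>S1 fell below one half</message></constraint>\n",
      "</listOfConstraints>\n")
    list(sbml = sbml_l3("constraint_violation", body),
         expected = list(type = "constraint", t_onset = log(2) / 0.7,
                         message = "S1 fell below one half"),
         settings = list(t_end = 2, output_steps = 100L,
                         solver = "rosenbrock"))
  },

  event_high_frequency = function() {
    ## two self-re-arming timers firing every 0.01 time units over
    ## [0, 10]: exactly 2 x 1000 firings
    mk <- function(id, par) x_event(
      id,
      paste0("<apply><geq/>", .time_ci, "<ci>", par, "</ci></apply>"),
      stats::setNames(list(paste0(
        "<apply><plus/><ci>", par, "</ci><cn>0.01</cn></apply>")), par))
    body <- paste0(
      "<listOfParameters>\n",
      x_param("nextA", 0.005, "false"), x_param("nextB", 0.005, "false"),
      x_param("drift", 0, "false"),
      "</listOfParameters>\n",
      "<listOfRules>\n<rateRule variable=\"drift\">",
      mml("<cn>0.1</cn>"), "</rateRule>\n</listOfRules>\n",
      "<listOfEvents>\n", mk("tickA", "nextA"), mk("tickB", "nextB"),
      "</listOfEvents>\n")
    list(sbml = sbml_l3("event_high_frequency", body),
         expected = list(type = "firing_count", count = 2000L,
                         per_event = c(tickA = 1000L, tickB = 1000L)),
         settings = list(t_end = 10, output_steps = 100L,
                         solver = "rosenbrock", h_min = 1e-6))
  },

  l1_decay = function() {
    sbml <- paste0(
      "<?xml version=\"1.0\" encoding=\"UTF-8\"?>\n",
      "<sbml xmlns=\"http://www.sbml.org/sbml/level1\" ",
      "level=\"1\" version=\"2\">\n",
      "<model name=\"l1_decay\">\n",
      "<listOfCompartments>\n",
      "<compartment name=\"c\" volume=\"1\"/>\n",
      "</listOfCompartments>\n",
      "<listOfSpecies>\n",
      "<specie name=\"S\" compartment=\"c\" initialAmount=\"10\" ",
      "boundaryCondition=\"false\"/>\n",
      "</listOfSpecies>\n",
      "<listOfParameters>\n",
      "<parameter name=\"k\" value=\"0.7\"/>\n",
      "</listOfParameters>\n",
      "<listOfReactions>\n",
      "<reaction name=\"deg\" reversible=\"false\">\n",
      "<listOfReactants><specieReference specie=\"S\" ",
      "stoichiometry=\"1\"/></listOfReactants>\n",
      "<kineticLaw formula=\"k*S\"/>\n",
      "</reaction>\n</listOfReactions>\n",
      "</model>\n</sbml>\n")
    list(sbml = sbml,
         expected = list(type = "analytic", id = "S",
                         fn = function(t) 10 * exp(-0.7 * t)),
         settings = list(t_end = 1, output_steps = 100L,
                         solver = "all"))
  },

  overdetermined_pair = function() {
    body <- paste0(
      "<listOfParameters>\n", x_param("x", 0, "false"),
      "</listOfParameters>\n",
      "<listOfRules>\n",
      "<algebraicRule>",
      mml(paste0("<apply><minus/><ci>x</ci>",
                 "<cn type=\"integer\">5</cn></apply>")),
      "</algebraicRule>\n",
      "<algebraicRule>",
      mml(paste0("<apply><minus/><ci>x</ci>",
                 "<cn type=\"integer\">6</cn></apply>")),
      "</algebraicRule>\n",
      "</listOfRules>\n")
    list(sbml = sbml_l3("overdetermined_pair", body),
         expected = list(type = "error", match = "overdetermined"),
         settings = list(t_end = 1, output_steps = 10L,
                         solver = "rosenbrock"),
         valid = FALSE)
  }
)

#' Names of the available fixture models
#' @param valid_only if `TRUE` (default) only fixtures that validate
#'   cleanly are listed; `FALSE` adds deliberately invalid ones.
#' @return Character vector.
#' @export
fixture_names <- function(valid_only = TRUE) {
  b <- fixture_builders()
  nms <- names(b)
  if (valid_only)
    nms <- nms[vapply(nms, function(n)
      !isFALSE(b[[n]]()$valid %||% TRUE), logical(1))]
  nms
}

#' Generate a fixture model
#'
#' Builds one of the registered small SBML models covering the supported
#' construct families, parses its serialized SBML text, and returns the
#' case with its expected-behavior descriptor and recommended solver
#' settings.
#'
#' @param name one of [fixture_names()] (including the deliberately
#'   invalid fixtures).
#' @return Object of class `fixture_case`: list with `name`, `sbml`
#'   (XML text), `model` (parsed `sbml_model`, or `NULL` for invalid
#'   fixtures that fail at parse/validation), `expected`, `settings`,
#'   `valid`.
#' @export
generate_fixture <- function(name) {
  b <- fixture_builders()
  if (!(name %in% names(b)))
    stop("unknown fixture: '", name, "' (see fixture_names())",
         call. = FALSE)
  fx <- b[[name]]()
  valid <- !isFALSE(fx$valid %||% TRUE)
  model <- tryCatch(read_sbml(fx$sbml)$model,
                    error = function(e) if (valid) stop(e) else NULL)
  structure(list(name = name, sbml = fx$sbml, model = model,
                 expected = fx$expected, settings = fx$settings,
                 valid = valid),
            class = "fixture_case")
}

#' Run a fixture with its recommended settings
#'
#' @param fx a `fixture_case` from [generate_fixture()], or a fixture
#'   name.
#' @param solver solver to use (defaults to the fixture's recommended
#'   one, or `"rosenbrock"` for fixtures runnable with any solver).
#' @param seed RNG seed.
#' @param ... overrides passed to [solver_config()].
#' @return An `sbml_simulation` (see [simulate_sbml()]).
#' @export
run_fixture <- function(fx, solver = NULL, seed = 1L, ...) {
  if (is.character(fx)) fx <- generate_fixture(fx)
  st <- fx$settings
  if (is.null(solver))
    solver <- if (identical(st$solver, "all")) "rosenbrock" else st$solver
  dots <- list(...)
  cfg_args <- list(solver = solver,
                   output_steps = st$output_steps %||% 100L,
                   seed = seed)
  for (nm in c("h_min", "h_max", "atol", "rtol"))
    if (!is.null(st[[nm]])) cfg_args[[nm]] <- st[[nm]]
  cfg_args[names(dots)] <- dots
  config <- do.call(solver_config, cfg_args)
  simulate_sbml(fx$model, t_end = st$t_end, config = config)
}
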