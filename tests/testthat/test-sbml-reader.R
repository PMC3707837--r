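# SBML reading across levels, normalization, and reader determinism.

l3_header <- "<?xml version=\"1.0\"?><sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" level=\"3\" version=\"1\">"

test_that("a minimal Level 3 model with one parameter reads correctly", {
  doc <- read_sbml(paste0(
    l3_header, "<model id=\"m\"><listOfParameters>",
    "<parameter id=\"p\" value=\"2\" constant=\"true\"/>",
    "</listOfParameters></model></sbml>"))
  expect_identical(doc$info$level, 3L)
  expect_identical(doc$info$version, 1L)
  expect_length(doc$model$parameters, 1L)
  expect_equal(doc$model$parameters$p$value, 2)
  expect_true(doc$model$parameters$p$constant)
})

test_that("Level 2 StoichiometryMath becomes an expression-valued stoichiometry", {
  fx <- generate_fixture("variable_stoichiometry")
  expect_identical(fx$model$level, 2L)
  prod <- fx$model$reactions[[1]]$products[[1]]
  expect_false(is.null(prod$stoich_math))
  expect_equal(eval_ast(prod$stoich_math, t = 3), 4)  # 1 + t
})

test_that("a Level 3 species-reference id targeted by a rule is a state quantity", {
  fx <- generate_fixture("stoich_reference_l3")
  expect_true("sB" %in% names(fx$model$stoich_ids))
  idx <- build_state_index(fx$model)
  expect_true("sB" %in% idx$ids)
  expect_identical(unname(idx$role[["sB"]]), "stoichiometry")
  tgt <- vapply(fx$model$rules, `[[`, character(1), "variable")
  expect_true("sB" %in% tgt)
})

test_that("the Level 1 dialect is normalized (specie spelling, formulas)", {
  fx <- generate_fixture("l1_decay")
  m <- fx$model
  expect_identical(m$level, 1L)
  expect_true("S" %in% names(m$species))
  expect_equal(m$compartments$c$size, 1)
  kin <- m$reactions[[1]]$kinetic_law
  expect_equal(eval_ast(kin, Q = c(k = 0.7, S = 10)), 7)
})

test_that("Level 1 rule elements map to assignment and rate rules", {
  doc <- read_sbml(paste0(
    "<?xml version=\"1.0\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level1\" level=\"1\" version=\"2\">",
    "<model name=\"m\"><listOfParameters>",
    "<parameter name=\"p\" value=\"1\"/><parameter name=\"q\" value=\"0\"/>",
    "</listOfParameters><listOfRules>",
    "<parameterRule name=\"p\" formula=\"2*q\"/>",
    "<parameterRule name=\"q\" type=\"rate\" formula=\"1\"/>",
    "</listOfRules></model></sbml>"))
  kinds <- vapply(doc$model$rules, `[[`, character(1), "kind")
  expect_identical(sort(kinds), c("assignment", "rate"))
})

test_that("initial concentrations convert to amounts with the resolved size", {
  # species with initialConcentration 2 in a compartment whose size an
  # initial assignment sets to 3 -> amount 6 at t0
  doc <- read_sbml(paste0(
    l3_header, "<model id=\"m\">",
    "<listOfCompartments><compartment id=\"c\" size=\"1\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies><species id=\"X\" compartment=\"c\" ",
    "initialConcentration=\"2\" hasOnlySubstanceUnits=\"false\" ",
    "boundaryCondition=\"true\" constant=\"false\"/></listOfSpecies>",
    "<listOfInitialAssignments><initialAssignment symbol=\"c\">",
    "<math xmlns=\"http://www.w3.org/1998/Math/MathML\"><cn>3</cn></math>",
    "</initialAssignment></listOfInitialAssignments>",
    "</model></sbml>"))
  m <- doc$model
  expect_false(m$species$X$initial_is_amount)
  sim <- sbml_interpreter(m)
  Q0 <- sim_initialize(sim)
  expect_equal(Q0[["c"]], 3)
  expect_equal(Q0[["X"]], 6)   # amount = concentration x size

  # initialAmount is compartment-independent
  doc2 <- read_sbml(paste0(
    l3_header, "<model id=\"m\">",
    "<listOfCompartments><compartment id=\"c\" size=\"5\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies><species id=\"X\" compartment=\"c\" ",
    "initialAmount=\"4\" hasOnlySubstanceUnits=\"false\" ",
    "boundaryCondition=\"true\" constant=\"false\"/></listOfSpecies>",
    "</model></sbml>"))
  sim2 <- sbml_interpreter(doc2$model)
  expect_equal(sim_initialize(sim2)[["X"]], 4)
})

test_that("species without substance units evaluate as concentrations in kinetics", {
  # amount 6 in a compartment of size 3: the kinetic law sees 2
  doc <- read_sbml(paste0(
    l3_header, "<model id=\"m\">",
    "<listOfCompartments><compartment id=\"c\" size=\"3\" constant=\"true\"/>",
    "</listOfCompartments>",
    "<listOfSpecies><species id=\"X\" compartment=\"c\" initialAmount=\"6\" ",
    "hasOnlySubstanceUnits=\"false\" boundaryCondition=\"true\" ",
    "constant=\"false\"/><species id=\"Y\" compartment=\"c\" ",
    "initialAmount=\"0\" hasOnlySubstanceUnits=\"true\" ",
    "boundaryCondition=\"false\" constant=\"false\"/></listOfSpecies>",
    "<listOfReactions><reaction id=\"r\" reversible=\"false\" fast=\"false\">",
    "<listOfProducts><speciesReference species=\"Y\" stoichiometry=\"1\" ",
    "constant=\"true\"/></listOfProducts>",
    "<kineticLaw><math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
    "<ci>X</ci></math></kineticLaw></reaction></listOfReactions>",
    "</model></sbml>"))
  sim <- sbml_interpreter(doc$model)
  Q0 <- sim_initialize(sim)
  dQ <- compute_derivatives(sim, Q0, 0)
  expect_equal(dQ[["Y"]], 2)   # velocity = [X] = 6/3
})

test_that("malformed XML and required packages are rejected", {
  expect_error(read_sbml("<sbml><model"), "parse error")
  expect_error(read_sbml("<notSBML/>"), "not an SBML")
  expect_error(read_sbml(paste0(
    "<?xml version=\"1.0\"?>",
    "<sbml xmlns=\"http://www.sbml.org/sbml/level3/version1/core\" ",
    "xmlns:comp=\"http://www.sbml.org/sbml/level3/version1/comp/version1\" ",
    "level=\"3\" version=\"1\" comp:required=\"true\"><model id=\"m\"/></sbml>")),
    "comp")
})

test_that("reading is deterministic and all fixtures parse and validate", {
  for (nm in fixture_names()) {
    fx <- generate_fixture(nm)
    d1 <- model_dump(read_sbml(fx$sbml)$model)
    d2 <- model_dump(read_sbml(fx$sbml)$model)
    expect_identical(d1, d2)
    expect_length(validate_model(fx$model), 0L)
  }
})

test_that("checked-in fixture files equal the generated documents", {
  dir <- system.file("extdata", "models", package = "sbmlode")
  expect_true(nzchar(dir))
  for (nm in fixture_names(valid_only = FALSE)) {
    path <- file.path(dir, paste0(nm, ".xml"))
    expect_true(file.exists(path))
    on_disk <- paste(readLines(path, warn = FALSE), collapse = "\n")
    generated <- sub("\n$", "", generate_fixture(nm)$sbml)
    expect_identical(on_disk, generated)
  }
})
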