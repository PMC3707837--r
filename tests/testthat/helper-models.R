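# Small constructors for building models programmatically in tests.

# internal helpers exercised directly by some tests
ast_key <- sbmlode:::ast_key
ast_distinct_subtrees <- sbmlode:::ast_distinct_subtrees
ast_symbols <- sbmlode:::ast_symbols
graph_lookup <- sbmlode:::graph_lookup
algebraic_residuals <- sbmlode:::algebraic_residuals

mk_comp <- function(id, size = 1, constant = TRUE)
  list(id = id, size = size, spatial_dimensions = 3, constant = constant)

mk_species <- function(id, comp = "c", amount = NA, conc = NA,
                       hosu = TRUE, boundary = FALSE, constant = FALSE) {
  list(id = id, compartment = comp,
       initial_value = if (!is.na(amount)) amount else conc,
       initial_is_amount = if (!is.na(amount)) TRUE
                           else if (!is.na(conc)) FALSE else hosu,
       has_only_substance_units = hosu, boundary_condition = boundary,
       constant = constant)
}

mk_param <- function(id, value = 0, constant = FALSE)
  list(id = id, value = value, constant = constant)

mk_ref <- function(species, stoichiometry = 1, stoich_math = NULL,
                   stoich_id = NA)
  list(species = species, stoichiometry = stoichiometry,
       stoich_math = stoich_math, stoich_id = stoich_id)

mk_reaction <- function(id, reactants = list(), products = list(),
                        kinetic_law = NULL, modifiers = character(0))
  list(id = id, reversible = TRUE, reactants = reactants,
       products = products, modifiers = modifiers,
       kinetic_law = kinetic_law, local_parameters = numeric(0))

mk_rule <- function(kind, variable, math)
  list(kind = kind, variable = variable, math = math)

mk_event <- function(id, trigger, assignments, priority = NULL,
                     delay = NULL, persistent = TRUE,
                     trigger_initial_value = TRUE,
                     use_trigger_time_values = FALSE) {
  list(id = id, trigger = trigger, persistent = persistent,
       trigger_initial_value = trigger_initial_value,
       use_trigger_time_values = use_trigger_time_values,
       delay = delay, priority = priority,
       assignments = assignments)
}

mk_assign <- function(variable, math) list(variable = variable, math = math)

# shorthand tree builders
num_ <- ast_number
sym_ <- ast_symbol
op_ <- function(op, ...) ast_op(op, list(...))
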