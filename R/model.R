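## Internal, solver-agnostic representation of an SBML model.
##
## The state vector Q holds the sizes of all compartments, the amounts of
## all species, and the values of all global parameters (plus, in Level 3,
## species-reference identifiers that can be governed by rules or events).
## Local reaction parameters are substituted into kinetic laws when the
## model is read and never receive a state slot.

#' Construct a model specification
#'
#' Assembles the in-memory model representation used by the simulator.
#' Normally produced by [read_sbml()] or [generate_fixture()]; the
#' constructor is exported so that models can also be built
#' programmatically.
#'
#' @param compartments,species,parameters,stoich_ids named lists of
#'   quantity specifications (see the reader for the field sets).
#' @param reactions,rules,events,constraints,initial_assignments lists.
#' @param functions named list of function definitions (`id`, `params`,
#'   `body`).
#' @param level,version SBML level/version the model was read from.
#' @param id optional model identifier.
#' @return An object of class `sbml_model`.
#' @export
sbml_model <- function(compartments = list(), species = list(),
                       parameters = list(), stoich_ids = list(),
                       reactions = list(), rules = list(),
                       events = list(), constraints = list(),
                       initial_assignments = list(), functions = list(),
                       level = 3L, version = 1L, id = "model") {
  m <- list(id = id, level = level, version = version,
            compartments = compartments, species = species,
            parameters = parameters, stoich_ids = stoich_ids,
            reactions = reactions, rules = rules, events = events,
            constraints = constraints,
            initial_assignments = initial_assignments,
            functions = functions)
  class(m) <- "sbml_model"
  m
}

#' @export
print.sbml_model <- function(x, ...) {
  cat("<sbml_model '", x$id, "' L", x$level, "V", x$version, ": ",
      length(x$compartments), " compartment(s), ",
      length(x$species), " species, ",
      length(x$parameters), " parameter(s), ",
      length(x$reactions), " reaction(s), ",
      length(x$rules), " rule(s), ",
      length(x$events), " event(s)>\n", sep = "")
  invisible(x)
}

## Roles of every global quantity, in state-vector order.
model_quantities <- function(model) {
  ids <- c(names(model$compartments), names(model$species),
           names(model$parameters), names(model$stoich_ids))
  roles <- c(rep("compartment", length(model$compartments)),
             rep("species", length(model$species)),
             rep("parameter", length(model$parameters)),
             rep("stoichiometry", length(model$stoich_ids)))
  stats::setNames(roles, ids)
}

model_quantity_constant <- function(model, id) {
  for (slot in c("compartments", "species", "parameters", "stoich_ids")) {
    q <- model[[slot]][[id]]
    if (!is.null(q)) return(isTRUE(q$constant))
  }
  NA
}

#' Build the state-vector index of a model
#'
#' Assigns one position in the state vector Q to every compartment,
#' species, and global parameter (and every rule- or event-assignable
#' species-reference identifier).  Local reaction parameters get no slot.
#'
#' @param model an `sbml_model`.
#' @return Object of class `state_index`: list with `ids` (ordered
#'   identifiers), `pos` (named integer positions), and `role` (named
#'   roles).
#' @export
build_state_index <- function(model) {
  roles <- model_quantities(model)
  ids <- names(roles)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L)
    stop("model is invalid: duplicate identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  idx <- list(ids = ids,
              pos = stats::setNames(seq_along(ids), ids),
              role = roles)
  class(idx) <- "state_index"
  idx
}

#' @export
print.state_index <- function(x, ...) {
  cat("<state_index: ", length(x$ids), " quantities>\n", sep = "")
  invisible(x)
}

#' @export
length.state_index <- function(x) length(x$ids)

## ---------------------------------------------------------------------------
## Validation

rule_targets <- function(model) {
  vapply(model$rules, function(r)
    if (is.null(r$variable)) NA_character_ else r$variable, character(1))
}

#' Validate a model against the interpreter's structural constraints
#'
#' Returns all violations as a character vector (violations are data, not
#' errors); an empty result means the model is admissible.  Checked are:
#' identifier uniqueness and resolution, the exclusion of rate-ruled
#' species from reactions, constancy conflicts (constant quantities
#' targeted by rules or event assignments), and duplicate rule variables.
#' Overdetermination by algebraic rules is a separate check
#' ([check_overdetermined()]), run by [simulate_sbml()] and the CLI.
#'
#' @param model an `sbml_model`.
#' @return Character vector of violation messages (possibly empty).
#' @export
validate_model <- function(model) {
  v <- character(0)
  roles <- model_quantities(model)
  ids <- names(roles)

  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L)
    v <- c(v, paste0("duplicate identifier: ", dup))

  for (sp in model$species) {
    if (is.null(model$compartments[[sp$compartment]]))
      v <- c(v, paste0("species '", sp$id, "' references unknown ",
                       "compartment '", sp$compartment, "'"))
  }

  ## species participating in reactions (as reactant or product)
  participants <- character(0)
  for (rx in model$reactions)
    for (ref in c(rx$reactants, rx$products))
      participants <- c(participants, ref$species)
  participants <- unique(participants)

  tgt <- rule_targets(model)
  dup_tgt <- unique(tgt[!is.na(tgt) & duplicated(tgt)])
  if (length(dup_tgt) > 0L)
    v <- c(v, paste0("identifier '", dup_tgt,
                     "' is the variable of more than one rule"))

  for (i in seq_along(model$rules)) {
    r <- model$rules[[i]]
    if (r$kind == "algebraic") next
    var <- r$variable
    if (is.null(var) || !(var %in% ids)) {
      v <- c(v, paste0(r$kind, " rule targets unknown identifier '",
                       var, "'"))
      next
    }
    if (isTRUE(model_quantity_constant(model, var)))
      v <- c(v, paste0(r$kind, " rule targets constant quantity '",
                       var, "'"))
    if (r$kind == "rate" && roles[[var]] == "species" &&
        var %in% participants &&
        !isTRUE(model$species[[var]]$boundary_condition))
      v <- c(v, paste0("species '", var, "' has a rate rule but ",
                       "participates in a reaction"))
    if (r$kind == "assignment" && roles[[var]] == "species" &&
        var %in% participants &&
        !isTRUE(model$species[[var]]$boundary_condition))
      v <- c(v, paste0("species '", var, "' has an assignment rule but ",
                       "participates in a reaction"))
  }

  for (ev in model$events) {
    for (asgn in ev$assignments) {
      var <- asgn$variable
      if (!(var %in% ids)) {
        v <- c(v, paste0("event '", ev$id, "' assigns to unknown ",
                         "identifier '", var, "'"))
      } else if (isTRUE(model_quantity_constant(model, var))) {
        v <- c(v, paste0("event '", ev$id, "' assigns to constant ",
                         "quantity '", var, "'"))
      }
    }
  }

  ## all symbols used in model mathematics must resolve
  known <- c(ids, names(model$functions),
             vapply(model$reactions, function(r) r$id, character(1)))
  for (expr in model_math_trees(model)) {
    for (s in ast_symbols(expr))
      if (!(s %in% known))
        v <- c(v, paste0("unresolved symbol '", s, "' in model mathematics"))
  }
  unique(v)
}

## every top-level math tree in the model (locals already substituted)
model_math_trees <- function(model) {
  out <- list()
  add <- function(x) if (!is.null(x)) out[[length(out) + 1L]] <<- x
  for (rx in model$reactions) {
    add(rx$kinetic_law)
    for (ref in c(rx$reactants, rx$products)) add(ref$stoich_math)
  }
  for (r in model$rules) add(r$math)
  for (ia in model$initial_assignments) add(ia$math)
  for (ev in model$events) {
    add(ev$trigger); add(ev$priority); add(ev$delay)
    for (a in ev$assignments) add(a$math)
  }
  for (cn in model$constraints) add(cn$math)
  out
}
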