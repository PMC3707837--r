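## SBML reader: Level 1 Version 2 through Level 3 Version 1 (core).
##
## Level idiosyncrasies normalized here: Level 1 "specie" spelling,
## formula strings instead of MathML, the Level 1 rule dialect
## ("scalar"/"rate" rule types), Level 2 StoichiometryMath, and Level 3
## species-reference identifiers assignable by rules and events.

attr_chr <- function(el, name, default = NA_character_) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) default else v
}

attr_num <- function(el, name, default = NA_real_) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) default else as.numeric(v)
}

attr_lgl <- function(el, name, default = NA) {
  v <- xml2::xml_attr(el, name)
  if (is.na(v)) default else tolower(v) %in% c("true", "1")
}

first_child <- function(el, name) {
  hit <- xml2::xml_find_first(el, paste0("./*[local-name()='", name, "']"))
  if (inherits(hit, "xml_missing")) NULL else hit
}

children_named <- function(el, name) {
  if (is.null(el)) return(list())
  as.list(xml2::xml_find_all(el, paste0("./*[local-name()='", name, "']")))
}

## math child of an element, or L1 formula attribute; NULL if neither
element_math <- function(el, formula_attr = "formula") {
  m <- first_child(el, "math")
  if (!is.null(m)) return(parse_mathml(m))
  f <- xml2::xml_attr(el, formula_attr)
  if (!is.na(f)) return(parse_formula(f))
  NULL
}

#' Read an SBML document
#'
#' Parses SBML XML (Level 1 Version 2 through Level 3 Version 1, core
#' namespace only) into the package's model representation.  A Level 3
#' document declaring a package with `required="true"` is rejected;
#' non-required package constructs are ignored with a warning.
#'
#' @param source path to an SBML file, or a character scalar of SBML XML.
#' @return List with elements `info` (list: `level`, `version`,
#'   `required_packages`) and `model` (an `sbml_model`).
#' @export
read_sbml <- function(source) {
  txt <- source
  if (length(source) == 1L && !grepl("<", source, fixed = TRUE)) {
    if (!file.exists(source))
      stop("SBML file not found: ", source, call. = FALSE)
    txt <- paste(readLines(source, warn = FALSE), collapse = "\n")
  }
  doc <- tryCatch(xml2::read_xml(txt),
                  error = function(e)
                    stop("SBML parse error: ", conditionMessage(e),
                         call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "sbml")
    stop("not an SBML document (root element is <",
         xml2::xml_name(root), ">)", call. = FALSE)
  level <- as.integer(xml2::xml_attr(root, "level"))
  version <- as.integer(xml2::xml_attr(root, "version"))
  if (is.na(level) || !(level %in% 1:3))
    stop("unsupported or missing SBML level", call. = FALSE)

  ## Level 3 packages: reject required ones, ignore the rest.  Package
  ## namespaces are the non-core SBML Level 3 namespace declarations.
  ns <- tryCatch(xml2::xml_ns(doc), error = function(e) character(0))
  pkg_prefixes <- names(ns)[grepl("sbml/level3", ns) &
                              !grepl("/core", ns)]
  attrs <- xml2::xml_attrs(root)
  req_true <- any(grepl("(^|:)required$", names(attrs)) &
                    tolower(attrs) == "true")
  req_pkgs <- sub("^d[0-9]+$", "unknown", pkg_prefixes)
  if (length(req_pkgs) > 0L) {
    if (req_true)
      stop("unsupported SBML package required by the model: '",
           paste(req_pkgs, collapse = "', '"), "'", call. = FALSE)
    warning("ignoring SBML package constructs: ",
            paste(req_pkgs, collapse = ", "), call. = FALSE)
  }

  xml2::xml_ns_strip(doc)
  model_el <- first_child(root, "model")
  if (is.null(model_el)) stop("SBML document has no <model>", call. = FALSE)

  model <- parse_model_element(model_el, level, version)
  list(info = list(level = level, version = version,
                   required_packages = req_pkgs),
       model = model)
}

id_of <- function(el, level) {
  id <- xml2::xml_attr(el, "id")
  if (is.na(id)) id <- xml2::xml_attr(el, "name")  # Level 1
  id
}

parse_model_element <- function(model_el, level, version) {
  lo <- function(name) first_child(model_el, name)

  compartments <- list()
  for (el in children_named(lo("listOfCompartments"), "compartment")) {
    id <- id_of(el, level)
    size <- attr_num(el, "size")
    if (is.na(size)) size <- attr_num(el, "volume")      # Level 1
    if (is.na(size) && level <= 2L) size <- 1            # L1/L2 default
    compartments[[id]] <- list(
      id = id, size = size,
      spatial_dimensions = attr_num(el, "spatialDimensions", 3),
      constant = attr_lgl(el, "constant", NA))
  }

  species <- list()
  sp_els <- c(children_named(lo("listOfSpecies"), "species"),
              children_named(lo("listOfSpecies"), "specie"))
  for (el in sp_els) {
    id <- id_of(el, level)
    comp <- attr_chr(el, "compartment")
    if (is.na(comp)) comp <- attr_chr(el, "compartment", "default")
    amt <- attr_num(el, "initialAmount")
    conc <- attr_num(el, "initialConcentration")
    init_is_amount <- if (!is.na(amt)) TRUE else if (!is.na(conc)) FALSE else NA
    species[[id]] <- list(
      id = id, compartment = comp,
      initial_value = if (!is.na(amt)) amt else conc,
      initial_is_amount = init_is_amount,
      has_only_substance_units = attr_lgl(el, "hasOnlySubstanceUnits",
                                          FALSE),
      boundary_condition = attr_lgl(el, "boundaryCondition", FALSE),
      constant = attr_lgl(el, "constant", NA))
  }

  parameters <- list()
  for (el in children_named(lo("listOfParameters"), "parameter")) {
    id <- id_of(el, level)
    parameters[[id]] <- list(id = id, value = attr_num(el, "value"),
                             constant = attr_lgl(el, "constant", NA))
  }

  functions <- list()
  for (el in children_named(lo("listOfFunctionDefinitions"),
                            "functionDefinition")) {
    id <- id_of(el, level)
    lam <- element_math(el)
    if (is.null(lam) || lam$kind != "lambda")
      stop("function definition '", id, "' must contain a lambda",
           call. = FALSE)
    functions[[id]] <- list(id = id, params = lam$params, body = lam$body)
  }

  stoich_ids <- list()
  reactions <- list()
  for (el in children_named(lo("listOfReactions"), "reaction")) {
    rid <- id_of(el, level)
    parse_refs <- function(list_name) {
      refs <- list()
      le <- first_child(el, list_name)
      ref_els <- c(children_named(le, "speciesReference"),
                   children_named(le, "specieReference"))
      for (re in ref_els) {
        sp <- attr_chr(re, "species")
        if (is.na(sp)) sp <- attr_chr(re, "specie")
        stoich <- attr_num(re, "stoichiometry", 1)
        den <- attr_num(re, "denominator", 1)            # Level 1
        sm <- first_child(re, "stoichiometryMath")       # Level 2
        sref_id <- attr_chr(re, "id")                    # Level 3
        if (!is.na(sref_id))
          stoich_ids[[sref_id]] <<- list(
            id = sref_id, value = stoich / den,
            reaction = rid, species = sp,
            constant = attr_lgl(re, "constant", NA))
        refs[[length(refs) + 1L]] <- list(
          species = sp, stoichiometry = stoich / den,
          stoich_math = if (is.null(sm)) NULL else parse_mathml(sm),
          stoich_id = sref_id)
      }
      refs
    }
    reactants <- parse_refs("listOfReactants")
    products <- parse_refs("listOfProducts")
    modifiers <- vapply(
      children_named(first_child(el, "listOfModifiers"),
                     "modifierSpeciesReference"),
      function(me) attr_chr(me, "species"), character(1))

    kl <- first_child(el, "kineticLaw")
    kinetic <- NULL
    locals <- numeric(0)
    if (!is.null(kl)) {
      kinetic <- element_math(kl)
      loc_els <- c(children_named(first_child(kl, "listOfParameters"),
                                  "parameter"),
                   children_named(first_child(kl, "listOfLocalParameters"),
                                  "localParameter"))
      for (pe in loc_els) {
        pid <- id_of(pe, level)
        locals[[pid]] <- attr_num(pe, "value")
      }
      if (!is.null(kinetic) && length(locals) > 0L) {
        ## local parameters shadow globals inside this kinetic law only:
        ## bind them lexically, they never enter the state vector
        subs <- lapply(locals, ast_number)
        kinetic <- ast_substitute(kinetic, subs)
      }
    }
    reactions[[length(reactions) + 1L]] <- list(
      id = rid, reversible = attr_lgl(el, "reversible", TRUE),
      reactants = reactants, products = products,
      modifiers = as.character(modifiers),
      kinetic_law = kinetic, local_parameters = locals)
  }

  rules <- list()
  rules_el <- lo("listOfRules")
  if (!is.null(rules_el)) {
    for (el in xml2::xml_children(rules_el)) {
      nm <- xml2::xml_name(el)
      if (nm %in% c("algebraicRule")) {
        rules[[length(rules) + 1L]] <- list(
          kind = "algebraic", variable = NULL, math = element_math(el))
      } else if (nm == "assignmentRule") {
        rules[[length(rules) + 1L]] <- list(
          kind = "assignment", variable = attr_chr(el, "variable"),
          math = element_math(el))
      } else if (nm == "rateRule") {
        rules[[length(rules) + 1L]] <- list(
          kind = "rate", variable = attr_chr(el, "variable"),
          math = element_math(el))
      } else if (nm %in% c("parameterRule", "speciesConcentrationRule",
                           "specieConcentrationRule",
                           "compartmentVolumeRule")) {
        ## Level 1 rule dialect
        var <- switch(nm,
          parameterRule = attr_chr(el, "name"),
          compartmentVolumeRule = attr_chr(el, "compartment"),
          {
            v <- attr_chr(el, "species")
            if (is.na(v)) attr_chr(el, "specie") else v
          })
        type <- attr_chr(el, "type", "scalar")
        rules[[length(rules) + 1L]] <- list(
          kind = if (type == "rate") "rate" else "assignment",
          variable = var, math = element_math(el))
      } else {
        stop("unsupported rule element: <", nm, ">", call. = FALSE)
      }
    }
  }

  initial_assignments <- list()
  for (el in children_named(lo("listOfInitialAssignments"),
                            "initialAssignment")) {
    initial_assignments[[length(initial_assignments) + 1L]] <- list(
      variable = attr_chr(el, "symbol"), math = element_math(el))
  }

  events <- list()
  for (el in children_named(lo("listOfEvents"), "event")) {
    eid <- id_of(el, level)
    if (is.na(eid)) eid <- paste0("event_", length(events) + 1L)
    trig_el <- first_child(el, "trigger")
    if (is.null(trig_el))
      stop("event '", eid, "' has no trigger", call. = FALSE)
    delay_el <- first_child(el, "delay")
    prio_el <- first_child(el, "priority")
    assignments <- list()
    for (ae in children_named(first_child(el, "listOfEventAssignments"),
                              "eventAssignment")) {
      assignments[[length(assignments) + 1L]] <- list(
        variable = attr_chr(ae, "variable"), math = element_math(ae))
    }
    events[[length(events) + 1L]] <- list(
      id = eid,
      trigger = element_math(trig_el),
      ## Level 2 events are persistent and an initially-true trigger is
      ## taken at its t0 value (no false-to-true transition at t0)
      persistent = attr_lgl(trig_el, "persistent", TRUE),
      trigger_initial_value = attr_lgl(trig_el, "initialValue",
                                       if (level >= 3L) TRUE else NA),
      use_trigger_time_values = attr_lgl(el, "useValuesFromTriggerTime",
                                         TRUE),
      delay = if (is.null(delay_el)) NULL else element_math(delay_el),
      priority = if (is.null(prio_el)) NULL else element_math(prio_el),
      assignments = assignments)
  }

  constraints <- list()
  for (el in children_named(lo("listOfConstraints"), "constraint")) {
    msg_el <- first_child(el, "message")
    constraints[[length(constraints) + 1L]] <- list(
      math = element_math(el),
      message = if (is.null(msg_el)) "constraint violated"
                else trimws(xml2::xml_text(msg_el)))
  }

  model <- sbml_model(
    compartments = compartments, species = species,
    parameters = parameters, stoich_ids = stoich_ids,
    reactions = reactions, rules = rules, events = events,
    constraints = constraints,
    initial_assignments = initial_assignments, functions = functions,
    level = level, version = version,
    id = attr_chr(model_el, "id", attr_chr(model_el, "name", "model")))

  model <- resolve_constancy_defaults(model)
  model <- expand_model_functions(model)
  normalize_initial_species(model)
}

## Fill in unspecified 'constant' flags: SBML defaults (L2: compartments
## and parameters constant, species variable), loosened to 'variable' for
## any quantity actually targeted by a rule, event, or initial assignment
## when the document did not set the flag explicitly (Level 1 has no
## constant attribute at all).
resolve_constancy_defaults <- function(model) {
  targets <- character(0)
  for (r in model$rules)
    if (!is.null(r$variable)) targets <- c(targets, r$variable)
  for (ev in model$events)
    for (a in ev$assignments) targets <- c(targets, a$variable)
  ## algebraic rules may determine any quantity appearing in them
  for (r in model$rules)
    if (r$kind == "algebraic") targets <- c(targets, ast_symbols(r$math))

  fix <- function(q, default_constant) {
    if (is.na(q$constant))
      q$constant <- if (q$id %in% targets) FALSE else default_constant
    q
  }
  model$compartments <- lapply(model$compartments, fix, default_constant = TRUE)
  model$species <- lapply(model$species, fix, default_constant = FALSE)
  model$parameters <- lapply(model$parameters, fix, default_constant = TRUE)
  model$stoich_ids <- lapply(model$stoich_ids, fix, default_constant = TRUE)
  model
}

## Expand user-defined function calls in every math tree (capture-safe
## substitution); downstream code never sees 'call' nodes.
expand_model_functions <- function(model) {
  fns <- model$functions
  ## function bodies may call other functions: expand bodies first
  if (length(fns) > 0L) {
    for (nm in names(fns))
      fns[[nm]]$body <- expand_calls(fns[[nm]]$body, fns, active = nm)
    model$functions <- fns
  }
  ex <- function(tree) {
    if (is.null(tree)) return(NULL)
    expand_calls(tree, fns, character(0))
  }
  for (i in seq_along(model$reactions)) {
    model$reactions[[i]]$kinetic_law <- ex(model$reactions[[i]]$kinetic_law)
    for (side in c("reactants", "products"))
      for (j in seq_along(model$reactions[[i]][[side]]))
        model$reactions[[i]][[side]][[j]]$stoich_math <-
          ex(model$reactions[[i]][[side]][[j]]$stoich_math)
  }
  for (i in seq_along(model$rules))
    model$rules[[i]]$math <- ex(model$rules[[i]]$math)
  for (i in seq_along(model$initial_assignments))
    model$initial_assignments[[i]]$math <-
      ex(model$initial_assignments[[i]]$math)
  for (i in seq_along(model$events)) {
    model$events[[i]]$trigger <- ex(model$events[[i]]$trigger)
    model$events[[i]]$priority <- ex(model$events[[i]]$priority)
    model$events[[i]]$delay <- ex(model$events[[i]]$delay)
    for (j in seq_along(model$events[[i]]$assignments))
      model$events[[i]]$assignments[[j]]$math <-
        ex(model$events[[i]]$assignments[[j]]$math)
  }
  for (i in seq_along(model$constraints))
    model$constraints[[i]]$math <- ex(model$constraints[[i]]$math)
  model
}

#' Normalize species initial-quantity bookkeeping
#'
#' Ensures every species records whether its initial value is an amount
#' or a concentration.  Species with neither an initial amount nor an
#' initial concentration are flagged from `hasOnlySubstanceUnits` (their
#' value, when later set by an initial assignment or rule, is interpreted
#' in the species' own units).  No numeric conversion happens here; the
#' conversion amount = concentration x compartment size is performed at
#' initialization, after compartment sizes are resolved.
#'
#' @param model an `sbml_model`.
#' @return The updated model.
#' @export
normalize_initial_species <- function(model) {
  model$species <- lapply(model$species, function(sp) {
    if (is.na(sp$initial_is_amount))
      sp$initial_is_amount <- isTRUE(sp$has_only_substance_units)
    sp
  })
  model
}

#' Canonical textual dump of a model specification
#'
#' Deterministic, human-readable rendering of every structural and
#' mathematical component; two models with identical dumps are
#' interpreted identically.  Used to check reader determinism.
#'
#' @param model an `sbml_model`.
#' @return Character vector, one line per component.
#' @export
model_dump <- function(model) {
  out <- c(sprintf("model %s L%dV%d", model$id, model$level, model$version))
  qd <- function(q) paste(
    vapply(names(q), function(f) paste0(f, "=", format(q[[f]])),
           character(1)), collapse = " ")
  for (q in model$compartments) out <- c(out, paste("compartment", qd(q)))
  for (q in model$species) out <- c(out, paste("species", qd(q)))
  for (q in model$parameters) out <- c(out, paste("parameter", qd(q)))
  for (q in model$stoich_ids) out <- c(out, paste("stoichRef", qd(q)))
  for (rx in model$reactions) {
    refs <- function(rr) paste(vapply(rr, function(ref)
      paste0(ref$species, ":",
             if (!is.null(ref$stoich_math)) ast_key(ref$stoich_math)
             else if (!is.na(ref$stoich_id %||% NA)) ref$stoich_id
             else format(ref$stoichiometry)), character(1)),
      collapse = ",")
    out <- c(out, sprintf(
      "reaction %s [%s] -> [%s] mod[%s] kin=%s", rx$id,
      refs(rx$reactants), refs(rx$products),
      paste(rx$modifiers, collapse = ","),
      if (is.null(rx$kinetic_law)) "-" else ast_key(rx$kinetic_law)))
  }
  for (r in model$rules)
    out <- c(out, sprintf("rule %s %s := %s", r$kind,
                          r$variable %||% "-", ast_key(r$math)))
  for (ia in model$initial_assignments)
    out <- c(out, sprintf("init %s := %s", ia$variable, ast_key(ia$math)))
  for (ev in model$events) {
    out <- c(out, sprintf(
      "event %s trig=%s persist=%s tiv=%s utt=%s delay=%s prio=%s [%s]",
      ev$id, ast_key(ev$trigger), ev$persistent,
      ev$trigger_initial_value, ev$use_trigger_time_values,
      if (is.null(ev$delay)) "-" else ast_key(ev$delay),
      if (is.null(ev$priority)) "-" else ast_key(ev$priority),
      paste(vapply(ev$assignments, function(a)
        paste0(a$variable, ":=", ast_key(a$math)), character(1)),
        collapse = "; ")))
  }
  for (cn in model$constraints)
    out <- c(out, sprintf("constraint %s '%s'", ast_key(cn$math),
                          cn$message))
  out
}
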