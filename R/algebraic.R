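## Algebraic rules: overdetermination check and conversion to assignment
## rules via maximum bipartite matching.
##
## A bipartite graph is built between equations (reactions with kinetic
## laws, assignment/rate rules, algebraic rules) and determinable
## variables (non-constant compartments, species, parameters).  A maximum
## matching is computed with the Hopcroft-Karp algorithm (greedy seed
## extended by augmenting paths).  If any equation vertex stays
## unmatched, the model is overdetermined and rejected; otherwise each
## algebraic rule is rearranged into an assignment rule for the variable
## it was matched to.

#' Build the equation/variable bipartite graph of a model
#'
#' Equation vertices: one per reaction with a kinetic law, one per
#' assignment rule, rate rule, and algebraic rule.  Variable vertices:
#' every non-constant compartment, species, parameter (and assignable
#' species-reference identifier), in document order.  Edges: a reaction
#' is connected to its non-boundary, non-constant reactant and product
#' species; an assignment or rate rule to its variable; an algebraic rule
#' to every variable vertex occurring in its expression.
#'
#' @param model an `sbml_model`.
#' @return Object of class `bipartite_graph`: list with `eq_labels`,
#'   `eq_type`, `eq_rule_index` (index into `model$rules` for rule
#'   equations, `NA` for reactions), `vars` (character), and `adj` (list
#'   of integer vectors, variable indices per equation).
#' @export
build_bipartite <- function(model) {
  roles <- model_quantities(model)
  is_const <- vapply(names(roles), function(id)
    isTRUE(model_quantity_constant(model, id)), logical(1))
  vars <- names(roles)[!is_const]
  vpos <- stats::setNames(seq_along(vars), vars)

  eq_labels <- character(0)
  eq_type <- character(0)
  eq_rule_index <- integer(0)
  adj <- list()
  add_eq <- function(label, type, rule_idx, var_ids) {
    eq_labels <<- c(eq_labels, label)
    eq_type <<- c(eq_type, type)
    eq_rule_index <<- c(eq_rule_index, rule_idx)
    idx <- unname(vpos[intersect(unique(var_ids), vars)])
    adj[[length(adj) + 1L]] <<- sort(idx)
  }

  for (rx in model$reactions) {
    if (is.null(rx$kinetic_law)) next
    sp_ids <- character(0)
    for (ref in c(rx$reactants, rx$products)) {
      sp <- model$species[[ref$species]]
      if (!is.null(sp) && !isTRUE(sp$boundary_condition) &&
          !isTRUE(sp$constant))
        sp_ids <- c(sp_ids, ref$species)
    }
    add_eq(rx$id, "reaction", NA_integer_, sp_ids)
  }
  for (i in seq_along(model$rules)) {
    r <- model$rules[[i]]
    if (r$kind == "algebraic") {
      add_eq(paste0("algebraic_", i), "algebraic", i, ast_symbols(r$math))
    } else {
      add_eq(paste0(r$kind, "_", i), r$kind, i, r$variable)
    }
  }

  ## Preference order within each adjacency list: variables adjacent to
  ## fewer equations first (ties by document order).  An algebraic rule
  ## should determine a variable whose value is not already defined
  ## through other equations of the model; scanning low-degree variables
  ## first makes the greedy seed (and the augmenting search) pick such
  ## variables deterministically.
  degree <- integer(length(vars))
  for (a in adj) degree[a] <- degree[a] + 1L
  adj <- lapply(adj, function(a) a[order(degree[a], a)])

  structure(list(eq_labels = eq_labels, eq_type = eq_type,
                 eq_rule_index = eq_rule_index, vars = vars, adj = adj),
            class = "bipartite_graph")
}

#' @export
print.bipartite_graph <- function(x, ...) {
  cat("<bipartite_graph: ", length(x$eq_labels), " equation(s), ",
      length(x$vars), " variable(s)>\n", sep = "")
  invisible(x)
}

#' Greedy seed matching
#'
#' Scans equations in document order and matches each to its first free
#' adjacent variable.
#'
#' @param graph a [build_bipartite()] graph.
#' @return A matching: list with `eq_to_var`, `var_to_eq` (integer
#'   vectors, `NA` = unmatched) and `maximal` flag (`FALSE` here).
#' @export
greedy_matching <- function(graph) {
  ne <- length(graph$adj)
  nv <- length(graph$vars)
  eq_to_var <- rep(NA_integer_, ne)
  var_to_eq <- rep(NA_integer_, nv)
  for (e in seq_len(ne)) {
    for (v in graph$adj[[e]]) {
      if (is.na(var_to_eq[v])) {
        eq_to_var[e] <- v
        var_to_eq[v] <- e
        break
      }
    }
  }
  list(eq_to_var = eq_to_var, var_to_eq = var_to_eq, maximal = FALSE)
}

#' Maximum bipartite matching by Hopcroft-Karp
#'
#' Extends a seed matching with shortest augmenting paths (BFS layering
#' followed by layered DFS), repeated until no augmenting path exists —
#' at which point the matching is maximum by Berge's theorem.
#'
#' @param graph a [build_bipartite()] graph.
#' @param seed_matching optional starting matching; defaults to
#'   [greedy_matching()].
#' @return A matching with the `maximal` flag set.
#' @export
hopcroft_karp <- function(graph, seed_matching = NULL) {
  if (is.null(seed_matching)) seed_matching <- greedy_matching(graph)
  ne <- length(graph$adj)
  eq_to_var <- seed_matching$eq_to_var
  var_to_eq <- seed_matching$var_to_eq
  INF <- Inf

  repeat {
    ## BFS from free equation vertices: layer distances over alternating
    ## paths (equation -> variable via non-matching edge, variable ->
    ## equation via matching edge)
    dist <- rep(INF, ne)
    queue <- which(is.na(eq_to_var))
    dist[queue] <- 0
    found_free_var <- FALSE
    qi <- 1L
    while (qi <= length(queue)) {
      e <- queue[qi]; qi <- qi + 1L
      for (v in graph$adj[[e]]) {
        e2 <- var_to_eq[v]
        if (is.na(e2)) {
          found_free_var <- TRUE
        } else if (dist[e2] == INF) {
          dist[e2] <- dist[e] + 1
          queue <- c(queue, e2)
        }
      }
    }
    if (!found_free_var) break

    dfs <- function(e) {
      for (v in graph$adj[[e]]) {
        e2 <- var_to_eq[v]
        if (is.na(e2) || (dist[e2] == dist[e] + 1 && dfs(e2))) {
          var_to_eq[v] <<- e
          eq_to_var[e] <<- v
          return(TRUE)
        }
      }
      dist[e] <<- INF   # dead end for this phase
      FALSE
    }
    for (e in which(is.na(eq_to_var))) if (dist[e] == 0) dfs(e)
  }
  list(eq_to_var = eq_to_var, var_to_eq = var_to_eq, maximal = TRUE)
}

#' Is the model overdetermined?
#'
#' True iff some equation vertex remains unmatched in a maximum matching;
#' per the SBML specifications such a model is invalid.
#'
#' @param matching a maximal matching from [hopcroft_karp()].
#' @param graph the matched [build_bipartite()] graph.
#' @return Logical scalar.
#' @export
check_overdetermined <- function(matching, graph) {
  stopifnot(isTRUE(matching$maximal))
  any(is.na(matching$eq_to_var))
}

## ---------------------------------------------------------------------------
## Rearrangement of an algebraic rule into an assignment rule

## fold a numeric-only operator application to a literal
fold <- function(op, args) {
  if (all(vapply(args, function(a) a$kind == "number", logical(1)))) {
    vals <- lapply(args, function(a) a$value)
    fake <- list(kind = "op", op = op, args = lapply(vals, wrap_value))
    return(ast_number(ast_eval_op(fake, list())))
  }
  ast_op(op, args)
}

## Split expr syntactically as a*target + b with a, b free of target;
## NULL when the occurrence of target is not linear.
linear_split <- function(node, target) {
  has_target <- function(n) target %in% ast_symbols(n)
  if (!has_target(node))
    return(list(a = ast_number(0), b = node))
  kind <- node$kind
  if (kind == "symbol" && node$id == target)
    return(list(a = ast_number(1), b = ast_number(0)))
  if (kind != "op") return(NULL)
  op <- node$op
  if (op == "plus") {
    parts <- lapply(node$args, linear_split, target = target)
    if (any(vapply(parts, is.null, logical(1)))) return(NULL)
    list(a = fold("plus", lapply(parts, `[[`, "a")),
         b = fold("plus", lapply(parts, `[[`, "b")))
  } else if (op == "minus") {
    parts <- lapply(node$args, linear_split, target = target)
    if (any(vapply(parts, is.null, logical(1)))) return(NULL)
    list(a = fold("minus", lapply(parts, `[[`, "a")),
         b = fold("minus", lapply(parts, `[[`, "b")))
  } else if (op == "times") {
    carrier <- vapply(node$args, has_target, logical(1))
    if (sum(carrier) != 1L) return(NULL)
    inner <- linear_split(node$args[[which(carrier)]], target)
    if (is.null(inner)) return(NULL)
    others <- node$args[!carrier]
    mul <- function(x) {
      if (x$kind == "number" && x$value == 0) return(ast_number(0))
      fold("times", c(others, list(x)))
    }
    list(a = mul(inner$a), b = mul(inner$b))
  } else if (op == "divide") {
    num <- node$args[[1L]]; den <- node$args[[2L]]
    if (has_target(den)) return(NULL)
    inner <- linear_split(num, target)
    if (is.null(inner)) return(NULL)
    dv <- function(x) {
      if (x$kind == "number" && x$value == 0) return(ast_number(0))
      fold("divide", list(x, den))
    }
    list(a = dv(inner$a), b = dv(inner$b))
  } else {
    NULL
  }
}

#' Rearrange an algebraic rule into an assignment rule
#'
#' For an algebraic expression that is syntactically linear in `target`
#' (decomposable as `a * target + b` with `a`, `b` free of `target`),
#' returns the assignment rule `target := -b / a`.  A nonlinear
#' occurrence of the target raises a transformation-unsupported error —
#' such rules cannot, in general, be rearranged symbolically.
#'
#' @param rule an algebraic rule (list with `kind = "algebraic"` and
#'   `math`).
#' @param target identifier of the matched variable.
#' @return An assignment rule (list with `kind`, `variable`, `math`).
#' @export
rearrange <- function(rule, target) {
  stopifnot(identical(rule$kind, "algebraic"))
  sp <- linear_split(rule$math, target)
  if (is.null(sp) || (sp$a$kind == "number" && sp$a$value == 0))
    stop("cannot rearrange algebraic rule for '", target,
         "': target does not occur linearly (transformation unsupported)",
         call. = FALSE)
  math <- if (sp$a$kind == "number" && sp$a$value == 1) {
    fold("minus", list(sp$b))
  } else if (sp$a$kind == "number" && sp$a$value == -1) {
    sp$b
  } else {
    fold("divide", list(fold("minus", list(sp$b)), sp$a))
  }
  ## -0 folds to plain 0
  if (math$kind == "number" && math$value == 0) math <- ast_number(0)
  list(kind = "assignment", variable = target, math = math,
       from_algebraic = TRUE)
}

#' Convert all algebraic rules of a model to assignment rules
#'
#' Runs the full pipeline: bipartite construction, greedy + Hopcroft-Karp
#' matching, overdetermination check, and rearrangement.  The converted
#' rules are temporary simulation rules: they replace the algebraic rules
#' in the returned model's rule list, while the original algebraic
#' expressions are retained (field `algebraic_originals`) so their
#' residuals can be monitored during simulation.
#'
#' @param model an `sbml_model`.
#' @return The converted model.
#' @export
convert_algebraic_rules <- function(model) {
  alg_idx <- which(vapply(model$rules, function(r)
    r$kind == "algebraic", logical(1)))
  model$algebraic_originals <- lapply(model$rules[alg_idx], `[[`, "math")
  if (length(alg_idx) == 0L) return(model)

  graph <- build_bipartite(model)
  matching <- hopcroft_karp(graph)
  if (check_overdetermined(matching, graph)) {
    un <- graph$eq_labels[is.na(matching$eq_to_var)]
    stop("model is overdetermined (unmatched equation vertex: ",
         paste(un, collapse = ", "), "); not a valid SBML model",
         call. = FALSE)
  }
  for (i in seq_along(graph$eq_labels)) {
    if (graph$eq_type[i] != "algebraic") next
    ridx <- graph$eq_rule_index[i]
    target <- graph$vars[matching$eq_to_var[i]]
    model$rules[[ridx]] <- rearrange(model$rules[[ridx]], target)
  }
  model
}
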