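## Abstract syntax trees for the MathML subset used by SBML.
##
## Trees are plain lists (class "sbml_ast"); after interning into a syntax
## graph (see graph.R) structurally identical subtrees become one shared
## node.  The same field names are used for both representations so the
## uncached evaluator below works on either.

#' Construct an expression node
#'
#' Low-level constructors for the expression trees used throughout the
#' package.  Most users never build trees by hand; they come out of
#' [parse_mathml()] or [parse_formula()].
#'
#' @param value numeric literal.
#' @param id symbol identifier.
#' @param op operator name (see `ast_ops()` for the supported set).
#' @param args list of child nodes.
#' @return A list of class `sbml_ast`.
#' @keywords internal
#' @name ast
NULL

#' @rdname ast
#' @export
ast_number <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L)
  structure(list(kind = "number", value = as.numeric(value)),
            class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_bool <- function(value) {
  structure(list(kind = "bool", value = isTRUE(value)), class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_symbol <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  structure(list(kind = "symbol", id = id), class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_time <- function() structure(list(kind = "time"), class = "sbml_ast")

#' @rdname ast
#' @export
ast_op <- function(op, args) {
  stopifnot(is.character(op), length(op) == 1L)
  if (!op %in% .ast_op_names)
    stop("unsupported operator in expression: '", op, "'", call. = FALSE)
  structure(list(kind = "op", op = op, args = args), class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_call <- function(fn, args) {
  structure(list(kind = "call", fn = fn, args = args), class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_lambda <- function(params, body) {
  structure(list(kind = "lambda", params = params, body = body),
            class = "sbml_ast")
}

#' @rdname ast
#' @export
ast_delay <- function(x, tau) {
  structure(list(kind = "delay", args = list(x, tau)), class = "sbml_ast")
}

## Operator vocabulary.  piecewise args are (value1, cond1, value2, cond2,
## ..., [otherwise]); relationals of arity > 2 hold pairwise (MathML chain).
.ast_op_names <- c(
  "plus", "minus", "times", "divide", "power", "root",
  "exp", "ln", "log", "abs", "floor", "ceiling", "factorial",
  "sin", "cos", "tan", "sec", "csc", "cot",
  "sinh", "cosh", "tanh", "sech", "csch", "coth",
  "arcsin", "arccos", "arctan", "arcsec", "arccsc", "arccot",
  "arcsinh", "arccosh", "arctanh", "arcsech", "arccsch", "arccoth",
  "piecewise", "min", "max",
  "lt", "leq", "gt", "geq", "eq", "neq",
  "and", "or", "not", "xor"
)

#' Supported operator names
#' @return Character vector of operator names accepted by [ast_op()].
#' @export
ast_ops <- function() .ast_op_names

is_ast <- function(x) inherits(x, "sbml_ast") ||
  (is.list(x) && !is.null(x$kind)) || is.environment(x)

## ---------------------------------------------------------------------------
## Evaluation (uncached; works on trees and on interned graph nodes)

num_domain_error <- function(msg, node) {
  stop(structure(class = c("sbmlode_numeric_error", "error", "condition"),
                 list(message = paste0(msg, " [in ", ast_deparse(node), "]"),
                      call = NULL)))
}

as_num <- function(v, node) {
  if (is.logical(v))
    num_domain_error("boolean used where a number is required", node)
  v
}

as_bool <- function(v, node) {
  if (!is.logical(v))
    num_domain_error("number used where a boolean is required", node)
  v
}

## ctx fields: Q (named numeric), t, t0, conc_div (named chr: species id ->
## compartment id, only species evaluated as concentration), history
## (history_buffer or NULL), bindings (named list of values, lambda args).
ast_eval <- function(node, ctx) {
  kind <- node$kind
  if (kind == "number") return(node$value)
  if (kind == "bool") return(node$value)
  if (kind == "time") return(ctx$t)
  if (kind == "symbol") {
    id <- node$id
    b <- ctx$bindings
    if (!is.null(b) && !is.null(b[[id]])) return(b[[id]])
    v <- ctx$Q[[id]]
    if (is.null(v))
      stop("unresolved symbol '", id, "' during evaluation", call. = FALSE)
    cd <- ctx$conc_div
    if (!is.null(cd)) {
      comp <- cd[[id]]
      if (!is.null(comp)) {
        size <- ctx$Q[[comp]]
        if (!is.null(size)) {
          if (size == 0)
            num_domain_error(
              paste0("compartment '", comp, "' has zero size"), node)
          v <- v / size
        }
      }
    }
    return(v)
  }
  if (kind == "delay") {
    tau <- as_num(ast_eval(node$args[[2L]], ctx), node)
    if (is.na(tau) || tau < 0)
      num_domain_error("delay requires a nonnegative lag", node)
    tq <- ctx$t - tau
    hist <- ctx$history
    if (is.null(hist)) {
      ## no history available (e.g. initialization): use current state,
      ## clamped to t0 semantics
      ctx2 <- ctx_with_state(ctx, ctx$Q, max(tq, ctx$t0))
      return(ast_eval(node$args[[1L]], ctx2))
    }
    st <- history_state(hist, tq)
    ctx2 <- ctx_with_state(ctx, as.list(st$Q), st$t)
    return(ast_eval(node$args[[1L]], ctx2))
  }
  if (kind == "op") return(ast_eval_op(node, ctx))
  if (kind == "call")
    stop("unexpanded function call '", node$fn,
         "' during evaluation; bind function definitions first",
         call. = FALSE)
  if (kind == "lambda")
    stop("cannot evaluate a bare lambda expression", call. = FALSE)
  stop("unknown expression node kind: ", kind, call. = FALSE)
}

## derived evaluation context sharing everything but state (used by delay)
ctx_with_state <- function(ctx, Q, t) {
  list(Q = Q, t = t, t0 = ctx$t0, conc_div = ctx$conc_div,
       history = ctx$history, bindings = ctx$bindings)
}

ast_eval_op <- function(node, ctx) {
  op <- node$op
  args <- node$args

  if (op == "piecewise") {
    n <- length(args)
    i <- 1L
    while (i + 1L <= n) {
      cond <- as_bool(ast_eval(args[[i + 1L]], ctx), node)
      if (isTRUE(cond)) return(ast_eval(args[[i]], ctx))
      i <- i + 2L
    }
    if (i <= n) return(ast_eval(args[[i]], ctx))  # otherwise branch
    num_domain_error("piecewise with no applicable branch", node)
  }
  if (op == "and") {
    for (a in args) if (!isTRUE(as_bool(ast_eval(a, ctx), node)))
      return(FALSE)
    return(TRUE)
  }
  if (op == "or") {
    for (a in args) if (isTRUE(as_bool(ast_eval(a, ctx), node)))
      return(TRUE)
    return(FALSE)
  }
  if (op == "not")
    return(!as_bool(ast_eval(args[[1L]], ctx), node))
  if (op == "xor") {
    v <- FALSE
    for (a in args) v <- xor(v, as_bool(ast_eval(a, ctx), node))
    return(v)
  }

  if (op %in% c("lt", "leq", "gt", "geq", "eq", "neq")) {
    vals <- lapply(args, ast_eval, ctx = ctx)
    if (op == "eq" || op == "neq") {
      vv <- unlist(vals)
    } else {
      vv <- vapply(vals, as_num, numeric(1), node = node)
    }
    cmp <- switch(op,
      lt  = all(vv[-length(vv)] <  vv[-1L]),
      leq = all(vv[-length(vv)] <= vv[-1L]),
      gt  = all(vv[-length(vv)] >  vv[-1L]),
      geq = all(vv[-length(vv)] >= vv[-1L]),
      eq  = all(vv[-length(vv)] == vv[-1L]),
      neq = length(unique(vv)) == length(vv))
    return(cmp)
  }

  vals <- lapply(args, function(a) as_num(ast_eval(a, ctx), node))
  switch(op,
    plus  = sum(unlist(vals)),
    times = prod(unlist(vals)),
    minus = if (length(vals) == 1L) -vals[[1L]] else vals[[1L]] - vals[[2L]],
    divide = {
      if (vals[[2L]] == 0) num_domain_error("division by zero", node)
      vals[[1L]] / vals[[2L]]
    },
    power = vals[[1L]]^vals[[2L]],
    root = {
      if (length(vals) == 1L) sqrt(vals[[1L]])
      else vals[[2L]]^(1 / vals[[1L]])   # args: (degree, radicand)
    },
    exp = exp(vals[[1L]]),
    ln = {
      if (vals[[1L]] <= 0)
        num_domain_error("logarithm of a non-positive number", node)
      log(vals[[1L]])
    },
    log = {
      if (length(vals) == 1L) {
        if (vals[[1L]] <= 0)
          num_domain_error("logarithm of a non-positive number", node)
        log10(vals[[1L]])
      } else {
        if (vals[[2L]] <= 0)
          num_domain_error("logarithm of a non-positive number", node)
        log(vals[[2L]], base = vals[[1L]])  # args: (logbase, x)
      }
    },
    abs = abs(vals[[1L]]),
    floor = floor(vals[[1L]]),
    ceiling = ceiling(vals[[1L]]),
    factorial = factorial(vals[[1L]]),
    sin = sin(vals[[1L]]), cos = cos(vals[[1L]]), tan = tan(vals[[1L]]),
    sec = 1 / cos(vals[[1L]]), csc = 1 / sin(vals[[1L]]),
    cot = 1 / tan(vals[[1L]]),
    sinh = sinh(vals[[1L]]), cosh = cosh(vals[[1L]]),
    tanh = tanh(vals[[1L]]),
    sech = 1 / cosh(vals[[1L]]), csch = 1 / sinh(vals[[1L]]),
    coth = 1 / tanh(vals[[1L]]),
    arcsin = asin(vals[[1L]]), arccos = acos(vals[[1L]]),
    arctan = atan(vals[[1L]]),
    arcsec = acos(1 / vals[[1L]]), arccsc = asin(1 / vals[[1L]]),
    arccot = atan(1 / vals[[1L]]),
    arcsinh = asinh(vals[[1L]]), arccosh = acosh(vals[[1L]]),
    arctanh = atanh(vals[[1L]]),
    arcsech = acosh(1 / vals[[1L]]), arccsch = asinh(1 / vals[[1L]]),
    arccoth = atanh(1 / vals[[1L]]),
    min = min(unlist(vals)),
    max = max(unlist(vals)),
    stop("unsupported operator: ", op, call. = FALSE))
}

#' Evaluate an expression tree
#'
#' Evaluates a tree produced by [parse_mathml()] (or an interned graph node)
#' against a named state vector, without using the graph's value cache.
#'
#' @param node expression tree or graph node.
#' @param Q named numeric vector of quantity values.
#' @param t simulation time (default 0).
#' @param t0 simulation start time (default 0); delay lookups are clamped
#'   to `t0`.
#' @param conc_div named character vector mapping species identifiers to
#'   their compartment identifiers, for species evaluated as
#'   concentrations; may be `NULL`.
#' @param history optional [history_buffer()] for `delay()` expressions.
#' @param bindings named list of values for lambda-bound identifiers.
#' @return Numeric or logical scalar.
#' @export
eval_ast <- function(node, Q = numeric(0), t = 0, t0 = 0,
                     conc_div = NULL, history = NULL, bindings = NULL) {
  ctx <- list(Q = as.list(Q), t = t, t0 = t0,
              conc_div = if (is.null(conc_div)) NULL else as.list(conc_div),
              history = history, bindings = bindings)
  ast_eval(node, ctx)
}

## ---------------------------------------------------------------------------
## Structural identity, substitution, traversal

## Canonical structural key.  Numbers use 17 significant digits, which
## round-trips IEEE doubles, so equal keys mean bit-equal literals.
ast_key <- function(node) {
  kind <- node$kind
  switch(kind,
    number = sprintf("n:%.17g", node$value),
    bool = if (node$value) "b:1" else "b:0",
    symbol = paste0("s:", node$id),
    time = "t",
    delay = paste0("d(", ast_key(node$args[[1L]]), ",",
                   ast_key(node$args[[2L]]), ")"),
    op = paste0("o:", node$op, "(",
                paste(vapply(node$args, ast_key, character(1)),
                      collapse = ","), ")"),
    call = paste0("c:", node$fn, "(",
                  paste(vapply(node$args, ast_key, character(1)),
                        collapse = ","), ")"),
    lambda = paste0("l[", paste(node$params, collapse = ","), "]",
                    ast_key(node$body)),
    stop("unknown node kind: ", kind))
}

## Simultaneous capture-safe substitution of symbols by subtrees.
## subs: named list id -> tree.  Lambda parameters shadow substitutions.
ast_substitute <- function(node, subs) {
  if (length(subs) == 0L) return(node)
  kind <- node$kind
  if (kind == "symbol") {
    r <- subs[[node$id]]
    if (!is.null(r)) return(r)
    return(node)
  }
  if (kind %in% c("number", "bool", "time")) return(node)
  if (kind == "lambda") {
    inner <- subs[setdiff(names(subs), node$params)]
    return(ast_lambda(node$params, ast_substitute(node$body, inner)))
  }
  if (!is.null(node$args)) {
    node$args <- lapply(node$args, ast_substitute, subs = subs)
    return(node)
  }
  node
}

## All free symbol identifiers in a tree (lambda params excluded).
ast_symbols <- function(node) {
  kind <- node$kind
  if (kind == "symbol") return(node$id)
  if (kind == "lambda")
    return(setdiff(ast_symbols(node$body), node$params))
  if (!is.null(node$args))
    return(unique(unlist(lapply(node$args, ast_symbols))))
  character(0)
}

## Count of distinct subtrees (brute-force sharing oracle used in tests).
ast_distinct_subtrees <- function(trees) {
  seen <- new.env(parent = emptyenv())
  walk <- function(node) {
    key <- ast_key(node)
    if (is.null(seen[[key]])) assign(key, TRUE, envir = seen)
    if (node$kind %in% c("op", "call", "delay"))
      for (a in node$args) walk(a)
    if (node$kind == "lambda") walk(node$body)
  }
  for (tr in trees) walk(tr)
  length(ls(seen, all.names = TRUE))
}

#' Deparse an expression tree to a readable infix string
#' @param node expression tree or graph node.
#' @return Character scalar.
#' @export
ast_deparse <- function(node) {
  if (is.null(node)) return("<null>")
  kind <- node$kind
  infix <- c(plus = "+", minus = "-", times = "*", divide = "/",
             power = "^", lt = "<", leq = "<=", gt = ">", geq = ">=",
             eq = "==", neq = "!=", and = "&&", or = "||")
  switch(kind,
    number = format(node$value),
    bool = if (node$value) "true" else "false",
    symbol = node$id,
    time = "time",
    delay = paste0("delay(", ast_deparse(node$args[[1L]]), ", ",
                   ast_deparse(node$args[[2L]]), ")"),
    lambda = paste0("lambda(", paste(node$params, collapse = ", "),
                    ": ", ast_deparse(node$body), ")"),
    call = paste0(node$fn, "(",
                  paste(vapply(node$args, ast_deparse, character(1)),
                        collapse = ", "), ")"),
    op = {
      parts <- vapply(node$args, ast_deparse, character(1))
      if (!is.na(infix[node$op]) && length(parts) >= 2L)
        paste0("(", paste(parts, collapse = paste0(" ", infix[node$op],
                                                   " ")), ")")
      else if (node$op == "minus" && length(parts) == 1L)
        paste0("(-", parts, ")")
      else paste0(node$op, "(", paste(parts, collapse = ", "), ")")
    },
    paste0("<", kind, ">"))
}
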