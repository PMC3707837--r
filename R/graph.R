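## Hash-consed directed acyclic syntax graph.
##
## All model mathematics is merged into one graph: structurally identical
## subexpressions are represented by a single shared node, so that during
## simulation each distinct subexpression is evaluated at most once per
## state ("epoch").  Nodes are environments; the store maps a structural
## key (operator kind + literal bits + ordered child ids) to the canonical
## node.

#' Create an empty syntax graph
#'
#' @return An object of class `syntax_graph`.
#' @export
syntax_graph <- function() {
  g <- new.env(parent = emptyenv())
  g$store <- new.env(parent = emptyenv())  # key -> node
  g$nodes <- list()                        # id -> node (dense)
  g$n <- 0L
  g$epoch <- 0L
  g$counting <- FALSE
  g$counts <- NULL                         # per-epoch eval counters (id)
  class(g) <- "syntax_graph"
  g
}

#' @export
print.syntax_graph <- function(x, ...) {
  cat("<syntax graph: ", x$n, " nodes, epoch ", x$epoch, ">\n", sep = "")
  invisible(x)
}

#' Number of nodes in a syntax graph
#' @param graph a [syntax_graph()].
#' @return Integer node count.
#' @export
graph_size <- function(graph) graph$n

#' Intern an expression tree into a syntax graph
#'
#' Recursively merges `tree` into `graph`.  Subtrees already present are
#' reused: interning the same tree twice returns the identical node and
#' grows the graph by zero nodes.  Each node records the set of its
#' distinct parents.
#'
#' @param tree an expression tree ([ast]).
#' @param graph a [syntax_graph()].
#' @return The canonical graph node (an environment).
#' @export
intern <- function(tree, graph) {
  kind <- tree$kind
  if (kind == "call")
    stop("function calls must be bound (see bind_function) before interning",
         call. = FALSE)

  children <- NULL
  if (kind == "lambda")
    stop("bare lambda expressions are not interned; bind them at call sites",
         call. = FALSE)
  if (!is.null(tree$args))
    children <- lapply(tree$args, intern, graph = graph)

  key <- switch(kind,
    number = sprintf("n:%.17g", tree$value),
    bool = if (tree$value) "b:1" else "b:0",
    symbol = paste0("s:", tree$id),
    time = "t",
    delay = paste0("d(", paste(vapply(children, function(ch) ch$id_str,
                                      character(1)), collapse = ","), ")"),
    op = paste0("o:", tree$op, "(",
                paste(vapply(children, function(ch) ch$id_str,
                             character(1)), collapse = ","), ")"),
    stop("cannot intern node kind: ", kind))

  node <- graph$store[[key]]
  if (is.null(node)) {
    node <- new.env(parent = emptyenv())
    node$kind <- kind
    node$key <- key
    if (kind == "number" || kind == "bool") node$value <- tree$value
    if (kind == "symbol") { node$id <- tree$id; node$slot <- NA_integer_ }
    if (kind == "op") {
      node$op <- tree$op
      node$lazy <- tree$op %in% c("piecewise", "and", "or", "xor")
    }
    node$args <- children
    graph$n <- graph$n + 1L
    node$nid <- graph$n
    node$id_str <- as.character(graph$n)
    node$epoch <- -1L
    node$val <- NULL
    node$parents <- character(0)   # keys of distinct parents
    graph$nodes[[graph$n]] <- node
    assign(key, node, envir = graph$store)
  }
  if (!is.null(children)) {
    for (ch in children)
      if (!(key %in% ch$parents)) ch$parents <- c(ch$parents, key)
  }
  node
}

#' Number of distinct parents of a graph node
#' @param node an interned graph node.
#' @return Integer.
#' @export
node_parent_count <- function(node) length(node$parents)

#' Look up the canonical node for a tree, without growing the graph
#' @param tree expression tree.
#' @param graph a [syntax_graph()].
#' @return The node, or `NULL` if the tree (or any subtree) is absent.
#' @keywords internal
graph_lookup <- function(tree, graph) {
  probe <- function(tr) {
    kind <- tr$kind
    ids <- character(0)
    if (!is.null(tr$args)) {
      for (a in tr$args) {
        ch <- probe(a)
        if (is.null(ch)) return(NULL)
        ids <- c(ids, ch$id_str)
      }
    }
    key <- switch(kind,
      number = sprintf("n:%.17g", tr$value),
      bool = if (tr$value) "b:1" else "b:0",
      symbol = paste0("s:", tr$id),
      time = "t",
      delay = paste0("d(", paste(ids, collapse = ","), ")"),
      op = paste0("o:", tr$op, "(", paste(ids, collapse = ","), ")"),
      return(NULL))
    graph$store[[key]]
  }
  probe(tree)
}

## ---------------------------------------------------------------------------
## Cached evaluation

#' Begin a new evaluation epoch
#'
#' Invalidates all cached node values.  Called whenever the state vector
#' or the time changes; within one epoch every shared node is computed at
#' most once.
#'
#' @param graph a [syntax_graph()].
#' @param count if `TRUE`, per-node evaluation counters are recorded for
#'   this epoch (retrievable with [graph_eval_counts()]).
#' @return The new epoch number, invisibly.
#' @export
graph_new_epoch <- function(graph, count = FALSE) {
  graph$epoch <- graph$epoch + 1L
  graph$counting <- isTRUE(count)
  if (graph$counting) graph$counts <- new.env(parent = emptyenv())
  invisible(graph$epoch)
}

#' Per-node evaluation counts of the current epoch
#' @param graph a [syntax_graph()].
#' @return Named integer vector (names are node keys); only meaningful
#'   after `graph_new_epoch(graph, count = TRUE)`.
#' @export
graph_eval_counts <- function(graph) {
  if (is.null(graph$counts)) return(integer(0))
  keys <- ls(graph$counts, all.names = TRUE)
  vapply(keys, function(k) graph$counts[[k]], integer(1))
}

#' Evaluate an interned node with value caching
#'
#' Within the current epoch (see [graph_new_epoch()]) each node is
#' computed at most once; repeated evaluation — including through a
#' different root sharing the node — returns the cached value.
#' `delay(x, tau)` subtrees are evaluated against the interpolated
#' historical state and bypass the cache (their value does not depend on
#' the current state alone).
#'
#' @param node interned graph node.
#' @param graph the owning [syntax_graph()].
#' @param Q named numeric state vector.
#' @param t current time.
#' @param t0 simulation start time.
#' @param conc_div named character vector (species id -> compartment id)
#'   for species read as concentrations, or `NULL`.
#' @param history optional [history_buffer()].
#' @return Numeric or logical scalar.
#' @export
evaluate <- function(node, graph, Q, t, t0 = 0,
                     conc_div = NULL, history = NULL) {
  ctx <- list(Q = as.list(Q), t = t, t0 = t0,
              conc_div = if (is.null(conc_div)) NULL else as.list(conc_div),
              history = history, bindings = NULL)
  eval_cached(node, graph, ctx)
}

eval_cached <- function(node, graph, ctx) {
  if (node$epoch == graph$epoch) return(node$val)
  kind <- node$kind
  v <- if (kind == "op") {
    op <- node$op
    args <- node$args
    na <- length(args)
    if (isTRUE(node$lazy)) {
      ## short-circuiting and piecewise ops control their own recursion
      eval_op_lazy(node, graph, ctx)
    } else if (na == 2L) {
      ## inlined fast paths for the common binary operators
      a <- eval_cached(args[[1L]], graph, ctx)
      b <- eval_cached(args[[2L]], graph, ctx)
      switch(op,
        plus = a + b, times = a * b, minus = a - b,
        divide = {
          if (b == 0) num_domain_error("division by zero", node)
          a / b
        },
        power = a^b,
        lt = a < b, leq = a <= b, gt = a > b, geq = a >= b,
        eq = a == b, neq = a != b,
        min = min(a, b), max = max(a, b),
        ast_eval_op(list(kind = "op", op = op,
                         args = list(wrap_value(a), wrap_value(b))), ctx))
    } else if (na == 1L && op == "minus") {
      -eval_cached(args[[1L]], graph, ctx)
    } else {
      vals <- lapply(args, eval_cached, graph = graph, ctx = ctx)
      fake <- list(kind = "op", op = op,
                   args = lapply(vals, wrap_value))
      ast_eval_op(fake, ctx)
    }
  } else if (kind == "symbol" || kind == "number" || kind == "bool" ||
             kind == "time") {
    ast_eval(node, ctx)
  } else {
    ast_eval(node, ctx)   # delay: uncached recursion through history
  }
  node$epoch <- graph$epoch
  node$val <- v
  if (graph$counting) {
    k <- node$key
    prev <- graph$counts[[k]]
    graph$counts[[k]] <- if (is.null(prev)) 1L else prev + 1L
  }
  v
}

wrap_value <- function(v) {
  if (is.logical(v)) list(kind = "bool", value = v)
  else list(kind = "number", value = v)
}

eval_op_lazy <- function(node, graph, ctx) {
  op <- node$op
  args <- node$args
  if (op == "piecewise") {
    n <- length(args)
    i <- 1L
    while (i + 1L <= n) {
      cond <- as_bool(eval_cached(args[[i + 1L]], graph, ctx), node)
      if (isTRUE(cond)) return(eval_cached(args[[i]], graph, ctx))
      i <- i + 2L
    }
    if (i <= n) return(eval_cached(args[[i]], graph, ctx))
    num_domain_error("piecewise with no applicable branch", node)
  }
  if (op == "and") {
    for (a in args)
      if (!isTRUE(as_bool(eval_cached(a, graph, ctx), node))) return(FALSE)
    return(TRUE)
  }
  if (op == "or") {
    for (a in args)
      if (isTRUE(as_bool(eval_cached(a, graph, ctx), node))) return(TRUE)
    return(FALSE)
  }
  v <- FALSE
  for (a in args) v <- xor(v, as_bool(eval_cached(a, graph, ctx), node))
  v
}

## ---------------------------------------------------------------------------
## User-defined functions (SBML function definitions, lambda calculus)

#' Bind a function definition at a call site
#'
#' Expands a call `f(a1, ..., an)` of a user-defined function by
#' capture-safe simultaneous substitution of the argument expressions into
#' the function body.  Nested calls to other user functions inside the body
#' are resolved recursively; recursive definitions are rejected.  Because
#' substitution is simultaneous and a body may only reference its own
#' parameters and global identifiers, two functions using the same
#' parameter name cannot capture each other's arguments.
#'
#' @param defn a function definition: list with `id`, `params`
#'   (character vector) and `body` (expression tree), as produced by the
#'   SBML reader for `functionDefinition` elements.
#' @param call_args list of expression trees, one per parameter.
#' @param fn_table named list of all function definitions (for nested
#'   calls); defaults to just `defn`.
#' @return The expanded expression tree.
#' @export
bind_function <- function(defn, call_args, fn_table = NULL) {
  if (is.null(fn_table)) fn_table <- stats::setNames(list(defn), defn$id)
  expand_calls(ast_call(defn$id, call_args), fn_table, active = character(0))
}

## Replace every user-function call by its substituted body.
expand_calls <- function(node, fn_table, active = character(0)) {
  kind <- node$kind
  if (kind == "call") {
    defn <- fn_table[[node$fn]]
    if (is.null(defn))
      stop("call to unknown function definition '", node$fn, "'",
           call. = FALSE)
    if (node$fn %in% active)
      stop("recursive function definitions are not supported ('",
           node$fn, "')", call. = FALSE)
    if (length(node$args) != length(defn$params))
      stop("function '", node$fn, "' called with ", length(node$args),
           " argument(s), expected ", length(defn$params), call. = FALSE)
    args <- lapply(node$args, expand_calls, fn_table = fn_table,
                   active = active)
    body <- expand_calls(defn$body, fn_table, active = c(active, node$fn))
    subs <- stats::setNames(args, defn$params)
    return(ast_substitute(body, subs))
  }
  if (!is.null(node$args)) {
    node$args <- lapply(node$args, expand_calls, fn_table = fn_table,
                        active = active)
    return(node)
  }
  if (kind == "lambda") {
    node$body <- expand_calls(node$body, fn_table, active)
    return(node)
  }
  node
}

## ---------------------------------------------------------------------------
## History buffer for delay expressions

#' Create a history buffer
#'
#' Records `(time, state)` pairs over the integrated interval; `delay(x,
#' tau)` expressions are evaluated against the state interpolated
#' (piecewise-linearly) at `t - tau`.  Queries before the start time
#' return the initial state (constant prehistory, the standard DDE
#' convention).
#'
#' @param t0 start time.
#' @param Q0 named numeric initial state.
#' @param capacity initial record capacity (grown as needed).
#' @return An object of class `history_buffer`.
#' @export
history_buffer <- function(t0, Q0, capacity = 256L) {
  h <- new.env(parent = emptyenv())
  h$t0 <- t0
  h$ids <- names(Q0)
  h$times <- numeric(capacity)
  h$states <- matrix(NA_real_, nrow = capacity, ncol = length(Q0))
  h$n <- 0L
  class(h) <- "history_buffer"
  history_append(h, t0, Q0)
  h
}

#' Append a record to a history buffer
#'
#' Times must be non-decreasing; a record at an already-stored latest time
#' replaces it (state after event processing supersedes the pre-event
#' state at the same instant).
#'
#' @param h a [history_buffer()].
#' @param t time of the record.
#' @param Q named numeric state.
#' @return `h`, invisibly.
#' @export
history_append <- function(h, t, Q) {
  if (h$n > 0L) {
    tl <- h$times[h$n]
    if (t < tl) stop("history times must be non-decreasing", call. = FALSE)
    if (t == tl) { h$states[h$n, ] <- as.numeric(Q[h$ids]); return(invisible(h)) }
  }
  if (h$n == length(h$times)) {
    h$times <- c(h$times, numeric(length(h$times)))
    h$states <- rbind(h$states,
                      matrix(NA_real_, nrow = nrow(h$states),
                             ncol = ncol(h$states)))
  }
  h$n <- h$n + 1L
  h$times[h$n] <- t
  h$states[h$n, ] <- as.numeric(Q[h$ids])
  invisible(h)
}

#' Interpolated historical state
#'
#' @param h a [history_buffer()].
#' @param t query time; clamped to `[t0, t_latest]`.
#' @return List with elements `t` (clamped time) and `Q` (named state).
#' @export
history_state <- function(h, t) {
  n <- h$n
  if (t <= h$times[1L]) {
    return(list(t = h$times[1L],
                Q = stats::setNames(h$states[1L, ], h$ids)))
  }
  if (t >= h$times[n]) {
    return(list(t = min(t, h$times[n]),
                Q = stats::setNames(h$states[n, ], h$ids)))
  }
  i <- findInterval(t, h$times[seq_len(n)])
  t1 <- h$times[i]; t2 <- h$times[i + 1L]
  w <- if (t2 > t1) (t - t1) / (t2 - t1) else 0
  Q <- (1 - w) * h$states[i, ] + w * h$states[i + 1L, ]
  list(t = t, Q = stats::setNames(Q, h$ids))
}
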