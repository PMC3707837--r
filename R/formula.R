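## Infix formula parser for SBML Level 1 kinetic laws and rules
## (Level 1 predates MathML and stores mathematics as formula strings).

#' Parse an SBML Level 1 formula string
#'
#' Recursive-descent parser for the Level 1 infix dialect: numbers,
#' identifiers, `+ - * / ^`, parentheses, and function calls.  The Level 1
#' builtins `abs, ceil, floor, exp, log, log10, pow, sqrt` and the
#' trigonometric family map onto the MathML operator set; any other call
#' target is treated as a (Level 2+) user-function reference.
#'
#' @param text formula string.
#' @return An expression tree ([ast]).
#' @export
parse_formula <- function(text) {
  toks <- formula_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  expr <- f_expr(st)
  if (st$i <= length(st$toks))
    stop("trailing input in formula: '", st$toks[[st$i]]$text, "'",
         call. = FALSE)
  expr
}

formula_tokens <- function(text) {
  toks <- list()
  i <- 1L
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (grepl("^[0-9.]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                              substr(text, i, n)))
      toks[[length(toks) + 1L]] <- list(type = "num", text = m,
                                        value = as.numeric(m))
      i <- i + nchar(m)
      next
    }
    if (grepl("^[A-Za-z_]$", ch)) {
      m <- regmatches(substr(text, i, n),
                      regexpr("^[A-Za-z_][A-Za-z0-9_]*",
                              substr(text, i, n)))
      toks[[length(toks) + 1L]] <- list(type = "id", text = m)
      i <- i + nchar(m)
      next
    }
    if (ch %in% c("+", "-", "*", "/", "^", "(", ")", ",")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch)
      i <- i + 1L
      next
    }
    stop("unexpected character in formula: '", ch, "'", call. = FALSE)
  }
  toks
}

f_peek <- function(st) if (st$i <= length(st$toks)) st$toks[[st$i]] else NULL
f_take <- function(st) { t <- f_peek(st); st$i <- st$i + 1L; t }
f_expect <- function(st, type) {
  t <- f_take(st)
  if (is.null(t) || t$type != type)
    stop("expected '", type, "' in formula", call. = FALSE)
  t
}

f_expr <- function(st) {
  left <- f_term(st)
  repeat {
    t <- f_peek(st)
    if (is.null(t) || !(t$type %in% c("+", "-"))) return(left)
    f_take(st)
    right <- f_term(st)
    left <- if (t$type == "+") ast_op("plus", list(left, right))
            else ast_op("minus", list(left, right))
  }
}

f_term <- function(st) {
  left <- f_unary(st)
  repeat {
    t <- f_peek(st)
    if (is.null(t) || !(t$type %in% c("*", "/"))) return(left)
    f_take(st)
    right <- f_unary(st)
    left <- if (t$type == "*") ast_op("times", list(left, right))
            else ast_op("divide", list(left, right))
  }
}

f_unary <- function(st) {
  t <- f_peek(st)
  if (!is.null(t) && t$type == "-") {
    f_take(st)
    return(ast_op("minus", list(f_unary(st))))
  }
  if (!is.null(t) && t$type == "+") f_take(st)
  f_power(st)
}

f_power <- function(st) {
  base <- f_atom(st)
  t <- f_peek(st)
  if (!is.null(t) && t$type == "^") {
    f_take(st)
    return(ast_op("power", list(base, f_unary(st))))  # right associative
  }
  base
}

.l1_fun_map <- c(abs = "abs", ceil = "ceiling", floor = "floor",
                 exp = "exp", ln = "ln", log = "ln", log10 = "log",
                 sin = "sin", cos = "cos", tan = "tan",
                 asin = "arcsin", acos = "arccos", atan = "arctan",
                 sinh = "sinh", cosh = "cosh", tanh = "tanh")

f_atom <- function(st) {
  t <- f_take(st)
  if (is.null(t)) stop("unexpected end of formula", call. = FALSE)
  if (t$type == "num") return(ast_number(t$value))
  if (t$type == "(") {
    e <- f_expr(st)
    f_expect(st, ")")
    return(e)
  }
  if (t$type == "id") {
    nxt <- f_peek(st)
    if (!is.null(nxt) && nxt$type == "(") {
      f_take(st)
      args <- list()
      if (!identical(f_peek(st)$type, ")")) {
        repeat {
          args[[length(args) + 1L]] <- f_expr(st)
          if (identical(f_peek(st)$type, ",")) { f_take(st); next }
          break
        }
      }
      f_expect(st, ")")
      fn <- t$text
      if (fn == "pow" || fn == "power") return(ast_op("power", args))
      if (fn == "sqrt") return(ast_op("root", args))
      if (fn == "root") return(ast_op("root", args))
      if (fn == "piecewise") return(ast_op("piecewise", args))
      if (!is.na(.l1_fun_map[fn]))
        return(ast_op(.l1_fun_map[[fn]], args))
      return(ast_call(fn, args))
    }
    return(ast_symbol(t$text))
  }
  stop("unexpected token in formula: '", t$text, "'", call. = FALSE)
}
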