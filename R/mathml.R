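## Content-MathML (the subset embedded in SBML) to expression trees, and
## back (the writer is used by the fixture generator).

.csymbol_time  <- "http://www.sbml.org/sbml/symbols/time"
.csymbol_delay <- "http://www.sbml.org/sbml/symbols/delay"
.csymbol_avogadro <- "http://www.sbml.org/sbml/symbols/avogadro"

#' Parse a MathML fragment into an expression tree
#'
#' Accepts the content-markup MathML subset used by SBML: `cn` (integer,
#' real, e-notation, rational), `ci`, `csymbol` (time, delay, avogadro),
#' arithmetic/relational/logical operators, `piecewise`, `lambda`, and
#' the elementary function set.  Unknown elements raise an error naming
#' the element.
#'
#' @param x MathML as a character string, an `xml2` document, or an
#'   `xml2` node (either the `math` element or its parent).
#' @return An expression tree ([ast]).
#' @export
parse_mathml <- function(x) {
  node <- if (inherits(x, "xml_node") || inherits(x, "xml_document")) {
    x
  } else {
    xml2::read_xml(paste(as.character(x), collapse = "\n"))
  }
  if (inherits(node, "xml_document")) node <- xml2::xml_root(node)
  nm <- xml2::xml_name(node)
  if (nm != "math") {
    hit <- xml2::xml_find_first(node, ".//*[local-name()='math']")
    if (inherits(hit, "xml_missing"))
      stop("no <math> element found", call. = FALSE)
    node <- hit
  }
  kids <- xml2::xml_children(node)
  if (length(kids) != 1L)
    stop("<math> must contain exactly one expression", call. = FALSE)
  mathml_to_ast(kids[[1L]])
}

mathml_to_ast <- function(el) {
  nm <- xml2::xml_name(el)
  switch(nm,
    cn = mathml_cn(el),
    ci = ast_symbol(trimws(xml2::xml_text(el))),
    csymbol = {
      url <- xml2::xml_attr(el, "definitionURL")
      if (grepl("symbols/time", url %||% "")) ast_time()
      else if (grepl("symbols/avogadro", url %||% ""))
        ast_number(6.02214179e23)
      else stop("unsupported csymbol '", url,
                "' outside an apply", call. = FALSE)
    },
    "true" = ast_bool(TRUE),
    "false" = ast_bool(FALSE),
    pi = ast_number(pi),
    exponentiale = ast_number(exp(1)),
    infinity = ast_number(Inf),
    notanumber = ast_number(NaN),
    apply = mathml_apply(el),
    piecewise = mathml_piecewise(el),
    lambda = mathml_lambda(el),
    semantics = {
      kids <- xml2::xml_children(el)
      mathml_to_ast(kids[[1L]])
    },
    stop("unsupported MathML element: <", nm, ">", call. = FALSE))
}

mathml_cn <- function(el) {
  type <- xml2::xml_attr(el, "type")
  txt <- xml2::xml_text(el)
  if (is.na(type) || type %in% c("real", "integer", "double"))
    return(ast_number(as.numeric(trimws(txt))))
  parts <- trimws(strsplit(txt, "\n")[[1]])
  ## e-notation and rational use a <sep/> element; xml_text drops it, so
  ## recover the two operands from the text nodes around it
  tn <- xml2::xml_find_all(el, "text()")
  vals <- as.numeric(trimws(vapply(tn, xml2::xml_text, character(1))))
  vals <- vals[!is.na(vals)]
  if (type == "e-notation") {
    if (length(vals) != 2L) stop("malformed e-notation <cn>", call. = FALSE)
    return(ast_number(vals[1L] * 10^vals[2L]))
  }
  if (type == "rational") {
    if (length(vals) != 2L) stop("malformed rational <cn>", call. = FALSE)
    return(ast_number(vals[1L] / vals[2L]))
  }
  stop("unsupported <cn> type: ", type, call. = FALSE)
}

mathml_apply <- function(el) {
  kids <- xml2::xml_children(el)
  if (length(kids) == 0L) stop("empty <apply>", call. = FALSE)
  head <- kids[[1L]]
  hname <- xml2::xml_name(head)
  rest <- kids[-1L]

  if (hname == "csymbol") {
    url <- xml2::xml_attr(head, "definitionURL") %||% ""
    if (grepl("symbols/delay", url)) {
      if (length(rest) != 2L)
        stop("delay() requires exactly two arguments", call. = FALSE)
      return(ast_delay(mathml_to_ast(rest[[1L]]), mathml_to_ast(rest[[2L]])))
    }
    stop("unsupported csymbol in apply: '", url, "'", call. = FALSE)
  }
  if (hname == "ci") {
    fn <- trimws(xml2::xml_text(head))
    return(ast_call(fn, lapply(rest, mathml_to_ast)))
  }

  if (hname == "root") {
    degree <- NULL
    args <- list()
    for (k in rest) {
      if (xml2::xml_name(k) == "degree")
        degree <- mathml_to_ast(xml2::xml_children(k)[[1L]])
      else args[[length(args) + 1L]] <- mathml_to_ast(k)
    }
    if (is.null(degree)) return(ast_op("root", args))
    return(ast_op("root", c(list(degree), args)))
  }
  if (hname == "log") {
    logbase <- NULL
    args <- list()
    for (k in rest) {
      if (xml2::xml_name(k) == "logbase")
        logbase <- mathml_to_ast(xml2::xml_children(k)[[1L]])
      else args[[length(args) + 1L]] <- mathml_to_ast(k)
    }
    if (is.null(logbase)) return(ast_op("log", args))
    return(ast_op("log", c(list(logbase), args)))
  }

  op <- switch(hname,
    ceiling = "ceiling",
    hname)
  if (!(op %in% .ast_op_names))
    stop("unsupported MathML operator: <", hname, ">", call. = FALSE)
  ast_op(op, lapply(rest, mathml_to_ast))
}

mathml_piecewise <- function(el) {
  args <- list()
  otherwise <- NULL
  for (k in xml2::xml_children(el)) {
    nm <- xml2::xml_name(k)
    kk <- xml2::xml_children(k)
    if (nm == "piece") {
      if (length(kk) != 2L) stop("malformed <piece>", call. = FALSE)
      args <- c(args, list(mathml_to_ast(kk[[1L]]), mathml_to_ast(kk[[2L]])))
    } else if (nm == "otherwise") {
      otherwise <- mathml_to_ast(kk[[1L]])
    } else stop("unsupported element in <piecewise>: <", nm, ">",
                call. = FALSE)
  }
  if (!is.null(otherwise)) args <- c(args, list(otherwise))
  ast_op("piecewise", args)
}

mathml_lambda <- function(el) {
  params <- character(0)
  body <- NULL
  for (k in xml2::xml_children(el)) {
    if (xml2::xml_name(k) == "bvar") {
      ci <- xml2::xml_children(k)[[1L]]
      params <- c(params, trimws(xml2::xml_text(ci)))
    } else {
      body <- mathml_to_ast(k)
    }
  }
  if (is.null(body)) stop("lambda without a body", call. = FALSE)
  ast_lambda(params, body)
}

`%||%` <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.atomic(a) && length(a) == 1L && is.na(a)) return(b)
  a
}

## ---------------------------------------------------------------------------
## Writer (content MathML; used to serialize fixture models)

#' Serialize an expression tree to content MathML
#'
#' @param tree expression tree.
#' @param wrap if `TRUE` (default) the result is wrapped in a `<math>`
#'   element with the MathML namespace.
#' @return Character scalar of XML.
#' @export
write_mathml <- function(tree, wrap = TRUE) {
  body <- ast_to_mathml(tree)
  if (!wrap) return(body)
  paste0("<math xmlns=\"http://www.w3.org/1998/Math/MathML\">",
         body, "</math>")
}

ast_to_mathml <- function(node) {
  kind <- node$kind
  switch(kind,
    number = {
      v <- node$value
      if (is.finite(v) && v == round(v) && abs(v) < 1e15)
        sprintf("<cn type=\"integer\">%d</cn>", as.integer(v))
      else sprintf("<cn>%.17g</cn>", v)
    },
    bool = if (node$value) "<true/>" else "<false/>",
    symbol = paste0("<ci>", node$id, "</ci>"),
    time = paste0("<csymbol encoding=\"text\" definitionURL=\"",
                  .csymbol_time, "\">t</csymbol>"),
    delay = paste0("<apply><csymbol encoding=\"text\" definitionURL=\"",
                   .csymbol_delay, "\">delay</csymbol>",
                   ast_to_mathml(node$args[[1L]]),
                   ast_to_mathml(node$args[[2L]]), "</apply>"),
    call = paste0("<apply><ci>", node$fn, "</ci>",
                  paste(vapply(node$args, ast_to_mathml, character(1)),
                        collapse = ""), "</apply>"),
    lambda = paste0("<lambda>",
                    paste0("<bvar><ci>", node$params, "</ci></bvar>",
                           collapse = ""),
                    ast_to_mathml(node$body), "</lambda>"),
    op = {
      op <- node$op
      if (op == "piecewise") {
        n <- length(node$args)
        npairs <- n %/% 2L
        out <- "<piecewise>"
        for (i in seq_len(npairs)) {
          out <- paste0(out, "<piece>",
                        ast_to_mathml(node$args[[2L * i - 1L]]),
                        ast_to_mathml(node$args[[2L * i]]), "</piece>")
        }
        if (n %% 2L == 1L)
          out <- paste0(out, "<otherwise>", ast_to_mathml(node$args[[n]]),
                        "</otherwise>")
        paste0(out, "</piecewise>")
      } else {
        paste0("<apply><", op, "/>",
               paste(vapply(node$args, ast_to_mathml, character(1)),
                     collapse = ""), "</apply>")
      }
    },
    stop("cannot serialize node kind: ", kind))
}
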